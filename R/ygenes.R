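#' Find candidate gene loci from protein-versus-genome hits
#'
#' Clusters the hits of each query protein per chromosome (hits within
#' `2 * pad` of each other belong to one locus), computes the hit
#' coverage of the query as the union of aligned query intervals over the
#' query length, and retains loci covering strictly more than
#' `min_query_cov`. Retained loci are padded by `pad` on both sides and
#' clipped to the chromosome. Genes with no retained locus are absent.
#'
#' @param protein_hits data.frame with `gene`, `query_len` (aa),
#'   `query_start`, `query_end` (aa, 0-based half-open), `chrom`,
#'   `target_start`, `target_end` (bp, 0-based half-open), `strand`.
#' @param chrom_lens named integer vector of chromosome lengths for
#'   clipping.
#' @param pad locus extension, bp (default 10 kb).
#' @param min_query_cov strict lower bound on query coverage (default
#'   0.5).
#' @return data.frame of loci: `gene`, `chrom`, `start`, `end`, `strand`,
#'   `query_len`, `coverage`.
#' @export
find_loci <- function(protein_hits, chrom_lens, pad = 10000L,
                      min_query_cov = 0.5) {
  out <- list()
  if (nrow(protein_hits)) {
    key <- paste(protein_hits$gene, protein_hits$chrom, sep = "\r")
    for (k in unique(key)) {
      h <- protein_hits[key == k, , drop = FALSE]
      h <- h[order(h$target_start), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(
        h$target_start[-1L] - cummax(h$target_end)[-nrow(h)] > 2L * pad)))
      for (g in unique(grp)) {
        hh <- h[grp == g, , drop = FALSE]
        cov <- union_bp(hh$query_start, hh$query_end) / hh$query_len[1L]
        if (cov <= min_query_cov) next
        len <- chrom_lens[[hh$chrom[1L]]]
        out[[length(out) + 1L]] <- data.frame(
          gene = hh$gene[1L], chrom = hh$chrom[1L],
          start = max(0L, min(hh$target_start) - pad),
          end = min(len, max(hh$target_end) + pad),
          strand = hh$strand[1L], query_len = hh$query_len[1L],
          coverage = cov, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      query_len = integer(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$gene, df$chrom, df$start), , drop = FALSE]
}

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character(0L))
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Find open reading frames in all six frames
#'
#' An ORF runs from an ATG to the nearest in-frame stop with no internal
#' stop; codons containing N break any ORF spanning them. Reverse-strand
#' ORFs are reported with coordinates on the forward strand.
#'
#' @param dna DNA string over `{A, C, G, T, N}`.
#' @param min_len_aa minimum ORF length in amino acids, start codon
#'   included, stop excluded (default 50; use 1 to report all).
#' @return data.frame: `start`, `end` (0-based half-open, forward-strand,
#'   stop codon included), `strand`, `frame` (0-2), `aa_len`.
#' @export
find_orfs <- function(dna, min_len_aa = 50L) {
  dna <- toupper(dna)
  n <- nchar(dna)
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand) {
    rows <- list()
    for (f in 0:2) {
      cod <- codon_split(substring(s, f + 1L))
      if (!length(cod)) next
      has_n <- grepl("N", cod, fixed = TRUE)
      is_stop <- cod %in% stops & !has_n
      is_atg <- cod == "ATG"
      i <- 1L
      nc <- length(cod)
      for (a in which(is_atg)) {
        # nearest in-frame stop, unbroken by N codons
        j <- a
        ok <- TRUE
        repeat {
          j <- j + 1L
          if (j > nc) { ok <- FALSE; break }
          if (has_n[j]) { ok <- FALSE; break }
          if (is_stop[j]) break
        }
        if (!ok) next
        aa <- j - a
        if (aa < min_len_aa) next
        s0 <- f + 3L * (a - 1L)        # 0-based start of ATG in this strand
        e0 <- f + 3L * j               # end of stop codon
        if (strand == "+") {
          rows[[length(rows) + 1L]] <- data.frame(
            start = s0, end = e0, strand = "+", frame = f, aa_len = aa,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            start = n - e0, end = n - s0, strand = "-", frame = f,
            aa_len = aa, stringsAsFactors = FALSE)
        }
      }
    }
    rows
  }
  rows <- c(scan_strand(dna, "+"), scan_strand(revcomp(dna), "-"))
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), aa_len = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify a gene locus as intact or pseudogene
#'
#' Measures the longest open reading frame within the locus and compares
#' it to the reference protein: a locus whose longest ORF covers at least
#' `min_orf_cov` of the query length is intact, anything else is a
#' pseudogene (frameshifts truncate the longest ORF well below the
#' threshold).
#'
#' @param locus one row of [find_loci()] output.
#' @param genome named character vector containing `locus$chrom`.
#' @param min_orf_cov intact threshold on ORF coverage (default 0.8).
#' @return data.frame (`gene_call`): locus columns plus `status`
#'   (`"intact"`/`"pseudo"`), `orf_aa`, `orf_coverage`.
#' @export
classify_gene <- function(locus, genome, min_orf_cov = 0.8) {
  seq <- substring(genome[[locus$chrom]], locus$start + 1L, locus$end)
  orfs <- find_orfs(seq, min_len_aa = 1L)
  orf_aa <- if (nrow(orfs)) max(orfs$aa_len) else 0L
  cov <- orf_aa / locus$query_len
  cbind(locus,
        data.frame(status = if (cov >= min_orf_cov) "intact" else "pseudo",
                   orf_aa = orf_aa, orf_coverage = cov,
                   stringsAsFactors = FALSE))
}

#' Classify every locus in a table
#'
#' @param loci [find_loci()] output.
#' @param genome named character vector.
#' @param min_orf_cov see [classify_gene()].
#' @return data.frame of gene calls.
#' @export
classify_genes <- function(loci, genome, min_orf_cov = 0.8) {
  if (!nrow(loci)) {
    return(cbind(loci, data.frame(status = character(), orf_aa = integer(),
                                  orf_coverage = numeric(),
                                  stringsAsFactors = FALSE)))
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    classify_gene(loci[i, , drop = FALSE], genome, min_orf_cov)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Gene-by-region copy-number table
#'
#' Counts intact and pseudogene copies of each gene per (non-overlapping)
#' region, assigning each call by locus midpoint; calls outside all
#' regions fall under `"unassigned"`.
#'
#' @param calls [classify_genes()] output.
#' @param regions data.frame `chrom`, `start`, `end`, `name`.
#' @return data.frame: `gene`, `region`, `intact`, `pseudo`.
#' @export
copy_table <- function(calls, regions) {
  check_disjoint_regions(regions)
  region_names <- c(regions$name, "unassigned")
  genes <- sort(unique(calls$gene))
  grid <- expand.grid(gene = genes, region = region_names,
                      stringsAsFactors = FALSE)
  grid$intact <- rep(0L, nrow(grid))
  grid$pseudo <- rep(0L, nrow(grid))
  if (nrow(calls)) {
    mid <- (calls$start + calls$end) %/% 2L
    for (i in seq_len(nrow(calls))) {
      inside <- regions$chrom == calls$chrom[i] &
        regions$start <= mid[i] & mid[i] < regions$end
      rn <- if (any(inside)) regions$name[which(inside)[1L]] else "unassigned"
      row <- grid$gene == calls$gene[i] & grid$region == rn
      col <- if (calls$status[i] == "intact") "intact" else "pseudo"
      grid[row, col] <- grid[row, col] + 1L
    }
  }
  grid[order(grid$gene, grid$region), , drop = FALSE]
}
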