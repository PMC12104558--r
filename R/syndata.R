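#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genome generator. Defaults encode
#' the study conditions the pipeline is designed around: a 24-unit
#' ancestral haploid karyotype (23 autosomes + X) with lineage fusion
#' plans of 11, 1 and 2 fusions; a focal X locus of four ancestral blocks
#' `SB1+ SB2+ SB3+ SB4+` receiving a Y-derived run `SB6- SB5-` between SB1
#' and SB2 followed by two inversions per lineage; 6 kb boundary
#' segmental-duplication (BASD) copies at 98% identity; a tandem repeat
#' region of 52 unit copies; and a heterozygous-SNP track stepping from
#' 0.1/kb (recombining PAR) to 5/kb (differentiated stratum) at the
#' boundary, around read-depth mode 42.
#'
#' @param seed integer PRNG seed; every generator draws from one stream
#'   seeded deterministically from it.
#' @param ancestral_n_chrom ancestral haploid chromosome count.
#' @param fusion_plan named list (one per species) of character pairs of
#'   chromosomes to fuse, applied in order.
#' @param block_layout pre-insertion arrangement of the focal locus.
#' @param insertion_spec list `blocks` (inserted [arrangement()]) and
#'   `gap` (0-based gap in `block_layout` after which they insert).
#' @param inversions_per_lineage random inversions applied to each lineage
#'   after the shared insertion.
#' @param lineages names of the derived lineages.
#' @param block_len realized length of each synteny block, bp.
#' @param basd_spec list: `length` (bp), `identity` (substitution-only
#'   divergence from the master), `n_copies` (planted at distinct block
#'   boundaries), `flanks` (plant alpha/gamma provenance flanks at the
#'   insertion boundaries).
#' @param repeat_spec list: `unit_len` (bp), `n_copies`, `mutation_rate`,
#'   `copy_fraction` (fraction of the unit each planted copy covers; 1 =
#'   full copies).
#' @param palindrome_spec list: `arm_len`, `spacer`, `identity`.
#' @param gene_spec list: `query_len_aa` (reference protein length) and
#'   `copies`, a data.frame with `gene` and `state` (`"intact"` /
#'   `"pseudo"`) of copies planted inside the Y-derived SB5 block.
#' @param snp_spec list: `chrom`, `chrom_len`, `boundary` (bp),
#'   `par_rate` / `stratum_rate` (SNVs per kb), `depth_mode`,
#'   `bad_fraction` (fraction of records violating the heterozygosity
#'   filters, to exercise filtering).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       ancestral_n_chrom = 24L,
                       fusion_plan = default_fusion_plan(),
                       block_layout = parse_arrangement("SB1+ SB2+ SB3+ SB4+"),
                       insertion_spec = list(
                         blocks = parse_arrangement("SB6- SB5-"), gap = 1L),
                       inversions_per_lineage = 2L,
                       lineages = c("osi", "tok"),
                       block_len = 20000L,
                       basd_spec = list(length = 6000L, identity = 0.98,
                                        n_copies = 2L, flanks = TRUE),
                       repeat_spec = list(unit_len = 5000L, n_copies = 52L,
                                          mutation_rate = 0.02,
                                          copy_fraction = 1.0),
                       palindrome_spec = list(arm_len = 30000L, spacer = 5000L,
                                              identity = 0.99),
                       gene_spec = list(
                         query_len_aa = 300L,
                         copies = data.frame(
                           gene = c("Ddx3y", "Uty", "Eif2s3y", "Usp9y"),
                           state = c("intact", "intact", "intact", "pseudo"),
                           stringsAsFactors = FALSE)),
                       snp_spec = list(chrom = "neoX", chrom_len = 10e6,
                                       boundary = 5e6, par_rate = 0.1,
                                       stratum_rate = 5.0, depth_mode = 42L,
                                       bad_fraction = 0.1)) {
  if (basd_spec$identity <= 0.9 || basd_spec$identity > 1) {
    stop("basd identity must lie in (0.9, 1]")
  }
  if (snp_spec$par_rate < 0 || snp_spec$stratum_rate < 0) {
    stop("SNP densities must be >= 0")
  }
  if (snp_spec$boundary <= 0 || snp_spec$boundary >= snp_spec$chrom_len) {
    stop("SNP boundary must lie inside the chromosome")
  }
  if (block_len < 1000L) stop("block_len must be >= 1 kb")
  structure(list(seed = as.integer(seed),
                 ancestral_n_chrom = as.integer(ancestral_n_chrom),
                 fusion_plan = fusion_plan, block_layout = block_layout,
                 insertion_spec = insertion_spec,
                 inversions_per_lineage = as.integer(inversions_per_lineage),
                 lineages = lineages, block_len = as.integer(block_len),
                 basd_spec = basd_spec, repeat_spec = repeat_spec,
                 palindrome_spec = palindrome_spec, gene_spec = gene_spec,
                 snp_spec = snp_spec),
            class = "sim_config")
}

#' Default lineage fusion plans
#'
#' Three lineages with 11, 1 and 2 fusions respectively; the two-fusion
#' lineage includes an autosome-to-sex-chromosome fusion, mirroring the
#' karyotype history the generator emulates.
#'
#' @return Named list of fusion pair lists.
#' @export
default_fusion_plan <- function() {
  anc <- ancestral_chrom_names(24L)
  list(
    osi = lapply(seq(1L, 21L, by = 2L), function(i) anc[c(i, i + 1L)]),
    tok = list(anc[c(1L, 2L)]),
    mue = list(anc[c(1L, 2L)], c(anc[5L], "X")))
}

ancestral_chrom_names <- function(n) c(LETTERS[seq_len(n - 1L)], "X")

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-replica substitution rate that yields the requested expected
# pairwise identity between two independently mutated replicas of one
# master: P(mismatch) = 2r(1-r) + (2/3)r^2 = 1 - pair_identity
copy_sub_rate <- function(pair_identity) {
  q <- 1 - pair_identity
  if (q <= 0) return(0)
  (1 - sqrt(1 - (4 / 3) * q)) / (4 / 3)
}

# substitution-only mutation at the given per-base rate
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(s)
  pos <- sample.int(n, k)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  paste(v, collapse = "")
}

#' Simulate fused karyotypes from a common ancestor
#'
#' Applies each lineage's fusion plan to the ancestral chromosome set.
#' A fusion concatenates two chromosomes (the joined ends are oriented at
#' random) and reduces the haploid count by exactly one; referencing an
#' already-consumed chromosome is a configuration error.
#'
#' @param config a [sim_config()].
#' @return A list with `ancestor` (chromosome names), `species` (per
#'   lineage, a list of chromosomes, each a data.frame of `unit`/`strand`
#'   segments) and `truth` (fusion events per species).
#' @export
simulate_karyotypes <- function(config) {
  set.seed(config$seed)
  anc <- ancestral_chrom_names(config$ancestral_n_chrom)
  species <- list()
  truth <- list()
  for (sp in names(config$fusion_plan)) {
    chroms <- lapply(anc, function(u) data.frame(unit = u, strand = "+",
                                                 stringsAsFactors = FALSE))
    names(chroms) <- anc
    for (pair in config$fusion_plan[[sp]]) {
      if (!all(pair %in% names(chroms))) {
        stop("fusion in ", sp, " references a consumed or unknown chromosome: ",
             paste(setdiff(pair, names(chroms)), collapse = ", "))
      }
      a <- chroms[[pair[1L]]]; b <- chroms[[pair[2L]]]
      if (stats::runif(1L) < 0.5) {  # random end orientation of the joined part
        b <- b[rev(seq_len(nrow(b))), , drop = FALSE]
        b$strand <- ifelse(b$strand == "+", "-", "+")
      }
      fused <- rbind(a, b)
      chroms[[pair[1L]]] <- NULL; chroms[[pair[2L]]] <- NULL
      chroms[[paste(pair, collapse = "-")]] <- fused
      truth[[length(truth) + 1L]] <- data.frame(
        species = sp, unit_a = pair[1L], unit_b = pair[2L],
        stringsAsFactors = FALSE)
    }
    species[[sp]] <- chroms
  }
  fus <- if (length(truth)) do.call(rbind, truth) else
    data.frame(species = character(), unit_a = character(),
               unit_b = character(), stringsAsFactors = FALSE)
  list(ancestor = anc, species = species,
       truth = list(fusions = fus,
                    fusion_counts = vapply(config$fusion_plan, length,
                                           integer(1L))))
}

#' Emit truth-derived windowed alignments for a karyotype simulation
#'
#' Realizes each ancestral unit at a fixed length and writes the window
#' alignments a whole-chromosome aligner would produce for each species
#' against the ancestor, directly from the simulated truth (no aligner is
#' run). Windows are named per the [window_genome()] contract.
#'
#' @param karyo result of [simulate_karyotypes()].
#' @param unit_len realized length of each ancestral unit, bp.
#' @param window_bp window size used for the synthetic alignment.
#' @return Named list (per species) of `alignment_hits`.
#' @export
simulate_karyotype_alignments <- function(karyo, unit_len = 1500000L,
                                          window_bp = 500000L) {
  out <- list()
  for (sp in names(karyo$species)) {
    rows <- list()
    for (ch in names(karyo$species[[sp]])) {
      segs <- karyo$species[[sp]][[ch]]
      seg_start <- (seq_len(nrow(segs)) - 1L) * unit_len
      chrom_len <- nrow(segs) * unit_len
      win_start <- seq(0L, chrom_len - 1L, by = window_bp)
      for (w in win_start) {
        w_end <- min(w + window_bp, chrom_len)
        for (i in seq_len(nrow(segs))) {
          lo <- max(w, seg_start[i]); hi <- min(w_end, seg_start[i] + unit_len)
          if (hi <= lo) next
          rows[[length(rows) + 1L]] <- data.frame(
            query_name = paste0(ch, ":", w),
            query_start = lo - w, query_end = hi - w,
            target_name = segs$unit[i],
            target_start = lo - seg_start[i], target_end = hi - seg_start[i],
            strand = segs$strand[i], matches = hi - lo, block_len = hi - lo,
            identity = 1.0, is_primary = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    class(df) <- c("alignment_hits", "data.frame")
    out[[sp]] <- df
  }
  out
}

#' Simulate the rearrangement history of the focal locus
#'
#' The shared ancestor of the derived lineages is the base layout with the
#' Y-derived insertion applied; each lineage then receives
#' `inversions_per_lineage` random signed inversions. Applied inversions
#' are recorded, so tests can verify that the computed inversion distance
#' never exceeds the number applied.
#'
#' @param config a [sim_config()].
#' @return List with `base`, `ancestor`, `species` (named list of derived
#'   arrangements) and `truth` (`insertion_gap`, `insertion_locus`,
#'   `inserted`, and per-lineage inversion tables).
#' @export
simulate_locus_history <- function(config) {
  set.seed(config$seed + 1L)
  base <- config$block_layout
  ins <- config$insertion_spec
  if (any(ins$blocks$ids %in% base$ids)) {
    stop("inserted blocks must be disjoint from the base layout")
  }
  ancestor <- insert_blocks(base, ins$blocks, after = ins$gap)
  n <- length(ancestor$ids)
  species <- list()
  invs <- list()
  for (sp in config$lineages) {
    arr <- ancestor
    tab <- data.frame(from = integer(), to = integer())
    for (k in seq_len(config$inversions_per_lineage)) {
      ij <- sort(sample.int(n, 2L, replace = TRUE))
      arr <- apply_inversion(arr, ij[1L], ij[2L])
      tab <- rbind(tab, data.frame(from = ij[1L], to = ij[2L]))
    }
    species[[sp]] <- arr
    invs[[sp]] <- tab
  }
  locus <- paste0(base$ids[ins$gap], "-", base$ids[ins$gap + 1L])
  list(base = base, ancestor = ancestor, species = species,
       truth = list(insertion_gap = ins$gap, insertion_locus = locus,
                    inserted = ins$blocks, inversions = invs))
}

# master sequences shared by all planted features of one run
make_masters <- function(config) {
  bs <- config$basd_spec
  gs <- config$gene_spec
  blocks <- unique(c(config$block_layout$ids, config$insertion_spec$blocks$ids))
  block_seq <- stats::setNames(
    vapply(blocks, function(b) random_bases(config$block_len), character(1L)),
    blocks)
  # gene CDS masters: ATG + non-stop codons + TAA
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA", "ATG"))
  genes <- unique(gs$copies$gene)
  gene_cds <- stats::setNames(vapply(genes, function(g) {
    paste0("ATG", paste(sample(codons, gs$query_len_aa - 1L, replace = TRUE),
                        collapse = ""), "TAA")
  }, character(1L)), genes)
  flanks <- c(`1a` = random_bases(1800L), `1g` = random_bases(10800L),
              `2a` = random_bases(1800L), `2g` = random_bases(10800L))
  list(blocks = block_seq,
       basd = random_bases(bs$length),
       flanks = flanks,
       repeat_unit = random_bases(config$repeat_spec$unit_len),
       gene_cds = gene_cds)
}

# plant gene copies into the SB5 block master; returns new block sequence
# plus a table of gene offsets within the block
plant_genes <- function(block_seq, masters, gene_spec) {
  copies <- gene_spec$copies
  if (is.null(copies) || nrow(copies) == 0L) {
    return(list(seq = block_seq, table = data.frame()))
  }
  cds_len <- nchar(masters$gene_cds[[1L]])
  spacing <- 500L
  need <- nrow(copies) * (cds_len + spacing)
  if (need > nchar(block_seq)) {
    stop("SB5 block too short for the requested gene copies")
  }
  tab <- list()
  offset <- 1L
  for (i in seq_len(nrow(copies))) {
    cds <- masters$gene_cds[[copies$gene[i]]]
    if (copies$state[i] == "pseudo") {
      # 1 bp deletion mid-CDS: frameshift
      mid <- nchar(cds) %/% 2L
      cds <- paste0(substring(cds, 1L, mid - 1L), substring(cds, mid + 1L))
    }
    block_seq <- paste0(substring(block_seq, 1L, offset - 1L), cds,
                        substring(block_seq, offset + nchar(cds)))
    tab[[i]] <- data.frame(gene = copies$gene[i], state = copies$state[i],
                           offset = offset - 1L, len = nchar(cds),
                           stringsAsFactors = FALSE)
    offset <- offset + cds_len + spacing
  }
  list(seq = block_seq, table = do.call(rbind, tab))
}

#' Realize the simulated locus as DNA with planted features
#'
#' Turns the block-level truth into sequence: each block becomes random
#' DNA (shared master per block id across lineages), BASD copies are
#' planted as substitution-mutated replicas of one master at block
#' boundaries, alpha/gamma provenance flanks are planted at the insertion
#' boundaries (gamma downstream of the left boundary copy, alpha upstream
#' of the right one — the split configuration produced by integration of
#' a circular intermediate), gene copies are embedded in the Y-derived
#' SB5 block, and the heterochromatin chromosome carries a tandem repeat
#' array plus an inverted duplication (palindrome). Alignment tables are
#' emitted from the planted truth, so detector tests need no external
#' aligner.
#'
#' @param config a [sim_config()].
#' @param history optionally, the result of [simulate_locus_history()]
#'   under the same config (recomputed when omitted).
#' @return A `sim_sequences` list: `genomes` (per lineage, named character
#'   vector with chromosome `Xq`), `het` (chromosomes `het` and `pal`),
#'   `masters`, `hits` (truth-derived `alignment_hits`: `basd` per
#'   lineage, `repeat_unit`, `self_repeat`, `self_pal`) and `truth`
#'   (tables `blocks`, `basd`, `repeats`, `palindrome`, `genes`).
#' @export
emit_sequences <- function(config, history = NULL) {
  if (is.null(history)) history <- simulate_locus_history(config)
  set.seed(config$seed + 2L)
  masters <- make_masters(config)
  bs <- config$basd_spec
  rs <- config$repeat_spec
  ps <- config$palindrome_spec

  # embed gene copies in SB5 (the Y-derived block)
  if ("SB5" %in% names(masters$blocks) &&
      !is.null(config$gene_spec$copies) && nrow(config$gene_spec$copies)) {
    g5 <- plant_genes(masters$blocks[["SB5"]], masters, config$gene_spec)
    masters$blocks[["SB5"]] <- g5$seq
  } else {
    g5 <- list(seq = NULL, table = data.frame())
  }

  genomes <- list()
  truth_blocks <- list(); truth_basd <- list(); truth_genes <- list()
  basd_hits <- list()
  mut_rate <- copy_sub_rate(bs$identity)

  for (sp in names(history$species)) {
    arr <- history$species[[sp]]
    n <- length(arr$ids)
    # boundaries carrying a BASD copy: the insertion boundaries first
    ins_ids <- history$truth$inserted$ids
    run <- which(arr$ids %in% ins_ids)
    pref <- sort(unique(c(min(run) - 1L, max(run))))
    pref <- pref[pref >= 1L & pref <= n - 1L]
    gaps <- unique(c(pref, setdiff(seq_len(n - 1L), pref)))
    n_copies <- min(bs$n_copies, n - 1L)
    basd_gaps <- sort(gaps[seq_len(n_copies)])

    pieces <- character(0L)
    pos <- 0L
    record <- function(lst, row) c(lst, list(row))
    copy_idx <- 0L
    for (i in seq_len(n)) {
      bseq <- masters$blocks[[arr$ids[i]]]
      if (arr$signs[i] < 0L) bseq <- revcomp(bseq)
      piece_start <- pos
      pieces <- c(pieces, bseq); pos <- pos + nchar(bseq)
      truth_blocks <- record(truth_blocks, data.frame(
        species = sp, block = arr$ids[i],
        strand = if (arr$signs[i] > 0L) "+" else "-",
        start = piece_start, end = pos, stringsAsFactors = FALSE))
      if (arr$ids[i] == "SB5" && nrow(g5$table)) {
        gt <- g5$table
        if (arr$signs[i] < 0L) {
          gstart <- piece_start + nchar(bseq) - (gt$offset + gt$len)
          gstrand <- "-"
        } else {
          gstart <- piece_start + gt$offset
          gstrand <- "+"
        }
        truth_genes <- record(truth_genes, data.frame(
          species = sp, chrom = "Xq", gene = gt$gene, state = gt$state,
          start = gstart, end = gstart + gt$len, strand = gstrand,
          stringsAsFactors = FALSE))
      }
      if (i %in% basd_gaps) {
        copy_idx <- copy_idx + 1L
        is_left_ins <- i == pref[1L] && bs$flanks
        is_right_ins <- length(pref) > 1L && i == pref[2L] && bs$flanks
        if (is_right_ins) {  # alpha flank upstream of the right boundary copy
          fl <- mutate_seq(masters$flanks[["2a"]], mut_rate)
          pieces <- c(pieces, fl); pos <- pos + nchar(fl)
        }
        cp <- mutate_seq(masters$basd, mut_rate)
        cp_start <- pos
        pieces <- c(pieces, cp); pos <- pos + nchar(cp)
        ident <- seq_identity(cp, masters$basd)
        truth_basd <- record(truth_basd, data.frame(
          species = sp, chrom = "Xq", start = cp_start, end = pos,
          identity = ident,
          boundary = paste0(arr$ids[i], "-", arr$ids[i + 1L]),
          flank_up = if (is_right_ins) "2a" else "none",
          flank_down = if (is_left_ins) "2g" else "none",
          stringsAsFactors = FALSE))
        basd_hits[[length(basd_hits) + 1L]] <- data.frame(
          species = sp, query_name = "basd_master", query_start = 0L,
          query_end = bs$length, target_name = "Xq",
          target_start = cp_start, target_end = pos, strand = "+",
          matches = as.integer(round(ident * bs$length)),
          block_len = bs$length, identity = ident, is_primary = TRUE,
          stringsAsFactors = FALSE)
        if (is_left_ins) {  # gamma flank downstream of the left boundary copy
          fl <- mutate_seq(masters$flanks[["2g"]], mut_rate)
          pieces <- c(pieces, fl); pos <- pos + nchar(fl)
        }
      }
    }
    genomes[[sp]] <- c(Xq = paste(pieces, collapse = ""))
  }

  # heterochromatin chromosome: tandem repeat array
  copy_len <- as.integer(round(rs$unit_len * rs$copy_fraction))
  pad <- random_bases(2000L)
  het_pieces <- pad
  hpos <- nchar(pad)
  truth_rep <- list(); unit_hits <- list()
  for (i in seq_len(rs$n_copies)) {
    cp <- mutate_seq(substring(masters$repeat_unit, 1L, copy_len),
                     rs$mutation_rate)
    truth_rep[[i]] <- data.frame(chrom = "het", start = hpos,
                                 end = hpos + copy_len,
                                 copy_fraction = rs$copy_fraction,
                                 stringsAsFactors = FALSE)
    unit_hits[[i]] <- data.frame(
      query_name = "repeat_unit", query_start = 0L, query_end = copy_len,
      target_name = "het", target_start = hpos, target_end = hpos + copy_len,
      strand = "+", matches = as.integer(round(copy_len * (1 - rs$mutation_rate))),
      block_len = copy_len, identity = 1 - rs$mutation_rate,
      is_primary = TRUE, stringsAsFactors = FALSE)
    het_pieces <- c(het_pieces, cp)
    hpos <- hpos + copy_len
  }
  het_pieces <- c(het_pieces, random_bases(2000L))
  het <- paste(het_pieces, collapse = "")

  # self-alignment of the repeat array, from truth: all ordered copy pairs
  reps <- do.call(rbind, truth_rep)
  self_rep <- list()
  if (nrow(reps) >= 2L) {
    for (i in seq_len(nrow(reps) - 1L)) {
      for (j in (i + 1L):nrow(reps)) {
        self_rep[[length(self_rep) + 1L]] <- data.frame(
          query_name = "het", query_start = reps$start[i],
          query_end = reps$end[i], target_name = "het",
          target_start = reps$start[j], target_end = reps$end[j],
          strand = "+",
          matches = as.integer(round(copy_len * (1 - 2 * rs$mutation_rate))),
          block_len = copy_len, identity = 1 - 2 * rs$mutation_rate,
          is_primary = TRUE, stringsAsFactors = FALSE)
      }
    }
  }

  # palindrome chromosome: arm - spacer - reverse-complemented arm
  arm <- random_bases(ps$arm_len)
  arm2 <- mutate_seq(arm, 1 - ps$identity)
  pal <- paste0(random_bases(3000L), arm, random_bases(ps$spacer),
                revcomp(arm2), random_bases(3000L))
  a1 <- 3000L; a2 <- a1 + ps$arm_len + ps$spacer
  truth_pal <- data.frame(chrom = "pal", left_start = a1,
                          left_end = a1 + ps$arm_len, right_start = a2,
                          right_end = a2 + ps$arm_len, spacer = ps$spacer,
                          identity = ps$identity, stringsAsFactors = FALSE)
  self_pal <- data.frame(
    query_name = "pal", query_start = a1, query_end = a1 + ps$arm_len,
    target_name = "pal", target_start = a2, target_end = a2 + ps$arm_len,
    strand = "-", matches = as.integer(round(ps$arm_len * ps$identity)),
    block_len = ps$arm_len, identity = ps$identity, is_primary = TRUE,
    stringsAsFactors = FALSE)

  as_hits <- function(lst) {
    if (!length(lst)) return(empty_hits())
    df <- do.call(rbind, lst)
    rownames(df) <- NULL
    class(df) <- c("alignment_hits", "data.frame")
    df
  }
  basd_df <- if (length(basd_hits)) {
    df <- do.call(rbind, basd_hits)
    rownames(df) <- NULL
    df
  } else data.frame()
  structure(list(
    genomes = genomes,
    het = c(het = het, pal = pal),
    masters = masters,
    hits = list(basd = basd_df, repeat_unit = as_hits(unit_hits),
                self_repeat = as_hits(self_rep), self_pal = {
                  class(self_pal) <- c("alignment_hits", "data.frame")
                  self_pal
                }),
    truth = list(blocks = do.call(rbind, truth_blocks),
                 basd = do.call(rbind, truth_basd),
                 repeats = reps, palindrome = truth_pal,
                 genes = do.call(rbind, truth_genes),
                 query_len_aa = config$gene_spec$query_len_aa)),
    class = "sim_sequences")
}

#' Simulate a heterozygous-SNP track with a PAR/stratum density step
#'
#' SNV positions are drawn uniformly at Poisson-distributed counts:
#' `par_rate`/kb before the boundary, `stratum_rate`/kb after. Read depth
#' is Poisson around `depth_mode`; heterozygous alt counts are
#' Binomial(depth, 0.5). A `bad_fraction` of records deliberately violate
#' the heterozygosity filters (indel allele, skewed allele fraction, or
#' out-of-range depth) so that filtering is exercised.
#'
#' @param config a [sim_config()]; see the `snp_spec` entry.
#' @return List with `snps` (data.frame in [read_vcf_snps()] layout),
#'   `truth` (`boundary`, rates, good-record counts per segment).
#' @export
simulate_snp_track <- function(config) {
  set.seed(config$seed + 3L)
  ss <- config$snp_spec
  seg_len <- c(ss$boundary, ss$chrom_len - ss$boundary)
  rates <- c(ss$par_rate, ss$stratum_rate)
  pos <- integer(0L); segment <- integer(0L)
  offset <- c(0, ss$boundary)
  for (k in 1:2) {
    n <- stats::rpois(1L, rates[k] * seg_len[k] / 1000)
    n <- min(n, seg_len[k])
    if (n > 0L) {
      p <- sort(sample.int(seg_len[k], n)) + offset[k]
      pos <- c(pos, as.integer(p)); segment <- c(segment, rep(k, n))
    }
  }
  n <- length(pos)
  if (n == 0L) {
    return(list(snps = data.frame(chrom = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  depth = integer(),
                                  allele_fraction = numeric(),
                                  is_snv = logical(), stringsAsFactors = FALSE),
                truth = list(boundary = ss$boundary, par_rate = ss$par_rate,
                             stratum_rate = ss$stratum_rate,
                             n_good = c(0L, 0L))))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L))
  depth <- pmax(1L, stats::rpois(n, ss$depth_mode))
  altn <- stats::rbinom(n, depth, 0.5)
  bad <- stats::runif(n) < ss$bad_fraction
  bad_kind <- sample(3L, n, replace = TRUE)
  # violation 1: indel allele; 2: skewed allele fraction; 3: depth blowout
  alt[bad & bad_kind == 1L] <- paste0(alt[bad & bad_kind == 1L], "T")
  k2 <- bad & bad_kind == 2L
  altn[k2] <- stats::rbinom(sum(k2), depth[k2], 0.05)
  k3 <- bad & bad_kind == 3L
  depth[k3] <- 3L * as.integer(ss$depth_mode)
  altn[k3] <- stats::rbinom(sum(k3), depth[k3], 0.5)
  af <- ifelse(depth > 0L, altn / depth, NA_real_)
  snps <- data.frame(chrom = ss$chrom, pos = pos + 1L, ref = ref, alt = alt,
                     depth = depth, allele_fraction = af,
                     is_snv = nchar(ref) == 1L & nchar(alt) == 1L,
                     stringsAsFactors = FALSE)
  list(snps = snps,
       truth = list(boundary = ss$boundary, par_rate = ss$par_rate,
                    stratum_rate = ss$stratum_rate,
                    n_total = c(sum(segment == 1L), sum(segment == 2L)),
                    n_good = c(sum(!bad & segment == 1L),
                               sum(!bad & segment == 2L))))
}

#' Shuffle a genome, destroying planted structure
#'
#' Base-composition-preserving negative control for detector specificity
#' tests.
#'
#' @param genome named character vector.
#' @param seed PRNG seed.
#' @return Shuffled genome of the same lengths.
#' @export
shuffle_genome <- function(genome, seed = 1L) {
  set.seed(seed)
  vapply(genome, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L))
}

#' Write a simulation to disk in standard formats
#'
#' Emits FASTA genomes, truth-derived PAF and BLAST-tabular alignment
#' tables, a VCF of the SNP track and TSV truth tables. Output is
#' deterministic for a fixed config.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- emit_sequences(config)
  for (sp in names(sim$genomes)) {
    write_fasta(sim$genomes[[sp]], file.path(dir, paste0(sp, ".fa")))
  }
  write_fasta(sim$het, file.path(dir, "het.fa"))
  write_fasta(c(basd_master = sim$masters$basd,
                repeat_unit = sim$masters$repeat_unit),
              file.path(dir, "masters.fa"))
  write_paf(sim$hits$repeat_unit, file.path(dir, "repeat_unit.paf"))
  write_blast_tab(sim$hits$basd[, setdiff(names(sim$hits$basd), "species")],
                  file.path(dir, "basd_hits.tsv"))
  snp <- simulate_snp_track(config)
  write_vcf(snp$snps, file.path(dir, "snps.vcf"))
  for (nm in names(sim$truth)) {
    if (is.data.frame(sim$truth[[nm]])) {
      write_tsv_report(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
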