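# Exact k-mer anchored ungapped alignment.
#
# Desk-scale aligner behind the iterative BASD search: seeds exact k-mers
# from the query at a fixed step, locates them in the subject with
# Biostrings::matchPDict, groups anchors by diagonal (substitution-only
# divergence keeps homologous anchors on one exact diagonal) and reports
# the anchor-spanning ungapped hit with a direct base-by-base identity.
# Real BLASTN/minimap2 output enters the same pipeline via read_blast_tab()
# / read_paf().

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# anchors of query vs one subject strand; returns data.frame(qstart, tstart)
# (1-based starts of matching k-mers)
kmer_anchors <- function(query, subject, k, step) {
  qlen <- nchar(query)
  if (qlen < k) return(data.frame(qstart = integer(), tstart = integer()))
  starts <- seq(1L, qlen - k + 1L, by = step)
  kmers <- substring(query, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  if (!any(ok)) return(data.frame(qstart = integer(), tstart = integer()))
  starts <- starts[ok]; kmers <- kmers[ok]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
  mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject))
  qs <- rep(starts, lengths(Biostrings::startIndex(mi)))
  ts <- unlist(Biostrings::startIndex(mi), use.names = FALSE)
  if (is.null(ts)) ts <- integer(0)
  data.frame(qstart = qs, tstart = as.integer(ts))
}

seq_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(va == vb)
}

# align one query against one subject sequence on both strands.
# Returns alignment_hits with 0-based half-open coordinates; query
# coordinates of minus-strand hits refer to the reverse complement of the
# query (target coordinates are always on the forward subject strand).
kmer_align_one <- function(query, qname, subject, tname,
                           k = 24L, step = 8L, min_anchors = 2L) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    an <- kmer_anchors(q, subject, k, step)
    if (!nrow(an)) next
    an$diag <- an$tstart - an$qstart
    for (dg in unique(an$diag)) {
      grp <- an[an$diag == dg, ]
      if (nrow(grp) < min_anchors) next
      q0 <- min(grp$qstart); q1 <- max(grp$qstart) + k - 1L
      t0 <- q0 + dg; t1 <- q1 + dg
      ident <- seq_identity(substring(q, q0, q1), substring(subject, t0, t1))
      n <- q1 - q0 + 1L
      out[[length(out) + 1L]] <- data.frame(
        query_name = qname, query_start = q0 - 1L, query_end = q1,
        target_name = tname, target_start = t0 - 1L, target_end = t1,
        strand = strand, matches = as.integer(round(ident * n)),
        block_len = n, identity = ident, is_primary = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_hits())
  df <- do.call(rbind, out)
  class(df) <- c("alignment_hits", "data.frame")
  df
}

#' Align query sequences to a genome by exact k-mer anchoring
#'
#' Lightweight ungapped aligner for seeded homology search at desk scale
#' (see the BASD detection stage). Sensitive down to roughly 85% identity
#' for the default `k` and `step` on kilobase-scale queries; external
#' aligner output can be substituted through [read_blast_tab()] or
#' [read_paf()].
#'
#' @param queries named character vector of query sequences.
#' @param genome named character vector of subject sequences.
#' @param k exact-match seed length (default 24).
#' @param step spacing between query seed positions (default 8).
#' @param min_anchors minimum seeds on a diagonal to report a hit.
#' @return An `alignment_hits` data.frame; minus-strand hits carry query
#'   coordinates in the reverse-complemented query frame.
#' @export
kmer_align <- function(queries, genome, k = 24L, step = 8L, min_anchors = 2L) {
  out <- list()
  for (qn in names(queries)) {
    for (tn in names(genome)) {
      h <- kmer_align_one(queries[[qn]], qn, genome[[tn]], tn,
                          k = k, step = step, min_anchors = min_anchors)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(empty_hits())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("alignment_hits", "data.frame")
  df
}
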