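#' Tile a repeat unit across a region and count copies
#'
#' Walks unit-versus-region alignment hits in target order and groups them
#' into copy clusters: a new copy starts when the query coordinate
#' restarts (the next hit begins at or before the previous hit's query
#' start — the signature of entering the next tandem copy) or when the
#' target gap exceeds `max_gap`. Clusters covering at least
#' `min_copy_fraction` of the unit count as copies; the rest are reported
#' separately as partial copies, with no claim about a canonical partial
#' cutoff.
#'
#' @param unit_len repeat unit length, bp.
#' @param region numeric `c(start, end)` of the tiled region (same
#'   coordinates as the hit targets).
#' @param hits `alignment_hits` of the unit (query) against the region's
#'   chromosome.
#' @param min_hit_len,min_identity per-hit filters.
#' @param min_copy_fraction unit coverage needed for a full copy.
#' @param max_gap target gap that still joins split hits of one copy
#'   (default half the unit).
#' @return A `tiling_report` list: `copies`, `partial`, `covered_bp`,
#'   `coverage_fraction`, `clusters` (per-cluster table).
#' @export
tile_unit <- function(unit_len, region, hits, min_hit_len = 1000L,
                      min_identity = 0.8, min_copy_fraction = 0.5,
                      max_gap = NULL) {
  region_len <- region[2L] - region[1L]
  if (region_len <= 0) stop("region length must be positive")
  if (is.null(max_gap)) max_gap <- unit_len %/% 2L
  h <- hits[hits$block_len >= min_hit_len & hits$identity >= min_identity &
              hits$target_start < region[2L] & hits$target_end > region[1L], ,
            drop = FALSE]
  mk <- function(copies, partial, clusters) {
    covered <- if (nrow(h)) union_bp(pmax(h$target_start, region[1L]),
                                     pmin(h$target_end, region[2L])) else 0L
    structure(list(copies = copies, partial = partial, covered_bp = covered,
                   coverage_fraction = covered / region_len,
                   clusters = clusters, unit_len = unit_len, region = region),
              class = "tiling_report")
  }
  if (!nrow(h)) {
    return(mk(0L, 0L, data.frame()))
  }
  h <- h[order(h$target_start, h$target_end), , drop = FALSE]
  cluster <- integer(nrow(h))
  cluster[1L] <- 1L
  for (i in seq_len(nrow(h))[-1L]) {
    restart <- h$query_start[i] <= h$query_start[i - 1L]
    gap <- h$target_start[i] - max(h$target_end[seq_len(i - 1L)][
      cluster[seq_len(i - 1L)] == cluster[i - 1L]])
    cluster[i] <- if (restart || gap > max_gap) cluster[i - 1L] + 1L else
      cluster[i - 1L]
  }
  tab <- do.call(rbind, lapply(split(seq_len(nrow(h)), cluster), function(idx) {
    data.frame(start = min(h$target_start[idx]), end = max(h$target_end[idx]),
               unit_coverage = union_bp(h$query_start[idx], h$query_end[idx]) /
                 unit_len,
               n_hits = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  full <- sum(tab$unit_coverage >= min_copy_fraction)
  mk(as.integer(full), as.integer(nrow(tab) - full), tab)
}

#' @export
print.tiling_report <- function(x, ...) {
  cat("<tiling report> unit ", x$unit_len, " bp over [",
      x$region[1L], ", ", x$region[2L], ")\n", sep = "")
  cat("  full copies: ", x$copies, ", partial: ", x$partial,
      ", covered: ", x$covered_bp, " bp (",
      sprintf("%.1f%%", 100 * x$coverage_fraction), " of region)\n", sep = "")
  invisible(x)
}

#' Propose basic repeat units from a self-alignment
#'
#' Automated stand-in for reading the repeat period off a self dot-plot:
#' the candidate period is the modal off-diagonal offset of plus-strand
#' self-hits (offsets clustered within `tol` relative distance, weighted
#' by aligned bp), and the candidate unit is the period-length window of
#' the region with the highest hit coverage. Candidates are returned
#' ranked; the final choice remains with the user.
#'
#' @param self_hits `alignment_hits` of a region against itself.
#' @param region numeric `c(start, end)` of the examined region.
#' @param tol relative offset tolerance when clustering periods.
#' @param max_candidates maximum candidates returned.
#' @return data.frame of candidates: `period`, `weight` (aligned bp
#'   supporting the period), `start`, `end` (best window); zero rows if
#'   there are no off-diagonal hits.
#' @export
propose_unit <- function(self_hits, region, tol = 0.05, max_candidates = 3L) {
  h <- self_hits[self_hits$strand == "+", , drop = FALSE]
  # remove the trivial self-diagonal
  h <- h[!(h$query_start == h$target_start & h$query_end == h$target_end), ,
         drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(period = integer(), weight = numeric(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  off <- abs(h$target_start - h$query_start)
  w <- h$block_len
  o <- order(off)
  off <- off[o]; w <- w[o]
  # jitter tolerance is scaled by the base (smallest) offset: in a tandem
  # array the off-diagonal offsets are the period and its multiples, and
  # consecutive multiples must never merge
  grp <- cumsum(c(1L, as.integer(diff(off) > tol * off[1L])))
  cand <- do.call(rbind, lapply(split(seq_along(off), grp), function(idx) {
    data.frame(period = as.integer(round(sum(off[idx] * w[idx]) / sum(w[idx]))),
               weight = sum(w[idx]), stringsAsFactors = FALSE)
  }))
  cand <- cand[order(-cand$weight), , drop = FALSE]
  cand <- utils::head(cand, max_candidates)
  # best window of each period length: maximal aligned coverage
  win <- t(vapply(cand$period, function(p) {
    starts <- seq(region[1L], max(region[1L], region[2L] - p), by = max(1L, p %/% 4L))
    cov <- vapply(starts, function(s) {
      union_bp(pmax(h$target_start, s), pmin(h$target_end, s + p)) +
        union_bp(pmax(h$query_start, s), pmin(h$query_end, s + p))
    }, numeric(1L))
    s <- starts[which.max(cov)]
    c(s, min(s + p, region[2L]))
  }, numeric(2L)))
  cand$start <- as.integer(win[, 1L])
  cand$end <- as.integer(win[, 2L])
  rownames(cand) <- NULL
  cand
}

#' Detect palindromic (inverted-duplication) structures
#'
#' Minus-strand self-alignment hits whose two arms are long enough,
#' similar enough and non-overlapping are reported as palindrome calls;
#' mirrored duplicate hits are collapsed and overlapping calls merged to
#' their maximal extent.
#'
#' @param self_hits `alignment_hits` of a sequence against itself.
#' @param min_arm minimum arm length, bp (default 10 kb).
#' @param min_identity minimum arm identity.
#' @return data.frame of calls: `chrom`, `left_start`, `left_end`,
#'   `right_start`, `right_end`, `spacer`, `identity`, `span`.
#' @export
detect_palindromes <- function(self_hits, min_arm = 10000L,
                               min_identity = 0.9) {
  h <- self_hits[self_hits$strand == "-" &
                   self_hits$identity >= min_identity, , drop = FALSE]
  empty <- data.frame(chrom = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), spacer = integer(),
                      identity = numeric(), span = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(h)) return(empty)
  # canonical arm order; drop mirrored duplicates
  ls <- pmin(h$query_start, h$target_start)
  le <- pmin(h$query_end, h$target_end)
  rs <- pmax(h$query_start, h$target_start)
  re <- pmax(h$query_end, h$target_end)
  keep <- !duplicated(paste(h$query_name, ls, le, rs, re))
  df <- data.frame(chrom = h$query_name, left_start = ls, left_end = le,
                   right_start = rs, right_end = re, identity = h$identity,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[(df$left_end - df$left_start) >= min_arm &
             (df$right_end - df$right_start) >= min_arm &
             df$left_end <= df$right_start, , drop = FALSE]
  if (!nrow(df)) return(empty)
  # merge calls whose total spans overlap, keeping the maximal extent
  out <- list()
  for (ch in unique(df$chrom)) {
    dd <- df[df$chrom == ch, , drop = FALSE]
    m <- merge_intervals(dd$left_start, dd$right_end)
    for (i in seq_len(nrow(m))) {
      inside <- dd$left_start >= m$start[i] & dd$right_end <= m$end[i]
      g <- dd[inside, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, left_start = min(g$left_start), left_end = max(g$left_end),
        right_start = min(g$right_start), right_end = max(g$right_end),
        spacer = min(g$right_start) - max(g$left_end),
        identity = max(g$identity),
        span = max(g$right_end) - min(g$left_start),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$left_start), , drop = FALSE]
}
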