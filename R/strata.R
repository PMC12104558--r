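#' Heterozygous-SNP filter configuration
#'
#' Encodes the heterozygosity selection rule: single-nucleotide
#' substitutions with allele fraction in `[af_min, af_max]` and read depth
#' in `[depth_mode / 2, 1.5 * depth_mode]`, all bounds inclusive. Depth
#' bounds may also be overridden explicitly for data-specific cutoffs.
#'
#' @param depth_mode modal read depth (estimate with
#'   [estimate_depth_mode()]).
#' @param af_min,af_max allele-fraction window (default 0.25-0.75).
#' @param depth_lo,depth_hi explicit depth bounds; default from the
#'   half-mode / 1.5-mode rule.
#' @param snv_only keep single-nucleotide substitutions only.
#' @return A `snp_filter_config` list.
#' @export
snp_filter_config <- function(depth_mode, af_min = 0.25, af_max = 0.75,
                              depth_lo = NULL, depth_hi = NULL,
                              snv_only = TRUE) {
  if (is.null(depth_lo)) depth_lo <- depth_mode / 2
  if (is.null(depth_hi)) depth_hi <- 1.5 * depth_mode
  if (!(af_min >= 0 && af_min < af_max && af_max <= 1)) {
    stop("need 0 <= af_min < af_max <= 1")
  }
  if (depth_lo >= depth_hi) stop("depth_lo must be below depth_hi")
  structure(list(depth_mode = depth_mode, af_min = af_min, af_max = af_max,
                 depth_lo = depth_lo, depth_hi = depth_hi,
                 snv_only = snv_only),
            class = "snp_filter_config")
}

#' Modal read depth of a SNP table
#'
#' Mode of the integer depth histogram; ties resolve to the smallest
#' depth.
#'
#' @param snps data.frame with a `depth` column.
#' @param min_records minimum records required for a stable mode.
#' @return Integer modal depth.
#' @export
estimate_depth_mode <- function(snps, min_records = 100L) {
  d <- snps$depth[!is.na(snps$depth)]
  if (length(d) < min_records) {
    stop("need >= ", min_records, " records to estimate the depth mode")
  }
  tab <- table(d)
  as.integer(names(tab)[which.max(tab)])  # which.max takes the first => smallest depth
}

#' Filter SNP records to confident heterozygous SNVs
#'
#' @param snps data.frame as from [read_vcf_snps()].
#' @param config a [snp_filter_config()].
#' @return The filtered rows.
#' @export
filter_het_snps <- function(snps, config) {
  keep <- snps$allele_fraction >= config$af_min &
    snps$allele_fraction <= config$af_max &
    snps$depth >= config$depth_lo & snps$depth <= config$depth_hi
  if (config$snv_only) keep <- keep & snps$is_snv
  snps[!is.na(keep) & keep, , drop = FALSE]
}

#' Windowed SNP density track
#'
#' Counts filtered SNPs in fixed windows along one chromosome. Windows
#' overlapping a mask (e.g. heterochromatin) are flagged and excluded from
#' downstream statistics; their density is `NA`.
#'
#' @param snps filtered SNP data.frame (`chrom`, `pos` 1-based).
#' @param chrom chromosome to profile.
#' @param chrom_len chromosome length, bp.
#' @param window_bp window size (default 100 kb).
#' @param mask optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of excluded regions.
#' @return A `density_track` data.frame: `chrom`, `start`, `end`, `count`,
#'   `density` (SNPs per kb), `masked`.
#' @export
windowed_density <- function(snps, chrom, chrom_len, window_bp = 100000L,
                             mask = NULL) {
  if (window_bp < 1L) stop("window_bp must be >= 1")
  starts <- seq(0L, max(0L, chrom_len - 1L), by = window_bp)
  ends <- pmin(starts + window_bp, chrom_len)
  pos0 <- snps$pos[snps$chrom == chrom] - 1L
  counts <- vapply(seq_along(starts), function(i) {
    sum(pos0 >= starts[i] & pos0 < ends[i])
  }, integer(1L))
  masked <- rep(FALSE, length(starts))
  if (!is.null(mask) && nrow(mask)) {
    mk <- mask[mask$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(mk))) {
      masked <- masked | (starts < mk$end[i] & ends > mk$start[i])
    }
  }
  out <- data.frame(chrom = chrom, start = starts, end = ends, count = counts,
                    density = ifelse(masked, NA_real_,
                                     counts / ((ends - starts) / 1000)),
                    masked = masked, stringsAsFactors = FALSE)
  class(out) <- c("density_track", "data.frame")
  out
}

#' Detect a PAR/stratum boundary as a single density change-point
#'
#' Fits a one-change-point mean-shift model to the unmasked window
#' densities by least squares: the boundary is the split minimising the
#' two-segment residual sum of squares. The call is valid only when the
#' post-boundary mean density exceeds the pre-boundary mean by at least
#' `min_factor` (recombining PAR densities are near-background; the
#' differentiated stratum runs far higher). A track with no such split —
#' e.g. a female X, uniformly low — yields a no-boundary call.
#'
#' @param track a [windowed_density()] result.
#' @param min_factor required post/pre mean-density ratio (default 3).
#' @param min_windows minimum unmasked windows required.
#' @return A `stratum_call` list: `boundary` (bp, or `NA`), `valid`,
#'   `segments` (data.frame of labels, spans and mean densities), and the
#'   `track`.
#' @export
detect_boundary <- function(track, min_factor = 3, min_windows = 10L) {
  tr <- track[!track$masked, , drop = FALSE]
  if (nrow(tr) < min_windows) {
    stop("need >= ", min_windows, " unmasked windows")
  }
  x <- tr$density
  m <- length(x)
  best_k <- NA_integer_; best_rss <- Inf
  for (k in seq_len(m - 1L)) {
    a <- x[seq_len(k)]; b <- x[(k + 1L):m]
    rss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (rss < best_rss) { best_rss <- rss; best_k <- k }
  }
  pre <- mean(x[seq_len(best_k)])
  post <- mean(x[(best_k + 1L):m])
  valid <- (pre == 0 && post > 0) || (pre > 0 && post / pre >= min_factor)
  boundary <- if (valid) tr$end[best_k] else NA_integer_
  segments <- if (valid) {
    data.frame(label = c("Strata0_PAR", "Strata1"),
               start = c(tr$start[1L], boundary),
               end = c(boundary, tr$end[m]),
               mean_density = c(pre, post), stringsAsFactors = FALSE)
  } else {
    data.frame(label = "no_boundary", start = tr$start[1L], end = tr$end[m],
               mean_density = mean(x), stringsAsFactors = FALSE)
  }
  structure(list(chrom = tr$chrom[1L], boundary = boundary, valid = valid,
                 segments = segments, track = track),
            class = "stratum_call")
}

#' @export
print.stratum_call <- function(x, ...) {
  if (x$valid) {
    cat("<stratum call> ", x$chrom, ": PAR/stratum boundary at ",
        format(x$boundary, big.mark = ",", scientific = FALSE),
        " bp\n", sep = "")
  } else {
    cat("<stratum call> ", x$chrom, ": no boundary (uniform track)\n", sep = "")
  }
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Subdivide the differentiated stratum at an inversion
#'
#' Splits Strata 1 into S1a (boundary to inversion) and S1b (inversion
#' end onward) and reports per-segment mean densities over unmasked
#' windows. Purely descriptive: no difference between the sub-strata is
#' asserted.
#'
#' @param call a valid [detect_boundary()] result.
#' @param inversion_interval numeric `c(start, end)` in bp, strictly
#'   inside Strata 1.
#' @return The `stratum_call` with S1a/S1b rows appended to `segments`.
#' @export
subdivide_stratum <- function(call, inversion_interval) {
  if (!call$valid) stop("cannot subdivide: no boundary in call")
  s <- inversion_interval[1L]; e <- inversion_interval[2L]
  chrom_end <- max(call$track$end)
  if (!(s > call$boundary && e < chrom_end && s < e)) {
    stop("inversion interval must lie strictly inside Strata 1")
  }
  tr <- call$track[!call$track$masked, , drop = FALSE]
  seg_mean <- function(lo, hi) {
    sel <- tr$start >= lo & tr$end <= hi
    if (!any(sel)) NA_real_ else mean(tr$density[sel])
  }
  call$segments <- rbind(call$segments, data.frame(
    label = c("S1a", "S1b"),
    start = c(call$boundary, e),
    end = c(s, chrom_end),
    mean_density = c(seg_mean(call$boundary, s), seg_mean(e, chrom_end)),
    stringsAsFactors = FALSE))
  call
}
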