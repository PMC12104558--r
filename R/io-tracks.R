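#' Write genomic intervals as BED
#'
#' BED is 0-based half-open — the package's internal convention — so
#' coordinates pass through unchanged.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  nm <- if ("name" %in% names(regions)) regions$name else "."
  sc <- if ("score" %in% names(regions)) regions$score else 0L
  st <- if ("strand" %in% names(regions)) regions$strand else "."
  writeLines(paste(regions$chrom, regions$start, regions$end, nm, sc, st,
                   sep = "\t"), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (>= 3 columns).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `name` when a fourth column is present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs >= 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1L]]), start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]), stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- as.character(df[[4L]])
  out
}

#' Write features as GFF3
#'
#' Converts the package's 0-based half-open intervals to GFF3's 1-based
#' inclusive convention at the boundary.
#'
#' @param features data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `source`, `type`, `score`, `strand`,
#'   `attributes`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  get <- function(col, default) {
    if (col %in% names(features)) features[[col]] else default
  }
  lines <- paste(features$chrom, get("source", "ytrace"),
                 get("type", "region"),
                 features$start + 1L, features$end,
                 get("score", "."), get("strand", "."), ".",
                 get("attributes", "."), sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write a tab-separated report table
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# interval utilities shared across modules ---------------------------------

# merge overlapping/adjacent [start, end) intervals; optionally merge
# across gaps of at most max_gap
merge_intervals <- function(start, end, max_gap = 0L) {
  if (!length(start)) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(0L); out_e <- integer(0L)
  for (i in seq_along(start)[-1L]) {
    if (start[i] - me <= max_gap) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# total bp covered by the union of [start, end) intervals
union_bp <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

check_disjoint_regions <- function(regions) {
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1L && any(r$start[-1L] < r$end[-nrow(r)])) {
      stop("regions overlap on ", ch)
    }
  }
  invisible(TRUE)
}
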