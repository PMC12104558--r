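#' Fragment a genome into fixed-size windows
#'
#' Non-overlapping windows (step = window size); the final partial window
#' is kept. Fragment names encode the source chromosome and 0-based offset
#' as `"<chrom>:<offset>"` and round-trip through
#' [parse_fragment_name()].
#'
#' @param genome named character vector of sequences.
#' @param window_bp window size in bp (default 500 kb, the whole-chromosome
#'   alignment granularity).
#' @return Named character vector of window sequences.
#' @export
window_genome <- function(genome, window_bp = 500000L) {
  if (window_bp < 1L) stop("window_bp must be >= 1")
  out <- character(0L)
  for (nm in names(genome)) {
    len <- nchar(genome[[nm]])
    starts <- seq(1L, len, by = window_bp)
    frags <- substring(genome[[nm]], starts, pmin(starts + window_bp - 1L, len))
    names(frags) <- paste0(nm, ":", starts - 1L)
    out <- c(out, frags)
  }
  out
}

#' Decode a window fragment name
#'
#' @param name fragment name(s) of the form `"<chrom>:<offset>"`.
#' @return data.frame with `chrom` and integer `offset` (0-based).
#' @export
parse_fragment_name <- function(name) {
  m <- regmatches(name, regexec("^(.*):([0-9]+)$", name))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("undecodable fragment name: ", name[bad][1L])
  data.frame(chrom = vapply(m, `[[`, character(1L), 2L),
             offset = as.integer(vapply(m, `[[`, character(1L), 3L)),
             stringsAsFactors = FALSE)
}

#' Filter whole-chromosome synteny alignments
#'
#' Keeps primary alignments strictly exceeding the length cutoff (the
#' "exceeding 100 kbp" rule: a hit of exactly `min_len_bp` is dropped).
#' Idempotent and order-preserving.
#'
#' @param hits `alignment_hits`.
#' @param min_len_bp strict lower bound on `block_len` (default 100 kb).
#' @return The filtered `alignment_hits`.
#' @export
filter_synteny_hits <- function(hits, min_len_bp = 100000L) {
  hits[hits$is_primary & hits$block_len > min_len_bp, , drop = FALSE]
}

#' Build a chromosome-pair synteny map from windowed alignments
#'
#' Lifts window-fragment hits back to source-chromosome coordinates (via
#' the fragment-name contract of [window_genome()]) and aggregates per
#' (query chromosome, target chromosome) pair: aligned bp is summed over
#' the merged union of lifted query intervals, so overlapping hits are
#' never double counted. The orientation consensus is the strand carrying
#' the majority of aligned bp; exact ties are reported as `"."`.
#'
#' @param hits filtered `alignment_hits` whose query names are window
#'   fragments.
#' @return A `synteny_map` data.frame: `query_chrom`, `target_chrom`,
#'   `aligned_bp`, `orientation`, `n_hits`, `query_lo`, `query_hi` (span of
#'   lifted query coverage).
#' @export
build_synteny_map <- function(hits) {
  if (!nrow(hits)) {
    out <- data.frame(query_chrom = character(), target_chrom = character(),
                      aligned_bp = integer(), orientation = character(),
                      n_hits = integer(), query_lo = integer(),
                      query_hi = integer(), stringsAsFactors = FALSE)
    class(out) <- c("synteny_map", "data.frame")
    return(out)
  }
  frag <- parse_fragment_name(hits$query_name)
  qs <- frag$offset + hits$query_start
  qe <- frag$offset + hits$query_end
  key <- paste(frag$chrom, hits$target_name, sep = "\r")
  out <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    plus <- sum(ifelse(hits$strand[idx] == "+", qe[idx] - qs[idx], 0L))
    minus <- sum(ifelse(hits$strand[idx] == "-", qe[idx] - qs[idx], 0L))
    data.frame(
      query_chrom = frag$chrom[idx[1L]],
      target_chrom = hits$target_name[idx[1L]],
      aligned_bp = union_bp(qs[idx], qe[idx]),
      orientation = if (plus > minus) "+" else if (minus > plus) "-" else ".",
      n_hits = length(idx),
      query_lo = min(qs[idx]), query_hi = max(qe[idx]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$query_chrom, out$target_chrom), ]
  rownames(out) <- NULL
  class(out) <- c("synteny_map", "data.frame")
  out
}

#' Reconstruct the ancestral karyotype under a fusion-only model
#'
#' Ancestral units are the chromosomes of a common reference (ancestor
#' proxy). A reference unit corresponds to the species chromosome that
#' carries at least `min_fraction` of the unit's aligned bp; a species
#' chromosome covering k units implies k - 1 fusion events in that
#' lineage, ordered along the chromosome. Fissions are outside the model:
#' a unit with no majority partner is reported as a model violation via a
#' warning and excluded from the fusion count.
#'
#' @param maps named list (one entry per species) of [build_synteny_map()]
#'   results, each aligned against the same reference genome.
#' @param min_fraction minimum fraction of a unit's aligned bp that must
#'   land on a single species chromosome to call correspondence.
#' @param sex_system `"XY"` or `"XO"`, used for the ancestral 2n report
#'   (see [ancestral_diploid_number()]); the reference haploid set is
#'   assumed to carry exactly one sex unit (the X).
#' @return An `ancestral_karyotype` list: `units`, `fusions` (data.frame
#'   `species`, `unit_a`, `unit_b`, `chrom`), `fusion_counts`,
#'   `extant_haploid`, `ancestral_haploid`, `ancestral_2n`, `violations`.
#' @export
infer_fusions <- function(maps, min_fraction = 0.5, sex_system = "XY") {
  if (length(maps) < 2L || is.null(names(maps))) {
    stop("need a named list of >= 2 species synteny maps")
  }
  units <- sort(unique(unlist(lapply(maps, function(m) m$target_chrom))))
  fus <- list()
  violations <- character(0L)
  counts <- integer(0L)
  extant <- integer(0L)
  for (sp in names(maps)) {
    m <- maps[[sp]]
    assign_unit <- character(0L)
    for (un in units) {
      mu <- m[m$target_chrom == un, , drop = FALSE]
      if (!nrow(mu)) {
        violations <- c(violations, paste0(sp, ": unit ", un, " unaligned"))
        next
      }
      tot <- sum(mu$aligned_bp)
      best <- which.max(mu$aligned_bp)
      if (mu$aligned_bp[best] < min_fraction * tot) {
        violations <- c(violations,
                        paste0(sp, ": unit ", un,
                               " split across chromosomes (possible fission)"))
        next
      }
      assign_unit[un] <- mu$query_chrom[best]
    }
    # order units along each species chromosome, emit consecutive pairs
    nf <- 0L
    for (ch in unique(assign_unit)) {
      uns <- names(assign_unit)[assign_unit == ch]
      if (length(uns) < 2L) next
      pos <- vapply(uns, function(un) {
        mu <- m[m$target_chrom == un & m$query_chrom == ch, , drop = FALSE]
        min(mu$query_lo)
      }, numeric(1L))
      uns <- uns[order(pos)]
      for (i in seq_len(length(uns) - 1L)) {
        nf <- nf + 1L
        fus[[length(fus) + 1L]] <- data.frame(
          species = sp, unit_a = uns[i], unit_b = uns[i + 1L], chrom = ch,
          stringsAsFactors = FALSE)
      }
    }
    counts[sp] <- nf
    extant[sp] <- length(unique(assign_unit))
  }
  if (length(violations)) {
    warning("fusion-only model violations: ",
            paste(violations, collapse = "; "))
  }
  fusions <- if (length(fus)) do.call(rbind, fus) else
    data.frame(species = character(), unit_a = character(),
               unit_b = character(), chrom = character(),
               stringsAsFactors = FALSE)
  anc_haploid <- length(units)
  res <- list(units = units, fusions = fusions, fusion_counts = counts,
              extant_haploid = extant, ancestral_haploid = anc_haploid,
              ancestral_2n = ancestral_diploid_number(
                anc_haploid, 0L,
                if (sex_system == "XY") "XY" else "XO_restore_Y"),
              sex_system = sex_system, violations = violations)
  class(res) <- "ancestral_karyotype"
  res
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("<ancestral karyotype> ", x$ancestral_haploid, " units, ancestral 2n = ",
      x$ancestral_2n, " (", x$sex_system, " male)\n", sep = "")
  for (sp in names(x$fusion_counts)) {
    cat(sprintf("  %-12s extant haploid %2d, fusions %2d\n", sp,
                x$extant_haploid[[sp]], x$fusion_counts[[sp]]))
  }
  if (length(x$violations)) cat("  model violations:", length(x$violations), "\n")
  invisible(x)
}

#' Ancestral diploid chromosome number under a fusion-only model
#'
#' Undoes lineage-specific fusions from an extant haploid count and
#' assembles the ancestral 2n for the requested sex system. The haploid
#' count includes exactly one sex chromosome (the X), so the ancestral
#' autosome count is `extant_haploid + fusion_count - 1`.
#'
#' * `"XY"`: ancestral male is XY, `2n = 2 * autosomes + 2`.
#' * `"XO"`: Y already lost, `2n = 2 * autosomes + 1`.
#' * `"XO_restore_Y"`: reconstructs the pre-loss XY ancestor from an XO
#'   species, `2n = 2 * autosomes + 2`.
#'
#' @param extant_haploid extant haploid chromosome count (autosomes + X).
#' @param fusion_count lineage-specific fusions to undo.
#' @param sex_system one of `"XY"`, `"XO"`, `"XO_restore_Y"`.
#' @return Integer ancestral 2n.
#' @examples
#' ancestral_diploid_number(13, 11, "XO_restore_Y")  # 48
#' ancestral_diploid_number(24, 0, "XO")             # 47
#' @export
ancestral_diploid_number <- function(extant_haploid, fusion_count,
                                     sex_system = c("XY", "XO", "XO_restore_Y")) {
  sex_system <- match.arg(sex_system)
  if (extant_haploid < 1L || fusion_count < 0L) {
    stop("counts must be non-negative (haploid >= 1)")
  }
  autosomes <- extant_haploid + fusion_count - 1L
  as.integer(switch(sex_system,
                    XY = 2L * autosomes + 2L,
                    XO = 2L * autosomes + 1L,
                    XO_restore_Y = 2L * autosomes + 2L))
}
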