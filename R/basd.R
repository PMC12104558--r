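#' Drop short alignments before segmental-duplication merging
#'
#' Alignments shorter than `min_len` (target-side length) are excluded;
#' the bound is inclusive, so a hit of exactly `min_len` is kept.
#'
#' @param hits `alignment_hits`.
#' @param min_len minimum block length in bp (default 500).
#' @return Filtered `alignment_hits`.
#' @export
filter_hits_by_length <- function(hits, min_len = 500L) {
  hits[hits$block_len >= min_len, , drop = FALSE]
}

#' Merge split alignments into candidate duplication intervals
#'
#' Hits from the same query on the same target chromosome and strand
#' whose target intervals lie within `max_gap` of one another are merged
#' into one union-span interval (strand partitioning prevents chimeric
#' palindromic merges). Merged intervals with span at least
#' `min_candidate` become duplication candidates.
#'
#' @param hits `alignment_hits`.
#' @param max_gap maximum target-coordinate gap bridged by a merge
#'   (default 3000).
#' @param min_candidate minimum merged span for candidate status
#'   (default 3000).
#' @return data.frame of merged intervals: `query_name`, `chrom`,
#'   `start`, `end`, `span`, `n_hits`, `identity` (aligned-bp-weighted),
#'   `is_candidate`.
#' @export
merge_split_hits <- function(hits, max_gap = 3000L, min_candidate = 3000L) {
  if (!nrow(hits)) {
    return(data.frame(query_name = character(), chrom = character(),
                      start = integer(), end = integer(), span = integer(),
                      n_hits = integer(), identity = numeric(),
                      is_candidate = logical(), stringsAsFactors = FALSE))
  }
  key <- paste(hits$query_name, hits$target_name, hits$strand, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    h <- hits[key == k, , drop = FALSE]
    h <- h[order(h$target_start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      h$target_start[-1L] - cummax(h$target_end)[-nrow(h)] > max_gap)))
    for (g in unique(grp)) {
      hh <- h[grp == g, , drop = FALSE]
      s <- min(hh$target_start); e <- max(hh$target_end)
      w <- hh$block_len
      out[[length(out) + 1L]] <- data.frame(
        query_name = hh$query_name[1L], chrom = hh$target_name[1L],
        start = s, end = e, span = e - s, n_hits = nrow(hh),
        identity = sum(hh$identity * w) / sum(w),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$is_candidate <- out$span >= min_candidate
  rownames(out) <- NULL
  out
}

# collapse candidate intervals that overlap across queries into one locus
normalize_candidates <- function(cand) {
  if (!nrow(cand)) return(data.frame(chrom = character(), start = integer(),
                                     end = integer(), identity = numeric(),
                                     stringsAsFactors = FALSE))
  out <- list()
  for (ch in unique(cand$chrom)) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    m <- merge_intervals(cc$start, cc$end, max_gap = 0L)
    for (i in seq_len(nrow(m))) {
      inside <- cc$start < m$end[i] & cc$end > m$start[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = m$start[i], end = m$end[i],
        identity = max(cc$identity[inside]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Iterative seeded detection of boundary-associated segmental duplications
#'
#' Repeats the cycle {align current seed sequences to the genome, drop
#' hits shorter than `min_len`, merge split hits within `max_gap`, keep
#' merged spans of at least `min_candidate` as candidates} with the
#' candidate sequences as next-round queries, until the candidate interval
#' set stabilises or `max_iter` rounds are reached (non-convergence
#' returns the current set with a warning). Candidates with span at least
#' `min_final_len` become final copies, named in genome coordinate order
#' with a species prefix (`To-BASD001` style).
#'
#' @param genome named character vector.
#' @param seed_sequences named character vector of seed queries.
#' @param min_len per-hit length cutoff (bp).
#' @param max_gap split-hit merge distance (bp).
#' @param min_candidate candidate span threshold (bp).
#' @param min_final_len final copy span threshold (bp).
#' @param max_iter iteration cap.
#' @param prefix species prefix used in copy names.
#' @param aligner function `(queries, genome) -> alignment_hits`; defaults
#'   to the internal [kmer_align()].
#' @return data.frame of `BasdCopy` rows: `name`, `chrom`, `start`, `end`,
#'   `length`, `identity_to_seed`, `iteration_found`.
#' @export
iterate_basd_detection <- function(genome, seed_sequences, min_len = 500L,
                                   max_gap = 3000L, min_candidate = 3000L,
                                   min_final_len = 5000L, max_iter = 10L,
                                   prefix = "Sim", aligner = kmer_align) {
  if (!length(seed_sequences)) stop("seed sequences required")
  queries <- seed_sequences
  prev_key <- NULL
  cand <- NULL
  iter_found <- integer(0L)
  for (it in seq_len(max_iter)) {
    hits <- aligner(queries, genome)
    hits <- filter_hits_by_length(hits, min_len)
    merged <- merge_split_hits(hits, max_gap, min_candidate)
    cand <- normalize_candidates(merged[merged$is_candidate, , drop = FALSE])
    key <- paste(cand$chrom, cand$start, cand$end, collapse = ";")
    if (identical(key, prev_key)) break
    prev_key <- key
    if (it == max_iter) {
      warning("BASD detection did not converge within ", max_iter,
              " iterations; returning current candidate set")
      break
    }
    if (!nrow(cand)) break
    queries <- stats::setNames(
      substring(genome[cand$chrom], cand$start + 1L, cand$end),
      paste0("cand", seq_len(nrow(cand))))
    iter_found <- it
  }
  final <- cand[cand$end - cand$start >= min_final_len, , drop = FALSE]
  if (!nrow(final)) {
    return(data.frame(name = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      identity_to_seed = numeric(),
                      iteration_found = integer(), stringsAsFactors = FALSE))
  }
  final <- final[order(final$chrom, final$start), , drop = FALSE]
  # identity is reported against the original seeds, not the last-round
  # candidate queries
  for (i in seq_len(nrow(final))) {
    cp <- substring(genome[final$chrom[i]], final$start[i] + 1L, final$end[i])
    h <- aligner(seed_sequences, c(copy = cp))
    if (nrow(h)) {
      final$identity[i] <- sum(h$identity * h$block_len) / sum(h$block_len)
    }
  }
  data.frame(name = sprintf("%s-BASD%03d", prefix, seq_len(nrow(final))),
             chrom = final$chrom, start = final$start, end = final$end,
             length = final$end - final$start,
             identity_to_seed = final$identity,
             iteration_found = if (length(iter_found)) iter_found else 1L,
             stringsAsFactors = FALSE)
}

#' Count copies per region by midpoint assignment
#'
#' Each copy is assigned to the (non-overlapping) region containing its
#' midpoint; copies outside every region are tallied under `"unassigned"`.
#'
#' @param copies data.frame with `chrom`, `start`, `end`.
#' @param regions data.frame with `chrom`, `start`, `end`, `name`
#'   (0-based half-open, non-overlapping).
#' @return data.frame `region`, `count`.
#' @export
count_by_region <- function(copies, regions) {
  check_disjoint_regions(regions)
  counts <- stats::setNames(rep(0L, nrow(regions) + 1L),
                            c(regions$name, "unassigned"))
  if (nrow(copies)) {
    mid <- (copies$start + copies$end) %/% 2L
    for (i in seq_len(nrow(copies))) {
      inside <- regions$chrom == copies$chrom[i] &
        regions$start <= mid[i] & mid[i] < regions$end
      nm <- if (any(inside)) regions$name[which(inside)[1L]] else "unassigned"
      counts[nm] <- counts[nm] + 1L
    }
  }
  data.frame(region = names(counts), count = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign flank provenance labels to duplication copies
#'
#' Aligns the window upstream of each copy against the ancestral alpha
#' flank references and the window downstream against the gamma
#' references; the best reference achieving at least `min_flank_bp`
#' aligned bp at `min_identity` or better gives the label, else `"none"`.
#' Window sizes default to the extents over which the ancestral flanks
#' remain alignable (1.8 kb upstream, 10.8 kb downstream).
#'
#' @param copies data.frame with `name`, `chrom`, `start`, `end`.
#' @param genome named character vector containing the copies.
#' @param ancestral_flanks named character vector of flank references;
#'   names ending `"a"` are upstream (alpha) references, `"g"` downstream
#'   (gamma), e.g. `c("1a" = ..., "1g" = ..., "2a" = ..., "2g" = ...)`.
#' @param up_window,down_window window sizes in bp.
#' @param min_flank_bp minimum aligned bp to assign a label.
#' @param min_identity minimum alignment identity.
#' @param aligner alignment function, defaulting to [kmer_align()].
#' @return data.frame `name`, `upstream`, `downstream`, `upstream_bp`,
#'   `downstream_bp`.
#' @export
assign_flanks <- function(copies, genome, ancestral_flanks,
                          up_window = 1800L, down_window = 10800L,
                          min_flank_bp = 500L, min_identity = 0.9,
                          aligner = kmer_align) {
  if (!length(ancestral_flanks) || is.null(names(ancestral_flanks))) {
    stop("named ancestral flank references required")
  }
  alpha <- ancestral_flanks[grepl("a$", names(ancestral_flanks))]
  gamma <- ancestral_flanks[grepl("g$", names(ancestral_flanks))]
  score_side <- function(window_seq, refs) {
    if (!nchar(window_seq) || !length(refs)) return(list(label = "none", bp = 0L))
    best <- "none"; best_bp <- 0L
    for (rn in names(refs)) {
      h <- aligner(stats::setNames(refs[rn], rn),
                   c(win = window_seq))
      if (!nrow(h)) next
      h <- h[h$identity >= min_identity, , drop = FALSE]
      if (!nrow(h)) next
      bp <- union_bp(h$target_start, h$target_end)
      if (bp >= min_flank_bp && bp > best_bp) { best <- rn; best_bp <- bp }
    }
    list(label = best, bp = best_bp)
  }
  out <- list()
  for (i in seq_len(nrow(copies))) {
    chrom_seq <- genome[[copies$chrom[i]]]
    up <- substring(chrom_seq, max(1L, copies$start[i] - up_window + 1L),
                    copies$start[i])
    down <- substring(chrom_seq, copies$end[i] + 1L,
                      min(nchar(chrom_seq), copies$end[i] + down_window))
    u <- score_side(up, alpha)
    d <- score_side(down, gamma)
    out[[i]] <- data.frame(name = copies$name[i],
                           upstream = u$label, downstream = d$label,
                           upstream_bp = u$bp, downstream_bp = d$bp,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Infer the insertion mechanism from boundary flank order
#'
#' At a two-boundary insertion locus, an ancestral `alpha-BASD-gamma`
#' context split into `BASD-gamma ... alpha-BASD` (gamma leading, alpha
#' trailing) is the signature of integration via a circular intermediate
#' (eccDNA followed by NAHR); the unsplit order `alpha-BASD ... BASD-gamma`
#' indicates direct insertion. Anything else is undetermined.
#'
#' @param assignments [assign_flanks()] rows for the two boundary copies,
#'   ordered by genomic position.
#' @return A list (`mechanism_call`): `call` one of
#'   `"circular-intermediate"`, `"direct-insertion"`, `"undetermined"`;
#'   `evidence` the ordered flank labels; `note` for degenerate input.
#' @export
infer_mechanism <- function(assignments) {
  mk <- function(call, evidence, note = NA_character_) {
    structure(list(call = call, evidence = evidence, note = note),
              class = "mechanism_call")
  }
  if (nrow(assignments) != 2L) {
    return(mk("undetermined", character(0L),
              paste0("expected 2 boundary copies, got ", nrow(assignments))))
  }
  left <- assignments[1L, ]; right <- assignments[2L, ]
  ev <- c(left$upstream, left$downstream, right$upstream, right$downstream)
  gamma_led <- grepl("g$", left$downstream) && grepl("a$", right$upstream)
  alpha_led <- grepl("a$", left$upstream) && grepl("g$", right$downstream)
  if (gamma_led && !alpha_led) return(mk("circular-intermediate", ev))
  if (alpha_led && !gamma_led) return(mk("direct-insertion", ev))
  mk("undetermined", ev)
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism call> ", x$call, "\n", sep = "")
  if (length(x$evidence)) {
    cat("  boundary flanks (up/down per copy): ",
        paste(x$evidence, collapse = " "), "\n", sep = "")
  }
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Single-linkage identity clustering of duplication copies
#'
#' Pairwise global-alignment identities (computed with
#' `Biostrings::pairwiseAlignment`) drive single-linkage clustering; the
#' tree is cut at `1 - linkage_threshold`. Cluster labels are renumbered
#' in genome coordinate order of their first member, so output is
#' deterministic. A lightweight stand-in for full phylogenetic analysis
#' of copy relationships.
#'
#' @param copies data.frame with `name`, `chrom`, `start`, `end`.
#' @param genome named character vector.
#' @param linkage_threshold identity at which copies join a cluster
#'   (default 0.95).
#' @return `copies` with an integer `cluster` column.
#' @export
cluster_by_identity <- function(copies, genome, linkage_threshold = 0.95) {
  n <- nrow(copies)
  if (n < 2L) stop("need >= 2 copies to cluster")
  seqs <- substring(genome[copies$chrom], copies$start + 1L, copies$end)
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pa <- Biostrings::pairwiseAlignment(seqs[i], seqs[j], type = "global")
      idm[i, j] <- idm[j, i] <- Biostrings::pid(pa) / 100
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - idm), method = "single")
  cl <- stats::cutree(hc, h = 1 - linkage_threshold)
  first <- vapply(split(seq_len(n), cl), min, integer(1L))
  copies$cluster <- match(as.character(cl), names(sort(first)))
  copies
}
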