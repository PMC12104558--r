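#' Signed inversion (reversal) distance
#'
#' Minimal number of signed inversions — reverse a contiguous block run and
#' flip its orientations — transforming one linear arrangement into another
#' with the same block content. Computed exactly through the extended
#' breakpoint graph: `d = (n + 1) - c + h + f`, where `c` counts alternating
#' cycles, `h` hurdles (minimal unoriented components on the framing
#' circle), and `f` is the fortress correction (1 when an odd number of
#' hurdles are all super-hurdles).
#'
#' @param a,b [arrangement()] objects (or plain signed integer vectors)
#'   over the same block set.
#' @return Integer inversion distance.
#' @examples
#' inversion_distance(parse_arrangement("SB2- SB1-"),
#'                    parse_arrangement("SB1+ SB2+"))  # 1
#' @seealso [bfs_distance_oracle()] for the exhaustive-search cross-check,
#'   [sorting_scenario()] for one optimal inversion sequence.
#' @export
inversion_distance <- function(a, b) {
  hp_distance(as_relative_perm(a, b))
}

# Hannenhalli-Pevzner distance of a signed permutation from the identity.
hp_distance <- function(p) {
  n <- length(p)
  if (n == 0L) return(0L)
  # double each element and frame with 0 and 2n+1; element i occupies
  # positions 2i and 2i+1 (1-based)
  u <- integer(2L * n + 2L)
  u[1L] <- 0L
  u[2L * n + 2L] <- 2L * n + 1L
  for (i in seq_len(n)) {
    x <- p[i]
    u[c(2L * i, 2L * i + 1L)] <-
      if (x > 0L) c(2L * x - 1L, 2L * x) else c(-2L * x, -2L * x - 1L)
  }
  pos <- integer(2L * n + 2L)
  pos[u + 1L] <- seq_len(2L * n + 2L)        # pos[v + 1] = position of value v

  # alternating cycles: black edges join position pairs (2i+1, 2i+2),
  # gray edges join value pairs (2i, 2i+1)
  cyc <- integer(2L * n + 2L)
  csize <- integer(0L)
  ncyc <- 0L
  for (v0 in u) {
    if (cyc[v0 + 1L] > 0L) next
    ncyc <- ncyc + 1L
    sz <- 0L
    v <- v0
    repeat {
      cyc[v + 1L] <- ncyc
      q <- pos[v + 1L]
      q2 <- if (q %% 2L == 1L) q + 1L else q - 1L   # black partner position
      w <- u[q2]
      cyc[w + 1L] <- ncyc
      sz <- sz + 2L
      v <- if (w %% 2L == 0L) w + 1L else w - 1L    # gray partner value
      if (v == v0) break
    }
    csize[ncyc] <- sz
  }

  # gray edges with spans and orientation (same position parity => the
  # reversal acting on the edge's black endpoints is useful => oriented)
  ne <- n + 1L
  e_lo <- integer(ne); e_hi <- integer(ne); e_cyc <- integer(ne)
  e_or <- logical(ne)
  for (i in 0:n) {
    p1 <- pos[2L * i + 1L]
    p2 <- pos[2L * i + 2L]
    e_lo[i + 1L] <- min(p1, p2)
    e_hi[i + 1L] <- max(p1, p2)
    e_cyc[i + 1L] <- cyc[2L * i + 1L]
    e_or[i + 1L] <- (p1 %% 2L) == (p2 %% 2L)
  }

  # components: union cycles whose gray edges interleave
  parent <- seq_len(ncyc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (ne >= 2L) {
    for (i in 1:(ne - 1L)) for (j in (i + 1L):ne) {
      inter <- (e_lo[i] < e_lo[j] && e_lo[j] < e_hi[i] && e_hi[i] < e_hi[j]) ||
               (e_lo[j] < e_lo[i] && e_lo[i] < e_hi[j] && e_hi[j] < e_hi[i])
      if (inter) {
        ri <- find(e_cyc[i]); rj <- find(e_cyc[j])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp_of_cycle <- vapply(seq_len(ncyc), find, integer(1L))
  comps <- unique(comp_of_cycle)

  # unoriented components: contain a nontrivial cycle and no oriented edge
  unoriented <- character(0L)
  is_unor <- logical(max(comps))
  for (cm in comps) {
    members <- which(comp_of_cycle == cm)
    nontrivial <- any(csize[members] > 2L)
    oriented <- any(e_or[e_cyc %in% members])
    is_unor[cm] <- nontrivial && !oriented
  }

  h <- 0L; f <- 0L
  if (any(is_unor)) {
    # component membership of each position, restricted to unoriented
    # components, read in circular position order and run-length compressed
    lab <- integer(2L * n + 2L)
    for (q in seq_len(2L * n + 2L)) {
      cm <- comp_of_cycle[cyc[u[q] + 1L]]
      if (is_unor[cm]) lab[q] <- cm
    }
    r <- rle(lab[lab > 0L])$values
    if (length(r) > 1L && r[1L] == r[length(r)]) r <- r[-length(r)]
    occ <- table(r)
    hurdles <- as.integer(names(occ)[occ == 1L])
    h <- length(hurdles)
    if (h %% 2L == 1L && h >= 3L && length(r) >= 3L) {
      m <- length(r)
      super <- vapply(hurdles, function(hh) {
        k <- which(r == hh)
        prv <- r[if (k == 1L) m else k - 1L]
        nxt <- r[if (k == m) 1L else k + 1L]
        prv == nxt && sum(r == prv) == 2L
      }, logical(1L))
      if (all(super)) f <- 1L
    }
  }

  (n + 1L) - ncyc + h + f
}

# cache of exhaustive BFS distance tables, keyed by n
.bfs_cache <- new.env(parent = emptyenv())

#' Exhaustive BFS distance table over all signed permutations
#'
#' Breadth-first search from the identity over the full reversal graph of
#' signed permutations of size `n`, using left-invariance of the distance.
#' Returns a raw vector `t` with `t[code + 1] = distance + 1` for every
#' signed permutation, where `code` encodes the permutation in base `2n`
#' (element `+k` as digit `k - 1`, `-k` as digit `n + k - 1`). Intended as
#' an independent verification oracle; results are cached per `n`.
#'
#' @param n permutation size, between 1 and 7 (the n = 7 table holds
#'   645,120 states).
#' @return Raw vector of length `(2n)^n`; zero entries are unreachable
#'   codes (not valid permutations).
#' @export
bfs_distance_table <- function(n) {
  stopifnot(n >= 1L, n <= 7L)
  key <- as.character(n)
  if (!is.null(.bfs_cache[[key]])) return(.bfs_cache[[key]])
  base <- 2L * n
  pw <- as.integer(round(base^(0:(n - 1L))))
  dist <- raw(as.integer(base^n))
  digit_id <- 0:(n - 1L)
  dist[sum(digit_id * pw) + 1L] <- as.raw(1L)
  frontier <- matrix(digit_id, nrow = 1L)
  revs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  level <- 1L
  while (nrow(frontier) > 0L) {
    level <- level + 1L
    nxt <- vector("list", nrow(revs))
    for (r in seq_len(nrow(revs))) {
      i <- revs[r, 1L]; j <- revs[r, 2L]
      nd <- frontier
      nd[, i:j] <- (frontier[, j:i, drop = FALSE] + n) %% base
      codes <- as.integer(nd %*% pw)
      new <- dist[codes + 1L] == as.raw(0L)
      if (any(new)) {
        nd <- nd[new, , drop = FALSE]
        codes <- codes[new]
        keep <- !duplicated(codes)
        dist[codes[keep] + 1L] <- as.raw(level)
        nxt[[r]] <- nd[keep, , drop = FALSE]
      }
    }
    nxt <- nxt[!vapply(nxt, is.null, logical(1L))]
    frontier <- if (length(nxt)) do.call(rbind, nxt) else matrix(integer(), ncol = n)
  }
  .bfs_cache[[key]] <- dist
  dist
}

# base-2n code of a signed permutation
perm_code <- function(p) {
  n <- length(p)
  d <- ifelse(p > 0L, p - 1L, n - p - 1L)
  as.integer(sum(d * (2 * n)^(seq_len(n) - 1L)))
}

#' Exact inversion distance by exhaustive breadth-first search
#'
#' Verification oracle for [inversion_distance()]: looks the pair up in the
#' full BFS table over the reversal graph (see [bfs_distance_table()]).
#' Independent of the breakpoint-graph machinery.
#'
#' @param a,b arrangements over the same block set.
#' @param max_n refuse inputs with more blocks than this (default 7; the
#'   search space grows as `2^n n!`).
#' @return Integer distance.
#' @export
bfs_distance_oracle <- function(a, b, max_n = 7L) {
  p <- as_relative_perm(a, b)
  if (length(p) > max_n) {
    stop("refusing BFS with ", length(p), " blocks (max_n = ", max_n, ")")
  }
  if (length(p) == 0L) return(0L)
  tab <- bfs_distance_table(length(p))
  as.integer(tab[perm_code(p) + 1L]) - 1L
}

#' Exhibit one optimal inversion sequence
#'
#' Greedy optimal sorting: at each step applies any inversion that reduces
#' [inversion_distance()] by one (Hannenhalli-Pevzner theory guarantees one
#' exists). The returned sequence has length exactly equal to the distance
#' and transforms `a` into `b`.
#'
#' @param a,b arrangements over the same block set.
#' @return A data.frame with one row per inversion (`step`, `from`, `to` —
#'   1-based block indices in the current arrangement, and the resulting
#'   arrangement as a string). Zero rows when `a` equals `b`.
#' @export
sorting_scenario <- function(a, b) {
  if (!inherits(a, "signed_arrangement")) a <- arrangement(as.character(abs(a)), sign(a))
  if (!inherits(b, "signed_arrangement")) b <- arrangement(as.character(abs(b)), sign(b))
  cur <- a
  d <- inversion_distance(cur, b)
  n <- length(cur$ids)
  out <- list()
  step <- 0L
  while (d > 0L) {
    found <- FALSE
    for (i in seq_len(n)) {
      for (j in i:n) {
        cand <- apply_inversion(cur, i, j)
        if (inversion_distance(cand, b) == d - 1L) {
          step <- step + 1L
          cur <- cand
          d <- d - 1L
          out[[step]] <- data.frame(step = step, from = i, to = j,
                                    arrangement = format(cur),
                                    stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) stop("internal error: no distance-reducing inversion found")
  }
  if (length(out) == 0L) {
    return(data.frame(step = integer(), from = integer(), to = integer(),
                      arrangement = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Enumerate candidate ancestral insertion configurations
#'
#' Builds every ancestral arrangement obtainable by inserting a contiguous
#' run of the `inserted` blocks — all orders and all orientation
#' assignments — into one of the internal gaps of the `base` arrangement.
#' With the default base of four blocks and two inserted blocks this yields
#' `3 * (2! * 2^2) = 24` configurations.
#'
#' @param base the pre-insertion arrangement (default `SB1+ SB2+ SB3+
#'   SB4+`).
#' @param inserted character vector of block ids inserted together at one
#'   locus (default `SB5`, `SB6`).
#' @param loci integer vector of insertion gaps: gap `k` means between base
#'   block `k` and `k + 1`. Default: all internal gaps.
#' @return A list of configurations, each a list with `locus` (label like
#'   `"SB1-SB2"`), `gap` (integer), `insert` (the inserted run) and
#'   `arrangement` (the full ancestral arrangement); class
#'   `ancestral_configs`.
#' @export
enumerate_ancestral_configs <- function(base = parse_arrangement("SB1+ SB2+ SB3+ SB4+"),
                                        inserted = c("SB5", "SB6"),
                                        loci = NULL) {
  if (any(inserted %in% base$ids)) stop("inserted blocks must be disjoint from base")
  nb <- length(base$ids)
  if (is.null(loci)) loci <- seq_len(nb - 1L)
  if (any(loci < 1L | loci > nb - 1L)) stop("locus gap outside base arrangement")
  m <- length(inserted)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  ords <- perms(inserted)
  sgn <- as.matrix(expand.grid(rep(list(c(1L, -1L)), m)))
  out <- list()
  seen <- character(0L)
  for (g in loci) {
    for (ord in ords) {
      for (s in seq_len(nrow(sgn))) {
        ins <- arrangement(ord, sgn[s, ])
        arr <- insert_blocks(base, ins, after = g)
        key <- format(arr)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- list(
          locus = paste0(base$ids[g], "-", base$ids[g + 1L]),
          gap = g, insert = ins, arrangement = arr)
      }
    }
  }
  structure(out, class = "ancestral_configs")
}

#' @export
print.ancestral_configs <- function(x, ...) {
  cat("<", length(x), " candidate ancestral configurations>\n", sep = "")
  for (cfg in x) {
    cat(sprintf("  %-9s %s\n", cfg$locus, format(cfg$arrangement)))
  }
  invisible(x)
}

#' Score ancestral configurations by inversion parsimony
#'
#' For each candidate ancestral configuration, computes the inversion
#' distance to every extant arrangement (after excluding duplicated blocks,
#' which the parsimony model removes before the edit distance), sums them,
#' and flags every configuration attaining the minimum total. Ties are all
#' reported.
#'
#' @param configs result of [enumerate_ancestral_configs()].
#' @param extant named list of [arrangement()]s, one per species.
#' @param exclude_ids block ids dropped from extant arrangements before
#'   distance computation (default `"SB5p"`, the duplicated block).
#' @return A `scenario_table` data.frame: `locus`, `insert`, one distance
#'   column per species, `total`, `rank`, and logical `minimal`.
#' @export
score_scenarios <- function(configs, extant, exclude_ids = "SB5p") {
  if (!length(extant) || is.null(names(extant))) {
    stop("extant must be a named list of arrangements")
  }
  ext <- lapply(extant, drop_blocks, ids = exclude_ids)
  dm <- sapply(ext, function(e) {
    vapply(configs, function(cfg) inversion_distance(cfg$arrangement, e), integer(1L))
  })
  dm <- matrix(dm, nrow = length(configs),
               dimnames = list(NULL, names(extant)))
  total <- rowSums(dm)
  tab <- data.frame(
    locus = vapply(configs, function(cfg) cfg$locus, character(1L)),
    insert = vapply(configs, function(cfg) format(cfg$insert), character(1L)),
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(dm))
  tab$total <- as.integer(total)
  tab$rank <- rank(total, ties.method = "min")
  tab$minimal <- total == min(total)
  class(tab) <- c("scenario_table", "data.frame")
  attr(tab, "species") <- names(extant)
  tab
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("Ancestral insertion scenarios (", nrow(x), " configurations)\n", sep = "")
  y <- as.data.frame(x)
  print(y[order(y$total, y$locus, y$insert), ], row.names = FALSE)
  mins <- x[x$minimal, ]
  cat("minimum total: ", min(x$total), " inversions, attained by ",
      nrow(mins), " configuration(s)\n", sep = "")
  invisible(x)
}
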