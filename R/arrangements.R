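#' Signed synteny-block arrangements
#'
#' A signed arrangement is an ordered list of oriented synteny blocks on one
#' linear chromosome or locus: the unit of rearrangement arithmetic. Blocks
#' carry an identifier (e.g. `"SB1"`, `"SB5p"`) and an orientation sign.
#'
#' @param ids character vector of block identifiers, unique within the
#'   arrangement.
#' @param signs integer or character vector of orientations: `+1`/`-1` or
#'   `"+"`/`"-"`. Defaults to all `+`.
#' @return An object of class `signed_arrangement`: a list with components
#'   `ids` (character) and `signs` (integer, +1/-1).
#' @examples
#' arrangement(c("SB1", "SB6", "SB5", "SB2"), c("+", "-", "-", "+"))
#' @export
arrangement <- function(ids, signs = NULL) {
  ids <- as.character(ids)
  if (is.null(signs)) signs <- rep(1L, length(ids))
  if (is.character(signs)) {
    if (!all(signs %in% c("+", "-"))) stop("signs must be '+' or '-'")
    signs <- ifelse(signs == "+", 1L, -1L)
  }
  signs <- as.integer(signs)
  if (length(ids) != length(signs)) stop("ids and signs differ in length")
  if (!all(signs %in% c(-1L, 1L))) stop("signs must be +1 or -1")
  if (anyDuplicated(ids)) {
    stop("duplicate block ids in arrangement: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(ids))) stop("empty block id")
  structure(list(ids = ids, signs = signs), class = "signed_arrangement")
}

#' Parse a signed arrangement from sign-suffixed tokens
#'
#' Accepts tokens of the form `"SB1+"` / `"SB6-"`, either as a character
#' vector or a single whitespace-separated string.
#'
#' @param x character vector of tokens, or one string of tokens.
#' @return A [arrangement()] object.
#' @examples
#' parse_arrangement("SB1+ SB6- SB5- SB2+")
#' @export
parse_arrangement <- function(x) {
  if (length(x) == 1L && grepl("\\s", x)) x <- strsplit(trimws(x), "\\s+")[[1L]]
  sgn <- substring(x, nchar(x))
  if (!all(sgn %in% c("+", "-"))) {
    stop("each token must end in '+' or '-': ",
         paste(x[!sgn %in% c("+", "-")], collapse = ", "))
  }
  arrangement(substring(x, 1L, nchar(x) - 1L), sgn)
}

#' @export
format.signed_arrangement <- function(x, ...) {
  paste(paste0(x$ids, ifelse(x$signs > 0, "+", "-")), collapse = " ")
}

#' @export
print.signed_arrangement <- function(x, ...) {
  cat("<signed arrangement> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
length.signed_arrangement <- function(x) length(x$ids)

#' Apply one signed inversion to an arrangement
#'
#' Reverses the contiguous block run `i:j` and flips its orientations.
#'
#' @param arr a [arrangement()].
#' @param i,j 1-based first and last block of the inverted segment,
#'   `i <= j`.
#' @return The rearranged `signed_arrangement`.
#' @examples
#' apply_inversion(parse_arrangement("SB1+ SB2+ SB3+"), 1, 2)
#' @export
apply_inversion <- function(arr, i, j) {
  stopifnot(inherits(arr, "signed_arrangement"))
  n <- length(arr$ids)
  if (!(i >= 1 && j <= n && i <= j)) stop("invalid inversion bounds")
  idx <- j:i
  arr$ids[i:j] <- arr$ids[idx]
  arr$signs[i:j] <- -arr$signs[idx]
  arr
}

#' Drop blocks from an arrangement by id
#'
#' Used to exclude duplicated blocks (e.g. `SB5p`) before distance
#' computation, as the parsimony model requires unique block content.
#'
#' @param arr a [arrangement()].
#' @param ids block ids to remove; absent ids are ignored.
#' @return The reduced `signed_arrangement`.
#' @export
drop_blocks <- function(arr, ids) {
  keep <- !(arr$ids %in% ids)
  arrangement(arr$ids[keep], arr$signs[keep])
}

#' Insert a run of blocks into an arrangement
#'
#' @param arr a [arrangement()].
#' @param insert a `signed_arrangement` of the inserted run.
#' @param after 0-based gap index: insert after block `after` (0 prepends).
#' @return The extended `signed_arrangement`.
#' @export
insert_blocks <- function(arr, insert, after) {
  n <- length(arr$ids)
  if (after < 0 || after > n) stop("insertion gap outside arrangement")
  arrangement(append(arr$ids, insert$ids, after = after),
              append(arr$signs, insert$signs, after = after))
}

# relative signed permutation pi with d(a, b) == d(pi, identity)
as_relative_perm <- function(a, b) {
  if (inherits(a, "signed_arrangement")) {
    ia <- a$ids; sa <- a$signs
  } else {
    ia <- as.character(abs(a)); sa <- sign(a)
  }
  if (inherits(b, "signed_arrangement")) {
    ib <- b$ids; sb <- b$signs
  } else {
    ib <- as.character(abs(b)); sb <- sign(b)
  }
  if (length(ia) != length(ib) || !setequal(ia, ib)) {
    d1 <- setdiff(ia, ib); d2 <- setdiff(ib, ia)
    stop("block sets differ; only in first: {",
         paste(d1, collapse = ","), "}, only in second: {",
         paste(d2, collapse = ","), "}")
  }
  pos <- match(ia, ib)
  as.integer(sb[pos] * sa * pos)
}
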