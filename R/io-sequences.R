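#' Read a FASTA file into a named genome vector
#'
#' Sequences are uppercased and returned in file order as a named character
#' vector (names = chromosome/record identifiers). All internal coordinates
#' in this package are 0-based half-open; FASTA carries no coordinates so
#' only case normalisation applies here.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(out))) stop("duplicate sequence names in ", path)
  out
}

#' Write a named genome vector to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# shared constructor: the common currency of the synteny, BASD and repeat
# stages. Coordinates 0-based half-open on both sides.
alignment_hits <- function(query_name, query_start, query_end,
                           target_name, target_start, target_end,
                           strand, matches = NA_integer_, block_len = NULL,
                           identity = NULL, is_primary = TRUE) {
  if (is.null(block_len)) block_len <- as.integer(target_end - target_start)
  if (is.null(identity)) identity <- ifelse(is.na(matches), NA_real_,
                                            matches / block_len)
  df <- data.frame(
    query_name = as.character(query_name),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    target_name = as.character(target_name),
    target_start = as.integer(target_start), target_end = as.integer(target_end),
    strand = as.character(strand),
    matches = as.integer(matches), block_len = as.integer(block_len),
    identity = as.numeric(identity),
    is_primary = as.logical(is_primary),
    stringsAsFactors = FALSE)
  bad <- with(df, query_start >= query_end | target_start >= target_end)
  if (any(bad)) stop("degenerate interval (start >= end) in hits: rows ",
                     paste(head(which(bad)), collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  oob <- !is.na(df$identity) & (df$identity < 0 | df$identity > 1)
  if (any(oob)) stop("identity outside [0,1]")
  class(df) <- c("alignment_hits", "data.frame")
  df
}

empty_hits <- function() {
  alignment_hits(character(0), integer(0), integer(0), character(0),
                 integer(0), integer(0), character(0), integer(0),
                 is_primary = logical(0))
}

#' Read minimap2 PAF alignments
#'
#' Parses the 12 mandatory tab-separated PAF columns plus the `tp:A` tag.
#' PAF is already 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged. `tp:A:P` marks a
#' primary alignment; any other (or missing) value is non-primary. All
#' other tags are ignored.
#'
#' @param path PAF file.
#' @return An `alignment_hits` data.frame: `query_name`, `query_start`,
#'   `query_end`, `target_name`, `target_start`, `target_end`, `strand`,
#'   `matches`, `block_len`, `identity` (= matches / block_len),
#'   `is_primary`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 12L
  if (any(short)) stop("PAF line ", which(short)[1L],
                       " has fewer than 12 mandatory columns")
  get <- function(k) vapply(fields, `[[`, character(1L), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.integer(get(k)))
    if (anyNA(v)) stop("non-integer ", what, " in PAF at line ",
                       which(is.na(v))[1L])
    v
  }
  tp <- vapply(fields, function(f) {
    tags <- f[-(1:12)]
    hit <- grep("^tp:A:", tags, value = TRUE)
    if (length(hit)) sub("^tp:A:", "", hit[1L]) else NA_character_
  }, character(1L))
  alignment_hits(
    query_name = get(1L),
    query_start = num(3L, "query start"), query_end = num(4L, "query end"),
    target_name = get(6L),
    target_start = num(8L, "target start"), target_end = num(9L, "target end"),
    strand = get(5L),
    matches = num(10L, "match count"), block_len = num(11L, "block length"),
    is_primary = !is.na(tp) & tp == "P")
}

#' Write alignments as PAF
#'
#' Inverse of [read_paf()]; emits the 12 mandatory columns plus `tp:A`.
#' Query/target lengths (columns 2 and 7), not tracked internally, are
#' written as the interval ends.
#'
#' @param hits `alignment_hits` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(hits, path) {
  lines <- with(hits, paste(
    query_name, query_end, query_start, query_end, strand,
    target_name, target_end, target_start, target_end,
    matches, block_len, 60L,
    paste0("tp:A:", ifelse(is_primary, "P", "S")),
    sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Expects the default 12 columns (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`). BLAST's 1-based
#' inclusive coordinates are converted to 0-based half-open; a hit with
#' `sstart > send` is recorded as strand `"-"` with subject coordinates
#' swapped so that `target_start < target_end` always holds.
#'
#' @param path outfmt-6 file.
#' @return An `alignment_hits` data.frame (see [read_paf()]). `identity` is
#'   `pident / 100`; `matches` is `length - mismatch`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("qseqid", "sseqid", "pident", "length",
                                        "mismatch", "gapopen", "qstart", "qend",
                                        "sstart", "send", "evalue", "bitscore"))
  if (nrow(df) == 0L) return(empty_hits())
  if (any(df$pident < 0 | df$pident > 100)) {
    stop("pident outside [0,100] at line ",
         which(df$pident < 0 | df$pident > 100)[1L])
  }
  minus <- df$sstart > df$send
  t0 <- ifelse(minus, df$send, df$sstart) - 1L
  t1 <- ifelse(minus, df$sstart, df$send)
  alignment_hits(
    query_name = df$qseqid,
    query_start = df$qstart - 1L, query_end = df$qend,
    target_name = df$sseqid,
    target_start = t0, target_end = t1,
    strand = ifelse(minus, "-", "+"),
    matches = df$length - df$mismatch, block_len = df$length,
    identity = df$pident / 100)
}

#' Write alignments as BLAST tabular (outfmt 6)
#'
#' Inverse of [read_blast_tab()]: converts internal 0-based half-open
#' coordinates back to 1-based inclusive and encodes minus-strand hits by
#' swapping subject start/end.
#'
#' @param hits `alignment_hits` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  minus <- hits$strand == "-"
  ss <- ifelse(minus, hits$target_end, hits$target_start + 1L)
  se <- ifelse(minus, hits$target_start + 1L, hits$target_end)
  lines <- paste(hits$query_name, hits$target_name,
                 formatC(hits$identity * 100, format = "f", digits = 3),
                 hits$block_len, hits$block_len - hits$matches, 0L,
                 hits$query_start + 1L, hits$query_end, ss, se,
                 "0.0", 100L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
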