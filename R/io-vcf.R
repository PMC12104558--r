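#' Read heterozygous-SNP candidate records from a VCF
#'
#' Extracts per-site records for one sample, splitting multiallelic sites
#' into one record per ALT allele. The allele fraction is computed from the
#' sample's `AD` field as `alt / (ref + alt)` when present, falling back to
#' the `AF` INFO field; records with neither (or zero depth) are skipped
#' and the skip count reported via a message.
#'
#' @param path VCF 4.x file (plain text or gzipped).
#' @param sample sample name; defaults to the first sample.
#' @return A data.frame of SNP records: `chrom`, `pos` (1-based, as in
#'   VCF), `ref`, `alt`, `depth`, `allele_fraction`, `is_snv` (TRUE iff
#'   both alleles are single bases).
#' @export
read_vcf_snps <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  samples <- colnames(v@gt)[-1L]
  if (is.null(sample)) sample <- samples[1L]
  if (!sample %in% samples) stop("sample not in VCF: ", sample)
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, sample]))
  af_info <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF")))

  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    adv <- if (!is.na(ad[i])) suppressWarnings(as.integer(strsplit(ad[i], ",")[[1L]])) else NULL
    for (k in seq_along(alts)) {
      if (!is.null(adv) && length(adv) >= k + 1L && !anyNA(adv)) {
        depth <- adv[1L] + adv[k + 1L]
        afrac <- if (depth > 0L) adv[k + 1L] / depth else NA_real_
      } else if (!is.na(af_info[i])) {
        depth <- if (!is.na(dp[i])) dp[i] else NA_integer_
        afrac <- af_info[i]
      } else {
        afrac <- NA_real_
        depth <- NA_integer_
      }
      if (is.na(afrac)) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        depth = depth, allele_fraction = afrac,
        is_snv = nchar(fix[i, "REF"]) == 1L & nchar(alts[k]) == 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) message(skipped, " record(s) skipped (no depth/AF information)")
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), depth = integer(),
                      allele_fraction = numeric(), is_snv = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Write SNP records as a minimal VCF 4.2 file
#'
#' Deterministic, byte-stable output (fixed header, no timestamps): the
#' same record table always yields an identical file. Emits one sample
#' column with `GT:AD:DP`; the AD pair is reconstructed from `depth` and
#' `allele_fraction`.
#'
#' @param snps data.frame as returned by [read_vcf_snps()].
#' @param path output file.
#' @param sample sample name for the single genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, sample = "sample1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  alt_n <- as.integer(round(snps$allele_fraction * snps$depth))
  ref_n <- snps$depth - alt_n
  body <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS",
                ".", "GT:AD:DP",
                paste0("0/1:", ref_n, ",", alt_n, ":", snps$depth),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
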