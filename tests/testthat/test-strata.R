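test_that("depth mode estimation uses the histogram with smallest-depth ties", {
  expect_equal(estimate_depth_mode(data.frame(depth = rep(42L, 150))), 42L)
  bim <- data.frame(depth = c(rep(40L, 1000), rep(80L, 1000)))
  expect_equal(estimate_depth_mode(bim), 40L)
  expect_error(estimate_depth_mode(data.frame(depth = 1:50)), ">= 100")

  set.seed(8)
  pois <- data.frame(depth = rpois(5000, 42))
  expect_true(estimate_depth_mode(pois) %in% 40:44)
})

test_that("the heterozygosity filter applies the half/1.5x mode rule inclusively", {
  cfg <- snp_filter_config(depth_mode = 42L)
  expect_equal(cfg$depth_lo, 21)
  expect_equal(cfg$depth_hi, 63)

  snps <- data.frame(
    chrom = "c", pos = 1:8, ref = "A",
    alt = c("T", "T", "AT", "T", "T", "T", "T", "T"),
    depth = c(40L, 40L, 40L, 40L, 21L, 63L, 20L, 64L),
    allele_fraction = c(0.5, 0.2, 0.5, 0.25, 0.75, 0.5, 0.5, 0.5),
    is_snv = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  kept <- filter_het_snps(snps, cfg)
  expect_equal(kept$pos, c(1L, 4L, 5L, 6L))  # AF 0.2, indel, depth 20/64 out

  # explicit overrides for data-specific cutoffs
  over <- snp_filter_config(42L, depth_lo = 21, depth_hi = 65)
  expect_equal(over$depth_hi, 65)
})

test_that("narrowing filter windows never increases the kept count", {
  set.seed(15)
  snps <- data.frame(chrom = "c", pos = 1:2000, ref = "A", alt = "T",
                     depth = rpois(2000, 42),
                     allele_fraction = runif(2000), is_snv = TRUE,
                     stringsAsFactors = FALSE)
  wide <- nrow(filter_het_snps(snps, snp_filter_config(42L, af_min = 0.2,
                                                       af_max = 0.8)))
  mid <- nrow(filter_het_snps(snps, snp_filter_config(42L)))
  narrow <- nrow(filter_het_snps(snps, snp_filter_config(
    42L, af_min = 0.4, af_max = 0.6, depth_lo = 30, depth_hi = 50)))
  expect_lte(mid, wide)
  expect_lte(narrow, mid)
})

test_that("windowed density counts, masks and conserves totals", {
  snps <- data.frame(chrom = "c", pos = c(1:10 * 1000L, 250000L),
                     stringsAsFactors = FALSE)
  mask <- data.frame(chrom = "c", start = 200000L, end = 300000L)
  tr <- windowed_density(snps, "c", 400000L, window_bp = 100000L, mask = mask)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$density[1], 0.1)       # 10 SNPs / 100 kb
  expect_true(tr$masked[3])
  expect_true(is.na(tr$density[3]))
  expect_equal(sum(tr$count[!tr$masked]), 10L)
  expect_equal(sum(tr$count), nrow(snps))
})

test_that("boundary detection recovers a planted density step", {
  cfg <- snp_track_config(71, par_rate = 0.05, stratum_rate = 1.0,
                          chrom_len = 10e6, boundary = 5e6)
  tr <- simulate_snp_track(cfg)
  track <- windowed_density(tr$snps, "neoX", 10e6, window_bp = 100000L)
  call <- detect_boundary(track)
  expect_true(call$valid)
  expect_lte(abs(call$boundary - 5e6), 100000L)
  expect_gt(call$segments$mean_density[2], call$segments$mean_density[1])

  # determinism
  call2 <- detect_boundary(windowed_density(
    simulate_snp_track(cfg)$snps, "neoX", 10e6, window_bp = 100000L))
  expect_identical(call$boundary, call2$boundary)
})

test_that("flat tracks and degenerate steps are handled", {
  flat <- data.frame(chrom = "c", start = 0:19 * 1e5, end = 1:20 * 1e5,
                     count = 10L, density = 0.1, masked = FALSE,
                     stringsAsFactors = FALSE)
  class(flat) <- c("density_track", "data.frame")
  expect_false(detect_boundary(flat)$valid)

  step1 <- flat
  step1$density <- c(0, rep(5, 19))
  step1$count <- as.integer(step1$density * 100)
  call <- detect_boundary(step1)
  expect_true(call$valid)
  expect_equal(call$boundary, 1e5)

  expect_error(detect_boundary(flat[1:5, ]), ">= 10")
})

test_that("stratum subdivision labels S1a/S1b and rejects bad intervals", {
  cfg <- snp_track_config(73, par_rate = 0.05, stratum_rate = 1.5)
  tr <- simulate_snp_track(cfg)
  track <- windowed_density(tr$snps, "neoX", 4e6, window_bp = 100000L)
  call <- detect_boundary(track)
  expect_true(call$valid)
  sub <- subdivide_stratum(call, c(2.8e6, 3.2e6))
  expect_setequal(c("Strata0_PAR", "Strata1", "S1a", "S1b"),
                  sub$segments$label)
  s1a <- sub$segments[sub$segments$label == "S1a", ]
  expect_true(s1a$mean_density > 0)
  expect_error(subdivide_stratum(call, c(call$boundary, 3e6)), "strictly inside")
})
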