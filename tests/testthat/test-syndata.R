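test_that("karyotype simulation reduces the haploid count by one per fusion", {
  cfg <- sim_config(seed = 3)
  ka <- simulate_karyotypes(cfg)
  expect_length(ka$ancestor, 24L)
  expect_length(ka$species$osi, 24L - 11L)
  expect_length(ka$species$tok, 23L)
  expect_length(ka$species$mue, 22L)

  cfg0 <- sim_config(seed = 3, fusion_plan = list(s = list()))
  expect_length(simulate_karyotypes(cfg0)$species$s, 24L)

  bad <- sim_config(seed = 3, fusion_plan = list(
    s = list(c("A", "B"), c("B", "C"))))  # B consumed by the first fusion
  expect_error(simulate_karyotypes(bad), "consumed")
})

test_that("locus history applies the insertion and records inversions", {
  cfg <- sim_config(seed = 9, inversions_per_lineage = 0L)
  h <- simulate_locus_history(cfg)
  expect_equal(format(h$ancestor), "SB1+ SB6- SB5- SB2+ SB3+ SB4+")
  expect_equal(format(h$species$osi), format(h$ancestor))
  expect_equal(h$truth$insertion_locus, "SB1-SB2")

  cfg_none <- sim_config(seed = 9, inversions_per_lineage = 0L,
                         insertion_spec = list(
                           blocks = arrangement(character(0)), gap = 1L))
  h0 <- simulate_locus_history(cfg_none)
  expect_equal(format(h0$species$osi), "SB1+ SB2+ SB3+ SB4+")
})

test_that("computed distance never exceeds the number of applied inversions", {
  for (seed in 1:8) {
    k <- (seed %% 3L) + 1L
    cfg <- sim_config(seed = seed, inversions_per_lineage = k)
    h <- simulate_locus_history(cfg)
    for (sp in names(h$species)) {
      d <- inversion_distance(h$ancestor, h$species[[sp]])
      expect_lte(d, k)
      expect_equal(d, bfs_distance_oracle(h$ancestor, h$species[[sp]]))
      # conservation: inversions never gain or lose blocks
      expect_setequal(h$species[[sp]]$ids, h$ancestor$ids)
    }
  }
})

test_that("sequence emission is deterministic and honours the truth tables", {
  cfg <- locus_sim_config(seed = 21)
  s1 <- emit_sequences(cfg)
  s2 <- emit_sequences(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)

  # every truth interval lies inside its chromosome; copies do not overlap
  for (sp in names(s1$genomes)) {
    len <- nchar(s1$genomes[[sp]][["Xq"]])
    tb <- s1$truth$basd[s1$truth$basd$species == sp, ]
    expect_true(all(tb$start >= 0 & tb$end <= len))
    tb <- tb[order(tb$start), ]
    if (nrow(tb) > 1) expect_true(all(tb$start[-1] >= tb$end[-nrow(tb)]))
  }
})

test_that("planted duplication identity follows the binomial mutation model", {
  extract_copies <- function(sim, sp) {
    tb <- sim$truth$basd[sim$truth$basd$species == sp, ]
    substring(sim$genomes[[sp]][["Xq"]], tb$start + 1, tb$end)
  }
  sim_exact <- emit_sequences(locus_sim_config(
    seed = 2, basd_spec = list(length = 6000L, identity = 1.0,
                               n_copies = 2L, flanks = FALSE)))
  cps <- extract_copies(sim_exact, "osi")
  expect_identical(cps[1], cps[2])

  sim <- emit_sequences(locus_sim_config(seed = 4))
  cps <- extract_copies(sim, "osi")
  pid <- ytrace:::seq_identity(cps[1], cps[2])
  # Binomial(6000, 0.02) pairwise mismatches: 0.98 +/- 3 sd
  expect_gt(pid, 0.965)
  expect_lt(pid, 0.995)
})

test_that("repeat planting emits the configured copy count", {
  sim <- emit_sequences(locus_sim_config(seed = 6))
  expect_equal(nrow(sim$truth$repeats), 52L)
  expect_equal(nrow(sim$hits$repeat_unit), 52L)
  expect_true(all(sim$truth$repeats$end <= nchar(sim$het[["het"]])))
})

test_that("SNP track obeys the configured Poisson densities", {
  cfg <- sim_config(seed = 17)  # 0.1 and 5 per kb, 10 Mb, boundary 5 Mb
  tr <- simulate_snp_track(cfg)
  n_par <- sum(tr$snps$pos <= 5e6)
  n_str <- sum(tr$snps$pos > 5e6)
  expect_lt(abs(n_par - 500), 3 * sqrt(500) + 1)
  expect_lt(abs(n_str - 25000), 3 * sqrt(25000) + 1)

  none <- sim_config(seed = 17, snp_spec = list(
    chrom = "neoX", chrom_len = 1e6, boundary = 5e5, par_rate = 0,
    stratum_rate = 1.0, depth_mode = 42L, bad_fraction = 0))
  tr0 <- simulate_snp_track(none)
  expect_equal(sum(tr0$snps$pos <= 5e5), 0L)
})
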