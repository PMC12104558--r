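mk_hits <- function(tstarts, tends, query = "q", strand = "+",
                    identity = 0.98) {
  alignment_hits(query_name = query, query_start = 0L,
                 query_end = tends - tstarts,
                 target_name = "chr", target_start = tstarts,
                 target_end = tends, strand = strand,
                 matches = as.integer(round((tends - tstarts) * identity)),
                 block_len = tends - tstarts, identity = identity)
}

test_that("length filtering keeps hits of exactly the cutoff", {
  h <- mk_hits(c(0L, 1000L, 2000L), c(400L, 1500L, 2600L))
  f <- filter_hits_by_length(h)
  expect_equal(nrow(f), 2L)                  # 400 bp dropped
  expect_true(all(f$block_len >= 500L))
  expect_equal(nrow(filter_hits_by_length(h[0, ])), 0L)
})

test_that("split-hit merging respects the gap rule and strand partition", {
  near <- mk_hits(c(0L, 4500L), c(2000L, 7000L))       # gap 2500
  m <- merge_split_hits(near)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 7000L))
  expect_true(m$is_candidate)

  far <- mk_hits(c(0L, 5500L), c(2000L, 7000L))        # gap 3500
  m2 <- merge_split_hits(far)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$is_candidate, c(FALSE, FALSE))       # spans 2000 and 1500

  opp <- rbind(mk_hits(0L, 2000L, strand = "+"),
               mk_hits(1000L, 3000L, strand = "-"))
  class(opp) <- c("alignment_hits", "data.frame")
  expect_equal(nrow(merge_split_hits(opp)), 2L)        # strands never merge
})

test_that("iterative detection recovers planted copies and nothing else", {
  cfg <- basd_recovery_config(seed = 41, n_copies = 4)
  sim <- emit_sequences(cfg)
  det <- iterate_basd_detection(sim$genomes$s1,
                                c(seed = sim$masters$basd), prefix = "To")
  truth <- sim$truth$basd
  expect_equal(nrow(det), 4L)
  expect_equal(det$name, sprintf("To-BASD%03d", 1:4))
  for (i in seq_len(nrow(det))) {
    mid <- (det$start[i] + det$end[i]) %/% 2
    expect_true(any(truth$start <= mid & mid < truth$end))
    expect_gte(det$identity_to_seed[i], 0.9)
    expect_gte(det$length[i], 5000L)
  }

  null <- shuffle_genome(sim$genomes$s1, seed = 1)
  expect_equal(nrow(iterate_basd_detection(null, c(seed = sim$masters$basd))),
               0L)
})

test_that("sub-threshold planted copies stay candidates, not final calls", {
  cfg <- basd_recovery_config(seed = 43, n_copies = 2)
  cfg$basd_spec$length <- 4500L
  sim <- emit_sequences(cfg)
  det <- iterate_basd_detection(sim$genomes$s1, c(seed = sim$masters$basd))
  expect_equal(nrow(det), 0L)
  # same pipeline with the final threshold below the copy length finds both
  det2 <- iterate_basd_detection(sim$genomes$s1, c(seed = sim$masters$basd),
                                 min_final_len = 4000L)
  expect_equal(nrow(det2), 2L)
})

test_that("detection is idempotent and monotone in its thresholds", {
  cfg <- basd_recovery_config(seed = 47, n_copies = 3)
  sim <- emit_sequences(cfg)
  det <- iterate_basd_detection(sim$genomes$s1, c(seed = sim$masters$basd))
  seqs <- substring(sim$genomes$s1["Xq"], det$start + 1, det$end)
  names(seqs) <- det$name
  det2 <- iterate_basd_detection(sim$genomes$s1, seqs)
  expect_equal(det2[, c("chrom", "start", "end")],
               det[, c("chrom", "start", "end")])
  for (thr in c(5000L, 6500L, 8000L)) {
    di <- iterate_basd_detection(sim$genomes$s1, c(seed = sim$masters$basd),
                                 min_final_len = thr)
    expect_lte(nrow(di), nrow(det))
  }
})

test_that("region counting assigns copies by midpoint", {
  regions <- data.frame(chrom = "chr", start = c(0L, 10000L),
                        end = c(10000L, 20000L), name = c("r1", "r2"),
                        stringsAsFactors = FALSE)
  copies <- data.frame(chrom = "chr",
                       start = c(100L, 2000L, 5000L, 9000L, 25000L),
                       end = c(1100L, 3000L, 6000L, 12000L, 26000L))
  tab <- count_by_region(copies, regions)
  expect_equal(tab$count[tab$region == "r1"], 3L)
  expect_equal(tab$count[tab$region == "r2"], 1L)  # straddler: midpoint 10500
  expect_equal(tab$count[tab$region == "unassigned"], 1L)
  expect_equal(sum(count_by_region(copies[0, ], regions)$count), 0L)
  bad <- regions; bad$start[2] <- 5000L
  expect_error(count_by_region(copies, bad), "overlap")
})

test_that("flank provenance labels recover the planted split configuration", {
  cfg <- locus_sim_config(seed = 51)
  sim <- emit_sequences(cfg)
  genome <- sim$genomes$osi
  tb <- sim$truth$basd[sim$truth$basd$species == "osi", ]
  tb <- tb[order(tb$start), ]
  copies <- data.frame(name = c("c1", "c2"), chrom = "Xq",
                       start = tb$start, end = tb$end,
                       stringsAsFactors = FALSE)
  fl <- assign_flanks(copies, genome, sim$masters$flanks)
  expect_equal(fl$upstream, c("none", "2a"))
  expect_equal(fl$downstream, c("2g", "none"))

  mech <- infer_mechanism(fl)
  expect_equal(mech$call, "circular-intermediate")
})

test_that("mechanism inference distinguishes direct insertion and degenerate input", {
  direct <- data.frame(name = c("c1", "c2"),
                       upstream = c("2a", "none"),
                       downstream = c("none", "2g"),
                       stringsAsFactors = FALSE)
  expect_equal(infer_mechanism(direct)$call, "direct-insertion")

  unk <- data.frame(name = c("c1", "c2"), upstream = c("none", "none"),
                    downstream = c("2g", "none"), stringsAsFactors = FALSE)
  expect_equal(infer_mechanism(unk)$call, "undetermined")

  one <- direct[1, ]
  m <- infer_mechanism(one)
  expect_equal(m$call, "undetermined")
  expect_match(m$note, "expected 2")
})

test_that("identity clustering separates copies from distinct masters", {
  set.seed(61)
  m1 <- ytrace:::random_bases(3000L)
  m2 <- ytrace:::random_bases(3000L)  # ~25% cross-difference to m1
  cps <- c(m1, ytrace:::mutate_seq(m1, 0.01), m2, ytrace:::mutate_seq(m2, 0.01))
  genome <- c(chr = paste(cps, collapse = ""))
  copies <- data.frame(name = paste0("c", 1:4), chrom = "chr",
                       start = (0:3) * 3000L, end = (1:4) * 3000L,
                       stringsAsFactors = FALSE)
  cl <- cluster_by_identity(copies, genome, linkage_threshold = 0.95)
  expect_equal(cl$cluster, c(1L, 1L, 2L, 2L))

  two <- cluster_by_identity(copies[1:2, ], genome)
  expect_equal(two$cluster, c(1L, 1L))
  expect_error(cluster_by_identity(copies[1, ], genome), ">= 2")
})
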