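# shared fixtures, built in code at test time

# compact simulation tuned for duplication-recovery runs: 8 base blocks
# give up to 9 internal boundaries for planted copies, all separated by a
# full block (>> 3 kb)
basd_recovery_config <- function(seed, n_copies, identity = 0.96,
                                 block_len = 8000L) {
  sim_config(
    seed = seed,
    block_layout = parse_arrangement(paste0("B", 1:8, "+", collapse = " ")),
    insertion_spec = list(blocks = parse_arrangement("SB6- SB5-"), gap = 1L),
    inversions_per_lineage = 0L,
    lineages = "s1",
    block_len = block_len,
    basd_spec = list(length = 6000L, identity = identity,
                     n_copies = n_copies, flanks = FALSE),
    repeat_spec = list(unit_len = 3000L, n_copies = 4L, mutation_rate = 0.01,
                       copy_fraction = 1.0),
    gene_spec = list(query_len_aa = 300L,
                     copies = data.frame(gene = character(),
                                         state = character(),
                                         stringsAsFactors = FALSE)))
}

# small locus simulation with flanks and genes, for flank/gene tests
locus_sim_config <- function(seed = 1L, inversions = 0L, ...) {
  sim_config(seed = seed, inversions_per_lineage = inversions,
             block_len = 12000L, ...)
}

random_signed_perm <- function(n) {
  as.integer(sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE))
}

# SNP track at given rates/boundary on a compact chromosome
snp_track_config <- function(seed, par_rate = 0.1, stratum_rate = 2.0,
                             chrom_len = 4e6, boundary = 2e6,
                             bad_fraction = 0) {
  sim_config(seed = seed,
             snp_spec = list(chrom = "neoX", chrom_len = chrom_len,
                             boundary = boundary, par_rate = par_rate,
                             stratum_rate = stratum_rate, depth_mode = 42L,
                             bad_fraction = bad_fraction))
}
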