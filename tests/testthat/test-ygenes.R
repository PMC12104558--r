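mk_phits <- function(gene, qlen, qs, qe, ts, te, chrom = "Xq") {
  data.frame(gene = gene, query_len = qlen, query_start = qs, query_end = qe,
             chrom = chrom, target_start = ts, target_end = te, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("locus discovery applies the strict coverage rule with padding", {
  lens <- c(Xq = 100000L)
  h60 <- mk_phits("Ddx3y", 100L, 0L, 60L, 30000L, 30180L)
  loc <- find_loci(h60, lens)
  expect_equal(nrow(loc), 1L)
  expect_equal(loc$start, 20000L)
  expect_equal(loc$end, 40180L)
  expect_equal(loc$coverage, 0.6)

  h40 <- mk_phits("Ddx3y", 100L, 0L, 40L, 30000L, 30120L)
  expect_equal(nrow(find_loci(h40, lens)), 0L)     # absent below 50%

  edge <- mk_phits("Uty", 100L, 0L, 80L, 2000L, 2240L)
  expect_equal(find_loci(edge, lens)$start, 0L)    # clipped at chromosome start

  # split hits within 2*pad merge into one locus; union coverage
  split2 <- rbind(mk_phits("Zfy", 100L, 0L, 35L, 10000L, 10105L),
                  mk_phits("Zfy", 100L, 30L, 70L, 15000L, 15120L))
  loc2 <- find_loci(split2, lens)
  expect_equal(nrow(loc2), 1L)
  expect_equal(loc2$coverage, 0.7)
})

test_that("ORF finding matches hand-computed and brute-force expectations", {
  o <- find_orfs("ATGAAATAG", min_len_aa = 1L)
  fwd <- o[o$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$aa_len, 2L)
  expect_equal(c(fwd$start, fwd$end), c(0L, 9L))

  expect_equal(nrow(find_orfs("CCCCCCAAATTTCCC", min_len_aa = 1L)), 0L)

  # N codons break ORFs
  expect_equal(nrow(find_orfs("ATGANATAG", min_len_aa = 1L)[
    find_orfs("ATGANATAG", min_len_aa = 1L)$strand == "+", ]), 0L)

  brute_orfs <- function(s, min_aa) {
    # independent enumeration: every ATG paired with its nearest clean
    # in-frame stop
    s <- toupper(s); n <- nchar(s)
    rows <- list()
    for (strand in c("+", "-")) {
      ss <- if (strand == "+") s else ytrace:::revcomp(s)
      for (i in seq_len(max(0, n - 2))) {
        if (substring(ss, i, i + 2) != "ATG") next
        j <- i + 3
        while (j + 2 <= n) {
          cod <- substring(ss, j, j + 2)
          if (grepl("N", cod)) break
          if (cod %in% c("TAA", "TAG", "TGA")) {
            aa <- (j - i) / 3
            if (aa >= min_aa) {
              st <- if (strand == "+") i - 1L else n - (j + 2L)
              en <- if (strand == "+") j + 2L else n - i + 1L
              rows[[length(rows) + 1L]] <- c(st, en, aa)
            }
            break
          }
          j <- j + 3
        }
      }
    }
    m <- do.call(rbind, rows)
    if (is.null(m)) m <- matrix(numeric(0), ncol = 3)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  set.seed(17)
  for (rep in 1:5) {
    s <- ytrace:::random_bases(1000L)
    got <- find_orfs(s, min_len_aa = 1L)
    want <- brute_orfs(s, 1L)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, as.integer(want[, 1]))
    expect_equal(got$aa_len, as.integer(want[, 3]))
  }
})

test_that("ORF sets are strand-symmetric under reverse complement", {
  set.seed(19)
  s <- ytrace:::random_bases(600L)
  a <- find_orfs(s, min_len_aa = 1L)
  b <- find_orfs(ytrace:::revcomp(s), min_len_aa = 1L)
  n <- nchar(s)
  a_flip <- data.frame(start = n - a$end, end = n - a$start,
                       strand = ifelse(a$strand == "+", "-", "+"),
                       aa_len = a$aa_len)
  o1 <- a_flip[order(a_flip$start, a_flip$end, a_flip$strand), ]
  o2 <- b[order(b$start, b$end, b$strand), c("start", "end", "strand", "aa_len")]
  expect_equal(o1$start, o2$start)
  expect_equal(o1$aa_len, o2$aa_len)
  expect_equal(o1$strand, o2$strand)
})

test_that("gene classification separates intact from frameshifted copies", {
  cfg <- locus_sim_config(seed = 23)
  sim <- emit_sequences(cfg)
  genome <- sim$genomes$osi
  tg <- sim$truth$genes[sim$truth$genes$species == "osi", ]
  qlen <- sim$truth$query_len_aa
  for (i in seq_len(nrow(tg))) {
    locus <- data.frame(gene = tg$gene[i], chrom = "Xq",
                        start = max(0L, tg$start[i] - 200L),
                        end = tg$end[i] + 200L, strand = tg$strand[i],
                        query_len = qlen, coverage = 0.9,
                        stringsAsFactors = FALSE)
    call <- classify_gene(locus, genome)
    expect_equal(call$status, tg$state[i],
                 info = paste(tg$gene[i], tg$state[i]))
    if (tg$state[i] == "intact") expect_gte(call$orf_coverage, 0.8)
  }
})

test_that("classification is monotone in the ORF threshold", {
  cfg <- locus_sim_config(seed = 29)
  sim <- emit_sequences(cfg)
  tg <- sim$truth$genes[sim$truth$genes$species == "osi", ]
  loci <- data.frame(gene = tg$gene, chrom = "Xq",
                     start = pmax(0L, tg$start - 200L), end = tg$end + 200L,
                     strand = tg$strand, query_len = sim$truth$query_len_aa,
                     coverage = 0.9, stringsAsFactors = FALSE)
  lo <- classify_genes(loci, sim$genomes$osi, min_orf_cov = 0.8)
  hi <- classify_genes(loci, sim$genomes$osi, min_orf_cov = 0.95)
  flipped <- lo$status == "pseudo" & hi$status == "intact"
  expect_false(any(flipped))
})

test_that("copy tables match planted truth and handle edge cases", {
  cfg <- locus_sim_config(seed = 37)
  sim <- emit_sequences(cfg)
  tg <- sim$truth$genes[sim$truth$genes$species == "osi", ]
  loci <- data.frame(gene = tg$gene, chrom = "Xq",
                     start = pmax(0L, tg$start - 200L), end = tg$end + 200L,
                     strand = tg$strand, query_len = sim$truth$query_len_aa,
                     coverage = 0.9, stringsAsFactors = FALSE)
  calls <- classify_genes(loci, sim$genomes$osi)
  regions <- data.frame(chrom = "Xq", start = 0L,
                        end = nchar(sim$genomes$osi[["Xq"]]),
                        name = "Xq-region1", stringsAsFactors = FALSE)
  tab <- copy_table(calls, regions)
  for (g in unique(tg$gene)) {
    row <- tab[tab$gene == g & tab$region == "Xq-region1", ]
    expect_equal(row$intact, sum(tg$gene == g & tg$state == "intact"))
    expect_equal(row$pseudo, sum(tg$gene == g & tg$state == "pseudo"))
  }

  empty <- copy_table(calls[0, ], regions)
  expect_true(all(empty$intact == 0L & empty$pseudo == 0L))

  multi <- data.frame(gene = "Zfy", chrom = "Xq",
                      start = (0:7) * 1000L, end = (0:7) * 1000L + 900L,
                      strand = "+", query_len = 100L, coverage = 1,
                      status = rep(c("intact", "pseudo"), c(5, 3)),
                      orf_aa = 80L, orf_coverage = 0.8,
                      stringsAsFactors = FALSE)
  t2 <- copy_table(multi, regions)
  r <- t2[t2$region == "Xq-region1", ]
  expect_equal(c(r$intact, r$pseudo), c(5L, 3L))
})
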