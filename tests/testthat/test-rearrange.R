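test_that("arrangements parse, format and validate", {
  a <- parse_arrangement("SB1+ SB6- SB5- SB2+")
  expect_equal(a$ids, c("SB1", "SB6", "SB5", "SB2"))
  expect_equal(a$signs, c(1L, -1L, -1L, 1L))
  expect_equal(format(parse_arrangement(format(a))), format(a))
  expect_error(arrangement(c("A", "A")), "duplicate")
  expect_error(parse_arrangement("SB1"), "\\+")

  inv <- apply_inversion(a, 2, 3)
  expect_equal(format(inv), "SB1+ SB5+ SB6+ SB2+")
})

test_that("inversion distance handles base cases and mismatched blocks", {
  a <- parse_arrangement("SB1+ SB2+")
  expect_equal(inversion_distance(a, a), 0L)
  expect_equal(inversion_distance(c(-2L, -1L), c(1L, 2L)), 1L)
  expect_error(inversion_distance(parse_arrangement("A+ B+"),
                                  parse_arrangement("A+ C+")),
               "only in first.*B.*only in second.*C")
})

test_that("distance agrees with the BFS oracle on exhaustive small cases", {
  for (n in 2:3) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, anyDuplicated) == 0, , drop = FALSE]
    sgns <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    id <- seq_len(n)
    for (i in seq_len(nrow(perms))) {
      for (s in seq_len(nrow(sgns))) {
        p <- as.integer(perms[i, ] * sgns[s, ])
        expect_equal(inversion_distance(p, id), bfs_distance_oracle(p, id),
                     info = paste(p, collapse = ","))
      }
    }
  }
})

test_that("distance agrees with the BFS oracle on random pairs up to n = 7", {
  set.seed(101)
  for (n in 5:7) {
    for (rep in 1:60) {
      a <- random_signed_perm(n)
      b <- random_signed_perm(n)
      expect_equal(inversion_distance(a, b), bfs_distance_oracle(a, b),
                   info = paste(n, paste(a, collapse = ","),
                                paste(b, collapse = ",")))
    }
  }
  expect_error(bfs_distance_oracle(random_signed_perm(8),
                                   random_signed_perm(8)), "refusing")
})

test_that("distance satisfies the metric axioms and the breakpoint bound", {
  breakpoints <- function(a, b) {
    # adjacencies of the capped relative permutation that differ from the
    # identity; an inversion repairs at most two
    p <- c(0L, ytrace:::as_relative_perm(a, b), length(a) + 1L)
    sum(diff(p) != 1L)
  }
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    a <- random_signed_perm(n)
    b <- random_signed_perm(n)
    c_ <- random_signed_perm(n)
    dab <- inversion_distance(a, b)
    expect_equal(inversion_distance(a, a), 0L)
    expect_equal(dab, inversion_distance(b, a))
    expect_lte(inversion_distance(a, c_), dab + inversion_distance(b, c_))
    expect_gte(dab, ceiling(breakpoints(a, b) / 2))
  }
})

test_that("sorting scenarios are optimal and land on the target", {
  a <- parse_arrangement("SB1+ SB2+")
  expect_equal(nrow(sorting_scenario(a, a)), 0L)

  s <- sorting_scenario(c(-2L, -1L), c(1L, 2L))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$from, s$to), c(1L, 2L))

  set.seed(13)
  for (rep in 1:10) {
    a <- arrangement(paste0("B", 1:6), sample(c(-1L, 1L), 6, replace = TRUE))
    b <- arrangement(paste0("B", sample(1:6)),
                     sample(c(-1L, 1L), 6, replace = TRUE))
    sc <- sorting_scenario(a, b)
    expect_equal(nrow(sc), bfs_distance_oracle(a, b))
    cur <- a
    for (i in seq_len(nrow(sc))) cur <- apply_inversion(cur, sc$from[i], sc$to[i])
    expect_equal(format(cur), format(b))
  }
})

test_that("ancestral configuration enumeration covers loci, orders and signs", {
  cfgs <- enumerate_ancestral_configs()
  expect_length(cfgs, 24L)
  expect_equal(sort(unique(vapply(cfgs, `[[`, character(1), "locus"))),
               c("SB1-SB2", "SB2-SB3", "SB3-SB4"))
  keys <- vapply(cfgs, function(x) format(x$arrangement), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # deterministic order
  keys2 <- vapply(enumerate_ancestral_configs(), function(x)
    format(x$arrangement), character(1))
  expect_identical(keys, keys2)

  expect_length(enumerate_ancestral_configs(inserted = "SB5"), 6L)
  expect_length(enumerate_ancestral_configs(loci = 1L), 8L)
  expect_error(enumerate_ancestral_configs(inserted = "SB1"), "disjoint")
})

test_that("scenario scoring reports all ties and honours exclusions", {
  cfgs <- enumerate_ancestral_configs()
  # an extant species equal to a config scores zero for it
  ext <- list(sp = cfgs[[1]]$arrangement)
  st <- score_scenarios(cfgs, ext, exclude_ids = character(0))
  expect_equal(st$sp[1], 0L)
  expect_true(st$minimal[1])
  expect_equal(st$total, st$sp)

  # totals invariant under consistent relabeling of block ids
  relabel <- function(arr) arrangement(paste0("X_", arr$ids), arr$signs)
  cfgs2 <- enumerate_ancestral_configs(
    base = relabel(parse_arrangement("SB1+ SB2+ SB3+ SB4+")),
    inserted = c("X_SB5", "X_SB6"))
  ext_named <- read_arrangements()
  st1 <- score_scenarios(enumerate_ancestral_configs(), ext_named)
  st2 <- score_scenarios(cfgs2, lapply(ext_named, relabel),
                         exclude_ids = "X_SB5p")
  expect_equal(sort(st1$total), sort(st2$total))

  expect_error(score_scenarios(cfgs, list(sp = parse_arrangement("SB1+ SB2+"))),
               "only in")
})
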