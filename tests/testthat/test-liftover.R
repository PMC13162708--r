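chain_text <- function(...) {
  f <- withr::local_tempfile(fileext = ".chain", .local_envir = parent.frame())
  writeLines(c(...), f)
  f
}

test_that("read_chain_file parses and validates headers and blocks", {
  f <- chain_text("chain 100 chr1 1000 + 0 100 chrA 1000 + 0 100 1", "100")
  ch <- read_chain_file(f)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]$blocks), 1)
  expect_equal(ch[[1]]$blocks$size, 100)

  # 50 + 10 + 50 = 110 on the source: consistent
  f <- chain_text("chain 100 chr1 1000 + 0 110 chrA 1000 + 0 100 1",
                  "50 10 0", "50")
  expect_length(read_chain_file(f), 1)

  # same blocks but a 120-wide header span: integrity error naming the chain
  f <- chain_text("chain 100 chr1 1000 + 0 120 chrA 1000 + 0 100 7",
                  "50 10 0", "50")
  expect_error(read_chain_file(f), "chain 7.*block sum")

  f <- chain_text("chain 100 chr1 1000 - 0 100 chrA 1000 + 0 100 1", "100")
  expect_error(read_chain_file(f), "source strand")
})

test_that("chain write/read round-trips", {
  set.seed(11)
  chains <- lapply(1:20, function(i) random_chain("chr1", 2000, i))
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(chains, f)
  back <- read_chain_file(f)
  expect_length(back, 20)
  for (i in seq_along(chains)) {
    expect_equal(back[[i]]$blocks, chains[[i]]$blocks)
    expect_equal(back[[i]]$q_strand, chains[[i]]$q_strand)
    expect_equal(back[[i]]$t_start, chains[[i]]$t_start)
  }
})

test_that("project_interval: identity, partial and uncovered cases", {
  idx <- build_chain_index(list(identity_chain(len = 1000)))
  r <- project_interval(genomic_intervals("chr1", 100, 200, name = "a"), idx)
  expect_equal(r$aligned_fraction, 1.0)
  expect_equal(r$segments$start, 100)
  expect_equal(r$segments$end, 200)

  # blocks 50 10 0 / 50 from t=0: aligned {0..49} u {60..109}
  ch <- relic:::new_chain(100, "chr1", 1000, "+", 0, 110,
                          "chrA", 1000, "+", 0, 100, 1,
                          data.frame(size = c(50, 50), dt = c(10, 0), dq = 0))
  idx <- build_chain_index(list(ch))
  r <- project_interval(genomic_intervals("chr1", 40, 70), idx)
  expect_equal(r$aligned_bases, 20)  # {40..49} u {60..69}
  expect_equal(r$aligned_fraction, 20 / 30)

  r <- project_interval(genomic_intervals("chr1", 500, 600), idx)
  expect_equal(r$aligned_fraction, 0)
  r <- project_interval(genomic_intervals("chrZ", 0, 10), idx)
  expect_equal(r$aligned_fraction, 0)

  # empty index answers every query with nothing
  r <- project_interval(genomic_intervals("chr1", 0, 10),
                        build_chain_index(list()))
  expect_equal(r$aligned_bases, 0)
})

test_that("minus-strand chains map to forward target coordinates", {
  # one 10-base block at t [100,110), q strand-coords [20,30) on a 100-base
  # target: forward coordinates are [100 - 30, 100 - 20) = [70, 80)
  ch <- relic:::new_chain(100, "chr1", 1000, "+", 100, 110,
                          "chrB", 100, "-", 20, 30, 1,
                          data.frame(size = 10, dt = 0, dq = 0))
  r <- project_interval(genomic_intervals("chr1", 100, 110),
                        build_chain_index(list(ch)))
  expect_equal(r$segments$start, 70)
  expect_equal(r$segments$end, 80)
  expect_equal(r$segments$strand, "-")

  # strand round-trip: the inverse chain (target forward coords as source)
  # recovers the original aligned source bases
  inv <- relic:::new_chain(100, "chrB", 100, "+", 70, 80,
                           "chr1", 1000, "-", 1000 - 110, 1000 - 100, 2,
                           data.frame(size = 10, dt = 0, dq = 0))
  r2 <- project_interval(r$segments, build_chain_index(list(inv)))
  expect_equal(r2$segments$seq_id, "chr1")
  expect_equal(r2$segments$start, 100)
  expect_equal(r2$segments$end, 110)
})

test_that("projection equals per-base brute force on random chains", {
  set.seed(42)
  for (rep in 1:4) {
    chains <- lapply(1:30, function(i) random_chain("chr1", 500, i))
    idx <- build_chain_index(chains)
    for (q in 1:60) {
      s <- sample(0:470, 1); e <- s + sample(1:30, 1)
      got <- project_interval(genomic_intervals("chr1", s, e), idx)
      expect_identical(got$aligned_bases, bf_aligned_bases("chr1", s, e, chains))
      # mapped segment lengths sum to aligned_bases
      expect_equal(sum(iv_width(got$segments)), got$aligned_bases)
    }
  }
})

test_that("index retrieval equals linear scan on many chains", {
  set.seed(5)
  chains <- lapply(1:300, function(i) random_chain("chr1", 5000, i))
  idx <- build_chain_index(chains)
  for (q in 1:50) {
    s <- sample(0:4950, 1); e <- s + sample(1:50, 1)
    got <- project_interval(genomic_intervals("chr1", s, e), idx)
    expect_identical(got$aligned_bases, bf_aligned_bases("chr1", s, e, chains))
  }
})

test_that("removing a chain never increases aligned_fraction (monotonicity)", {
  set.seed(9)
  chains <- lapply(1:15, function(i) random_chain("chr1", 400, i))
  full <- build_chain_index(chains)
  ivs <- random_intervals(25, "chr1", 400, c(5, 60))
  for (drop in sample(15, 5)) {
    sub <- build_chain_index(chains[-drop])
    for (i in seq_len(nrow(ivs))) {
      expect_lte(project_interval(ivs[i, ], sub)$aligned_fraction,
                 project_interval(ivs[i, ], full)$aligned_fraction)
    }
  }
})

test_that("aligned bases are additive over adjacent halves", {
  set.seed(13)
  chains <- lapply(1:20, function(i) random_chain("chr1", 600, i))
  idx <- build_chain_index(chains)
  for (q in 1:40) {
    s <- sample(0:540, 1); len <- sample(2:40, 1); mid <- s + len %/% 2
    whole <- project_interval(genomic_intervals("chr1", s, s + len), idx)
    left <- project_interval(genomic_intervals("chr1", s, mid), idx)
    right <- project_interval(genomic_intervals("chr1", mid, s + len), idx)
    expect_identical(whole$aligned_bases,
                     left$aligned_bases + right$aligned_bases)
  }
})

test_that("conservation_matrix matches per-interval projection and oracle", {
  idx1 <- build_chain_index(list(identity_chain(len = 1000)))
  m <- conservation_matrix(genomic_intervals("chr1", 10, 20, name = "r1"),
                           list(gA = idx1))
  expect_equal(unclass(m)[1, 1], 1.0, ignore_attr = TRUE)

  # genome B omits RE3's locus -> forced zero
  chB <- relic:::new_chain(100, "chr1", 1000, "+", 0, 100, "x", 100, "+",
                           0, 100, 1, data.frame(size = 100, dt = 0, dq = 0))
  res3 <- genomic_intervals("chr1", c(0, 50, 500), c(40, 90, 550),
                            name = c("r1", "r2", "r3"))
  m <- conservation_matrix(res3, list(A = idx1, B = build_chain_index(list(chB))))
  expect_equal(unname(m["r3", "B"]), 0)
  expect_equal(unname(m["r3", "A"]), 1)

  set.seed(21)
  res <- random_intervals(50, "chr1", 900, c(10, 80), prefix = "re")
  genomes <- lapply(1:4, function(g)
    lapply(1:12, function(i) random_chain("chr1", 900, i)))
  idx <- lapply(genomes, build_chain_index)
  names(idx) <- paste0("g", 1:4)
  m <- conservation_matrix(res, idx)
  for (i in seq_len(nrow(res)))
    for (g in 1:4) {
      expect_equal(unname(m[i, g]),
                   bf_aligned_bases(res$seq_id[i], res$start[i], res$end[i],
                                    genomes[[g]]) / iv_width(res)[i])
      expect_equal(unname(m[i, g]),
                   project_interval(res[i, ], idx[[g]])$aligned_fraction)
    }
  expect_error(conservation_matrix(res, setNames(idx, rep("g1", 4))),
               "duplicate")
})

test_that("best-score mode restricts to the top chain", {
  low <- relic:::new_chain(10, "chr1", 1000, "+", 0, 50, "a", 50, "+", 0, 50,
                           1, data.frame(size = 50, dt = 0, dq = 0))
  high <- relic:::new_chain(99, "chr1", 1000, "+", 100, 150, "b", 50, "+",
                            0, 50, 2, data.frame(size = 50, dt = 0, dq = 0))
  idx <- build_chain_index(list(low, high))
  iv <- genomic_intervals("chr1", 0, 150)
  expect_equal(project_interval(iv, idx, mode = "any")$aligned_bases, 100)
  expect_equal(project_interval(iv, idx, mode = "best")$aligned_bases, 50)
})
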