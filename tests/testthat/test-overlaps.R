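test_that("te_coverage merges TEs before counting", {
  res <- genomic_intervals("chr1", 0, 100, name = "r1")
  tes <- genomic_intervals("chr1", c(10, 20), c(30, 50),
                           te_class = c("LINE", "LINE"))
  cov <- te_coverage(res, tes)
  expect_equal(cov$te_covered_bases[cov$category == "all"], 40)
  expect_equal(cov$coverage_fraction[cov$category == "all"], 0.40)

  empty_te <- genomic_intervals(character(0), numeric(0), numeric(0))
  expect_equal(te_coverage(res, empty_te)$coverage_fraction, 0)
  full <- genomic_intervals("chr1", 0, 100)
  expect_equal(te_coverage(res, full)$coverage_fraction, 1)
  expect_error(te_coverage(res[0, ], tes), "empty")
})

test_that("te_class_composition attributes overlapping classes disjointly", {
  res <- genomic_intervals("chr1", 0, 30, name = "r1")
  tes <- genomic_intervals("chr1", c(0, 10), c(20, 30),
                           te_class = c("LINE", "LTR"))
  comp <- te_class_composition(res, tes)
  comp <- comp[comp$category == "all", ]
  # LINE is longer (20 vs 20... equal length 20 bp): tie broken
  # lexicographically -> LINE claims [0,20), LTR keeps [20,30)
  expect_equal(comp$covered_bases[comp$te_class == "LINE"], 20)
  expect_equal(comp$covered_bases[comp$te_class == "LTR"], 10)
  expect_equal(sum(comp$covered_bases),
               te_coverage(res, tes)$te_covered_bases[1])
})

test_that("coverage is invariant under TE splitting and merge idempotent", {
  set.seed(19)
  res <- random_intervals(30, c("chr1", "chr2"), 5000, c(20, 200), prefix = "re")
  tes <- random_intervals(60, c("chr1", "chr2"), 5000, c(10, 150), prefix = "te")
  tes$te_class <- sample(c("LINE", "SINE"), 60, replace = TRUE)
  base <- te_coverage(res, tes)

  # split every TE into two adjacent pieces of the same class
  mid <- tes$start + pmax(1, iv_width(tes) %/% 2)
  split_tes <- genomic_intervals(rep(tes$seq_id, 2),
                                 c(tes$start, mid), c(mid, tes$end),
                                 te_class = rep(tes$te_class, 2))
  expect_equal(te_coverage(res, split_tes)$coverage_fraction,
               base$coverage_fraction)
  merged <- merge_intervals(tes)
  expect_equal(te_coverage(res, merged)$coverage_fraction,
               base$coverage_fraction)
})

test_that("motif report matches the enumerated fixture", {
  # 10 REs, 4 with hits; 6 distinct hits inside REs, 3 of them touching TEs
  res <- genomic_intervals("chr1", seq(0, 900, 100), seq(50, 950, 100),
                           name = sprintf("r%02d", 1:10))
  motifs <- genomic_intervals("chr1",
                              c(10, 20, 110, 210, 220, 310, 2000, 2100),
                              c(18, 28, 118, 218, 228, 318, 2008, 2108),
                              name = sprintf("m%d", 1:8))
  tes <- genomic_intervals("chr1", c(5, 205), c(19, 230), te_class = "LINE")
  rep_ <- motif_reports(res, motifs, tes)
  all_row <- rep_[rep_$category == "all", ]
  expect_equal(all_row$n_res_with_motif, 4)
  expect_equal(all_row$prop_res_with_motif, 0.40)
  expect_equal(all_row$n_hits_in_res, 6)
  expect_equal(all_row$n_hits_in_res_te, 3)  # m1, m4, m5
  expect_equal(all_row$prop_te_of_in_re_hits, 0.50)
  expect_equal(all_row$prop_te_of_all_hits, 3 / 8)

  none <- motif_reports(res, motifs[0, ], tes)
  expect_equal(none$prop_res_with_motif[none$category == "all"], 0)
  expect_true(is.na(none$prop_te_of_in_re_hits[none$category == "all"]))
})

test_that("qtl_overlap applies the strict length filter", {
  res <- genomic_intervals("chr1", 5e5, 5e5 + 1000, name = "re1")
  qtls <- genomic_intervals("chr1", c(0, 0, 4e5), c(2e6, 1e6, 6e5),
                            name = c("big", "exact1mb", "small"))
  pairs <- qtl_overlap(res, qtls)
  # 2 Mb QTL excluded (strictly larger); exactly 1 Mb retained
  expect_setequal(pairs$qtl_name, c("exact1mb", "small"))
})

test_that("overlap statistics equal quadratic brute force on random fixtures", {
  set.seed(101)
  L <- 20000
  res <- random_intervals(100, c("chr1", "chr2"), L, c(50, 400), prefix = "re")
  tes <- random_intervals(200, c("chr1", "chr2"), L, c(20, 300), prefix = "te")
  tes$te_class <- sample(c("LINE", "SINE", "LTR"), 200, replace = TRUE)
  motifs <- random_intervals(50, c("chr1", "chr2"), L, c(8, 15), prefix = "m")
  qtls <- random_intervals(20, c("chr1", "chr2"), L, c(100, 2000), prefix = "q")
  cats <- sample(re_categories(), 100, replace = TRUE)

  # TE coverage per category vs per-base marking
  cov <- te_coverage(res, tes, cats)
  for (cc in unique(cats)) {
    sel <- which(cats == cc)
    bf <- sum(sapply(sel, function(i) {
      same <- tes$seq_id == res$seq_id[i]
      bf_covered(res$start[i], res$end[i], tes$start[same], tes$end[same])
    }))
    expect_equal(cov$te_covered_bases[cov$category == cc], bf)
  }
  # overall coverage is the length-weighted mean of category coverages
  by_cat <- cov[cov$category != "all", ]
  expect_equal(cov$coverage_fraction[cov$category == "all"],
               sum(by_cat$coverage_fraction * by_cat$total_re_bases) /
                 sum(by_cat$total_re_bases))

  # motif presence vs all-pairs loops
  mrep <- motif_reports(res, motifs, tes)
  all_row <- mrep[mrep$category == "all", ]
  bf_has <- sapply(seq_len(nrow(res)), function(i)
    any(sapply(seq_len(nrow(motifs)), function(j)
      res$seq_id[i] == motifs$seq_id[j] &&
        overlaps_1bp(res$start[i], res$end[i], motifs$start[j], motifs$end[j]))))
  expect_equal(all_row$n_res_with_motif, sum(bf_has))

  # QTL pair set vs all-pairs intersection
  pairs <- qtl_overlap(res, qtls, max_qtl_len = 1000)
  bf_pairs <- do.call(rbind, lapply(seq_len(nrow(res)), function(i)
    do.call(rbind, lapply(seq_len(nrow(qtls)), function(j) {
      if (qtls$end[j] - qtls$start[j] > 1000) return(NULL)
      if (res$seq_id[i] == qtls$seq_id[j] &&
          overlaps_1bp(res$start[i], res$end[i], qtls$start[j], qtls$end[j]))
        data.frame(re_name = res$name[i], qtl_name = qtls$name[j])
      else NULL
    }))))
  expect_equal(nrow(pairs), nrow(bf_pairs))
  expect_setequal(paste(pairs$re_name, pairs$qtl_name),
                  paste(bf_pairs$re_name, bf_pairs$qtl_name))
  # the filter removed exactly the strictly-larger QTLs
  expect_false(any(pairs$qtl_name %in%
                     qtls$name[iv_width(qtls) > 1000]))

  # class composition sums to merged coverage per category
  comp <- te_class_composition(res, tes, cats)
  for (cc in c(unique(cats), "all"))
    expect_equal(sum(comp$covered_bases[comp$category == cc]),
                 cov$te_covered_bases[cov$category == cc])
})
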