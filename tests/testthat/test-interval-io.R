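test_that("read_bed parses coordinates, strand and names; rejects bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tRE1",
               "chr2\t0\t1\tX\t0\t-",
               "chr3\t5\t50"), f)
  iv <- read_bed(f)
  expect_equal(iv$seq_id, c("chr1", "chr2", "chr3"))
  expect_equal(iv$start, c(100, 0, 5))
  expect_equal(iv$end, c(200, 1, 50))
  expect_equal(iv$strand, c(".", "-", "."))
  expect_equal(iv$name[1:2], c("RE1", "X"))

  writeLines("chr1\t200\t100", f)
  expect_error(read_bed(f), "invalid BED interval")
  writeLines("chr1\tx\t100", f)
  expect_error(read_bed(f), "non-integer")
  writeLines("chr1\t100", f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("BED round-trip preserves coordinates and strands; extra columns ignored", {
  f <- withr::local_tempfile(fileext = ".bed")
  set.seed(7)
  iv <- random_intervals(40, c("chr1", "chr2"), 1e5)
  iv$strand <- sample(c("+", "-", "."), 40, replace = TRUE)
  write_bed(iv, f)
  back <- read_bed(f)
  expect_equal(back$seq_id, iv$seq_id)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$strand, iv$strand)
  # BED12-ish extras are tolerated
  writeLines("chr1\t10\t20\tn\t0\t+\t10\t20\t0\t1\t10\t0", f)
  expect_equal(read_bed(f)$end, 20)
})

test_that("gzip-compressed input is accepted", {
  f <- withr::local_tempfile(fileext = ".bed.gz")
  con <- gzfile(f, "wt")
  writeLines("chr1\t100\t200\tRE1", con)
  close(con)
  expect_equal(read_bed(f)$start, 100)
})

test_that("read_gff_genes converts coordinates, derives TSS, filters biotype", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\t.\tgene\t1001\t2000\t.\t+\t.\tID=g1;biotype=protein_coding",
    "chr1\t.\texon\t1001\t1200\t.\t+\t.\tParent=g1",
    "chr1\t.\texon\t1801\t2000\t.\t+\t.\tParent=g1",
    "chr1\t.\tgene\t3001\t4000\t.\t-\t.\tID=g2;biotype=protein_coding",
    "chr1\t.\tgene\t5001\t6000\t.\t+\t.\tID=g3;biotype=lncRNA"), f)
  genes <- read_gff_genes(f, "protein_coding")
  expect_length(genes, 2)
  g1 <- genes[[1]]
  expect_equal(g1$interval$start, 1000)
  expect_equal(g1$interval$end, 2000)
  expect_equal(g1$tss, 1000)
  expect_equal(g1$exons$start, c(1000, 1800))
  g2 <- genes[[2]]
  expect_equal(g2$tss, 3999)  # end - 1 on the minus strand
  expect_length(read_gff_genes(f, NULL), 3)

  writeLines("chr1\t.\tgene\t1\t10\t.\t+\t.\tbiotype=protein_coding", f)
  expect_error(read_gff_genes(f), "lacks ID")
  writeLines("chr1\t.\tgene\t1\t10\t.\t?\t.\tID=g1;biotype=protein_coding", f)
  expect_error(read_gff_genes(f), "unknown strand")
})

test_that("read_repeatmasker_out converts conventions and splits class/family", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left) ID",
    "",
    "  463   12.1  0.0  0.0  chr1      1001  2000  (8000) + L1_Ssc    LINE/L1          1  1000  (0)  1",
    "  120    5.0  0.0  0.0  chr2        51   100  (9900) C (TA)n     Simple_repeat    1    50  (0)  2"), f)
  te <- read_repeatmasker_out(f)
  expect_equal(te$start, c(1000, 50))
  expect_equal(te$end, c(2000, 100))
  expect_equal(te$te_class, c("LINE", "Simple_repeat"))
  expect_equal(te$te_family, c("L1", ""))
  expect_equal(te$strand, c("+", "-"))

  writeLines(c("   SW banner", "score banner", "", "  463 12.1 0.0"), f)
  expect_error(read_repeatmasker_out(f), "truncated")
  writeLines(c("   SW banner", "score banner", ""), f)
  expect_equal(nrow(read_repeatmasker_out(f)), 0)
})

test_that("read_score_track handles bedGraph and fixed-step wig, rejects overlap", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1 0 10 0.5", f)
  tr <- read_score_track(f)
  expect_equal(tr$start, 0)
  expect_equal(tr$end, 10)
  expect_equal(tr$score, 0.5)

  writeLines(c("chr1 0 10 0.5", "chr1 5 15 0.7"), f)
  expect_error(read_score_track(f), "overlapping")

  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "0.1", "0.2", "0.3"), f)
  tr <- read_score_track(f)
  expect_equal(tr$start, c(0, 1, 2))
  expect_equal(tr$end, c(1, 2, 3))
  expect_equal(tr$score, c(0.1, 0.2, 0.3))
})

test_that("one locus encoded as BED, GFF3 and RepeatMasker yields identical internals", {
  # the same [1000, 2000) interval on chr7 in three source dialects
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  rm_out <- withr::local_tempfile(fileext = ".out")
  writeLines("chr7\t1000\t2000\tx\t0\t+", bed)
  writeLines("chr7\t.\tgene\t1001\t2000\t.\t+\t.\tID=x;biotype=protein_coding", gff)
  writeLines(c("   SW   banner", "score   banner", "",
               "1 1 1 1 chr7 1001 2000 (0) + x LINE/L1 1 1 (0) 1"), rm_out)
  a <- read_bed(bed)
  b <- read_gff_genes(gff)[[1]]$interval
  c_ <- read_repeatmasker_out(rm_out)
  for (iv in list(b, c_)) {
    expect_equal(iv$seq_id, a$seq_id)
    expect_equal(iv$start, a$start)
    expect_equal(iv$end, a$end)
  }
})

test_that("divergence table reader validates structure", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tdivergence_mya\tclade",
               "sus_b\t4\tclade", "human\t96\toutgroup"), f)
  d <- read_divergence_table(f)
  expect_equal(d$taxon, c("sus_b", "human"))
  writeLines(c("taxon\tdivergence_mya\tclade", "a\t4\tclade", "a\t5\tclade"), f)
  expect_error(read_divergence_table(f), "duplicate")
  writeLines(c("taxon\tdivergence_mya\tclade", "a\t-1\tclade"), f)
  expect_error(read_divergence_table(f), "finite")
})

test_that("zero-length and inverted intervals are rejected at construction", {
  expect_error(genomic_intervals("chr1", 5, 5), "start < end")
  expect_error(genomic_intervals("chr1", -1, 5), "start < end")
  expect_silent(genomic_intervals("chr1", 0, 1))
})
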