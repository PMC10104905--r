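test_that("genome construction enforces its invariants", {
  g <- genome(c(chr1 = 1000, chr2 = 500))
  expect_s3_class(g, "genome")
  expect_equal(genome_size(g), 1500)
  expect_error(genome(c(100, 200)), "named")
  expect_error(genome(c(a = 100, a = 200)), "duplicate")
  expect_error(genome(c(a = 0)), "positive")
  expect_error(genome(c(a = -5)), "positive")
})

test_that("chrom.sizes round-trips through read/write", {
  g <- genome(c(chr1 = 123456, chr2 = 20000000))
  path <- withr::local_tempfile()
  write_chrom_sizes(g, path)
  expect_equal(unclass(read_chrom_sizes(path)), unclass(g))
})

test_that("BED parsing validates coordinates and reports line numbers", {
  g <- genome(c(chr1 = 1e6))
  path <- withr::local_tempfile()

  writeLines(c("track name=demo", "# a comment",
               "chr1\t100\t200\tpk1\t5",
               "chr1\t300\t400",
               "chr1\t500\t600"), path)
  iv <- read_bed(path, g)
  expect_equal(nrow(iv), 3)            # header lines skipped silently
  expect_equal(iv$start, c(100, 300, 500))
  expect_equal(iv$name[1], "pk1")
  expect_equal(iv$score[1], 5)

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_bed(path, g), "line 2")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path, g), "line 1")
  writeLines("chr1\t100\t2000000", path)
  expect_error(read_bed(path, g), "exceeds")
})

test_that("BED writing reproduces coordinates exactly", {
  g <- genome(c(chr1 = 1e6, chr2 = 5e5))
  set.seed(7)
  s <- sample(4e5, 30)
  iv <- interval_set(sample(names(g), 30, replace = TRUE), s, s + sample(1:999, 30),
                     name = sprintf("p%02d", 1:30), score = round(runif(30), 3),
                     genome = g, role = "peaks")
  path <- withr::local_tempfile()
  write_bed(iv, path)
  back <- read_bed(path, g, role = "peaks")
  expect_equal(back$chrom, iv$chrom)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$name, iv$name)
  expect_equal(back$score, iv$score)
})

test_that("extend clamps at chromosome bounds and is identity at flank 0", {
  g <- genome(c(chr1 = 1e6))
  iv <- interval_set("chr1", c(100, 999500), c(200, 999600), genome = g)
  ex <- extend_intervals(iv, 1000)
  expect_equal(ex$start, c(0, 998500))
  expect_equal(ex$end, c(1200, 1e6))
  expect_equal(as.data.frame(extend_intervals(iv, 0)), as.data.frame(iv))
})

test_that("merge coalesces overlaps, keeps disjoint intervals and is idempotent", {
  g <- genome(c(chr1 = 1e4))
  a <- interval_set("chr1", 100, 200, genome = g)
  b <- interval_set("chr1", 150, 300, genome = g)
  m <- merge_intervals(a, b)
  expect_equal(as.data.frame(m)[c("start", "end")], data.frame(start = 100, end = 300))

  d <- merge_intervals(interval_set("chr1", c(0, 20), c(10, 30), genome = g))
  expect_equal(nrow(d), 2)

  m2 <- merge_intervals(m)
  expect_equal(as.data.frame(m2), as.data.frame(m))

  g2 <- genome(c(chrX = 1e4))
  expect_error(merge_intervals(a, interval_set("chrX", 1, 2, genome = g2)),
               "different genomes")
})

test_that("merge coverage matches a per-base mask oracle on random intervals", {
  for (seed in c(101, 202)) {
    inst <- random_instance(seed)
    iv <- inst$mk(50)
    m <- merge_intervals(iv)
    mask <- bf_mask(list(iv), inst$genome)
    expect_equal(sum(m$end - m$start), sum(vapply(mask, sum, 0)))
    # merged set reproduces the mask segment-for-segment
    mm <- bf_mask(list(m), inst$genome)
    expect_identical(mm, mask)
    # non-overlapping and sorted
    gc <- epifeed:::global_coords(m, epifeed:::genome_offsets(inst$genome))
    expect_true(all(diff(gc$s) > 0))
    expect_true(all(gc$s[-1] >= gc$e[-nrow(m)]))
  }
})

test_that("associate_within matches hand-checked and degenerate cases", {
  g <- genome(c(chr1 = 1e6))
  A <- interval_set("chr1", c(100, 5000), c(200, 5100), genome = g)
  B <- interval_set("chr1", 1150, 1160, genome = g)
  r <- associate_within(A, B, 1000)
  expect_equal(r$fraction, 0.5)        # extended A1 = [0, 1200) catches B
  expect_equal(r$associated, c(TRUE, FALSE))

  expect_equal(associate_within(A, A, 0)$fraction, 1.0)
  empty <- interval_set(character(), numeric(), numeric(), genome = g)
  expect_equal(associate_within(A, empty, 1000)$fraction, 0.0)
  expect_error(associate_within(empty, A, 1000), "empty reference set")
})

test_that("shuffle preserves lengths, handles forced placement, and errors on oversize", {
  g1 <- genome(c(chrA = 10))
  iv <- interval_set("chrA", 0, 10, genome = g1)
  for (i in 1:5) {
    s <- shuffle_intervals(iv)
    expect_equal(as.data.frame(s)[c("chrom", "start", "end")],
                 data.frame(chrom = "chrA", start = 0, end = 10))
  }

  g2 <- genome(c(chrA = 100, chrB = 3000))
  set.seed(3)
  lens <- sample(1:50, 40, replace = TRUE)
  iv2 <- interval_set("chrB", cumsum(lens + 1) - lens, cumsum(lens + 1), genome = g2)
  s2 <- shuffle_intervals(iv2)
  expect_equal(sort(s2$end - s2$start), sort(iv2$end - iv2$start))
  expect_equal(nrow(s2), nrow(iv2))

  expect_error(shuffle_intervals(interval_set("chrB", 0, 200, genome = g2),
                                 genome(c(chrA = 100))),
               "longer than every chromosome")
})

test_that("shuffle chromosome choice is proportional to placeable positions", {
  g <- genome(c(chrA = 100, chrB = 300))
  iv <- interval_set("chrA", 0, 1, genome = g)
  set.seed(11)
  n <- 10000
  offs <- epifeed:::genome_offsets(g)
  draws <- epifeed:::shuffle_global(rep(1, n), g, offs)
  frac_b <- mean(draws$chrom_idx == 2)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(frac_b - 0.75), 4 * se)
})

test_that("association via reference flanking equals a pairwise gap scan", {
  for (seed in 301:305) {
    inst <- random_instance(seed)
    A <- inst$mk(6)
    B <- inst$mk(6)
    for (w in c(0, 5, 25)) {
      expect_equal(associate_within(A, B, w)$associated,
                   bf_associate(A, B, w, inst$genome))
    }
  }
})
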