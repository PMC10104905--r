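make_genome <- function() genome(c(chr1 = 1e5, chr2 = 5e4))

test_that("quantify counts fragments in centered windows", {
  g <- make_genome()
  peaks <- interval_set("chr1", c(10000, 50000), c(10200, 50400),
                        name = c("p1", "p2"), genome = g, role = "peaks")

  none <- interval_set(character(), numeric(), numeric(), genome = g)
  sm0 <- quantify_signal(peaks, list(r1 = none), conditions = "a")
  expect_true(all(sm0$counts == 0))

  one <- interval_set("chr1", 10050, 10150, genome = g)   # inside p1's window
  sm1 <- quantify_signal(peaks, list(r1 = one), conditions = "a")
  expect_equal(unname(sm1$counts[, 1]), c(1, 0))

  # fragment extension: a 1 bp fragment 200 bp upstream of the window edge
  # only counts once extended to 250 bp
  frag <- interval_set("chr1", 8900, 8901, genome = g)    # window starts at 9100
  expect_equal(unname(quantify_signal(peaks, list(r = frag), conditions = "a")$counts[1, 1]), 0)
  expect_equal(unname(quantify_signal(peaks, list(r = frag), conditions = "a",
                                      frag_length = 250)$counts[1, 1]), 1)
})

test_that("quantify agrees with a pairwise brute-force count on random data", {
  for (seed in c(21, 22)) {
    set.seed(seed)
    g <- make_genome()
    ps <- sample(9e4, 3)
    peaks <- interval_set("chr1", ps, ps + 500, genome = g)
    fs <- sample(99000, 20)
    frags <- interval_set("chr1", fs, fs + sample(50:400, 20, replace = TRUE),
                          genome = g)
    got <- quantify_signal(peaks, list(r = frags), conditions = "a",
                           half_window = 1000)
    expect_equal(unname(got$counts[, 1]),
                 bf_quantify(peaks, frags, 1000, g))
    got250 <- quantify_signal(peaks, list(r = frags), conditions = "a",
                              half_window = 1000, frag_length = 250)
    expect_equal(unname(got250$counts[, 1]),
                 bf_quantify(peaks, frags, 1000, g, frag_length = 250))
  }
})

test_that("quantify sums bedGraph coverage exactly", {
  g <- make_genome()
  trk <- coverage_track(c("chr1", "chr1", "chr1"),
                        c(900, 1500, 3000), c(1200, 1600, 3100),
                        c(2, 5, 1), g)
  peaks <- interval_set("chr1", 1450, 1550, genome = g)  # center 1500, window [500,2500)
  sm <- quantify_signal(peaks, list(cov = trk), conditions = "a")
  expect_equal(unname(sm$counts[1, 1]), 2 * 300 + 5 * 100)

  g2 <- genome(c(other = 1e5))
  expect_error(coverage_track("chrZ", 0, 10, 1, g), "unknown chromosome")
  expect_error(quantify_signal(peaks, list(cov = coverage_track("other", 0, 10, 1, g2)),
                               conditions = "a"), "does not match")
})

test_that("bedGraph files round-trip and reject overlapping segments", {
  g <- make_genome()
  path <- withr::local_tempfile()
  writeLines(c("track type=bedGraph", "chr1\t0\t100\t1.5", "chr1\t100\t250\t2"), path)
  trk <- read_bedgraph(path, g)
  expect_equal(trk$value, c(1.5, 2))
  expect_error(coverage_track(c("chr1", "chr1"), c(0, 50), c(100, 150), c(1, 2), g),
               "overlap")
})

test_that("normalize_total equalizes totals and preserves structure", {
  m <- cbind(a = c(10, 30, 60), b = c(100, 150, 50))
  sm <- signal_matrix(m, c("x", "y"))
  nm <- normalize_total(sm)
  expect_equal(unname(colSums(nm$counts)), c(200, 200))
  expect_true(nm$normalized)
  expect_equal(sum(nm$counts), sum(m))               # grand total conserved
  expect_equal(order(nm$counts[, 1]), order(m[, 1])) # ranks untouched

  same <- signal_matrix(cbind(c(1, 2), c(2, 1)), c("x", "y"))
  expect_equal(normalize_total(same)$counts, same$counts)

  expect_error(normalize_total(signal_matrix(cbind(c(0, 0), c(1, 1)), c("x", "y"))),
               "zero-total")

  # library sizes override column sums
  lib <- signal_matrix(m, c("x", "y"), lib_size = c(2e6, 4e6))
  nl <- normalize_total(lib)
  expect_equal(unname(nl$counts[, 2]), unname(m[, 2] * 3e6 / 4e6))
})

test_that("simple_differential reproduces hand arithmetic and guards ties", {
  m <- cbind(a1 = rep(10, 4), a2 = rep(10, 4), b1 = rep(310, 4), b2 = rep(310, 4))
  sm <- signal_matrix(m, c("a", "a", "b", "b"), normalized = TRUE)
  d <- simple_differential(sm, "a", "b")
  expect_equal(d$log2fc, rep(log2(311 / 11), 4), tolerance = 1e-12)

  same <- signal_matrix(cbind(a1 = 1:4, a2 = 1:4, b1 = 1:4, b2 = 1:4),
                        c("a", "a", "b", "b"), normalized = TRUE)
  ds <- simple_differential(same, "a", "b")
  expect_equal(ds$log2fc, rep(0, 4))
  expect_equal(ds$pvalue, rep(1, 4))

  expect_error(simple_differential(signal_matrix(cbind(1:3, 1:3), c("a", "b")),
                                   "a", "b"), ">= 2 replicates")
})

test_that("simple_differential p-values match Welch t.test", {
  set.seed(12)
  m <- matrix(rnbinom(60, mu = 80, size = 20), ncol = 6)
  sm <- signal_matrix(m, rep(c("a", "b"), each = 3), normalized = TRUE)
  d <- simple_differential(sm, "a", "b")
  for (i in 1:10) {
    ref <- t.test(log2(m[i, 4:6] + 1), log2(m[i, 1:3] + 1))$p.value
    expect_equal(d$pvalue[i], ref, tolerance = 1e-10)
  }
})

test_that("feeding classification applies the cutoff rule and partitions peaks", {
  d <- make_diff(c("p1", "p2", "p3", "p4"),
                 log2fc = c(1, 0.2, -0.3, -2),
                 pvalue = c(0.005, 0.5, 0.009, 0.5))
  cl <- classify_feeding(d, alpha = 0.01)
  expect_equal(as.character(cl),
               c("feeding_gained", "static", "feeding_lost", "static"))
  expect_equal(sum(table(cl)), 4)     # labels partition the universe
})

test_that("temporal classification gives week 1 precedence", {
  ids <- paste0("p", 1:5)
  d1 <- make_diff(ids, log2fc = c(2, 0.1, 0, 1.5, -1),
                  pvalue = c(0.001, 0.2, 0.9, 0.001, 0.004))
  d3 <- make_diff(ids, log2fc = c(0.1, -1.4, 0, -2, 1),
                  pvalue = c(0.5, 0.004, 0.8, 0.001, 0.5))
  cl <- classify_temporal(d1, d3, alpha = 0.01)
  expect_equal(as.character(cl),
               c("gained_first_wk1",   # sig wk1 up, ns wk3
                 "lost_first_wk3",     # ns wk1, sig wk3 down
                 "static",
                 "gained_first_wk1",   # sig both: wk1 wins
                 "lost_first_wk1"))
  # shuffled row order of the second table must not matter
  cl2 <- classify_temporal(d1, d3[c(3, 1, 5, 2, 4), ], alpha = 0.01)
  expect_equal(cl, cl2)
  expect_error(classify_temporal(d1, make_diff("px", 1, 0.5)), "different peak universes")
})

test_that("signal correlation behaves at the rank extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(signal_correlation(x, x)$rho, 1)
  expect_equal(signal_correlation(x, -x)$rho, -1)
})

test_that("class summaries compute 1.5*IQR whiskers and mean ratios", {
  sig <- c(2, 4, 1, 1)
  lab <- factor(c("A", "A", "B", "B"))
  cs <- class_signal_summary(sig, lab)
  expect_equal(unname(cs$mean_ratio["A", "B"]), 3)
  expect_equal(unname(cs$mean_ratio["B", "A"]), 1 / 3)
  expect_equal(diag(cs$mean_ratio), c(A = 1, B = 1))

  set.seed(4)
  v <- c(rnorm(50), 8, -7)            # outliers beyond the whiskers
  lab2 <- factor(rep("A", 52))
  st <- class_signal_summary(v, lab2)$stats
  bx <- grDevices::boxplot.stats(v, coef = 1.5)$stats
  expect_equal(st$whisker_lo, bx[1])
  expect_equal(st$whisker_hi, bx[5])
  expect_equal(st$median, bx[3])
})

test_that("binned profiles localize a delta-like track at peak centers", {
  g <- genome(c(chr1 = 1e5))
  centers <- c(20000, 50000, 80000)
  trk <- coverage_track(rep("chr1", 3), centers - 10, centers + 10,
                        rep(5, 3), g)
  peaks <- interval_set("chr1", centers - 250, centers + 250, genome = g)
  pr <- binned_profile(trk, peaks, span = 2000, bin_bp = 100)
  expect_equal(nrow(pr), 40)
  top <- which.max(pr$mean_signal)
  expect_lte(abs(pr$offset_start[top]), 100)   # maximum at the central bins
  expect_equal(sum(pr$mean_signal * 100), 5 * 20)  # total mass conserved
})
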