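link_genome <- function() genome(c(chr1 = 1e6, chr2 = 1e6))

test_that("anchor flanking extends and clamps both anchors", {
  g <- link_genome()
  a1 <- interval_set("chr1", c(10000, 2000), c(15000, 4000), genome = g)
  a2 <- interval_set("chr1", c(50000, 900000), c(55000, 999000), genome = g)
  lp <- loop_set(a1, a2)
  fl <- flank_anchors(lp, 5000)
  expect_equal(fl$start1, c(5000, 0))          # clamp at 0
  expect_equal(fl$end1, c(20000, 9000))
  expect_equal(fl$end2, c(60000, 1e6))         # clamp at chromosome end
  expect_equal(as.data.frame(flank_anchors(lp, 0)), as.data.frame(lp))
})

test_that("variant filtering is strictly below the cutoff", {
  g <- link_genome()
  v <- variant_table("chr1", c(100, 200, 300), c("a", "b", "c"),
                     c(0.05, 0.049, 0.5), g)
  kept <- filter_variants(v, 0.05)
  expect_equal(kept$id, "b")                   # p = 0.05 excluded
  empty <- variant_table(character(), numeric(), character(), numeric(), g)
  expect_equal(nrow(filter_variants(empty)), 0)
  expect_error(variant_table("chr1", 100, "x", 0, g), "p-values")
  expect_error(variant_table("chr1", 2e6, "x", 0.5, g), "outside")
})

test_that("sites link to genes through flanked co-anchoring", {
  g <- link_genome()
  lp <- loop_set(interval_set("chr1", 10000, 15000, genome = g),
                 interval_set("chr1", 50000, 55000, genome = g),
                 name = "L1")
  prom <- interval_set("chr1", 52000, 52001, name = "geneA", genome = g)
  site <- interval_set("chr1", 6000, 6100, name = "S1", genome = g)
  lk <- link_sites_to_genes(site, lp, prom, flank_bp = 5000)
  expect_equal(lk$site_id, "S1")               # site in anchor1 +/- 5 kb
  expect_equal(lk$gene_id, "geneA")            # TSS in anchor2 +/- 5 kb

  far <- interval_set("chr1", 700000, 700100, name = "S2", genome = g)
  expect_equal(nrow(link_sites_to_genes(far, lp, prom)), 0)

  # swapping anchors changes nothing
  swapped <- loop_set(interval_set("chr1", 50000, 55000, genome = g),
                      interval_set("chr1", 10000, 15000, genome = g),
                      name = "L1")
  expect_equal(link_sites_to_genes(site, swapped, prom, flank_bp = 5000),
               lk)

  # a site spanning both flanked anchors yields one deduplicated row
  wide <- interval_set("chr1", 12000, 52500, name = "S3", genome = g)
  lk3 <- link_sites_to_genes(wide, lp, prom, flank_bp = 5000)
  expect_equal(nrow(lk3), 1)

  expect_error(link_sites_to_genes(site, lp,
                                   interval_set("chr1", 1, 2, genome = g)),
               "gene id")
})

test_that("link tables are monotone in the anchor flank", {
  g <- link_genome()
  set.seed(71)
  s <- sample(9e5, 30)
  sites <- interval_set("chr1", s, s + 200, name = sprintf("S%02d", 1:30),
                        genome = g)
  a1 <- sample(9e5, 15); a2 <- sample(9e5, 15)
  lp <- loop_set(interval_set("chr1", a1, a1 + 4000, genome = g),
                 interval_set("chr1", a2, a2 + 4000, genome = g))
  tp <- sample(9e5, 40)
  prom <- interval_set("chr1", tp, tp + 1, name = sprintf("G%02d", 1:40),
                       genome = g)
  prev <- 0
  for (fl in c(0, 2000, 5000, 20000)) {
    lk <- link_sites_to_genes(sites, lp, prom, flank_bp = fl)
    expect_gte(nrow(lk), prev)
    prev <- nrow(lk)
  }
})

test_that("variant-linked gene sets restrict to variant-bearing sites", {
  g <- link_genome()
  sites <- interval_set("chr1", c(6000, 300000), c(6100, 300100),
                        name = c("S1", "S2"), genome = g, role = "sites")
  lp <- loop_set(interval_set("chr1", c(10000, 295000), c(15000, 299000), genome = g),
                 interval_set("chr1", c(50000, 600000), c(55000, 604000), genome = g),
                 name = c("L1", "L2"))
  prom <- interval_set("chr1", c(52000, 601000), c(52001, 601001),
                       name = c("geneA", "geneB"), genome = g)

  # no qualifying variant -> empty set
  v0 <- variant_table("chr1", 6050, "rs1", 0.5, g)
  r0 <- variant_linked_geneset(sites, v0, lp, prom)
  expect_equal(r0$genes, character())

  # one variant in S1 links geneA only
  v1 <- variant_table("chr1", c(6050, 1000), c("rs1", "rs2"), c(0.01, 0.001), g)
  r1 <- variant_linked_geneset(sites, v1, lp, prom)
  expect_equal(r1$genes, "geneA")
  expect_equal(r1$links$variant_id, "rs1")

  # a site linked to two genes via two loops yields a two-gene set
  lp2 <- loop_set(interval_set("chr1", c(10000, 4000), c(15000, 8000), genome = g),
                  interval_set("chr1", c(50000, 600000), c(55000, 604000), genome = g),
                  name = c("L1", "L2"))
  r2 <- variant_linked_geneset(sites, v1, lp2, prom)
  expect_equal(r2$genes, c("geneA", "geneB"))

  # p exactly at alpha does not qualify
  v_edge <- variant_table("chr1", 6050, "rs1", 0.05, g)
  expect_equal(variant_linked_geneset(sites, v_edge, lp, prom)$genes, character())

  # the flanked-site rule is opt-in
  v_near <- variant_table("chr1", 6150, "rs9", 0.01, g)   # 50 bp past S1
  expect_equal(variant_linked_geneset(sites, v_near, lp, prom)$genes, character())
  expect_equal(variant_linked_geneset(sites, v_near, lp, prom,
                                      variant_in_flanked = TRUE)$genes, "geneA")
})

test_that("BEDPE and variant tables round-trip", {
  g <- link_genome()
  lp <- loop_set(interval_set("chr1", c(100, 5000), c(600, 9000), genome = g),
                 interval_set(c("chr1", "chr2"), c(90000, 100), c(94000, 4100), genome = g),
                 name = c("La", "Lb"), score = c(1.5, NA))
  path <- withr::local_tempfile()
  write_bedpe(lp, path)
  back <- read_bedpe(path, g)
  expect_equal(back$start1, lp$start1)
  expect_equal(back$chrom2, lp$chrom2)
  expect_equal(back$trans, c(FALSE, TRUE))     # trans loop flagged

  v <- variant_table("chr2", c(10, 20), c("rs1", "rs2"), c(0.5, 0.001), g)
  pv <- withr::local_tempfile()
  write_variants(v, pv)
  expect_equal(as.data.frame(read_variants(pv, g)), as.data.frame(v))
})
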