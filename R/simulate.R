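#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the feeding/fasting study design the pipeline targets:
#' 3 replicates per nutrient state, negative-binomial peak counts with
#' dispersion 0.05, 44% of peaks nutrient-regulated with 99.9% of those
#' gaining signal on feeding (planted |log2FC| = 2), DE-gene TSSs enriched
#' near gained peaks at 5-fold odds within +/- 10 kb, a second bound-factor
#' track rank-correlated with peak signal at rho = 0.8, loops wiring
#' variant-bearing bound sites to isolated promoters, and trait variants
#' with uniform background p-values but low p-values inside designated
#' sites.
#'
#' @param seed master seed; every component draws from a named substream of
#'   it, so components are reproducible independently and in any order.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_peaks number of (non-overlapping) peaks.
#' @param peak_len min/max peak length in bp.
#' @param replicates replicates per condition.
#' @param nb_mean,nb_sdlog baseline negative-binomial mean and the log-normal
#'   spread of per-peak means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth_sdlog log-normal sd of per-replicate sequencing-depth
#'   factors (0 gives equal-depth libraries).
#' @param lib_tags notional total tags per library at unit depth; each
#'   replicate's emitted library size is `lib_tags` times its depth factor,
#'   the quantity depth normalization divides out.
#' @param f_gained,f_lost planted fractions of feeding-gained / -lost peaks.
#' @param log2fc planted |log2 fold change| for regulated peaks.
#' @param n_tss number of genes/TSSs; `f_de` of them are "DE genes".
#' @param f_de fraction of genes planted as differentially expressed.
#' @param tss_window window (bp) defining TSS-to-gained-peak proximity.
#' @param tss_odds odds multiplier for DE-gene TSSs landing near gained peaks.
#' @param rho_second target Spearman correlation of the second binding track
#'   with peak signal (Gaussian copula).
#' @param f_bound fraction of peaks called bound by the second factor.
#' @param n_loops total loops; `n_true_links` of them wire a designated
#'   variant-bearing bound site to a gene promoter, the rest are decoys whose
#'   promoter-side anchor is kept clear of every TSS.
#' @param n_true_links number of planted site-to-gene links.
#' @param anchor_half loop anchor half-width (bp).
#' @param flank_bp anchor flank used downstream (kept here so decoy
#'   placement respects it).
#' @param n_variants background variants (uniform p, placed outside bound
#'   sites).
#' @param variant_alpha retention cutoff the designated in-site variants are
#'   guaranteed to pass (their p is Beta(0.1, 1) conditioned below it).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chr1 = 2e7, chr2 = 2e7, chr3 = 2e7),
                       n_peaks = 2000, peak_len = c(200, 1000),
                       replicates = 3, nb_mean = 100, nb_sdlog = 1,
                       dispersion = 0.05, depth_sdlog = 0.15, lib_tags = 2e7,
                       f_gained = 0.44, f_lost = 0.001, log2fc = 2,
                       n_tss = 1000, f_de = 0.3,
                       tss_window = 10000, tss_odds = 5,
                       rho_second = 0.8, f_bound = 0.3,
                       n_loops = 120, n_true_links = 20,
                       anchor_half = 2000, flank_bp = 5000,
                       n_variants = 500, variant_alpha = 0.05) {
  stopifnot(f_gained >= 0, f_lost >= 0, f_gained + f_lost <= 1,
            dispersion > 0, n_peaks >= 1, replicates >= 1,
            peak_len[1] >= 1, peak_len[2] >= peak_len[1],
            tss_odds > 0, rho_second > -1, rho_second < 1,
            n_true_links <= n_loops)
  structure(as.list(environment()), class = "sim_config")
}

# place n non-overlapping intervals of the given lengths uniformly, avoiding
# an optional merged exclusion region; error when the genome cannot hold them
place_nonoverlapping <- function(lens, g, offs, avoid_s = numeric(), avoid_e = numeric(),
                                 max_rounds = 200) {
  n <- length(lens)
  if (sum(lens) + sum(avoid_e - avoid_s) > genome_size(g))
    stop2("infeasible placement: genome too small for the requested intervals")
  acc_s <- avoid_s; acc_e <- avoid_e
  out_s <- numeric(n); out_e <- numeric(n)
  todo <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    if (length(todo) == 0) break
    prop <- shuffle_global(lens[todo], g, offs)
    m <- length(acc_s)
    s <- c(acc_s, prop$s); e <- c(acc_e, prop$e)
    is_new <- c(rep(FALSE, m), rep(TRUE, length(todo)))
    o <- order(s, e)
    s <- s[o]; e <- e[o]; idx <- c(rep(0L, m), seq_along(todo))[o]
    cm <- cummax(c(-Inf, e[-length(e)]))
    ok_sorted <- s >= cm & is_new[o]
    keep <- idx[ok_sorted]
    if (length(keep)) {
      ki <- todo[keep]
      pos <- match(keep, seq_along(todo))
      out_s[ki] <- prop$s[pos]; out_e[ki] <- prop$e[pos]
      acc_s <- c(acc_s, prop$s[pos]); acc_e <- c(acc_e, prop$e[pos])
      todo <- setdiff(todo, ki)
    }
  }
  if (length(todo) > 0)
    stop2("infeasible placement: could not place ", length(todo),
          " interval(s) without overlap")
  list(s = out_s, e = out_e)
}

# complement of sorted disjoint global segments within chromosome bounds
complement_global <- function(cov_s, cov_e, g, offs) {
  L <- as.numeric(g)
  gs <- numeric(0); ge <- numeric(0)
  for (c in seq_along(L)) {
    lo <- offs[c]; hi <- offs[c] + L[c]
    in_c <- cov_s < hi & cov_e > lo
    cs <- pmax(cov_s[in_c], lo); ce <- pmin(cov_e[in_c], hi)
    o <- order(cs)
    cs <- cs[o]; ce <- ce[o]
    edges_s <- c(lo, ce); edges_e <- c(cs, hi)
    keep <- edges_e > edges_s
    gs <- c(gs, edges_s[keep]); ge <- c(ge, edges_e[keep])
  }
  list(s = gs, e = ge)
}

# uniform positions inside a union of global segments
sample_positions_in <- function(n, seg_s, seg_e) {
  lens <- seg_e - seg_s
  if (n == 0) return(numeric(0))
  if (sum(lens) <= 0) stop2("cannot sample positions: empty region")
  i <- sample.int(length(lens), n, replace = TRUE, prob = lens)
  floor(seg_s[i] + stats::runif(n) * lens[i])
}

global_to_chrom <- function(pos, g, offs) {
  ci <- findInterval(pos, offs)
  list(chrom = names(g)[ci], pos = pos - offs[ci])
}

#' Simulate a complete synthetic chromatin dataset with planted truth
#'
#' Generates an internally consistent toy dataset mirroring the statistical
#' structure of a fed/fasted chromatin study: a genome, non-overlapping
#' peaks with replicate negative-binomial counts and planted
#' feeding-gained/lost classes, gene TSSs spatially enriched near gained
#' peaks for the planted DE genes, a second bound-factor signal
#' rank-correlated with peak signal via a Gaussian copula, bound sites,
#' chromatin loops wiring designated variant-bearing sites to isolated
#' promoters (plus decoy loops that can never produce a link), and a
#' variant table whose designated in-site variants are guaranteed to pass
#' the nominal-association filter. Every planted label is returned as
#' machine-readable truth.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; when given, the bundle is written out as
#'   plain-text files (chrom.sizes, peaks.bed, counts.tsv, tss.bed,
#'   second_signal.tsv, bound_sites.bed, loops.bedpe, variants.tsv,
#'   truth.json).
#' @return a `sim_bundle` list: `genome`, `peaks`, `counts`
#'   ([signal_matrix()]), `tss`, `second_signal` (numeric per peak),
#'   `bound_sites`, `loops`, `variants`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  g <- genome(cf$chrom_lengths)
  offs <- genome_offsets(g)

  ## peaks + classes ---------------------------------------------------------
  pk <- with_seed(substream_seed(cf$seed, "peaks"), {
    lens <- sample(cf$peak_len[1]:cf$peak_len[2], cf$n_peaks, replace = TRUE)
    pl <- place_nonoverlapping(lens, g, offs)
    n_g <- round(cf$f_gained * cf$n_peaks)
    n_l <- round(cf$f_lost * cf$n_peaks)
    cls <- rep("static", cf$n_peaks)
    cls[sample.int(cf$n_peaks, n_g + n_l)] <- c(rep("feeding_gained", n_g),
                                                rep("feeding_lost", n_l))
    list(s = pl$s, e = pl$e, class = cls)
  })
  loc <- global_to_chrom(pk$s, g, offs)
  peak_ids <- sprintf("peak_%04d", seq_len(cf$n_peaks))
  peaks <- interval_set(loc$chrom, loc$pos, loc$pos + (pk$e - pk$s),
                        name = peak_ids, genome = g, role = "peaks")
  peak_class <- factor(setNames(pk$class, peak_ids),
                       levels = c("feeding_gained", "feeding_lost", "static"))

  ## replicate NB counts -----------------------------------------------------
  counts <- with_seed(substream_seed(cf$seed, "counts"), {
    base_mu <- stats::rlnorm(cf$n_peaks, log(cf$nb_mean) - cf$nb_sdlog^2 / 2,
                             cf$nb_sdlog)
    mult <- ifelse(pk$class == "feeding_gained", 2^cf$log2fc,
                   ifelse(pk$class == "feeding_lost", 2^-cf$log2fc, 1))
    size <- 1 / cf$dispersion
    depth <- stats::rlnorm(2 * cf$replicates, -cf$depth_sdlog^2 / 2, cf$depth_sdlog)
    m <- matrix(0, cf$n_peaks, 2 * cf$replicates)
    for (r in seq_len(cf$replicates)) {
      m[, r] <- stats::rnbinom(cf$n_peaks, mu = base_mu * depth[r], size = size)
      m[, cf$replicates + r] <- stats::rnbinom(
        cf$n_peaks, mu = base_mu * mult * depth[cf$replicates + r], size = size)
    }
    rownames(m) <- peak_ids
    colnames(m) <- c(sprintf("fasted_%d", seq_len(cf$replicates)),
                     sprintf("fed_%d", seq_len(cf$replicates)))
    list(m = m, base_mu = base_mu, lib_size = round(cf$lib_tags * depth))
  })
  sm <- signal_matrix(counts$m,
                      rep(c("fasted", "fed"), each = cf$replicates),
                      peaks = peaks, lib_size = counts$lib_size)

  ## TSSs with planted proximity odds ---------------------------------------
  gained <- peaks[peak_class == "feeding_gained"]
  attr(gained, "role") <- "gained_peaks"
  near <- if (nrow(gained) > 0)
    merge_intervals(extend_intervals(gained, cf$tss_window)) else NULL
  tss_dat <- with_seed(substream_seed(cf$seed, "tss"), {
    n_de <- round(cf$f_de * cf$n_tss)
    de <- rep(FALSE, cf$n_tss)
    de[sample.int(cf$n_tss, n_de)] <- TRUE
    if (is.null(near) || nrow(near) == 0) {
      pos <- sample_positions_in(cf$n_tss, offs, offs + as.numeric(g))
    } else {
      cov <- global_coords(near, offs)
      comp <- complement_global(cov$s, cov$e, g, offs)
      p0 <- sum(cov$e - cov$s) / genome_size(g)
      odds1 <- cf$tss_odds * p0 / (1 - p0)
      p1 <- min(odds1 / (1 + odds1), 0.99)
      inside <- ifelse(de, stats::runif(cf$n_tss) < p1,
                       stats::runif(cf$n_tss) < p0)
      pos <- numeric(cf$n_tss)
      pos[inside] <- sample_positions_in(sum(inside), cov$s, cov$e)
      pos[!inside] <- sample_positions_in(sum(!inside), comp$s, comp$e)
    }
    list(pos = pos, de = de)
  })
  gene_ids <- sprintf("gene_%04d", seq_len(cf$n_tss))
  tl <- global_to_chrom(tss_dat$pos, g, offs)
  tss <- interval_set(tl$chrom, tl$pos, tl$pos + 1, name = gene_ids,
                      genome = g, role = "TSS")

  ## second binding track (Gaussian copula on realized peak signal) ---------
  second <- with_seed(substream_seed(cf$seed, "second"), {
    x <- rowMeans(counts$m)
    z1 <- stats::qnorm((rank(x, ties.method = "average") - 0.5) / cf$n_peaks)
    r <- 2 * sin(pi * cf$rho_second / 6)     # Spearman -> Pearson on the copula
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(cf$n_peaks)
    exp(z2)                                   # monotone map; rank structure kept
  })
  names(second) <- peak_ids
  n_bound <- round(cf$f_bound * cf$n_peaks)
  bound_idx <- order(second, decreasing = TRUE)[seq_len(n_bound)]
  bound_idx <- sort(bound_idx)
  bound_sites <- peaks[bound_idx]
  attr(bound_sites, "role") <- "bound_sites"

  ## loops + variants with planted links ------------------------------------
  lv <- with_seed(substream_seed(cf$seed, "loops"), {
    bs <- pk$s[bound_idx]; be <- pk$e[bound_idx]
    bctr <- floor((bs + be) / 2)
    reach <- cf$anchor_half + cf$flank_bp
    # designated sites: pairwise separation > 3x reach so one flanked anchor
    # can only ever touch its own site
    ord <- sample.int(length(bctr))
    chosen <- integer(0)
    for (i in ord) {
      if (all(abs(bctr[i] - bctr[chosen]) > 3 * reach)) chosen <- c(chosen, i)
      if (length(chosen) == cf$n_true_links) break
    }
    if (length(chosen) < cf$n_true_links)
      stop2("infeasible placement: cannot space ", cf$n_true_links,
            " designated sites")
    # target genes: TSSs isolated from every other TSS by > reach
    tpos <- sort(tss_dat$pos)
    gap_ok <- c(Inf, diff(tpos)) > reach & c(diff(tpos), Inf) > reach
    iso <- match(tpos[gap_ok], tss_dat$pos)
    iso <- iso[!is.na(iso)]
    if (length(iso) < cf$n_true_links)
      stop2("infeasible placement: too few isolated TSSs for true links")
    tgt <- sample(iso, cf$n_true_links)
    a1s <- bctr[chosen] - cf$anchor_half
    a1e <- bctr[chosen] + cf$anchor_half
    a2s <- tss_dat$pos[tgt] - cf$anchor_half
    a2e <- tss_dat$pos[tgt] + cf$anchor_half
    # decoy loops: promoter-side anchor sampled outside TSS reach so a decoy
    # can never satisfy the linking rule
    n_dec <- cf$n_loops - cf$n_true_links
    tss_near <- list(s = tss_dat$pos - reach, e = tss_dat$pos + reach + 1)
    o <- order(tss_near$s)
    ts <- tss_near$s[o]; te <- tss_near$e[o]
    cm <- cummax(te)
    grp <- cumsum(ts > c(-Inf, cm[-length(cm)]))
    ms <- ts[!duplicated(grp)]; me <- as.numeric(tapply(te, grp, max))
    ms <- pmax(ms, 0)
    comp <- complement_global(ms, me, g, offs)
    d2 <- sample_positions_in(n_dec, comp$s, comp$e)
    d1 <- sample_positions_in(n_dec, offs, offs + as.numeric(g))
    list(chosen = chosen, tgt = tgt,
         a1s = c(a1s, d1 - cf$anchor_half), a1e = c(a1e, d1 + cf$anchor_half),
         a2s = c(a2s, d2 - cf$anchor_half), a2e = c(a2e, d2 + cf$anchor_half))
  })
  clamp_anchor <- function(s, e) {
    ci <- findInterval(pmax(s, (e + s) / 2), offs)  # chrom of the anchor center
    lo <- offs[ci]; hi <- offs[ci] + as.numeric(g)[ci]
    list(s = pmax(s, lo), e = pmin(e, hi), ci = ci)
  }
  a1 <- clamp_anchor(lv$a1s, lv$a1e)
  a2 <- clamp_anchor(lv$a2s, lv$a2e)
  loop_ids <- sprintf("loop_%03d", seq_along(a1$s))
  loops <- loop_set(
    interval_set(names(g)[a1$ci], a1$s - offs[a1$ci], a1$e - offs[a1$ci], genome = g),
    interval_set(names(g)[a2$ci], a2$s - offs[a2$ci], a2$e - offs[a2$ci], genome = g),
    name = loop_ids)

  site_ids <- bound_sites$name
  true_links <- data.frame(site_id = site_ids[lv$chosen],
                           gene_id = gene_ids[lv$tgt],
                           loop_id = loop_ids[seq_len(cf$n_true_links)],
                           stringsAsFactors = FALSE)

  variants <- with_seed(substream_seed(cf$seed, "variants"), {
    cov <- list(s = pk$s[bound_idx], e = pk$e[bound_idx])
    comp <- complement_global(cov$s, cov$e, g, offs)
    bg_pos <- sample_positions_in(cf$n_variants, comp$s, comp$e)
    bg_p <- stats::runif(cf$n_variants)
    ds <- pk$s[bound_idx][lv$chosen]; de <- pk$e[bound_idx][lv$chosen]
    in_pos <- floor(ds + stats::runif(length(ds)) * (de - ds))
    # Beta(0.1, 1)-style low p, conditioned below the retention cutoff so the
    # planted links are real by construction
    in_p <- vapply(seq_along(ds), function(i) {
      repeat { p <- stats::rbeta(1, 0.1, 1); if (p < cf$variant_alpha && p > 0) return(p) }
    }, numeric(1))
    pos <- c(bg_pos, in_pos)
    p <- c(bg_p, in_p)
    lc <- global_to_chrom(pos, g, offs)
    variant_table(lc$chrom, lc$pos,
                  sprintf("rs%05d", seq_along(pos)), pmin(p, 1), g)
  })
  truth_variant_sites <- setNames(site_ids[lv$chosen],
                                  sprintf("rs%05d", cf$n_variants + seq_len(cf$n_true_links)))

  truth <- list(peak_class = as.character(peak_class),
                peak_ids = peak_ids,
                de_genes = gene_ids[tss_dat$de],
                bound_sites = site_ids,
                designated_sites = site_ids[lv$chosen],
                links = true_links,
                variant_site = as.list(truth_variant_sites),
                rho_target = cf$rho_second,
                log2fc = cf$log2fc,
                seed = cf$seed)

  bundle <- structure(list(genome = g, peaks = peaks, counts = sm,
                           peak_class = peak_class, tss = tss,
                           second_signal = second, bound_sites = bound_sites,
                           loops = loops, variants = variants,
                           truth = truth, config = cf),
                      class = "sim_bundle")
  if (!is.null(dir)) write_sim_bundle(bundle, dir)
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("synthetic dataset (seed %d): %d peaks (%s), %d TSSs, %d bound sites, %d loops, %d variants\n",
              x$config$seed, nrow(x$peaks),
              paste(sprintf("%s=%d", levels(x$peak_class), table(x$peak_class)),
                    collapse = ", "),
              nrow(x$tss), nrow(x$bound_sites), nrow(x$loops), nrow(x$variants)))
  invisible(x)
}

#' Write a simulated bundle to plain-text files
#'
#' @param bundle a `sim_bundle` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_chrom_sizes(bundle$genome, p("chrom.sizes"))
  write_bed(bundle$peaks, p("peaks.bed"))
  write_bed(bundle$tss, p("tss.bed"))
  write_bed(bundle$bound_sites, p("bound_sites.bed"))
  write_bedpe(bundle$loops, p("loops.bedpe"))
  write_variants(bundle$variants, p("variants.tsv"))
  cm <- data.frame(peak_id = rownames(bundle$counts$counts),
                   bundle$counts$counts, check.names = FALSE)
  utils::write.table(cm, p("counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cond <- data.frame(replicate = colnames(bundle$counts$counts),
                     condition = bundle$counts$conditions)
  if (!is.null(bundle$counts$lib_size)) cond$library_size <- bundle$counts$lib_size
  utils::write.table(cond, p("conditions.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(peak_id = names(bundle$second_signal),
                                signal = bundle$second_signal),
                     p("second_signal.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a counts TSV + conditions TSV back into a signal matrix
#'
#' @param counts_path TSV with `peak_id` then one column per replicate.
#' @param conditions_path TSV with `replicate`, `condition`.
#' @param peaks optional [interval_set()] aligned with the rows.
#' @return a raw [signal_matrix()].
#' @export
read_signal_matrix <- function(counts_path, conditions_path, peaks = NULL) {
  cm <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cond <- utils::read.table(conditions_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(cm[, -1, drop = FALSE])
  rownames(m) <- cm[[1]]
  i <- match(colnames(m), cond$replicate)
  if (any(is.na(i))) stop2("conditions file does not cover every replicate column")
  signal_matrix(m, cond$condition[i], peaks = peaks,
                lib_size = cond$library_size[i])
}

#' Simulate a two-comparison expression log2FC matrix with planted clusters
#'
#' Genes fall into `k` Gaussian clusters in the 2-D space of log2 fold
#' changes (comparison 1 = feeding response, comparison 2 = disease-model
#' response). One cluster sits in the (+,+) quadrant: the planted
#' "nutrient-response" block upregulated in both comparisons.
#'
#' @param n_genes number of genes.
#' @param k number of clusters (>= 2; cluster 1 is the (+,+) block).
#' @param centers k x 2 matrix of cluster centers; the default puts cluster
#'   1 at (1.5, 1.5) and spreads the rest across the other quadrants.
#' @param sizes integer cluster sizes (default: 15% of genes in the planted
#'   block, remainder split evenly).
#' @param sigma per-gene Gaussian noise sd around the center.
#' @param seed integer seed.
#' @return list with `log2fc` (genes x 2 matrix, columns `cmp1`, `cmp2`),
#'   `truth` (named integer cluster per gene), `nutrient_genes` (ids of the
#'   planted (+,+) block).
#' @export
simulate_expression <- function(n_genes = 2000, k = 4, centers = NULL,
                                sizes = NULL, sigma = 0.25, seed = 1) {
  stopifnot(k >= 2)
  if (is.null(centers)) {
    base <- matrix(c(1.5, 1.5, -1.5, -1.5, 1.5, -1.5, 0, 0, -1.5, 1.5),
                   ncol = 2, byrow = TRUE)
    if (k > nrow(base)) stop2("provide centers for k > 5")
    centers <- base[seq_len(k), , drop = FALSE]
  }
  stopifnot(nrow(centers) == k, ncol(centers) == 2)
  if (is.null(sizes)) {
    n1 <- round(0.15 * n_genes)
    rest <- n_genes - n1
    sizes <- c(n1, rep(rest %/% (k - 1), k - 1))
    sizes[k] <- sizes[k] + rest - sum(sizes[-1])
  }
  stopifnot(sum(sizes) == n_genes, all(sizes >= 1))
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  dat <- with_seed(seed, {
    cl <- sample(rep(seq_len(k), sizes))   # decouple cluster from gene id
    list(cl = cl,
         m = centers[cl, , drop = FALSE] +
           matrix(stats::rnorm(2 * n_genes, 0, sigma), ncol = 2))
  })
  cl <- dat$cl
  m <- dat$m
  dimnames(m) <- list(ids, c("cmp1", "cmp2"))
  list(log2fc = m, truth = setNames(cl, ids), nutrient_genes = ids[cl == 1])
}
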