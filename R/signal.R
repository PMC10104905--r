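#' Replicate signal matrix at peaks
#'
#' Holds raw or depth-normalized per-peak, per-replicate signal (tag counts
#' or summed coverage) together with the condition label of each replicate
#' column and, optionally, the peak coordinates.
#'
#' @param counts numeric matrix, peaks x replicates, non-negative; rownames
#'   are peak ids (generated when absent).
#' @param conditions character/factor of length `ncol(counts)` giving each
#'   replicate's condition (e.g. "fasted"/"fed", "wk1_ctrl"/"wk1_ko").
#' @param peaks optional [interval_set()] aligned with the rows.
#' @param lib_size optional per-replicate library sizes (total tags in each
#'   library). When present, depth normalization scales by library size
#'   rather than by the column sums over the quantified peaks — the matrix
#'   is only a window on the library, so its column sums confound depth with
#'   genuine signal change.
#' @param normalized logical; TRUE once depth normalization has been applied.
#' @return an object of class `signal_matrix`.
#' @export
signal_matrix <- function(counts, conditions, peaks = NULL, lib_size = NULL,
                          normalized = FALSE) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop2("counts must be finite and non-negative")
  if (length(conditions) != ncol(counts))
    stop2("one condition label per replicate column required")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("peak_%d", seq_len(nrow(counts)))
  if (anyDuplicated(rownames(counts))) stop2("peak ids must be unique")
  if (!is.null(peaks)) {
    stopifnot(inherits(peaks, "interval_set"))
    if (nrow(peaks) != nrow(counts)) stop2("peaks and counts row mismatch")
  }
  if (!is.null(lib_size)) {
    if (length(lib_size) != ncol(counts) || any(!is.finite(lib_size)) ||
        any(lib_size <= 0))
      stop2("lib_size needs one positive value per replicate column")
  }
  structure(list(counts = counts, conditions = as.character(conditions),
                 peaks = peaks, lib_size = lib_size,
                 normalized = isTRUE(normalized)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d peaks x %d replicates (%s)%s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$conditions), collapse = ", "),
              if (x$normalized) " [normalized]" else " [raw]"))
  invisible(x)
}

#' @export
as.matrix.signal_matrix <- function(x, ...) x$counts

#' Per-base coverage track (bedGraph)
#'
#' A sorted, non-overlapping set of scored segments giving signal per base.
#'
#' @param chrom,start,end 0-based half-open segment coordinates.
#' @param value numeric signal over each segment.
#' @param genome bound [genome()].
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(chrom, start, end, value, genome) {
  iv <- interval_set(chrom, start, end, genome = genome, role = "coverage")
  if (length(value) != nrow(iv)) stop2("one value per segment required")
  if (any(!is.finite(value))) stop2("values must be finite")
  offs <- genome_offsets(genome)
  gc <- global_coords(iv, offs)
  o <- order(gc$s)
  if (any(gc$s[o][-1] < gc$e[o][-length(o)]))
    stop2("coverage segments overlap; bedGraph tracks must be non-overlapping")
  structure(data.frame(chrom = iv$chrom[o], start = iv$start[o], end = iv$end[o],
                       value = as.numeric(value)[o], stringsAsFactors = FALSE),
            genome = genome, class = c("coverage_track", "data.frame"))
}

#' Read a 4-column bedGraph file
#'
#' @param path file path; `track`, `browser` and `#` lines are skipped.
#' @param genome [genome()] for validation; a segment on a chromosome absent
#'   from the genome is an error.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, genome) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  if (!any(keep))
    return(coverage_track(character(), numeric(), numeric(), numeric(), genome))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) stop2("bedGraph requires 4 columns: ", path)
  coverage_track(vapply(f, `[[`, "", 1),
                 as.numeric(vapply(f, `[[`, "", 2)),
                 as.numeric(vapply(f, `[[`, "", 3)),
                 as.numeric(vapply(f, `[[`, "", 4)), genome)
}

# cumulative coverage mass helper: F(x) = sum of value * bp over [0, x)
coverage_cdf <- function(track) {
  g <- attr(track, "genome")
  offs <- genome_offsets(g)
  s <- offs[track$chrom] + track$start
  e <- offs[track$chrom] + track$end
  v <- track$value
  cw <- cumsum(v * (e - s))
  function(x) {
    k <- findInterval(x - 0.5, s)      # last segment with s < x
    out <- numeric(length(x))
    hit <- k > 0
    kk <- k[hit]
    out[hit] <- c(0, cw)[kk] + v[kk] * pmax(0, pmin(x[hit], e[kk]) - s[kk])
    out
  }
}

peak_centers <- function(peaks) floor((peaks$start + peaks$end) / 2)

# window [center - hw, center + hw) clamped to the chromosome
center_windows <- function(peaks, half_window) {
  g <- iv_genome(peaks)
  ctr <- peak_centers(peaks)
  len <- unclass(g)[peaks$chrom]
  list(ws = pmax(0, ctr - half_window), we = pmin(len, ctr + half_window),
       chrom = peaks$chrom)
}

#' Quantify signal in fixed windows around peak centers
#'
#' For every peak, signal is summed in the window `[center - half_window,
#' center + half_window)` where the center is the floor of the interval
#' midpoint. Each replicate track is either a fragment [interval_set()]
#' (the entry is the number of fragments overlapping the window, after
#' optional extension of each fragment to `frag_length` bp from its start,
#' mirroring the 250 bp tag-extension convention) or a [coverage_track()]
#' (the entry is the summed per-base coverage in the window).
#'
#' @param peaks [interval_set()] of peaks; names become peak ids.
#' @param tracks named list of per-replicate tracks (all fragments or all
#'   coverage); names become column names.
#' @param conditions condition label per track.
#' @param half_window half window in bp (default 1000, i.e. +/- 1 kb).
#' @param frag_length optional fragment extension length in bp applied to
#'   fragment tracks (each fragment becomes `[start, start + frag_length)`,
#'   clamped to the chromosome).
#' @return a raw [signal_matrix()].
#' @export
quantify_signal <- function(peaks, tracks, conditions, half_window = 1000,
                            frag_length = NULL) {
  stopifnot(inherits(peaks, "interval_set"), is.list(tracks),
            length(conditions) == length(tracks), half_window >= 0)
  g <- iv_genome(peaks)
  offs <- genome_offsets(g)
  w <- center_windows(peaks, half_window)
  ws <- offs[w$chrom] + w$ws
  we <- offs[w$chrom] + w$we
  cols <- lapply(tracks, function(tr) {
    if (inherits(tr, "coverage_track")) {
      if (!identical(names(attr(tr, "genome")), names(g)))
        stop2("track chromosome set does not match the peak genome")
      F <- coverage_cdf(tr)
      F(we) - F(ws)
    } else if (inherits(tr, "interval_set")) {
      if (!same_genome(tr, peaks))
        stop2("fragment track genome does not match the peak genome")
      fs <- tr$start
      fe <- tr$end
      if (!is.null(frag_length)) {
        fe <- pmin(unclass(g)[tr$chrom], fs + frag_length)
      }
      gs <- sort(offs[tr$chrom] + fs)
      ge <- sort(offs[tr$chrom] + fe)
      # overlap count = #(frag start < window end) - #(frag end <= window start)
      findInterval(we - 0.5, gs) - findInterval(ws, ge)
    } else stop2("each track must be an interval_set (fragments) or coverage_track")
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(tracks) %||% sprintf("rep_%d", seq_along(tracks))
  rownames(m) <- peaks$name %||% sprintf("peak_%d", seq_len(nrow(peaks)))
  signal_matrix(m, conditions, peaks = peaks, normalized = FALSE)
}

#' Depth-normalize replicate columns to a common total
#'
#' Scales every replicate column so its total equals the mean of the raw
#' totals; within-column structure (and therefore peak ranks) is unchanged.
#' When the matrix carries library sizes those are used as the totals
#' (normalization to total library tags); otherwise the column sums over the
#' quantified peaks are used, in which case the grand total of the matrix is
#' conserved. Column sums are a biased depth estimate when a large share of
#' peaks genuinely changes in one condition, so supply library sizes when
#' they are known.
#'
#' @param x a [signal_matrix()].
#' @param totals optional explicit per-column totals, overriding both the
#'   stored library sizes and the column sums.
#' @return a normalized [signal_matrix()].
#' @export
normalize_total <- function(x, totals = NULL) {
  stopifnot(inherits(x, "signal_matrix"))
  tot <- totals %||% x$lib_size %||% colSums(x$counts)
  if (length(tot) != ncol(x$counts)) stop2("one total per replicate column required")
  if (any(tot == 0)) stop2("zero-total replicate column: ",
                           paste(colnames(x$counts)[tot == 0], collapse = ", "))
  target <- mean(tot)
  counts <- sweep(x$counts, 2, target / tot, `*`)
  signal_matrix(counts, x$conditions, peaks = x$peaks, normalized = TRUE)
}

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Simple per-peak differential test between two conditions
#'
#' A deliberately transparent differential stage: on depth-normalized counts,
#' the effect is `log2((mean_B + 1) / (mean_A + 1))` and the p-value is a
#' two-sided Welch t-test on `log2(count + 1)`. It is a stand-in for a full
#' negative-binomial differential analysis; externally computed tables can be
#' ingested with [read_differential()] instead.
#'
#' @param x a [signal_matrix()]; normalized internally if raw.
#' @param group_a,group_b condition labels (A is the baseline: positive
#'   log2fc means higher in B). Each needs >= 2 replicates.
#' @return a `differential_table` data frame: `peak_id`, `log2fc`, `pvalue`,
#'   `comparison`.
#' @export
simple_differential <- function(x, group_a, group_b) {
  stopifnot(inherits(x, "signal_matrix"))
  if (!x$normalized) x <- normalize_total(x)
  ia <- which(x$conditions == group_a)
  ib <- which(x$conditions == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop2("need >= 2 replicates per group (", group_a, ": ", length(ia),
          ", ", group_b, ": ", length(ib), ")")
  A <- x$counts[, ia, drop = FALSE]
  B <- x$counts[, ib, drop = FALSE]
  log2fc <- log2((rowMeans(B) + 1) / (rowMeans(A) + 1))
  la <- log2(A + 1); lb <- log2(B + 1)
  na <- ncol(la); nb <- ncol(lb)
  va <- row_vars(la); vb <- row_vars(lb)
  se2 <- va / na + vb / nb
  tstat <- (rowMeans(lb) - rowMeans(la)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero] <- ifelse(rowMeans(lb)[zero] == rowMeans(la)[zero], 1, .Machine$double.eps)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  structure(data.frame(peak_id = rownames(x$counts), log2fc = log2fc,
                       pvalue = p,
                       comparison = paste(group_b, "vs", group_a),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("differential_table", "data.frame"))
}

#' Read / write a differential table
#'
#' Tab-separated with header `peak_id`, `log2fc`, `pvalue` (optionally
#' `comparison`); this is also the ingestion point for externally computed
#' differential results.
#'
#' @param path file path.
#' @return `read_differential` returns a `differential_table`.
#' @export
read_differential <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("peak_id", "log2fc", "pvalue")
  if (!all(need %in% names(d)))
    stop2("differential table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(d$pvalue)) || any(d$pvalue <= 0) || any(d$pvalue > 1))
    stop2("p-values must lie in (0, 1]")
  if (is.null(d$comparison)) d$comparison <- NA_character_
  structure(d[c("peak_id", "log2fc", "pvalue", "comparison")],
            class = c("differential_table", "data.frame"))
}

#' @rdname read_differential
#' @param x a `differential_table`.
#' @export
write_differential <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify peaks by feeding response
#'
#' A peak is `feeding_gained` when significantly higher in the fed state
#' (`pvalue < alpha` and `log2fc > 0` with fed as group B), `feeding_lost`
#' when significantly lower, and `static` otherwise. The three labels
#' partition the peak universe.
#'
#' @param diff a `differential_table` (fed vs fasted).
#' @param alpha significance cutoff (default 0.01).
#' @return named factor of labels, one per peak.
#' @export
classify_feeding <- function(diff, alpha = 0.01) {
  lab <- rep("static", nrow(diff))
  lab[diff$pvalue < alpha & diff$log2fc > 0] <- "feeding_gained"
  lab[diff$pvalue < alpha & diff$log2fc < 0] <- "feeding_lost"
  factor(setNames(lab, diff$peak_id),
         levels = c("feeding_gained", "feeding_lost", "static"))
}

#' Classify peaks by the first time point reaching significance
#'
#' Given differential tables for an early (week 1) and a late (week 3)
#' comparison over the same peak universe, each peak is labelled by the first
#' time point at which it reaches `pvalue < alpha`, with direction from the
#' log2 fold change at that time point. Week 1 takes precedence when both
#' are significant; never-significant peaks are `static`.
#'
#' @param diff_wk1,diff_wk3 `differential_table`s over one peak universe.
#' @param alpha significance cutoff (default 0.01).
#' @return named factor with levels `gained_first_wk1`, `lost_first_wk1`,
#'   `gained_first_wk3`, `lost_first_wk3`, `static`.
#' @export
classify_temporal <- function(diff_wk1, diff_wk3, alpha = 0.01) {
  if (!setequal(diff_wk1$peak_id, diff_wk3$peak_id) ||
      nrow(diff_wk1) != nrow(diff_wk3))
    stop2("the two differential tables cover different peak universes")
  d3 <- diff_wk3[match(diff_wk1$peak_id, diff_wk3$peak_id), ]
  lab <- rep("static", nrow(diff_wk1))
  s3 <- d3$pvalue < alpha
  lab[s3 & d3$log2fc > 0] <- "gained_first_wk3"
  lab[s3 & d3$log2fc < 0] <- "lost_first_wk3"
  s1 <- diff_wk1$pvalue < alpha           # week 1 overrides week 3
  lab[s1 & diff_wk1$log2fc > 0] <- "gained_first_wk1"
  lab[s1 & diff_wk1$log2fc < 0] <- "lost_first_wk1"
  factor(setNames(lab, diff_wk1$peak_id),
         levels = c("gained_first_wk1", "lost_first_wk1",
                    "gained_first_wk3", "lost_first_wk3", "static"))
}

#' Spearman correlation between two signal columns
#'
#' Rank correlation (ties mid-ranked) over a shared peak universe, as used to
#' compare co-occupancy of two chromatin signals at the same peaks.
#'
#' @param a,b numeric vectors of equal length.
#' @return list with `rho`, `p`, `n`.
#' @export
signal_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Per-class signal summaries and mean ratios
#'
#' Box-plot statistics per peak class (whiskers span data points within
#' 1.5 x the interquartile range) and the matrix of pairwise ratios of class
#' means, e.g. signal at feeding-gained peaks relative to static peaks.
#'
#' @param signal numeric vector of per-peak signal, or a matrix whose row
#'   means are used.
#' @param labels factor of class labels aligned with `signal`.
#' @return list with `stats` (per-class n, mean, median, q1, q3,
#'   whisker_lo, whisker_hi) and `mean_ratio` (classes x classes matrix,
#'   entry [i, j] = mean_i / mean_j).
#' @export
class_signal_summary <- function(signal, labels) {
  if (is.matrix(signal)) signal <- rowMeans(signal)
  stopifnot(length(signal) == length(labels))
  labels <- as.factor(labels)
  cls <- levels(labels)
  st <- lapply(cls, function(cl) {
    v <- signal[labels == cl]
    if (length(v) == 0)
      return(data.frame(class = cl, n = 0, mean = NA, median = NA, q1 = NA,
                        q3 = NA, whisker_lo = NA, whisker_hi = NA))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(class = cl, n = length(v), mean = mean(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  })
  stats <- do.call(rbind, st)
  mu <- setNames(stats$mean, stats$class)
  ratio <- outer(mu, mu, `/`)
  list(stats = stats, mean_ratio = ratio)
}

#' Average signal profile in bins around peak centers
#'
#' Tiles `[center - span, center + span)` with `bin_bp`-wide bins and
#' reports, per bin, the mean per-base signal averaged over peaks (positions
#' clamped off the chromosome contribute zero).
#'
#' @param track a [coverage_track()].
#' @param peaks an [interval_set()].
#' @param span half-extent of the profile in bp.
#' @param bin_bp bin width in bp; must divide `2 * span`.
#' @return data frame with `offset_start`, `offset_end` (bp relative to the
#'   center) and `mean_signal` (per-base average).
#' @export
binned_profile <- function(track, peaks, span = 2000, bin_bp = 100) {
  stopifnot(inherits(track, "coverage_track"), inherits(peaks, "interval_set"),
            span > 0, bin_bp > 0, (2 * span) %% bin_bp == 0)
  g <- iv_genome(peaks)
  offs <- genome_offsets(g)
  F <- coverage_cdf(track)
  ctr <- offs[peaks$chrom] + peak_centers(peaks)
  lo <- offs[peaks$chrom]                       # chromosome bounds on the axis
  hi <- offs[peaks$chrom] + unclass(g)[peaks$chrom]
  edges <- seq(-span, span, by = bin_bp)
  nb <- length(edges) - 1
  ms <- numeric(nb)
  for (j in seq_len(nb)) {
    bs <- pmin(pmax(ctr + edges[j], lo), hi)
    be <- pmin(pmax(ctr + edges[j + 1], lo), hi)
    ms[j] <- mean(F(be) - F(bs)) / bin_bp
  }
  data.frame(offset_start = edges[-length(edges)], offset_end = edges[-1],
             mean_signal = ms)
}
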