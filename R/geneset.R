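#' Ranked gene list
#'
#' Orders genes by a ranking statistic (decreasing), breaking ties
#' deterministically by gene id, as input for pre-ranked GSEA.
#'
#' @param ids character gene ids (unique).
#' @param stat numeric ranking statistic (e.g. log2 fold change).
#' @return a `ranked_list` data frame with columns `id`, `stat`.
#' @export
ranked_list <- function(ids, stat) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop2("gene ids must be unique")
  if (length(ids) != length(stat)) stop2("ids and stat lengths differ")
  if (any(!is.finite(stat))) stop2("ranking statistic must be finite")
  o <- order(-stat, ids)
  structure(data.frame(id = ids[o], stat = as.numeric(stat)[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Read / write ranked lists (.rnk-style TSV: gene, statistic)
#' @param path file path.
#' @return `read_rnk` returns a [ranked_list()].
#' @export
read_rnk <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("id", "stat"),
                         colClasses = c("character", "numeric"))
  ranked_list(d$id, d$stat)
}

#' @rdname read_rnk
#' @param x a [ranked_list()].
#' @export
write_rnk <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) stop2("GMT lines need name, description, >=1 gene")
  setNames(lapply(f, function(x) x[-(1:2)]), vapply(f, `[[`, "", 1))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  writeLines(vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# absw: |stat|^weight over the whole ranking; pos: sorted hit positions.
# The running sum increments absw[pos]/sum(absw[pos]) at hits and decrements
# 1/(N - k) at misses; its extrema occur just after a hit (maxima) or just
# before a hit (minima), which is all we need to evaluate.
es_stat <- function(absw, pos, N) {
  k <- length(pos)
  w <- absw[pos]
  W <- sum(w)
  cw <- if (W > 0) cumsum(w) / W else seq_len(k) / k
  miss <- if (N > k) (pos - seq_len(k)) / (N - k) else rep(0, k)
  after <- cw - miss                 # value just after hit i
  before <- c(0, cw[-k]) - miss      # value just before hit i
  i_max <- which.max(after)
  i_min <- which.min(before)
  # exact magnitude ties (up to accumulated rounding) resolve to the
  # positive extremum
  if (after[i_max] >= -before[i_min] - 1e-12) {
    list(es = after[i_max], hit_index = i_max, sign = 1L)
  } else {
    list(es = before[i_min], hit_index = i_min, sign = -1L)
  }
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA on a ranked list:
#' walking down the ranking, the sum increments by `|stat|^weight`
#' (normalized over set members) at set genes and decrements by
#' `1/(N - |S|)` elsewhere; the enrichment score (ES) is the signed extremum.
#' Significance comes from gene-set permutation: `n_perm` random same-size
#' sets drawn from the ranked universe. NES divides ES by the mean magnitude
#' of sign-matched null ES, and the empirical p-value is sign-matched with
#' the add-the-observed correction.
#'
#' @param ranked a [ranked_list()].
#' @param geneset character vector of gene ids; members absent from the
#'   ranking are dropped with a message (an empty intersection is an error).
#' @param weight exponent on `|stat|` (0 = unweighted KS, 1 = classic
#'   weighted; default 1).
#' @param n_perm number of random gene sets for the null (default 1000).
#' @param seed integer seed.
#' @param set_name label carried into results.
#' @return object of class `gsea_result`: `es`, `nes`, `p`, `leading_edge`
#'   (gene ids), `n_set`, `n_ranked`, `n_dropped`, `null_es`, `weight`,
#'   `n_perm`, `set_name`. `fdr` is NA until [gsea_batch_fdr()].
#' @export
gsea_preranked <- function(ranked, geneset, weight = 1, n_perm = 1000,
                           seed = NULL, set_name = "geneset") {
  stopifnot(inherits(ranked, "ranked_list"), n_perm >= 1, weight >= 0)
  geneset <- unique(as.character(geneset))
  inset <- ranked$id %in% geneset
  n_dropped <- length(geneset) - sum(inset)
  if (sum(inset) == 0) stop2("gene set not represented in the ranked list")
  if (n_dropped > 0)
    message(n_dropped, " gene(s) of '", set_name, "' absent from the ranking; dropped")
  N <- nrow(ranked)
  k <- sum(inset)
  absw <- abs(ranked$stat)^weight
  obs <- es_stat(absw, which(inset), N)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    es_stat(absw, sort.int(sample.int(N, k)), N)$es, numeric(1)))
  if (obs$es >= 0) {
    same <- null_es[null_es >= 0]
    p <- (1 + sum(same >= obs$es)) / (1 + length(same))
    nes <- if (length(same) && mean(same) > 0) obs$es / mean(same) else NA_real_
  } else {
    same <- null_es[null_es < 0]
    p <- (1 + sum(same <= obs$es)) / (1 + length(same))
    nes <- if (length(same) && mean(-same) > 0) obs$es / mean(-same) else NA_real_
  }
  pos <- which(inset)
  le <- if (obs$sign > 0) ranked$id[pos[seq_len(obs$hit_index)]]
        else ranked$id[pos[seq(obs$hit_index, k)]]
  structure(list(es = obs$es, nes = nes, p = p, fdr = NA_real_,
                 leading_edge = le, n_set = k, n_ranked = N,
                 n_dropped = n_dropped, null_es = null_es, weight = weight,
                 n_perm = n_perm, set_name = set_name, seed = seed),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA '%s': %d/%d genes in ranking of %d\n",
              x$set_name, x$n_set, x$n_set + x$n_dropped, x$n_ranked))
  cat(sprintf("  ES = %.4f, NES = %.3f, p = %.4g, FDR = %s, leading edge %d gene(s)\n",
              x$es, x$nes, x$p,
              if (is.na(x$fdr)) "NA" else sprintf("%.3g", x$fdr),
              length(x$leading_edge)))
  invisible(x)
}

#' NES-based FDR across a batch of GSEA results
#'
#' Normalizes every null ES by the sign-matched mean magnitude of its own
#' set's null (so null NES are comparable across sets), pools them, and for
#' each observed NES computes the sign-stratified ratio of null-vs-observed
#' tail fractions, clipped to [0, 1].
#'
#' @param results list of [gsea_preranked()] results (with stored `null_es`).
#' @return data frame: `set`, `es`, `nes`, `p`, `fdr`, `n_set`,
#'   `leading_edge_size`.
#' @export
gsea_batch_fdr <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (inherits(results, "gsea_result")) results <- list(results)
  null_nes <- unlist(lapply(results, function(r) {
    ne <- r$null_es
    mp <- mean(ne[ne >= 0]); mn <- mean(-ne[ne < 0])
    out <- numeric(length(ne))
    out[ne >= 0] <- if (is.finite(mp) && mp > 0) ne[ne >= 0] / mp else 0
    out[ne < 0] <- if (is.finite(mn) && mn > 0) ne[ne < 0] / mn else 0
    out
  }), use.names = FALSE)
  obs_nes <- vapply(results, function(r) r$nes, numeric(1))
  fdr <- vapply(seq_along(results), function(i) {
    nes <- obs_nes[i]
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(obs_nes[obs_nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(obs_nes[obs_nes < 0] <= nes)
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, max(0, num / den))
  }, numeric(1))
  data.frame(set = vapply(results, function(r) r$set_name, ""),
             es = vapply(results, function(r) r$es, numeric(1)),
             nes = obs_nes,
             p = vapply(results, function(r) r$p, numeric(1)),
             fdr = fdr,
             n_set = vapply(results, function(r) r$n_set, integer(1)),
             leading_edge_size = vapply(results, function(r) length(r$leading_edge), integer(1)),
             stringsAsFactors = FALSE)
}

#' K-means clustering of per-gene log2 fold changes
#'
#' Lloyd's algorithm with Euclidean distance over a genes x comparisons
#' matrix of log2 fold changes, taking the best of `n_init` seeded restarts
#' by total within-cluster sum of squares. Rows with non-finite values are
#' dropped with a message.
#'
#' @param mat numeric matrix (rownames = gene ids) with >= 2 comparison
#'   columns, or any object coercible to one.
#' @param k number of clusters (must not exceed the number of usable genes).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param n_init number of restarts (default 10).
#' @return object of class `cluster_assignment`: `cluster` (named integer),
#'   `centers` (k x comparisons), `tot_withinss`, `dropped` (gene ids).
#' @export
kmeans_logfc <- function(mat, k, seed = NULL, n_init = 10) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("gene_%d", seq_len(nrow(mat)))
  ok <- apply(is.finite(mat), 1, all)
  dropped <- rownames(mat)[!ok]
  if (length(dropped) > 0)
    message("dropping ", length(dropped), " gene(s) with non-finite log2fc")
  m <- mat[ok, , drop = FALSE]
  if (k > nrow(m)) stop2("k exceeds the number of usable genes")
  best <- NULL
  with_seed(seed, for (i in seq_len(n_init)) {
    fit <- try(suppressWarnings(
      stats::kmeans(m, centers = k, iter.max = 200, nstart = 1,
                    algorithm = "Lloyd")), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  })
  if (is.null(best)) stop2("k-means failed in every restart")
  structure(list(cluster = setNames(as.integer(best$cluster), rownames(m)),
                 centers = best$centers, tot_withinss = best$tot.withinss,
                 dropped = dropped, k = k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("k-means assignment: k = %d, %d genes (%d dropped), tot within-SS %.3f\n",
              x$k, length(x$cluster), length(x$dropped), x$tot_withinss))
  print(table(x$cluster))
  invisible(x)
}

#' Select the nutrient-response cluster
#'
#' From a [kmeans_logfc()] fit over log2 fold-change comparisons, returns the
#' cluster whose centroid is positive in every comparison column, i.e. the
#' genes upregulated under all conditions; with several candidates the one
#' with the largest centroid norm wins.
#'
#' @param assignment a `cluster_assignment`.
#' @return list with `cluster` (index), `genes` (character ids), `centroid`.
#' @export
select_nutrient_response_cluster <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ctr <- assignment$centers
  up <- which(apply(ctr > 0, 1, all))
  if (length(up) == 0) stop2("no up-up cluster: no centroid is positive in all comparisons")
  if (length(up) > 1) up <- up[which.max(rowSums(ctr[up, , drop = FALSE]^2))]
  list(cluster = as.integer(up),
       genes = names(assignment$cluster)[assignment$cluster == up],
       centroid = ctr[up, ])
}
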