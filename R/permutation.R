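#' Permutation test for association between two coordinate sets
#'
#' Tests whether the observed fraction of reference intervals with a test
#' interval within `window_bp` is larger (enrichment) or smaller (depletion)
#' than expected by chance. The null distribution is built by repeatedly
#' relocating the TEST set with the length-preserving [shuffle_intervals()]
#' and recomputing the association fraction; the reference set stays fixed.
#' Empirical one-sided p-values use the add-the-observed correction
#' `p = (1 + #{null at least as extreme}) / (n_iter + 1)`, so the smallest
#' attainable p is `1/(n_iter + 1)`.
#'
#' @param reference non-empty [interval_set()]; the set whose association
#'   fraction is reported (the "plot title" set).
#' @param test [interval_set()] that gets shuffled.
#' @param window_bp association window in bp (1000 and 10000 are the usual
#'   choices for peak-peak and peak-TSS analyses).
#' @param n_iter number of shuffles (default 10000).
#' @param seed integer seed; the test is fully reproducible given the seed.
#' @param alpha significance level used only for the `call` field.
#' @param keep_null keep the full vector of null fractions (default TRUE).
#' @return object of class `perm_test`: `observed`, `null_mean`, `null_sd`,
#'   `null_q` (2.5/50/97.5% quantiles), `p_enrich`, `p_deplete`, `call`
#'   (one of "enriched", "depleted", "ns"), `n_iter`, `window_bp`,
#'   `reference`, `test` (role labels), `seed`, and `null` when kept.
#' @export
#' @examples
#' g <- genome(c(chr1 = 1e6))
#' ref <- interval_set("chr1", seq(0, 9e5, 1e5), seq(0, 9e5, 1e5) + 100,
#'                     genome = g, role = "ref")
#' tst <- interval_set("chr1", seq(0, 9e5, 1e5) + 50, seq(0, 9e5, 1e5) + 150,
#'                     genome = g, role = "tst")
#' permutation_test(ref, tst, window_bp = 0, n_iter = 200, seed = 1)
permutation_test <- function(reference, test, window_bp = 1000,
                             n_iter = 10000, seed = NULL, alpha = 0.05,
                             keep_null = TRUE) {
  stopifnot(inherits(reference, "interval_set"), inherits(test, "interval_set"),
            n_iter >= 1, window_bp >= 0)
  if (!same_genome(reference, test))
    stop2("interval sets are bound to different genomes")
  if (nrow(reference) == 0) stop2("empty reference set")
  g <- iv_genome(reference)
  offs <- genome_offsets(g)
  ref <- extend_intervals(reference, window_bp)
  rg <- global_coords(ref, offs)

  if (nrow(test) == 0) {
    res <- list(observed = 0, null = rep(0, n_iter), degenerate = TRUE)
  } else {
    tg <- global_coords(test, offs)
    observed <- mean(hits_any(rg$s, rg$e, tg$s, tg$e))
    ilen <- test$end - test$start
    null <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
      sh <- shuffle_global(ilen, g, offs)
      mean(hits_any(rg$s, rg$e, sh$s, sh$e))
    }, numeric(1)))
    res <- list(observed = observed, null = null, degenerate = FALSE)
  }

  p_enrich <- (1 + sum(res$null >= res$observed)) / (n_iter + 1)
  p_deplete <- (1 + sum(res$null <= res$observed)) / (n_iter + 1)
  call <- if (res$degenerate) "ns"
          else if (min(p_enrich, p_deplete) > alpha) "ns"
          else if (p_enrich <= p_deplete) "enriched" else "depleted"
  out <- list(observed = res$observed,
              null_mean = mean(res$null), null_sd = stats::sd(res$null),
              null_q = stats::quantile(res$null, c(0.025, 0.5, 0.975), names = TRUE),
              p_enrich = p_enrich, p_deplete = p_deplete, call = call,
              n_iter = n_iter, window_bp = window_bp, alpha = alpha,
              reference = attr(reference, "role"), test = attr(test, "role"),
              n_reference = nrow(reference), n_test = nrow(test), seed = seed)
  if (keep_null) out$null <- res$null
  structure(out, class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: reference '%s' (n=%d) vs test '%s' (n=%d), window +/-%g bp\n",
              x$reference, x$n_reference, x$test, x$n_test, x$window_bp))
  cat(sprintf("  observed fraction %.4f | expected by chance %.4f (null sd %.4f)\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p(enrich) = %.4g, p(deplete) = %.4g  [%d shuffles] -> %s\n",
              x$p_enrich, x$p_deplete, x$n_iter, x$call))
  invisible(x)
}

#' Run a grid of permutation tests with independent substreams
#'
#' Each (reference, test) pair is tested with its own RNG substream derived
#' deterministically from the master seed and the pair id, so results do not
#' depend on the order in which pairs are listed or computed.
#'
#' @param pairs named list; each element is `list(reference = , test = )` of
#'   [interval_set()] objects. Names are the pair ids used for substream
#'   derivation (defaults to "ref_role|test_role" when unnamed).
#' @param window_bp,n_iter,alpha as in [permutation_test()].
#' @param seed master seed.
#' @return data frame with one row per pair: id, reference, test, n_reference,
#'   n_test, observed, expected (null mean), null_sd, p_enrich, p_deplete,
#'   call, failed (TRUE when a pair raised an error; its message is in
#'   `error`).
#' @export
batch_permutation <- function(pairs, window_bp = 1000, n_iter = 10000,
                              seed = 0, alpha = 0.05) {
  stopifnot(is.list(pairs), length(pairs) >= 1)
  ids <- names(pairs)
  if (is.null(ids)) ids <- rep("", length(pairs))
  auto <- !nzchar(ids)
  ids[auto] <- vapply(pairs[auto], function(p)
    paste(attr(p$reference, "role"), attr(p$test, "role"), sep = "|"), "")
  if (anyDuplicated(ids)) stop2("pair ids must be unique")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    sub <- substream_seed(seed, ids[i])
    r <- try(permutation_test(p$reference, p$test, window_bp = window_bp,
                              n_iter = n_iter, seed = sub, alpha = alpha,
                              keep_null = FALSE), silent = TRUE)
    if (inherits(r, "try-error")) {
      data.frame(id = ids[i],
                 reference = attr(p$reference, "role") %||% NA_character_,
                 test = attr(p$test, "role") %||% NA_character_,
                 n_reference = NA, n_test = NA, observed = NA_real_,
                 expected = NA_real_, null_sd = NA_real_,
                 p_enrich = NA_real_, p_deplete = NA_real_, call = NA_character_,
                 failed = TRUE,
                 error = sub("^Error[^:]*: *", "", trimws(as.character(r))),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = ids[i], reference = r$reference, test = r$test,
                 n_reference = r$n_reference, n_test = r$n_test,
                 observed = r$observed, expected = r$null_mean,
                 null_sd = r$null_sd, p_enrich = r$p_enrich,
                 p_deplete = r$p_deplete, call = r$call, failed = FALSE,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
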