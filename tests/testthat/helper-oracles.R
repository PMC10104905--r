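# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (per-base masks, O(n*m) scans, full running sums) so
# it cannot share a bug with the vectorized implementations it checks.

# O(n*m) pairwise association: is any B interval overlapping the flanked A_i?
bf_associate <- function(A, B, window, genome) {
  len <- unclass(genome)
  vapply(seq_len(nrow(A)), function(i) {
    s <- max(0, A$start[i] - window)
    e <- min(len[A$chrom[i]], A$end[i] + window)
    any(B$chrom == A$chrom[i] & B$start < e & B$end > s)
  }, logical(1))
}

# per-base boolean coverage mask of an interval set, one vector per chromosome
bf_mask <- function(ivs, genome) {
  len <- unclass(genome)
  masks <- lapply(len, function(L) rep(FALSE, L))
  for (iv in ivs) {
    for (i in seq_len(nrow(iv))) {
      ch <- iv$chrom[i]
      masks[[ch]][(iv$start[i] + 1):iv$end[i]] <- TRUE
    }
  }
  masks
}

# O(n*m) fragment counting in +/- hw windows around peak centers
bf_quantify <- function(peaks, frags, hw, genome, frag_length = NULL) {
  len <- unclass(genome)
  vapply(seq_len(nrow(peaks)), function(i) {
    ctr <- floor((peaks$start[i] + peaks$end[i]) / 2)
    ws <- max(0, ctr - hw)
    we <- min(len[peaks$chrom[i]], ctr + hw)
    fs <- frags$start
    fe <- if (is.null(frag_length)) frags$end else pmin(len[frags$chrom], fs + frag_length)
    sum(frags$chrom == peaks$chrom[i] & fs < we & fe > ws)
  }, numeric(1))
}

# full running-sum GSEA enrichment score (signed extremum)
bf_es <- function(stat_sorted, hit, weight) {
  N <- length(stat_sorted)
  k <- sum(hit)
  w <- abs(stat_sorted)^weight
  W <- sum(w[hit])
  step <- numeric(N)
  step[hit] <- if (W > 0) w[hit] / W else 1 / k
  if (N > k) step[!hit] <- -1 / (N - k)
  rs <- cumsum(step)
  mx <- max(rs)
  mn <- min(rs)
  if (mx >= -mn - 1e-12) mx else mn   # tie -> positive extremum, as documented
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}

# random valid interval set on a random genome
random_instance <- function(seed) {
  set.seed(seed)
  nch <- sample(1:3, 1)
  g <- genome(setNames(sample(50:500, nch), paste0("c", seq_len(nch))))
  mk <- function(n) {
    ch <- sample(names(g), n, replace = TRUE)
    len <- unclass(g)[ch]
    w <- pmin(sample(1:40, n, replace = TRUE), len)
    s <- floor(runif(n) * (len - w + 1))
    interval_set(ch, s, s + w, genome = g)
  }
  list(genome = g, mk = mk)
}

# differential table builder for classifier tests
make_diff <- function(peak_id, log2fc, pvalue) {
  structure(data.frame(peak_id = peak_id, log2fc = log2fc, pvalue = pvalue,
                       comparison = "b vs a", stringsAsFactors = FALSE),
            class = c("differential_table", "data.frame"))
}
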