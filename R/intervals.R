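#' Interval sets on a genome
#'
#' An `interval_set` is a data frame of 0-based half-open genomic intervals
#' (`chrom`, `start`, `end`, optional `name` and `score`) bound to a
#' [genome()]. It is the shared currency of every analysis stage: peaks,
#' TSSs, bound sites, fragments and loop anchors are all interval sets.
#'
#' Coordinates follow the BED convention: `start` is 0-based inclusive,
#' `end` exclusive, so interval length is `end - start`.
#'
#' @param chrom character chromosome names (must exist in `genome`).
#' @param start,end numeric 0-based half-open coordinates, `0 <= start < end <=`
#'   chromosome length.
#' @param name optional character labels (e.g. peak ids).
#' @param score optional numeric scores.
#' @param genome the bound [genome()].
#' @param role free-text tag describing what the set is (e.g. "H3K27ac_peaks").
#' @param merged logical; TRUE if the set is known sorted and non-overlapping.
#' @return an object of class `interval_set` (a data frame with attributes
#'   `genome`, `role`, `merged`).
#' @export
#' @examples
#' g <- genome(c(chr1 = 1e6))
#' interval_set("chr1", 100, 200, genome = g, role = "demo")
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         genome, role = "", merged = FALSE) {
  stopifnot(inherits(genome, "genome"))
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop2("chrom, start, end must have equal length")
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  bad <- !(chrom %in% names(genome))
  if (any(bad))
    stop2("unknown chromosome(s): ", paste(unique(chrom[bad]), collapse = ", "))
  if (n > 0) {
    len <- unclass(genome)[chrom]
    if (any(start != floor(start)) || any(end != floor(end)))
      stop2("coordinates must be integers")
    if (any(start < 0) || any(start >= end))
      stop2("require 0 <= start < end")
    if (any(end > len))
      stop2("interval end exceeds chromosome length")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  structure(df, genome = genome, role = role, merged = isTRUE(merged),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set '%s': %d interval(s) on %d chromosome(s)%s\n",
              attr(x, "role"), nrow(x), length(attr(x, "genome")),
              if (isTRUE(attr(x, "merged"))) " [merged]" else ""))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
`[.interval_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome = attr(x, "genome"), role = attr(x, "role"),
            merged = FALSE, class = c("interval_set", "data.frame"))
}

iv_genome <- function(x) attr(x, "genome")

same_genome <- function(a, b) {
  identical(names(iv_genome(a)), names(iv_genome(b))) &&
    identical(as.numeric(iv_genome(a)), as.numeric(iv_genome(b)))
}

#' Read and write BED files
#'
#' `read_bed` parses BED3/BED6 (tab-separated, 0-based half-open) into an
#' [interval_set()], validating every interval against `genome`. Lines
#' starting with `#`, `track` or `browser` are skipped. `write_bed` writes
#' coordinates back out so that a read/write round trip reproduces them
#' exactly.
#'
#' @param path file path.
#' @param genome the [genome()] used for validation.
#' @param role role tag for the resulting set.
#' @return `read_bed` returns an [interval_set()]; `write_bed` returns
#'   `path` invisibly.
#' @export
read_bed <- function(path, genome, role = basename(path)) {
  lines <- readLines(path)
  skip <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(lines)
  keep <- which(!skip)
  if (length(keep) == 0)
    return(interval_set(character(), numeric(), numeric(), genome = genome, role = role))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop2("malformed BED line ", keep[which(nf < 3)[1]], " in ", path,
          ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    stop2("malformed BED line ", keep[bad[1]], " in ", path,
          ": non-numeric coordinates")
  name <- if (any(nf >= 4)) vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "") else NULL
  score <- if (any(nf >= 5)) {
    suppressWarnings(vapply(fields, function(f) if (length(f) >= 5) as.numeric(f[[5]]) else NA_real_, 0))
  } else NULL
  ok <- try(interval_set(chrom, start, end, name = name, score = score,
                         genome = genome, role = role), silent = TRUE)
  if (inherits(ok, "try-error")) {
    # re-validate row by row to report the offending line number
    for (j in seq_along(keep)) {
      r <- try(interval_set(chrom[j], start[j], end[j], genome = genome), silent = TRUE)
      if (inherits(r, "try-error"))
        stop2("invalid interval at line ", keep[j], " in ", path, ": ",
              sub("^Error[^:]*: *", "", as.character(r)))
    }
    stop(attr(ok, "condition"))
  }
  ok
}

#' @rdname read_bed
#' @param x an [interval_set()].
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  df <- as.data.frame(x)
  cols <- list(df$chrom,
               format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name) || !is.null(df$score)) {
    nm <- df$name %||% rep(".", nrow(df))
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
    if (!is.null(df$score)) {
      sc <- df$score
      sc <- ifelse(is.na(sc), ".", format(sc, scientific = FALSE, trim = TRUE))
      cols <- c(cols, list(sc))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Extend intervals by a symmetric flank
#'
#' Adds `flank_bp` on both sides of every interval, clamping at 0 and at the
#' chromosome end. A window of "+/- 1 kb" around a feature is
#' `extend_intervals(x, 1000)`.
#'
#' @param x an [interval_set()].
#' @param flank_bp non-negative flank in bp.
#' @return an [interval_set()] of the same length.
#' @export
extend_intervals <- function(x, flank_bp) {
  stopifnot(inherits(x, "interval_set"), flank_bp >= 0)
  if (nrow(x) == 0) return(x)
  g <- iv_genome(x)
  len <- unclass(g)[x$chrom]
  interval_set(x$chrom, pmax(0, x$start - flank_bp), pmin(len, x$end + flank_bp),
               name = x$name, score = x$score, genome = g, role = attr(x, "role"))
}

#' Merge interval sets into a sorted, non-overlapping union
#'
#' Pools all input sets (which must share one genome) and coalesces
#' overlapping or book-ended intervals, as `bedtools merge` does. Total
#' covered bp is preserved.
#'
#' @param ... one or more [interval_set()] objects.
#' @param role role tag for the merged set.
#' @return a sorted, non-overlapping [interval_set()] flagged `merged`.
#' @export
merge_intervals <- function(..., role = "merged") {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  g <- iv_genome(sets[[1]])
  for (s in sets) {
    stopifnot(inherits(s, "interval_set"))
    if (!same_genome(s, sets[[1]])) stop2("interval sets are bound to different genomes")
  }
  chrom <- unlist(lapply(sets, function(s) s$chrom), use.names = FALSE)
  start <- unlist(lapply(sets, function(s) s$start), use.names = FALSE)
  end <- unlist(lapply(sets, function(s) s$end), use.names = FALSE)
  if (length(chrom) == 0)
    return(interval_set(character(), numeric(), numeric(), genome = g,
                        role = role, merged = TRUE))
  offs <- genome_offsets(g)
  s <- offs[chrom] + start
  e <- offs[chrom] + end
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  grp <- cumsum(s > c(-Inf, cm[-length(cm)]))
  ms <- s[!duplicated(grp)]
  me <- as.numeric(tapply(e, grp, max))
  ci <- findInterval(ms, offs)
  interval_set(names(g)[ci], ms - offs[ci], me - offs[ci], genome = g,
               role = role, merged = TRUE)
}

# --- fast internal kernels on the concatenated genome axis ------------------

global_coords <- function(x, offs) {
  o <- offs[x$chrom]
  list(s = o + x$start, e = o + x$end)
}

# For each reference interval [rs, re), is there any test interval [ts, te)
# with ts < re and te > rs?  O((n+m) log m), fully vectorized.
hits_any <- function(rs, re, ts, te) {
  if (length(ts) == 0) return(rep(FALSE, length(rs)))
  o <- order(ts)
  ts <- ts[o]
  cme <- cummax(te[o])
  idx <- findInterval(re - 0.5, ts)   # number of tests with ts < re
  idx > 0 & c(-Inf, cme)[idx + 1] > rs
}

#' Associate a reference set with a test set within a window
#'
#' A reference interval is "associated" when some test interval overlaps its
#' `window_bp`-flanked extension (half-open overlap: `start < other.end` and
#' `other.start < end`). This reproduces the +/- 1 kb / +/- 10 kb coordinate-set
#' association used throughout peak/TSS analyses: the fraction of reference
#' sites with a test site nearby.
#'
#' @param reference,test [interval_set()] objects sharing one genome.
#' @param window_bp symmetric window in bp applied to the reference set.
#' @return a list with `associated` (logical per reference interval),
#'   `fraction` (= mean of `associated`), `n_reference`, `window_bp`.
#' @export
associate_within <- function(reference, test, window_bp) {
  stopifnot(inherits(reference, "interval_set"), inherits(test, "interval_set"))
  if (!same_genome(reference, test))
    stop2("interval sets are bound to different genomes")
  if (nrow(reference) == 0) stop2("empty reference set")
  g <- iv_genome(reference)
  offs <- genome_offsets(g)
  ref <- extend_intervals(reference, window_bp)
  rg <- global_coords(ref, offs)
  tg <- global_coords(test, offs)
  assoc <- unname(hits_any(rg$s, rg$e, tg$s, tg$e))
  list(associated = assoc, fraction = mean(assoc),
       n_reference = nrow(reference), window_bp = window_bp)
}

# length-preserving relocation on plain vectors; returns global s/e.
# Chromosome drawn with probability proportional to placeable starts
# (len_c - len_i + 1), start uniform among them.
shuffle_global <- function(ilen, g, offs) {
  L <- as.numeric(g)
  n <- length(ilen)
  C <- length(L)
  W <- outer(ilen, L, function(a, b) b - a + 1)
  W[W < 0] <- 0
  tot <- rowSums(W)
  if (any(tot == 0)) stop2("interval longer than every chromosome")
  cw <- W
  if (C > 1) for (j in 2:C) cw[, j] <- cw[, j - 1] + W[, j]
  u <- stats::runif(n) * tot
  ci <- rowSums(cw < u) + 1L    # first column whose cumulative weight exceeds u
  ns <- floor(stats::runif(n) * (L[ci] - ilen + 1))
  s <- offs[ci] + ns
  list(s = s, e = s + ilen, chrom_idx = ci, start = ns)
}

#' Randomly relocate intervals, preserving their lengths
#'
#' Each interval is independently placed uniformly among all positions where
#' it fits: a chromosome is drawn with probability proportional to its number
#' of placeable start positions (`chrom_len - interval_len + 1`) and the
#' start is uniform on `[0, chrom_len - len]`. Shuffled intervals may overlap
#' one another; input order and the multiset of lengths are preserved. This
#' is the null model for permutation-based overlap enrichment.
#'
#' @param x an [interval_set()].
#' @param genome optional [genome()] to shuffle within (defaults to the
#'   genome bound to `x`).
#' @return an [interval_set()] of relocated intervals.
#' @export
shuffle_intervals <- function(x, genome = NULL) {
  stopifnot(inherits(x, "interval_set"))
  g <- genome %||% iv_genome(x)
  if (nrow(x) == 0) return(x)
  offs <- genome_offsets(g)
  sh <- shuffle_global(x$end - x$start, g, offs)
  interval_set(names(g)[sh$chrom_idx], sh$start, sh$start + (x$end - x$start),
               name = x$name, score = x$score, genome = g, role = attr(x, "role"))
}
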