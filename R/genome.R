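#' Genome reference frame
#'
#' A genome is an ordered, named vector of chromosome lengths in bp. It is the
#' coordinate frame every interval set is validated against and the sampling
#' space for the length-preserving shuffle that builds permutation nulls.
#'
#' @param lengths named numeric/integer vector of chromosome lengths (bp).
#' @return an object of class `genome` (named numeric vector).
#' @export
#' @examples
#' g <- genome(c(chr1 = 2e6, chr2 = 1e6))
#' genome_size(g)
genome <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop2("all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop2("duplicate chromosome names")
  nm <- names(lengths)
  lengths <- as.numeric(lengths)
  names(lengths) <- nm
  if (any(!is.finite(lengths)) || any(lengths <= 0) || any(lengths != floor(lengths)))
    stop2("chromosome lengths must be positive integers")
  structure(lengths, class = "genome")
}

#' @rdname genome
#' @param x a `genome`.
#' @export
genome_size <- function(x) sum(unclass(x))

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "chromosome(s),", format(genome_size(x), big.mark = ","), "bp\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read / write a chrom.sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a [genome()]; `write_chrom_sizes`
#'   returns `path` invisibly.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "numeric"),
                           col.names = c("chrom", "length"))
  genome(setNames(tab$length, tab$chrom))
}

#' @rdname read_chrom_sizes
#' @param x a `genome`.
#' @export
write_chrom_sizes <- function(x, path) {
  stopifnot(inherits(x, "genome"))
  utils::write.table(data.frame(names(x), format(as.numeric(x), scientific = FALSE, trim = TRUE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Offsets mapping each chromosome onto one concatenated axis, with a 1 bp
# guard gap so intervals on adjacent chromosomes can never touch.
genome_offsets <- function(g) {
  len <- as.numeric(g)
  setNames(cumsum(c(0, len[-length(len)] + 1)), names(g))
}
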