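#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so library functions can be deterministic without clobbering the
#' caller's random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# FNV-1a over the bytes of a string, folded into [0, 2^31 - 2]. Used to derive
# named RNG substreams; all arithmetic in doubles to stay exact below 2^53.
fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(as.character(x)))) {
    h <- xor_bits(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h %% 2147483646
}

xor_bits <- function(a, b) {
  # bitwXor on doubles that fit in 32 bits
  bitwXor(as.integer(a %% 2147483648), as.integer(b)) +
    (if (a >= 2147483648) 2147483648 else 0)
}

#' Derive a deterministic RNG substream seed
#'
#' Combines a master seed with a character label into an independent 31-bit
#' seed. Components seeded this way can be recomputed in any order (or alone)
#' and still reproduce the same draws.
#'
#' @param master integer master seed.
#' @param label character tag naming the substream (e.g. "peaks", "counts").
#' @return an integer in [1, 2^31 - 1].
#' @export
#' @examples
#' substream_seed(1, "peaks")
substream_seed <- function(master, label) {
  stopifnot(length(master) == 1, is.finite(master))
  h <- fnv1a(paste0(label, ":", format(master, scientific = FALSE)))
  as.integer((h %% 2147483645) + 1)
}

# short stable hash of an R object (config fingerprinting in reports)
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", fnv1a(s))
}

stop2 <- function(...) stop(..., call. = FALSE)
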