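#' Derive a named substream seed from a global seed
#'
#' All randomized stages draw from substreams derived deterministically from
#' one global seed, keyed by a short stage name. Adding a new randomized stage
#' therefore never perturbs the draws of existing ones.
#'
#' @param seed integer global seed.
#' @param name character substream label (e.g. "cohort", "microbiome").
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483423
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Evaluate an expression under a named RNG substream
#'
#' Sets the RNG to a substream derived from (seed, name), evaluates `expr`,
#' and restores the caller's RNG state.
#'
#' @param seed integer global seed.
#' @param name substream label.
#' @param expr expression to evaluate.
#' @keywords internal
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' Natural log with half-minimum offset for zeros
#'
#' Zeros are replaced by half the smallest positive value of the vector before
#' taking logs; negative input is an error. The offset used is recorded in the
#' "offset" attribute.
#'
#' @param x non-negative numeric vector.
#' @return log-transformed vector with attribute "offset".
#' @export
log_offset <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("log_offset: negative values")
  pos <- x[!is.na(x) & x > 0]
  if (!length(pos)) stop("log_offset: no positive values")
  off <- min(pos) / 2
  out <- log(ifelse(!is.na(x) & x == 0, off, x))
  attr(out, "offset") <- off
  out
}

# Deterministic string hash (hex), used only to stamp configs into manifests.
string_hash <- function(s) {
  h <- 216613626
  for (b in utf8ToInt(s)) h <- ((h + b) * 69069) %% 2147483647
  sprintf("%08x", h)
}
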