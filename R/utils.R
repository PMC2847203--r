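#' @useDynLib markovcea, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif rexp quantile setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

# log(sum(exp(x))) with max-subtraction; finite for any x with max(x) finite
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix (column-loop pmax: much faster than apply)
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m) - 1L) + 1L) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic per-stage seed fan-out from a single master seed; kept < 2^31
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
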