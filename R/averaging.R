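#' Bayesian-bootstrap observation weights
#'
#' Draws `B` replicate weight vectors from the flat Dirichlet(1, ..., 1)
#' distribution over the `n` observations (normalized unit exponentials).
#' Under the Bayesian bootstrap these are posterior draws of the distribution
#' of the observation-generating variable given the sample and an improper
#' prior; a replicate of any statistic that is a sum over observations is the
#' weighted sum with weights `n * q_i`.
#'
#' @param n number of observations.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @return `B x n` matrix; each row sums to 1.
#' @export
bayesian_bootstrap_weights <- function(n, B, seed = 1L) {
  if (n < 1L || B < 1L) stopf("n and B must be >= 1")
  set.seed(as.integer(seed))
  e <- matrix(rexp(B * n), nrow = B, ncol = n)
  e / rowSums(e)
}

#' Bootstrap replicates of a sum-over-observations statistic
#'
#' For per-observation contributions `v_i` (log CPOs, DIC contributions, ...)
#' each replicate is `sum_i n q_i v_i`, so a uniform weight vector reproduces
#' the original total `sum_i v_i`.
#'
#' @param v per-observation values (length n).
#' @param weights `B x n` weight matrix from [bayesian_bootstrap_weights()].
#' @return vector of B replicate totals.
#' @export
bootstrap_statistic_replicates <- function(v, weights) {
  if (!all(is.finite(v))) stopf("non-finite per-observation value")
  if (length(v) != ncol(weights)) stopf("length of v must match the weight columns")
  drop(weights %*% (length(v) * v))
}

#' Bootstrap model selection probabilities
#'
#' Estimates, for each candidate model, the probability that it would be
#' selected by the predictive criterion on a replicate data set: the same
#' flat-Dirichlet weight draw is applied to every model's per-observation
#' contributions (a paired comparison on common replicates), and the
#' selection probability is the proportion of replicates in which the model
#' has the highest log(PML) replicate (criterion `"PML"`, contributions = log
#' CPOs) or the lowest DIC replicate (criterion `"DIC"`, contributions =
#' per-row DIC).  Exact ties within a replicate are split equally among the
#' tied models.
#'
#' @param per_obs matrix of per-observation contributions (observations x
#'   models, column names label the models) on a common data set, or a list of
#'   equal-length vectors.
#' @param criterion `"PML"` (maximize) or `"DIC"` (minimize).
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @return object of class `model_weights`: `prob` (named selection
#'   probabilities summing to 1), `replicates` (B x models replicate matrix of
#'   the summed statistic; log PML, or DIC), `criterion`, `B`, `seed`.
#' @export
selection_probabilities <- function(per_obs, criterion = c("PML", "DIC"),
                                    B = 1000L, seed = 1L) {
  criterion <- match.arg(criterion)
  if (is.list(per_obs) && !is.data.frame(per_obs)) {
    if (length(unique(lengths(per_obs))) != 1L)
      stopf("models have mismatched observation indexing")
    per_obs <- do.call(cbind, per_obs)
  }
  per_obs <- as.matrix(per_obs)
  K <- ncol(per_obs)
  if (K < 1L) stopf("at least one model is required")
  if (is.null(colnames(per_obs))) colnames(per_obs) <- paste0("M", seq_len(K))
  W <- bayesian_bootstrap_weights(nrow(per_obs), B, seed)
  reps <- vapply(seq_len(K),
                 function(k) bootstrap_statistic_replicates(per_obs[, k], W),
                 numeric(B))
  reps <- matrix(reps, nrow = B, dimnames = list(NULL, colnames(per_obs)))
  score <- if (criterion == "PML") reps else -reps
  wins <- numeric(K)
  best <- apply(score, 1L, max)
  for (b in seq_len(B)) {
    tied <- which(score[b, ] == best[b])
    wins[tied] <- wins[tied] + 1 / length(tied)
  }
  structure(list(prob = setNames(wins / B, colnames(per_obs)),
                 replicates = reps, criterion = criterion,
                 B = B, seed = as.integer(seed)),
            class = "model_weights")
}

#' @export
print.model_weights <- function(x, ...) {
  cat(sprintf("model selection probabilities (%s criterion, B = %d):\n",
              x$criterion, x$B))
  print(round(x$prob, 3))
  invisible(x)
}

#' Export model weights and their bootstrap replicates as CSV
#'
#' Writes the selection probabilities to `path` and the full B x models
#' replicate matrix of the summed criterion to `<path>.replicates.csv`.
#'
#' @param weights a [selection_probabilities()] result.
#' @param path CSV path for the probabilities.
#' @export
write_model_weights <- function(weights, path) {
  write.csv(data.frame(model = names(weights$prob),
                       prob = unname(weights$prob),
                       criterion = weights$criterion,
                       B = weights$B, seed = weights$seed),
            path, row.names = FALSE)
  write.csv(as.data.frame(weights$replicates),
            paste0(path, ".replicates.csv"), row.names = FALSE)
  invisible(path)
}

#' Model-averaged posterior sample of a scalar functional
#'
#' Draws `N_out` values from the mixture posterior: a model is chosen with
#' its selection probability and a draw of the functional (incremental cost,
#' QALY, net benefit, ...) is resampled from that model's posterior sample.
#' The deterministic alternative concatenates blocks of each model's draws
#' proportional to its weight (resampling within model to the block size),
#' which estimates the same mixture.
#'
#' @param samples list of numeric vectors, one per model: posterior draws of
#'   the functional.
#' @param weights numeric weights summing to 1 (e.g. `prob` from
#'   [selection_probabilities()]), aligned with `samples`.
#' @param N_out number of output draws.
#' @param seed RNG seed.
#' @param method `"resample"` (random model label per draw) or
#'   `"proportional"` (deterministic block allocation).
#' @return numeric vector of `N_out` draws from the model-averaged posterior,
#'   with the chosen model label per draw in attribute `"model"`.
#' @export
model_average <- function(samples, weights, N_out = 10000L, seed = 1L,
                          method = c("resample", "proportional")) {
  method <- match.arg(method)
  stopifnot(length(samples) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stopf("weights must sum to 1")
  if (all(weights == 0)) stopf("all weights are zero")
  if (any(lengths(samples) < 1L & weights > 0)) stopf("a positively weighted model has no draws")
  K <- length(samples)
  labels <- names(samples) %||% paste0("M", seq_len(K))
  set.seed(as.integer(seed))
  if (method == "resample") {
    pick <- sample.int(K, N_out, replace = TRUE, prob = weights)
  } else {
    sizes <- floor(weights * N_out)
    rem <- N_out - sum(sizes)
    if (rem > 0L) {                        # largest remainders get the slack
      frac <- weights * N_out - sizes
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      sizes[add] <- sizes[add] + 1L
    }
    pick <- rep(seq_len(K), times = sizes)
  }
  out <- numeric(N_out)
  for (k in seq_len(K)) {
    idx <- which(pick == k)
    if (length(idx))
      out[idx] <- samples[[k]][sample.int(length(samples[[k]]), length(idx),
                                          replace = TRUE)]
  }
  attr(out, "model") <- labels[pick]
  out
}
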