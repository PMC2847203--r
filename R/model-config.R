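#' @title Model configurations: covariate structure, ties and zero constraints
#'
#' @description A model configuration fixes the state space, the covariates
#' entering each multinomial-logit transition row, and the constraint system
#' that maps the full grid of coefficient slots `(r, s, k)` (from-state,
#' to-state, covariate; `k = 0` is the intercept) onto a flat vector of free
#' parameters.  Each slot has exactly one status: *free* (its own parameter),
#' *tied* (shares a parameter with other slots, e.g. the death row common to
#' all source states), or *zero* (fixed at 0).
#'
#' @name model_config
NULL

age_term_names <- function(tr) {
  switch(tr$type,
         none       = character(0),
         piecewise  = c("age60_70", "age70p"),
         polynomial = paste0("age", seq_len(tr$degree)),
         stopf("unknown age transform '%s'", tr$type))
}

# evaluate the age basis at a vector of ages -> matrix with one column per term
age_basis <- function(tr, age) {
  switch(tr$type,
         none = matrix(numeric(0), nrow = length(age), ncol = 0L),
         piecewise = cbind(age60_70 = as.numeric(age >= tr$cutpoints[1L] & age < tr$cutpoints[2L]),
                           age70p   = as.numeric(age >= tr$cutpoints[2L])),
         polynomial = {
           z <- (age - tr$center) / tr$scale
           out <- vapply(seq_len(tr$degree), function(d) z^d, numeric(length(age)))
           out <- matrix(out, nrow = length(age))
           colnames(out) <- paste0("age", seq_len(tr$degree))
           out
         })
}

#' Construct a model configuration from an explicit structure
#'
#' @param space a [state_space()].
#' @param baseline character vector of baseline covariate names (values are
#'   supplied per observation and may be fractional, e.g. `female = 0.13`).
#' @param age_transform list describing the time-dependent age effect:
#'   `list(type = "none")`, `list(type = "piecewise", cutpoints = c(60, 70))`
#'   or `list(type = "polynomial", degree = d, center = 63, scale = 10)`.
#'   Polynomial age is centered and scaled as `(age - center)/scale` before
#'   powering so high powers stay well conditioned; the constants are stored so
#'   a fitted model is self-describing.
#' @param slots data frame with columns `r`, `s`, `k`, `par_name`: one row per
#'   coefficient slot of every non-reference permitted transition, `k = 0` for
#'   the intercept and `k = 1..K` indexing the covariates in order (baseline,
#'   then age terms, then treatment-age interactions).  `par_name = NA` fixes
#'   the slot at zero; slots sharing a `par_name` are tied to one parameter.
#' @param interactions logical; include treatment-by-age interaction columns.
#' @param label identifying label for the variant.
#' @return an object of class `model_config`.
#' @export
model_config <- function(space, baseline = character(0),
                         age_transform = list(type = "none"),
                         slots, interactions = FALSE, label = "custom") {
  stopifnot(inherits(space, "state_space"))
  age_names <- age_term_names(age_transform)
  inter_names <- if (interactions) paste0("treat_", age_names) else character(0)
  if (interactions && !("treat" %in% baseline))
    stopf("treatment-age interactions need a 'treat' baseline covariate")
  cov_names <- c(baseline, age_names, inter_names)
  kinds <- c(rep("baseline", length(baseline)),
             rep("age", length(age_names)),
             rep("interaction", length(inter_names)))
  K <- length(cov_names)

  slots <- as.data.frame(slots)
  stopifnot(all(c("r", "s", "k", "par_name") %in% names(slots)))
  slots$r <- as.integer(slots$r); slots$s <- as.integer(slots$s)
  slots$k <- as.integer(slots$k)

  # the slot grid must exactly cover every non-reference permitted transition
  trans <- transient_states(space)
  want <- do.call(rbind, lapply(trans, function(r) {
    dests <- setdiff(permitted_dests(space, r), reference_dest(space, r))
    if (!length(dests)) return(NULL)
    expand.grid(r = r, s = dests, k = 0:K)
  }))
  key <- function(d) paste(d$r, d$s, d$k)
  if (!setequal(key(slots), key(want)) || anyDuplicated(key(slots)))
    stopf("slot table must cover each (r,s,k) of the non-reference permitted transitions exactly once")

  slots <- slots[order(slots$r, slots$s, slots$k), , drop = FALSE]
  rownames(slots) <- NULL
  free_names <- unique(slots$par_name[!is.na(slots$par_name)])
  slots$par_id <- ifelse(is.na(slots$par_name), 0L,
                         match(slots$par_name, free_names))

  cfg <- structure(list(label = label, space = space,
                        covariates = data.frame(name = cov_names, kind = kinds,
                                                stringsAsFactors = FALSE),
                        baseline = baseline, age_transform = age_transform,
                        interactions = interactions,
                        slots = slots, par_names = free_names,
                        n_free = length(free_names)),
                   class = "model_config")
  cfg$coef_maps <- build_coef_maps(cfg)
  cfg
}

# per transient row r: list(dests = non-reference destinations,
#   map = (K+1) x length(dests) matrix of free-parameter ids, 0 = fixed zero)
build_coef_maps <- function(cfg) {
  K <- nrow(cfg$covariates)
  maps <- vector("list", cfg$space$n)
  for (r in transient_states(cfg$space)) {
    sl <- cfg$slots[cfg$slots$r == r, , drop = FALSE]
    dests <- sort(unique(sl$s))
    m <- matrix(0L, nrow = K + 1L, ncol = length(dests),
                dimnames = list(c("(intercept)", cfg$covariates$name), dests))
    m[cbind(sl$k + 1L, match(sl$s, dests))] <- sl$par_id
    maps[[r]] <- list(dests = dests, ref = reference_dest(cfg$space, r), map = m)
  }
  maps
}

#' Flat free-parameter index of a model configuration
#'
#' @param config a [model_config()].
#' @return list with the slot table (columns `r`, `s`, `k`, `par_name`,
#'   `par_id`; id 0 marks slots fixed at zero), the free-parameter names and
#'   the free-parameter count `n_free`.
#' @export
build_parameter_index <- function(config) {
  stopifnot(inherits(config, "model_config"))
  list(slots = config$slots, par_names = config$par_names, n_free = config$n_free)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model config '%s': %d states, %d covariates, %d free parameters\n",
              x$label, x$space$n, nrow(x$covariates), x$n_free))
  invisible(x)
}

# ---- variant factories -------------------------------------------------------

# age transform for each labelled variant of the hospitalization/death model
variant_age_transform <- function(label) {
  deg <- c(M5 = 2L, M6 = 3L, M7 = 4L, M8 = 2L, M9 = 3L, M10 = 4L)[label]
  if (is.na(deg)) list(type = "piecewise", cutpoints = c(60, 70))
  else list(type = "polynomial", degree = unname(deg), center = 63, scale = 10)
}

#' Build one of the candidate model variants M1--M10 (or a custom structure)
#'
#' `M1` is the base case: four binary baseline covariates (treatment, sex,
#' LVEF, country) and a piecewise-constant age effect (cutpoints 60 and 70) on
#' the six admission transitions and on death; the death row is common to all
#' source states; length of hospital stay depends only on country; no country
#' effect on admission or stay for drug side effects (state 7).  The variants:
#' \describe{
#'   \item{M2}{adds a piecewise age effect on length of stay in each hospital
#'     state (+12 parameters).}
#'   \item{M3}{drops every covariate except treatment from admission for drug
#'     side effects (-4).}
#'   \item{M4}{drops sex everywhere except death and arrhythmic admission (-5).}
#'   \item{M5--M7}{replace piecewise age by a quadratic / cubic / quartic in
#'     centred age on the seven age-bearing transitions (+0 / +7 / +14).}
#'   \item{M8--M10}{additionally interact every age term with treatment
#'     (+14 / +28 / +42).}
#' }
#'
#' @param label one of `"M1"`..`"M10"`, or a list of arguments forwarded to
#'   [model_config()] for an explicit structure.
#' @return a [model_config()].
#' @export
build_model_config <- function(label) {
  if (is.list(label)) return(do.call(model_config, label))
  if (!(is.character(label) && label %in% paste0("M", 1:10)))
    stopf("unknown model label '%s'", paste(label, collapse = ","))
  space <- icd_state_space()
  tr <- variant_age_transform(label)
  age_names <- age_term_names(tr)
  interactions <- label %in% c("M8", "M9", "M10")
  inter_names <- if (interactions) paste0("treat_", age_names) else character(0)
  baseline <- c("treat", "female", "lvef", "uk")
  cov_names <- c(baseline, age_names, inter_names)
  K <- length(cov_names)

  status <- function(r, s, k) {               # par name, or NA for zero
    cov <- if (k > 0L) cov_names[k] else "(intercept)"
    if (s == 8L) {                            # death row, tied across sources
      return(if (k == 0L) "mu_D" else paste0("b_D_", cov))
    }
    if (r == 1L) {                            # admissions from out of hospital
      if (k == 0L) return(paste0("mu_1", s))
      drop <- (cov == "uk" && s == 7L) ||
        (label == "M3" && s == 7L && cov != "treat") ||
        (label == "M4" && s >= 3L && cov == "female")
      if (drop) return(NA_character_)
      return(paste0("b_1", s, "_", cov))
    }
    # self transitions of hospital states: length of stay
    if (k == 0L) return(paste0("mu_", r, r))
    keep <- (cov == "uk" && r != 7L) ||
      (label == "M2" && cov %in% age_names)
    if (keep) paste0("b_", r, r, "_", cov) else NA_character_
  }

  rows <- list()
  for (r in 1:7) {
    dests <- setdiff(permitted_dests(space, r), 1L)
    for (s in dests) for (k in 0:K)
      rows[[length(rows) + 1L]] <- data.frame(r = r, s = s, k = k,
                                              par_name = status(r, s, k),
                                              stringsAsFactors = FALSE)
  }
  model_config(space, baseline = baseline, age_transform = tr,
               slots = do.call(rbind, rows), interactions = interactions,
               label = label)
}

# ---- covariate evaluation ----------------------------------------------------

# full covariate matrix (columns in config order) from a data frame holding the
# baseline covariate columns plus an `age` column (years, may be fractional)
covariate_matrix <- function(config, df) {
  n <- nrow(df)
  need <- config$baseline
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing covariate column(s): %s", paste(miss, collapse = ", "))
  out <- matrix(0, nrow = n, ncol = nrow(config$covariates),
                dimnames = list(NULL, config$covariates$name))
  for (nm in need) out[, nm] <- as.numeric(df[[nm]])
  if (config$age_transform$type != "none") {
    if (!("age" %in% names(df))) stopf("missing covariate column(s): age")
    ab <- age_basis(config$age_transform, as.numeric(df$age))
    out[, colnames(ab)] <- ab
    if (config$interactions)
      out[, paste0("treat_", colnames(ab))] <- ab * as.numeric(df[["treat"]])
  }
  out
}

# single covariate vector from a named list/vector (must include `age` when the
# config has age terms)
covariate_vector <- function(config, covariates) {
  df <- as.data.frame(as.list(covariates))
  drop(covariate_matrix(config, df))
}

# ---- predictors and probabilities -------------------------------------------

# coefficient matrix for row r at theta: (K+1) x n_dest
row_beta <- function(theta, config, r) {
  cm <- config$coef_maps[[r]]
  b <- matrix(0, nrow = nrow(cm$map), ncol = ncol(cm$map))
  nz <- cm$map > 0L
  b[nz] <- theta[cm$map[nz]]
  b
}

#' Linear predictors (log odds) for one transition row
#'
#' Returns `log(p_rs / p_r,ref)` for each permitted non-reference destination
#' `s` of from-state `r`; the reference destination is state 1 when the return
#' transition `(r, 1)` is permitted, otherwise the self state.
#'
#' @param theta free-parameter vector (length `config$n_free`).
#' @param config a [model_config()].
#' @param covariates named list/vector of covariate values (may be fractional);
#'   must include `age` in years when the configuration has age terms.
#' @param r from-state index (transient).
#' @return named numeric vector of log odds, one per non-reference destination.
#' @export
linear_predictors <- function(theta, config, covariates, r) {
  stopifnot(length(theta) == config$n_free)
  if (r %in% config$space$absorbing) stopf("state %d is absorbing", r)
  x <- c(1, covariate_vector(config, covariates))
  cm <- config$coef_maps[[r]]
  eta <- drop(crossprod(row_beta(theta, config, r), x))
  names(eta) <- config$space$states[cm$dests]
  eta
}

#' One-day transition probabilities from a state
#'
#' Inverse multinomial logit of [linear_predictors()], completed with the
#' reference destination; exactly zero on non-permitted pairs.  Computed with
#' max-subtraction so the output is finite for log odds up to |700|.
#'
#' @inheritParams linear_predictors
#' @return numeric vector over all states, summing to 1.
#' @export
transition_probabilities <- function(theta, config, covariates, r) {
  R <- config$space$n
  p <- numeric(R)
  names(p) <- config$space$states
  if (r %in% config$space$absorbing) { p[r] <- 1; return(p) }
  eta <- linear_predictors(theta, config, covariates, r)
  cm <- config$coef_maps[[r]]
  all_eta <- c(0, eta)                       # reference first
  w <- exp(all_eta - max(all_eta))
  pr <- w / sum(w)
  p[c(cm$ref, cm$dests)] <- pr
  p
}

# full R x R one-day matrix for a covariate setting
transition_matrix <- function(theta, config, covariates) {
  R <- config$space$n
  P <- matrix(0, R, R, dimnames = list(config$space$states, config$space$states))
  for (r in seq_len(R)) {
    if (r %in% config$space$absorbing) P[r, r] <- 1
    else P[r, ] <- transition_probabilities(theta, config, covariates, r)
  }
  P
}

# ---- serialization -----------------------------------------------------------

#' Write / read a model configuration as JSON
#'
#' The serialized form lists the states, permitted pairs, covariates, age
#' transform and the explicit slot table (tie and zero statuses), so a round
#' trip is lossless.
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `read_model_config` returns the reconstructed [model_config()].
#' @export
write_model_config <- function(config, path) {
  obj <- list(label = config$label,
              states = config$space$states,
              absorbing = config$space$absorbing,
              permitted = unname(config$space$permitted),
              baseline = config$baseline,
              age_transform = config$age_transform,
              interactions = config$interactions,
              slots = config$slots[c("r", "s", "k", "par_name")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- as.list(obj$age_transform)
  if (!is.null(tr$cutpoints)) tr$cutpoints <- as.numeric(tr$cutpoints)
  space <- state_space(obj$states, as.integer(obj$absorbing),
                       matrix(as.integer(as.matrix(obj$permitted)), ncol = 2L))
  slots <- as.data.frame(obj$slots)
  slots$par_name <- as.character(slots$par_name)
  slots$par_name[slots$par_name %in% c("NA", "")] <- NA_character_
  model_config(space, baseline = as.character(obj$baseline %||% character(0)),
               age_transform = tr, slots = slots,
               interactions = isTRUE(obj$interactions), label = obj$label)
}
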