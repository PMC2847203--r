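#' Define a multi-state space with permitted one-day transitions
#'
#' A state space is an ordered set of labelled states (1-based indices), a set
#' of absorbing states, and the set of ordered pairs `(r, s)` of transitions
#' that can occur in one time unit.  Every transient state must be able to
#' remain where it is and reach at least one other state; absorbing states can
#' only remain where they are.
#'
#' @param states character vector of state labels; state index is position.
#' @param absorbing integer indices of absorbing states.
#' @param permitted two-column integer matrix (from, to) of permitted pairs.
#' @return an object of class `state_space`.
#' @seealso [icd_state_space()] for the eight-state hospitalization/death space.
#' @export
state_space <- function(states, absorbing, permitted) {
  R <- length(states)
  stopifnot(R >= 2L, is.character(states))
  absorbing <- as.integer(absorbing)
  permitted <- matrix(as.integer(permitted), ncol = 2L,
                      dimnames = list(NULL, c("from", "to")))
  if (any(permitted < 1L | permitted > R)) stopf("permitted pair out of range 1..%d", R)
  key <- paste(permitted[, 1L], permitted[, 2L])
  if (anyDuplicated(key)) stopf("duplicated permitted pair")
  for (r in seq_len(R)) {
    dests <- permitted[permitted[, 1L] == r, 2L]
    if (!(r %in% dests)) stopf("state %d lacks the self pair (r,r)", r)
    if (r %in% absorbing) {
      if (length(dests) != 1L) stopf("absorbing state %d has outgoing transitions", r)
    } else {
      if (length(dests) < 2L) stopf("transient state %d can reach no other state", r)
    }
  }
  structure(list(states = states, n = R, absorbing = absorbing,
                 permitted = permitted),
            class = "state_space")
}

#' Eight-state hospitalization and death state space
#'
#' The daily-cycle state space used throughout: state 1 is alive and out of
#' hospital, states 2--7 are hospital admission for six distinct causes, and
#' state 8 is death (absorbing).  From state 1 a patient can stay, be admitted
#' to any hospital state, or die; from a hospital state they can stay, return
#' home, or die.
#'
#' @return a `state_space` with 8 states.
#' @export
icd_state_space <- function() {
  states <- c("out_of_hospital", "arrhythmic", "other_cardiac", "non_cardiac",
              "icd_maintenance", "icd_replacement", "aad_side_effects", "death")
  perm <- rbind(cbind(1L, 1:8),                     # leave home or stay
                cbind(2:7, 2:7), cbind(2:7, 1L), cbind(2:7, 8L),
                cbind(8L, 8L))
  state_space(states, absorbing = 8L, permitted = perm)
}

#' Two-state alive/dead space (minimal testing structure)
#' @return a `state_space` with states alive (1) and dead (2).
#' @export
alive_dead_state_space <- function() {
  state_space(c("alive", "dead"), absorbing = 2L,
              permitted = rbind(c(1L, 1L), c(1L, 2L), c(2L, 2L)))
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("state space: %d states (%s absorbing)\n", x$n,
              paste(x$states[x$absorbing], collapse = ", ")))
  cat(sprintf("  permitted transitions: %d\n", nrow(x$permitted)))
  invisible(x)
}

transient_states <- function(ss) setdiff(seq_len(ss$n), ss$absorbing)

#' Permitted destinations of a from-state
#' @param ss a [state_space()].
#' @param r from-state index.
#' @return sorted destination indices.
#' @export
permitted_dests <- function(ss, r) sort(unname(ss$permitted[ss$permitted[, 1L] == r, 2L]))

#' Reference destination of a transition row
#'
#' The multinomial logit of row `r` is parameterized against state 1 when the
#' return transition `(r, 1)` is permitted (the sum-to-one completion is on
#' the out-of-hospital destination), otherwise against the self state.
#' @inheritParams permitted_dests
#' @return state index of the reference destination.
#' @export
reference_dest <- function(ss, r) {
  dests <- permitted_dests(ss, r)
  if (1L %in% dests) 1L else r
}
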