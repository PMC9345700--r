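#' Compartment states
#'
#' The full model tracks eight mutually exclusive social states, in the
#' fixed order `S` (susceptible), `V` (violence-infected), `U`
#' (negotiated), `R` (racism-infected), `Ivr` (violence-racism
#' coinfected), `R1` (recuperated from violence), `R2` (recuperated from
#' racism), `R3` (recuperated from coinfection).  The violence submodel
#' keeps `(S, V, U, R1)`, the racism submodel `(S, R, R2)`.
#'
#' @param S,V,U,R,Ivr,R1,R2,R3 Nonnegative compartment counts (persons).
#' @return A named numeric vector in the fixed compartment order.
#' @examples
#' initial_state(S = 497, V = 1, R = 1, Ivr = 1)
#' @export
initial_state <- function(S = 0, V = 0, U = 0, R = 0, Ivr = 0,
                          R1 = 0, R2 = 0, R3 = 0) {
  y <- c(S = S, V = V, U = U, R = R, Ivr = Ivr, R1 = R1, R2 = R2, R3 = R3)
  check_state(y, full_compartments())
  y
}

full_compartments <- function() c("S", "V", "U", "R", "Ivr", "R1", "R2", "R3")
violence_compartments <- function() c("S", "V", "U", "R1")
racism_compartments <- function() c("S", "R", "R2")

model_compartments <- function(model = c("full", "violence", "racism")) {
  switch(match.arg(model),
         full = full_compartments(),
         violence = violence_compartments(),
         racism = racism_compartments())
}

check_state <- function(y, compartments) {
  if (is.data.frame(y)) y <- unlist(y[1, intersect(names(y), compartments)])
  if (is.null(names(y))) {
    if (length(y) != length(compartments)) {
      rlang::abort(
        paste0("State must have ", length(compartments), " components (",
               paste(compartments, collapse = ", "), ")"),
        class = "cocontagion_invalid_state"
      )
    }
    names(y) <- compartments
  }
  missing <- setdiff(compartments, names(y))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("State is missing compartment(s): ",
             paste(missing, collapse = ", ")),
      class = "cocontagion_invalid_state"
    )
  }
  y <- y[compartments]
  if (any(!is.finite(y))) {
    rlang::abort("State components must be finite",
                 class = "cocontagion_invalid_state")
  }
  if (any(y < 0)) {
    rlang::abort("State components must be nonnegative",
                 class = "cocontagion_invalid_state")
  }
  y
}

#' Forces of infection
#'
#' Per-susceptible acquisition rates of the two behaviours.  Coinfected
#' individuals contribute to both, weighted by the modification factors:
#' the violence force of infection is `beta1 * (V + theta2 * Ivr)` and
#' the racism force of infection is `beta2 * (R + theta1 * Ivr)`.
#'
#' @param state Named state vector (or one-row data frame) containing at
#'   least the compartments the force depends on; missing compartments
#'   count as zero, so submodel states work unchanged.
#' @param params A `cc_parameters` object.
#' @return A nonnegative rate (1/year).
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' foi_violence(initial_state(V = 10, Ivr = 5), p)
#' @export
foi_violence <- function(state, params) {
  s <- state_lookup(state)
  params$beta1 * (s["V"] + params$theta2 * s["Ivr"])[[1]]
}

#' @rdname foi_violence
#' @export
foi_racism <- function(state, params) {
  s <- state_lookup(state)
  params$beta2 * (s["R"] + params$theta1 * s["Ivr"])[[1]]
}

state_lookup <- function(state) {
  if (is.data.frame(state)) state <- unlist(state[1, , drop = FALSE])
  out <- stats::setNames(numeric(8), full_compartments())
  common <- intersect(names(state), names(out))
  out[common] <- state[common]
  out
}

#' Model right-hand sides
#'
#' Time derivatives of the compartment counts.  `rhs_full()` implements
#' the eight-equation coexistence system; `rhs_violence()` and
#' `rhs_racism()` are the reduced single-behaviour submodels obtained by
#' emptying the other behaviour's compartments.  The three systems share
#' the exact conservation identity `sum(dy) = Lambda - mu * N`, which
#' drives the invariant population bound `N <= Lambda / mu`.
#'
#' @param state Named nonnegative state vector — 8 compartments for the
#'   full model, `(S, V, U, R1)` for violence, `(S, R, R2)` for racism.
#' @param params A `cc_parameters` object.
#' @param t Time (years); the systems are autonomous, the argument
#'   exists for solver compatibility.
#' @return Named numeric vector of derivatives (persons/year) in state
#'   order.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' rhs_full(dfe_state(p), p)           # all zero: equilibrium
#' @export
rhs_full <- function(state, params, t = 0) {
  y <- check_state(state, full_compartments())
  p <- params
  lv <- p$beta1 * (y[["V"]] + p$theta2 * y[["Ivr"]])
  lr <- p$beta2 * (y[["R"]] + p$theta1 * y[["Ivr"]])
  c(
    S   = p$Lambda + p$alpha * y[["R1"]] + p$rho * y[["R2"]] +
          p$theta * y[["R3"]] - (lv + lr + p$mu) * y[["S"]],
    V   = lv * y[["S"]] - (p$delta + p$kappa * lr + p$mu) * y[["V"]],
    U   = p$delta * y[["V"]] - (p$epsilon + p$mu) * y[["U"]],
    R   = lr * y[["S"]] + p$omega * y[["Ivr"]] -
          (p$sigma + p$beta_mod * lv + p$mu) * y[["R"]],
    Ivr = p$beta_mod * lv * y[["R"]] + p$kappa * lr * y[["V"]] -
          (p$phi + p$omega + p$mu) * y[["Ivr"]],
    R1  = p$epsilon * y[["U"]] - (p$alpha + p$mu) * y[["R1"]],
    R2  = p$sigma * y[["R"]] - (p$rho + p$mu) * y[["R2"]],
    R3  = p$phi * y[["Ivr"]] - (p$theta + p$mu) * y[["R3"]]
  )
}

#' @rdname rhs_full
#' @export
rhs_violence <- function(state, params, t = 0) {
  y <- check_state(state, violence_compartments())
  p <- params
  lv <- p$beta1 * y[["V"]]
  c(
    S  = p$Lambda + p$alpha * y[["R1"]] - (lv + p$mu) * y[["S"]],
    V  = lv * y[["S"]] - (p$delta + p$mu) * y[["V"]],
    U  = p$delta * y[["V"]] - (p$epsilon + p$mu) * y[["U"]],
    R1 = p$epsilon * y[["U"]] - (p$alpha + p$mu) * y[["R1"]]
  )
}

#' @rdname rhs_full
#' @export
rhs_racism <- function(state, params, t = 0) {
  y <- check_state(state, racism_compartments())
  p <- params
  lr <- p$beta2 * y[["R"]]
  c(
    S  = p$Lambda + p$rho * y[["R2"]] - (lr + p$mu) * y[["S"]],
    R  = lr * y[["S"]] - (p$sigma + p$mu) * y[["R"]],
    R2 = p$sigma * y[["R"]] - (p$rho + p$mu) * y[["R2"]]
  )
}

model_rhs <- function(model = c("full", "violence", "racism")) {
  switch(match.arg(model),
         full = rhs_full, violence = rhs_violence, racism = rhs_racism)
}
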