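#' Default initial state
#'
#' The reference experiments start from a nearly susceptible community
#' seeded with `iota` persons in each contagious class of the chosen
#' model (`V`, `R`, `Ivr` for the full model), with the susceptible
#' class making up the rest of the invariant population `Lambda / mu`.
#'
#' @param params A `cc_parameters` object.
#' @param iota Seed size per contagious class (persons).
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @return A named nonnegative state vector with total `Lambda / mu`.
#' @examples
#' default_initial_state(preset_parameters("table2_reconciled"))
#' @export
default_initial_state <- function(params, iota = 1,
                                  model = c("full", "violence", "racism")) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  N <- p$Lambda / p$mu
  seeded <- switch(model, full = c("V", "R", "Ivr"),
                   violence = "V", racism = "R")
  if (N <= iota * length(seeded)) {
    rlang::abort("Population Lambda/mu too small for the requested seeding",
                 class = "cocontagion_invalid_state")
  }
  y <- stats::setNames(numeric(length(model_compartments(model))),
                       model_compartments(model))
  y[seeded] <- iota
  y["S"] <- N - iota * length(seeded)
  y
}

#' Integrate the model over time
#'
#' Solves the chosen ODE system with an adaptive explicit Runge--Kutta
#' 4(5) pair (Dormand--Prince, `deSolve` method `"ode45"`) and reports
#' the solution on an even time grid.
#'
#' Positivity is monitored: reported values in `(-undershoot_tol, 0)`
#' are solver noise and are clipped to zero (the number of clipped
#' entries is kept in the `n_clipped` attribute); anything below
#' `-undershoot_tol` aborts with diagnostics rather than being silently
#' clipped, since it indicates a misconfigured solve.
#'
#' @param params A `cc_parameters` object.
#' @param y0 Initial state (named vector); defaults to
#'   [default_initial_state()].
#' @param t_end Horizon (years).
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @param n_out Number of report times (even grid from 0 to `t_end`).
#' @param rtol,atol Solver tolerances.
#' @param undershoot_tol Absolute negativity budget before aborting.
#'   Defaults to `max(1e-9, rtol * N(0))`, the integration error the
#'   requested tolerances themselves permit.
#' @return A tibble of class `cc_trajectory`: column `time` plus one
#'   column per compartment, one row per report time.  Attributes:
#'   `params`, `model`, `rtol`, `atol`, `n_clipped`.
#' @examples
#' p <- preset_parameters("fig4_eradication")
#' traj <- simulate_model(p, t_end = 50)
#' tail(traj)
#' @export
simulate_model <- function(params, y0 = NULL, t_end = 50,
                           model = c("full", "violence", "racism"),
                           n_out = 201, rtol = 1e-8, atol = 1e-10,
                           undershoot_tol = NULL) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  if (is.null(y0)) y0 <- default_initial_state(p, model = model)
  cmp <- model_compartments(model)
  y0 <- check_state(y0, cmp)
  if (!is.numeric(t_end) || length(t_end) != 1 || t_end <= 0) {
    rlang::abort("t_end must be a positive number of years",
                 class = "cocontagion_invalid_state")
  }
  if (is.null(undershoot_tol)) undershoot_tol <- max(1e-9, rtol * sum(y0))
  rhs <- model_rhs(model)
  times <- seq(0, t_end, length.out = max(n_out, 2))
  deriv <- function(t, y, parms) {
    names(y) <- cmp
    list(unname(eval_rhs_raw(rhs, y, parms)))
  }
  sol <- deSolve::ode(y = unname(y0), times = times, func = deriv,
                      parms = p, method = "ode45",
                      rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    rlang::abort(
      paste0("ODE solver failed before t_end; last time reached ",
             max(sol[, 1])),
      class = "cocontagion_solver_failure"
    )
  }
  states <- sol[, -1, drop = FALSE]
  colnames(states) <- cmp
  worst <- min(states)
  if (worst < -undershoot_tol) {
    idx <- which(states == worst, arr.ind = TRUE)[1, ]
    rlang::abort(
      sprintf(paste0("Positivity violated beyond tolerance: %s = %.3e at ",
                     "t = %.4g (rtol = %g, atol = %g)"),
              cmp[idx[2]], worst, times[idx[1]], rtol, atol),
      class = "cocontagion_invariant_violation"
    )
  }
  n_clipped <- sum(states < 0)
  states[states < 0] <- 0
  out <- tibble::as_tibble(as.data.frame(states))
  out <- dplyr::bind_cols(tibble::tibble(time = times), out)
  structure(out,
            class = c("cc_trajectory", class(tibble::tibble())),
            params = p, model = model, rtol = rtol, atol = atol,
            n_clipped = n_clipped)
}

#' Long-format and summary views of a trajectory
#'
#' `tidy()` pivots the compartment columns into
#' `(time, compartment, count)`; `glance()` gives a one-row summary of
#' the run.
#'
#' @param x A `cc_trajectory`.
#' @param ... Unused.
#' @method tidy cc_trajectory
#' @export
tidy.cc_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "compartment", values_to = "count")
}

#' @rdname tidy.cc_trajectory
#' @method glance cc_trajectory
#' @export
glance.cc_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cmp <- setdiff(names(x), "time")
  last <- x[nrow(x), ]
  tibble::tibble(
    model = attr(x, "model"),
    t_end = max(x$time),
    n_times = nrow(x),
    N_end = sum(unlist(last[cmp])),
    N_limit = p$Lambda / p$mu,
    n_clipped = attr(x, "n_clipped")
  )
}

#' Plot a trajectory
#'
#' @param object A `cc_trajectory`.
#' @param compartments Optional subset of compartments to draw.
#' @param ... Unused.
#' @return A ggplot object, one line per compartment.
#' @method autoplot cc_trajectory
#' @export
autoplot.cc_trajectory <- function(object, compartments = NULL, ...) {
  df <- tidy.cc_trajectory(object)
  if (!is.null(compartments)) {
    df <- dplyr::filter(df, .data$compartment %in% compartments)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$count,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "persons",
                  colour = "compartment") +
    ggplot2::theme_minimal()
}

#' Reproduction-number parameter sweep
#'
#' Recomputes the three thresholds along a grid of values for one
#' parameter.  Rows whose value yields an invalid parameter set are
#' reported with `NA` thresholds and the validation message, not
#' dropped and not fatal.
#'
#' @param params Baseline `cc_parameters`.
#' @param parameter Name of the swept parameter.
#' @param values Numeric grid.
#' @return A tibble of class `cc_sweep` with columns `value`,
#'   `r0_violence`, `r0_racism`, `r0_full`, `error`.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' sweep_r0(p, "beta2", seq(0, 0.01, by = 0.002))
#' @export
sweep_r0 <- function(params, parameter, values) {
  p0 <- validate_parameters(as.list(params))
  if (length(values) == 0) {
    return(structure(
      tibble::tibble(value = numeric(), r0_violence = numeric(),
                     r0_racism = numeric(), r0_full = numeric(),
                     error = character()),
      class = c("cc_sweep", class(tibble::tibble())),
      parameter = parameter
    ))
  }
  rows <- purrr::map(values, function(v) {
    res <- tryCatch({
      p <- set_parameters(p0, !!!stats::setNames(list(v), parameter))
      tibble::tibble(value = v,
                     r0_violence = r0_violence(p),
                     r0_racism = r0_racism(p),
                     r0_full = r0_full(p),
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(value = v, r0_violence = NA_real_,
                     r0_racism = NA_real_, r0_full = NA_real_,
                     error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("cc_sweep", class(tibble::tibble())),
            parameter = parameter)
}

#' @method autoplot cc_sweep
#' @export
autoplot.cc_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(tibble::as_tibble(object), is.na(.data$error)),
    dplyr::all_of(c("r0_violence", "r0_racism", "r0_full")),
    names_to = "threshold", values_to = "r0"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$r0,
                                   colour = .data$threshold)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = attr(object, "parameter"),
                  y = "basic reproduction number") +
    ggplot2::theme_minimal()
}

#' Control-rate experiments
#'
#' Re-runs the same scenario for each value of a control rate (`omega`,
#' the violence-only control on the coinfected class, or `phi`, the
#' coinfection recuperation rate), holding everything else fixed, and
#' returns the runs stacked in long form for direct comparison of the
#' coinfected trajectory.
#'
#' @param params Baseline `cc_parameters`.
#' @param parameter `"omega"` or `"phi"` (any model parameter is
#'   accepted).
#' @param values Ascending numeric control values.
#' @param y0 Initial state; defaults to [default_initial_state()].
#' @param t_end Horizon (years).
#' @param ... Passed to [simulate_model()].
#' @return A tibble with a `control` column (the control value) bound
#'   to the trajectory columns of each run.
#' @examples
#' \donttest{
#' p <- preset_parameters("fig6_omega")
#' y0 <- initial_state(S = 400, V = 50, R = 40, Ivr = 10)
#' runs <- control_effect(p, "omega", c(0.6, 0.7, 0.8), y0, t_end = 20)
#' dplyr::summarise(dplyr::group_by(runs, control),
#'                  peak = max(Ivr), final = Ivr[dplyr::n()])
#' }
#' @export
control_effect <- function(params, parameter = c("omega", "phi"),
                           values, y0 = NULL, t_end = 50, ...) {
  if (length(parameter) > 1) parameter <- match.arg(parameter)
  p0 <- validate_parameters(as.list(params))
  if (is.unsorted(values, strictly = TRUE)) {
    rlang::abort("Control values must be strictly ascending",
                 class = "cocontagion_invalid_parameter")
  }
  purrr::map_dfr(values, function(v) {
    p <- set_parameters(p0, !!!stats::setNames(list(v), parameter))
    traj <- simulate_model(p, y0 = y0, t_end = t_end, ...)
    dplyr::bind_cols(tibble::tibble(control = v), tibble::as_tibble(traj))
  })
}

#' Trajectory invariant checks
#'
#' Verifies, on a computed trajectory, the analytic guarantees of the
#' model: nonnegativity of every compartment, the population bound
#' `N(t) <= max(N(0), Lambda/mu) * (1 + 1e-6)`, and agreement of
#' `N(t)` with its exact closed form
#' `Lambda/mu + (N(0) - Lambda/mu) exp(-mu t)` (the total population
#' solves a scalar linear ODE, which doubles as an integration-accuracy
#' oracle).
#'
#' @param traj A `cc_trajectory`.
#' @param n_tol Relative tolerance for the closed-form population
#'   check.
#' @return A tibble with one row per invariant: `invariant`, `pass`,
#'   `worst_value`, `worst_time`.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' check_invariants(simulate_model(p, t_end = 20))
#' @export
check_invariants <- function(traj, n_tol = 1e-6) {
  stopifnot(inherits(traj, "cc_trajectory"))
  p <- attr(traj, "params")
  cmp <- setdiff(names(traj), "time")
  states <- as.matrix(traj[, cmp])
  times <- traj$time
  N <- rowSums(states)
  N0 <- N[1]
  Ninf <- p$Lambda / p$mu
  # positivity (post-clipping the stored minimum is >= 0; report the
  # pre-clip information through n_clipped)
  min_i <- which.min(apply(states, 1, min))
  bound <- max(N0, Ninf) * (1 + n_tol)
  max_i <- which.max(N)
  closed <- Ninf + (N0 - Ninf) * exp(-p$mu * times)
  err <- abs(N - closed) / max(N0, .Machine$double.eps)
  err_i <- which.max(err)
  tibble::tibble(
    invariant = c("positivity", "population_bound", "population_closed_form"),
    pass = c(min(states) >= 0,
             max(N) <= bound,
             max(err) <= n_tol),
    worst_value = c(min(states), max(N), max(err)),
    worst_time = times[c(min_i, max_i, err_i)]
  )
}
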