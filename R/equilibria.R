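#' Contagion-free equilibria
#'
#' Every variant of the model has the contagion-free steady state with
#' the whole population susceptible: `S = Lambda / mu`, all other
#' compartments zero.
#'
#' @param params A `cc_parameters` object.
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @return A named state vector at which the corresponding RHS is
#'   exactly zero.
#' @examples
#' dfe_state(preset_parameters("table2_printed"))  # S = 5000
#' @export
dfe_state <- function(params, model = c("full", "violence", "racism")) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  y <- stats::setNames(numeric(length(model_compartments(model))),
                       model_compartments(model))
  y["S"] <- p$Lambda / p$mu
  y
}

#' Equilibrium reports
#'
#' An equilibrium report couples a steady state with the diagnostics
#' needed to trust it: the max-norm residual of the RHS, the Jacobian
#' eigenvalues at the state, and a local-stability verdict
#' (`"stable"` if every eigenvalue real part is below `-tol`,
#' `"unstable"` if any exceeds `+tol`, `"marginal"` otherwise).
#'
#' @name equilibrium_report
#' @keywords internal
NULL

new_equilibrium_report <- function(state, kind, model, params,
                                   lambda_star = NA_real_, tol = 1e-9,
                                   extra = list()) {
  rhs <- model_rhs(model)
  resid <- max(abs(rhs(state, params)))
  J <- model_jacobian(params, state, model)
  ev <- eigen(J, only.values = TRUE)$values
  structure(
    c(list(
      state = state, kind = kind, model = model, params = params,
      lambda_star = lambda_star, residual_norm = resid,
      jacobian = J, eigenvalues = ev,
      stable = classify_stability(ev, tol = tol)
    ), extra),
    class = "cc_equilibrium"
  )
}

#' @export
print.cc_equilibrium <- function(x, ...) {
  cat(sprintf("<cc_equilibrium> %s equilibrium of the %s model\n",
              x$kind, x$model))
  print(x$state)
  cat(sprintf("residual (max-norm): %.3e   verdict: %s\n",
              x$residual_norm, x$stable))
  cat("eigenvalue real parts:",
      paste(sprintf("%.4g", sort(Re(x$eigenvalues))), collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy cc_equilibrium
#' @export
tidy.cc_equilibrium <- function(x, ...) {
  tibble::tibble(compartment = names(x$state),
                 value = unname(x$state))
}

#' @method glance cc_equilibrium
#' @export
glance.cc_equilibrium <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    kind = x$kind,
    residual_norm = x$residual_norm,
    lambda_star = x$lambda_star,
    max_re_eigenvalue = max(Re(x$eigenvalues)),
    stable = x$stable
  )
}

#' Closed-form endemic equilibria of the submodels
#'
#' Each submodel admits a unique persistent (endemic) equilibrium
#' exactly when its reproduction number exceeds one.  The equilibrium
#' force of infection has the closed forms
#'
#' \preformatted{
#' violence: lv* = (alpha+mu)(epsilon+mu) mu (delta+mu) (R0v - 1) /
#'                 ((alpha+mu)(epsilon+mu)(delta+mu) - alpha epsilon delta)
#' racism:   lr* = (rho+mu) mu (sigma+mu) (R0r - 1) /
#'                 ((rho+mu)(sigma+mu) - rho sigma)
#' }
#'
#' with the compartments recovered by back-substitution
#' (`S* = Lambda / (mu * R0)`, `V* = lv* / beta1`, and the downstream
#' recuperation classes from their balance equations).  Both factors in
#' the denominator are positive whenever `mu > 0`, so the equilibrium
#' is positive iff `R0 > 1`; below threshold the functions signal a
#' `cocontagion_no_endemic` error.
#'
#' @param params A `cc_parameters` object.
#' @param tol Stability tolerance passed to [classify_stability()].
#' @return A `cc_equilibrium` report (see [glance.cc_equilibrium()]),
#'   recording the equilibrium force of infection as `lambda_star`.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' eq <- endemic_violence(p)
#' eq$lambda_star      # ~0.4518
#' glance(eq)
#' @export
endemic_violence <- function(params, tol = 1e-9) {
  p <- validate_parameters(as.list(params))
  R0 <- r0_violence(p)
  if (R0 <= 1) {
    rlang::abort(
      sprintf("No endemic violence equilibrium: R0v = %.4g <= 1", R0),
      class = "cocontagion_no_endemic"
    )
  }
  am <- p$alpha + p$mu; em <- p$epsilon + p$mu; dm <- p$delta + p$mu
  lv <- am * em * p$mu * dm * (R0 - 1) /
    (am * em * dm - p$alpha * p$epsilon * p$delta)
  S <- dm / p$beta1
  V <- lv / p$beta1
  U <- p$delta * V / em
  R1 <- p$epsilon * U / am
  state <- c(S = S, V = V, U = U, R1 = R1)
  new_equilibrium_report(state, "endemic", "violence", p,
                         lambda_star = lv, tol = tol)
}

#' @rdname endemic_violence
#' @export
endemic_racism <- function(params, tol = 1e-9) {
  p <- validate_parameters(as.list(params))
  R0 <- r0_racism(p)
  if (R0 <= 1) {
    rlang::abort(
      sprintf("No endemic racism equilibrium: R0r = %.4g <= 1", R0),
      class = "cocontagion_no_endemic"
    )
  }
  rm_ <- p$rho + p$mu; sm <- p$sigma + p$mu
  lr <- rm_ * p$mu * sm * (R0 - 1) / (rm_ * sm - p$rho * p$sigma)
  S <- sm / p$beta2
  R <- lr / p$beta2
  R2 <- p$sigma * R / rm_
  state <- c(S = S, R = R, R2 = R2)
  new_equilibrium_report(state, "endemic", "racism", p,
                         lambda_star = lr, tol = tol)
}

#' Contagion-free equilibrium report
#'
#' Wraps [dfe_state()] in a full `cc_equilibrium` report (residual,
#' Jacobian eigenvalues, verdict).
#'
#' @inheritParams endemic_violence
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @export
dfe_report <- function(params, model = c("full", "violence", "racism"),
                       tol = 1e-9) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  new_equilibrium_report(dfe_state(p, model), "free", model, p, tol = tol)
}

#' Numeric endemic equilibrium of the full model
#'
#' The coexistence model has no closed-form endemic state; this routine
#' finds a root of [rhs_full()] by damped Newton iteration with a
#' finite-difference Jacobian.  The default initial guess is the
#' long-time state of an integration run (`t_guess` years), so with
#' default arguments the routine converges to the attractor the
#' dynamics actually select — which may be a boundary state in which
#' one behaviour is absent.
#'
#' @param params A `cc_parameters` object.
#' @param guess Optional starting state (named 8-vector).  When `NULL`,
#'   the endpoint of a `t_guess`-year simulation from
#'   [default_initial_state()] is used.
#' @param t_guess Horizon (years) of the guess-generating simulation.
#' @param tol_step Convergence tolerance on the Newton step (max-norm).
#' @param tol_resid Residual tolerance; defaults to `1e-8 * Lambda`.
#' @param max_iter Iteration cap.
#' @param tol Stability tolerance for the verdict.
#' @return A `cc_equilibrium` report.  Signals
#'   `cocontagion_no_convergence` if the iteration stalls and rejects
#'   (with the same condition class) roots with meaningfully negative
#'   components.
#' @examples
#' \donttest{
#' p <- preset_parameters("fig5_persistence")
#' eq <- endemic_full(p)
#' glance(eq)
#' }
#' @export
endemic_full <- function(params, guess = NULL, t_guess = 500,
                         tol_step = 1e-10, tol_resid = NULL,
                         max_iter = 200, tol = 1e-9) {
  p <- validate_parameters(as.list(params))
  if (is.null(tol_resid)) tol_resid <- 1e-8 * p$Lambda
  if (is.null(guess)) {
    traj <- simulate_model(p, t_end = t_guess, n_out = 201)
    guess <- unlist(traj[nrow(traj), full_compartments()])
  }
  y <- check_state(guess, full_compartments())
  f <- function(y) eval_rhs_raw(rhs_full, y, p)
  res <- f(y)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (max(abs(res)) < tol_resid) break
    J <- model_jacobian(p, y, "full")
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) {
      rlang::abort("Newton iteration failed: singular Jacobian",
                   class = "cocontagion_no_convergence")
    }
    # damped update: halve until the residual no longer grows
    lam <- 1
    repeat {
      y_new <- y + lam * step
      res_new <- f(y_new)
      if (max(abs(res_new)) <= max(abs(res)) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- y_new
    res <- res_new
    if (max(abs(lam * step)) < tol_step) break
  }
  if (max(abs(res)) >= tol_resid) {
    rlang::abort(
      sprintf("Newton iteration did not converge: residual %.3e after %d iterations",
              max(abs(res)), max_iter),
      class = "cocontagion_no_convergence"
    )
  }
  if (any(y < -1e-8 * p$Lambda)) {
    bad <- names(y)[y < -1e-8 * p$Lambda]
    rlang::abort(
      paste0("Root has negative component(s): ",
             paste(bad, collapse = ", ")),
      class = "cocontagion_no_convergence"
    )
  }
  y[y < 0] <- 0
  kind <- if (max(y[c("V", "R", "Ivr")]) > 1e-6) "endemic" else "free"
  new_equilibrium_report(y, kind, "full", p, tol = tol,
                         extra = list(newton_iterations = iter))
}

#' Numeric Jacobian of a model RHS
#'
#' Central finite differences with relative step `1e-6`.  The RHS of
#' every model variant is quadratic in the state (mass-action
#' incidence), so central differencing is exact up to rounding — in
#' particular the linear terms carry no truncation error at all.
#'
#' @param params A `cc_parameters` object.
#' @param state State vector at which to linearize.
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @param h_rel Relative step size.
#' @return A square matrix (1/year) with compartment dimnames.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' eigen(model_jacobian(p, dfe_state(p, "violence"), "violence"))$values
#' @export
model_jacobian <- function(params, state, model = c("full", "violence", "racism"),
                           h_rel = 1e-6) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  cmp <- model_compartments(model)
  y <- check_state(state, cmp)
  rhs <- model_rhs(model)
  n <- length(y)
  J <- matrix(0, n, n, dimnames = list(cmp, cmp))
  h <- h_rel * pmax(abs(y), 1)
  for (i in seq_len(n)) {
    yp <- y; ym <- y
    yp[i] <- y[i] + h[i]
    ym[i] <- y[i] - h[i]   # may dip below zero; harmless for the polynomial RHS
    J[, i] <- (eval_rhs_raw(rhs, yp, p) - eval_rhs_raw(rhs, ym, p)) /
      (yp[i] - ym[i])
  }
  J
}

# RHS algebra without the nonnegativity gate of check_state():
# finite-difference probes and Newton trial points may step slightly
# below zero, where the polynomial vector field is still well defined
eval_rhs_raw <- function(rhs, y, p) {
  if (identical(rhs, rhs_full)) {
    lv <- p$beta1 * (y[["V"]] + p$theta2 * y[["Ivr"]])
    lr <- p$beta2 * (y[["R"]] + p$theta1 * y[["Ivr"]])
    c(S = p$Lambda + p$alpha * y[["R1"]] + p$rho * y[["R2"]] +
        p$theta * y[["R3"]] - (lv + lr + p$mu) * y[["S"]],
      V = lv * y[["S"]] - (p$delta + p$kappa * lr + p$mu) * y[["V"]],
      U = p$delta * y[["V"]] - (p$epsilon + p$mu) * y[["U"]],
      R = lr * y[["S"]] + p$omega * y[["Ivr"]] -
        (p$sigma + p$beta_mod * lv + p$mu) * y[["R"]],
      Ivr = p$beta_mod * lv * y[["R"]] + p$kappa * lr * y[["V"]] -
        (p$phi + p$omega + p$mu) * y[["Ivr"]],
      R1 = p$epsilon * y[["U"]] - (p$alpha + p$mu) * y[["R1"]],
      R2 = p$sigma * y[["R"]] - (p$rho + p$mu) * y[["R2"]],
      R3 = p$phi * y[["Ivr"]] - (p$theta + p$mu) * y[["R3"]])
  } else if (identical(rhs, rhs_violence)) {
    lv <- p$beta1 * y[["V"]]
    c(S = p$Lambda + p$alpha * y[["R1"]] - (lv + p$mu) * y[["S"]],
      V = lv * y[["S"]] - (p$delta + p$mu) * y[["V"]],
      U = p$delta * y[["V"]] - (p$epsilon + p$mu) * y[["U"]],
      R1 = p$epsilon * y[["U"]] - (p$alpha + p$mu) * y[["R1"]])
  } else {
    lr <- p$beta2 * y[["R"]]
    c(S = p$Lambda + p$rho * y[["R2"]] - (lr + p$mu) * y[["S"]],
      R = lr * y[["S"]] - (p$sigma + p$mu) * y[["R"]],
      R2 = p$sigma * y[["R"]] - (p$rho + p$mu) * y[["R2"]])
  }
}

#' Classify local stability from Jacobian eigenvalues
#'
#' `"stable"` iff every eigenvalue real part is `< -tol`, `"unstable"`
#' iff any real part is `> +tol`, otherwise `"marginal"`.  Real parts
#' within the tolerance band are never silently rounded to a side.
#'
#' @param eigenvalues Complex (or numeric) eigenvalue vector.
#' @param tol Tolerance band half-width (1/year).
#' @return One of `"stable"`, `"unstable"`, `"marginal"`.
#' @examples
#' classify_stability(c(-0.3, -0.01))        # stable
#' classify_stability(c(-0.3, 0.2))          # unstable
#' classify_stability(c(-0.3, 1e-12))        # marginal
#' @export
classify_stability <- function(eigenvalues, tol = 1e-9) {
  re <- Re(eigenvalues)
  if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "marginal"
}
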