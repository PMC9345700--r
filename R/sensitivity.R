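#' Normalized forward sensitivity indices
#'
#' The normalized forward sensitivity index (elasticity) of a
#' reproduction number `X` with respect to a parameter `p` is
#' `SI(p) = (dX/dp) * (p / X)`: the fractional change in `X` per
#' fractional change in `p`.  For the closed-form thresholds the
#' indices are themselves closed-form:
#'
#' * `R0v = beta1 Lambda / (mu (delta + mu))`:
#'   `SI(beta1) = SI(Lambda) = +1`,
#'   `SI(delta) = -delta / (delta + mu)`,
#'   `SI(mu) = -1 - mu / (delta + mu)`; every other parameter 0.
#' * `R0r` analogously with `beta2`, `sigma`.
#'
#' `sensitivity_index()` evaluates the analytic form (or the central
#' finite difference via [finite_difference_si()]);
#' `sensitivity_report()` tabulates all 16 parameters, sorted by
#' absolute index.
#'
#' For the full-model threshold `R0vr = max(R0v, R0r)` the index is
#' taken from whichever submodel threshold is strictly larger; an exact
#' tie is non-differentiable and signals an error.
#'
#' @param params A `cc_parameters` object.
#' @param parameter Parameter name (ASCII, as in [model_parameters()]).
#' @param target One of `"r0_violence"`, `"r0_racism"`, `"r0_full"`.
#' @param method `"analytic"` (default) or `"finite_difference"`.
#' @return `sensitivity_index()`: a dimensionless scalar.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' sensitivity_index(p, "beta1", "r0_violence")   # +1
#' sensitivity_index(p, "delta", "r0_violence")   # -delta/(delta+mu)
#' @export
sensitivity_index <- function(params, parameter,
                              target = c("r0_violence", "r0_racism", "r0_full"),
                              method = c("analytic", "finite_difference")) {
  target <- match.arg(target)
  method <- match.arg(method)
  p <- validate_parameters(as.list(params))
  if (!parameter %in% parameter_names()) {
    rlang::abort(paste0("Unknown parameter: ", parameter),
                 class = "cocontagion_invalid_parameter")
  }
  target <- resolve_target(p, target)
  if (method == "finite_difference") {
    return(finite_difference_si(p, parameter, target))
  }
  fm <- target_formula(target)
  if (fm$r0(p) <= 0) {
    rlang::abort("Sensitivity index undefined: reproduction number is zero",
                 class = "cocontagion_undefined_index")
  }
  switch(parameter,
    Lambda = 1,
    mu = -1 - p$mu / (p[[fm$removal]] + p$mu),
    {
      if (parameter == fm$beta) 1
      else if (parameter == fm$removal) -p[[fm$removal]] / (p[[fm$removal]] + p$mu)
      else 0
    }
  )
}

resolve_target <- function(p, target) {
  if (target != "r0_full") return(target)
  rv <- r0_violence(p); rr <- r0_racism(p)
  if (rv == rr) {
    rlang::abort(
      "R0 of the full model is a tie between the two submodels; the max is not differentiable there",
      class = "cocontagion_undefined_index"
    )
  }
  if (rv > rr) "r0_violence" else "r0_racism"
}

target_formula <- function(target) {
  switch(target,
    r0_violence = list(r0 = r0_violence, beta = "beta1", removal = "delta"),
    r0_racism   = list(r0 = r0_racism,  beta = "beta2", removal = "sigma")
  )
}

#' Finite-difference sensitivity index
#'
#' Independent numerical route to the same elasticity: a central
#' difference on a multiplicative perturbation,
#' `(X(p (1+h)) - X(p (1-h))) / (2 h X(p))`.
#'
#' @inheritParams sensitivity_index
#' @param h_rel Relative perturbation (default `1e-6`).
#' @return A dimensionless scalar.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' finite_difference_si(p, "beta2", "r0_racism")  # 1 to ~1e-10
#' @export
finite_difference_si <- function(params, parameter,
                                 target = c("r0_violence", "r0_racism", "r0_full"),
                                 h_rel = 1e-6) {
  target <- match.arg(target)
  p <- validate_parameters(as.list(params))
  if (!parameter %in% parameter_names()) {
    rlang::abort(paste0("Unknown parameter: ", parameter),
                 class = "cocontagion_invalid_parameter")
  }
  target <- resolve_target(p, target)
  r0_fun <- target_formula(target)$r0
  x0 <- r0_fun(p)
  if (x0 <= 0) {
    rlang::abort("Sensitivity index undefined: reproduction number is zero",
                 class = "cocontagion_undefined_index")
  }
  v <- p[[parameter]]
  if (v <= 0) {
    # the elasticity normalizes by the parameter value; at zero the
    # index is 0 exactly when the target does not depend on it
    return(0)
  }
  pp <- p; pm <- p
  pp[[parameter]] <- v * (1 + h_rel)
  pm[[parameter]] <- v * (1 - h_rel)
  (r0_fun(validate_parameters(pp)) - r0_fun(validate_parameters(pm))) /
    (2 * h_rel * x0)
}

#' Full sensitivity table
#'
#' @inheritParams sensitivity_index
#' @return A tibble of class `cc_sensitivity` with columns `parameter`,
#'   `index`, `method` and attributes `target` (the submodel threshold
#'   actually differentiated) and `r0` (its value), sorted by `|index|`
#'   descending.  Parameters the target does not depend on have index
#'   exactly 0.
#' @examples
#' sensitivity_report(preset_parameters("table2_reconciled"), "r0_violence")
#' @export
sensitivity_report <- function(params,
                               target = c("r0_violence", "r0_racism", "r0_full"),
                               method = c("analytic", "finite_difference")) {
  target <- match.arg(target)
  method <- match.arg(method)
  p <- validate_parameters(as.list(params))
  resolved <- resolve_target(p, target)
  idx <- vapply(parameter_names(), function(nm) {
    sensitivity_index(p, nm, resolved, method)
  }, numeric(1))
  out <- tibble::tibble(
    parameter = parameter_names(),
    index = unname(idx),
    method = method
  )
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$index)), .data$parameter)
  structure(out,
            class = c("cc_sensitivity", class(tibble::tibble())),
            target = resolved,
            requested_target = target,
            r0 = target_formula(resolved)$r0(p))
}

#' @method glance cc_sensitivity
#' @export
glance.cc_sensitivity <- function(x, ...) {
  tibble::tibble(
    target = attr(x, "target"),
    r0 = attr(x, "r0"),
    n_nonzero = sum(x$index != 0),
    most_sensitive = x$parameter[[1]]
  )
}

#' Tornado plot of sensitivity indices
#'
#' @param object A `cc_sensitivity` report.
#' @param ... Unused.
#' @return A ggplot object: horizontal bars of the nonzero indices.
#' @method autoplot cc_sensitivity
#' @export
autoplot.cc_sensitivity <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$index != 0)
  df$parameter <- stats::reorder(df$parameter, abs(df$index))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$parameter,
                                   fill = .data$index > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "normalized forward sensitivity index",
      y = NULL,
      title = paste0("Sensitivity of ", attr(object, "target"))
    ) +
    ggplot2::theme_minimal()
}
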