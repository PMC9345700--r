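#' Basic reproduction numbers
#'
#' Closed-form thresholds from the next-generation-matrix construction
#' linearized at the contagion-free equilibrium `S0 = Lambda / mu`:
#'
#' * violence submodel: `R0v = beta1 * Lambda / (mu * (delta + mu))`
#' * racism submodel:   `R0r = beta2 * Lambda / (mu * (sigma + mu))`
#' * full model:        `R0vr = max(R0v, R0r)`
#'
#' Each behaviour dies out when its threshold is below one and invades
#' when it exceeds one.
#'
#' @param params A `cc_parameters` object (validated; `mu > 0`).
#' @return A dimensionless nonnegative number.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' r0_violence(p)  # ~3.66, prints as 3.7 to one decimal
#' r0_racism(p)    # ~6.86
#' r0_full(p)      # the max of the two
#' @export
r0_violence <- function(params) {
  p <- validate_parameters(as.list(params))
  p$beta1 * (p$Lambda / p$mu) / (p$delta + p$mu)
}

#' @rdname r0_violence
#' @export
r0_racism <- function(params) {
  p <- validate_parameters(as.list(params))
  p$beta2 * (p$Lambda / p$mu) / (p$sigma + p$mu)
}

#' @rdname r0_violence
#' @export
r0_full <- function(params) {
  max(r0_violence(params), r0_racism(params))
}

#' Next-generation matrices
#'
#' Builds the new-infection matrix `F` and transition matrix `V` of the
#' chosen model, linearized at the contagion-free equilibrium, and
#' reports the spectral radius of `F %*% solve(V)` — the basic
#' reproduction number.  The submodels have a single infectious class
#' (1x1 matrices); the full model has three (`V`, `R`, `Ivr`):
#'
#' \preformatted{
#' F = | b1*L/mu    0       b1*t2*L/mu |   V = diag(delta + mu,
#'     |   0     b2*L/mu    b2*t1*L/mu |            sigma + mu,
#'     |   0        0           0      |            phi + omega + mu)
#' }
#'
#' The third row of `F` is zero (coinfection arises only through the
#' nonlinear incidence, absent at the linearization point), so the
#' nonzero eigenvalues of `F V^-1` are exactly the two submodel
#' reproduction numbers.
#'
#' @param params A `cc_parameters` object.
#' @param model One of `"full"`, `"violence"`, `"racism"`.
#' @return An object of class `cc_ngm` with elements `F`, `V`,
#'   `spectral_radius`, `model`.
#' @examples
#' ngm <- build_ngm(preset_parameters("table2_reconciled"))
#' ngm$spectral_radius
#' @export
build_ngm <- function(params, model = c("full", "violence", "racism")) {
  model <- match.arg(model)
  p <- validate_parameters(as.list(params))
  S0 <- p$Lambda / p$mu
  if (model == "violence") {
    Fm <- matrix(p$beta1 * S0, 1, 1, dimnames = list("V", "V"))
    Vm <- matrix(p$delta + p$mu, 1, 1, dimnames = list("V", "V"))
  } else if (model == "racism") {
    Fm <- matrix(p$beta2 * S0, 1, 1, dimnames = list("R", "R"))
    Vm <- matrix(p$sigma + p$mu, 1, 1, dimnames = list("R", "R"))
  } else {
    cls <- c("V", "R", "Ivr")
    Fm <- matrix(c(
      p$beta1 * S0, 0,            p$beta1 * p$theta2 * S0,
      0,            p$beta2 * S0, p$beta2 * p$theta1 * S0,
      0,            0,            0
    ), 3, 3, byrow = TRUE, dimnames = list(cls, cls))
    Vm <- diag(c(p$delta + p$mu, p$sigma + p$mu, p$phi + p$omega + p$mu))
    dimnames(Vm) <- list(cls, cls)
  }
  if (any(abs(diag(Vm)) < .Machine$double.eps)) {
    rlang::abort("Transition matrix V is singular (a removal rate is zero)",
                 class = "cocontagion_invalid_parameter")
  }
  K <- Fm %*% solve(Vm)
  rho <- max(Mod(eigen(K, only.values = TRUE)$values))
  # 1x1 case: the spectral radius is the single entry, computed with
  # the same operation order as the closed form
  if (nrow(Fm) == 1) rho <- Fm[1, 1] / Vm[1, 1]
  structure(
    list(F = Fm, V = Vm, K = K, spectral_radius = rho, model = model),
    class = "cc_ngm"
  )
}

#' @export
print.cc_ngm <- function(x, ...) {
  cat("<cc_ngm> next-generation matrix,", x$model, "model\n")
  cat("F (new infections):\n"); print(x$F)
  cat("V (transitions):\n"); print(x$V)
  cat(sprintf("spectral radius of F V^-1 (R0): %.6g\n", x$spectral_radius))
  invisible(x)
}

#' Tidy and glance methods for next-generation matrices
#'
#' `tidy()` returns the entries of `F`, `V` and `K = F V^-1` in long
#' form; `glance()` returns a one-row summary with the spectral radius
#' and the closed-form reproduction numbers it must match.
#'
#' @param x A `cc_ngm` object.
#' @param ... Unused.
#' @method tidy cc_ngm
#' @export
tidy.cc_ngm <- function(x, ...) {
  one <- function(m, which) {
    tibble::tibble(
      matrix = which,
      from = rep(colnames(m), each = nrow(m)),
      to = rep(rownames(m), times = ncol(m)),
      value = as.vector(m)
    )
  }
  dplyr::bind_rows(one(x$F, "F"), one(x$V, "V"), one(x$K, "K"))
}

#' @rdname tidy.cc_ngm
#' @method glance cc_ngm
#' @export
glance.cc_ngm <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_infectious = nrow(x$F),
    spectral_radius = x$spectral_radius
  )
}
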