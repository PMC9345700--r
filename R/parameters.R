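#' Model parameter sets
#'
#' `model_parameters()` builds and validates the 16 nonnegative rate and
#' modification constants that drive the violence--racism co-contagion
#' model.  All rates are per year; the two transmission rates are per
#' person per year; the modification factors are dimensionless.
#'
#' @param Lambda Recruitment rate into the susceptible class
#'   (persons/year).
#' @param mu Natural exit (death/emigration) rate (1/year).  Must be
#'   strictly positive: the invariant population size is `Lambda / mu`.
#' @param beta1 Violence transmission rate (1/(person year)).
#' @param beta2 Racism transmission rate (1/(person year)).
#' @param theta1 Modification factor for the contribution of coinfected
#'   individuals to racism transmission (dimensionless).
#' @param theta2 Modification factor for the contribution of coinfected
#'   individuals to violence transmission (dimensionless).
#' @param beta_mod Modification factor for racism-infected individuals
#'   acquiring violence (dimensionless).
#' @param kappa Modification factor for violence-infected individuals
#'   acquiring racism (dimensionless).
#' @param delta Negotiation rate of violence-infected individuals
#'   (1/year).
#' @param epsilon Recuperation rate of negotiated individuals (1/year).
#' @param alpha Return rate of violence-recuperated individuals to the
#'   susceptible class (1/year).
#' @param sigma Recuperation rate of racism-infected individuals
#'   (1/year).
#' @param rho Return rate of racism-recuperated individuals to the
#'   susceptible class (1/year).
#' @param omega Violence-only control rate acting on the coinfected
#'   class (1/year).
#' @param phi Recuperation rate from coinfection (1/year).
#' @param theta Return rate of coinfection-recuperated individuals to
#'   the susceptible class (1/year).
#'
#' @return A named list of class `cc_parameters`.
#' @seealso [preset_parameters()] for the bundled reference presets,
#'   [read_parameters()] / [write_parameters()] for file round trips.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' r0_full(p)
#' @export
model_parameters <- function(Lambda, mu, beta1, beta2,
                             theta1 = 1, theta2 = 1,
                             beta_mod, kappa,
                             delta, epsilon, alpha,
                             sigma, rho,
                             omega, phi, theta) {
  p <- list(
    Lambda = Lambda, mu = mu, beta1 = beta1, beta2 = beta2,
    theta1 = theta1, theta2 = theta2, beta_mod = beta_mod,
    kappa = kappa, delta = delta, epsilon = epsilon, alpha = alpha,
    sigma = sigma, rho = rho, omega = omega, phi = phi, theta = theta
  )
  validate_parameters(p)
}

#' @rdname model_parameters
#' @param x Object to test or coerce.
#' @export
is_model_parameters <- function(x) inherits(x, "cc_parameters")

parameter_names <- function() {
  c("Lambda", "mu", "beta1", "beta2", "theta1", "theta2", "beta_mod",
    "kappa", "delta", "epsilon", "alpha", "sigma", "rho", "omega",
    "phi", "theta")
}

validate_parameters <- function(p) {
  nm <- parameter_names()
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Missing parameter(s): ", paste(missing, collapse = ", ")),
      class = "cocontagion_invalid_parameter"
    )
  }
  unknown <- setdiff(names(p), nm)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Unknown parameter key(s): ", paste(unknown, collapse = ", ")),
      class = "cocontagion_invalid_parameter"
    )
  }
  p <- p[nm]
  vals <- vapply(p, function(v) {
    if (!is.numeric(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  bad <- names(vals)[is.na(vals) | !is.finite(vals)]
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Parameter(s) not finite scalar numbers: ",
             paste(bad, collapse = ", ")),
      class = "cocontagion_invalid_parameter"
    )
  }
  neg <- names(vals)[vals < 0]
  if (length(neg) > 0) {
    rlang::abort(
      paste0("Negative value for parameter(s): ",
             paste(neg, collapse = ", ")),
      class = "cocontagion_invalid_parameter"
    )
  }
  if (vals[["mu"]] <= 0) {
    rlang::abort("Parameter 'mu' must be strictly positive",
                 class = "cocontagion_invalid_parameter")
  }
  structure(as.list(vals), class = "cc_parameters")
}

#' @export
print.cc_parameters <- function(x, ...) {
  cat("<cc_parameters> violence-racism co-contagion rates (per year)\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

#' @export
as.data.frame.cc_parameters <- function(x, ...) {
  as.data.frame(tibble::tibble(parameter = names(x),
                               value = unlist(x, use.names = FALSE)))
}

#' Tidy a parameter set into a two-column tibble
#'
#' @param x A `cc_parameters` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @method tidy cc_parameters
#' @export
tidy.cc_parameters <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unlist(x, use.names = FALSE))
}

#' Bundled reference parameter presets
#'
#' Ships the reference numerical-simulation parameter set in two
#' variants plus the four scenario presets used by the simulation
#' experiments.  `table2_printed` carries the recruitment rate
#' `Lambda = 50` exactly as tabulated in the source material for the
#' model; `table2_reconciled` is identical except `Lambda = 5`, the
#' value consistent with the headline reproduction numbers 3.7 (at
#' `beta1 = 0.003`) and 6.9 (at `beta2 = 0.007`) quoted alongside that
#' table.  The discrepancy between the tabulated recruitment rate and
#' the quoted thresholds is a documented inconsistency; both variants
#' are provided so either reading can be reproduced.
#'
#' Scenario presets (all on the reconciled base):
#' * `fig4_eradication`: `beta1 = 1e-4`, `beta2 = 2e-4`, giving
#'   reproduction numbers below one (dying-out regime).
#' * `fig5_persistence`: `beta1 = 0.001`, `beta2 = 0.004`, giving a
#'   super-threshold regime that settles on an endemic state.
#' * `fig6_omega`, `fig7_phi`: the persistence parameters, used as the
#'   baseline for the violence-only control (`omega`) and coinfection
#'   recuperation (`phi`) experiments.
#'
#' The modification factors `theta1` and `theta2` are not tabulated in
#' the source; both default to 1 (coinfected individuals transmit like
#' singly infected ones).
#'
#' @param name Preset name, one of `"table2_printed"`,
#'   `"table2_reconciled"`, `"fig4_eradication"`, `"fig5_persistence"`,
#'   `"fig6_omega"`, `"fig7_phi"`.
#' @return A `cc_parameters` object.
#' @examples
#' preset_parameters("table2_printed")$Lambda   # 50
#' preset_parameters("table2_reconciled")$Lambda # 5
#' @export
preset_parameters <- function(name = c("table2_printed", "table2_reconciled",
                                       "fig4_eradication", "fig5_persistence",
                                       "fig6_omega", "fig7_phi")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".json"),
                      package = "cocontagion", mustWork = TRUE)
  read_parameters(path)
}

#' Read and write parameter configuration files
#'
#' Parameter sets serialize to flat key-value files in JSON or YAML,
#' keyed by the ASCII names of [model_parameters()].  Unknown keys are
#' rejected with the offending name; Greek-letter aliases are not
#' accepted.
#'
#' @param path File path; the extension (`.json`, `.yaml`, `.yml`)
#'   selects the dialect.
#' @return `read_parameters()` returns a validated `cc_parameters`
#'   object; `write_parameters()` returns `path` invisibly.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' f <- tempfile(fileext = ".json")
#' write_parameters(p, f)
#' identical(unlist(read_parameters(f)), unlist(p))
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Config file not found: ", path),
                 class = "cocontagion_bad_config")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      yaml = ,
      yml  = yaml::read_yaml(path),
      rlang::abort(paste0("Unsupported config format: .", ext),
                   class = "cocontagion_bad_config")
    ),
    error = function(e) {
      if (inherits(e, "rlang_error")) rlang::cnd_signal(e)
      rlang::abort(paste0("Failed to parse ", path, ": ",
                          conditionMessage(e)),
                   class = "cocontagion_bad_config")
    }
  )
  validate_parameters(as.list(raw))
}

#' @rdname read_parameters
#' @param params A `cc_parameters` object (or coercible named list).
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(as.list(params))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                                digits = I(17), pretty = TRUE),
    yaml = ,
    yml  = writeLines(yaml::as.yaml(
      unclass(params),
      # %.17g keeps the round trip bit-exact; the yaml precision
      # argument caps below that
      handlers = list(numeric = function(v) {
        structure(sprintf("%.17g", v), class = "verbatim")
      })
    ), path),
    rlang::abort(paste0("Unsupported config format: .", ext),
                 class = "cocontagion_bad_config")
  )
  invisible(path)
}

#' Replace parameter values
#'
#' Convenience for scenario overrides: returns a new validated
#' parameter set with the named values replaced.
#'
#' @param params A `cc_parameters` object.
#' @param ... Named scalar replacements, e.g. `beta1 = 0.001`.
#' @return A `cc_parameters` object.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' set_parameters(p, beta2 = 0.004)$beta2
#' @export
set_parameters <- function(params, ...) {
  over <- rlang::list2(...)
  if (length(over) == 0) return(validate_parameters(as.list(params)))
  unknown <- setdiff(names(over), parameter_names())
  if (length(unknown) > 0 || is.null(names(over)) || any(names(over) == "")) {
    rlang::abort(
      paste0("Unknown parameter key(s): ",
             paste(unknown, collapse = ", ")),
      class = "cocontagion_invalid_parameter"
    )
  }
  p <- as.list(params)
  p[names(over)] <- over
  validate_parameters(p)
}
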