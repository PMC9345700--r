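#' Write analysis results to disk
#'
#' Serializes the package's result objects with deterministic
#' formatting: identical inputs produce byte-identical files.  Floats
#' are written with 12 significant digits.  Trajectories (and
#' control-effect tables) go to CSV with the header
#' `t,S,V,U,R,Ivr,R1,R2,R3`; sensitivity reports, equilibrium reports,
#' NGMs and sweeps serialize to either CSV or JSON.
#'
#' @param obj A `cc_trajectory`, `cc_sensitivity`, `cc_equilibrium`,
#'   `cc_ngm`, `cc_sweep`, or plain data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @examples
#' p <- preset_parameters("table2_reconciled")
#' f <- tempfile(fileext = ".csv")
#' write_results(simulate_model(p, t_end = 5, n_out = 11), f)
#' readLines(f, n = 2)
#' @export
write_results <- function(obj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    rlang::abort(paste0("Output directory does not exist: ", dir),
                 class = "cocontagion_unwritable_path")
  }
  payload <- results_payload(obj)
  if (format == "csv") {
    write_csv_stable(payload$table, path)
  } else {
    txt <- jsonlite::toJSON(payload$json, auto_unbox = TRUE, digits = I(12),
                            pretty = TRUE, na = "null")
    writeLines(txt, path)
  }
  invisible(path)
}

results_payload <- function(obj) {
  if (inherits(obj, "cc_trajectory")) {
    tab <- tibble::as_tibble(obj)
    names(tab)[names(tab) == "time"] <- "t"
    list(table = tab, json = as.list(tab))
  } else if (inherits(obj, "cc_sensitivity")) {
    tab <- tibble::as_tibble(obj)
    list(table = tab,
         json = list(target = attr(obj, "target"),
                     r0 = attr(obj, "r0"),
                     indices = stats::setNames(as.list(tab$index),
                                               tab$parameter)))
  } else if (inherits(obj, "cc_equilibrium")) {
    tab <- tidy.cc_equilibrium(obj)
    list(table = tab,
         json = list(model = obj$model, kind = obj$kind,
                     state = as.list(obj$state),
                     residual_norm = obj$residual_norm,
                     eigenvalues_re = Re(obj$eigenvalues),
                     eigenvalues_im = Im(obj$eigenvalues),
                     stable = obj$stable))
  } else if (inherits(obj, "cc_ngm")) {
    list(table = tidy.cc_ngm(obj),
         json = list(model = obj$model,
                     F = apply(obj$F, 1, as.list, simplify = FALSE),
                     V = apply(obj$V, 1, as.list, simplify = FALSE),
                     spectral_radius = obj$spectral_radius))
  } else if (is.data.frame(obj)) {
    tab <- tibble::as_tibble(obj)
    list(table = tab, json = as.list(tab))
  } else {
    rlang::abort("Unsupported object type for write_results()",
                 class = "cocontagion_unwritable_path")
  }
}

# deterministic CSV: fixed 12-significant-digit float rendering
write_csv_stable <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) sprintf("%.12g", x)
    else as.character(x)
  }
  cols <- lapply(df, fmt_col)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
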