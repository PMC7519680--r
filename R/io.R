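#' Read or write vital rates as CSV or YAML
#'
#' CSV files have columns `parameter` (the symbols `phi1`, `phi2`, `phiA`,
#' `tau3`..`tau7`, `gamma3`..`gamma7`, `F`, `Fprime`, `x`) and `value`; YAML
#' files use the same names as keys, with `tau` and `gamma` as age-keyed
#' maps.
#'
#' @param path File path (`.csv` or `.yml`/`.yaml` decided by extension).
#' @return A `vital_rates` (read) or `path` invisibly (write).
#' @export
read_vital_rates <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    vital_rates(
      phi1 = y$phi1, phi2 = y$phi2, phiA = y$phiA,
      tau = unlist(y$tau)[as.character(3:7)],
      gamma = unlist(y$gamma)[as.character(3:7)],
      F = y$F, Fprime = y$Fprime, x = y$x %||% 0.5
    )
  } else {
    d <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    val <- setNames(d$value, d$parameter)
    vital_rates(
      phi1 = val[["phi1"]], phi2 = val[["phi2"]], phiA = val[["phiA"]],
      tau = val[paste0("tau", 3:7)], gamma = val[paste0("gamma", 3:7)],
      F = val[["F"]], Fprime = val[["Fprime"]],
      x = if ("x" %in% names(val)) val[["x"]] else 0.5
    )
  }
}

#' @rdname read_vital_rates
#' @param vr A `vital_rates`.
#' @export
write_vital_rates <- function(vr, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(
      phi1 = vr$phi1, phi2 = vr$phi2, phiA = vr$phiA,
      tau = as.list(vr$tau), gamma = as.list(vr$gamma),
      F = vr$F, Fprime = vr$Fprime, x = vr$x
    ), path)
  } else {
    readr::write_csv(tidy(vr), path)
  }
  invisible(path)
}

#' Export a labeled projection matrix as CSV
#' @param M A `projection_matrix` (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  d <- tibble::as_tibble(unclass(M), .name_repair = "minimal")
  d <- dplyr::bind_cols(tibble::tibble(state = rownames(M)), d)
  readr::write_csv(d, path)
  invisible(path)
}

#' Write the latent truth record of a simulated dataset as JSON
#'
#' @param data An `encounter_df` from [simulate_histories()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(data, path) {
  tr <- truth_record(data)
  jsonlite::write_json(
    list(
      seed = tr$seed,
      phi = tr$phi, p = tr$p,
      tau = as.data.frame(tr$tau),
      individuals = tr$individuals
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' Write a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config_yaml <- function(config, path) {
  yaml::write_yaml(
    list(
      n_occasions = config$n_occasions,
      groups = config$groups,
      releases = apply(config$releases, 1L, identity, simplify = FALSE),
      phi = config$phi, p = config$p,
      tau = apply(config$tau, 1L, identity, simplify = FALSE),
      tau_link = config$tau_link,
      covariate = config$covariate
    ),
    path
  )
  invisible(path)
}
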