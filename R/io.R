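# File interfaces: CSV curve I/O, YAML model/topology configs, JSON fit
# results, and the two file-level drivers run_fit() / run_simulate().

# tolerate the unicode minus that spreadsheet exports produce
ascii_minus <- function(x) gsub("−", "-", x)

#' Read and write denaturation-curve CSV files
#'
#' The dialect is comma-separated UTF-8 with a header row and columns
#' `construct_id`, `denaturant_M`, `signal`. Unicode minus signs are
#' normalized to ASCII hyphens on read. One file holds a whole series;
#' curves are split on consecutive runs of `construct_id` so replicate
#' curves of one construct survive a round trip.
#'
#' @param path file path.
#' @param normalized are the signals normalized (0-1) rather than raw CD?
#' @return `read_curves()`: list of [denaturation_curve()] (normalized) or
#'   data.frame (raw); `write_curves()`: the path, invisibly.
#' @export
read_curves <- function(path, normalized = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct_id", "denaturant_M", "signal")
  if (!all(need %in% names(df)))
    stop("curve file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in c("denaturant_M", "signal"))
    if (is.character(df[[col]])) df[[col]] <- as.numeric(ascii_minus(df[[col]]))
  if (anyNA(df$denaturant_M) || anyNA(df$signal))
    stop("non-numeric values in curve file: ", path, call. = FALSE)
  if (!normalized) return(df)
  # a new curve starts when the construct changes or the denaturant resets
  run <- cumsum(c(TRUE, df$construct_id[-1L] != df$construct_id[-nrow(df)] |
                    df$denaturant_M[-1L] < df$denaturant_M[-nrow(df)]))
  curves <- lapply(split(df, run), function(d)
    denaturation_curve(d$construct_id[1L], d$denaturant_M, d$signal))
  names(curves) <- make.unique(vapply(curves, `[[`, "", "construct_id"))
  curves
}

#' @rdname read_curves
#' @param curves list of [denaturation_curve()] objects.
#' @export
write_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(construct_id = cv$construct_id, denaturant_M = cv$x,
               signal = cv$y)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize energy models and topologies as YAML configs
#'
#' @param model an [energy_model()].
#' @param path file path.
#' @return read functions return the object; write functions the path,
#'   invisibly.
#' @export
write_energy_model <- function(model, path) {
  stopifnot(inherits(model, "energy_model"))
  cfg <- list(variant = model$variant, temperature = model$temperature,
              gas_constant = model$gas_constant,
              classes = setNames(lapply(model$classes, function(cl) list(
                G_intr = unname(model$G_intr[[cl]]),
                G_int = unname(model$G_int[[cl]]),
                m_intr = unname(model$m_intr[[cl]]),
                m_int = unname(model$m_int[[cl]]))), model$classes))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_energy_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  cls <- names(cfg$classes)
  get <- function(field) setNames(vapply(cfg$classes, function(c)
    as.numeric(c[[field]]), 0), cls)
  margs <- switch(cfg$variant,
    both_m      = list(m_intr = get("m_intr"), m_int = get("m_int")),
    interface_m = list(m_int = get("m_int")),
    intrinsic_m = list(m_intr = get("m_intr")),
    stop("unknown variant in config: ", cfg$variant, call. = FALSE))
  do.call(energy_model, c(
    list(G_intr = get("G_intr"), G_int = get("G_int"), variant = cfg$variant,
         temperature = cfg$temperature, gas_constant = cfg$gas_constant),
    margs))
}

#' @rdname write_energy_model
#' @param top a [topology()].
#' @export
write_topology <- function(top, path) {
  stopifnot(inherits(top, "topology"))
  yaml::write_yaml(list(construct_id = top$construct_id,
                        helices = as.list(top$helices),
                        interfaces = as.list(top$interfaces)), path)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_topology <- function(path) {
  cfg <- yaml::read_yaml(path)
  topology(unlist(cfg$helices), unlist(cfg$interfaces), cfg$construct_id)
}

#' Serialize a global fit to JSON
#'
#' Records the fitted parameters, the optimizer provenance (seed, number of
#' starts, best objective, convergence codes) and the per-curve residual
#' statistics, so a fit can be audited and reproduced.
#'
#' @param fit an `ising_fit` from [global_fit()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "ising_fit"))
  out <- list(variant = fit$variant,
              temperature = fit$model$temperature,
              gas_constant = fit$model$gas_constant,
              parameters = as.list(fit$parameters),
              objective = fit$objective,
              per_curve_rms = as.list(fit$per_curve_rms),
              n_starts = fit$n_starts, seed = fit$seed,
              best_start = fit$best_start,
              convergence = fit$convergence)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit a curve file end to end
#'
#' Reads a normalized curve CSV, builds canonical topologies from the
#' construct identifiers (or uses the supplied ones), runs [global_fit()]
#' and optionally writes the result as JSON.
#'
#' @param curves_path input CSV, see [read_curves()].
#' @param out_path optional JSON output path.
#' @param topologies optional named list of [topology()] objects.
#' @inheritParams global_fit
#' @return the `ising_fit`, invisibly when `out_path` is given.
#' @export
run_fit <- function(curves_path, out_path = NULL, topologies = NULL,
                    variant = "interface_m", n_starts = 256L, seed = 1L) {
  curves <- read_curves(curves_path)
  fit <- global_fit(curves, topologies = topologies, variant = variant,
                    n_starts = n_starts, seed = seed)
  if (!is.null(out_path)) {
    write_fit_result(fit, out_path)
    return(invisible(fit))
  }
  fit
}

table1_model <- function(name) {
  switch(name,
         ctprn_table1 = ctprn_table1(),
         ctpran_table1 = ctpran_table1(),
         stop("unknown parameter set '", name, "'", call. = FALSE))
}

#' Simulate a construct from a packaged parameter set
#'
#' One-call driver for predictions: builds the topology from a construct
#' identifier (switch constructs compose CTPRn core with CTPRan cap), binds
#' the requested published parameter set, and returns the simulated
#' denaturation curve plus the C-cap-unfolded intermediate profile.
#' Optionally writes a CSV of `(x, fraction_unfolded, population)` and a
#' JSON metrics block (`alpha`, `beta`, `x_at_max`, `amplitude`).
#'
#' @param construct_id e.g. `"CTPR3"`, `"CTPRa10"`, `"CTPR3sw"`.
#' @param params `"ctprn_table1"` or `"ctpran_table1"`; ignored for switch
#'   constructs, which always pair the CTPRn core with the CTPRan cap.
#' @param x_grid denaturant grid.
#' @param out_csv,out_json optional output paths.
#' @return list with `topology`, `model`, `curve`, `profile`.
#' @export
#' @examples
#' sim <- run_simulate("CTPR3sw")
#' sim$profile
run_simulate <- function(construct_id, params = c("ctprn_table1",
                                                  "ctpran_table1"),
                         x_grid = seq(0, 8, by = 0.01),
                         out_csv = NULL, out_json = NULL) {
  if (length(x_grid) == 0L) stop("x_grid must be non-empty", call. = FALSE)
  info <- parse_construct_id(construct_id)
  if (info$switch) {
    sw <- build_switch_chimera(ctprn_table1(), ctpran_table1(),
                               info$n_repeats)
    top <- sw$topology
    model <- sw$model
  } else {
    params <- match.arg(params)
    top <- build_topology(info$n_repeats, info$series, info$n_cap, info$c_cap)
    model <- table1_model(params)
  }
  curve <- simulate_curve(top, model, x_grid)
  profile <- if (top$helices[n_helices(top)] == "S")
    intermediate_profile(top, model, x_grid) else NULL
  if (!is.null(out_csv)) {
    df <- data.frame(x = curve$x, fraction_unfolded = curve$y)
    if (!is.null(profile)) df$population <- profile$population
    write.csv(df, out_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out_json) && !is.null(profile))
    jsonlite::write_json(list(construct_id = construct_id,
                              alpha = profile$alpha, beta = profile$beta,
                              x_at_max = profile$x_at_max,
                              amplitude = profile$amplitude),
                         out_json, auto_unbox = TRUE, digits = NA)
  list(topology = top, model = model, curve = curve, profile = profile)
}
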