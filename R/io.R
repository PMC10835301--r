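#' Write a simulation to delimited text with a run manifest
#'
#' Trajectories are written as tab-separated text: first column `time_h`,
#' then one column per state variable (plus `mean_field` for ensembles; the
#' drawn periods go to a `<stem>_tau.tsv` sidecar). All run parameters, the
#' seed, the solver and the step size are logged to a JSON manifest
#' `<stem>_manifest.json`, so every run is reproducible from its files.
#'
#' @param sim A `redox_ensemble_sim` or `goodwin_sim`.
#' @param stem Output path stem (directory must exist); files
#'   `<stem>.tsv`, `<stem>_manifest.json` and (for ensembles)
#'   `<stem>_tau.tsv` are written.
#'
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(sim, stem) {
  if (inherits(sim, "redox_ensemble_sim")) {
    tab <- data.frame(time_h = sim$times,
                      t(sim$x), t(sim$y), mean_field = sim$mean_field,
                      check.names = FALSE)
    n <- nrow(sim$x)
    names(tab) <- c("time_h", paste0("x", seq_len(n)), paste0("y", seq_len(n)),
                    "mean_field")
    manifest <- list(
      model = "coupled Poincare ensemble", solver = "euler-maruyama",
      n_oscillators = sim$spec$n, tau_mean_h = sim$spec$tau_mean,
      tau_sd_h = sim$spec$tau_sd, amplitude = sim$spec$shared$A,
      lambda_per_h = sim$spec$shared$lam, twist_per_h = sim$spec$shared$eps,
      sigma = c(sim$spec$shared$sigma_x, sim$spec$shared$sigma_y),
      kc = sim$spec$kc, k_ttfl = sim$spec$k_ttfl,
      dt_h = sim$grid$dt, t_end_h = sim$grid$t_end,
      transient_h = sim$grid$transient,
      record_stride = sim$grid$record_stride, seed = sim$seed,
      package_version = as.character(packageVersion("redoxclock"))
    )
    tau_path <- paste0(stem, "_tau.tsv")
    write.table(data.frame(oscillator = seq_len(n), tau_h = sim$tau_i),
                tau_path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(sim, "goodwin_sim")) {
    tab <- data.frame(time_h = sim$times, CB = sim$CB, PCc = sim$PCc,
                      PCn = sim$PCn)
    if (!is.null(sim$drive)) tab$drive <- sim$drive
    manifest <- c(list(model = "goodwin TTFL", solver = "lsoda",
                       dt_h = sim$grid$dt, t_end_h = sim$grid$t_end,
                       transient_h = sim$grid$transient,
                       period_h = sim$period, cb_mean = sim$cb_mean,
                       package_version =
                         as.character(packageVersion("redoxclock"))),
                  unclass(sim$params))
    tau_path <- NULL
  } else {
    stop("`sim` must be a redox_ensemble_sim or goodwin_sim")
  }
  tsv_path <- paste0(stem, ".tsv")
  man_path <- paste0(stem, "_manifest.json")
  write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv_path, man_path, tau_path))
}

#' Read a delimited time-series table
#'
#' Reads a delimited text table whose first column is `time_h`, as written
#' by [write_trajectory()] or supplied by the user for the analysis
#' operations (any delimiter understood by [read.table()]; default tab).
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return data.frame with a `time_h` column.
#' @export
read_series <- function(path, sep = "\t") {
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!"time_h" %in% names(tab))
    stop("series table must have a `time_h` column")
  tab
}
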