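#' Read and write source trajectories as CSV
#'
#' The interchange schema has columns \code{k}, \code{t_seconds},
#' \code{theta_deg}, \code{omega_deg_s}.
#'
#' @param trajectory a \code{source_trajectory}.
#' @param path file path.
#' @return \code{write_trajectory} returns the path invisibly;
#'   \code{read_trajectory} returns a \code{source_trajectory}.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "source_trajectory"))
  utils::write.csv(
    trajectory[, c("k", "t_seconds", "theta_deg", "omega_deg_s")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("k", "t_seconds", "theta_deg", "omega_deg_s")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns: ", paste(need, collapse = ", "))
  dt <- if (nrow(df) > 1) stats::median(diff(df$t_seconds)) else NA_real_
  new_trajectory(df$k, df$t_seconds, df$theta_deg, df$omega_deg_s, dt)
}

#' Export the belief sequences of a fitted track as CSV
#'
#' Writes tracking and predictive beliefs in the common schema
#' \code{(k, mean_theta, mean_omega, s11, s12, s22, kind)}.
#'
#' @param track an [itd_track()] fit.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_beliefs <- function(track, path) {
  stopifnot(inherits(track, "itd_track"))
  cols <- c("k", "mean_theta", "mean_omega", "s11", "s12", "s22", "kind")
  utils::write.csv(rbind(track$filtered[, cols], track$predicted[, cols]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return \code{write_config} returns the path invisibly;
#'   \code{read_config} returns a [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x[!vapply(x, is.null, logical(1))])
}

#' Write an evaluation table with a JSON run manifest
#'
#' Saves a [run_grid()] result as CSV alongside a JSON manifest recording
#' the grid shape, population size, seed and package version.
#'
#' @param result a \code{pv_eval} table.
#' @param dir output directory (created if missing).
#' @param stem file name stem.
#' @return The two file paths, invisibly.
#' @export
write_eval <- function(result, dir, stem = "pv_eval") {
  stopifnot(inherits(result, "pv_eval"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  man <- file.path(dir, paste0(stem, "_manifest.json"))
  utils::write.csv(as.data.frame(result), csv, row.names = FALSE)
  jsonlite::write_json(
    list(n_conditions = nrow(result),
         n_neurons = attr(result, "N"),
         duration_s = attr(result, "duration_s"),
         seed = attr(result, "seed"),
         package = "itdtrack",
         version = as.character(utils::packageVersion("itdtrack")),
         created = format(Sys.time(), tz = "UTC")),
    man, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, manifest = man))
}
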