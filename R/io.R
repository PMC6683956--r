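#' Read observed consumption series from CSV
#'
#' Expects columns `time_min, species, value, scale` with
#' `scale` in `{normalized, uM}`. Rows are grouped by species into one
#' [observed_series()] each; malformed content is rejected with the
#' offending line numbers (header is line 1).
#'
#' @param path CSV file.
#' @return A named list of `observed_series`, one per species.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_min", "species", "value", "scale")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  lineno <- seq_len(nrow(df)) + 1L
  bad <- which(!is.finite(df$time_min) | df$time_min < 0 |
                 !is.finite(df$value) | df$value < 0 |
                 !df$scale %in% c("normalized", "uM"))
  if (length(bad))
    stop("malformed rows at line ", paste(lineno[bad], collapse = ", "),
         " of ", path, call. = FALSE)
  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    dup <- which(duplicated(sub$time_min))
    if (length(dup))
      stop("duplicated time for species '", sp, "' at line ",
           lineno[df$species == sp][dup[1]], " of ", path, call. = FALSE)
    o <- order(sub$time_min)
    if (any(o != seq_along(o))) {
      first_bad <- which(diff(sub$time_min) < 0)[1] + 1L
      stop("non-monotone times for species '", sp, "' at line ",
           lineno[df$species == sp][first_bad], " of ", path, call. = FALSE)
    }
    if (length(unique(sub$scale)) != 1)
      stop("mixed scales for species '", sp, "' in ", path, call. = FALSE)
    out[[sp]] <- observed_series(sub$time_min, sub$value, sp,
                                 sub$scale[1])
  }
  out
}

#' Write observed series to CSV
#'
#' Inverse of [read_timeseries_csv()]: long format
#' `time_min,species,value,scale`, decimal point, no thousands separators.
#'
#' @param series_list An `observed_series` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series_list, path) {
  if (inherits(series_list, "observed_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(s)
    data.frame(time_min = s$time, species = attr(s, "species"),
               value = s$value, scale = attr(s, "scale")))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Trajectory CSV export / import
#'
#' Header `time_min,C_A_uM,C_R_uM,C_C_uM,C_CM_uM`; one row per output time.
#'
#' @param traj A `kinetic_trajectory`.
#' @param path File path.
#' @return `path` (write) or a data.frame (read), invisibly for the writer.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  df <- data.frame(time_min = traj$time, C_A_uM = traj$C_A,
                   C_R_uM = traj$C_R, C_C_uM = traj$C_C,
                   C_CM_uM = traj$C_CM)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  required <- c("time_min", "C_A_uM", "C_R_uM", "C_C_uM", "C_CM_uM")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read a declarative model configuration
#'
#' YAML with explicit unit suffixes on every numeric key. Recognized keys:
#' `aaph_mM`, `curcumin_uM`, `curcumin_ugml`, `monoacrylate_uM`,
#' `horizon_min`, `k_A_per_min`, `k_el_per_min`, `k_C_per_uM_min`,
#' `k_CM_per_uM_min`, `mode`, `release_uM_min` (constant curcumin release
#' over the whole horizon) and `bolus_uM` (curcumin bolus at t = 0).
#' Unit conversions (mM to uM, ug/ml to uM) happen here, at the boundary.
#'
#' @param path YAML file.
#' @return A [kinetic_config()].
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- c("aaph_mM", "curcumin_uM", "curcumin_ugml", "monoacrylate_uM",
             "horizon_min", "k_A_per_min", "k_el_per_min", "k_C_per_uM_min",
             "k_CM_per_uM_min", "mode", "release_uM_min", "bolus_uM")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unrecognized config key(s) (unit suffix required): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grab <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  k <- rate_constants(k_A = grab("k_A_per_min", 1.26e-6),
                      k_el = grab("k_el_per_min", 4.16e4),
                      k_C = grab("k_C_per_uM_min", 0),
                      k_CM = grab("k_CM_per_uM_min", 0))
  C_C <- grab("curcumin_uM", 0) +
    curcumin_ugml_to_uM(grab("curcumin_ugml", 0))
  horizon <- grab("horizon_min", 1440)
  boluses <- NULL
  segs <- NULL
  if (!is.null(y$bolus_uM))
    boluses <- data.frame(time = 0, species = "curcumin", amount = y$bolus_uM)
  if (!is.null(y$release_uM_min))
    segs <- data.frame(t_start = 0, t_end = horizon, species = "curcumin",
                       rate = y$release_uM_min)
  kinetic_config(k,
                 species_state(C_A = aaph_mM_to_uM(grab("aaph_mM", 0)),
                               C_C = C_C,
                               C_CM = grab("monoacrylate_uM", 0)),
                 horizon = horizon,
                 dosing = dosing_scheme(boluses = boluses,
                                        rate_segments = segs),
                 mode = grab("mode", "full_stiff"))
}
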