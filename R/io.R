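#' Read a titration dataset from CSV
#'
#' Reads the package's CSV schema (comma-separated, header row) and
#' validates it into a [titration_dataset()]. Exchange-rate datasets carry
#' columns `chi` or `f_z` (exactly one populated), `kex` and optional
#' `sigma`; shift datasets carry `P_total_uM`, `N_total_uM`, `probe_id`,
#' `nucleus`, `ddelta_obs_ppm`, `sigma_ppm` and optional `f_z`,
#' `f_z_sigma` rows (with empty `probe_id`) keyed by composition.
#' Concentration columns may alternatively use `_nM` or `_mM` suffixes and
#' are converted to uM. Malformed cells are reported with their row and
#' column.
#'
#' @param path Path to a CSV file.
#' @param observable_kind Optional; inferred from the columns when `NULL`
#'   (`chi` implies `kex_vs_chi`; `f_z` + `kex` implies `kex_zform` unless
#'   overridden; shift columns imply `shift_and_fz`).
#' @return A [titration_dataset()]. Metadata columns `pH`, `salt_mM`,
#'   `sequence`, if present and constant, populate the dataset metadata.
#' @export
read_titration_csv <- function(path, observable_kind = NULL) {
  if (!file.exists(path))
    stop_bz("io", paste("file not found:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    stop_bz("empty_dataset", paste("empty data section in", path))
  raw <- convert_conc_units(raw)
  nms <- names(raw)
  if (is.null(observable_kind)) {
    observable_kind <- if ("ddelta_obs_ppm" %in% nms) "shift_and_fz"
      else if ("chi" %in% nms && any(!is.na(raw$chi))) "kex_vs_chi"
      else if ("f_z" %in% nms) "kex_zform"
      else stop_bz("invalid_dataset",
                   paste("cannot infer observable kind from columns:",
                         paste(nms, collapse = ", ")))
  }
  num_cols <- intersect(c("chi", "f_z", "kex", "sigma", "P_total_uM",
                          "N_total_uM", "ddelta_obs_ppm", "sigma_ppm",
                          "f_z_sigma"), nms)
  for (cn in num_cols) {
    v <- raw[[cn]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad))
        stop_bz("parse",
                sprintf("non-numeric value in column %s, row %d of %s: '%s'",
                        cn, bad[1], path, v[bad[1]]))
      raw[[cn]] <- conv
    }
  }
  for (cn in intersect(c("P_total_uM", "N_total_uM"), nms)) {
    bad <- which(!is.na(raw[[cn]]) & raw[[cn]] < 0)
    if (length(bad))
      stop_bz("parse", sprintf("negative concentration in column %s, row %d of %s",
                               cn, bad[1], path))
  }
  if (observable_kind == "shift_and_fz") {
    if (!all(c("P_total_uM", "N_total_uM") %in% nms))
      stop_bz("invalid_dataset",
              "shift datasets need absolute concentrations (P_total, N_total): ratios alone cannot constrain binding constants")
    if ("probe_id" %in% nms) raw$probe_id[raw$probe_id %in% c("", "NA")] <- NA
  }
  meta <- function(col) {
    if (col %in% nms && length(u <- unique(stats::na.omit(raw[[col]]))) == 1L) u
    else NA
  }
  titration_dataset(observable_kind,
                    raw[, setdiff(nms, c("pH", "salt_mM", "sequence")), drop = FALSE],
                    pH = as.numeric(meta("pH")), salt_mM = as.numeric(meta("salt_mM")),
                    sequence = as.character(meta("sequence")))
}

# accept _nM / _mM concentration columns and convert to the package's uM
convert_conc_units <- function(df) {
  for (base in c("P_total", "N_total")) {
    if (paste0(base, "_nM") %in% names(df)) {
      df[[paste0(base, "_uM")]] <- suppressWarnings(as.numeric(df[[paste0(base, "_nM")]])) * 1e-3
      df[[paste0(base, "_nM")]] <- NULL
    }
    if (paste0(base, "_mM") %in% names(df)) {
      df[[paste0(base, "_uM")]] <- suppressWarnings(as.numeric(df[[paste0(base, "_mM")]])) * 1e3
      df[[paste0(base, "_mM")]] <- NULL
    }
  }
  df
}

#' Write a titration dataset to CSV
#'
#' Inverse of [read_titration_csv()]: writes the points table plus
#' constant metadata columns, losslessly (full double precision).
#'
#' @param data A [titration_dataset()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_titration_csv <- function(data, path) {
  stopifnot(inherits(data, "titration_dataset"))
  pts <- data$points
  if (!is.na(data$pH)) pts$pH <- data$pH
  if (!is.na(data$salt_mM)) pts$salt_mM <- data$salt_mM
  if (!is.na(data$sequence)) pts$sequence <- data$sequence
  con <- file(path, "w")
  on.exit(close(con))
  # format doubles at full round-trip precision
  fmt <- lapply(pts, function(col)
    if (is.double(col)) ifelse(is.na(col), "", sprintf("%.17g", col))
    else ifelse(is.na(col), "", as.character(col)))
  utils::write.table(as.data.frame(fmt, stringsAsFactors = FALSE), con,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' Loads a YAML configuration for the command-line tools and fills in
#' defaults. Every run's report embeds a provenance block (tool version,
#' config hash, seed) built from this object.
#'
#' @param path Path to a YAML file, or `NULL` for an all-defaults config.
#' @return An object of class `bz_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_bz("io", paste("config file not found:", path))
    yaml::read_yaml(path)
  }
  defaults <- list(
    seed = 1L, eq = "global", fz_denominator = "dna", n_starts = 8L,
    noise = list(kex_cv = 0.05, shift_sigma = 0.005, fz_sigma = 0.02),
    n_rep = 200L, quiet = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  cfg$config_hash <- if (is.null(path)) "defaults" else unname(tools::md5sum(path))
  class(cfg) <- "bz_config"
  cfg
}

provenance_block <- function(cfg) {
  list(tool = "bzfit", version = as.character(utils::packageVersion("bzfit")),
       config_hash = cfg$config_hash, seed = cfg$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a fit report
#'
#' Serialises a `bz_fit` to JSON (estimates, uncertainties, objective,
#' convergence flags, provenance) plus a residuals CSV next to it.
#' Non-finite values appear only in explicitly flagged non-converged
#' entries.
#'
#' @param fit A `bz_fit` object.
#' @param path Output JSON path; the residual CSV gets the same stem with
#'   `_residuals.csv`.
#' @param cfg A `bz_config` (for the provenance block); defaults used if
#'   `NULL`.
#' @return Invisibly, `path`.
#' @export
write_fit_report <- function(fit, path, cfg = NULL) {
  stopifnot(inherits(fit, "bz_fit"))
  if (is.null(cfg)) cfg <- read_run_config(NULL)
  rep <- list(
    provenance = provenance_block(cfg),
    model = fit$model,
    estimates = as.list(fit$estimates),
    standard_errors = as.list(fit$se),
    objective = fit$objective,
    n_points = fit$n_points, n_free_parameters = fit$n_free,
    converged = fit$converged, flags = fit$flags)
  if (!is.null(fit$probe_shifts)) rep$probe_shifts <- fit$probe_shifts
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  utils::write.csv(fit$residuals,
                   sub("\\.json$", "_residuals.csv", path), row.names = FALSE)
  invisible(path)
}
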