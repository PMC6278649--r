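#' Titration dataset container
#'
#' One titration experiment: a set of composition points with observed
#' values, optional standard errors, and sample metadata. Four observable
#' kinds are supported, matching the forward models of the package:
#'
#' * `"kex_vs_chi"` — Z-form imino-proton exchange rates versus the molar
#'   ratio `chi` ([kex_vs_chi()]); point columns `chi`, `kex`, `sigma`.
#' * `"kex_bform"` — B-form imino exchange rates versus Z-fraction
#'   ([kex_bform_vs_fz()]); point columns `f_z`, `kex`, `sigma`.
#' * `"kex_zform"` — Z-form imino exchange rates versus Z-fraction
#'   ([kex_zform_vs_fz()]); point columns `f_z`, `kex`, `sigma`.
#' * `"shift_and_fz"` — per-probe amide shift perturbations plus Z-fraction
#'   readings across absolute compositions ([delta_obs()]); point columns
#'   `P_total_uM`, `N_total_uM`, `probe_id`, `nucleus`, `ddelta_obs_ppm`,
#'   `sigma_ppm`, and (on rows with `probe_id` `NA`) `f_z`, `f_z_sigma`.
#'
#' @param observable_kind One of the four kinds above.
#' @param points A data frame with the columns listed for the kind.
#' @param pH Sample pH (metadata, optional).
#' @param salt_mM NaCl concentration in mM (metadata, optional).
#' @param sequence DNA duplex label, e.g. `"d(CGCGCG)2"` (optional).
#' @param n_free_parameters If known, the number of parameters a fit will
#'   estimate; used for the points-per-parameter design warning.
#' @return An object of class `titration_dataset`.
#' @export
titration_dataset <- function(observable_kind, points, pH = NA_real_,
                              salt_mM = NA_real_, sequence = NA_character_,
                              n_free_parameters = NULL) {
  kinds <- c("kex_vs_chi", "kex_bform", "kex_zform", "shift_and_fz")
  if (!is.character(observable_kind) || length(observable_kind) != 1L ||
      !observable_kind %in% kinds)
    stop_bz("invalid_dataset",
            paste("observable_kind must be one of:", paste(kinds, collapse = ", ")))
  if (!is.data.frame(points) || nrow(points) == 0L)
    stop_bz("empty_dataset", "points must be a non-empty data frame")
  required <- switch(observable_kind,
    kex_vs_chi = c("chi", "kex"),
    kex_bform = c("f_z", "kex"),
    kex_zform = c("f_z", "kex"),
    shift_and_fz = c("P_total_uM", "N_total_uM", "probe_id", "ddelta_obs_ppm"))
  miss <- setdiff(required, names(points))
  if (length(miss))
    stop_bz("invalid_dataset",
            paste("points is missing required columns:", paste(miss, collapse = ", ")))
  sig_cols <- intersect(c("sigma", "sigma_ppm", "f_z_sigma"), names(points))
  for (sc in sig_cols) {
    bad <- which(!is.na(points[[sc]]) & points[[sc]] <= 0)
    if (length(bad))
      stop_bz("invalid_dataset",
              sprintf("column %s must be > 0 where provided (rows %s)",
                      sc, paste(bad, collapse = ", ")))
  }
  ds <- structure(
    list(observable_kind = observable_kind, points = points,
         pH = pH, salt_mM = salt_mM, sequence = sequence),
    class = "titration_dataset"
  )
  if (!is.null(n_free_parameters) &&
      n_obs_points(ds) < 5L * n_free_parameters)
    warn_bz("under_determined_design",
            sprintf("only %d points for %d free parameters (< 5 per parameter)",
                    n_obs_points(ds), n_free_parameters))
  ds
}

# number of observation rows actually carrying a value
n_obs_points <- function(ds) {
  p <- ds$points
  if (ds$observable_kind == "shift_and_fz") {
    sum(!is.na(p$ddelta_obs_ppm)) +
      if ("f_z" %in% names(p)) sum(is.na(p$probe_id) & !is.na(p$f_z)) else 0L
  } else {
    sum(!is.na(p$kex))
  }
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("Titration dataset [%s]: %d observations\n",
              x$observable_kind, n_obs_points(x)))
  meta <- c(if (!is.na(x$sequence)) paste0("sequence ", x$sequence),
            if (!is.na(x$pH)) paste0("pH ", x$pH),
            if (!is.na(x$salt_mM)) paste0(x$salt_mM, " mM NaCl"))
  if (length(meta)) cat("  ", paste(meta, collapse = ", "), "\n", sep = "")
  print(utils::head(x$points, 4))
  if (nrow(x$points) > 4) cat("  ...", nrow(x$points) - 4, "more rows\n")
  invisible(x)
}
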