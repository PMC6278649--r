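#' Literature-reported equilibrium constants for ZBP-DNA systems
#'
#' Reported constants of the four-state B-Z transition mechanism for
#' representative Z-DNA-binding-domain / 6-bp duplex pairs, used as truth
#' values for the synthetic fixtures and recovery studies. `alpha_printed`
#' is the ratio as published; `alpha_is_inverse_ratio` flags the one
#' system (hZa_ADAR1 with d(CGTACG)2) whose published ratio matches
#' `Kd_BP/Kd_ZP2` rather than the stated definition `Kd_ZP2/Kd_BP` - the
#' fixtures record the published numbers unchanged and flag the
#' inconsistency instead of silently correcting it. `Kd` values are uM;
#' `NA` means not determined.
#'
#' @return A data frame with one row per system: `zbp`, `dna`,
#'   `alpha_printed`, `K_BZ1`, `Kd_BP_uM`, `Kd_ZP2_uM`, `observable`,
#'   `alpha_is_inverse_ratio`.
#' @examples
#' zbp_reference_constants()
#' @export
zbp_reference_constants <- function() {
  data.frame(
    zbp = c("hZa_ADAR1", "hZa_ADAR1", "hZa_ADAR1", "yabZa_E3L"),
    dna = c("d(CGCGCG)2", "d(CACGTG)2", "d(CGTACG)2", "d(CGCGCG)2"),
    alpha_printed = c(1.15e-2, 1.42, 13.9, 0.154),
    K_BZ1 = c(1, 0.4, 6.3, 1.02),
    Kd_BP_uM = c(NA, 260, 400, NA),
    Kd_ZP2_uM = c(NA, 180, 29, NA),
    observable = c("kex_vs_chi", "kex_bform", "kex_bform", "kex_zform"),
    alpha_is_inverse_ratio = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Reported caZa_PKZ equilibrium constants across pH and ionic strength
#'
#' Constants of the caZa_PKZ-induced transition of 7-bp/6-bp duplexes
#' determined by global fitting of amide shift-perturbation and Z-fraction
#' titrations, across pH and NaCl series. Used as the truth grid for the
#' global-fit fixtures and recovery studies. All `Kd` in uM.
#'
#' @return A data frame with columns `dna`, `pH`, `NaCl_mM`, `K_BZ1`,
#'   `Kd_BP_uM`, `Kd_ZP2_uM`.
#' @examples
#' pkz_salt_constants()
#' @export
pkz_salt_constants <- function() {
  data.frame(
    dna = c("d(TCGCGCG)2", "d(TCGCGCG)2", "d(TCGCGCG)2",
            "d(TCGCGCG)2", "d(TCGCGCG)2", "d(CGCGCG)2"),
    pH = c(6, 6, 6, 8, 8, 8),
    NaCl_mM = c(10, 100, 250, 10, 100, 10),
    K_BZ1 = c(0.87, 0.19, 0.01, 1.18, 0.18, 0.11),
    Kd_BP_uM = c(0.028, 16.4, 64.1, 0.157, 5.41, 5.18),
    Kd_ZP2_uM = c(0.345, 8.76, 9.57, 0.129, 2.41, 1.79),
    stringsAsFactors = FALSE
  )
}

# fixed default probe set for shift simulations: 8 amide probes with
# limiting shifts spanning the magnitudes typical of ZBP titrations
default_probe_shifts <- function() {
  data.frame(
    probe_id = c("A1-H", "A2-H", "A3-H", "A4-H", "A5-N", "A6-N", "A7-N", "A8-N"),
    nucleus = c(rep("1H", 4), rep("15N", 4)),
    delta_B = c(0.12, -0.08, 0.05, 0.20, 0.9, -0.6, 1.4, -0.3),
    delta_Z = c(0.30, 0.15, -0.12, 0.08, 2.1, 1.2, -0.8, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Specification of one synthetic titration dataset
#'
#' Declares the truth parameters, composition design, noise model and seed
#' from which [simulate_dataset()] generates a [titration_dataset()].
#' Noise-free means are always computed through the package's own forward
#' models; noise is additive Gaussian on shifts and Z-fractions
#' (Z-fractions clipped to `[0, 1]`) and multiplicative log-normal on
#' exchange rates (rates must stay positive).
#'
#' Default designs: exchange-rate kinds use 12 points on the molar-ratio
#' grid 0.17-2.0 at `[N]_t = 100` uM (or the matching `f_z` grid);
#' shift/Z-fraction titrations cross `[N]_t` in {0.1, 1, 10, 100} uM with
#' ratios {0.5, 1, 2} - a dilution series in the duplex keeps the absolute
#' dissociation constants identifiable across their reported range.
#'
#' @param observable_kind One of `"kex_vs_chi"`, `"kex_bform"`,
#'   `"kex_zform"`, `"shift_and_fz"`.
#' @param truth A list with the generating parameters: for exchange kinds
#'   `alpha`, `K_BZ1` (ignored by `kex_vs_chi`) and `rates`
#'   ([exchange_rates()]); for `shift_and_fz` a [bz_params()] in `params`
#'   and optionally `probes` (data frame like [default_probe_shifts()]).
#' @param design Optional list overriding the composition grid: `chi`
#'   and/or `N_total` (exchange/shift kinds), or `f_z` (Z-fraction kinds).
#' @param noise List: `kex_cv` (multiplicative CV of rates),
#'   `shift_sigma` (ppm), `fz_sigma` (fraction). Zero means noise-free.
#' @param seed Integer seed making the dataset reproducible.
#' @return An object of class `bz_simspec`.
#' @export
simulation_spec <- function(observable_kind, truth, design = list(),
                            noise = list(), seed = 1L) {
  kinds <- c("kex_vs_chi", "kex_bform", "kex_zform", "shift_and_fz")
  if (!observable_kind %in% kinds)
    stop_bz("invalid_spec", paste("observable_kind must be one of:",
                                  paste(kinds, collapse = ", ")))
  noise <- utils::modifyList(list(kex_cv = 0, shift_sigma = 0, fz_sigma = 0), noise)
  if (any(unlist(noise) < 0))
    stop_bz("invalid_spec", "noise parameters must be >= 0")
  design <- utils::modifyList(
    switch(observable_kind,
      kex_vs_chi = list(chi = seq(0.17, 2, length.out = 12), N_total = 100),
      kex_bform = list(f_z = seq(0.04, 0.92, length.out = 12)),
      kex_zform = list(f_z = seq(0.05, 1, length.out = 12)),
      shift_and_fz = list(N_total = c(0.1, 1, 10, 100), chi = c(0.5, 1, 2))),
    design)
  if (!is.null(design$chi) && is.unsorted(design$chi, strictly = TRUE))
    stop_bz("invalid_spec", "design chi grid must be strictly increasing")
  if (observable_kind == "shift_and_fz") {
    if (is.null(truth$params) || !inherits(truth$params, "bz_params"))
      stop_bz("invalid_spec", "truth$params must be a bz_params object")
    if (is.null(truth$probes)) truth$probes <- default_probe_shifts()
  } else {
    if (is.null(truth$alpha))
      stop_bz("invalid_spec", "truth$alpha is required for exchange-rate kinds")
    if (observable_kind != "kex_vs_chi" && is.null(truth$K_BZ1))
      stop_bz("invalid_spec", "truth$K_BZ1 is required for f_Z-parameterised kinds")
    if (is.null(truth$rates) || !inherits(truth$rates, "exchange_rates"))
      stop_bz("invalid_spec", "truth$rates must be an exchange_rates object")
  }
  structure(list(observable_kind = observable_kind, truth = truth,
                 design = design, noise = noise, seed = as.integer(seed)),
            class = "bz_simspec")
}

#' Generate a synthetic titration dataset
#'
#' Computes noise-free observations through the package's forward models
#' ([kex_vs_chi()], [kex_bform_vs_fz()], [kex_zform_vs_fz()],
#' [delta_obs()] plus the equilibrium solver) at the spec's design points,
#' applies the spec's noise model, and returns a [titration_dataset()]
#' whose `truth` attribute records the generating parameters. Byte-
#' reproducible under the spec's seed.
#'
#' @param spec A [simulation_spec()].
#' @return A [titration_dataset()]; `attr(, "truth")` holds the truth
#'   list, including the noise-free means in `attr(, "truth")$noisefree`.
#' @examples
#' sp <- simulation_spec("kex_zform",
#'   truth = list(alpha = 0.154, K_BZ1 = 1.02,
#'                rates = exchange_rates(kex_ZP = 12, kex_ZP2 = 0.8)),
#'   noise = list(kex_cv = 0.05), seed = 7)
#' simulate_dataset(sp)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "bz_simspec"))
  k <- spec$observable_kind
  tr <- spec$truth
  withr::with_seed(spec$seed, {
    if (k == "kex_vs_chi") {
      chi <- spec$design$chi
      mu <- kex_vs_chi(tr$rates, tr$alpha, chi)
      kex <- apply_kex_noise(mu, spec$noise$kex_cv)
      pts <- data.frame(chi = chi, kex = kex,
                        sigma = sigma_or_na(mu * spec$noise$kex_cv))
      ds <- titration_dataset(k, pts)
    } else if (k %in% c("kex_bform", "kex_zform")) {
      fz <- spec$design$f_z
      mu <- if (k == "kex_bform")
        kex_bform_vs_fz(tr$rates, tr$alpha, tr$K_BZ1, fz)
      else kex_zform_vs_fz(tr$rates, tr$alpha, tr$K_BZ1, fz)
      kex <- apply_kex_noise(mu, spec$noise$kex_cv)
      pts <- data.frame(f_z = fz, kex = kex,
                        sigma = sigma_or_na(mu * spec$noise$kex_cv))
      ds <- titration_dataset(k, pts)
    } else {
      grid <- expand.grid(N_total = spec$design$N_total, chi = spec$design$chi,
                          KEEP.OUT.ATTRS = FALSE)
      grid$P_total <- grid$N_total * grid$chi
      probes <- tr$probes
      states <- lapply(seq_len(nrow(grid)), function(i)
        equilibrium_state(tr$params, bz_mixture(grid$P_total[i], grid$N_total[i])))
      shift_mu <- lapply(seq_len(nrow(probes)), function(j)
        vapply(states, function(st)
          delta_obs(st, shift_pair(probes$probe_id[j], probes$delta_B[j],
                                   probes$delta_Z[j])), 0))
      sh <- do.call(rbind, lapply(seq_len(nrow(probes)), function(j) {
        mu <- shift_mu[[j]]
        data.frame(P_total_uM = grid$P_total, N_total_uM = grid$N_total,
                   probe_id = probes$probe_id[j], nucleus = probes$nucleus[j],
                   ddelta_obs_ppm = mu + if (spec$noise$shift_sigma > 0)
                     stats::rnorm(length(mu), 0, spec$noise$shift_sigma) else 0,
                   sigma_ppm = sigma_or_na(rep(spec$noise$shift_sigma, length(mu))),
                   f_z = NA_real_, f_z_sigma = NA_real_)
      }))
      fz_mu <- vapply(states, function(st) st$f_Z_dna, 0)
      fz_obs <- fz_mu + if (spec$noise$fz_sigma > 0)
        stats::rnorm(length(fz_mu), 0, spec$noise$fz_sigma) else 0
      fzr <- data.frame(P_total_uM = grid$P_total, N_total_uM = grid$N_total,
                        probe_id = NA_character_, nucleus = NA_character_,
                        ddelta_obs_ppm = NA_real_, sigma_ppm = NA_real_,
                        f_z = pmin(1, pmax(0, fz_obs)),
                        f_z_sigma = sigma_or_na(rep(spec$noise$fz_sigma, length(fz_mu))))
      ds <- titration_dataset(k, rbind(sh, fzr))
      tr$noisefree <- list(shift_mu = unlist(shift_mu), fz_mu = fz_mu)
    }
    attr(ds, "truth") <- tr
    attr(ds, "spec") <- spec
    ds
  })
}

apply_kex_noise <- function(mu, cv) {
  if (cv <= 0) return(mu)
  # log-normal multiplicative noise with unit mean and the requested CV
  sdlog <- sqrt(log1p(cv^2))
  mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sigma_or_na <- function(s) ifelse(s > 0, s, NA_real_)

#' Write a versioned suite of synthetic fixture datasets
#'
#' Generates CSV datasets covering all four observable kinds, every
#' reference-constant row ([zbp_reference_constants()] for the exchange
#' observables, [pkz_salt_constants()] for the global shift/Z-fraction
#' observable) and three noise levels (none, low, nominal), together with
#' a JSON manifest recording the truth parameters, seeds and MD5 hashes of
#' every file. Running twice with the same seed reproduces identical
#' files.
#'
#' @param output_dir Writable directory (created if missing).
#' @param seed Base seed; each dataset derives its own from it.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(output_dir, seed = 1L) {
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (file.access(output_dir, 2) != 0)
    stop_bz("io", paste("output directory not writable:", output_dir))
  noise_levels <- list(
    none = list(kex_cv = 0, shift_sigma = 0, fz_sigma = 0),
    low = list(kex_cv = 0.02, shift_sigma = 0.002, fz_sigma = 0.01),
    nominal = list(kex_cv = 0.05, shift_sigma = 0.005, fz_sigma = 0.02)
  )
  default_rates <- list(
    kex_vs_chi = exchange_rates(kex_ZP = 10, kex_ZP2 = 1),
    kex_bform = exchange_rates(kex_B = 2, kex_BP = 30),
    kex_zform = exchange_rates(kex_ZP = 12, kex_ZP2 = 0.8)
  )
  entries <- list()
  idx <- 0L
  add_entry <- function(name, spec, truth_rec) {
    idx <<- idx + 1L
    ds <- simulate_dataset(spec)
    path <- file.path(output_dir, paste0(name, ".csv"))
    write_titration_csv(ds, path)
    entries[[length(entries) + 1L]] <<- list(
      file = basename(path), observable_kind = spec$observable_kind,
      seed = spec$seed, noise = spec$noise, truth = truth_rec,
      md5 = unname(tools::md5sum(path)))
  }
  ref <- zbp_reference_constants()
  for (i in seq_len(nrow(ref))) {
    kind <- ref$observable[i]
    for (nl in names(noise_levels)) {
      nm <- sprintf("%02d_%s_%s_%s", i, gsub("[^A-Za-z0-9]", "", ref$zbp[i]),
                    kind, nl)
      spec <- simulation_spec(
        kind,
        truth = list(alpha = ref$alpha_printed[i], K_BZ1 = ref$K_BZ1[i],
                     rates = default_rates[[kind]]),
        noise = noise_levels[[nl]],
        seed = seed + 1000L * i + match(nl, names(noise_levels)))
      add_entry(nm, spec, list(
        system = paste(ref$zbp[i], ref$dna[i]),
        alpha = ref$alpha_printed[i], K_BZ1 = ref$K_BZ1[i],
        alpha_is_inverse_ratio = ref$alpha_is_inverse_ratio[i]))
    }
  }
  pkz <- pkz_salt_constants()
  for (i in seq_len(nrow(pkz))) {
    for (nl in names(noise_levels)) {
      nm <- sprintf("pkz%02d_pH%g_%gmM_%s", i, pkz$pH[i], pkz$NaCl_mM[i], nl)
      spec <- simulation_spec(
        "shift_and_fz",
        truth = list(params = bz_params(pkz$Kd_BP_uM[i], pkz$Kd_ZP2_uM[i],
                                        pkz$K_BZ1[i])),
        noise = noise_levels[[nl]],
        seed = seed + 100000L + 1000L * i + match(nl, names(noise_levels)))
      add_entry(nm, spec, list(
        system = paste("caZa_PKZ", pkz$dna[i]), pH = pkz$pH[i],
        NaCl_mM = pkz$NaCl_mM[i], K_BZ1 = pkz$K_BZ1[i],
        Kd_BP_uM = pkz$Kd_BP_uM[i], Kd_ZP2_uM = pkz$Kd_ZP2_uM[i],
        fz_sigma_note = "placeholder noise level; realistic NMR-integral sigma unstated"))
    }
  }
  manifest <- list(version = as.character(utils::packageVersion("bzfit")),
                   base_seed = seed, n_datasets = length(entries),
                   datasets = entries)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
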