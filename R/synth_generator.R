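# Seeded synthetic scan-series generator: Gaussian m/z clouds with
# controlled per-scan intensity fluctuation, and calibration scenarios with
# a concentration-dependent variance law.

#' Specify one emitting species
#'
#' One species (ion, tautomer) emits one centroid per scan: m/z drawn from
#' `Normal(mean_mz, mz_sd)` and intensity either Gaussian around
#' `weight * base_intensity` (sd `noise_sd`, clamped at 0 counts) or Poisson
#' with that mean.
#'
#' @param mean_mz centre of the m/z cloud (Thomson)
#' @param mz_sd m/z spread (Thomson, >= 0)
#' @param base_intensity mean intensity (counts, > 0)
#' @param noise `"gaussian"` or `"poisson"`
#' @param noise_sd Gaussian intensity sd (counts); ignored for Poisson
#' @param weight mixture fraction scaling the mean intensity
#' @return object of class `species_spec`
#' @export
species_spec <- function(mean_mz, mz_sd, base_intensity,
                         noise = c("gaussian", "poisson"),
                         noise_sd = 0, weight = 1) {
  noise <- match.arg(noise)
  if (!is_number(mean_mz) || mean_mz <= 0) stop_validation("'mean_mz' must be > 0")
  if (!is_number(mz_sd) || mz_sd < 0) stop_validation("'mz_sd' must be >= 0")
  if (!is_number(base_intensity) || base_intensity <= 0) {
    stop_validation("'base_intensity' must be > 0")
  }
  if (!is_number(noise_sd) || noise_sd < 0) stop_validation("'noise_sd' must be >= 0")
  if (!is_number(weight) || weight <= 0 || weight > 1) {
    stop_validation("'weight' must lie in (0, 1]")
  }
  structure(list(mean_mz = mean_mz, mz_sd = mz_sd,
                 base_intensity = base_intensity, noise = noise,
                 noise_sd = noise_sd, weight = weight),
            class = "species_spec")
}

#' Simulate a scan series
#'
#' Deterministic for a fixed seed: every scan records one centroid per
#' species. Negative Gaussian intensity draws are clamped at 0 counts.
#'
#' @param species list of [species_spec()]; mixture weights should sum to 1
#'   when the species model one tautomer mixture
#' @param n_scans number of scans (>= 2)
#' @param dt scan interval (minutes), default 0.01
#' @param seed integer seed
#' @param segment_label segment identifier for the result
#' @return a [scan_series()]
#' @export
#' @examples
#' ser <- simulate_srm(list(species_spec(212.21, 0.02, 1000, noise_sd = 30)),
#'                     n_scans = 50, seed = 7)
simulate_srm <- function(species, n_scans, dt = 0.01, seed = 1L,
                         segment_label = "SIM_SEG_1") {
  if (inherits(species, "species_spec")) species <- list(species)
  if (!is.list(species) || length(species) == 0L ||
      !all(vapply(species, inherits, logical(1L), "species_spec"))) {
    stop_validation("'species' must be a list of species_spec objects")
  }
  if (!is_count(n_scans, min = 2)) stop_validation("'n_scans' must be an integer >= 2")
  if (!is_number(dt) || dt <= 0) stop_validation("'dt' must be > 0")

  peaks <- with_seed(seed, {
    rows <- lapply(seq_along(species), function(si) {
      sp <- species[[si]]
      mz <- rnorm(n_scans, sp$mean_mz, sp$mz_sd)
      mean_int <- sp$weight * sp$base_intensity
      intensity <- if (sp$noise == "poisson") {
        rpois(n_scans, mean_int)
      } else {
        pmax(rnorm(n_scans, mean_int, sp$noise_sd), 0)
      }
      data.frame(scan = seq_len(n_scans) - 1L,
                 time_min = (seq_len(n_scans) - 1L) * dt,
                 mz = mz, intensity = intensity)
    })
    do.call(rbind, rows)
  })
  scan_series(peaks, segment_label = segment_label,
              metadata = list(mode = "SRM"))
}

#' Specify a calibration scenario
#'
#' Emulates a dilution series measured in SRM mode. Per concentration level
#' `c`, scan intensities are drawn around a mean that grows linearly with
#' concentration, with a log-linear variance law
#' `ln var = var_a + var_b * c` so that `ln[D''_SD]` is linear in
#' concentration by construction; `law_noise_sd` adds a lognormal
#' run-to-run perturbation to each level's variance (relative noise on the
#' variance). A `power` variance law `var = exp(var_a) * c^var_b` is
#' selectable instead.
#'
#' @param concentrations concentration grid (ng/mL), default the biocide
#'   calibration grid 2-80 ng/mL
#' @param var_a,var_b variance-law coefficients (defaults: `var_a = 9`,
#'   `var_b = 0.08` per ng/mL, spanning about 2.7 decades of variance over
#'   the default grid)
#' @param law `"log_linear"` (default) or `"power"`
#' @param law_noise_sd lognormal sd of the per-level variance perturbation
#'   (default 0.05, i.e. 5 percent relative noise)
#' @param scans_per_level scans per concentration level (default 100)
#' @param intensity_per_conc mean-intensity slope (counts per ng/mL)
#' @param intensity_offset mean-intensity intercept (counts)
#' @param intensity_level_noise_sd lognormal sd of a per-level multiplicative
#'   perturbation of the mean intensity (matrix/injection variability)
#' @param mean_mz,mz_sd m/z cloud of the monitored fragment
#' @param dt scan interval (minutes)
#' @param seed integer seed
#' @return object of class `calibration_scenario`
#' @export
calibration_scenario <- function(concentrations = c(2, 6, 10, 20, 40, 80),
                                 var_a = 9, var_b = 0.08,
                                 law = c("log_linear", "power"),
                                 law_noise_sd = 0.05,
                                 scans_per_level = 100L,
                                 intensity_per_conc = 200,
                                 intensity_offset = 1000,
                                 intensity_level_noise_sd = 0,
                                 mean_mz = 212.209, mz_sd = 0.02,
                                 dt = 0.01, seed = 1L) {
  law <- match.arg(law)
  check_numeric_vector(concentrations, "concentrations")
  if (any(concentrations <= 0)) stop_validation("concentrations must be > 0")
  if (!is_count(scans_per_level, min = 2)) {
    stop_validation("'scans_per_level' must be an integer >= 2")
  }
  if (!is_number(law_noise_sd) || law_noise_sd < 0) {
    stop_validation("'law_noise_sd' must be >= 0")
  }
  structure(list(concentrations = concentrations, var_a = var_a,
                 var_b = var_b, law = law, law_noise_sd = law_noise_sd,
                 scans_per_level = as.integer(scans_per_level),
                 intensity_per_conc = intensity_per_conc,
                 intensity_offset = intensity_offset,
                 intensity_level_noise_sd = intensity_level_noise_sd,
                 mean_mz = mean_mz, mz_sd = mz_sd, dt = dt,
                 seed = as.integer(seed)),
            class = "calibration_scenario")
}

scenario_variance <- function(scenario, conc) {
  if (scenario$law == "log_linear") {
    exp(scenario$var_a + scenario$var_b * conc)
  } else {
    exp(scenario$var_a) * conc^scenario$var_b
  }
}

#' Simulate a calibration dilution series
#'
#' @param scenario a [calibration_scenario()]
#' @return named list (names = concentrations) of [scan_series()]
#' @export
#' @examples
#' sims <- simulate_calibration(calibration_scenario(scans_per_level = 50))
#' names(sims)
simulate_calibration <- function(scenario) {
  if (!inherits(scenario, "calibration_scenario")) {
    stop_validation("'scenario' must be a calibration_scenario")
  }
  with_seed(scenario$seed, {
    out <- lapply(seq_along(scenario$concentrations), function(i) {
      conc <- scenario$concentrations[i]
      v <- scenario_variance(scenario, conc)
      if (scenario$law_noise_sd > 0) {
        v <- v * exp(rnorm(1L, 0, scenario$law_noise_sd))
      }
      base <- scenario$intensity_offset + scenario$intensity_per_conc * conc
      if (scenario$intensity_level_noise_sd > 0) {
        base <- base * exp(rnorm(1L, 0, scenario$intensity_level_noise_sd))
      }
      n <- scenario$scans_per_level
      peaks <- data.frame(
        scan = seq_len(n) - 1L,
        time_min = (seq_len(n) - 1L) * scenario$dt,
        mz = rnorm(n, scenario$mean_mz, scenario$mz_sd),
        intensity = pmax(rnorm(n, base, sqrt(v)), 0)
      )
      scan_series(peaks,
                  segment_label = sprintf("CAL_c%g", conc),
                  metadata = list(mode = "SRM"))
    })
    names(out) <- as.character(scenario$concentrations)
    out
  })
}

#' Run the full diffusion-parameter calibration pipeline on simulated data
#'
#' Convenience wrapper: simulate the dilution series, extract the measurand
#' window from every level, compute `D''_SD,tot` over a single span covering
#' the level, and regress per [calibrate()].
#'
#' @param scenario a [calibration_scenario()]
#' @param window a [measurand_window()]; default centred on the scenario's
#'   `mean_mz` with tolerance 0.1 Th
#' @param transform passed to [calibrate()]
#' @return list with `model` (a [calibrate()] result), `concentrations` and
#'   `d_second_tot` per level
#' @export
calibration_pipeline <- function(scenario, window = NULL,
                                 transform = c("log_e", "identity")) {
  transform <- match.arg(transform)
  sims <- simulate_calibration(scenario)
  if (is.null(window)) {
    window <- measurand_window(scenario$mean_mz, 0.1)
  }
  d <- vapply(sims, function(ser) {
    iser <- extract_window(ser, window)
    spans <- span_spec("explicit", boundaries = list(c(1L, nrow(iser))))
    d_sd_second(iser, spans)$d_second_tot
  }, numeric(1L))
  list(model = calibrate(scenario$concentrations, unname(d), transform),
       concentrations = scenario$concentrations,
       d_second_tot = unname(d))
}
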