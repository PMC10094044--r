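# Quantum-chemical diffusion parameter from ground-state/transition-state
# vibrational wavenumbers and an activation enthalpy, plus the structure
# assignment correlating it with the experimental D''_SD.

# gas constant per supported activation-enthalpy unit
R_GAS <- c("hartree" = 3.1668116e-6,   # hartree / K
           "kJ/mol" = 8.314462618e-3)  # kJ / (mol K)

HARTREE_PER_KJ_MOL <- 1 / 2625.4996394799  # CODATA: 1 Eh = 2625.49964 kJ/mol

#' Convert kJ/mol to hartree
#' @param x energy in kJ/mol
#' @return energy in hartree (atomic units)
#' @export
#' @examples
#' kj_per_mol_to_hartree(1.5)  # ~ 5.71e-4 a.u.
kj_per_mol_to_hartree <- function(x) x * HARTREE_PER_KJ_MOL

#' Convert hartree to kJ/mol
#' @param x energy in hartree
#' @return energy in kJ/mol
#' @export
hartree_to_kj_per_mol <- function(x) x / HARTREE_PER_KJ_MOL

#' Vibrational model of one MS ion
#'
#' Bundles the ground-state and transition-state vibrational wavenumbers and
#' the activation enthalpy used to evaluate the quantum-chemical diffusion
#' parameter. The transition-state list must be exactly one mode shorter
#' than the ground-state list (the reaction coordinate is removed); imaginary
#' modes must be excluded by the caller, and non-positive wavenumbers are
#' rejected rather than dropped.
#'
#' @param label ion label, e.g. `"152_a"`
#' @param gs_wavenumbers ground-state wavenumbers (cm^-1, all > 0)
#' @param ts_wavenumbers transition-state wavenumbers (cm^-1, all > 0),
#'   length `length(gs_wavenumbers) - 1`
#' @param activation_enthalpy activation enthalpy in `unit` (default 0)
#' @param unit `"hartree"` (default) or `"kJ/mol"`; fixes the matching gas
#'   constant
#' @param temperature kelvin (> 0), default 298.15
#' @return object of class `qc_ion_model`
#' @export
qc_ion_model <- function(label, gs_wavenumbers, ts_wavenumbers,
                         activation_enthalpy = 0,
                         unit = c("hartree", "kJ/mol"),
                         temperature = 298.15) {
  unit <- match.arg(unit)
  check_numeric_vector(gs_wavenumbers, "gs_wavenumbers")
  check_numeric_vector(ts_wavenumbers, "ts_wavenumbers")
  if (any(gs_wavenumbers <= 0) || any(ts_wavenumbers <= 0)) {
    stop_validation("all wavenumbers must be > 0 (remove imaginary modes explicitly)")
  }
  if (length(ts_wavenumbers) != length(gs_wavenumbers) - 1L) {
    stop_validation("need length(ts) == length(gs) - 1 (got %d and %d)",
                    length(ts_wavenumbers), length(gs_wavenumbers))
  }
  if (!is_number(activation_enthalpy)) {
    stop_validation("'activation_enthalpy' must be a finite number")
  }
  if (!is_number(temperature) || temperature <= 0) {
    stop_validation("'temperature' must be > 0")
  }
  structure(list(label = as.character(label),
                 gs_wavenumbers = as.numeric(gs_wavenumbers),
                 ts_wavenumbers = as.numeric(ts_wavenumbers),
                 activation_enthalpy = activation_enthalpy,
                 unit = unit, temperature = temperature),
            class = "qc_ion_model")
}

#' Quantum-chemical diffusion parameter
#'
#' Evaluates the frequency-product/Arrhenius expression
#' `D_QC = (prod nu_gs / prod nu_ts) * exp(-dH / (R T))` entirely in log
#' space, `exp(sum(log nu_gs) - sum(log nu_ts) - dH / (R T))`, so that the
#' frequency products of large ions cannot overflow. The gas constant is
#' chosen to match the activation-enthalpy unit of the model.
#'
#' @param model a [qc_ion_model()]
#' @return the D_QC value (dimension follows the wavenumber unit; one
#'   uncancelled cm^-1 factor remains because the ground state has one more
#'   mode)
#' @export
#' @examples
#' d_qc(qc_ion_model("toy", c(100, 200, 300), c(150, 250)))  # 160
d_qc <- function(model) {
  if (!inherits(model, "qc_ion_model")) {
    stop_validation("'model' must be a qc_ion_model")
  }
  R <- R_GAS[[model$unit]]
  exp(sum(log(model$gs_wavenumbers)) - sum(log(model$ts_wavenumbers)) -
        model$activation_enthalpy / (R * model$temperature))
}

#' Absolute difference between two D_QC values
#'
#' The structure-discrimination measure contrasted with total-energy
#' differences: near-degenerate ions in energy can still differ markedly in
#' their diffusion parameters.
#'
#' @param a,b finite D_QC values
#' @return `|a - b|`
#' @export
delta_d_qc <- function(a, b) {
  if (!is_number(a) || !is_number(b)) stop_validation("inputs must be finite numbers")
  abs(a - b)
}

#' Read wavenumber lists from text files
#'
#' Accepts either one wavenumber per line, or a two-column CSV with header
#' `state,wavenumber` where `state` is `gs` or `ts`.
#'
#' @param path input file
#' @return for the one-column format, a numeric vector; for the two-column
#'   format, a list with `gs` and `ts`
#' @export
read_wavenumbers <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (grepl("^\\s*state\\s*,\\s*wavenumber\\s*$", first)) {
    df <- read.csv(path)
    if (!all(df$state %in% c("gs", "ts"))) {
      stop_parse("'state' column must contain only 'gs' and 'ts'")
    }
    return(list(gs = as.numeric(df$wavenumber[df$state == "gs"]),
                ts = as.numeric(df$wavenumber[df$state == "ts"])))
  }
  x <- suppressWarnings(as.numeric(readLines(path)))
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop_parse("no wavenumbers found in %s", path)
  x
}

#' Correlate experimental and quantum-chemical diffusion parameters
#'
#' Pearson correlation and fitted line of `D''_SD = f(D_QC)` over a set of
#' ions; a |r| near 1 is the structure-confirmation criterion, since only
#' the correct candidate structures should place every ion on one line.
#'
#' @param d_second experimental `D''_SD` values (cm^2 s^-1), >= 3 ions
#' @param d_qc candidate `D_QC` values, same length
#' @param labels optional ion labels
#' @return object of class `structure_correlation`: list with `ion_labels`,
#'   `d_second_values`, `d_qc_values`, `pearson_r`, `slope`, `slope_sd`,
#'   `intercept`, `intercept_sd`
#' @export
correlate_structure <- function(d_second, d_qc, labels = NULL) {
  check_numeric_vector(d_second, "d_second", min_len = 3L)
  if (!is.numeric(d_qc) || length(d_qc) != length(d_second)) {
    stop_validation("'d_qc' must be numeric of the same length as 'd_second'")
  }
  if (is.null(labels)) labels <- sprintf("ion%d", seq_along(d_second))
  if (length(labels) != length(d_second)) {
    stop_validation("'labels' must match the number of ions")
  }
  fit <- lm(d_second ~ d_qc)
  # exactly proportional inputs (the ideal assignment) are legitimate;
  # silence the "essentially perfect fit" warning from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(ion_labels = as.character(labels),
                 d_second_values = d_second, d_qc_values = d_qc,
                 pearson_r = pearson_r(d_qc, d_second),
                 slope = sm[2L, 1L], slope_sd = sm[2L, 2L],
                 intercept = sm[1L, 1L], intercept_sd = sm[1L, 2L]),
            class = "structure_correlation")
}

#' @export
print.structure_correlation <- function(x, ...) {
  cat(sprintf("<structure_correlation> %d ions, |r| = %.6f, D'' = %.4g + %.4g * D_QC\n",
              length(x$ion_labels), abs(x$pearson_r), x$intercept, x$slope))
  invisible(x)
}

#' Assign candidate structures by maximising |r|
#'
#' Exhaustive search over all combinations of candidate structures (one per
#' ion) for the combination whose `D_QC` values correlate best (largest |r|)
#' with the experimental `D''_SD` values. Ties keep the first-listed
#' combination (enumeration varies the first ion's candidate fastest), so
#' the result is deterministic.
#'
#' @param d_second experimental `D''_SD` values, one per ion (>= 3 ions)
#' @param candidates named list, one entry per ion, each either a numeric
#'   vector of candidate `D_QC` values (optionally named by structure) or a
#'   list of [qc_ion_model()] objects
#' @param cap refuse searches whose candidate product space exceeds this
#'   size (default 1e6)
#' @return list with `assignment` (data frame: ion, candidate, d_qc) and
#'   `correlation` (a [correlate_structure()] result for the best
#'   combination)
#' @export
assign_structures <- function(d_second, candidates, cap = 1e6) {
  check_numeric_vector(d_second, "d_second", min_len = 3L)
  if (!is.list(candidates) || length(candidates) != length(d_second)) {
    stop_validation("'candidates' must be a list with one entry per ion")
  }
  ions <- names(candidates)
  if (is.null(ions)) ions <- sprintf("ion%d", seq_along(candidates))

  cand <- lapply(seq_along(candidates), function(i) {
    ci <- candidates[[i]]
    if (length(ci) == 0L) {
      stop_validation("ion '%s' has no candidate structures", ions[i])
    }
    if (is.list(ci) && all(vapply(ci, inherits, logical(1L), "qc_ion_model"))) {
      vals <- vapply(ci, d_qc, numeric(1L))
      names(vals) <- vapply(ci, `[[`, character(1L), "label")
      vals
    } else if (is.numeric(ci)) {
      if (is.null(names(ci))) names(ci) <- sprintf("%s_%d", ions[i], seq_along(ci))
      ci
    } else {
      stop_validation("candidates for ion '%s' must be numeric or qc_ion_model objects",
                      ions[i])
    }
  })

  sizes <- lengths(cand)
  if (prod(sizes) > cap) {
    stop_validation(paste0(
      "candidate product space (%.3g combinations) exceeds the cap (%.3g); ",
      "prune candidates per ion or raise 'cap'"), prod(sizes), cap)
  }

  grid <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  best_r <- -Inf
  best_idx <- NULL
  for (row in seq_len(nrow(grid))) {
    vals <- vapply(seq_along(cand), function(i) cand[[i]][[grid[row, i]]],
                   numeric(1L))
    r <- tryCatch(abs(pearson_r(vals, d_second)), sdms_error = function(e) NA_real_)
    if (!is.na(r) && r > best_r) {
      best_r <- r
      best_idx <- as.integer(grid[row, ])
    }
  }
  if (is.null(best_idx)) {
    stop_degenerate("no candidate combination yields a defined correlation")
  }
  chosen <- vapply(seq_along(cand), function(i) cand[[i]][[best_idx[i]]], numeric(1L))
  chosen_names <- vapply(seq_along(cand), function(i) names(cand[[i]])[best_idx[i]],
                         character(1L))
  list(assignment = data.frame(ion = ions, candidate = chosen_names, d_qc = chosen),
       correlation = correlate_structure(d_second, chosen, labels = ions))
}
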