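# Independent oracles and small fixture builders used across the suite.

# two-pass population variance (oracle for the raw-moment implementation)
brute_variance <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / length(x)
}

# brute-force window extraction over a peak table: for each scan take the
# most intense in-window peak (ties: proximity to centre, then lower m/z)
brute_extract <- function(peaks, center, tol) {
  out <- lapply(split(peaks, peaks$scan), function(df) {
    df <- df[abs(df$mz - center) <= tol, , drop = FALSE]
    if (nrow(df) == 0L) return(data.frame(intensity = NA_real_, mz = NA_real_))
    best <- df[order(-df$intensity, abs(df$mz - center), df$mz), ][1L, ]
    data.frame(intensity = best$intensity, mz = best$mz)
  })
  do.call(rbind, out)
}

# direct-product evaluation of the quantum-chemical diffusion parameter
# (overflow-prone; valid for small inputs only)
brute_d_qc <- function(gs, ts, dh = 0, R = 3.1668116e-6, temp = 298.15) {
  prod(gs) / prod(ts) * exp(-dh / (R * temp))
}

# enumeration oracle for isotope patterns: every atom independently takes
# one of its element's isotopes; masses summed, abundances multiplied,
# aggregated into 0.01 Da bins. Feasible for a handful of atoms only.
enum_isotope_pattern <- function(formula) {
  comp <- sdms::parse_formula(formula)
  tabs <- list(
    H  = data.frame(mass = c(1.00782503207, 2.0141017778), ab = c(0.999885, 0.000115)),
    C  = data.frame(mass = c(12, 13.0033548378), ab = c(0.9893, 0.0107)),
    N  = data.frame(mass = c(14.0030740048, 15.0001088982), ab = c(0.99636, 0.00364)),
    O  = data.frame(mass = c(15.9949146196, 16.99913170, 17.9991610),
                    ab = c(0.99757, 0.00038, 0.00205)),
    Cl = data.frame(mass = c(34.96885268, 36.96590259), ab = c(0.7576, 0.2424))
  )
  atoms <- rep(names(comp$counts), comp$counts)
  stopifnot(all(atoms %in% names(tabs)), length(atoms) <= 8L)
  grid <- expand.grid(lapply(atoms, function(a) seq_len(nrow(tabs[[a]]))))
  mass <- apply(grid, 1L, function(idx) {
    sum(vapply(seq_along(atoms), function(i) tabs[[atoms[i]]]$mass[idx[i]], 0))
  })
  ab <- apply(grid, 1L, function(idx) {
    prod(vapply(seq_along(atoms), function(i) tabs[[atoms[i]]]$ab[idx[i]], 0))
  })
  key <- round(mass / 0.01)
  agg_ab <- tapply(ab, key, sum)
  agg_m <- tapply(mass * ab, key, sum) / agg_ab
  ord <- order(agg_m)
  data.frame(mz = as.numeric(agg_m[ord]), ab = as.numeric(agg_ab[ord]))
}

# deterministic peak table for I/O tests
random_scan_table <- function(n_scans, peaks_per_scan, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_scans) - 1L, function(s) {
    data.frame(scan = s,
               time_min = s * 0.01,
               mz = sort(runif(peaks_per_scan, 100, 500)),
               intensity = runif(peaks_per_scan, 0, 1e5))
  }))
}
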