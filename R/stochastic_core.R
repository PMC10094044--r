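# Stochastic-dynamic diffusion parameters over short spans of scan time,
# the SineSqr temporal fit, and the collision-energy intensity relation.

# Proportionality constants of the two diffusion-parameter forms, applied
# verbatim to intensities in counts; K2 = 2 * K1 bridges the two forms.
K1_DSD <- 1.3194e-17
K2_DSD <- 2.6388e-17
stopifnot(isTRUE(all.equal(K2_DSD, 2 * K1_DSD)))

#' Constants of the stochastic-dynamic diffusion parameters
#'
#' Returns the proportionality constants (cm^2 s^-1 per squared count)
#' relating intensity fluctuation statistics to the diffusion parameters:
#' `K1` for the SineSqr-amplitude form D'_SD and `K2 = 2 * K1` for the
#' variance form D''_SD.
#'
#' @return named numeric vector `c(K1 = 1.3194e-17, K2 = 2.6388e-17)`
#' @export
dsd_constants <- function() c(K1 = K1_DSD, K2 = K2_DSD)

#' Population variance of an intensity sequence
#'
#' Raw-moment (denominator n) variance `mean(I^2) - mean(I)^2`, the
#' fluctuation statistic of the D''_SD parameter; tiny negative rounding
#' results are clamped at zero.
#'
#' @param values numeric vector, length >= 1
#' @return population variance (counts^2)
#' @export
#' @examples
#' population_variance(c(0, 2))      # 1
#' population_variance(c(1, 2, 3, 4)) # 1.25
population_variance <- function(values) {
  check_numeric_vector(values, "values")
  max(mean(values^2) - mean(values)^2, 0)
}

#' Specify spans of scan time
#'
#' Spans are the short, non-overlapping stretches of consecutive scans over
#' which fluctuation statistics are computed. `fixed_count` cuts the series
#' into consecutive blocks of `span_length` scans (a trailing remainder of a
#' single scan is dropped); `explicit` takes user boundaries, e.g. to follow
#' acquisition-method segments. Boundaries address 1-based positions within
#' the intensity series.
#'
#' @param mode `"fixed_count"` or `"explicit"`
#' @param span_length scans per span (integer >= 2), `fixed_count` mode
#' @param boundaries list of `c(start, end)` pairs (or a 2-column matrix),
#'   `explicit` mode; spans must not overlap and must each cover >= 2 scans
#' @return object of class `span_spec`
#' @export
span_spec <- function(mode = c("fixed_count", "explicit"), span_length = 5L,
                      boundaries = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed_count") {
    if (!is_count(span_length, min = 2)) {
      stop_validation("'span_length' must be an integer >= 2")
    }
    boundaries <- NULL
  } else {
    if (is.matrix(boundaries)) {
      boundaries <- lapply(seq_len(nrow(boundaries)), function(i) boundaries[i, ])
    }
    if (!is.list(boundaries) || length(boundaries) == 0L) {
      stop_validation("'boundaries' must be a non-empty list of c(start, end) pairs")
    }
    b <- do.call(rbind, boundaries)
    if (ncol(b) != 2L || any(b != trunc(b)) || any(b[, 1L] < 1)) {
      stop_validation("each boundary must be a pair of positive integers")
    }
    if (any(b[, 2L] - b[, 1L] + 1 < 2)) {
      stop_validation("each span must cover at least 2 scans")
    }
    b <- b[order(b[, 1L]), , drop = FALSE]
    if (nrow(b) > 1L && any(b[-nrow(b), 2L] >= b[-1L, 1L])) {
      stop_validation("spans must not overlap")
    }
    boundaries <- b
  }
  structure(list(mode = mode, span_length = as.integer(span_length),
                 boundaries = boundaries),
            class = "span_spec")
}

resolve_spans <- function(spec, n) {
  stopifnot(inherits(spec, "span_spec"))
  if (spec$mode == "fixed_count") {
    start <- seq(1L, n, by = spec$span_length)
    end <- pmin(start + spec$span_length - 1L, n)
    keep <- (end - start + 1L) >= 2L
    start <- start[keep]; end <- end[keep]
    if (length(start) == 0L) {
      stop_validation("series too short (%d scans) for spans of >= 2 scans", n)
    }
  } else {
    start <- spec$boundaries[, 1L]
    end <- spec$boundaries[, 2L]
    if (any(end > n)) {
      stop_validation("span [%d, %d] lies outside the series (n = %d)",
                      start[which(end > n)[1L]], end[which(end > n)[1L]], n)
    }
  }
  data.frame(start = start, end = end)
}

#' Variance-form diffusion parameter D''_SD over spans of scan time
#'
#' For each span, `D''_SD,i = K2 * (mean(I^2) - mean(I)^2)` with
#' `K2 = 2.6388e-17`; the total is the sum over spans, so the parameter is
#' additive over any partition of the series.
#'
#' @param series an [intensity_series()]
#' @param spans a [span_spec()]; default: consecutive spans of 5 scans
#' @return object of class `diffusion_total`: list with `per_span` (data
#'   frame: start, end, n, mean_I, var_I, d_second), `d_second_tot`
#'   (cm^2 s^-1) and `label`
#' @export
#' @examples
#' ser <- intensity_series(times = (0:9) / 100, intensities = rep(c(0, 2), 5))
#' d_sd_second(ser, span_spec(span_length = 10))$d_second_tot  # K2 * 1
d_sd_second <- function(series, spans = span_spec()) {
  stopifnot(inherits(series, "intensity_series"))
  sp <- resolve_spans(spans, nrow(series))
  per <- lapply(seq_len(nrow(sp)), function(k) {
    v <- series$intensity[sp$start[k]:sp$end[k]]
    data.frame(start = sp$start[k], end = sp$end[k], n = length(v),
               mean_I = mean(v), var_I = population_variance(v))
  })
  per <- do.call(rbind, per)
  per$d_second <- K2_DSD * per$var_I
  structure(list(per_span = per,
                 d_second_tot = sum(per$d_second),
                 d_first_tot = NA_real_,
                 label = attr(series, "label")),
            class = "diffusion_total")
}

#' @export
print.diffusion_total <- function(x, ...) {
  cat(sprintf("<diffusion_total> '%s': %d spans, D''_tot = %.6g cm^2/s",
              x$label, nrow(x$per_span), x$d_second_tot))
  if (!is.na(x$d_first_tot)) cat(sprintf(", D'_tot = %.6g cm^2/s", x$d_first_tot))
  cat("\n")
  invisible(x)
}

#' Fit the SineSqr temporal model
#'
#' Least-squares fit of `y = y0 + A * sin(pi * (x - xc) / w)^2`, the model
#' used for squared-deviation traces `(I - <I>)^2 = f(t)` and for the
#' collision-energy profiles. A seeded multi-start schedule (10 restarts of
#' Levenberg-Marquardt) makes the fit deterministic; a negative fitted
#' amplitude is folded into the phase so that `amplitude_A >= 0`.
#'
#' @param x abscissa values (>= 4 distinct points)
#' @param y ordinate values, same length
#' @param seed integer seed for the multi-start schedule
#' @param n_starts number of restarts
#' @return object of class `sinesqr_fit`: list with `amplitude_A`,
#'   `center_xc`, `width_w`, `offset_y0`, `rss` and the logical `degenerate`
#'   (TRUE for a constant ordinate, where `A = 0` and `y0 = mean(y)`)
#' @export
fit_sinesqr <- function(x, y, seed = 1L, n_starts = 10L) {
  check_numeric_vector(x, "x", min_len = 4L)
  if (!is.numeric(y) || length(y) != length(x) || any(!is.finite(y))) {
    stop_validation("'y' must be finite numeric of the same length as 'x'")
  }
  span <- diff(range(x))
  if (span <= 0) stop_validation("'x' must contain distinct values")

  if (diff(range(y)) == 0) {
    return(structure(list(amplitude_A = 0, center_xc = x[1L], width_w = span,
                          offset_y0 = y[1L], rss = 0, degenerate = TRUE),
                     class = "sinesqr_fit"))
  }

  a0 <- diff(range(y)); xc0 <- x[which.max(y)]; w0 <- 2 * span; y00 <- min(y)
  starts <- with_seed(seed, {
    rand <- data.frame(
      A  = a0 * runif(n_starts - 1L, 0.5, 1.5),
      xc = runif(n_starts - 1L, min(x), max(x)),
      w  = span * runif(n_starts - 1L, 0.25, 3),
      y0 = y00 + a0 * runif(n_starts - 1L, -0.25, 0.25)
    )
    rbind(data.frame(A = a0, xc = xc0, w = w0, y0 = y00), rand)
  })

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    # parameters are bounded to the data scale: an unbounded width lets the
    # model degenerate into a locally-quadratic ramp with runaway amplitude
    rng <- diff(range(y))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ y0 + A * sin(pi * (x - xc) / w)^2,
        start = as.list(starts[i, ]),
        lower = c(A = -10 * rng, xc = min(x) - 4 * span, w = span * 1e-3,
                  y0 = min(y) - 2 * rng),
        upper = c(A = 10 * rng, xc = max(x) + 4 * span, w = 4 * span,
                  y0 = max(y) + 2 * rng),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- c(as.list(coef(fit)), list(rss = rss))
    }
  }
  if (is.null(best)) stop_degenerate("SineSqr fit failed from every start")

  A <- best$A; xc <- best$xc; w <- best$w; y0 <- best$y0
  if (A < 0) {  # y0 + A sin^2 == (y0 + A) + (-A) sin^2 shifted by w/2
    y0 <- y0 + A
    A <- -A
    xc <- xc - w / 2
  }
  structure(list(amplitude_A = A, center_xc = xc, width_w = w,
                 offset_y0 = y0, rss = best$rss, degenerate = FALSE),
            class = "sinesqr_fit")
}

#' Evaluate a SineSqr fit
#' @param object a `sinesqr_fit`
#' @param x abscissa values
#' @param ... unused
#' @return fitted ordinate values
#' @export
predict.sinesqr_fit <- function(object, x, ...) {
  object$offset_y0 +
    object$amplitude_A * sin(pi * (x - object$center_xc) / object$width_w)^2
}

#' @export
print.sinesqr_fit <- function(x, ...) {
  cat(sprintf("<sinesqr_fit> A = %.6g, xc = %.6g, w = %.6g, y0 = %.6g, rss = %.3g%s\n",
              x$amplitude_A, x$center_xc, x$width_w, x$offset_y0, x$rss,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Amplitude-form diffusion parameter D'_SD over spans of scan time
#'
#' Within each span the squared-deviation trace `(I - <I>)^2` against scan
#' time is fitted with [fit_sinesqr()], giving the amplitude `A_i`. The span
#' contribution is `D'_SD,i = K1 * A_i * var_I / msd_I` with
#' `K1 = 1.3194e-17`, where `var_I` is the span's population variance and
#' `msd_I` is, by default, the time-average of the fitted SineSqr curve over
#' the span's scan times (a smooth mean-squared-deviation estimate that
#' differs from `var_I` under noise, which is what separates D' from D'').
#' With `denominator = "sample"` the same-sample statistic is used instead,
#' making the ratio exactly 1 and `D'_SD,i = K1 * A_i`.
#'
#' Spans must cover >= 4 scans so the SineSqr fit is determined.
#'
#' @inheritParams d_sd_second
#' @param seed seed for the SineSqr multi-start schedule
#' @param denominator `"fitted"` (default) or `"sample"`
#' @return a `diffusion_total` whose `per_span` additionally carries `A_i`,
#'   `msd_I` and `d_first`, with both `d_first_tot` and `d_second_tot` set
#' @export
d_sd_first <- function(series, spans = span_spec(), seed = 1L,
                       denominator = c("fitted", "sample")) {
  denominator <- match.arg(denominator)
  out <- d_sd_second(series, spans)
  per <- out$per_span
  if (any(per$n < 4L)) {
    stop_validation("D'_SD needs spans of >= 4 scans for the SineSqr fit")
  }
  A <- msd <- d1 <- numeric(nrow(per))
  for (k in seq_len(nrow(per))) {
    idx <- per$start[k]:per$end[k]
    I <- series$intensity[idx]
    t <- series$time_min[idx]
    y <- (I - mean(I))^2
    fit <- fit_sinesqr(t, y, seed = seed)
    A[k] <- fit$amplitude_A
    msd[k] <- if (denominator == "sample") per$var_I[k] else {
      max(mean(predict(fit, t)), 0)
    }
    if (msd[k] > 0) {
      d1[k] <- K1_DSD * A[k] * per$var_I[k] / msd[k]
    } else {
      d1[k] <- 0
      if (A[k] == 0) {
        warning(sprintf("degenerate span [%d, %d]: A = 0 and msd = 0; D'_SD,i set to 0",
                        per$start[k], per$end[k]), call. = FALSE)
      }
    }
  }
  per$A_i <- A
  per$msd_I <- msd
  per$d_first <- d1
  out$per_span <- per
  out$d_first_tot <- sum(d1)
  out
}

#' Correlation between the two diffusion-parameter forms
#'
#' Computes `D'_SD,tot` and `D''_SD,tot` for each series of a family and
#' reports the Pearson correlation and fitted line between them. Close
#' agreement (|r| near 1) reflects the derivation of the variance form from
#' the amplitude form; departures stem from the SineSqr fitting error.
#'
#' @param series_list list of >= 3 [intensity_series()]
#' @inheritParams d_sd_first
#' @return list with `r`, `slope`, `intercept`, and the per-series vectors
#'   `d_first_tot`, `d_second_tot`
#' @export
d_prime_vs_dsecond <- function(series_list, spans = span_spec(), seed = 1L,
                               denominator = c("fitted", "sample")) {
  denominator <- match.arg(denominator)
  if (!is.list(series_list) || length(series_list) < 3L) {
    stop_validation("need at least 3 intensity series")
  }
  tot <- lapply(series_list, d_sd_first, spans = spans, seed = seed,
                denominator = denominator)
  d1 <- vapply(tot, `[[`, numeric(1L), "d_first_tot")
  d2 <- vapply(tot, `[[`, numeric(1L), "d_second_tot")
  r <- pearson_r(d1, d2)
  line <- lm(d2 ~ d1)
  list(r = r, slope = unname(coef(line)[2L]), intercept = unname(coef(line)[1L]),
       d_first_tot = d1, d_second_tot = d2)
}

#' Theoretical mean intensity from the collision-energy relation
#'
#' `<I>_theor = 0.5 * (A_I / A_D) * D''_SD,tot`, where `A_I` and `A_D` are
#' the SineSqr amplitudes of the mean-intensity and diffusion-parameter
#' profiles over collision energy.
#'
#' @param amp_intensity amplitude `A_I` of the `<I> = f(CE)` fit
#' @param amp_diffusion amplitude `A_D` of the `D'' = f(CE)` fit (non-zero)
#' @param d_second_tot `D''_SD,tot` value(s)
#' @return theoretical mean intensity (counts)
#' @export
eq4_intensity <- function(amp_intensity, amp_diffusion, d_second_tot) {
  if (!is_number(amp_diffusion) || amp_diffusion == 0) {
    stop_degenerate("A_D must be non-zero: the intensity relation is undefined")
  }
  0.5 * (amp_intensity / amp_diffusion) * d_second_tot
}

#' Collision-energy profile of diffusion parameter and mean intensity
#'
#' Fits `D''_SD,tot = f(CE)` and `<I> = f(CE)` each with [fit_sinesqr()],
#' takes the two amplitudes `A_D` and `A_I`, computes the theoretical mean
#' intensities via [eq4_intensity()] and reports their Pearson correlation
#' with the experimental means.
#'
#' @param collision_energies collision energies (volts), >= 4 points
#' @param d_second_values `D''_SD,tot` per collision energy (cm^2 s^-1)
#' @param mean_intensities experimental mean intensities per collision energy
#' @param seed seed for the SineSqr multi-start schedule
#' @return object of class `ce_profile`: list with the inputs, `fits`
#'   (`$diffusion`, `$intensity`), `amp_D`, `amp_I`,
#'   `theoretical_intensities` and `r`
#' @export
eq4_profile <- function(collision_energies, d_second_values, mean_intensities,
                        seed = 1L) {
  check_numeric_vector(collision_energies, "collision_energies", min_len = 4L)
  if (length(d_second_values) != length(collision_energies) ||
      length(mean_intensities) != length(collision_energies)) {
    stop_validation("profile vectors must have equal lengths")
  }
  fit_d <- fit_sinesqr(collision_energies, d_second_values, seed = seed)
  fit_i <- fit_sinesqr(collision_energies, mean_intensities, seed = seed)
  if (fit_d$amplitude_A == 0) {
    stop_degenerate("A_D = 0: the collision-energy intensity relation is undefined")
  }
  theor <- eq4_intensity(fit_i$amplitude_A, fit_d$amplitude_A, d_second_values)
  structure(list(collision_energies = collision_energies,
                 d_second_values = d_second_values,
                 mean_intensities = mean_intensities,
                 fits = list(diffusion = fit_d, intensity = fit_i),
                 amp_D = fit_d$amplitude_A, amp_I = fit_i$amplitude_A,
                 theoretical_intensities = theor,
                 r = pearson_r(theor, mean_intensities)),
            class = "ce_profile")
}

#' @export
print.ce_profile <- function(x, ...) {
  cat(sprintf("<ce_profile> %d CE points, A_D = %.4g, A_I = %.4g, |r| = %.5f\n",
              length(x$collision_energies), x$amp_D, x$amp_I, abs(x$r)))
  invisible(x)
}
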