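# Chemometrics: measurand grouping (Shapiro-Wilk / Welch t / ANOVA),
# calibration regression on diffusion parameters, and the classical
# trapezoidal-integration comparator.

#' Shapiro-Wilk normality test
#'
#' Thin, validated wrapper around [stats::shapiro.test()] used to check the
#' normality of per-scan m/z measurands within a candidate group.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-constant
#' @return named list with `W` and `p`
#' @export
shapiro_wilk <- function(values) {
  check_numeric_vector(values, "values")
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop_validation("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", n)
  }
  if (diff(range(values)) == 0) {
    stop_validation("Shapiro-Wilk is undefined for a constant sample")
  }
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant
#' @return the correlation coefficient
#' @export
pearson_r <- function(x, y) {
  check_numeric_vector(x, "x", min_len = 3L)
  if (!is.numeric(y) || length(y) != length(x) || any(!is.finite(y))) {
    stop_validation("'y' must be finite numeric of the same length as 'x'")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_validation("correlation is undefined for a constant input")
  }
  cor(x, y)
}

#' Group m/z measurands into statistically homogeneous subsets
#'
#' Partitions per-scan m/z values into species-level groups (e.g. tautomers
#' of a fragmention observed as overlapping m/z clouds). Candidate groups are
#' formed by splitting the sorted values at empty gaps wider than `gap`; each
#' candidate is then refined by 1-D Gaussian-mixture model selection (EM with
#' BIC over equal/unequal-variance models), which resolves overlapping clouds
#' that leave no empty gap. Groups smaller than 3 are absorbed into the
#' nearest-mean group. Finally all pairs are compared by Welch t-tests and
#' pairs with `p >= alpha` are merged (single linkage, iterated to a
#' fixpoint); one-way ANOVA across the final groups is reported along with a
#' per-group Shapiro-Wilk normality check.
#'
#' @param mz_values per-scan m/z values (Thomson), n >= 6
#' @param alpha significance level in (0, 0.5]
#' @param gap pre-split gap width (Thomson)
#' @param max_components maximum number of mixture components tried per
#'   candidate chunk
#' @return object of class `grouping_report`: list with `groups` (data frame
#'   label, mean_mz, sd_mz, n, shapiro_W, shapiro_p), `membership` (group
#'   label per input value, input order), `pairwise_t`, `pairwise_p`
#'   (matrices), `anova` (`F`, `p`; NA for a single group), `alpha` and
#'   `all_distinct` (TRUE when every pairwise p < alpha)
#' @export
#' @examples
#' set.seed(1)
#' mz <- c(rnorm(40, 212.21, 0.10), rnorm(40, 211.79, 0.15))
#' group_measurands(mz)$groups
group_measurands <- function(mz_values, alpha = 0.05, gap = 0.2,
                             max_components = 5L) {
  check_numeric_vector(mz_values, "mz_values", min_len = 6L)
  if (!is_number(alpha) || alpha <= 0 || alpha > 0.5) {
    stop_validation("'alpha' must lie in (0, 0.5]")
  }
  if (!is_number(gap) || gap <= 0) stop_validation("'gap' must be > 0")

  n <- length(mz_values)
  ord <- order(mz_values)
  sorted <- mz_values[ord]

  # 1. conservative pre-split at empty gaps
  chunk <- cumsum(c(1, as.integer(diff(sorted) > gap)))

  # 2. mixture refinement within each chunk
  member_sorted <- integer(n)
  next_id <- 0L
  for (ch in unique(chunk)) {
    idx <- which(chunk == ch)
    x <- sorted[idx]
    k <- rep(1L, length(idx))
    if (length(idx) >= 6L && diff(range(x)) > 0) {
      gmax <- min(max_components, floor(length(idx) / 3))
      if (gmax >= 2L) {
        fit <- tryCatch(
          Mclust(x, G = 1:gmax, modelNames = c("E", "V"), verbose = FALSE),
          error = function(e) NULL
        )
        if (!is.null(fit)) k <- as.integer(fit$classification)
      }
    }
    member_sorted[idx] <- next_id + k
    next_id <- next_id + max(k)
  }

  # 3. absorb groups with n < 3 into the nearest-mean neighbour
  repeat {
    tab <- table(member_sorted)
    small <- names(tab)[tab < 3L]
    if (length(small) == 0L || length(tab) == 1L) break
    g <- as.integer(small[1L])
    means <- tapply(sorted, member_sorted, mean)
    others <- setdiff(as.integer(names(means)), g)
    tgt <- others[which.min(abs(means[as.character(others)] - means[as.character(g)]))]
    member_sorted[member_sorted == g] <- tgt
  }

  # 4. Welch-t merge to fixpoint (single linkage)
  repeat {
    ids <- sort(unique(member_sorted))
    if (length(ids) == 1L) break
    merged <- FALSE
    best_p <- -Inf; best_pair <- NULL
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in seq((i + 1L), length(ids))) {
        xi <- sorted[member_sorted == ids[i]]
        xj <- sorted[member_sorted == ids[j]]
        p <- welch_p(xi, xj)
        if (p >= alpha && p > best_p) {
          best_p <- p; best_pair <- c(ids[i], ids[j])
        }
      }
    }
    if (!is.null(best_pair)) {
      member_sorted[member_sorted == best_pair[2L]] <- best_pair[1L]
      merged <- TRUE
    }
    if (!merged) break
  }

  # 5. report, groups labelled in ascending mean order
  ids <- sort(unique(member_sorted))
  means <- tapply(sorted, member_sorted, mean)[as.character(ids)]
  ids <- ids[order(means)]
  labels <- sprintf("G%d", seq_along(ids))
  relabel <- setNames(labels, as.character(ids))
  member_sorted <- unname(relabel[as.character(member_sorted)])

  groups <- do.call(rbind, lapply(labels, function(lb) {
    x <- sorted[member_sorted == lb]
    sw <- tryCatch(shapiro_wilk(x), sdms_validation_error = function(e) list(W = NA_real_, p = NA_real_))
    data.frame(label = lb, mean_mz = mean(x), sd_mz = sd(x), n = length(x),
               shapiro_W = sw$W, shapiro_p = sw$p)
  }))

  k <- length(labels)
  tmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        xi <- sorted[member_sorted == labels[i]]
        xj <- sorted[member_sorted == labels[j]]
        ht <- t.test(xi, xj)
        tmat[i, j] <- tmat[j, i] <- unname(ht$statistic)
        pmat[i, j] <- pmat[j, i] <- ht$p.value
      }
    }
  }

  anova_res <- list(F = NA_real_, p = NA_real_)
  if (k > 1L) {
    fit <- aov(sorted ~ factor(member_sorted))
    tabl <- anova(fit)
    anova_res <- list(F = tabl$`F value`[1L], p = tabl$`Pr(>F)`[1L])
  }

  membership <- character(n)
  membership[ord] <- member_sorted

  structure(list(groups = groups,
                 membership = membership,
                 pairwise_t = tmat, pairwise_p = pmat,
                 anova = anova_res, alpha = alpha,
                 all_distinct = k > 1L && all(pmat[upper.tri(pmat)] < alpha)),
            class = "grouping_report")
}

welch_p <- function(x, y) {
  # Welch t-test p-value; zero-variance pairs compare by exact equality
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  tryCatch(t.test(x, y)$p.value, error = function(e) 0)
}

#' @export
print.grouping_report <- function(x, ...) {
  cat(sprintf("<grouping_report> %d group(s) at alpha = %g%s\n",
              nrow(x$groups), x$alpha,
              if (isTRUE(x$all_distinct)) ", all pairwise distinct" else ""))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Calibration regression on diffusion parameters
#'
#' Ordinary least squares of the (optionally log-transformed) diffusion
#' parameter on concentration: the quantification models
#' `ln[D''_SD] = f(conc.)` (transform `"log_e"`) and `D''_SD = f(conc.)`
#' (transform `"identity"`).
#'
#' @param concentrations concentrations (ng/mL), n >= 3
#' @param d_values diffusion parameters (cm^2 s^-1); must be > 0 under
#'   `"log_e"`
#' @param transform `"log_e"` (default) or `"identity"`
#' @return object of class `calibration_model`: list with `transform`,
#'   `slope`, `slope_sd`, `intercept`, `intercept_sd`, `pearson_r`,
#'   `n_points`, `fitted`
#' @export
calibrate <- function(concentrations, d_values,
                      transform = c("log_e", "identity")) {
  transform <- match.arg(transform)
  check_numeric_vector(concentrations, "concentrations", min_len = 3L)
  if (!is.numeric(d_values) || length(d_values) != length(concentrations)) {
    stop_validation("'d_values' must be numeric of the same length as 'concentrations'")
  }
  if (transform == "log_e" && any(d_values <= 0)) {
    stop_validation("log_e transform requires positive D values (offending point %d)",
                    which(d_values <= 0)[1L])
  }
  y <- if (transform == "log_e") log(d_values) else d_values
  fit <- lm(y ~ concentrations)
  # a noiseless calibration is a legitimate input; silence the
  # "essentially perfect fit" warning from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(list(transform = transform,
                 slope = sm[2L, 1L], slope_sd = sm[2L, 2L],
                 intercept = sm[1L, 1L], intercept_sd = sm[1L, 2L],
                 pearson_r = pearson_r(concentrations, y),
                 n_points = length(y),
                 fitted = unname(fitted(fit)),
                 concentration_units = "ng/mL"),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  lhs <- if (x$transform == "log_e") "ln[D''_SD]" else "D''_SD"
  cat(sprintf("<calibration_model> %s = (%.5g +/- %.2g) + (%.5g +/- %.2g) * conc, |r| = %.6f (n = %d)\n",
              lhs, x$intercept, x$intercept_sd, x$slope, x$slope_sd,
              abs(x$pearson_r), x$n_points))
  invisible(x)
}

#' Trapezoidal-integration quantification (classical comparator)
#'
#' The classical peak-area path: optional Savitzky-Golay smoothing, optional
#' endpoint-anchored linear baseline subtraction, then trapezoidal
#' integration of the non-negative residual. Provided as the documented
#' comparator to the diffusion-parameter quantification; the vendor ICIS
#' peak-detection algorithm itself is proprietary and is not reproduced.
#'
#' @param xs strictly increasing abscissa grid (m/z or minutes), >= 5 points
#' @param ys intensities on the grid
#' @param baseline `"linear_endpoints"` or `"none"`
#' @param smoothing `NULL`, or `c(window, polyorder)` with an odd window
#'   greater than the polynomial order
#' @return object of class `tia_result`: list with `area`, `baseline_model`
#'   (intercept/slope or NULL) and `smoothing`
#' @export
#' @examples
#' xs <- seq(-1, 1, length.out = 21)
#' tia_quantify(xs, pmax(1 - abs(xs), 0), baseline = "none")$area  # 1
tia_quantify <- function(xs, ys, baseline = c("linear_endpoints", "none"),
                         smoothing = NULL) {
  baseline <- match.arg(baseline)
  check_numeric_vector(xs, "xs", min_len = 5L)
  if (!is.numeric(ys) || length(ys) != length(xs) || any(!is.finite(ys))) {
    stop_validation("'ys' must be finite numeric of the same length as 'xs'")
  }
  if (any(diff(xs) <= 0)) stop_validation("'xs' must be strictly increasing")

  y <- ys
  if (!is.null(smoothing)) {
    if (length(smoothing) != 2L || !is_count(smoothing[1L], min = 3) ||
        !is_count(smoothing[2L], min = 0)) {
      stop_validation("'smoothing' must be c(window, polyorder)")
    }
    window <- as.integer(smoothing[1L]); polyorder <- as.integer(smoothing[2L])
    if (window %% 2L == 0L) stop_validation("smoothing window must be odd")
    if (window <= polyorder) {
      stop_validation("smoothing window must exceed the polynomial order")
    }
    y <- signal::sgolayfilt(y, p = polyorder, n = window)
  }

  baseline_model <- NULL
  if (baseline == "linear_endpoints") {
    n <- length(xs)
    slope <- (y[n] - y[1L]) / (xs[n] - xs[1L])
    intercept <- y[1L] - slope * xs[1L]
    y <- y - (intercept + slope * xs)
    baseline_model <- c(intercept = intercept, slope = slope)
  }
  y <- pmax(y, 0)
  structure(list(area = pracma::trapz(xs, y),
                 baseline_model = baseline_model,
                 smoothing = smoothing),
            class = "tia_result")
}

#' @export
print.tia_result <- function(x, ...) {
  cat(sprintf("<tia_result> area = %.6g%s%s\n", x$area,
              if (is.null(x$baseline_model)) "" else " (baseline-corrected)",
              if (is.null(x$smoothing)) "" else
                sprintf(", Savitzky-Golay window %d order %d",
                        x$smoothing[1L], x$smoothing[2L])))
  invisible(x)
}
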