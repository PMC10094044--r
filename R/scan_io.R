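# Scan-level I/O: ScanSeries / IntensitySeries containers, the CSV dialect,
# a minimal mzML reader (via mzR), and measurand-window extraction.

#' Construct a scan series
#'
#' A scan series holds the ordered, centroided scans of one acquisition
#' segment as a long table of peaks. Peaks are sorted by scan and then by
#' m/z; rows sharing a scan index are merged into one scan and must agree on
#' the scan time.
#'
#' @param peaks data frame with columns `scan` (non-negative integer),
#'   `time_min` (minutes), `mz` (Thomson) and `intensity` (counts, >= 0).
#'   May have zero rows.
#' @param segment_label non-empty segment identifier, e.g. an acquisition
#'   method segment name.
#' @param metadata named list of optional acquisition metadata; recognised
#'   entries are `mode` (one of `"SRM"`, `"SIM"`, `"CID-MS/MS"`, `"full"`)
#'   and `collision_energy` (volts).
#' @return object of class `scan_series`: the validated peak table with the
#'   segment label and metadata attached as attributes.
#' @seealso [read_scan_table()], [extract_window()]
#' @export
#' @examples
#' peaks <- data.frame(scan = c(0, 0, 1), time_min = c(0, 0, 0.01),
#'                     mz = c(212.21, 211.80, 212.20),
#'                     intensity = c(100, 40, 110))
#' ser <- scan_series(peaks, segment_label = "SEG_1")
#' n_scans(ser)
scan_series <- function(peaks, segment_label = "SEG_1", metadata = list()) {
  required <- c("scan", "time_min", "mz", "intensity")
  if (!is.data.frame(peaks) || !all(required %in% names(peaks))) {
    stop_validation("'peaks' must be a data frame with columns %s",
                    paste(required, collapse = ", "))
  }
  if (!is.character(segment_label) || length(segment_label) != 1L ||
      is.na(segment_label) || !nzchar(segment_label)) {
    stop_validation("'segment_label' must be a non-empty string")
  }
  if (!is.list(metadata)) stop_validation("'metadata' must be a list")
  if (!is.null(metadata$mode) &&
      !metadata$mode %in% c("SRM", "SIM", "CID-MS/MS", "full")) {
    stop_validation("metadata$mode must be one of SRM, SIM, CID-MS/MS, full")
  }
  peaks <- peaks[required]
  if (nrow(peaks) > 0L) {
    for (col in required) {
      if (!is.numeric(peaks[[col]]) || any(!is.finite(peaks[[col]]))) {
        stop_validation("column '%s' must be finite numeric", col)
      }
    }
    if (any(peaks$scan < 0) || any(peaks$scan != trunc(peaks$scan))) {
      stop_validation("scan indices must be non-negative integers")
    }
    if (any(peaks$time_min < 0)) stop_validation("scan times must be non-negative")
    if (any(peaks$intensity < 0)) stop_validation("intensities must be >= 0")
    # one time per scan; merged rows must agree
    tms <- tapply(peaks$time_min, peaks$scan, function(t) diff(range(t)))
    if (any(tms > 0)) {
      stop_validation("conflicting scan times for scan index %s",
                      names(tms)[which(tms > 0)[1L]])
    }
    peaks <- peaks[order(peaks$scan, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    st <- scan_times_from(peaks)
    if (is.unsorted(st$time_min)) {
      stop_validation("scan times must be non-decreasing across scans")
    }
  }
  structure(peaks,
            segment_label = segment_label,
            metadata = metadata,
            class = c("scan_series", "data.frame"))
}

scan_times_from <- function(peaks) {
  idx <- !duplicated(peaks$scan)
  data.frame(scan = peaks$scan[idx], time_min = peaks$time_min[idx])
}

#' Number of scans in a scan series
#' @param series a [scan_series()]
#' @return integer scan count
#' @export
n_scans <- function(series) {
  stopifnot(inherits(series, "scan_series"))
  length(unique(series$scan))
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf("<scan_series> segment '%s': %d scans, %d peaks\n",
              attr(x, "segment_label"), n_scans(x), nrow(x)))
  if (nrow(x) > 0L) {
    cat(sprintf("  time %.4f..%.4f min, m/z %.4f..%.4f\n",
                min(x$time_min), max(x$time_min), min(x$mz), max(x$mz)))
  }
  invisible(x)
}

#' Read scan-level data from CSV or mzML
#'
#' The CSV dialect is a comma-separated table with header
#' `scan,time_min,mz,intensity` (dot decimal separator). The mzML path reads
#' centroided spectra through the `mzR` package; retention times (seconds in
#' mzML) are converted to minutes.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"mzml"`.
#' @param segment_label segment identifier attached to the result; defaults
#'   to the file name without extension.
#' @param metadata optional metadata list, see [scan_series()].
#' @return a [scan_series()]
#' @export
read_scan_table <- function(path, dialect = c("csv", "mzml"),
                            segment_label = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (is.null(segment_label)) {
    segment_label <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "csv") {
    read_scan_csv(path, segment_label, metadata)
  } else {
    read_scan_mzml(path, segment_label, metadata)
  }
}

read_scan_csv <- function(path, segment_label, metadata) {
  header <- readLines(path, n = 1L)
  expected <- "scan,time_min,mz,intensity"
  if (length(header) == 0L || gsub("[[:space:]\"]", "", header) != expected) {
    stop_parse("line 1: expected header '%s', got '%s'", expected,
               if (length(header)) header else "<empty file>")
  }
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  n <- nrow(raw)
  cols <- lapply(raw, function(x) suppressWarnings(as.numeric(x)))
  bad <- if (n) which(Reduce(`|`, lapply(cols, is.na))) else integer()
  if (length(bad)) {
    stop_parse("malformed row at line %d of %s", bad[1L] + 1L, path)
  }
  peaks <- data.frame(scan = cols$scan, time_min = cols$time_min,
                      mz = cols$mz, intensity = cols$intensity)
  scan_series(peaks, segment_label = segment_label, metadata = metadata)
}

read_scan_mzml <- function(path, segment_label, metadata) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop_io("reading mzML requires the 'mzR' package")
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hd <- mzR::header(ms)
  if (nrow(hd) == 0L) stop_validation("mzML file contains no spectra: %s", path)
  if (!is.null(hd$centroided) && any(!hd$centroided, na.rm = TRUE)) {
    stop_validation("mzML file contains profile-mode spectra; centroided data required")
  }
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scan_idx <- if (!is.null(hd$acquisitionNum)) hd$acquisitionNum else seq_len(nrow(hd)) - 1L
  rows <- lapply(seq_len(nrow(hd)), function(i) {
    m <- pk[[i]]
    if (is.null(m) || nrow(m) == 0L) return(NULL)
    data.frame(scan = scan_idx[i], time_min = hd$retentionTime[i] / 60,
               mz = m[, 1L], intensity = m[, 2L])
  })
  peaks <- do.call(rbind, rows)
  if (is.null(peaks)) peaks <- data.frame(scan = numeric(), time_min = numeric(),
                                          mz = numeric(), intensity = numeric())
  scan_series(peaks, segment_label = segment_label, metadata = metadata)
}

#' Write a scan series in the package CSV dialect
#'
#' Rows are ordered deterministically by scan and then m/z; the header is
#' `scan,time_min,mz,intensity`. An empty series produces a header-only file.
#'
#' @param series a [scan_series()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scan_table <- function(series, path) {
  stopifnot(inherits(series, "scan_series"))
  df <- as.data.frame(series)[c("scan", "time_min", "mz", "intensity")]
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Define a measurand window
#'
#' A closed m/z interval `[center_mz - tolerance, center_mz + tolerance]`
#' monitoring one measurand, e.g. the BAC-C12 fragment window
#' 212.209 +/- 0.1 Th.
#'
#' @param center_mz window centre (Thomson)
#' @param tolerance half-width (Thomson, > 0)
#' @param label window label; defaults to `"mz<center>"`
#' @return object of class `measurand_window`
#' @export
measurand_window <- function(center_mz, tolerance, label = NULL) {
  if (!is_number(center_mz)) stop_validation("'center_mz' must be a finite number")
  if (!is_number(tolerance) || tolerance <= 0) {
    stop_validation("'tolerance' must be > 0")
  }
  if (is.null(label)) label <- sprintf("mz%.4f", center_mz)
  structure(list(center_mz = center_mz, tolerance = tolerance, label = label),
            class = "measurand_window")
}

#' Construct an intensity series
#'
#' Per-scan trace of one measurand window: the scan times, the matched
#' intensities and the matched m/z values (`NA` where no peak matched).
#'
#' @param times scan times (minutes), strictly increasing
#' @param intensities counts (>= 0), same length as `times`
#' @param matched_mz matched m/z per scan (`NA` allowed), same length
#' @param label series label
#' @return object of class `intensity_series` (a data frame with columns
#'   `time_min`, `intensity`, `matched_mz`)
#' @export
intensity_series <- function(times, intensities, matched_mz = NULL,
                             label = "series") {
  check_numeric_vector(times, "times")
  if (!is.numeric(intensities) || length(intensities) != length(times)) {
    stop_validation("'intensities' must be numeric of the same length as 'times'")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop_validation("intensities must be finite and >= 0")
  }
  if (is.null(matched_mz)) matched_mz <- rep(NA_real_, length(times))
  if (length(matched_mz) != length(times)) {
    stop_validation("'matched_mz' must have the same length as 'times'")
  }
  if (any(diff(times) <= 0)) stop_validation("times must be strictly increasing")
  structure(data.frame(time_min = times, intensity = intensities,
                       matched_mz = as.numeric(matched_mz)),
            label = label,
            class = c("intensity_series", "data.frame"))
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("<intensity_series> '%s': %d scans, mean intensity %.4g\n",
              attr(x, "label"), nrow(x), mean(x$intensity)))
  invisible(x)
}

#' Extract a per-window intensity series from a scan series
#'
#' For each scan the most intense peak within the window is taken. Ties are
#' broken deterministically: first by proximity to the window centre, then by
#' lower m/z. Under policy `"zero"` scans without an in-window peak
#' contribute intensity 0 with `matched_mz = NA`; under `"skip"` they are
#' omitted.
#'
#' @param series a [scan_series()] with at least one scan
#' @param window a [measurand_window()]
#' @param no_match_policy `"zero"` (default) or `"skip"`
#' @return an [intensity_series()]
#' @export
#' @examples
#' ser <- simulate_srm(list(species_spec(212.21, 0.02, 1000, noise_sd = 30)),
#'                     n_scans = 20, seed = 1)
#' extract_window(ser, measurand_window(212.209, 0.1))
extract_window <- function(series, window, no_match_policy = c("zero", "skip")) {
  stopifnot(inherits(series, "scan_series"))
  if (!inherits(window, "measurand_window")) {
    stop_validation("'window' must be a measurand_window")
  }
  no_match_policy <- match.arg(no_match_policy)
  if (n_scans(series) == 0L) stop_validation("cannot extract from an empty scan series")

  st <- scan_times_from(series)
  lo <- window$center_mz - window$tolerance
  hi <- window$center_mz + window$tolerance
  inwin <- series$mz >= lo & series$mz <= hi
  sub <- as.data.frame(series)[inwin, , drop = FALSE]

  pick <- function(scan_id) {
    rows <- sub[sub$scan == scan_id, , drop = FALSE]
    if (nrow(rows) == 0L) return(c(NA_real_, NA_real_))
    rows <- rows[order(-rows$intensity,
                       abs(rows$mz - window$center_mz),
                       rows$mz), , drop = FALSE]
    c(rows$intensity[1L], rows$mz[1L])
  }
  sel <- vapply(st$scan, pick, numeric(2L))
  intensity <- sel[1L, ]
  mz <- sel[2L, ]

  if (no_match_policy == "zero") {
    intensity[is.na(intensity)] <- 0
  } else {
    keep <- !is.na(intensity)
    st <- st[keep, , drop = FALSE]
    intensity <- intensity[keep]
    mz <- mz[keep]
    if (nrow(st) == 0L) {
      stop_validation("no scan matched window '%s' under policy 'skip'", window$label)
    }
  }
  intensity_series(st$time_min, intensity, mz, label = window$label)
}
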