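test_that("CSV round trip echoes scans and sorts peaks", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scan,time_min,mz,intensity",
               "0,0.00,212.21,100",
               "1,0.01,212.20,110"), path)
  ser <- read_scan_table(path, "csv")
  expect_s3_class(ser, "scan_series")
  expect_equal(n_scans(ser), 2L)
  expect_equal(ser$intensity, c(100, 110))

  # unsorted peaks within a scan come back sorted by m/z
  writeLines(c("scan,time_min,mz,intensity",
               "0,0.00,250.5,10",
               "0,0.00,100.1,20",
               "0,0.00,180.3,30"), path)
  ser <- read_scan_table(path, "csv")
  expect_equal(ser$mz, c(100.1, 180.3, 250.5))
  expect_equal(ser$intensity, c(20, 30, 10))
})

test_that("CSV reader reports malformed rows and bad headers by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scan,time_min,mz,intensity",
               "0,0.00,212.21,100",
               "1,oops,212.20,110"), path)
  expect_error(read_scan_table(path, "csv"), "line 3", class = "sdms_parse_error")

  writeLines(c("scan,time,mz,intensity", "0,0,1,1"), path)
  expect_error(read_scan_table(path, "csv"), "header", class = "sdms_parse_error")

  # non-monotone scan times are a validation error
  writeLines(c("scan,time_min,mz,intensity",
               "0,0.50,212.21,100",
               "1,0.10,212.20,110"), path)
  expect_error(read_scan_table(path, "csv"), "non-decreasing",
               class = "sdms_validation_error")
})

test_that("write_scan_table is deterministic and inverts read_scan_table", {
  path <- withr::local_tempfile(fileext = ".csv")

  empty <- scan_series(data.frame(scan = numeric(), time_min = numeric(),
                                  mz = numeric(), intensity = numeric()))
  write_scan_table(empty, path)
  expect_equal(readLines(path), "scan,time_min,mz,intensity")

  one <- scan_series(data.frame(scan = 0, time_min = 0,
                                mz = c(120.5, 118.2), intensity = c(5, 7)))
  write_scan_table(one, path)
  expect_length(readLines(path), 3L)

  # property: round trip is the identity on values (6 decimals), many seeds
  for (seed in 1:5) {
    tab <- random_scan_table(n_scans = 6L, peaks_per_scan = 4L, seed = seed)
    ser <- scan_series(tab, segment_label = "RT")
    write_scan_table(ser, path)
    back <- read_scan_table(path, "csv", segment_label = "RT")
    expect_equal(round(as.data.frame(back), 6), round(as.data.frame(ser), 6))
  }
})

test_that("extract_window picks the most intense in-window peak with deterministic ties", {
  peaks <- data.frame(scan = c(0, 0, 1, 1), time_min = c(0, 0, 0.01, 0.01),
                      mz = c(212.15, 212.25, 212.18, 212.22),
                      intensity = c(80, 100, 100, 100))
  ser <- scan_series(peaks)
  win <- measurand_window(212.209, 0.1)
  iser <- extract_window(ser, win)
  # scan 0: max rule (100 beats 80); scan 1: tie broken by proximity to centre
  expect_equal(iser$intensity, c(100, 100))
  expect_equal(iser$matched_mz, c(212.25, 212.22))

  # equally intense and equidistant -> lower m/z
  peaks2 <- data.frame(scan = 0, time_min = 0, mz = c(212.1, 212.3),
                       intensity = c(50, 50))
  iser2 <- extract_window(scan_series(peaks2), measurand_window(212.2, 0.15))
  expect_equal(iser2$matched_mz, 212.1)
})

test_that("no-match policies: zero keeps length, skip drops scans", {
  peaks <- data.frame(scan = 0:2, time_min = (0:2) / 100,
                      mz = c(212.21, 300.00, 212.19),
                      intensity = c(10, 20, 30))
  ser <- scan_series(peaks)
  win <- measurand_window(212.2, 0.05)
  zero <- extract_window(ser, win, "zero")
  skip <- extract_window(ser, win, "skip")
  expect_equal(nrow(zero), n_scans(ser))
  expect_lte(nrow(skip), n_scans(ser))
  expect_equal(zero$intensity, c(10, 0, 30))
  expect_true(is.na(zero$matched_mz[2L]))
  expect_equal(skip$intensity, c(10, 30))

  expect_error(extract_window(scan_series(peaks[0, ]), win),
               class = "sdms_validation_error")
})

test_that("extraction targets one cloud of a two-cloud spectrum and matches a brute-force oracle", {
  ser <- simulate_srm(list(species_spec(212.21, 0.03, 1000, noise_sd = 50),
                           species_spec(211.71, 0.03, 800, noise_sd = 50)),
                      n_scans = 60, seed = 42)
  win <- measurand_window(212.21, 0.15)
  iser <- extract_window(ser, win)
  # clouds are 0.5 Th apart with sd 0.03: every matched centroid belongs to
  # the targeted cloud
  expect_true(all(abs(iser$matched_mz - 212.21) <= 0.15, na.rm = TRUE))
  oracle <- brute_extract(as.data.frame(ser), 212.21, 0.15)
  got <- iser$intensity
  want <- oracle$intensity
  want[is.na(want)] <- 0
  expect_equal(got, want)

  # idempotence / permutation invariance: shuffling the peak rows changes nothing
  shuffled <- as.data.frame(ser)
  set.seed(9)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  iser2 <- extract_window(scan_series(shuffled), win)
  expect_equal(as.data.frame(iser2), as.data.frame(iser))
})

test_that("mzML spectra read back identically to the CSV dialect", {
  skip_if_not_installed("mzR")
  ser <- simulate_srm(list(species_spec(212.21, 0.05, 1000, noise_sd = 100),
                           species_spec(211.75, 0.05, 500, noise_sd = 50)),
                      n_scans = 5, seed = 3)
  df <- as.data.frame(ser)
  hdr <- data.frame(
    seqNum = 1:5, acquisitionNum = 0:4, msLevel = 1L, polarity = 1L,
    peaksCount = as.integer(table(df$scan)),
    totIonCurrent = as.numeric(tapply(df$intensity, df$scan, sum)),
    retentionTime = unique(df$time_min) * 60,
    basePeakMZ = 0, basePeakIntensity = 0, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 0, highMZ = 0, precursorScanNum = 0L,
    precursorMZ = 0, precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_, spectrumId = paste0("scan=", 0:4),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
  pk <- lapply(split(df, df$scan), function(d) cbind(mz = d$mz, intensity = d$intensity))
  path <- withr::local_tempfile(fileext = ".mzML")
  mzR::writeMSData(unname(pk), path, header = hdr, outformat = "mzml")

  back <- read_scan_table(path, "mzml", segment_label = "SEG")
  expect_equal(n_scans(back), 5L)
  expect_equal(back$mz, df$mz, tolerance = 1e-6)
  expect_equal(back$intensity, df$intensity, tolerance = 1e-6)
  expect_equal(back$time_min, df$time_min, tolerance = 1e-9)
})
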