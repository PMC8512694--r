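test_that("ecg_record validates its invariants", {
  rec <- ecg_record("r1", 250, rnorm(1000),
                    data.frame(start_s = c(0, 30), end_s = c(30, 60) / 15,
                               cls = c(0L, 2L))[0, ])
  expect_s3_class(rec, "ecg_record")
  expect_equal(duration(rec), 4)
  expect_error(ecg_record("r", 0, rnorm(10)), "fs")
  expect_error(ecg_record("r", 250, numeric(0)), "nonempty")
  # overlapping intervals rejected
  expect_error(
    ecg_record("r", 250, rnorm(250 * 60),
               data.frame(start_s = c(0, 30), end_s = c(40, 60),
                          cls = c(0L, 1L))),
    "overlap")
  # unsorted input is sorted, not rejected
  rec2 <- ecg_record("r", 10, rnorm(600),
                     data.frame(start_s = c(30, 0), end_s = c(60, 30),
                                cls = c(2L, 0L)))
  expect_equal(rec2$labels$start_s, c(0, 30))
  expect_equal(rec2$labels$cls, c(0L, 2L))
})

test_that("CSV record round-trips through read_record", {
  rec <- ecg_record("rt", 250, sin(2 * pi * 1.2 * (0:999) / 250),
                    data.frame(start_s = c(0, 2), end_s = c(2, 4),
                               cls = c(0L, 2L)))
  path <- tempfile(fileext = ".csv")
  lab_path <- tempfile(fileext = ".csv")
  write_record(rec, path, lab_path)
  back <- read_record(path, dialect = "csv", labels_path = lab_path)
  expect_equal(back$fs, rec$fs, tolerance = 1e-9)
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)
  expect_equal(back$labels, rec$labels)
  # 2-column CSV of 1000 rows at 250 Hz parses to 1000 samples
  expect_length(back$samples, 1000L)
})

test_that("malformed record and annotation files raise parse errors", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("t,mv", "0,0.1", "0.004,not_a_number"), bad)
  expect_error(read_record(bad), "line")
  ann <- tempfile(fileext = ".csv")
  writeLines(c("start_s,end_s,cls", "0,40,0", "30,60,1"), ann)
  expect_error(read_annotations(ann), "overlap")
  expect_error(read_record(tempfile(), dialect = "csv"), "not found")
})

test_that("class_at follows the half-open convention and a linear scan", {
  rec <- ecg_record("c", 100, rnorm(100 * 80),
                    data.frame(start_s = c(0, 30, 62), end_s = c(30, 60, 70),
                               cls = c(0L, 2L, 1L)))
  expect_identical(class_at(rec, 30), 2L)
  expect_identical(class_at(rec, 29.999), 0L)
  expect_identical(class_at(rec, 75), NA_integer_)
  expect_identical(class_at(rec, 61), NA_integer_)   # gap between intervals
  # agreement with a per-point linear scan oracle
  scan <- function(t) {
    for (i in seq_len(nrow(rec$labels)))
      if (t >= rec$labels$start_s[i] && t < rec$labels$end_s[i])
        return(rec$labels$cls[i])
    NA_integer_
  }
  ts <- seq(0, 79, by = 0.37)
  expect_identical(class_at(rec, ts), vapply(ts, scan, integer(1)))
  expect_error(class_at(rec, -1), ">= 0")
})

test_that("feature tables round-trip with their sidecar header", {
  set.seed(4)
  fs <- feature_set(matrix(rnorm(10 * 6), 10, 6),
                    matrix(sample(0:2, 20, TRUE), 10, 2),
                    horizons = c(1L, 5L), L = 2L,
                    record_id = rep(c("a", "b"), each = 5),
                    t_ref_s = seq_len(10), seed = 42L)
  path <- tempfile(fileext = ".csv")
  write_feature_table(fs, path)
  back <- read_feature_table(path)
  expect_equal(back$features, fs$features, tolerance = 1e-9)
  expect_identical(back$labels, fs$labels)
  expect_identical(back$horizons, fs$horizons)
  expect_identical(back$L, fs$L)
  expect_equal(back$seed, 42L)
  # empty set still writes a valid header-only file
  empty <- feature_set(matrix(numeric(0), 0, 6), matrix(integer(0), 0, 2),
                       horizons = c(1L, 5L), L = 2L,
                       record_id = character(0), t_ref_s = numeric(0))
  p2 <- tempfile(fileext = ".csv")
  write_feature_table(empty, p2)
  back2 <- read_feature_table(p2)
  expect_equal(nrow(back2$features), 0L)
  # mismatched horizon count between table and sidecar is an error
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  hdr$horizons <- c(1L, 5L, 9L)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_feature_table(path), "mismatch")
})

test_that("the WFDB format-16 adapter reads a programmatic record", {
  dir <- tempfile(); dir.create(dir)
  fs <- 128; n <- 512; gain <- 200
  x <- sin(2 * pi * 3 * (0:(n - 1)) / fs)
  writeBin(as.integer(round(x * gain)), file.path(dir, "tiny.dat"),
           size = 2L, endian = "little")
  writeLines(c(sprintf("tiny 1 %d %d", fs, n),
               sprintf("tiny.dat 16 %d 16 0 0 0 0 ECG", gain)),
             file.path(dir, "tiny.hea"))
  rec <- read_record(file.path(dir, "tiny"), dialect = "wfdb")
  expect_equal(rec$fs, fs)
  expect_length(rec$samples, n)
  expect_lt(max(abs(rec$samples - x)), 1 / gain)
  # unsupported format is a clear error
  writeLines(c("tiny 1 128 512", "tiny.dat 212 200 12 0 0 0 0 ECG"),
             file.path(dir, "tiny.hea"))
  expect_error(read_record(file.path(dir, "tiny"), dialect = "wfdb"),
               "format 16")
})

test_that("run_config enforces its invariants", {
  cfg <- run_config()
  expect_equal(cfg$L, 100L)
  expect_equal(cfg$horizons, 1:60)
  expect_equal(cfg$k_folds, 10L)
  expect_error(run_config(L = 1), "L")
  expect_error(run_config(horizons = c(3, 2, 1)), "increasing")
  expect_error(run_config(k_folds = 1), "k_folds")
  expect_error(run_config(training = list(nope = 1)), "unknown")
})
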