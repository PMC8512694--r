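#' Construct a labeled single-lead ECG record
#'
#' The unit of I/O for the whole pipeline: a raw amplitude trace at a fixed
#' sampling rate plus an optional track of non-overlapping class intervals
#' (stress level or sleep stage, coded 0/1/2). Record time 0 corresponds to
#' the first sample; label intervals are half-open `[start_s, end_s)` so a
#' class transition at `t` belongs to the new class.
#'
#' @param record_id Character scalar identifying the record.
#' @param fs Sampling rate in Hz (> 0).
#' @param samples Numeric vector of amplitudes (mV-like, arbitrary units).
#' @param labels Data frame with columns `start_s`, `end_s`, `cls`
#'   (class id in 0:2), or `NULL` for an unlabeled record.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, fs, samples, labels = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) == 0L || !is.numeric(samples))
    stop("`samples` must be a nonempty numeric vector")
  labels <- validate_label_intervals(labels, duration = length(samples) / fs)
  structure(
    list(record_id = as.character(record_id), fs = fs,
         samples = as.numeric(samples), labels = labels),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.1f s), %d label interval(s)>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, nrow(x$labels)))
  invisible(x)
}

#' @export
duration.ecg_record <- function(x) length(x$samples) / x$fs

#' Duration of a record in seconds
#' @param x An object with a duration.
#' @export
duration <- function(x) UseMethod("duration")

empty_labels <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), cls = integer(0))
}

validate_label_intervals <- function(labels, duration = Inf) {
  if (is.null(labels) || nrow(labels) == 0L) return(empty_labels())
  need <- c("start_s", "end_s", "cls")
  if (!all(need %in% names(labels)))
    stop("label intervals need columns start_s, end_s, cls")
  labels <- labels[need]
  labels$start_s <- as.numeric(labels$start_s)
  labels$end_s <- as.numeric(labels$end_s)
  labels$cls <- as.integer(labels$cls)
  if (any(labels$end_s <= labels$start_s))
    stop("label intervals must satisfy end_s > start_s")
  if (!all(labels$cls %in% 0:2))
    stop("label classes must be in {0, 1, 2}")
  o <- order(labels$start_s)
  labels <- labels[o, , drop = FALSE]
  if (nrow(labels) > 1L &&
      any(labels$start_s[-1L] < labels$end_s[-nrow(labels)] - 1e-9))
    stop("label intervals overlap or are not sortable")
  if (any(labels$start_s < -1e-9) ||
      (is.finite(duration) && any(labels$end_s > duration + 1e-6)))
    stop("label intervals must lie within [0, record duration]")
  rownames(labels) <- NULL
  labels
}

#' Read an ECG record from disk
#'
#' Two dialects are supported. `"csv"` is a two-column delimited text file
#' (time, amplitude); the first column holds seconds when
#' `time_unit = "seconds"` or 0-based sample indices when
#' `time_unit = "index"`, and in either case the sampling rate is taken from
#' `fs` (required for index files; inferred from the median time step
#' otherwise). `"wfdb"` reads a minimal WFDB record: a `.hea` header next to
#' a 16-bit little-endian `.dat` signal file (format 16); the first signal
#' channel is used.
#'
#' An optional annotation file (`start_s,end_s,class` per line, header
#' allowed) supplies the class-label track.
#'
#' @param path Path to the record (`.csv`, or WFDB header/record name).
#' @param dialect `"csv"` or `"wfdb"`.
#' @param labels_path Optional path to a label-interval CSV.
#' @param fs Sampling rate in Hz; required for `time_unit = "index"`.
#' @param time_unit Interpretation of the first CSV column.
#' @param record_id Identifier; defaults to the file stem.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, dialect = c("csv", "wfdb"), labels_path = NULL,
                        fs = NULL, time_unit = c("seconds", "index"),
                        record_id = NULL) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (is.null(record_id))
    record_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    if (!file.exists(path)) stop("record file not found: ", path)
    tab <- utils::read.csv(path, header = csv_has_header(path))
    if (ncol(tab) < 2L)
      stop("record CSV must have 2 columns (time/index, amplitude): ", path)
    tcol <- suppressWarnings(as.numeric(tab[[1L]]))
    vcol <- suppressWarnings(as.numeric(tab[[2L]]))
    bad <- which(!is.finite(tcol) | !is.finite(vcol))
    if (length(bad))
      stop(sprintf("record CSV parse error at data line %d: non-numeric field",
                   bad[1L]))
    if (time_unit == "index") {
      if (is.null(fs)) stop("`fs` is required when time_unit = \"index\"")
    } else if (is.null(fs)) {
      dt <- stats::median(diff(tcol))
      if (!is.finite(dt) || dt <= 0)
        stop("cannot infer sampling rate from time column; pass `fs`")
      fs <- 1 / dt
    }
    samples <- vcol
  } else {
    parsed <- read_wfdb_signal(path)
    samples <- parsed$samples
    fs <- parsed$fs
    record_id <- parsed$record_id
  }
  labels <- if (!is.null(labels_path)) read_annotations(labels_path) else NULL
  ecg_record(record_id, fs, samples, labels)
}

csv_has_header <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "[,\t;]")[[1L]]
  any(is.na(suppressWarnings(as.numeric(fields))))
}

#' Read a label-interval annotation file
#'
#' Delimited text with columns `start_s`, `end_s`, `cls` (class id 0/1/2),
#' one interval per line, header optional. Intervals are validated:
#' sorted, non-overlapping, `end_s > start_s`.
#'
#' @param path Path to the annotation CSV.
#' @return Data frame of validated label intervals.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.csv(path, header = csv_has_header(path))
  if (ncol(tab) < 3L) stop("annotation CSV needs 3 columns: start_s,end_s,cls")
  names(tab)[1:3] <- c("start_s", "end_s", "cls")
  validate_label_intervals(tab[1:3])
}

#' Write a record and its labels as delimited text
#'
#' @param record An [ecg_record()].
#' @param path Output CSV path for the signal (`t_s,amplitude`).
#' @param labels_path Optional output CSV for the label intervals.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, labels_path = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  t_s <- (seq_along(record$samples) - 1L) / record$fs
  utils::write.csv(data.frame(t_s = t_s, amplitude = record$samples),
                   path, row.names = FALSE)
  if (!is.null(labels_path))
    utils::write.csv(record$labels, labels_path, row.names = FALSE)
  invisible(path)
}

# Minimal WFDB adapter: parses the .hea header and reads a format-16
# (16-bit two's-complement little-endian) .dat file; first channel only.
read_wfdb_signal <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_f <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(head_f) < 4L) stop("malformed WFDB header line: ", lines[1L])
  rec_name <- head_f[1L]
  n_sig <- as.integer(head_f[2L])
  fs <- as.numeric(sub("/.*$", "", head_f[3L]))
  n_samp <- as.integer(head_f[4L])
  if (!is.finite(fs) || fs <= 0 || !is.finite(n_sig) || n_sig < 1L)
    stop("malformed WFDB header fields in: ", hea)
  sig_f <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  dat_file <- sig_f[1L]
  fmt <- sub("x.*$", "", sig_f[2L])
  if (fmt != "16")
    stop("WFDB adapter supports format 16 only, got format ", fmt)
  gain_field <- if (length(sig_f) >= 3L) sig_f[3L] else "200"
  gain <- as.numeric(sub("\\(.*$", "", sub("/.*$", "", gain_field)))
  baseline <- if (grepl("\\(", gain_field))
    as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_field)) else 0
  if (!is.finite(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, integer(), n = n_sig * n_samp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig) stop("WFDB signal file shorter than header claims")
  ch1 <- raw[seq(1L, length(raw), by = n_sig)]
  list(record_id = rec_name, fs = fs, samples = (ch1 - baseline) / gain)
}

#' Class label at a time point
#'
#' Looks up the class of the half-open interval `[start_s, end_s)` containing
#' `t`; returns `NA` for uncovered times. Vectorized over `t`.
#'
#' @param record An [ecg_record()] (or a label-interval data frame).
#' @param t Time(s) in seconds, `>= 0`.
#' @return Integer vector of class ids (0/1/2) with `NA` where unlabeled.
#' @export
class_at <- function(record, t) {
  labels <- if (inherits(record, "ecg_record")) record$labels else record
  if (any(t < 0)) stop("`t` must be >= 0")
  if (is.null(labels) || nrow(labels) == 0L)
    return(rep(NA_integer_, length(t)))
  idx <- findInterval(t, labels$start_s)       # half-open: start inclusive
  out <- rep(NA_integer_, length(t))
  hit <- idx >= 1L
  inside <- hit & t < labels$end_s[pmax(idx, 1L)]
  out[inside] <- labels$cls[idx[inside]]
  out
}

#' Assemble a feature set
#'
#' Container for model-ready samples: one row per consecutive beat pair,
#' `2*(2L-1)` feature columns (full convolution then full cross-correlation)
#' and one class label per prediction horizon.
#'
#' @param features Numeric matrix, one row per sample.
#' @param labels Integer matrix (values 0/1/2), one column per horizon.
#' @param horizons Integer vector of look-ahead times in seconds.
#' @param L Standardized beat length the features were computed from.
#' @param record_id Character vector (recycled) of source record ids.
#' @param t_ref_s Numeric vector of reference times (ending R wave of each
#'   beat pair).
#' @param seed Generator seed recorded for provenance, or `NA`.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(features, labels, horizons, L,
                        record_id = "rec", t_ref_s = NA_real_, seed = NA) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (nrow(features) != nrow(labels))
    stop("features and labels must have the same number of rows")
  if (nrow(labels) > 0L) {
    if (ncol(labels) != length(horizons))
      stop("label columns must match the number of horizons")
    if (!all(labels %in% 0:2)) stop("labels must be class ids in {0,1,2}")
    if (ncol(features) != 2L * (2L * L - 1L))
      stop(sprintf("expected %d feature columns for L=%d, got %d",
                   2L * (2L * L - 1L), L, ncol(features)))
  }
  structure(
    list(features = unname(features), labels = unname(labels),
         horizons = as.integer(horizons), L = as.integer(L),
         record_id = rep_len(as.character(record_id), nrow(features)),
         t_ref_s = rep_len(as.numeric(t_ref_s), nrow(features)),
         seed = seed),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set: %d samples x %d features, %d horizon(s), L=%d>\n",
              nrow(x$features), ncol(x$features), length(x$horizons), x$L))
  invisible(x)
}

#' Write / read a feature table
#'
#' The table is delimited text (one row per sample: record id, reference
#' time, features, labels) with a JSON sidecar `<path>.json` recording the
#' beat length `L`, the horizon list and the generator seed, so that
#' `read_feature_table(write_feature_table(x))` round-trips losslessly.
#'
#' @param fset A [feature_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a [feature_set()] (reader).
#' @export
write_feature_table <- function(fset, path) {
  stopifnot(inherits(fset, "feature_set"))
  n_feat <- ncol(fset$features)
  n_lab <- length(fset$horizons)
  header <- list(L = fset$L, horizons = fset$horizons,
                 seed = if (is.na(fset$seed)) NULL else fset$seed,
                 n_features = n_feat)
  jsonlite::write_json(header, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  df <- data.frame(record_id = fset$record_id, t_ref_s = fset$t_ref_s)
  if (nrow(fset$features) > 0L) {
    feat <- as.data.frame(fset$features)
    names(feat) <- sprintf("f%03d", seq_len(n_feat) - 1L)
    lab <- as.data.frame(fset$labels)
    names(lab) <- sprintf("y%02d", fset$horizons)
    df <- cbind(df, feat, lab)
  } else {
    # header-only file: still emit the full column set
    cols <- c(sprintf("f%03d", seq_len(n_feat) - 1L),
              sprintf("y%02d", fset$horizons))
    for (cl in cols) df[[cl]] <- numeric(0)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("feature table sidecar not found: ", side)
  header <- jsonlite::read_json(side, simplifyVector = TRUE)
  tab <- utils::read.csv(path)
  horizons <- as.integer(header$horizons)
  lab_cols <- sprintf("y%02d", horizons)
  feat_cols <- grep("^f[0-9]+$", names(tab), value = TRUE)
  if (length(feat_cols) != header$n_features)
    stop("feature table/sidecar mismatch: feature column count")
  if (!all(lab_cols %in% names(tab)))
    stop("feature table/sidecar mismatch: horizon label columns")
  feature_set(
    features = as.matrix(tab[feat_cols]),
    labels = matrix(as.integer(as.matrix(tab[lab_cols])),
                    nrow = nrow(tab), ncol = length(lab_cols)),
    horizons = horizons,
    L = as.integer(header$L),
    record_id = if (nrow(tab)) tab$record_id else character(0),
    t_ref_s = if (nrow(tab)) tab$t_ref_s else numeric(0),
    seed = if (is.null(header$seed)) NA else header$seed)
}

#' Run configuration with pipeline defaults
#'
#' Central bundle of tunables for the whole pipeline. Defaults follow the
#' method's stated dimensioning (beat length `L = 100`, horizons 1-60 s in
#' 1 s steps, 10-fold cross-validation) with Pan-Tompkins-conventional
#' detector settings and NSGA-III literature-default variation operators.
#'
#' @param L Standardized beat length (>= 2).
#' @param horizons Strictly increasing positive integers (seconds ahead).
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param rng_seed Base seed for all stochastic steps.
#' @param filter,detector,training,nsga Named lists overriding individual
#'   parameters within each block.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(L = 100L, horizons = 1:60, k_folds = 10L,
                       rng_seed = 1L, filter = list(), detector = list(),
                       training = list(), nsga = list()) {
  horizons <- as.integer(horizons)
  if (L < 2L) stop("L must be >= 2")
  if (length(horizons) == 0L || any(horizons <= 0L) ||
      any(diff(horizons) <= 0L))
    stop("horizons must be strictly increasing positive integers")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  merge_block <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  structure(list(
    L = as.integer(L), horizons = horizons, k_folds = as.integer(k_folds),
    rng_seed = as.integer(rng_seed),
    filter = merge_block(list(band_hz = c(10, 30), order = 4L), filter),
    detector = merge_block(list(integration_window_s = 0.15,
                                refractory_s = 0.2, threshold_frac = 0.25),
                           detector),
    training = merge_block(list(hidden = 16L, window = 8L, epochs = 30L,
                                learning_rate = 1e-3, batch_size = 32L,
                                alpha = 3L, beta = 3), training),
    nsga = merge_block(list(pop_size = 92L, generations = 50L,
                            divisions_p = 6L, sbx_eta = 30, mutation_eta = 20,
                            mutation_rate = NA_real_), nsga)),
    class = "run_config")
}
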