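#' Full (linear) convolution of two equal-length beats
#'
#' `out[n] = sum_k x1[k] * x2[n-k]` over all valid `k`, for
#' `n = 0 .. 2L-2`, i.e. the full convolution of length `2L - 1`.
#' For the standard beat length `L = 100` this yields 199 coefficients.
#' Commutative in its arguments.
#'
#' @param x1,x2 Numeric vectors of equal length `L >= 1`.
#' @return Numeric vector of length `2L - 1`.
#' @export
full_convolution <- function(x1, x2) {
  L <- length(x1)
  if (length(x2) != L) stop("x1 and x2 must have equal length")
  if (L == 0L) stop("inputs must be nonempty")
  if (L == 1L) return(x1 * x2)
  stats::convolve(x1, rev(x2), type = "open")
}

#' Full cross-correlation of two equal-length beats
#'
#' `out[k + L] = sum_n x1[n] * x2[n + k]` for lags
#' `k = -(L-1) .. (L-1)`, stored left-to-right (most negative lag first;
#' zero lag at the center index `L`). Length `2L - 1`; 199 for `L = 100`.
#' Related to convolution by `xcorr(x1, x2) = conv(x2, rev(x1))`.
#'
#' @param x1,x2 Numeric vectors of equal length `L >= 1`.
#' @return Numeric vector of length `2L - 1`.
#' @export
full_cross_correlation <- function(x1, x2) {
  L <- length(x1)
  if (length(x2) != L) stop("x1 and x2 must have equal length")
  if (L == 0L) stop("inputs must be nonempty")
  if (L == 1L) return(x1 * x2)
  stats::convolve(x2, x1, type = "open")  # convolve reverses its 2nd arg
}

#' Featurize one beat pair
#'
#' Concatenates the full convolution and full cross-correlation of two
#' consecutive standardized beats into a single `2 * (2L - 1)`-length
#' vector (398 for `L = 100`): the convolution captures the symmetric
#' content of the pair, the cross-correlation the asymmetric content.
#'
#' @param x1,x2 Equal-length numeric vectors (earlier beat, following beat).
#' @return Numeric feature vector of length `2 * (2 * length(x1) - 1)`.
#' @export
beat_pair_features <- function(x1, x2) {
  c(full_convolution(x1, x2), full_cross_correlation(x1, x2))
}

#' Build model-ready samples from segmented beats
#'
#' Forms all strictly consecutive beat pairs (stride 1, overlapping), each
#' anchored at `t_ref_s`, the ending R-wave time of the pair - the latest
#' causal landmark. Features are the convolution/cross-correlation
#' concatenation of the pair; labels are the record's class at
#' `t_ref_s + k` for every horizon `k`. Pairs with any horizon falling
#' outside the labeled intervals are dropped rather than imputed.
#'
#' @param beats List of `beat` objects from [segment_beats()], time-sorted.
#' @param record The source [ecg_record()] carrying the label track.
#' @param horizons Integer look-ahead times in seconds (default 1-60).
#' @param L Standardized beat length (consistency check).
#' @return A [feature_set()] (possibly with zero rows).
#' @export
build_samples <- function(beats, record, horizons = 1:60, L = 100L) {
  stopifnot(inherits(record, "ecg_record"))
  horizons <- as.integer(horizons)
  n_feat <- 2L * (2L * L - 1L)
  if (length(beats) < 2L)
    return(feature_set(matrix(numeric(0), 0L, n_feat),
                       matrix(integer(0), 0L, length(horizons)),
                       horizons, L, character(0), numeric(0)))
  n_pairs <- length(beats) - 1L
  t_ref <- vapply(beats[-1L], function(b) b$r_end_s, numeric(1))
  lab <- vapply(seq_len(n_pairs), function(i) class_at(record, t_ref[i] + horizons),
                integer(length(horizons)))
  lab <- matrix(lab, nrow = n_pairs, ncol = length(horizons), byrow = TRUE)
  keep <- which(rowSums(is.na(lab)) == 0L)
  feats <- matrix(0, length(keep), n_feat)
  for (j in seq_along(keep)) {
    i <- keep[j]
    feats[j, ] <- beat_pair_features(beats[[i]]$samples, beats[[i + 1L]]$samples)
  }
  feature_set(feats, lab[keep, , drop = FALSE], horizons, L,
              record_id = record$record_id, t_ref_s = t_ref[keep])
}

#' Concatenate feature sets
#'
#' Row-binds compatible feature sets (same `L` and horizons) from several
#' records into one corpus.
#'
#' @param ... [feature_set()] objects, or a single list of them.
#' @return A single [feature_set()].
#' @export
bind_feature_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "feature_set"))
    sets <- sets[[1L]]
  stopifnot(all(vapply(sets, inherits, logical(1), "feature_set")))
  ref <- sets[[1L]]
  for (s in sets[-1L])
    if (s$L != ref$L || !identical(s$horizons, ref$horizons))
      stop("feature sets differ in L or horizons")
  feature_set(do.call(rbind, lapply(sets, `[[`, "features")),
              do.call(rbind, lapply(sets, `[[`, "labels")),
              ref$horizons, ref$L,
              record_id = unlist(lapply(sets, `[[`, "record_id")),
              t_ref_s = unlist(lapply(sets, `[[`, "t_ref_s")),
              seed = ref$seed)
}
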