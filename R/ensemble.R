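## Fusion of the three recurrent classifiers: per-horizon simplex weights
## over the RNN/GRU/LSTM class scores, evaluated on cross-validated
## predictions under four accuracy objectives (overall + one per class)
## and searched by NSGA-III. Also provides the stand-alone and boosting
## baselines and the accuracy-vs-horizon reports.

#' Per-class accuracy (class-wise recall)
#'
#' Fraction of samples whose true class is `cls` that are predicted as
#' `cls`. Returns `NA` (with a warning) when `cls` is absent from
#' `y_true`, in which case the caller should exclude it from objectives.
#'
#' @param y_true,y_pred Equal-length class-id vectors.
#' @param cls Class id.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
per_class_accuracy <- function(y_true, y_pred, cls) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  sel <- y_true == cls
  if (!any(sel)) {
    warning(sprintf("class %s absent from y_true; accuracy undefined", cls))
    return(NA_real_)
  }
  mean(y_pred[sel] == cls)
}

#' Overall accuracy
#'
#' Matching fraction; algebraically equal to the support-weighted mean of
#' the per-class recalls.
#'
#' @param y_true,y_pred Equal-length, nonempty class-id vectors.
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  mean(y_true == y_pred)
}

#' Normalize an ensemble genome to per-horizon simplex weights
#'
#' The genome is `3 * K` nonnegative reals; each horizon's triple
#' (RNN, GRU, LSTM) is divided by its sum (uniform weights when the sum
#' is ~0).
#'
#' @param genome Numeric vector of length `3 * K`.
#' @param K Number of horizons.
#' @return K x 3 weight matrix with rows summing to 1.
#' @export
genome_to_weights <- function(genome, K) {
  w <- matrix(genome, K, 3L, byrow = TRUE)
  s <- rowSums(w)
  w[s < 1e-12, ] <- 1
  w / rowSums(w)
}

one_hot_genome <- function(model_idx, K) {
  w <- matrix(0, K, 3L)
  w[, model_idx] <- 1
  as.vector(t(w))
}

#' Combine base-model scores into ensemble predictions
#'
#' Per horizon `h`, the combined class score is
#' `sum_m weights[h, m] * scores_m[, , h]`; the predicted class is the
#' argmax, ties broken toward the lowest class id.
#'
#' @param weights K x 3 matrix of per-horizon model weights
#'   (columns: RNN, GRU, LSTM).
#' @param base_scores List of 3 arrays, each `n x 3 x K` (class scores from
#'   one base model).
#' @return List with `classes` (n x K) and `scores` (n x 3 x K).
#' @export
ensemble_predict <- function(weights, base_scores) {
  stopifnot(length(base_scores) == 3L)
  dims <- dim(base_scores[[1L]])
  for (m in 2:3)
    if (!identical(dim(base_scores[[m]]), dims))
      stop("base score arrays differ in shape")
  K <- dims[3L]
  if (!identical(dim(weights), c(K, 3L)))
    stop("weights must be a K x 3 matrix matching the score arrays")
  n <- dims[1L]
  classes <- matrix(0L, n, K)
  scores <- array(0, dims)
  for (h in seq_len(K)) {
    S <- weights[h, 1L] * base_scores[[1L]][, , h, drop = FALSE][, , 1L] +
      weights[h, 2L] * base_scores[[2L]][, , h, drop = FALSE][, , 1L] +
      weights[h, 3L] * base_scores[[3L]][, , h, drop = FALSE][, , 1L]
    S <- matrix(S, n, 3L)
    scores[, , h] <- S
    classes[, h] <- max.col(S, ties.method = "first") - 1L
  }
  list(classes = classes, scores = scores)
}

# Deterministic per-(fold, cell, replicate) training seed.
fold_seed <- function(seed, fold, cell_idx, b = 1L)
  (as.integer(seed) * 7919L + fold * 373L + cell_idx * 59L + b) %% 2147483587L

#' Stratified cross-validation folds
#'
#' Assigns each sample to one of `k` validation folds, stratified by the
#' first-horizon label (or grouped by record when `group_by_record` is
#' `TRUE`, which prevents within-record leakage at the cost of
#' stratification).
#'
#' @param fset A [feature_set()].
#' @param k Number of folds.
#' @param seed RNG seed.
#' @param group_by_record Keep whole records inside one fold.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
create_folds <- function(fset, k, seed = 1L, group_by_record = FALSE) {
  n <- nrow(fset$features)
  if (k < 2L) stop("k must be >= 2")
  old_seed <- sub_seed(seed, 503L)
  on.exit(restore_seed(old_seed))
  fold <- integer(n)
  if (group_by_record) {
    recs <- unique(fset$record_id)
    rec_fold <- stats::setNames(
      rep_len(sample.int(k), length(recs))[sample.int(length(recs))], recs)
    fold <- unname(rec_fold[fset$record_id])
  } else {
    y1 <- fset$labels[, 1L]
    for (cl in unique(y1)) {
      rows <- which(y1 == cl)
      fold[rows] <- rep_len(sample.int(k), length(rows))[sample.int(length(rows))]
    }
  }
  fold
}

#' Train the three base models per fold and cache validation scores
#'
#' For every fold, trains one RNN, one GRU and one LSTM classifier on the
#' training split (with sliding windows taken from the full time-ordered
#' corpus, so fold subsetting never fabricates false neighbours) and
#' stores their class-score arrays on the validation split. This cache is
#' what the NSGA-III objective evaluation consumes; base models are
#' trained exactly once per fold.
#'
#' @param fset A [feature_set()].
#' @param config A [run_config()] (uses `k_folds`, `rng_seed`, `training`).
#' @param group_by_record Passed to [create_folds()].
#' @return List of class `ensemble_cache`.
#' @export
build_ensemble_cache <- function(fset, config = run_config(),
                                 group_by_record = FALSE) {
  K <- length(fset$horizons)
  if (length(unique(as.vector(fset$labels[, 1L]))) < 3L)
    stop("all three classes must be present in the first-horizon labels")
  tr_cfg <- config$training
  fold <- create_folds(fset, config$k_folds, seed = config$rng_seed,
                       group_by_record = group_by_record)
  windows_all <- build_windows(fset$features, fset$record_id, tr_cfg$window)
  cells <- c("rnn", "gru", "lstm")
  folds <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    val <- which(fold == f)
    tr <- which(fold != f)
    if (!length(val) || !length(tr)) stop("fold ", f, " is empty")
    sub_win <- function(rows) lapply(windows_all, function(m)
      m[rows, , drop = FALSE])
    models <- list(); scores <- list()
    for (mi in seq_along(cells)) {
      m <- horizon_classifier(cells[mi], ncol(fset$features),
                              hidden = tr_cfg$hidden, n_horizons = K,
                              window = tr_cfg$window,
                              seed = fold_seed(config$rng_seed, f, mi),
                              alpha = tr_cfg$alpha, beta = tr_cfg$beta)
      m <- hc_train(m, subset_fset(fset, tr), epochs = tr_cfg$epochs,
                    learning_rate = tr_cfg$learning_rate,
                    batch_size = tr_cfg$batch_size, windows = sub_win(tr))
      pr <- hc_predict(m, subset_fset(fset, val), windows = sub_win(val))
      models[[cells[mi]]] <- m
      scores[[cells[mi]]] <- pr$scores
    }
    folds[[f]] <- list(val_rows = val, labels = fset$labels[val, , drop = FALSE],
                       scores = scores, models = models)
  }
  present <- vapply(0:2, function(cl) any(fset$labels == cl), logical(1))
  if (!all(present))
    warning("some classes never occur in the horizon labels; their ",
            "accuracy objectives will be treated as missing")
  structure(list(folds = folds, horizons = fset$horizons, fold_id = fold,
                 config = config),
            class = "ensemble_cache")
}

# Fold/horizon accuracy table for a K x 3 weight matrix.
weights_report <- function(weights, cache) {
  K <- length(cache$horizons)
  rows <- list()
  for (f in seq_along(cache$folds)) {
    fd <- cache$folds[[f]]
    pred <- ensemble_predict(weights, fd$scores)$classes
    for (h in seq_len(K)) {
      yt <- fd$labels[, h]; yp <- pred[, h]
      pcs <- vapply(0:2, function(cl)
        if (any(yt == cl)) mean(yp[yt == cl] == cl) else NA_real_,
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, horizon = cache$horizons[h],
        OA_all = mean(yt == yp), OA_class0 = pcs[1L],
        OA_class1 = pcs[2L], OA_class2 = pcs[3L])
    }
  }
  do.call(rbind, rows)
}

#' Evaluate an ensemble genome under the four accuracy objectives
#'
#' Objectives are the overall accuracy and the three per-class recalls of
#' the ensemble's cross-validated predictions, averaged over folds and
#' horizons (unweighted across horizons; fold/horizon cells where a class
#' is absent are excluded from that class's mean).
#'
#' @param genome Numeric vector of length `3 * K` (see
#'   [genome_to_weights()]).
#' @param cache An `ensemble_cache` from [build_ensemble_cache()].
#' @return Named numeric vector `c(OA_all, OA_class0, OA_class1,
#'   OA_class2)`, each in `[0, 1]`.
#' @export
evaluate_genome <- function(genome, cache) {
  K <- length(cache$horizons)
  weights <- genome_to_weights(genome, K)
  acc <- matrix(0, 0L, 4L)
  for (fd in cache$folds) {
    pred <- ensemble_predict(weights, fd$scores)$classes
    for (h in seq_len(K)) {
      yt <- fd$labels[, h]; yp <- pred[, h]
      pcs <- vapply(0:2, function(cl)
        if (any(yt == cl)) mean(yp[yt == cl] == cl) else NA_real_,
        numeric(1))
      acc <- rbind(acc, c(mean(yt == yp), pcs))
    }
  }
  out <- colMeans(acc, na.rm = TRUE)
  names(out) <- c("OA_all", "OA_class0", "OA_class1", "OA_class2")
  out
}

#' Optimize the RNN-GRU-LSTM fusion with NSGA-III
#'
#' Trains the three base classifiers per cross-validation fold (once),
#' then runs NSGA-III over per-horizon ensemble weights, maximizing the
#' four objectives of [evaluate_genome()]. The initial population is
#' seeded with the three one-hot genomes (each base model alone) plus
#' random simplex genomes, so the search can never lose to the best
#' stand-alone model on the selection folds. The returned selection is
#' the archive member maximizing `OA_all`, ties broken by the largest
#' minimum per-class accuracy.
#'
#' @param fset A [feature_set()] containing all three classes.
#' @param config A [run_config()].
#' @param cache Optional precomputed [build_ensemble_cache()] result.
#' @param group_by_record Passed to the fold builder.
#' @return List of class `ensemble_fit`: `weights` (K x 3 selected),
#'   `objectives`, `archive_weights`, `archive_objs`, `report`
#'   (fold x horizon accuracy table), `cache`, `nsga`.
#' @export
optimize_ensemble <- function(fset, config = run_config(), cache = NULL,
                              group_by_record = FALSE) {
  if (is.null(cache))
    cache <- build_ensemble_cache(fset, config, group_by_record)
  K <- length(cache$horizons)
  n_var <- 3L * K
  init <- rbind(one_hot_genome(1L, K), one_hot_genome(2L, K),
                one_hot_genome(3L, K))
  nsga_cfg <- config$nsga
  nsga_cfg$seed <- config$rng_seed
  res <- nsga3_evolve(function(g) evaluate_genome(g, cache),
                      n_var = n_var, n_obj = 4L, config = nsga_cfg,
                      maximize = TRUE, lower = 0, upper = 1, init = init)
  ao <- res$archive_objs
  best_oa <- max(ao[, 1L])
  tied <- which(ao[, 1L] >= best_oa - 1e-12)
  sel <- tied[which.max(apply(ao[tied, -1L, drop = FALSE], 1L, min))]
  weights <- genome_to_weights(res$archive_pop[sel, ], K)
  structure(list(weights = weights,
                 objectives = stats::setNames(ao[sel, ],
                   c("OA_all", "OA_class0", "OA_class1", "OA_class2")),
                 archive_weights = res$archive_pop,
                 archive_objs = ao,
                 report = weights_report(weights, cache),
                 cache = cache, nsga = res),
            class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("<ensemble_fit: OA_all=%.3f, per-class (%.3f, %.3f, %.3f), archive %d>\n",
              x$objectives[1L], x$objectives[2L], x$objectives[3L],
              x$objectives[4L], nrow(x$archive_objs)))
  invisible(x)
}

#' Stand-alone and boosting baselines
#'
#' `standalone`: each base cell alone (one-hot ensemble weights over the
#' cached fold models). `boosting`: for each cell kind, `B` replicates
#' trained with different seeds per fold, combined by score averaging
#' weighted by each replicate's validation overall accuracy; `B = 1`
#' reduces exactly to the stand-alone baseline.
#'
#' @param fset A [feature_set()].
#' @param config A [run_config()].
#' @param B Number of boosting replicates per cell (default 5).
#' @param cache Optional precomputed cache (replicate 1 is reused from it).
#' @param group_by_record Passed to the fold builder.
#' @return List with `standalone` and `boosting`, each a named list (rnn,
#'   gru, lstm) of fold x horizon accuracy tables, plus `summary`
#'   (mean OA_all per method).
#' @export
run_baselines <- function(fset, config = run_config(), B = 5L,
                          cache = NULL, group_by_record = FALSE) {
  if (is.null(cache))
    cache <- build_ensemble_cache(fset, config, group_by_record)
  K <- length(cache$horizons)
  cells <- c("rnn", "gru", "lstm")
  standalone <- stats::setNames(lapply(seq_along(cells), function(mi)
    weights_report(genome_to_weights(one_hot_genome(mi, K), K), cache)),
    cells)
  tr_cfg <- config$training
  windows_all <- build_windows(fset$features, fset$record_id, tr_cfg$window)
  sub_win <- function(rows) lapply(windows_all, function(m)
    m[rows, , drop = FALSE])
  boosting <- list()
  for (mi in seq_along(cells)) {
    rows <- list()
    for (f in seq_along(cache$folds)) {
      fd <- cache$folds[[f]]
      val <- fd$val_rows
      tr <- setdiff(seq_len(nrow(fset$features)), val)
      combined <- 0
      wsum <- 0
      for (b in seq_len(B)) {
        if (b == 1L) {
          pr_scores <- fd$scores[[cells[mi]]]
          m <- fd$models[[cells[mi]]]
        } else {
          m <- horizon_classifier(cells[mi], ncol(fset$features),
                                  hidden = tr_cfg$hidden, n_horizons = K,
                                  window = tr_cfg$window,
                                  seed = fold_seed(config$rng_seed, f, mi, b),
                                  alpha = tr_cfg$alpha, beta = tr_cfg$beta)
          m <- hc_train(m, subset_fset(fset, tr), epochs = tr_cfg$epochs,
                        learning_rate = tr_cfg$learning_rate,
                        batch_size = tr_cfg$batch_size,
                        windows = sub_win(tr))
          pr_scores <- hc_predict(m, subset_fset(fset, val),
                                  windows = sub_win(val))$scores
        }
        pred_b <- apply(pr_scores, c(1L, 3L), which.max) - 1L
        w_b <- mean(pred_b == fd$labels)
        combined <- combined + w_b * pr_scores
        wsum <- wsum + w_b
      }
      combined <- combined / max(wsum, 1e-12)
      pred <- matrix(as.integer(apply(combined, c(1L, 3L), which.max) - 1L),
                     length(val), K)
      for (h in seq_len(K)) {
        yt <- fd$labels[, h]; yp <- pred[, h]
        pcs <- vapply(0:2, function(cl)
          if (any(yt == cl)) mean(yp[yt == cl] == cl) else NA_real_,
          numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, horizon = cache$horizons[h],
          OA_all = mean(yt == yp), OA_class0 = pcs[1L],
          OA_class1 = pcs[2L], OA_class2 = pcs[3L])
      }
    }
    boosting[[cells[mi]]] <- do.call(rbind, rows)
  }
  summary <- data.frame(
    method = c(paste0("standalone_", cells), paste0("boosting_", cells)),
    OA_all = c(vapply(standalone, function(r) mean(r$OA_all), numeric(1)),
               vapply(boosting, function(r) mean(r$OA_all), numeric(1))))
  list(standalone = standalone, boosting = boosting, summary = summary,
       cache = cache)
}

#' Accuracy-vs-horizon curve
#'
#' Collapses a fold x horizon report to one row per horizon (mean over
#' folds), the shape used to inspect how accuracy decays with the
#' prediction lead time.
#'
#' @param report A report data frame (`fold`, `horizon`, `OA_all`, ...).
#' @return Data frame with one row per horizon.
#' @export
horizon_curve <- function(report) {
  agg <- stats::aggregate(
    report[c("OA_all", "OA_class0", "OA_class1", "OA_class2")],
    by = list(horizon = report$horizon), FUN = mean, na.rm = TRUE)
  agg[order(agg$horizon), ]
}

#' Map predicted classes to warning flags
#'
#' Classes 1 and 2 are the undesirable driving statuses (medium/high
#' stress, or sleep stages 1/2) that trigger a driver warning.
#'
#' @param classes Integer vector/matrix of predicted class ids.
#' @return Logical object of the same shape: `TRUE` where a warning fires.
#' @export
warn_flag <- function(classes) classes == 1L | classes == 2L
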