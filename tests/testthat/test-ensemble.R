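test_that("accuracy metrics match direct counts and the support identity", {
  expect_equal(per_class_accuracy(c(0, 0, 1), c(0, 1, 1), 0), 0.5)
  expect_equal(per_class_accuracy(c(0, 0, 1), c(0, 0, 1), 1), 1.0)
  expect_warning(pc <- per_class_accuracy(c(0, 0), c(0, 1), 2), "absent")
  expect_true(is.na(pc))
  expect_equal(overall_accuracy(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(overall_accuracy(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0.75)
  expect_error(overall_accuracy(integer(0), integer(0)), "empty")
  # OA_all equals the support-weighted mean of per-class recalls
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(10:60, 1)
    yt <- sample(0:2, n, TRUE)
    yp <- sample(0:2, n, TRUE)
    present <- intersect(0:2, yt)
    rec <- vapply(present, function(cl)
      suppressWarnings(per_class_accuracy(yt, yp, cl)), numeric(1))
    sup <- vapply(present, function(cl) sum(yt == cl), numeric(1))
    expect_equal(overall_accuracy(yt, yp), sum(sup * rec) / n,
                 tolerance = 1e-9)
  }
})

test_that("genome normalization yields per-horizon simplex weights", {
  g <- runif(3 * 5)
  w <- genome_to_weights(g, 5L)
  expect_equal(dim(w), c(5L, 3L))
  expect_equal(rowSums(w), rep(1, 5))
  expect_true(all(w >= 0))
  # all-zero horizon falls back to uniform
  g0 <- rep(0, 15)
  expect_equal(genome_to_weights(g0, 5L), matrix(1 / 3, 5, 3))
})

test_that("ensemble_predict reproduces one-hot, majority and hand-set cases", {
  set.seed(52)
  n <- 7L; K <- 4L
  sc <- lapply(1:3, function(m) {
    a <- array(runif(n * 3 * K), c(n, 3L, K))
    for (h in 1:K) a[, , h] <- a[, , h] / rowSums(a[, , h])
    a
  })
  # one-hot weights reproduce the base model exactly
  for (m in 1:3) {
    w <- matrix(0, K, 3L); w[, m] <- 1
    got <- ensemble_predict(w, sc)
    base <- apply(sc[[m]], c(1, 3), which.max) - 1L
    expect_equal(got$classes, matrix(as.integer(base), n, K))
  }
  # two agreeing models with combined weight > 0.5 win
  agree <- array(0, c(1, 3, 1)); agree[1, 2, 1] <- 1
  other <- array(0, c(1, 3, 1)); other[1, 3, 1] <- 1
  w <- matrix(c(0.3, 0.3, 0.4), 1, 3)
  expect_equal(ensemble_predict(w, list(agree, agree, other))$classes[1, 1], 1L)
  # uniform weights match a hand-computed weighted argmax
  w_u <- matrix(1 / 3, K, 3L)
  got <- ensemble_predict(w_u, sc)
  for (h in 1:K) {
    S <- (sc[[1]][, , h] + sc[[2]][, , h] + sc[[3]][, , h]) / 3
    expect_equal(got$classes[, h],
                 as.integer(max.col(S, ties.method = "first") - 1L))
  }
  expect_error(ensemble_predict(matrix(1, 2, 3), sc), "K x 3")
})

test_that("stratified folds partition samples; record grouping keeps records whole", {
  fs <- fixture_corpus()$features
  fold <- create_folds(fs, 3L, seed = 2L)
  expect_length(fold, nrow(fs$features))
  expect_setequal(unique(fold), 1:3)
  # each sample in exactly one fold is implied; check balance per class
  for (cl in 0:2) {
    tab <- table(fold[fs$labels[, 1] == cl])
    if (length(tab) == 3L) expect_lt(max(tab) - min(tab), 3L)
  }
  gfold <- create_folds(fs, 2L, seed = 2L, group_by_record = TRUE)
  for (r in unique(fs$record_id))
    expect_length(unique(gfold[fs$record_id == r]), 1L)
})

test_that("evaluate_genome is consistent with one-hot base models and an independent recomputation", {
  cache <- fixture_cache()
  K <- length(cache$horizons)
  # one-hot genomes match a direct per-fold recomputation
  for (m in 1:3) {
    g <- rep(0, 3 * K); g[seq(m, 3 * K, by = 3)] <- 1
    obj <- evaluate_genome(g, cache)
    expect_true(all(obj >= 0 & obj <= 1))
    # independent recomputation: loop folds/horizons on raw scores
    accs <- c(); pcs <- list(c(), c(), c())
    for (fd in cache$folds) {
      pred <- apply(fd$scores[[m]], c(1, 3), which.max) - 1L
      for (h in seq_len(K)) {
        accs <- c(accs, mean(pred[, h] == fd$labels[, h]))
        for (cl in 0:2) {
          sel <- fd$labels[, h] == cl
          pcs[[cl + 1]] <- c(pcs[[cl + 1]],
                             if (any(sel)) mean(pred[sel, h] == cl) else NA)
        }
      }
    }
    expect_equal(unname(obj[1]), mean(accs), tolerance = 1e-9)
    for (cl in 0:2)
      expect_equal(unname(obj[cl + 2]), mean(pcs[[cl + 1]], na.rm = TRUE),
                   tolerance = 1e-9)
  }
  # perfect base models give the all-ones objective vector
  perfect <- cache
  for (f in seq_along(perfect$folds)) {
    lab <- perfect$folds[[f]]$labels
    n <- nrow(lab)
    arr <- array(0, c(n, 3L, K))
    for (h in seq_len(K)) arr[cbind(seq_len(n), lab[, h] + 1L, h)] <- 1
    perfect$folds[[f]]$scores <- list(rnn = arr, gru = arr, lstm = arr)
  }
  expect_equal(unname(evaluate_genome(runif(3 * K), perfect)), rep(1, 4))
})

test_that("every report row satisfies the OA identity and covers all horizons", {
  cache <- fixture_cache()
  K <- length(cache$horizons)
  w <- genome_to_weights(runif(3 * K, 0.2, 1), K)
  rep_tab <- ecgfusion:::weights_report(w, cache)
  expect_equal(nrow(rep_tab), length(cache$folds) * K)
  expect_setequal(unique(rep_tab$horizon), cache$horizons)
  for (i in seq_len(nrow(rep_tab))) {
    fd <- cache$folds[[rep_tab$fold[i]]]
    h <- which(cache$horizons == rep_tab$horizon[i])
    sup <- vapply(0:2, function(cl) sum(fd$labels[, h] == cl), numeric(1))
    rec <- unlist(rep_tab[i, c("OA_class0", "OA_class1", "OA_class2")])
    expect_equal(rep_tab$OA_all[i],
                 sum(sup * rec, na.rm = TRUE) / sum(sup[!is.na(rec)]),
                 tolerance = 1e-9)
  }
})

test_that("the optimized ensemble dominates every one-hot genome and is reproducible", {
  fit <- optimize_ensemble(fixture_corpus()$features, fixture_config(),
                           cache = fixture_cache())
  K <- length(fit$cache$horizons)
  onehot_oa <- vapply(1:3, function(m) {
    g <- rep(0, 3 * K); g[seq(m, 3 * K, by = 3)] <- 1
    evaluate_genome(g, fit$cache)[1]
  }, numeric(1))
  expect_gte(fit$objectives[1], max(onehot_oa))
  # selection is drawn from the archive, whose members are nondominated
  fr <- nondominated_sort(fit$archive_objs, maximize = TRUE)
  expect_length(fr, 1L)
  fit2 <- optimize_ensemble(fixture_corpus()$features, fixture_config(),
                            cache = fixture_cache())
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$objectives, fit2$objectives)
})

test_that("boosting with B = 1 reduces exactly to the stand-alone baseline", {
  bl <- run_baselines(fixture_corpus()$features, fixture_config(), B = 1L,
                      cache = fixture_cache())
  for (cell in c("rnn", "gru", "lstm")) {
    expect_equal(bl$boosting[[cell]]$OA_all, bl$standalone[[cell]]$OA_all,
                 tolerance = 1e-12)
  }
  expect_equal(nrow(bl$standalone$rnn),
               length(fixture_cache()$folds) * 10L)
  expect_true(all(c("fold", "horizon", "OA_all") %in%
                    names(bl$standalone$gru)))
})

test_that("horizon-1 accuracy beats the majority class on drifting synthetic data", {
  cache <- fixture_cache()
  fs <- fixture_corpus()$features
  maj <- max(table(fs$labels[, 1])) / nrow(fs$labels)
  K <- length(cache$horizons)
  g <- rep(1, 3 * K)   # uniform ensemble
  h1 <- mean(vapply(cache$folds, function(fd) {
    pred <- ensemble_predict(genome_to_weights(g, K), fd$scores)$classes
    mean(pred[, 1] == fd$labels[, 1])
  }, numeric(1)))
  expect_gt(h1, maj + 0.05)
})

test_that("warning flags fire for the undesirable classes", {
  cls <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  expect_equal(warn_flag(cls), matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(warn_flag(c(0L, 1L, 2L)), c(FALSE, TRUE, TRUE))
})
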