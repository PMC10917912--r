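# Evaluation stack: confusion counting, one-vs-rest PRF, ROC/AUC — each
# validated against independent brute-force or rank-statistic oracles.

test_that("confusion matrix counts true-by-predicted cells", {
  all_good <- tibble::tibble(truth = rep(1:2, each = 50),
                             pred = rep(1:2, each = 50))
  cm <- confusion_matrix(all_good, truth, pred, k = 2)
  expect_equal(unclass(unname(cm)), diag(c(50L, 50L)), ignore_attr = TRUE)

  one <- confusion_matrix(tibble::tibble(truth = 3, pred = 1), truth, pred,
                          k = 4)
  expect_equal(sum(one), 1L)
  expect_equal(one[3, 1], 1L)

  expect_error(confusion_matrix(tibble::tibble(truth = 5, pred = 1), truth,
                                pred, k = 4), "1..4")
  expect_error(confusion_matrix(tibble::tibble(truth = integer(0),
                                               pred = integer(0)),
                                truth, pred, k = 4), "no prediction")
})

test_that("confusion matrix equals a nested-loop counting oracle", {
  withr::with_seed(1, {
    recs <- random_records(30)
    cm <- confusion_matrix(recs, truth, pred, k = 4)
    oracle <- matrix(0L, 4, 4)
    for (r in seq_len(30)) {
      i <- recs$truth[r]; j <- recs$pred[r]
      oracle[i, j] <- oracle[i, j] + 1L
    }
    expect_equal(unclass(cm), oracle, ignore_attr = TRUE)
    expect_equal(sum(cm), 30L)
    expect_equal(unname(rowSums(cm)),
                 vapply(1:4, function(c) sum(recs$truth == c), numeric(1)))
  })
})

test_that("precision, recall, F1 and macro-F1 follow their defining formulas", {
  # class 1: TP=8, FP=2, FN=2 -> precision = recall = F1 = 0.8
  recs <- tibble::tibble(
    truth = c(rep(1, 8), rep(2, 2), rep(1, 2), rep(2, 8)),
    pred = c(rep(1, 8), rep(1, 2), rep(2, 2), rep(2, 8))
  )
  met <- prf_accuracy(confusion_matrix(recs, truth, pred, k = 2))
  expect_equal(met$per_class$precision[1], 0.8)
  expect_equal(met$per_class$recall[1], 0.8)
  expect_equal(met$per_class$f1[1], 0.8)
  expect_equal(met$accuracy, 16 / 20)
  # macro-F1 is the unweighted mean of per-class F1
  expect_equal(met$macro_f1, mean(met$per_class$f1))
  expect_equal(mean(c(1, 0.5, 0.75)), 0.75)  # the rule at its simplest
})

test_that("metrics agree with an independent per-cell hand computation", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      recs <- random_records(60)
      cm <- confusion_matrix(recs, truth, pred, k = 4)
      met <- prf_accuracy(cm)
      m <- unclass(cm)
      total <- sum(m)
      acc_o <- sum(diag(m)) / total
      f1s <- numeric(4)
      for (c in 1:4) {
        tp <- m[c, c]; fp <- sum(m[, c]) - tp; fn <- sum(m[c, ]) - tp
        p <- if (tp + fp == 0) 0 else tp / (tp + fp)
        r <- if (tp + fn == 0) 0 else tp / (tp + fn)
        f1s[c] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
        expect_equal(met$per_class$tn[c], total - tp - fp - fn)
      }
      expect_equal(met$accuracy, acc_o, tolerance = 1e-12)
      expect_equal(met$macro_f1, mean(f1s), tolerance = 1e-12)
    }
  })
})

test_that("zero-denominator cells report 0 with a note", {
  recs <- tibble::tibble(truth = c(1, 1, 2), pred = c(1, 1, 1))
  expect_message(met <- prf_accuracy(confusion_matrix(recs, truth, pred,
                                                      k = 2)),
                 "reported as 0")
  expect_equal(met$per_class$precision[2], 0)
})

test_that("AUC hits the perfect and random limits", {
  perfect <- tibble::tibble(truth = rep(1:2, each = 5),
                            pred = rep(1:2, each = 5),
                            score_1 = c(5:1 + 10, 5:1),
                            score_2 = c(5:1, 5:1 + 10))
  r <- roc_auc(perfect, truth)
  expect_equal(r$auc$auc, c(1, 1))
  flat <- tibble::tibble(truth = rep(1:2, each = 5), pred = 1,
                         score_1 = 1, score_2 = 1)
  expect_equal(roc_auc(flat, truth)$auc$auc, c(0.5, 0.5))
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      n <- 20L
      truth <- sample(1:2, n, replace = TRUE, prob = c(0.4, 0.6))
      if (length(unique(truth)) < 2) next
      s <- round(rnorm(n), 1)  # rounding forces ties
      recs <- tibble::tibble(truth = truth, pred = truth,
                             score_1 = s, score_2 = -s)
      got <- roc_auc(recs, truth)$auc$auc[1]
      pos <- truth == 1
      rk <- rank(s)
      n1 <- sum(pos); n0 <- sum(!pos)
      u <- sum(rk[pos]) - n1 * (n1 + 1) / 2
      expect_equal(got, u / (n1 * n0), tolerance = 1e-12)
    }
  })
})

test_that("record order never changes any metric", {
  withr::with_seed(4, {
    recs <- random_records(50)
    perm <- recs[sample(50), ]
    a <- metric_report(recs, truth, pred)
    b <- metric_report(perm, truth, pred)
    expect_identical(unclass(a$confusion), unclass(b$confusion))
    expect_equal(a$metrics$macro_f1, b$metrics$macro_f1)
    expect_equal(a$roc$auc$auc, b$roc$auc$auc)
  })
})

test_that("a class absent from the truth is dropped from the macro AUC with a warning", {
  recs <- tibble::tibble(truth = c(1, 1, 2, 2), pred = c(1, 1, 2, 2),
                         score_1 = c(3, 2, 1, 0), score_2 = c(0, 1, 2, 3),
                         score_3 = c(1, 1, 1, 1))
  expect_warning(r <- roc_auc(recs, truth), "absent")
  expect_true(is.na(r$auc$auc[3]))
  expect_equal(r$macro_auc, mean(r$auc$auc[1:2]))
})

test_that("per-class AUC matches pROC on a randomized four-class toy", {
  withr::with_seed(5, {
    recs <- random_records(80)
    r <- roc_auc(recs, truth)
    for (cls in 1:4) {
      ref <- suppressMessages(pROC::auc(
        response = as.integer(recs$truth == cls),
        predictor = recs[[paste0("score_", cls)]],
        direction = "<", quiet = TRUE))
      expect_equal(r$auc$auc[cls], as.numeric(ref), tolerance = 1e-12)
    }
  })
})

test_that("row-normalized confusion and tidiers expose consistent views", {
  withr::with_seed(6, {
    recs <- random_records(40)
    repo <- metric_report(recs, truth, pred)
    norm <- wfpn:::normalize_confusion(repo$confusion)
    expect_equal(unname(rowSums(norm)), rep(1, 4))
    td <- tidy(repo)
    expect_true(all(c("precision", "recall", "f1", "auc") %in% names(td)))
    gl <- glance(repo)
    expect_equal(gl$accuracy, repo$metrics$accuracy)
    expect_equal(nrow(tidy(repo$confusion)), 16L)
    # writers round-trip
    dir <- withr::local_tempdir()
    write_metrics(repo, dir)
    expect_true(all(file.exists(file.path(dir, c("confusion.csv",
                                                 "metrics.json",
                                                 "roc_stage1.csv")))))
    js <- jsonlite::read_json(file.path(dir, "metrics.json"))
    expect_equal(js$accuracy, repo$metrics$accuracy)
  })
})
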