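test_that("mse follows the definition", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  expect_equal(mse(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_error(mse(numeric(), numeric()), class = "affipose_invalid_input")
})

test_that("concordance index credits ties 0.5 over strictly ordered label pairs", {
  expect_equal(concordance_index(1:5, 1:5 * 2), 1)
  expect_equal(concordance_index(1:5, 5:1), 0)
  expect_equal(concordance_index(c(1, 2, 3), c(5, 5, 6)), 2.5 / 3)
  expect_error(concordance_index(c(1, 1, 1), c(1, 2, 3)),
               class = "affipose_undefined_metric")
  expect_error(concordance_index(1, 1), class = "affipose_invalid_input")
})

test_that("concordance index equals the exhaustive pair oracle and is rank invariant", {
  oracle_ci <- function(y, yhat) {
    num <- 0; z <- 0
    for (i in seq_along(y)) for (j in seq_along(y)) {
      if (y[i] > y[j]) {
        z <- z + 1
        if (yhat[i] > yhat[j]) num <- num + 1
        else if (yhat[i] == yhat[j]) num <- num + 0.5
      }
    }
    num / z
  }
  set.seed(1)
  for (k in 1:10) {
    n <- sample(5:60, 1)
    y <- sample(1:8, n, replace = TRUE)          # ties in both vectors
    yhat <- round(rnorm(n), 1)
    expect_identical(concordance_index(y, yhat), oracle_ci(y, yhat))
    # strictly increasing transform of predictions leaves CI unchanged
    expect_identical(concordance_index(y, exp(yhat / 2)),
                     concordance_index(y, yhat))
  }
})

test_that("rm-squared follows the origin-regression definition with clipping", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(rm_squared(y, y)), 1)
  # independent closed-form evaluation for a fixed printed vector pair
  yhat <- c(1.2, 1.9, 3.4, 3.8, 5.4)
  r2 <- cor(y, yhat)^2
  k <- sum(y * yhat) / sum(y^2)
  r02 <- 1 - sum((yhat - k * y)^2) / sum((yhat - mean(yhat))^2)
  expect_equal(as.numeric(rm_squared(y, yhat)),
               r2 * (1 - sqrt(r2 - r02)), tolerance = 1e-12)
  # rm2 <= R2 always: the origin fit is a constrained affine fit, so the
  # radicand R2 - R02 is nonnegative up to rounding and the clip keeps the
  # metric real
  set.seed(4)
  for (k in 1:20) {
    yy <- rnorm(8, 5); yy_hat <- 1.3 * yy + rnorm(8, 0, 0.4)
    v <- rm_squared(yy, yy_hat)
    expect_true(is.finite(v))
    expect_lte(as.numeric(v), cor(yy, yy_hat)^2 + 1e-12)
  }
  # exactly proportional predictions: radicand 0, rm2 equals R2 (= 1)
  prop <- rm_squared(y, pi * y)
  expect_equal(as.numeric(prop), 1, tolerance = 1e-12)
  expect_error(rm_squared(c(1, 1, 1), c(1, 2, 3)),
               class = "affipose_undefined_metric")
})

test_that("pearson and spearman follow their invariances", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson(y, 2 * y + 1), 1)
  expect_equal(spearman(y, exp(y)), 1)           # monotone transform
  expect_equal(spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_error(pearson(c(1, 1), c(1, 2)), class = "affipose_undefined_metric")
})

test_that("Top1 selects the best-scored pose with the inclusive 2 Angstrom rule", {
  three <- list(
    a = list(predicted_score = c(0.5, 2.0), true_rmsd = c(1.0, 0.2)),
    b = list(predicted_score = c(1.0, 0.2), true_rmsd = c(0.4, 2.5)),
    c = list(predicted_score = c(3, 1), true_rmsd = c(4.0, 0.5)))
  t1 <- top1_success_rate(three)
  expect_equal(t1$rate, 2 / 3)
  expect_equal(t1$per_complex$success, c(TRUE, FALSE, TRUE))
  # exactly 2.0 Angstrom counts as success
  edge <- top1_success_rate(list(x = list(predicted_score = 1, true_rmsd = 2.0)))
  expect_equal(edge$rate, 1)
  # perfect predictions
  perf <- top1_success_rate(list(x = list(predicted_score = c(1, 2),
                                          true_rmsd = c(0, 3))))
  expect_equal(perf$rate, 1)
  # ties break to the lowest pose index
  tie <- top1_success_rate(list(x = list(predicted_score = c(1, 1),
                                         true_rmsd = c(5, 0))))
  expect_equal(tie$per_complex$top1_pose, 1L)
  expect_error(top1_success_rate(list(x = list(predicted_score = numeric(),
                                               true_rmsd = numeric()))),
               class = "affipose_invalid_input")
})

test_that("Top1 is invariant to pose ordering within a complex", {
  set.seed(2)
  for (k in 1:5) {
    scores <- rnorm(6); rmsds <- runif(6, 0, 4)
    base <- top1_success_rate(list(x = list(predicted_score = scores,
                                            true_rmsd = rmsds)))$rate
    perm <- sample(6)
    expect_equal(top1_success_rate(list(x = list(predicted_score = scores[perm],
                                                 true_rmsd = rmsds[perm])))$rate,
                 base)
  }
})

test_that("metric reports include only applicable fields and serialize to JSON", {
  rep <- evaluate_metrics(y = c(5, 6, 7, 8), yhat = c(5.1, 6.2, 6.8, 8.3))
  expect_true(all(c("mse", "ci", "pcc", "scc", "rm2") %in% names(rep)))
  expect_false("top1_success_rate" %in% names(rep))
  rep2 <- evaluate_metrics(pose_sets = list(a = list(predicted_score = 1,
                                                     true_rmsd = 1)))
  expect_false("mse" %in% names(rep2))
  expect_equal(rep2$top1_success_rate, 1)
  f <- tempfile(fileext = ".json")
  ft <- tempfile(fileext = ".tsv")
  write_metric_report(rep2, f, ft)
  j <- jsonlite::read_json(f)
  expect_equal(j$top1_success_rate, 1)
  expect_true(file.exists(ft))
})
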