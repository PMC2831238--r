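test_that("mutual information matches hand-computed joint tables", {
  y <- rep(c(-1, 1), each = 10)
  # feature identical to the label, two occupied bins, balanced classes:
  # I = log 2 nats
  expect_equal(mutual_information(as.numeric(y), y, n_bins = 2), log(2))
  # constant feature carries no information
  expect_equal(mutual_information(rep(3.7, 20), y), 0)
  # hand-computed 2x2 joint: 8/10 of class -1 in low bin
  v <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  jt <- matrix(c(8, 2, 2, 8) / 20, 2)
  expected <- sum(jt * log(jt / outer(rowSums(jt), colSums(jt))))
  expect_equal(mutual_information(v, y, n_bins = 2), expected)
  expect_error(mutual_information(v, rep(1, 20)), "constant")
})

test_that("permuting an informative feature destroys its mutual information", {
  set.seed(101)
  y <- rep(c(-1, 1), each = 30)
  v <- y + rnorm(60, sd = 0.5)
  mi0 <- mutual_information(v, y)
  mi_perm <- replicate(100, mutual_information(sample(v), y))
  expect_gt(mi0, mean(mi_perm))
})

test_that("the SVM dual solution satisfies its constraints and objective identity", {
  set.seed(110)
  em <- toy_expression(cbind(rep(c(-1, 1), each = 10) * 2 + rnorm(20, sd = 0.1),
                             rnorm(20)),
                       rep(c(-1, 1), each = 10))
  fit <- fit_svm(em, c("f1", "f2"), regularization = 10)
  expect_true(all(fit$alpha >= -1e-8 & fit$alpha <= 10 + 1e-8))
  expect_lt(abs(sum(fit$alpha * em$labels)), 1e-6)
  # objective recomputed independently from alpha equals the stored one
  ay <- fit$alpha * em$labels
  K <- tcrossprod(em$values[, c("f1", "f2")])
  expect_equal(fit$objective,
               sum(fit$alpha) - 0.5 * as.numeric(t(ay) %*% K %*% ay),
               tolerance = 1e-10)
  # feature order within the subset does not change the objective
  fit_r <- fit_svm(em, c("f2", "f1"), regularization = 10)
  expect_equal(fit_r$objective, fit$objective, tolerance = 1e-8)
  expect_error(fit_svm(em, "nope"), "unknown feature")
})

test_that("duplicating every sample leaves the decision function unchanged", {
  set.seed(115)
  x <- cbind(rep(c(-1, 1), each = 8) + rnorm(16, sd = 0.4), rnorm(16))
  em1 <- toy_expression(x, rep(c(-1, 1), each = 8))
  em2 <- toy_expression(x[rep(1:16, 2), ], rep(c(-1, 1), each = 8)[rep(1:16, 2)])
  f1 <- fit_svm(em1, c("f1", "f2"))
  f2 <- fit_svm(em2, c("f1", "f2"))
  w1 <- colSums(f1$alpha * em1$labels * em1$values)
  w2 <- colSums(f2$alpha * em2$labels * em2$values)
  expect_equal(w1, w2, tolerance = 1e-4)
})

test_that("empty-subset fits satisfy the dual constraints exactly", {
  em <- toy_expression(matrix(rnorm(30), 10, 3),
                       rep(c(-1, 1), times = c(4, 6)))
  f0 <- fit_svm(em, character(0), regularization = 2)
  expect_length(f0$features, 0)
  expect_lt(abs(sum(f0$alpha * em$labels)), 1e-12)
  expect_true(all(f0$alpha > 0 & f0$alpha <= 2 + 1e-12))
  expect_equal(f0$objective, sum(f0$alpha))
})

test_that("marginal power equals the literal objective difference and closed form", {
  set.seed(120)
  for (rep in 1:20) {
    n <- sample(c(12, 20, 30), 1)
    em <- toy_expression(matrix(rnorm(n * 6), n, 6), rep(c(-1, 1), n / 2))
    sel <- c("f1", "f2")
    fit <- fit_svm(em, sel, regularization = sample(c(0.5, 1, 5), 1))
    for (cand in c("f3", "f4", "f5")) {
      dj <- marginal_power(em, fit, sel, cand)
      expect_lte(dj, 0)
      expect_equal(dj, oracle_delta_j_literal(em, fit, sel, cand),
                   tolerance = 1e-9)
      w <- sum(fit$alpha * em$labels * em$values[, cand])
      expect_equal(dj, -0.5 * w^2, tolerance = 1e-12)
    }
  }
})

test_that("marginal power is zero for a null column and -w^2/2 for a copy", {
  set.seed(125)
  x <- cbind(rep(c(-1, 1), each = 10) + rnorm(20, sd = 0.3),
             0,                      # null candidate
             NA)
  x[, 3] <- x[, 1]                   # duplicate of the selected column
  em <- toy_expression(x, rep(c(-1, 1), each = 10))
  fit <- fit_svm(em, "f1")
  expect_identical(marginal_power(em, fit, "f1", "f2"), 0)
  w1 <- sum(fit$alpha * em$labels * em$values[, "f1"])
  expect_equal(marginal_power(em, fit, "f1", "f3"), -0.5 * w1^2,
               tolerance = 1e-12)
  expect_error(marginal_power(em, fit, c("f1", "f2"), "f3"), "not trained")
})

test_that("candidate ranking matches a full-sort oracle and breaks ties by id", {
  set.seed(130)
  em <- toy_expression(matrix(rnorm(40 * 50), 40, 50), rep(c(-1, 1), 20))
  fit <- fit_svm(em, "f1")
  pool <- setdiff(feature_ids(em), "f1")
  top <- rank_candidates(em, fit, "f1", pool, t = 10)
  expect_equal(nrow(top), 10)
  scores <- vapply(pool, function(m) abs(marginal_power(em, fit, "f1", m)),
                   numeric(1))
  oracle <- pool[order(-scores, pool)][1:10]
  expect_equal(top$feature, oracle)
  expect_true(all(diff(top$score) <= 1e-15))
  # all-tied candidates: identical columns -> first t in id order
  emt <- toy_expression(matrix(rep(rnorm(20), 5), 20, 5),
                        rep(c(-1, 1), 10))
  fitt <- fit_svm(emt, "f1")
  tied <- rank_candidates(emt, fitt, "f1", c("f4", "f2", "f5", "f3"), t = 2)
  expect_equal(tied$feature, c("f2", "f3"))
  expect_warning(rank_candidates(em, fit, "f1", pool[1:3], t = 10), "exceeds")
})

test_that("retrained delta J differs from fixed-multiplier delta J and can be positive", {
  set.seed(135)
  em <- toy_expression(cbind(rnorm(20),
                             rep(c(-1, 1), each = 10) * 1.5 + rnorm(20, sd = .3)),
                       rep(c(-1, 1), each = 10))
  fit <- fit_svm(em, "f1")
  rt <- rank_candidates(em, fit, "f1", "f2", t = 1, retrain_per_candidate = TRUE)
  fx <- rank_candidates(em, fit, "f1", "f2", t = 1)
  # retraining re-optimizes, so the objective can only go down or stay
  expect_lte(rt$delta_j, 1e-8)
  expect_false(isTRUE(all.equal(rt$delta_j, fx$delta_j)))
})
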