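test_that("AUC equals brute-force pairwise counting with 0.5 tie credit", {
  # hand-listed 6 cases vs 6 controls with ties
  scores <- c(3.1, 2.0, 2.0, 5.5, 4.2, 1.0,   # cases
              2.0, 1.0, 0.5, 3.1, 2.5, 0.0)   # controls
  labels <- rep(c(TRUE, FALSE), each = 6)
  brute <- 0
  for (i in which(labels)) for (j in which(!labels))
    brute <- brute + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_identical(auc_score(scores, labels), brute / 36)

  expect_equal(auc_score(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(2, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(auc_score(1:4, rep(TRUE, 4)), "both classes")

  # random data, parameterised over tie structure
  set.seed(31)
  for (r in 1:20) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    brute <- mean(outer(s[y == 1], s[y == 0],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_score(s, y), brute)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  s <- rnorm(80); y <- rbinom(80, 1, 0.3)
  expect_equal(auc_score(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("ROC curve is consistent with the Mann-Whitney AUC", {
  s <- c(0.9, 0.8, 0.8, 0.3, 0.2); y <- c(1, 1, 0, 1, 0)
  roc <- roc_curve(s, y)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_lt(abs(roc_auc(roc) - auc_score(s, y)), 1e-12)

  # perfect separation passes through (0, 1)
  rp <- roc_curve(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_true(any(rp$fpr == 0 & rp$tpr == 1))

  set.seed(33)
  for (r in 1:20) {
    s <- sample(seq(0, 1, 0.2), 40, replace = TRUE)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_lt(abs(roc_auc(roc_curve(s, y)) - auc_score(s, y)), 1e-12)
  }
})

test_that("pointwise logistic fits attain the grid-search likelihood optimum", {
  # 8-row toy, 3 parameters
  X <- cbind(1, c(90, 95, 100, 92, 96, 88, 103, 97),
             c(61, 72, 66, 78, 64, 70, 75, 68))
  y <- c(0, 0, 1, 1, 0, 0, 1, 1)
  fit <- retinocog:::logistic_fit(X, y)
  ll_hat <- logistic_loglik(fit$coef, X, y)
  # coarse independent grid around plausible values, refined near optimum
  Xs <- scale(X[, 2:3])
  fs <- retinocog:::logistic_fit(cbind(1, Xs), y)
  grid <- expand.grid(b0 = seq(-3, 3, 0.25),
                      b1 = seq(-5, 5, 0.25), b2 = seq(-5, 5, 0.25))
  ll_grid <- max(apply(grid, 1, function(b)
    logistic_loglik(b, cbind(1, Xs), y)))
  ll_hat_s <- logistic_loglik(fs$coef, cbind(1, Xs), y)
  expect_gte(ll_hat_s, ll_grid - 1e-6)
  # and the unscaled fit reproduces glm()
  gf <- suppressWarnings(glm(y ~ X[, 2] + X[, 3], family = binomial()))
  expect_equal(unname(fit$coef), unname(coef(gf)), tolerance = 1e-6)
  expect_equal(ll_hat, as.numeric(logLik(gf)), tolerance = 1e-8)
})

test_that("permuted labels give null-calibrated pointwise logistic maps", {
  cfg <- quick_config(n_participants = 200, seed = 41, classify = TRUE,
                      effect_map = list())
  ch <- align_orientation(generate_cohort(cfg))
  set.seed(42)
  ch$participants$dx_mci <- sample(ch$participants$dx_mci)
  res <- fit_pointwise_logistic(ch, "dx_mci")
  expect_s3_class(res, "pointwise_result")
  frac_raw <- mean(res$p_value[!res$unfit] < 0.05)
  expect_lt(frac_raw, 0.25)            # spatially correlated, hence loose
  expect_lt(significant_fraction(res), 5)
  expect_true(all(res$auc[!res$unfit] > 0.5))  # in-sample optimism
})

test_that("a simulated case thinning is localised by the logistic map", {
  hits <- vapply(1:3, function(r) {
    cfg <- sim_config(n_participants = 350, prob_both_eyes = 0.85,
                      seed = 500 + r, effect_map = list(),
                      dx_effect_map = list(dx_mci = list(
                        list(interval = c(45, 90), delta = -6))))
    ch <- align_orientation(generate_cohort(cfg))
    res <- fit_pointwise_logistic(ch, "dx_mci")
    sig <- which(res$significant & !res$unfit)
    in_arc <- res$angle_deg[sig] >= 45 & res$angle_deg[sig] < 90
    length(sig) > 0 && mean(in_arc) >= 0.7 &&
      all(res$coefficient[sig[in_arc]] < 0)
  }, logical(1))
  expect_true(all(hits))
})

test_that("permutation AUC inference is deterministic and well-behaved", {
  set.seed(51)
  n <- 120
  d <- data.frame(y = rbinom(n, 1, 0.3), x = rnorm(n), a = runif(n, 60, 79))
  p1 <- permutation_auc_pvalue(y ~ x + a, d, n_perm = 200, seed = 7)
  p2 <- permutation_auc_pvalue(y ~ x + a, d, n_perm = 200, seed = 7)
  expect_identical(p1$null_aucs, p2$null_aucs)
  expect_identical(p1$p_empirical, p2$p_empirical)
  # empirical p has the exchangeability floor 1/n_perm
  expect_gte(p1$p_empirical, 1 / 200)
  expect_lte(p1$p_empirical, 1)
  expect_equal(p1$n_used + p1$n_nonconverged, 200)

  # a strong true effect is detected
  d$y <- rbinom(n, 1, plogis(-1 + 3 * d$x))
  if (length(unique(d$y)) == 2) {
    ps <- permutation_auc_pvalue(y ~ x + a, d, n_perm = 200, seed = 7)
    expect_gt(ps$observed_auc, 0.8)
    expect_lte(ps$p_empirical, 0.01)
  }
})

test_that("subject-level shuffling keeps both eyes of a subject tied", {
  set.seed(52)
  n_subj <- 60
  subj <- rep(sprintf("S%02d", 1:n_subj), each = 2)
  y_subj <- rbinom(n_subj, 1, 0.3)
  d <- data.frame(y = y_subj[rep(1:n_subj, each = 2)], x = rnorm(2 * n_subj))
  ps <- permutation_auc_pvalue(y ~ x, d, n_perm = 100, seed = 3,
                               shuffle = "subject", subject = subj)
  expect_gte(ps$p_empirical, 1 / 100)
  # inconsistent within-subject labels are rejected
  d2 <- d; d2$y[1] <- 1 - d2$y[2]
  if (length(unique(d2$y)) == 2)
    expect_error(permutation_auc_pvalue(y ~ x, d2, n_perm = 10, seed = 1,
                                        shuffle = "subject", subject = subj),
                 "within subject")
})

test_that("type-I error of the permutation test is controlled under the null", {
  set.seed(53)
  reject <- vapply(1:40, function(r) {
    d <- data.frame(y = rbinom(70, 1, 0.3), x = rnorm(70))
    if (length(unique(d$y)) < 2) return(NA)
    permutation_auc_pvalue(y ~ x, d, n_perm = 60, seed = r)$p_empirical <= 0.05
  }, logical(1))
  reject <- reject[!is.na(reject)]
  mc_se <- sqrt(0.05 * 0.95 / length(reject))
  expect_lte(mean(reject), 0.05 + 2 * mc_se)
})
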