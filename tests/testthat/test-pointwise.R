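test_that("pointwise OLS matches the normal-equations oracle", {
  set.seed(11)
  n <- 10
  th <- matrix(95 + rnorm(n * 768, sd = 5), n, 768)
  z <- rnorm(n)
  ch <- make_toy_cohort(n, thickness = th, z = z)
  res <- fit_pointwise_linear(ch, "attention")
  expect_s3_class(res, "pointwise_result")
  expect_false(any(res$unfit))

  X <- cbind(1, z, ch$participants$age,
             as.numeric(ch$participants$sex == "male"),
             ch$eyes$scan_radius_mm,
             c(low = 1, intermediate = 2, high = 3)[ch$participants$education])
  XtXinv <- solve(t(X) %*% X)
  for (j in c(1, 97, 345, 768)) {
    beta <- XtXinv %*% t(X) %*% th[, j]
    resid <- th[, j] - X %*% beta
    s2 <- sum(resid^2) / (n - ncol(X))
    se <- sqrt(s2 * XtXinv[2, 2])
    expect_equal(res$coefficient[j], beta[2], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(res$se[j], se, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(res$p_value[j],
                 2 * pt(-abs(beta[2] / se), df = n - ncol(X)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("masked points drop the eye from that location only", {
  set.seed(12)
  n <- 20
  th <- matrix(95 + rnorm(n * 768, sd = 5), n, 768)
  ch <- make_toy_cohort(n, thickness = th, z = rnorm(n))
  ch$missing[3, 10] <- TRUE
  ch$unreliable[5, 10] <- TRUE
  res <- fit_pointwise_linear(ch, "attention")
  expect_equal(res$n[10], n - 2)
  expect_equal(res$n[11], n)
  # the reduced fit equals an oracle on the remaining rows
  keep <- setdiff(seq_len(n), c(3, 5))
  X <- cbind(1, ch$participants$z_attention, ch$participants$age,
             as.numeric(ch$participants$sex == "male"),
             ch$eyes$scan_radius_mm,
             c(low = 1, intermediate = 2,
               high = 3)[ch$participants$education])[keep, ]
  beta <- solve(t(X) %*% X, t(X) %*% th[keep, 10])
  expect_equal(res$coefficient[10], beta[2], tolerance = 1e-8)
})

test_that("BH adjustment reproduces the step-up procedure", {
  # hand-computed example
  adj <- fdr_adjust(c(0.01, 0.02, 0.03, 0.9))
  expect_equal(adj$q_value, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(adj$significant, c(TRUE, TRUE, TRUE, FALSE))
  # fixed point: identical p-values are their own adjustment
  adj <- fdr_adjust(rep(0.01, 768))
  expect_equal(adj$q_value, rep(0.01, 768))
  expect_true(all(adj$significant))
  # properties: adjusted >= raw, order preserved, empty family empty
  set.seed(13)
  p <- runif(50)
  adj <- fdr_adjust(p)
  expect_true(all(adj$q_value >= p))
  expect_equal(order(adj$q_value[order(p)]), seq_len(50))
  expect_length(fdr_adjust(numeric(0))$q_value, 0)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significant fractions use the requested denominator", {
  mask <- c(rep(TRUE, 75), rep(FALSE, 768 - 75))
  expect_equal(significant_fraction(mask), 100 * 75 / 768)
  expect_equal(round(significant_fraction(mask), 1), 9.8)
  expect_equal(significant_fraction(logical(768)), 0)
  expect_equal(significant_fraction(rep(TRUE, 768)), 100)

  set.seed(14)
  ch <- make_toy_cohort(12, z = rnorm(12))
  res <- fit_pointwise_linear(ch, "attention")
  res$significant[] <- FALSE
  res$significant[1:10] <- TRUE
  res$unfit[1:384] <- FALSE
  res$unfit[385:768] <- TRUE
  expect_equal(significant_fraction(res, "fitted"), 100 * 10 / 384)
  expect_equal(significant_fraction(res, "all"), 100 * 10 / 768)
})

test_that("sector summaries partition the circle and conserve counts", {
  set.seed(15)
  ch <- make_toy_cohort(12, z = rnorm(12))
  res <- fit_pointwise_linear(ch, "attention")
  res$significant <- res$angle_deg >= 45 & res$angle_deg < 90
  ss <- sector_summary(res, sector_scheme_6())
  expect_equal(sum(ss$n_locations), 768)
  expect_equal(sum(ss$n_significant), sum(res$significant))
  expect_equal(ss$n_significant[ss$label == "TS"], 96)
  expect_true(all(ss$n_significant[ss$label != "TS"] == 0))
  # uniform mask: equal per-sector fractions
  res$significant <- rep(c(TRUE, FALSE), 384)
  ss <- sector_summary(res, sector_scheme_6())
  expect_true(all(abs(ss$frac_significant - 0.5) < 1e-12))
})

test_that("global-mean regression matches its oracle and flags degeneracy", {
  set.seed(16)
  n <- 5
  th <- matrix(90 + rnorm(n * 768, sd = 4), n, 768)
  z <- rnorm(n)
  ch <- make_toy_cohort(n, thickness = th, z = z)
  gm <- fit_global_mean(ch, "attention", covariates = c("age"))
  X <- cbind(1, z, ch$participants$age)
  beta <- solve(t(X) %*% X, t(X) %*% rowMeans(th))
  expect_equal(unname(gm$beta), beta[2], tolerance = 1e-8)

  ch2 <- make_toy_cohort(n, thickness = matrix(95, n, 768), z = z)
  expect_error(fit_global_mean(ch2, "attention"), "degenerate")
})

test_that("permuting the domain score yields uniform raw p-values", {
  cfg <- quick_config(n_participants = 150, seed = 17, effect_map = list())
  ch <- align_orientation(generate_cohort(cfg))
  set.seed(99)
  fracs <- vapply(1:300, function(r) {
    ch$participants$z_attention <- sample(ch$participants$z_attention)
    res <- fit_pointwise_linear(ch, "attention")
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("effect recovery works on simulated cohorts", {
  cfg <- quick_config(n_participants = 400, seed = 21,
                      effect_map = list(attention = list(
                        list(interval = c(45, 135), beta = 1.5))))
  ch <- align_orientation(generate_cohort(cfg))
  res <- fit_pointwise_linear(ch, "attention")
  arc <- res$angle_deg >= 45 & res$angle_deg < 135
  expect_lt(abs(mean(res$coefficient[arc]) - 1.5), 0.3)
})

test_that("sex-stratified fits share the code path and bracket the pooled fit", {
  cfg <- quick_config(n_participants = 500, seed = 22,
                      effect_map = list(attention = list(
                        list(interval = c(45, 135), beta = 1.5))))
  ch <- align_orientation(generate_cohort(cfg))
  strat_covars <- c("age", "scan_radius", "education")
  arc_mean <- function(co, covars) {
    r <- fit_pointwise_linear(co, "attention", covariates = covars)
    mean(r$coefficient[r$angle_deg >= 45 & r$angle_deg < 135])
  }
  males <- subset_cohort(ch, subject_ids =
    ch$participants$subject_id[ch$participants$sex == "male"])
  females <- subset_cohort(ch, subject_ids =
    ch$participants$subject_id[ch$participants$sex == "female"])
  bm <- arc_mean(males, strat_covars)
  bf <- arc_mean(females, strat_covars)
  ba <- arc_mean(ch, c("age", "sex", "scan_radius", "education"))
  expect_gte(ba, min(bm, bf) - 0.1)
  expect_lte(ba, max(bm, bf) + 0.1)
})

test_that("cluster-robust and reversed-direction modes are coherent", {
  set.seed(23)
  cfg <- quick_config(n_participants = 150, seed = 23)
  ch <- align_orientation(generate_cohort(cfg))
  res <- fit_pointwise_linear(ch, "attention")
  resc <- fit_pointwise_linear(ch, "attention", cluster_se = TRUE)
  expect_equal(resc$coefficient, res$coefficient)   # same point estimates
  expect_true(all(resc$se > 0))
  expect_true(all(resc$p_value >= 0 & resc$p_value <= 1))
  resd <- fit_pointwise_linear(ch, "attention", direction = "domain_outcome")
  arc <- res$angle_deg >= 45 & res$angle_deg < 135
  # reversed regression keeps the sign of the association
  expect_gt(mean(sign(resd$coefficient[arc]) == sign(res$coefficient[arc])),
            0.9)
})
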