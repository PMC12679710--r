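test_that("tmt_ratio computes B/A and rejects non-positive times", {
  expect_equal(tmt_ratio(60, 30), 2.0)
  expect_equal(tmt_ratio(45, 45), 1.0)
  expect_equal(tmt_ratio(100, 40), 2.5)
  expect_equal(tmt_ratio(c(60, 90), c(30, 30)), c(2, 3))
  expect_error(tmt_ratio(60, 0), "positive")
  expect_error(tmt_ratio(-1, 30), "positive")
})

test_that("domain z-scores are standardised with timed tests sign-inverted", {
  set.seed(3)
  n <- 40
  p <- data.frame(tmt_a_s = runif(n, 25, 70), tmt_b_s = runif(n, 60, 200),
                  wordlist = sample(15:30, n, TRUE),
                  visuoconstruction = sample(6:11, n, TRUE),
                  verbal_fluency = sample(12:35, n, TRUE),
                  rmet = sample(15:30, n, TRUE))
  z <- zscore_domains(p)
  for (dom in c("attention", "executive", "memory", "perceptual_motor",
                "language", "social")) {
    zc <- z[[paste0("z_", dom)]]
    expect_equal(mean(zc), 0, tolerance = 1e-12)
    expect_equal(sd(zc), 1, tolerance = 1e-12)
  }
  # faster TMT-A (fewer seconds) must score higher
  expect_equal(z$z_attention, as.vector(scale(-p$tmt_a_s)))
  expect_equal(z$z_executive, as.vector(scale(-(p$tmt_b_s / p$tmt_a_s))))
  expect_gt(z$z_attention[which.min(p$tmt_a_s)],
            z$z_attention[which.max(p$tmt_a_s)])

  p$wordlist <- 20            # zero variance names the offending domain
  expect_error(zscore_domains(p), "memory")
})

test_that("norms equal whole-sample moments when there is one stratum", {
  set.seed(4)
  n <- 60
  p <- data.frame(subject_id = sprintf("S%02d", 1:n), age = runif(n, 60, 64),
                  sex = "female", education = "low",
                  tmt_a_s = runif(n, 25, 70), tmt_b_s = runif(n, 60, 200),
                  wordlist = sample(15:30, n, TRUE),
                  visuoconstruction = sample(6:11, n, TRUE),
                  verbal_fluency = sample(12:35, n, TRUE),
                  rmet = sample(15:30, n, TRUE))
  nt <- compute_norms(p, age_bands = c(60, 65), min_stratum_n = 10)
  expect_equal(nrow(nt), 6)
  att <- nt[nt$domain == "attention", ]
  expect_equal(att$mean, mean(-p$tmt_a_s))
  expect_equal(att$sd, sd(-p$tmt_a_s))
  expect_equal(unique(nt$n), n)
})

test_that("norm deviations are computed against the own stratum", {
  set.seed(5)
  mk <- function(sex, wl_mean, n = 30) {
    data.frame(subject_id = paste0(sex, 1:n), age = runif(n, 60, 64),
               sex = sex, education = "low",
               tmt_a_s = runif(n, 30, 50), tmt_b_s = runif(n, 70, 150),
               wordlist = round(rnorm(n, wl_mean, 3)),
               visuoconstruction = sample(6:11, n, TRUE),
               verbal_fluency = sample(12:35, n, TRUE),
               rmet = sample(15:30, n, TRUE))
  }
  p <- rbind(mk("female", 26), mk("male", 18))
  nt <- compute_norms(p, age_bands = c(60, 65), min_stratum_n = 10)
  nzf <- nt[nt$sex == "female" & nt$domain == "memory", ]
  nzm <- nt[nt$sex == "male" & nt$domain == "memory", ]
  expect_equal(nzf$mean, mean(p$wordlist[p$sex == "female"]))
  expect_equal(nzm$mean, mean(p$wordlist[p$sex == "male"]))
  # a male at the male mean deviates ~0 from his own stratum, but would be
  # far below the pooled mean
  p1 <- p[p$sex == "male", ][1, ]
  p1$wordlist <- round(nzm$mean)
  p1$subjective_decline <- FALSE; p1$sidam_adl <- 0
  cl <- classify_mci_ncd(rbind(cbind(p, subjective_decline = FALSE,
                                     sidam_adl = 0)[0, ], p1), nt)
  expect_lt(abs(cl$nz_memory), 0.5)
})

test_that("small strata merge until every stratum is large enough", {
  set.seed(6)
  n <- 43
  p <- data.frame(subject_id = sprintf("S%02d", 1:n),
                  age = c(runif(40, 60, 70), runif(3, 75, 79)),
                  sex = "female", education = "low",
                  tmt_a_s = runif(n, 25, 70), tmt_b_s = runif(n, 60, 200),
                  wordlist = sample(15:30, n, TRUE),
                  visuoconstruction = sample(6:11, n, TRUE),
                  verbal_fluency = sample(12:35, n, TRUE),
                  rmet = sample(15:30, n, TRUE))
  nt <- compute_norms(p, age_bands = seq(60, 80, 5), min_stratum_n = 20)
  expect_true(all(nt$n >= 20))
  # every participant still finds a stratum
  expect_silent(classify_mci_ncd(cbind(p, subjective_decline = FALSE,
                                       sidam_adl = 0), nt))
})

test_that("diagnostic criteria implement the deficit band and exclusions", {
  nt <- manual_norms()
  check <- function(shift, decline = TRUE, adl = 1) {
    classify_mci_ncd(norm_participant(shift, decline, adl), nt)
  }
  # isolated memory deficit: MCI and amnestic MCI
  r <- check(c(memory = -1.5))
  expect_true(r$dx_mci); expect_true(r$dx_amnestic_mci)
  expect_true(r$dx_mild_ncd); expect_true(r$dx_amnestic_mild_ncd)
  expect_false(r$dx_dementia_excluded)
  # dementia-range deviation in any domain excludes the diagnosis
  r <- check(c(language = -2.5))
  expect_true(r$dx_dementia_excluded); expect_false(r$dx_mci)
  # two deficit domains: still MCI but not amnestic
  r <- check(c(memory = -1.5, attention = -1.5))
  expect_true(r$dx_mci); expect_false(r$dx_amnestic_mci)
  # exactly -2 counts as deficit, just below -2 as exclusion
  r <- check(c(memory = -2))
  expect_true(r$dx_mci); expect_false(r$dx_dementia_excluded)
  r <- check(c(memory = -2.0001))
  expect_false(r$dx_mci); expect_true(r$dx_dementia_excluded)
  # without subjective decline or with lost independence: no diagnosis
  expect_false(check(c(memory = -1.5), decline = FALSE)$dx_mci)
  expect_false(check(c(memory = -1.5), adl = 2)$dx_mci)
  # amnestic flags imply the non-amnestic flag on a simulated cohort
  ch <- generate_cohort(sim_config(n_participants = 200, seed = 8))
  p <- ch$participants
  ok <- !is.na(p$dx_mci)
  expect_true(all(!p$dx_amnestic_mci[ok] | p$dx_mci[ok]))
  expect_true(all(!p$dx_amnestic_mild_ncd[ok] | p$dx_mild_ncd[ok]))
  # identical criteria configuration: MCI <=> mild NCD
  expect_identical(p$dx_mci, p$dx_mild_ncd)
})

test_that("missing scores yield unclassifiable, not silently negative", {
  p <- norm_participant(c(memory = -1.5))
  p$wordlist <- NA
  r <- classify_mci_ncd(p, manual_norms())
  expect_true(r$dx_unclassifiable)
  expect_true(is.na(r$dx_mci))
})

test_that("diagnosis cross-tabulation reproduces overlap arithmetic", {
  mk <- function(n_a, n_b, n_both, n_total) {
    a <- c(rep(TRUE, n_a), rep(FALSE, n_total - n_a))
    b <- c(rep(TRUE, n_both), rep(FALSE, n_a - n_both),
           rep(TRUE, n_b - n_both), rep(FALSE, n_total - n_a - (n_b - n_both)))
    data.frame(dx_mci = a, dx_mild_ncd = b)
  }
  ct <- crosstab_diagnoses(mk(136, 123, 120, 1000))
  expect_equal(ct$n_a_only, 16)
  expect_equal(ct$n_b_only, 3)
  ct <- crosstab_diagnoses(mk(94, 94, 91, 800))
  expect_equal(ct$n_a_only, 3)
  expect_equal(ct$n_b_only, 3)
  ct0 <- crosstab_diagnoses(data.frame(dx_mci = logical(0),
                                       dx_mild_ncd = logical(0)))
  expect_equal(unlist(ct0), c(n_a = 0, n_b = 0, n_both = 0,
                              n_a_only = 0, n_b_only = 0))
})
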