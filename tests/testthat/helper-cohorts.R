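# hand-buildable cohort: one eye per participant, covariates and domain
# z-scores settable directly, thickness defaults to a flat 95 um profile
make_toy_cohort <- function(n, thickness = NULL, z = NULL, dx = NULL,
                            age = NULL, sex = NULL, education = NULL,
                            radius = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(thickness))
    thickness <- matrix(95 + rnorm(n * 768), n, 768)
  part <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    age = age %||% runif(n, 60, 79),
    sex = sex %||% rep_len(c("female", "male"), n),
    education = education %||% rep_len(c("low", "intermediate", "high"), n),
    stringsAsFactors = FALSE)
  if (!is.null(z)) part$z_attention <- z
  if (!is.null(dx)) part$dx_mci <- dx
  eyes <- data.frame(
    eye_id = paste0(part$subject_id, "_r"),
    subject_id = part$subject_id,
    laterality = "right",
    scan_radius_mm = radius %||% rnorm(n, 1.73, 0.05),
    snr_db = 25, n_bscans = 80, oriented = TRUE,
    stringsAsFactors = FALSE)
  cohort(part, eyes, thickness)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulation config for fast tests; classification off unless needed
quick_config <- function(n_participants = 150, seed = 1, classify = FALSE,
                         ...) {
  sim_config(n_participants = n_participants, seed = seed,
             classify = classify, ...)
}

# single-stratum norm table with hand-set means/SDs of the oriented scores
manual_norms <- function(means = c(attention = -40, executive = -2,
                                   memory = 24, perceptual_motor = 9.5,
                                   language = 23, social = 22),
                         sds = c(attention = 10, executive = 0.5,
                                 memory = 4, perceptual_motor = 1.5,
                                 language = 5, social = 4),
                         sex = "female", education = "low") {
  doms <- names(means)
  out <- data.frame(sex = sex, education = education,
                    age_lo = -Inf, age_hi = Inf, domain = doms,
                    mean = unname(means), sd = unname(sds), n = 100,
                    stringsAsFactors = FALSE)
  class(out) <- c("norm_table", "data.frame")
  out
}

# a participant whose oriented scores sit exactly at the manual_norms means,
# shifted by `shift` (in SD units) for the named domains
norm_participant <- function(shift = c(), subjective_decline = TRUE,
                             sidam_adl = 1) {
  m <- c(attention = -40, executive = -2, memory = 24,
         perceptual_motor = 9.5, language = 23, social = 22)
  s <- c(attention = 10, executive = 0.5, memory = 4,
         perceptual_motor = 1.5, language = 5, social = 4)
  val <- m
  for (d in names(shift)) val[d] <- m[d] + shift[d] * s[d]
  tmt_a <- -val["attention"]
  data.frame(subject_id = "P1", age = 70, sex = "female", education = "low",
             tmt_a_s = tmt_a, tmt_b_s = -val["executive"] * tmt_a,
             wordlist = val["memory"],
             visuoconstruction = val["perceptual_motor"],
             verbal_fluency = val["language"], rmet = val["social"],
             mmse = 28, subjective_decline = subjective_decline,
             sidam_adl = sidam_adl, stringsAsFactors = FALSE)
}

# log-likelihood of a logistic model, for independent grid-search oracles
logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}
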