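#' Configuration for the synthetic cohort generator
#'
#' Defaults describe an ageing population cohort (60-79 years) scanned with a
#' circumpapillary OCT protocol: a double-hump TSNIT baseline profile with
#' peaks near the superior and inferior poles, age-related thinning, a small
#' sex offset, a scan-radius (ocular magnification) effect, angularly
#' correlated measurement noise, and a location-restricted association
#' between attention performance and thickness in the temporal-superior to
#' nasal-superior arc. Cognitive raw scores are generated with a latent-factor
#' model in which trail-making time (TMT-A) and the TMT B/A ratio are
#' negatively correlated.
#'
#' @param n_participants number of participants.
#' @param prob_both_eyes probability that both eyes of a participant are
#'   scanned (otherwise one eye, random side).
#' @param age_range ages drawn uniformly on `[low, high]` years.
#' @param sex_ratio probability of male sex.
#' @param education_probs probabilities of CASMIN low/intermediate/high;
#'   must sum to 1.
#' @param baseline_shape_params list with `offset` (um) and vectors
#'   `amplitudes` (um), `centres` (degrees from temporal midline) and
#'   `widths` (degrees) of the Gaussian bumps forming the TSNIT double hump.
#' @param age_slope thickness change per year of age (um/yr).
#' @param sex_offset additive thickness for males (um).
#' @param radius_slope thickness change per mm of scan radius (um/mm).
#' @param education_slope thickness change per CASMIN level (um/level).
#' @param age_ref,radius_ref centring constants: the baseline profile refers
#'   to a female participant of `age_ref` years scanned at `radius_ref` mm.
#' @param scan_radius_sd between-eye SD of the scan radius (mm).
#' @param noise_sd_white SD of white (independent per location) noise, um.
#' @param noise_sd_smooth SD of the regional angularly correlated noise
#'   component, um.
#' @param noise_correlation_length Gaussian kernel length of the regional
#'   smooth component, degrees.
#' @param noise_sd_local SD of the short-range local anatomical variability
#'   component, um.
#' @param local_correlation_length Gaussian kernel length of the local
#'   component, degrees.
#' @param subject_offset_sd SD of the per-eye global thickness offset, um.
#'   Together the four noise components emulate the between-subject
#'   anatomical variability of real profiles at several angular scales
#'   (per-point SD roughly 8 um at the defaults).
#' @param missing_rate per-location probability of an acquisition-missing
#'   point.
#' @param snr_mean,snr_sd scan signal-to-noise ratio distribution (dB).
#' @param bscans_mean,bscans_sd averaged B-scan count distribution.
#' @param effect_map named list (by cognitive domain) of effect entries, each
#'   `list(interval = c(lo, hi), beta = um_per_z)`: thickness gains
#'   `beta * domain_z` inside the angular interval (degrees, half-open,
#'   wrapping allowed).
#' @param dx_effect_map named list (by diagnosis flag column, e.g. `dx_mci`)
#'   of entries `list(interval = c(lo, hi), delta = um)` added to carriers.
#' @param tmt_params trail-making generator: log-scale means/SDs of TMT-A
#'   seconds and of the B/A ratio, the latent correlation `cor_a_ratio`
#'   between them, and age/education slopes on the log scale.
#' @param score_params per-test list `c(mean, sd, age, edu, min, max)` for the
#'   remaining raw scores (word-list learning, visuoconstruction copy,
#'   semantic verbal fluency, RMET, MMSE).
#' @param diagnosis_params subjective-decline fraction, SIDAM-ADL score
#'   probabilities (0/1/2), CNS-condition and eye-disease flag rates, and the
#'   age-band width / minimum stratum size used for norm tables.
#' @param classify if TRUE (default) diagnosis flags are derived by running
#'   [classify_mci_ncd()] on the simulated scores, so simulator and
#'   classifier cannot drift apart.
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 300,
                       prob_both_eyes = 0.85,
                       age_range = c(60, 79),
                       sex_ratio = 0.5,
                       education_probs = c(low = 0.20, intermediate = 0.55,
                                           high = 0.25),
                       baseline_shape_params = list(
                         offset = 60,
                         amplitudes = c(70, 75),
                         centres = c(75, 285),
                         widths = c(40, 45)),
                       age_slope = -0.2,
                       sex_offset = 2,
                       radius_slope = -15,
                       education_slope = 0.5,
                       age_ref = 70,
                       radius_ref = 1.73,
                       scan_radius_sd = 0.05,
                       noise_sd_white = 2,
                       noise_sd_smooth = 3,
                       noise_correlation_length = 15,
                       noise_sd_local = 4,
                       local_correlation_length = 5,
                       subject_offset_sd = 6,
                       missing_rate = 0.003,
                       snr_mean = 25, snr_sd = 3,
                       bscans_mean = 85, bscans_sd = 18,
                       effect_map = list(
                         attention = list(list(interval = c(45, 135),
                                               beta = 1.5))),
                       dx_effect_map = list(),
                       tmt_params = list(
                         log_a_mean = log(40), log_a_sd = 0.25,
                         log_ratio_mean = log(2.2), log_ratio_sd = 0.25,
                         cor_a_ratio = -0.21,
                         age_slope_log_a = 0.008,
                         age_slope_log_ratio = 0.004,
                         education_slope_log_a = -0.03),
                       score_params = list(
                         wordlist = c(mean = 24, sd = 3.5, age = -0.08,
                                      edu = 0.5, min = 0, max = 30),
                         visuoconstruction = c(mean = 9.5, sd = 1.3,
                                               age = -0.03, edu = 0.2,
                                               min = 0, max = 11),
                         verbal_fluency = c(mean = 23, sd = 5.5, age = -0.15,
                                            edu = 1.5, min = 0, max = 60),
                         rmet = c(mean = 22, sd = 3.5, age = -0.08,
                                  edu = 0.8, min = 0, max = 36),
                         mmse = c(mean = 28.3, sd = 1.2, age = -0.05,
                                  edu = 0.3, min = 0, max = 30)),
                       diagnosis_params = list(
                         frac_subjective_decline = 0.3,
                         adl_probs = c(0.75, 0.20, 0.05),
                         cns_rate = 0.15,
                         eye_disease_rate = 0.05,
                         age_band_width = 5,
                         min_stratum_n = 20),
                       classify = TRUE,
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              prob_both_eyes = prob_both_eyes, age_range = age_range,
              sex_ratio = sex_ratio, education_probs = education_probs,
              baseline_shape_params = baseline_shape_params,
              age_slope = age_slope, sex_offset = sex_offset,
              radius_slope = radius_slope, education_slope = education_slope,
              age_ref = age_ref, radius_ref = radius_ref,
              scan_radius_sd = scan_radius_sd,
              noise_sd_white = noise_sd_white,
              noise_sd_smooth = noise_sd_smooth,
              noise_correlation_length = noise_correlation_length,
              noise_sd_local = noise_sd_local,
              local_correlation_length = local_correlation_length,
              subject_offset_sd = subject_offset_sd,
              missing_rate = missing_rate,
              snr_mean = snr_mean, snr_sd = snr_sd,
              bscans_mean = bscans_mean, bscans_sd = bscans_sd,
              effect_map = effect_map, dx_effect_map = dx_effect_map,
              tmt_params = tmt_params, score_params = score_params,
              diagnosis_params = diagnosis_params,
              classify = isTRUE(classify), seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  if (abs(sum(cfg$education_probs) - 1) > 1e-9)
    stop("education_probs must sum to 1")
  if (length(cfg$education_probs) != 3 || any(cfg$education_probs < 0))
    stop("education_probs must be a non-negative 3-vector")
  if (cfg$age_range[1] >= cfg$age_range[2])
    stop("age_range must satisfy low < high")
  sds <- c(cfg$noise_sd_white, cfg$noise_sd_smooth, cfg$noise_sd_local,
           cfg$subject_offset_sd, cfg$scan_radius_sd,
           cfg$snr_sd, cfg$bscans_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  for (p in c(cfg$prob_both_eyes, cfg$sex_ratio, cfg$missing_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  for (map in c(cfg$effect_map, cfg$dx_effect_map))
    for (entry in map) {
      iv <- entry$interval
      if (length(iv) != 2 || any(iv < 0) || any(iv >= 360))
        stop("effect-map intervals must lie within [0, 360)")
    }
  # the baseline must be strictly positive everywhere
  baseline_profile(profile_angles(), cfg$baseline_shape_params)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_participants, "participants, seed", x$seed, "\n")
  cat("  effects:", if (length(x$effect_map))
    paste(names(x$effect_map), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Baseline TSNIT thickness profile
#'
#' Builds the noise-free double-hump cpRNFLT profile as a constant offset plus
#' circular Gaussian bumps (typically one superior and one inferior peak).
#'
#' @param angles angular grid in degrees, equidistant on `[0, 360)`
#'   (see [profile_angles()]).
#' @param params list with `offset`, `amplitudes`, `centres`, `widths`
#'   (see [sim_config()]).
#' @return strictly positive thickness vector (um), circularly continuous.
#' @export
baseline_profile <- function(angles, params) {
  stopifnot(is.numeric(angles), length(angles) > 0)
  step <- diff(angles)
  if (length(step) && (any(abs(step - step[1]) > 1e-9) || angles[1] != 0))
    stop("angles must be equidistant starting at 0")
  prof <- rep(params$offset, length(angles))
  k <- length(params$amplitudes %||% numeric(0))
  if (k > 0) {
    stopifnot(length(params$centres) == k, length(params$widths) == k)
    for (j in seq_len(k)) {
      d <- circ_diff(angles, params$centres[j])
      prof <- prof + params$amplitudes[j] *
        exp(-0.5 * (d / params$widths[j])^2)
    }
  }
  if (any(prof <= 0))
    stop("invalid baseline shape: profile not strictly positive")
  prof
}

#' Generate raw cognitive scores
#'
#' Latent-factor generator for the neuropsychological battery. TMT-A seconds
#' and the TMT B/A ratio are log-normal; their logs share a configurable
#' latent correlation (`cor_a_ratio`, negative by default) so that slower
#' simple processing speed co-occurs with a relatively smaller B/A ratio, as
#' observed empirically. The remaining scores are Gaussian with age and
#' education slopes, rounded and clamped to their instrument ranges.
#'
#' @param participants data.frame with `age` and `education`
#'   (`"low"`/`"intermediate"`/`"high"` or 1/2/3).
#' @param tmt_params,score_params see [sim_config()].
#' @param seed integer seed (per-participant substreams are derived from it,
#'   so scores are reproducible under reordering).
#' @return `participants` with columns `tmt_a_s`, `tmt_b_s`, `wordlist`,
#'   `visuoconstruction`, `verbal_fluency`, `rmet`, `mmse` appended.
#' @export
generate_cognition <- function(participants,
                               tmt_params = sim_config()$tmt_params,
                               score_params = sim_config()$score_params,
                               seed = 1L) {
  n <- nrow(participants)
  age <- participants$age
  edu <- education_ordinal(participants$education)
  tp <- tmt_params
  if (abs(tp$cor_a_ratio) > 1) stop("cor_a_ratio must lie in [-1, 1]")
  norms <- matrix(0, n, 7)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, 2L))
    norms[i, ] <- rnorm(7)
  }
  u <- norms[, 1]                       # latent of log TMT-A
  q <- norms[, 2]
  w <- tp$cor_a_ratio * u + sqrt(1 - tp$cor_a_ratio^2) * q  # latent of log B/A
  log_a <- tp$log_a_mean + tp$age_slope_log_a * (age - 70) +
    tp$education_slope_log_a * (edu - 2) + tp$log_a_sd * u
  log_r <- tp$log_ratio_mean + tp$age_slope_log_ratio * (age - 70) +
    tp$log_ratio_sd * w
  participants$tmt_a_s <- exp(log_a)
  participants$tmt_b_s <- exp(log_a + log_r)
  sc <- function(name, z) {
    p <- score_params[[name]]
    raw <- p[["mean"]] + p[["age"]] * (age - 70) + p[["edu"]] * (edu - 2) +
      p[["sd"]] * z
    pmin(pmax(round(raw), p[["min"]]), p[["max"]])
  }
  participants$wordlist          <- sc("wordlist", norms[, 3])
  participants$visuoconstruction <- sc("visuoconstruction", norms[, 4])
  participants$verbal_fluency    <- sc("verbal_fluency", norms[, 5])
  participants$rmet              <- sc("rmet", norms[, 6])
  participants$mmse              <- sc("mmse", norms[, 7])
  participants
}

# CASMIN education as ordinal 1/2/3
education_ordinal <- function(education) {
  if (is.numeric(education)) {
    stopifnot(all(education %in% 1:3))
    return(as.numeric(education))
  }
  lv <- c(low = 1, intermediate = 2, high = 3)
  out <- unname(lv[as.character(education)])
  if (anyNA(out)) stop("education must be low/intermediate/high or 1/2/3")
  out
}

#' Generate a synthetic cohort
#'
#' Deterministically simulates participants (covariates, cognitive raw
#' scores, diagnosis-related flags), derives domain z-scores and — unless
#' `config$classify` is FALSE — MCI / mild-NCD diagnosis flags by running the
#' package's own norm-referenced classifier on the simulated scores, and then
#' simulates per-eye cpRNFLT profiles as
#' `baseline + covariate terms + embedded effects + correlated noise`.
#' Cognitive effects from `effect_map` multiply the participant's observed
#' domain z-score; diagnosis effects from `dx_effect_map` add a constant
#' offset for flag carriers. Left-eye profiles are stored mirrored (device
#' frame, `oriented = FALSE`); use [align_orientation()] before analysis.
#'
#' @param config a [sim_config()].
#' @return a [cohort()] with `provenance = config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- config$n_participants
  dp <- config$diagnosis_params
  edu_levels <- c("low", "intermediate", "high")

  age <- sex <- numeric(n); edu <- character(n)
  decline <- logical(n); adl <- integer(n); cns <- logical(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, 1L))
    age[i] <- runif(1, config$age_range[1], config$age_range[2])
    sex[i] <- rbinom(1, 1, config$sex_ratio)
    edu[i] <- sample(edu_levels, 1, prob = config$education_probs)
    decline[i] <- runif(1) < dp$frac_subjective_decline
    adl[i] <- sample(0:2, 1, prob = dp$adl_probs)
    cns[i] <- runif(1) < dp$cns_rate
  }
  part <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                     age = age,
                     sex = ifelse(sex == 1, "male", "female"),
                     education = edu,
                     subjective_decline = decline,
                     sidam_adl = adl,
                     cns_condition = cns,
                     stringsAsFactors = FALSE)
  part <- generate_cognition(part, config$tmt_params, config$score_params,
                             seed = config$seed)
  part <- zscore_domains(part)
  if (config$classify) {
    bands <- seq(floor(config$age_range[1]),
                 ceiling(config$age_range[2]) + dp$age_band_width,
                 by = dp$age_band_width)
    norms <- compute_norms(part, age_bands = bands,
                           min_stratum_n = dp$min_stratum_n)
    part <- classify_mci_ncd(part, norms)
  }

  # eye-level draws from per-participant substreams
  eye_rows <- vector("list", n)
  white <- smooth_w <- local_w <- miss <- vector("list", n)
  offset <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i, 3L))
    both <- runif(1) < config$prob_both_eyes
    sides <- if (both) c("right", "left") else
      sample(c("right", "left"), 1)
    k <- length(sides)
    eye_rows[[i]] <- data.frame(
      eye_id = paste0(part$subject_id[i], "_", substr(sides, 1, 1)),
      subject_id = part$subject_id[i],
      laterality = sides,
      scan_radius_mm = rnorm(k, config$radius_ref, config$scan_radius_sd),
      snr_db = rnorm(k, config$snr_mean, config$snr_sd),
      n_bscans = pmax(1L, as.integer(round(rnorm(k, config$bscans_mean,
                                                 config$bscans_sd)))),
      eye_disease = runif(k) < dp$eye_disease_rate,
      oriented = FALSE,
      stringsAsFactors = FALSE)
    white[[i]] <- matrix(rnorm(k * N_LOCATIONS), k, N_LOCATIONS)
    smooth_w[[i]] <- matrix(rnorm(k * N_LOCATIONS), k, N_LOCATIONS)
    local_w[[i]] <- matrix(rnorm(k * N_LOCATIONS), k, N_LOCATIONS)
    offset[[i]] <- rnorm(k)
    miss[[i]] <- matrix(runif(k * N_LOCATIONS) < config$missing_rate,
                        k, N_LOCATIONS)
  }
  eyes <- do.call(rbind, eye_rows)
  white <- do.call(rbind, white)
  smooth_w <- do.call(rbind, smooth_w)
  local_w <- do.call(rbind, local_w)
  offset <- unlist(offset)
  missing <- do.call(rbind, miss)

  angles <- profile_angles()
  base <- baseline_profile(angles, config$baseline_shape_params)
  idx <- match(eyes$subject_id, part$subject_id)
  male <- as.numeric(part$sex[idx] == "male")
  edu_ord <- education_ordinal(part$education[idx])

  # anatomy: one row per eye, in the TSNIT frame
  thick <- matrix(base, nrow(eyes), N_LOCATIONS, byrow = TRUE)
  shift <- config$age_slope * (part$age[idx] - config$age_ref) +
    config$sex_offset * male +
    config$radius_slope * (eyes$scan_radius_mm - config$radius_ref) +
    config$education_slope * (edu_ord - 2)
  thick <- thick + shift
  for (dom in names(config$effect_map)) {
    zcol <- paste0("z_", dom)
    if (!zcol %in% names(part)) stop("unknown domain in effect_map: ", dom)
    z <- part[[zcol]][idx]
    for (entry in config$effect_map[[dom]]) {
      arc <- in_arc(angles, entry$interval[1], entry$interval[2])
      thick[, arc] <- thick[, arc] + entry$beta * z
    }
  }
  for (flag in names(config$dx_effect_map)) {
    if (!flag %in% names(part)) stop("unknown flag in dx_effect_map: ", flag)
    carrier <- as.numeric(isTRUE_vec(part[[flag]][idx]))
    for (entry in config$dx_effect_map[[flag]]) {
      arc <- in_arc(angles, entry$interval[1], entry$interval[2])
      thick[, arc] <- thick[, arc] + entry$delta * carrier
    }
  }
  thick <- thick + config$noise_sd_white * white +
    config$noise_sd_smooth * circular_smooth_noise(
      smooth_w, config$noise_correlation_length) +
    config$noise_sd_local * circular_smooth_noise(
      local_w, config$local_correlation_length) +
    config$subject_offset_sd * offset
  thick <- pmin(pmax(thick, 0.5), 299.5)  # instrument dynamic range

  # left eyes are exported in the device frame (mirrored about the temporal
  # midline); align_orientation() undoes this
  left <- eyes$laterality == "left"
  if (any(left)) {
    mir <- mirror_index()
    thick[left, ] <- thick[left, mir, drop = FALSE]
    missing[left, ] <- missing[left, mir, drop = FALSE]
  }
  rownames(eyes) <- NULL
  cohort(part, eyes, thick, missing = missing, provenance = config)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# index permutation that mirrors a profile about the temporal midline
mirror_index <- function(n = N_LOCATIONS) c(1L, seq(n, 2L))

# turn unit white noise (eyes x 768) into unit-variance angularly correlated
# noise by circular Gaussian-kernel convolution (FFT over locations)
circular_smooth_noise <- function(white, correlation_length_deg) {
  if (correlation_length_deg <= 0) return(white)
  n <- ncol(white)
  d <- circ_diff(profile_angles(n), 0)
  k <- exp(-0.5 * (d / correlation_length_deg)^2)
  k <- k / sum(k)
  scale <- sqrt(sum(k^2))
  kf <- fft(k)
  wf <- mvfft(t(white))
  sm <- Re(mvfft(wf * kf, inverse = TRUE)) / n
  t(sm) / scale
}

#' Parameters of the brain-volume simulator
#'
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param hcv_mean,hcv_sd per-side hippocampal volume distribution (mm^3).
#' @param beta_icv slope of hippocampal on intracranial volume (mm^3/mm^3).
#' @param age_slope hippocampal volume change per year (mm^3/yr).
#' @param dx_flag,dx_effect diagnosis flag column and additive hippocampal
#'   effect for carriers (mm^3).
#' @param wml_log_mean,wml_log_sd log-normal white-matter lesion volume.
#' @return list of class `brain_params`.
#' @export
brain_params <- function(icv_mean = 1.45e6, icv_sd = 1.3e5,
                         hcv_mean = 3600, hcv_sd = 300,
                         beta_icv = 0.0015, age_slope = -8,
                         dx_flag = "dx_mci", dx_effect = -250,
                         wml_log_mean = log(2500), wml_log_sd = 0.9) {
  structure(as.list(environment()), class = "brain_params")
}

#' Simulate brain volumes for a cohort
#'
#' Hippocampal volumes scale linearly with intracranial volume and decline
#' with age; carriers of the configured diagnosis flag lose a fixed volume.
#' White-matter lesion volume is log-normal.
#'
#' @param cohort a [cohort()].
#' @param params a [brain_params()].
#' @param seed integer seed.
#' @return data.frame: `subject_id`, `hcv_left_mm3`, `hcv_right_mm3`,
#'   `icv_mm3`, `wm_lesion_mm3`.
#' @export
simulate_brain_volumes <- function(cohort, params = brain_params(),
                                   seed = 1L) {
  p <- cohort$participants
  n <- nrow(p)
  dx <- if (params$dx_flag %in% names(p))
    isTRUE_vec(p[[params$dx_flag]]) else rep(FALSE, n)
  out <- data.frame(subject_id = p$subject_id, hcv_left_mm3 = NA_real_,
                    hcv_right_mm3 = NA_real_, icv_mm3 = NA_real_,
                    wm_lesion_mm3 = NA_real_)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, i, 4L))
    icv <- rnorm(1, params$icv_mean, params$icv_sd)
    mu <- params$hcv_mean + params$beta_icv * (icv - params$icv_mean) +
      params$age_slope * (p$age[i] - 70) + params$dx_effect * dx[i]
    hl <- rnorm(1, mu, params$hcv_sd)
    hr <- rnorm(1, mu + 50, params$hcv_sd)
    out$icv_mm3[i] <- icv
    out$hcv_left_mm3[i] <- max(hl, 500)
    out$hcv_right_mm3[i] <- max(hr, 500)
    out$wm_lesion_mm3[i] <- rlnorm(1, params$wml_log_mean +
                                     0.03 * (p$age[i] - 70),
                                   params$wml_log_sd)
  }
  out
}
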