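#' Trail-making ratio B/A
#'
#' Executive function net of psychomotor speed: TMT-B time divided by TMT-A
#' time.
#'
#' @param tmt_b_s,tmt_a_s times in seconds, strictly positive.
#' @return `tmt_b_s / tmt_a_s` (vectorised).
#' @export
tmt_ratio <- function(tmt_b_s, tmt_a_s) {
  if (any(!is.na(tmt_b_s) & tmt_b_s <= 0) ||
      any(!is.na(tmt_a_s) & tmt_a_s <= 0))
    stop("TMT times must be strictly positive")
  tmt_b_s / tmt_a_s
}

# oriented raw scores per domain: higher always means better performance.
# attention and executive are sign-inverted timed measures.
oriented_scores <- function(participants) {
  p <- participants
  need <- c("tmt_a_s", "tmt_b_s", "wordlist", "visuoconstruction",
            "verbal_fluency", "rmet")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing score columns: ", paste(miss, collapse = ", "))
  data.frame(attention = -p$tmt_a_s,
             executive = -tmt_ratio(p$tmt_b_s, p$tmt_a_s),
             memory = p$wordlist,
             perceptual_motor = p$visuoconstruction,
             language = p$verbal_fluency,
             social = p$rmet)
}

#' Standardise cognitive domain scores over the analysis sample
#'
#' Maps the raw test battery onto the six cognitive domains and z-scores each
#' over the sample: attention is the z of minus TMT-A time and executive
#' function the z of minus the TMT B/A ratio, so a higher z always means
#' better performance; memory (word-list learning), perceptual-motor
#' (visuoconstruction copy), language (semantic verbal fluency) and social
#' cognition (RMET) are standardised directly.
#'
#' @param participants data.frame with the raw score columns `tmt_a_s`,
#'   `tmt_b_s`, `wordlist`, `visuoconstruction`, `verbal_fluency`, `rmet`.
#' @return `participants` with columns `z_attention`, `z_executive`,
#'   `z_memory`, `z_perceptual_motor`, `z_language`, `z_social` appended.
#' @export
zscore_domains <- function(participants) {
  sc <- oriented_scores(participants)
  for (dom in COG_DOMAINS) {
    x <- sc[[dom]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop("zero variance in domain '", dom, "': cannot z-score")
    participants[[paste0("z_", dom)]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  participants
}

#' Age-, sex- and education-specific norm tables
#'
#' Computes per-stratum means and SDs of the oriented raw domain scores,
#' where a stratum is an age band crossed with sex and CASMIN education
#' level. Age bands whose stratum falls below `min_stratum_n` are merged with
#' the nearest adjacent band of the same sex/education cell until every
#' remaining stratum is large enough (or a single band spans the whole age
#' range).
#'
#' @param participants data.frame with `age`, `sex`, `education` and the raw
#'   score columns.
#' @param age_bands breakpoints of the age bands (default 5-year bins over
#'   60-80); ages outside are assigned to the closest band.
#' @param min_stratum_n minimum participants per stratum before merging.
#' @return a `norm_table`: data.frame with columns `sex`, `education`,
#'   `age_lo`, `age_hi`, `domain`, `mean`, `sd`, `n`.
#' @export
compute_norms <- function(participants, age_bands = seq(60, 80, by = 5),
                          min_stratum_n = 20) {
  if (nrow(participants) == 0) stop("empty cohort")
  sc <- oriented_scores(participants)
  sexes <- unique(participants$sex)
  edus <- unique(as.character(participants$education))
  nb <- length(age_bands) - 1
  band <- pmin(pmax(findInterval(participants$age, age_bands), 1L), nb)
  rows <- list()
  for (sx in sexes) for (ed in edus) {
    cell <- participants$sex == sx & as.character(participants$education) == ed
    if (!any(cell))
      stop("empty sex x education cell at every age band: ", sx, " / ", ed)
    counts <- tabulate(band[cell], nbins = nb)
    groups <- as.list(seq_len(nb))
    gcount <- function(g) sum(counts[unlist(g)])
    repeat {
      sizes <- vapply(groups, function(g) sum(counts[g]), numeric(1))
      if (length(groups) == 1 || all(sizes >= min_stratum_n)) break
      j <- which.min(sizes)                    # smallest stratum merges first
      nb_left <- if (j > 1) sizes[j - 1] else Inf
      nb_right <- if (j < length(groups)) sizes[j + 1] else Inf
      k <- if (nb_left <= nb_right) j - 1 else j + 1
      groups[[min(j, k)]] <- c(groups[[min(j, k)]], groups[[max(j, k)]])
      groups[[max(j, k)]] <- NULL
    }
    for (g in groups) {
      lo <- age_bands[min(g)]
      hi <- age_bands[max(g) + 1]
      # clamp outer strata so out-of-range ages still match
      if (min(g) == 1) lo <- -Inf
      if (max(g) == nb) hi <- Inf
      in_stratum <- cell & band %in% g
      n_s <- sum(in_stratum)
      if (n_s == 0) next
      for (dom in COG_DOMAINS) {
        x <- sc[[dom]][in_stratum]
        m <- mean(x, na.rm = TRUE)
        s <- sd(x, na.rm = TRUE)
        if (is.na(s) || s == 0)
          stop("stratum SD is zero for domain '", dom, "' (", sx, "/", ed,
               ", ages ", lo, "-", hi, "); enlarge min_stratum_n")
        rows[[length(rows) + 1]] <- data.frame(
          sex = sx, education = ed, age_lo = lo, age_hi = hi,
          domain = dom, mean = m, sd = s, n = n_s,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("norm_table", "data.frame")
  out
}

# per-participant norm-referenced z (n x 6 matrix) against a norm_table
norm_referenced_z <- function(participants, norms) {
  sc <- oriented_scores(participants)
  n <- nrow(participants)
  nz <- matrix(NA_real_, n, length(COG_DOMAINS),
               dimnames = list(NULL, COG_DOMAINS))
  for (i in seq_len(n)) {
    hit <- norms$sex == participants$sex[i] &
      norms$education == as.character(participants$education[i]) &
      norms$age_lo <= participants$age[i] &
      participants$age[i] < norms$age_hi
    if (!any(hit))
      stop("no norm stratum covers participant ",
           participants$subject_id[i] %||% i)
    sub <- norms[hit, ]
    for (dom in COG_DOMAINS) {
      r <- sub[sub$domain == dom, ]
      nz[i, dom] <- (sc[[dom]][i] - r$mean[1]) / r$sd[1]
    }
  }
  nz
}

#' Diagnostic criteria for MCI / mild NCD
#'
#' The four operational criteria: subjective decline, at least one domain
#' with performance between `deficit_high_sd` and `deficit_low_sd` standard
#' deviations below the stratum norm (the deficit band is closed at the lower
#' edge and open at the upper: `[-high, -low)`), preserved daily-living
#' independence (`sidam_adl <= adl_max`), and exclusion of dementia (any
#' domain more than `dementia_sd` SD below norm).
#'
#' @param deficit_low_sd,deficit_high_sd deficit band bounds in SD units
#'   (defaults 1 and 2).
#' @param adl_max maximum SIDAM-ADL score compatible with independence.
#' @param dementia_sd exclusion threshold in SD units (strict).
#' @return list of class `dx_criteria`.
#' @export
dx_criteria <- function(deficit_low_sd = 1, deficit_high_sd = 2,
                        adl_max = 1, dementia_sd = 2) {
  structure(list(deficit_low_sd = deficit_low_sd,
                 deficit_high_sd = deficit_high_sd,
                 adl_max = adl_max, dementia_sd = dementia_sd),
            class = "dx_criteria")
}

#' Classify participants into MCI and mild NCD
#'
#' Applies norm-referenced stratification: a domain deficit is a
#' norm-referenced z in `[-deficit_high_sd, -deficit_low_sd)`; a diagnosis
#' requires subjective decline, at least one deficit domain, preserved
#' activities of daily living and no dementia-range deviation. The amnestic
#' subtype additionally requires learning/memory to be the only deficit
#' domain. MCI and mild NCD use independently configurable criteria sets
#' (identical by default). Participants with missing required inputs are
#' flagged unclassifiable rather than silently negative.
#'
#' @param participants data.frame with raw scores, `subjective_decline` and
#'   `sidam_adl`.
#' @param norms a `norm_table` from [compute_norms()].
#' @param criteria_mci,criteria_ncd [dx_criteria()] for each diagnosis.
#' @return `participants` with norm-z columns `nz_<domain>` and logical
#'   columns `dx_mci`, `dx_amnestic_mci`, `dx_mild_ncd`,
#'   `dx_amnestic_mild_ncd`, `dx_dementia_excluded`, `dx_unclassifiable`.
#' @export
classify_mci_ncd <- function(participants, norms,
                             criteria_mci = dx_criteria(),
                             criteria_ncd = criteria_mci) {
  need <- c("subjective_decline", "sidam_adl")
  miss <- setdiff(need, names(participants))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  nz <- norm_referenced_z(participants, norms)
  unclass_row <- apply(nz, 1, anyNA) |
    is.na(participants$subjective_decline) | is.na(participants$sidam_adl)

  apply_criteria <- function(cr) {
    deficit <- nz >= -cr$deficit_high_sd & nz < -cr$deficit_low_sd
    dementia <- apply(nz < -cr$dementia_sd, 1, any)
    n_def <- rowSums(deficit)
    dx <- participants$subjective_decline & n_def >= 1 &
      participants$sidam_adl <= cr$adl_max & !dementia
    amnestic <- dx & n_def == 1 & deficit[, "memory"]
    list(dx = dx, amnestic = amnestic, dementia = dementia)
  }
  mci <- apply_criteria(criteria_mci)
  ncd <- apply_criteria(criteria_ncd)

  for (nm in colnames(nz)) participants[[paste0("nz_", nm)]] <- nz[, nm]
  participants$dx_mci <- ifelse(unclass_row, NA, mci$dx)
  participants$dx_amnestic_mci <- ifelse(unclass_row, NA, mci$amnestic)
  participants$dx_mild_ncd <- ifelse(unclass_row, NA, ncd$dx)
  participants$dx_amnestic_mild_ncd <- ifelse(unclass_row, NA, ncd$amnestic)
  participants$dx_dementia_excluded <-
    ifelse(unclass_row, NA, mci$dementia | ncd$dementia)
  participants$dx_unclassifiable <- unclass_row
  participants
}

#' Cross-tabulate two diagnosis flags
#'
#' Counts participants (not eyes) carrying each of two diagnoses and their
#' overlap; exclusive counts follow by subtraction.
#'
#' @param participants data.frame with the two logical flag columns.
#' @param flag_a,flag_b flag column names (default MCI and mild NCD).
#' @return list with `n_a` (`flag_a` carriers), `n_b`, `n_both`,
#'   `n_a_only = n_a - n_both`, `n_b_only = n_b - n_both`.
#' @export
crosstab_diagnoses <- function(participants, flag_a = "dx_mci",
                               flag_b = "dx_mild_ncd") {
  a <- isTRUE_vec(participants[[flag_a]] %||% logical(0))
  b <- isTRUE_vec(participants[[flag_b]] %||% logical(0))
  n_a <- sum(a); n_b <- sum(b); n_both <- sum(a & b)
  list(n_a = n_a, n_b = n_b, n_both = n_both,
       n_a_only = n_a - n_both, n_b_only = n_b - n_both)
}
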