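#' Flag unreliable cpRNFLT measurements by pooled percentiles
#'
#' Pools every acquisition-present thickness value across all eyes and
#' locations, computes the empirical 0.5 % and 99.5 % percentiles (inclusive
#' linear-interpolation convention), and marks values strictly outside that
#' range as unreliable. Flags are stored in the cohort's `unreliable` mask;
#' raw values are retained for audit. Because the pool always uses the
#' acquisition-present values (including previously flagged ones), the
#' operation is idempotent.
#'
#' @param cohort a [cohort()] with at least one non-missing value.
#' @param lower,upper percentile bounds as probabilities (defaults 0.005 and
#'   0.995).
#' @return the cohort with an updated `unreliable` mask; the pooled bounds
#'   are attached as attribute `percentile_bounds`.
#' @export
flag_unreliable <- function(cohort, lower = 0.005, upper = 0.995) {
  stopifnot(inherits(cohort, "cohort"))
  pool <- cohort$thickness[!cohort$missing]
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0) stop("empty thickness pool")
  bounds <- quantile(pool, c(lower, upper), type = 7, names = FALSE)
  # 'above'/'below' read strictly: boundary ties are not flagged
  bad <- (cohort$thickness < bounds[1] | cohort$thickness > bounds[2]) &
    !cohort$missing
  bad[is.na(bad)] <- FALSE
  cohort$unreliable <- bad
  attr(cohort, "percentile_bounds") <- bounds
  cohort
}

#' Scan-reliability filter
#'
#' Applies the per-eye reliability rules: signal-to-noise ratio at least
#' `snr_min_db`, at least `bscans_min` averaged B-scans, and no more than
#' `missing_frac_max` of the 768 locations missing or flagged unreliable
#' (the fraction comparison is strict: 38/768 passes at the 5 % limit,
#' 39/768 fails).
#'
#' @param cohort a [cohort()] (run [flag_unreliable()] first so percentile
#'   flags count towards the missing fraction).
#' @param thresholds list with `snr_min_db` (default 20), `bscans_min`
#'   (default 50), `missing_frac_max` (default 0.05).
#' @return data.frame of class `qc_report`: `eye_id`, `passed`, `reasons`
#'   (comma-separated codes `LOW_SNR`, `FEW_BSCANS`, `TOO_MANY_MISSING`),
#'   `n_missing`, `n_unreliable`.
#' @export
qc_filter <- function(cohort, thresholds = list(snr_min_db = 20,
                                                bscans_min = 50,
                                                missing_frac_max = 0.05)) {
  stopifnot(inherits(cohort, "cohort"))
  th <- thresholds
  n_missing <- rowSums(cohort$missing)
  n_unrel <- rowSums(cohort$unreliable & !cohort$missing)
  frac_bad <- rowSums(effective_mask(cohort)) / N_LOCATIONS
  low_snr <- cohort$eyes$snr_db < th$snr_min_db
  few_bscans <- cohort$eyes$n_bscans < th$bscans_min
  too_missing <- frac_bad > th$missing_frac_max
  reasons <- mapply(function(a, b, c) {
    paste(c(if (a) "LOW_SNR", if (b) "FEW_BSCANS",
            if (c) "TOO_MANY_MISSING"), collapse = ",")
  }, low_snr, few_bscans, too_missing)
  out <- data.frame(eye_id = cohort$eyes$eye_id,
                    passed = !(low_snr | few_bscans | too_missing),
                    reasons = unname(reasons),
                    n_missing = n_missing,
                    n_unreliable = n_unrel,
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Standardise profile orientation to the TSNIT frame
#'
#' Puts every eye's profile into a common frame with index 0 at the temporal
#' midline and indices running temporal -> superior -> nasal -> inferior.
#' Right-eye device exports are already in this frame; left-eye profiles are
#' mirrored about the temporal midline (`mirror_left = TRUE`, the default;
#' set to FALSE if the device exports both eyes in a common frame already).
#' Eyes marked `oriented` are left untouched, so the operation is idempotent.
#'
#' @param cohort a [cohort()] whose eyes carry a known `laterality`.
#' @param mirror_left whether left eyes need mirroring.
#' @return the cohort with all eyes `oriented = TRUE`.
#' @export
align_orientation <- function(cohort, mirror_left = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  lat <- cohort$eyes$laterality
  if (anyNA(lat) || !all(lat %in% c("left", "right")))
    stop("unknown laterality: cannot orient")
  todo <- !cohort$eyes$oriented & lat == "left" & mirror_left
  if (any(todo)) {
    mir <- mirror_index()
    cohort$thickness[todo, ] <- cohort$thickness[todo, mir, drop = FALSE]
    cohort$missing[todo, ] <- cohort$missing[todo, mir, drop = FALSE]
    cohort$unreliable[todo, ] <- cohort$unreliable[todo, mir, drop = FALSE]
  }
  cohort$eyes$oriented <- TRUE
  cohort
}

# analysis functions need oriented profiles; align lazily with a message
ensure_oriented <- function(cohort) {
  if (!all(cohort$eyes$oriented)) {
    message("aligning profiles to the TSNIT frame")
    cohort <- align_orientation(cohort)
  }
  cohort
}
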