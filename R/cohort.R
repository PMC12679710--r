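#' Construct a cohort object
#'
#' A `cohort` bundles participant-level data with eye-level cpRNFLT profiles.
#' Thickness is held as a numeric matrix (eyes x 768, micrometres) alongside
#' two logical masks: `missing` marks points absent at acquisition, and
#' `unreliable` marks points flagged by [flag_unreliable()]. The effective
#' analysis mask is their union; raw thickness values are never overwritten,
#' so flagged values remain available for audit.
#'
#' @param participants data.frame with one row per participant; must contain
#'   `subject_id` and any covariate / cognitive-score columns used downstream
#'   (`age`, `sex`, `education`, raw test scores, diagnosis flags).
#' @param eyes data.frame with one row per eye: `eye_id`, `subject_id`,
#'   `laterality` (`"left"`/`"right"`), `scan_radius_mm`, `snr_db`,
#'   `n_bscans`, and logical `oriented` (TRUE once in the standard TSNIT
#'   frame).
#' @param thickness numeric matrix, `nrow(eyes)` x 768, in micrometres.
#' @param missing logical matrix of the same dimension (default: no missing).
#' @param unreliable logical matrix of the same dimension (default: none).
#' @param provenance free-form description or the generating [sim_config()].
#' @return an object of class `cohort`.
#' @export
cohort <- function(participants, eyes, thickness,
                   missing = NULL, unreliable = NULL, provenance = NULL) {
  stopifnot(is.data.frame(participants), is.data.frame(eyes),
            is.matrix(thickness))
  if (!"subject_id" %in% names(participants))
    stop("participants must contain 'subject_id'")
  req <- c("eye_id", "subject_id", "laterality")
  if (!all(req %in% names(eyes)))
    stop("eyes must contain: ", paste(req, collapse = ", "))
  if (nrow(thickness) != nrow(eyes))
    stop("thickness must have one row per eye")
  if (ncol(thickness) != N_LOCATIONS)
    stop("thickness must have ", N_LOCATIONS, " columns")
  if (anyDuplicated(participants$subject_id))
    stop("duplicated subject_id in participants")
  if (anyDuplicated(eyes$eye_id)) stop("duplicated eye_id")
  if (!all(eyes$subject_id %in% participants$subject_id))
    stop("every eye must reference an existing participant")
  lat_ok <- eyes$laterality %in% c("left", "right")
  if (!all(lat_ok)) stop("laterality must be 'left' or 'right'")
  per <- table(paste(eyes$subject_id, eyes$laterality))
  if (any(per > 1))
    stop("at most one eye per participant and laterality")
  if (is.null(missing)) missing <- matrix(FALSE, nrow(eyes), N_LOCATIONS)
  if (is.null(unreliable)) unreliable <- matrix(FALSE, nrow(eyes), N_LOCATIONS)
  stopifnot(identical(dim(missing), dim(thickness)),
            identical(dim(unreliable), dim(thickness)))
  if (is.null(eyes$oriented)) eyes$oriented <- FALSE
  rownames(thickness) <- rownames(missing) <- rownames(unreliable) <- eyes$eye_id
  vals <- thickness[!missing]
  if (length(vals) && any(!is.finite(vals) | vals <= 0 | vals >= 300))
    stop("non-missing thickness values must lie in (0, 300) um")
  structure(list(participants = participants, eyes = eyes,
                 thickness = thickness, missing = missing,
                 unreliable = unreliable, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("cpRNFLT cohort:", nrow(x$participants), "participants,",
      nrow(x$eyes), "eyes\n")
  cat("  oriented to TSNIT frame:", sum(x$eyes$oriented), "/",
      nrow(x$eyes), "eyes\n")
  n_flag <- sum(x$unreliable)
  cat("  masked points: ", sum(x$missing), " missing, ",
      n_flag, " flagged unreliable\n", sep = "")
  invisible(x)
}

# union of acquisition-missing and percentile-flagged points
effective_mask <- function(cohort) cohort$missing | cohort$unreliable

#' Subset a cohort by eyes and/or participants
#'
#' Retains the selected eyes and every participant that still owns at least
#' one eye (participants without eyes are dropped unless `keep_all_participants`).
#'
#' @param x a [cohort()].
#' @param eye_ids character vector of eye ids to keep (default: all).
#' @param subject_ids keep only eyes of these participants (default: all).
#' @param keep_all_participants if TRUE, participants without remaining eyes
#'   stay in the participant table.
#' @return a `cohort`.
#' @export
subset_cohort <- function(x, eye_ids = NULL, subject_ids = NULL,
                          keep_all_participants = FALSE) {
  stopifnot(inherits(x, "cohort"))
  keep <- rep(TRUE, nrow(x$eyes))
  if (!is.null(eye_ids)) keep <- keep & x$eyes$eye_id %in% eye_ids
  if (!is.null(subject_ids)) keep <- keep & x$eyes$subject_id %in% subject_ids
  eyes <- x$eyes[keep, , drop = FALSE]
  part <- x$participants
  if (!keep_all_participants)
    part <- part[part$subject_id %in% eyes$subject_id, , drop = FALSE]
  rownames(eyes) <- rownames(part) <- NULL
  structure(list(participants = part, eyes = eyes,
                 thickness = x$thickness[keep, , drop = FALSE],
                 missing = x$missing[keep, , drop = FALSE],
                 unreliable = x$unreliable[keep, , drop = FALSE],
                 provenance = x$provenance),
            class = "cohort")
}
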