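#' Angular sector schemes
#'
#' A sector scheme is an ordered partition of the scan circle into half-open
#' arcs `[start, start + width)`, measured in degrees from the temporal
#' midline in TSNIT direction. Arcs may wrap through 0 degrees. The
#' constructor verifies that the scheme partitions the circle: every grid
#' location is assigned to exactly one sector.
#'
#' @param labels sector labels, in order.
#' @param start_deg start angle of each sector (degrees, may be negative).
#' @param width_deg angular width of each sector (degrees); widths must sum
#'   to 360.
#' @param name scheme name.
#' @return data.frame of class `sector_scheme` with columns `label`,
#'   `start_deg`, `width_deg`.
#' @export
sector_scheme <- function(labels, start_deg, width_deg, name = "custom") {
  stopifnot(length(labels) == length(start_deg),
            length(labels) == length(width_deg), !anyDuplicated(labels))
  if (abs(sum(width_deg) - 360) > 1e-9)
    stop("sector widths must sum to 360 degrees")
  sch <- data.frame(label = as.character(labels),
                    start_deg = start_deg %% 360,
                    width_deg = width_deg, stringsAsFactors = FALSE)
  class(sch) <- c("sector_scheme", "data.frame")
  attr(sch, "name") <- name
  hits <- vapply(profile_angles(), function(a)
    sum(((a - sch$start_deg) %% 360) < sch$width_deg), numeric(1))
  if (any(hits != 1))
    stop("sectors must partition the circle (no overlap, no gap)")
  sch
}

#' Six anatomical sectors (T, TS, NS, N, NI, TI)
#'
#' Standard circumpapillary sector widths 90/45/45/90/45/45 degrees:
#' temporal `[-45, 45)`, temporal-superior `[45, 90)`, nasal-superior
#' `[90, 135)`, nasal `[135, 225)`, nasal-inferior `[225, 270)`,
#' temporal-inferior `[270, 315)`.
#'
#' @return a [sector_scheme()].
#' @export
sector_scheme_6 <- function() {
  sector_scheme(c("T", "TS", "NS", "N", "NI", "TI"),
                start_deg = c(-45, 45, 90, 135, 225, 270),
                width_deg = c(90, 45, 45, 90, 45, 45),
                name = "anatomical6")
}

#' Twenty-four 15-degree sectors
#'
#' Equal 15-degree sectors labelled `S1` ... `S24`, anchored so that `S1`
#' straddles the temporal midline (`[-7.5, 7.5)` at the default offset).
#'
#' @param offset_deg start angle of the first sector (default -7.5).
#' @return a [sector_scheme()].
#' @export
sector_scheme_24 <- function(offset_deg = -7.5) {
  sector_scheme(paste0("S", 1:24),
                start_deg = offset_deg + 15 * (0:23),
                width_deg = rep(15, 24),
                name = "sectors24")
}

#' Assign angles to sectors
#'
#' @param angles angles in degrees.
#' @param scheme a [sector_scheme()].
#' @return factor of sector labels (levels in scheme order).
#' @export
sector_of_angle <- function(angles, scheme) {
  lab <- rep(NA_character_, length(angles))
  for (j in seq_len(nrow(scheme))) {
    inj <- ((angles - scheme$start_deg[j]) %% 360) < scheme$width_deg[j]
    lab[inj] <- scheme$label[j]
  }
  factor(lab, levels = scheme$label)
}

#' Per-sector mean thickness
#'
#' Unweighted mean over the non-masked locations of each sector, per eye.
#' With a single full-circle sector this reproduces the global mean used by
#' [fit_global_mean()]. A sector whose locations are all masked yields `NA`
#' for that eye.
#'
#' @param cohort a [cohort()] (oriented; aligned automatically if not).
#' @param scheme a [sector_scheme()].
#' @return numeric matrix, eyes x sectors, in micrometres.
#' @export
aggregate_sectors <- function(cohort, scheme = sector_scheme_24()) {
  cohort <- ensure_oriented(cohort)
  sec <- sector_of_angle(profile_angles(), scheme)
  th <- cohort$thickness
  th[effective_mask(cohort)] <- NA
  out <- matrix(NA_real_, nrow(th), nrow(scheme),
                dimnames = list(cohort$eyes$eye_id, scheme$label))
  for (j in seq_len(nrow(scheme))) {
    cols <- which(sec == scheme$label[j])
    out[, j] <- rowMeans(th[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA
  out
}
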