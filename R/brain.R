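#' Adjust hippocampal volumes for intracranial volume
#'
#' Residual-method head-size correction: for each side,
#' `HCVadj = HCVraw - beta * (ICVraw - ICVmean)`, where `beta` is the
#' unstandardised slope of hippocampal on intracranial volume and `ICVmean`
#' the intracranial mean, both estimated on the reference set (the full
#' sample by default). Subjects at the reference intracranial mean are
#' unchanged, and within the reference set the adjusted volumes are linearly
#' unrelated to intracranial volume.
#'
#' @param volumes data.frame with `hcv_left_mm3`, `hcv_right_mm3`,
#'   `icv_mm3` (and any id columns, which are preserved).
#' @param reference logical mask selecting the subjects on which `beta` and
#'   `ICVmean` are estimated (default: all).
#' @return `volumes` with `hcv_left_adj_mm3` and `hcv_right_adj_mm3`
#'   appended; the per-side slopes and the reference mean are attached as
#'   attributes `beta` and `icv_mean`.
#' @export
adjust_hcv_for_icv <- function(volumes, reference = NULL) {
  need <- c("hcv_left_mm3", "hcv_right_mm3", "icv_mm3")
  miss <- setdiff(need, names(volumes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(reference)) reference <- rep(TRUE, nrow(volumes))
  stopifnot(length(reference) == nrow(volumes))
  icv_ref <- volumes$icv_mm3[reference]
  if (sum(reference) < 3) stop("need at least 3 reference subjects")
  if (var(icv_ref) == 0) stop("zero intracranial-volume variance")
  icv_mean <- mean(icv_ref)
  betas <- c(left = NA_real_, right = NA_real_)
  for (side in c("left", "right")) {
    hcv <- volumes[[paste0("hcv_", side, "_mm3")]]
    b <- cov(hcv[reference], icv_ref) / var(icv_ref)
    betas[side] <- b
    volumes[[paste0("hcv_", side, "_adj_mm3")]] <-
      hcv - b * (volumes$icv_mm3 - icv_mean)
  }
  attr(volumes, "beta") <- betas
  attr(volumes, "icv_mean") <- icv_mean
  volumes
}

#' Two-group comparison of an imaging marker
#'
#' Two-sample t-test (Welch unequal-variance by default) between a diagnosis
#' group and its control group.
#'
#' @param values numeric marker values (e.g. adjusted hippocampal volume).
#' @param groups two-level grouping (logical or factor/character); for a
#'   logical, TRUE is the diagnosis group.
#' @param var_equal if TRUE, Student's pooled-variance t-test.
#' @return list with `t`, `df`, `p_value`, `means` (named per group),
#'   `n` (named per group).
#' @export
group_compare <- function(values, groups, var_equal = FALSE) {
  if (is.logical(groups))
    groups <- factor(groups, levels = c(TRUE, FALSE),
                     labels = c("case", "control"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  n <- table(groups)
  if (any(n < 2)) stop("each group needs at least 2 members")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  tt <- tryCatch(t.test(x, y, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # degenerate (constant) data: identical groups compare equal
    if (isTRUE(all.equal(mean(x), mean(y))))
      tt <- list(statistic = c(t = 0), parameter = c(df = length(values) - 2),
                 p.value = 1)
    else stop("t-test failed on degenerate data with unequal means")
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       means = c(setNames(mean(x), levels(groups)[1]),
                 setNames(mean(y), levels(groups)[2])),
       n = setNames(as.integer(n), names(n)))
}
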