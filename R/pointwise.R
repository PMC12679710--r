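# eye-level covariate matrix (no intercept); rows follow cohort$eyes
covariate_matrix <- function(cohort, covariates = c("age", "sex",
                                                    "scan_radius",
                                                    "education"),
                             education_coding = c("ordinal", "dummy")) {
  education_coding <- match.arg(education_coding)
  p <- cohort$participants
  idx <- match(cohort$eyes$subject_id, p$subject_id)
  cols <- list()
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = p$age[idx],
      sex = as.numeric(p$sex[idx] == "male"),
      scan_radius = cohort$eyes$scan_radius_mm,
      education = if (education_coding == "ordinal") {
        education_ordinal(p$education[idx])
      } else {
        e <- education_ordinal(p$education[idx])
        cbind(edu_intermediate = as.numeric(e == 2),
              edu_high = as.numeric(e == 3))
      },
      stop("unknown covariate: ", cv))
  }
  X <- do.call(cbind, cols)
  nm <- unlist(lapply(names(cols), function(cv) {
    k <- if (is.matrix(cols[[cv]])) colnames(cols[[cv]]) else cv
    k
  }))
  colnames(X) <- nm
  list(X = X, subject = cohort$eyes$subject_id[seq_len(nrow(X))])
}

# masked thickness matrix (NA where missing/unreliable)
masked_thickness <- function(cohort) {
  th <- cohort$thickness
  th[effective_mask(cohort)] <- NA
  th
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values over one family of tests (typically the 768
#' locations of one domain x sample x stratum analysis), with significance
#' declared at adjusted p below `alpha`.
#'
#' @param p_values raw p-values in `[0, 1]` (NAs propagate).
#' @param alpha significance level (default 0.05).
#' @return list with `q_value` (BH-adjusted p) and logical `significant`.
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(q_value = numeric(0), significant = logical(0)))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  list(q_value = q, significant = !is.na(q) & q < alpha)
}

#' Pointwise linear association between cpRNFLT and a cognitive domain
#'
#' At each of the 768 locations, ordinary least squares of thickness on the
#' domain z-score plus covariates (age, sex indicator, scan radius, ordinal
#' CASMIN education by default). Both eyes of a participant enter as separate
#' rows; an optional cluster-robust (CR1, by subject) standard-error mode
#' accounts for within-person eye correlation. Locations where an eye's value
#' is masked drop that eye from that location's fit only. Raw p-values are
#' BH-adjusted over the family of fitted locations.
#'
#' @param cohort a [cohort()] with domain z-scores (see [zscore_domains()]).
#' @param domain one of `attention`, `executive`, `memory`,
#'   `perceptual_motor`, `language`, `social`.
#' @param covariates covariate names; use e.g. `c("age", "scan_radius",
#'   "education")` for sex-stratified runs.
#' @param alpha FDR significance level.
#' @param education_coding `"ordinal"` (1/2/3) or `"dummy"`.
#' @param direction `"thickness_outcome"` (default: thickness regressed on
#'   domain score) or `"domain_outcome"` (reversed).
#' @param cluster_se if TRUE, CR1 cluster-robust SEs by subject.
#' @return data.frame of class `pointwise_result`: `location_index` (0-767),
#'   `angle_deg`, `n`, `coefficient` (um per z-unit, or z per um when
#'   reversed), `se`, `statistic`, `p_value`, `q_value`, `significant`,
#'   `unfit`.
#' @export
fit_pointwise_linear <- function(cohort, domain,
                                 covariates = c("age", "sex", "scan_radius",
                                                "education"),
                                 alpha = 0.05,
                                 education_coding = c("ordinal", "dummy"),
                                 direction = c("thickness_outcome",
                                               "domain_outcome"),
                                 cluster_se = FALSE) {
  direction <- match.arg(direction)
  cohort <- ensure_oriented(cohort)
  zcol <- paste0("z_", domain)
  if (!zcol %in% names(cohort$participants))
    stop("no column '", zcol, "': run zscore_domains() first")
  cm <- covariate_matrix(cohort, covariates, education_coding)
  idx <- match(cohort$eyes$subject_id, cohort$participants$subject_id)
  z <- cohort$participants[[zcol]][idx]
  Y <- masked_thickness(cohort)
  keep <- !is.na(z) & complete.cases(cm$X)
  z <- z[keep]; Y <- Y[keep, , drop = FALSE]
  Xc <- cm$X[keep, , drop = FALSE]
  subject <- cm$subject[keep]

  if (direction == "thickness_outcome") {
    X <- cbind(`(Intercept)` = 1, domain = z, Xc)
    res <- ols_by_column(X, Y, term = 2L, subject = subject,
                         cluster_se = cluster_se)
  } else {
    res <- matrix(NA_real_, N_LOCATIONS, 5)
    colnames(res) <- c("coefficient", "se", "statistic", "p_value", "n")
    for (j in seq_len(N_LOCATIONS)) {
      Xj <- cbind(`(Intercept)` = 1, thickness = Y[, j], Xc)
      r <- ols_by_column(Xj[!is.na(Y[, j]), , drop = FALSE],
                         matrix(z[!is.na(Y[, j])], ncol = 1), term = 2L,
                         subject = subject[!is.na(Y[, j])],
                         cluster_se = cluster_se)
      res[j, ] <- r[1, ]
    }
  }
  out <- data.frame(location_index = 0:(N_LOCATIONS - 1),
                    angle_deg = profile_angles(),
                    n = res[, "n"],
                    coefficient = res[, "coefficient"],
                    se = res[, "se"],
                    statistic = res[, "statistic"],
                    p_value = res[, "p_value"])
  out$unfit <- is.na(out$p_value)
  if (any(out$unfit))
    warning(sum(out$unfit), " location(s) could not be fitted; ",
            "excluded from the FDR family")
  adj <- fdr_adjust(out$p_value, alpha = alpha)
  out$q_value <- adj$q_value
  out$significant <- adj$significant
  attr(out, "domain") <- domain
  attr(out, "alpha") <- alpha
  attr(out, "direction") <- direction
  class(out) <- c("pointwise_result", "data.frame")
  out
}

# shared OLS engine: regress every column of Y on X, report the `term`-th
# coefficient. Columns without NA share one normal-equations solve.
ols_by_column <- function(X, Y, term, subject = NULL, cluster_se = FALSE) {
  n <- nrow(X); p <- ncol(X)
  m <- ncol(Y)
  out <- matrix(NA_real_, m, 5,
                dimnames = list(NULL, c("coefficient", "se", "statistic",
                                        "p_value", "n")))
  fit_block <- function(Xs, Ys, rows_subject) {
    ns <- nrow(Xs)
    if (ns < p + 1) return(NULL)
    XtX <- crossprod(Xs)
    XtXinv <- tryCatch(chol2inv(chol(XtX)), error = function(e) NULL)
    if (is.null(XtXinv)) return(NULL)
    beta <- XtXinv %*% crossprod(Xs, Ys)
    resid <- Ys - Xs %*% beta
    df <- ns - p
    if (cluster_se) {
      se <- stat <- pv <- numeric(ncol(Ys))
      G <- length(unique(rows_subject))
      corr <- G / (G - 1) * (ns - 1) / df
      for (jj in seq_len(ncol(Ys))) {
        S <- rowsum(Xs * resid[, jj], rows_subject)
        V <- XtXinv %*% crossprod(S) %*% XtXinv * corr
        se[jj] <- sqrt(V[term, term])
        stat[jj] <- beta[term, jj] / se[jj]
        pv[jj] <- 2 * pt(-abs(stat[jj]), df = G - 1)
      }
    } else {
      sigma2 <- colSums(resid^2) / df
      se <- sqrt(sigma2 * XtXinv[term, term])
      stat <- beta[term, ] / se
      pv <- 2 * pt(-abs(stat), df = df)
    }
    cbind(coefficient = beta[term, ], se = se, statistic = stat,
          p_value = pv, n = ns)
  }
  na_count <- colSums(is.na(Y))
  complete <- which(na_count == 0)
  if (length(complete)) {
    blk <- fit_block(X, Y[, complete, drop = FALSE], subject)
    if (!is.null(blk)) out[complete, ] <- blk
  }
  for (j in which(na_count > 0)) {
    rows <- !is.na(Y[, j])
    blk <- fit_block(X[rows, , drop = FALSE],
                     Y[rows, j, drop = FALSE], subject[rows])
    if (!is.null(blk)) out[j, ] <- blk
  }
  out
}

#' Fraction of significant locations
#'
#' @param x a `pointwise_result` (or a logical significance mask).
#' @param denominator `"fitted"` counts q-significant locations out of the
#'   locations actually fitted; `"all"` uses all 768.
#' @return percentage (0-100).
#' @export
significant_fraction <- function(x, denominator = c("fitted", "all")) {
  denominator <- match.arg(denominator)
  if (is.logical(x)) return(100 * sum(x, na.rm = TRUE) / length(x))
  stopifnot(inherits(x, "pointwise_result"))
  n_sig <- sum(x$significant & !x$unfit, na.rm = TRUE)
  denom <- if (denominator == "fitted") sum(!x$unfit) else nrow(x)
  if (denom == 0) return(0)
  100 * n_sig / denom
}

#' Summarise a pointwise result by sector
#'
#' @param result a `pointwise_result`.
#' @param scheme a [sector_scheme()] (default: the six anatomical sectors).
#' @return data.frame per sector: `label`, `n_locations`, `n_fitted`,
#'   `n_significant`, `frac_significant`, `mean_coefficient`.
#' @export
sector_summary <- function(result, scheme = sector_scheme_6()) {
  sec <- sector_of_angle(result$angle_deg, scheme)
  do.call(rbind, lapply(scheme$label, function(lb) {
    r <- result[sec == lb, ]
    fitted <- !r$unfit
    data.frame(label = lb,
               n_locations = nrow(r),
               n_fitted = sum(fitted),
               n_significant = sum(r$significant & fitted, na.rm = TRUE),
               frac_significant = if (sum(fitted) > 0)
                 sum(r$significant & fitted, na.rm = TRUE) / sum(fitted)
               else NA_real_,
               mean_coefficient = mean(r$coefficient[fitted]),
               stringsAsFactors = FALSE)
  }))
}

#' Global-mean thickness regression
#'
#' The same linear model as [fit_pointwise_linear()] with each eye's mean
#' thickness over its non-masked locations as outcome.
#'
#' @inheritParams fit_pointwise_linear
#' @return list with `beta` (um per z-unit), `se`, `statistic`, `p_value`,
#'   `n`.
#' @export
fit_global_mean <- function(cohort, domain,
                            covariates = c("age", "sex", "scan_radius",
                                           "education"),
                            education_coding = c("ordinal", "dummy"),
                            cluster_se = FALSE) {
  cohort <- ensure_oriented(cohort)
  zcol <- paste0("z_", domain)
  if (!zcol %in% names(cohort$participants))
    stop("no column '", zcol, "': run zscore_domains() first")
  cm <- covariate_matrix(cohort, covariates, education_coding)
  idx <- match(cohort$eyes$subject_id, cohort$participants$subject_id)
  z <- cohort$participants[[zcol]][idx]
  gm <- rowMeans(masked_thickness(cohort), na.rm = TRUE)
  keep <- !is.na(z) & complete.cases(cm$X) & is.finite(gm)
  if (sd(gm[keep]) == 0) stop("degenerate outcome: global mean has no variance")
  X <- cbind(`(Intercept)` = 1, domain = z[keep], cm$X[keep, , drop = FALSE])
  res <- ols_by_column(X, matrix(gm[keep], ncol = 1), term = 2L,
                       subject = cm$subject[keep], cluster_se = cluster_se)
  list(beta = res[1, "coefficient"], se = res[1, "se"],
       statistic = res[1, "statistic"], p_value = res[1, "p_value"],
       n = res[1, "n"])
}

#' Plot a pointwise coefficient track
#'
#' Coefficient versus angle from the temporal midline, with FDR-significant
#' arcs highlighted and the six anatomical sector boundaries annotated.
#'
#' @param x a `pointwise_result`.
#' @param scheme sector scheme used for the axis annotation.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.pointwise_result <- function(x, scheme = sector_scheme_6(), ...) {
  ok <- !x$unfit
  graphics::plot(x$angle_deg[ok], x$coefficient[ok], type = "l",
                 xlab = "angle from temporal midline (deg, TSNIT)",
                 ylab = "coefficient", xaxt = "n", ...)
  graphics::axis(1, at = seq(0, 360, 45))
  graphics::abline(h = 0, lty = 3)
  bounds <- sort(scheme$start_deg %% 360)
  graphics::abline(v = bounds, col = "grey80")
  mids <- (scheme$start_deg + scheme$width_deg / 2) %% 360
  graphics::mtext(scheme$label, side = 3, at = mids, line = 0.2, cex = 0.8)
  sig <- ok & x$significant
  if (any(sig))
    graphics::points(x$angle_deg[sig], x$coefficient[sig], col = "red",
                     pch = 16, cex = 0.4)
  invisible(x)
}
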