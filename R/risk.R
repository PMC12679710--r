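#' Pointwise logistic regression of a diagnosis on cpRNFLT
#'
#' At each location, maximum-likelihood logistic regression of the
#' participant-level diagnosis flag (carried by every eye row) on thickness
#' plus covariates. Locations with non-converged fits or degenerate standard
#' errors (e.g. complete separation) are flagged unfit and excluded from the
#' BH-FDR family. The in-sample AUC of each location's full model is also
#' reported.
#'
#' @param cohort a [cohort()] with diagnosis flags (see [classify_mci_ncd()]).
#' @param outcome diagnosis flag column, e.g. `"dx_mci"`.
#' @param covariates,alpha,education_coding as in [fit_pointwise_linear()].
#' @return data.frame of class `pointwise_result` with `coefficient`
#'   (log-odds per um), `se`, `statistic`, `p_value`, `q_value`,
#'   `significant`, `unfit`, `auc`.
#' @export
fit_pointwise_logistic <- function(cohort, outcome = "dx_mci",
                                   covariates = c("age", "sex",
                                                  "scan_radius", "education"),
                                   alpha = 0.05,
                                   education_coding = c("ordinal", "dummy")) {
  cohort <- ensure_oriented(cohort)
  if (!outcome %in% names(cohort$participants))
    stop("no column '", outcome, "' in participants")
  cm <- covariate_matrix(cohort, covariates, education_coding)
  idx <- match(cohort$eyes$subject_id, cohort$participants$subject_id)
  y <- cohort$participants[[outcome]][idx]
  Y <- masked_thickness(cohort)
  keep <- !is.na(y) & complete.cases(cm$X)
  y <- as.numeric(y[keep]); Y <- Y[keep, , drop = FALSE]
  Xc <- cm$X[keep, , drop = FALSE]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")

  res <- matrix(NA_real_, N_LOCATIONS, 6,
                dimnames = list(NULL, c("coefficient", "se", "statistic",
                                        "p_value", "n", "auc")))
  for (j in seq_len(N_LOCATIONS)) {
    rows <- !is.na(Y[, j])
    yj <- y[rows]
    if (length(unique(yj)) < 2) next
    Xj <- cbind(`(Intercept)` = 1, thickness = Y[rows, j],
                Xc[rows, , drop = FALSE])
    fit <- logistic_fit(Xj, yj)
    if (is.null(fit)) next
    res[j, ] <- c(fit$coef[2], fit$se[2], fit$coef[2] / fit$se[2],
                  2 * pnorm(-abs(fit$coef[2] / fit$se[2])),
                  length(yj), auc_score(fit$fitted, yj))
  }
  out <- data.frame(location_index = 0:(N_LOCATIONS - 1),
                    angle_deg = profile_angles(),
                    n = res[, "n"],
                    coefficient = res[, "coefficient"],
                    se = res[, "se"],
                    statistic = res[, "statistic"],
                    p_value = res[, "p_value"],
                    auc = res[, "auc"])
  out$unfit <- is.na(out$p_value)
  if (any(out$unfit))
    warning(sum(out$unfit), " location(s) unfit (separation or ",
            "non-convergence); excluded from the FDR family")
  adj <- fdr_adjust(out$p_value, alpha = alpha)
  out$q_value <- adj$q_value
  out$significant <- adj$significant
  attr(out, "outcome") <- outcome
  attr(out, "alpha") <- alpha
  attr(out, "model") <- "logistic"
  class(out) <- c("pointwise_result", "data.frame")
  out
}

# IRLS logistic fit with convergence / separation guards; NULL when unusable
logistic_fit <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) return(NULL)
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  se <- sqrt(diag(cov))
  if (any(!is.finite(se))) return(NULL)
  # complete separation: every fitted probability at the 0/1 boundary
  if (max(fit$fitted.values * (1 - fit$fitted.values)) < 1e-8) return(NULL)
  list(coef = fit$coefficients, se = se, fitted = fit$fitted.values,
       deviance = fit$deviance, aic = fit$aic)
}

#' Area under the ROC curve from scores and labels
#'
#' Normalised Mann-Whitney U statistic: the probability that a random case
#' outscores a random control, with ties credited 0.5.
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted logistic model
#'
#' In-sample AUC of the model's predicted probabilities against the outcome
#' it was fitted to.
#'
#' @param model a fitted [stats::glm()] object (binomial family).
#' @return AUC in `[0, 1]`.
#' @export
auc_of_model <- function(model) {
  stopifnot(inherits(model, "glm"))
  auc_score(fitted(model), model$y)
}

#' ROC curve from scores and labels
#'
#' Stepwise curve over the distinct score thresholds (decreasing); the
#' trapezoidal area under it equals the Mann-Whitney AUC.
#'
#' @inheritParams auc_score
#' @return data.frame with `threshold`, `fpr`, `tpr`, starting at (0, 0).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- rev(!duplicated(rev(s)))      # last row of each tied-score block
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / n0),
             tpr = c(0, tp[last] / n1))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc a data.frame from [roc_curve()].
#' @return area in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Permutation-calibrated AUC p-value
#'
#' Fits a logistic model, then builds an empirical null by shuffling the
#' outcome labels `n_perm` times and refitting the full model (covariates
#' included) on each permutation, recording each refit's in-sample AUC
#' against its permuted labels. The empirical p-value is the fraction of
#' null AUCs greater than or equal to the observed AUC. Non-converged refits
#' are counted and excluded from the null sample. Note that the in-sample
#' null distribution centres above 0.5 in finite samples because every refit
#' enjoys the same optimism as the observed model; the comparison is
#' therefore like-with-like.
#'
#' @param formula model formula with the binary outcome on the left.
#' @param data data.frame of eye-level rows.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed; results are deterministic given it.
#' @param shuffle `"row"` permutes labels across rows; `"subject"` permutes
#'   participant labels jointly so both eyes of a subject stay tied.
#' @param subject subject identifier per row (required for
#'   `shuffle = "subject"`).
#' @param label optional label stored in the result.
#' @return object of class `auc_result`: `observed_auc`, `null_aucs`,
#'   `p_empirical`, `n_perm`, `n_used`, `n_nonconverged`, `seed`, `label`.
#' @export
permutation_auc_pvalue <- function(formula, data, n_perm = 5000, seed = 1L,
                                   shuffle = c("row", "subject"),
                                   subject = NULL, label = NULL) {
  shuffle <- match.arg(shuffle)
  stopifnot(n_perm >= 1)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  obs <- logistic_fit(X, y)
  if (is.null(obs)) stop("observed model did not converge")
  observed_auc <- auc_score(obs$fitted, y)

  if (shuffle == "subject") {
    if (is.null(subject)) stop("subject ids required for subject-level shuffle")
    subject <- as.character(subject)
    us <- unique(subject)
    ylab <- y[match(us, subject)]
    if (any(tapply(y, subject, function(v) length(unique(v))) > 1))
      stop("labels differ within subject: cannot shuffle at subject level")
  }
  set.seed(seed)
  null_aucs <- rep(NA_real_, n_perm)
  for (b in seq_len(n_perm)) {
    yp <- if (shuffle == "row") sample(y) else {
      yl <- sample(ylab)
      yl[match(subject, us)]
    }
    fit <- logistic_fit(X, yp)
    if (!is.null(fit)) null_aucs[b] <- auc_score(fit$fitted, yp)
  }
  ok <- !is.na(null_aucs)
  structure(list(label = label,
                 observed_auc = observed_auc,
                 null_aucs = null_aucs[ok],
                 p_empirical = sum(null_aucs[ok] >= observed_auc) / sum(ok),
                 n_perm = n_perm,
                 n_used = sum(ok),
                 n_nonconverged = sum(!ok),
                 seed = seed),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat("Permutation AUC test", if (!is.null(x$label)) paste0("[", x$label, "]"),
      "\n")
  cat(sprintf("  observed AUC %.3f, null mean %.3f (n_perm = %d, %d excluded)\n",
              x$observed_auc, mean(x$null_aucs), x$n_perm, x$n_nonconverged))
  cat(sprintf("  empirical p = %.4g\n", x$p_empirical))
  invisible(x)
}
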