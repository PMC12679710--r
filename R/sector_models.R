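# eye-level modelling frame: outcome, covariates, per-sector mean thickness
sector_model_frame <- function(cohort, outcome, scheme,
                               covariates = c("age", "sex", "scan_radius",
                                              "education"),
                               education_coding = c("ordinal", "dummy")) {
  cohort <- ensure_oriented(cohort)
  if (!outcome %in% names(cohort$participants))
    stop("no column '", outcome, "' in participants")
  sm <- aggregate_sectors(cohort, scheme)
  cm <- covariate_matrix(cohort, covariates, education_coding)
  idx <- match(cohort$eyes$subject_id, cohort$participants$subject_id)
  y <- cohort$participants[[outcome]][idx]
  df <- data.frame(y = as.numeric(y), cm$X, sm, check.names = FALSE)
  df <- df[complete.cases(df), , drop = FALSE]
  attr(df, "covariate_names") <- colnames(cm$X)
  attr(df, "sector_labels") <- colnames(sm)
  df
}

# logistic fit of y on covariates + the selected sectors; NULL if unusable
fit_sector_glm <- function(frame, selected,
                           covar_names = attr(frame, "covariate_names")) {
  vars <- c(covar_names, selected)
  f <- stats::as.formula(paste("y ~",
                               if (length(vars))
                                 paste(sprintf("`%s`", vars), collapse = " + ")
                               else "1"))
  fit <- tryCatch(suppressWarnings(glm(f, data = frame, family = binomial())),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit
}

sector_model_summary <- function(fit, selected, criterion, search = NULL,
                                 trace = NULL) {
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  n <- length(fit$y)
  cf <- coef(fit)
  sec_cf <- cf[names(cf) %in% sprintf("`%s`", selected) |
                 names(cf) %in% selected]
  names(sec_cf) <- gsub("`", "", names(sec_cf))
  structure(list(selected = selected,
                 coefficients = cf,
                 sector_coefficients = sec_cf,
                 signs = sign(sec_cf),
                 auc = auc_score(fitted(fit), fit$y),
                 loglik = ll, k = k, n = n,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 criterion = criterion, search = search, trace = trace),
            class = "sector_model")
}

#' @export
print.sector_model <- function(x, ...) {
  cat("Sector logistic model (", x$criterion,
      if (!is.null(x$search)) paste0(", ", x$search, " search"), ")\n",
      sep = "")
  cat("  sectors:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  AUC %.3f | AIC %.2f | BIC %.2f | logLik %.2f | n %d | k %d\n",
              x$auc, x$aic, x$bic, x$loglik, x$n, x$k))
  invisible(x)
}

#' Best-discriminating combination of cpRNFLT sectors
#'
#' Searches combinations of sector mean thicknesses for the logistic model
#' (covariates always included) minimising AIC or BIC. Forward stepwise
#' selection adds at each step the sector that most improves the criterion
#' and stops when no addition improves it or `max_k` sectors are included;
#' exhaustive search (allowed for at most 12 candidate sectors) enumerates
#' every subset including the empty one. Ties break towards the lower sector
#' index, so the search is deterministic. `AIC = 2k - 2l` and
#' `BIC = k ln(n) - 2l` with `k` the number of estimated parameters and `l`
#' the maximised log-likelihood.
#'
#' @param cohort a [cohort()] with diagnosis flags.
#' @param outcome diagnosis flag column, e.g. `"dx_amnestic_mci"`.
#' @param scheme a [sector_scheme()] (default: 24 x 15-degree sectors).
#' @param criterion `"AIC"` or `"BIC"`.
#' @param search `"forward"` or `"exhaustive"`.
#' @param max_k maximum number of sectors for forward selection.
#' @param covariates,education_coding as in [fit_pointwise_linear()].
#' @return object of class `sector_model`: selected sector labels, signed
#'   coefficients, in-sample AUC, AIC/BIC/log-likelihood, and (for forward
#'   search) a step-by-step `trace` of candidate criterion values.
#' @export
best_sector_subset <- function(cohort, outcome, scheme = sector_scheme_24(),
                               criterion = c("AIC", "BIC"),
                               search = c("forward", "exhaustive"),
                               max_k = Inf,
                               covariates = c("age", "sex", "scan_radius",
                                              "education"),
                               education_coding = c("ordinal", "dummy")) {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  frame <- sector_model_frame(cohort, outcome, scheme, covariates,
                              education_coding)
  labels <- attr(frame, "sector_labels")
  crit_of <- function(fit) if (criterion == "AIC") AIC(fit) else BIC(fit)

  if (search == "exhaustive") {
    if (length(labels) > 12)
      stop("exhaustive search allowed for at most 12 sectors")
    best <- NULL; best_sel <- character(0); best_crit <- Inf
    idx_sets <- c(list(integer(0)), unlist(lapply(seq_along(labels),
      function(k) utils::combn(seq_along(labels), k, simplify = FALSE)),
      recursive = FALSE))
    for (is in idx_sets) {
      sel <- labels[is]
      fit <- fit_sector_glm(frame, sel)
      if (is.null(fit)) { warning("skipping non-convergent subset"); next }
      cr <- crit_of(fit)
      if (cr < best_crit - 1e-12) {   # strict improvement keeps earlier ties
        best <- fit; best_sel <- sel; best_crit <- cr
      }
    }
    return(sector_model_summary(best, best_sel, criterion, search))
  }

  selected <- character(0)
  fit0 <- fit_sector_glm(frame, selected)
  if (is.null(fit0)) stop("covariates-only model did not converge")
  current <- crit_of(fit0)
  best_fit <- fit0
  trace <- list()
  step <- 0L
  while (length(selected) < min(max_k, length(labels))) {
    step <- step + 1L
    cand <- setdiff(labels, selected)
    crits <- rep(NA_real_, length(cand))
    for (i in seq_along(cand)) {
      fit <- fit_sector_glm(frame, c(selected, cand[i]))
      if (is.null(fit)) { warning("skipping non-convergent candidate ",
                                  cand[i]); next }
      crits[i] <- crit_of(fit)
    }
    trace[[step]] <- data.frame(step = step, candidate = cand,
                                criterion_value = crits,
                                stringsAsFactors = FALSE)
    if (all(is.na(crits)) || min(crits, na.rm = TRUE) >= current) break
    pick <- which.min(crits)           # first minimum = lowest sector index
    selected <- c(selected, cand[pick])
    best_fit <- fit_sector_glm(frame, selected)
    current <- crits[pick]
  }
  sector_model_summary(best_fit, selected, criterion, "forward",
                       trace = do.call(rbind, trace))
}

#' Evaluate a fixed, externally specified sector subset
#'
#' Single logistic fit of the outcome on the named sector means plus
#' covariates, reporting signed per-sector coefficients (so mixed
#' thinning/thickening patterns stay visible) alongside AUC, AIC and BIC.
#'
#' @param cohort a [cohort()] with diagnosis flags.
#' @param outcome diagnosis flag column.
#' @param sector_labels labels of the sectors to include (may be empty, which
#'   evaluates the covariates-only model).
#' @param scheme,covariates,education_coding as in [best_sector_subset()].
#' @return object of class `sector_model`.
#' @export
evaluate_fixed_subset <- function(cohort, outcome, sector_labels,
                                  scheme = sector_scheme_24(),
                                  covariates = c("age", "sex", "scan_radius",
                                                 "education"),
                                  education_coding = c("ordinal", "dummy")) {
  frame <- sector_model_frame(cohort, outcome, scheme, covariates,
                              education_coding)
  labels <- attr(frame, "sector_labels")
  bad <- setdiff(sector_labels, labels)
  if (length(bad)) stop("unknown sector label(s): ", paste(bad, collapse = ", "))
  fit <- fit_sector_glm(frame, sector_labels)
  if (is.null(fit)) stop("model did not converge")
  sector_model_summary(fit, sector_labels, criterion = "fixed")
}
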