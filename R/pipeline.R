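#' Configuration of a full analysis run
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param sim a [sim_config()] used when no cohort is supplied.
#' @param domains cognitive domains for the pointwise linear analyses.
#' @param outcomes diagnosis flags for pointwise logistic analyses.
#' @param amnestic_outcomes diagnosis flags for the sector-combination
#'   models.
#' @param n_perm permutations for AUC calibration.
#' @param alpha FDR level.
#' @param scheme `"sectors24"` or `"sectors6"`.
#' @param stratum `"all"`, `"female"` or `"male"` (stratified runs drop sex
#'   from the covariates).
#' @param min_cases minimum diagnosis carriers needed to run an outcome;
#'   rarer outcomes are skipped with a note in the manifest.
#' @param seed seed for permutation tests and the brain-volume simulator.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = sim_config(),
                       domains = c("attention", "executive", "memory",
                                   "perceptual_motor", "language", "social"),
                       outcomes = c("dx_mci", "dx_mild_ncd"),
                       amnestic_outcomes = c("dx_amnestic_mci",
                                             "dx_amnestic_mild_ncd"),
                       n_perm = 200, alpha = 0.05,
                       scheme = c("sectors24", "sectors6"),
                       stratum = c("all", "female", "male"),
                       min_cases = 10,
                       seed = sim$seed) {
  scheme <- match.arg(scheme)
  stratum <- match.arg(stratum)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(out_dir = out_dir, sim = sim, domains = domains,
                 outcomes = outcomes, amnestic_outcomes = amnestic_outcomes,
                 n_perm = as.integer(n_perm), alpha = alpha, scheme = scheme,
                 stratum = stratum, min_cases = min_cases,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; the `sim` key (if
#' present) holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` if given.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(raw$sim, tmp)
    defaults <- unclass(sim_config())
    user <- yaml::read_yaml(tmp)
    merged <- utils::modifyList(defaults, user)
    yaml::write_yaml(merged, tmp, precision = 15)
    raw$sim <- read_sim_config(tmp)
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' Split a cohort into samples A and B
#'
#' Sample A keeps QC-passed eyes without eye disease; sample B additionally
#' removes participants carrying a CNS condition or centrally acting
#' medication flag, so B is a subset of A.
#'
#' @param cohort a [cohort()] (aligned; [flag_unreliable()] applied).
#' @param qc a `qc_report` from [qc_filter()] (computed if NULL).
#' @param cns_flag participant column marking CNS conditions / centrally
#'   acting drugs.
#' @param eye_disease_flag eye-level column marking relevant eye pathology
#'   (ignored when absent).
#' @return list with cohorts `sample_A` and `sample_B`.
#' @export
build_samples <- function(cohort, qc = NULL, cns_flag = "cns_condition",
                          eye_disease_flag = "eye_disease") {
  cohort <- ensure_oriented(cohort)
  if (is.null(qc)) qc <- qc_filter(cohort)
  ok <- qc$passed[match(cohort$eyes$eye_id, qc$eye_id)]
  if (eye_disease_flag %in% names(cohort$eyes))
    ok <- ok & !isTRUE_vec(cohort$eyes[[eye_disease_flag]])
  sample_A <- subset_cohort(cohort, eye_ids = cohort$eyes$eye_id[ok])
  cns <- if (cns_flag %in% names(sample_A$participants))
    isTRUE_vec(sample_A$participants[[cns_flag]]) else
      rep(FALSE, nrow(sample_A$participants))
  keep_subj <- sample_A$participants$subject_id[!cns]
  sample_B <- subset_cohort(sample_A, subject_ids = keep_subj)
  if (nrow(sample_B$eyes) == 0) warning("sample B is empty")
  list(sample_A = sample_A, sample_B = sample_B)
}

# 32-bit FNV-1a hash of a deparsed object, for manifest provenance
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> orient -> flag unreliable points ->
#' QC filter -> score and classify -> sample A/B construction -> pointwise
#' linear association per domain -> global-mean models -> pointwise logistic
#' discrimination with AUC by location and sector and permutation-calibrated
#' p-values for the best and worst locations -> sector-combination models ->
#' brain-volume group comparisons. All outputs are delimited text or JSON in
#' the run directory; `manifest.json` records the configuration hash, seeds,
#' package version and row/eye counts at every stage, so identical
#' configurations yield identical runs.
#'
#' @param config a [run_config()].
#' @param cohort optional pre-built [cohort()]; simulated from `config$sim`
#'   when NULL.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "retinocog",
                   version = as.character(packageVersion("retinocog")),
                   seed = config$seed,
                   config_hash = config_hash(unclass(config)),
                   stages = list(), notes = list(), files = character(0))
  finish <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name, obj, writer) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    manifest$files <<- c(manifest$files, name)
  }
  wcsv <- function(obj, path) write.csv(obj, path, row.names = FALSE)
  wjson <- function(obj, path)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)

  # --- simulate / ingest -------------------------------------------------
  cohort <- stage("simulate", {
    ch <- cohort %||% generate_cohort(config$sim)
    write_cohort(ch, config$out_dir)
    manifest$stages$simulate <- list(
      n_participants = nrow(ch$participants), n_eyes = nrow(ch$eyes))
    ch
  })

  # --- qc ----------------------------------------------------------------
  samples <- stage("qc", {
    ch <- align_orientation(cohort)
    ch <- flag_unreliable(ch)
    qc <- qc_filter(ch)
    emit("qc_report.csv", qc, wcsv)
    ss <- build_samples(ch, qc)
    manifest$stages$qc <- list(
      n_eyes_in = nrow(ch$eyes), n_eyes_passed = sum(qc$passed),
      n_points_unreliable = sum(ch$unreliable),
      n_sample_A_eyes = nrow(ss$sample_A$eyes),
      n_sample_A_participants = nrow(ss$sample_A$participants),
      n_sample_B_eyes = nrow(ss$sample_B$eyes),
      n_sample_B_participants = nrow(ss$sample_B$participants))
    ss
  })

  # --- stratum and covariates -------------------------------------------
  covars <- c("age", "sex", "scan_radius", "education")
  if (config$stratum != "all") {
    covars <- setdiff(covars, "sex")
    for (nm in names(samples)) {
      keep <- samples[[nm]]$participants$sex == config$stratum
      samples[[nm]] <- subset_cohort(
        samples[[nm]],
        subject_ids = samples[[nm]]$participants$subject_id[keep])
    }
  }

  # --- diagnoses ---------------------------------------------------------
  stage("classify", {
    p <- samples$sample_A$participants
    keep <- grep("^(subject_id|dx_|z_|nz_)", names(p), value = TRUE)
    emit("diagnoses.csv", p[, keep], wcsv)
    manifest$stages$classify <- lapply(
      c(config$outcomes, config$amnestic_outcomes),
      function(o) if (o %in% names(p)) sum(isTRUE_vec(p[[o]])) else NA)
    names(manifest$stages$classify) <-
      c(config$outcomes, config$amnestic_outcomes)
  })

  scheme <- if (config$scheme == "sectors24") sector_scheme_24()
            else sector_scheme_6()

  # --- pointwise linear associations ------------------------------------
  stage("associate", {
    sect_rows <- list()
    for (nm in names(samples)) for (dom in config$domains) {
      res <- fit_pointwise_linear(samples[[nm]], dom, covariates = covars,
                                  alpha = config$alpha)
      tag <- paste0(dom, "_", sub("sample_", "", nm),
                    if (config$stratum != "all")
                      paste0("_", config$stratum))
      emit(sprintf("pointwise_%s.csv", tag), res, wcsv)
      gm <- fit_global_mean(samples[[nm]], dom, covariates = covars)
      ss <- sector_summary(res, sector_scheme_6())
      ss <- cbind(domain = dom, sample = sub("sample_", "", nm), ss)
      sect_rows[[tag]] <- ss
      manifest$stages$associate[[tag]] <- list(
        pct_significant_fitted = significant_fraction(res, "fitted"),
        pct_significant_all = significant_fraction(res, "all"),
        global_mean_beta = gm$beta, global_mean_p = gm$p_value, n = gm$n)
    }
    emit("sector_summary.csv", do.call(rbind, sect_rows), wcsv)
  })

  # --- pointwise logistic discrimination --------------------------------
  stage("discriminate", {
    for (outc in config$outcomes) {
      p <- samples$sample_A$participants
      n_cases <- sum(isTRUE_vec(p[[outc]]))
      if (n_cases < config$min_cases) {
        manifest$notes[[outc]] <-
          sprintf("skipped: only %d cases", n_cases)
        next
      }
      res <- fit_pointwise_logistic(samples$sample_A, outc,
                                    covariates = covars,
                                    alpha = config$alpha)
      emit(sprintf("auc_by_location_%s.csv", outc), res, wcsv)
      # sector-mean logistic AUCs
      sm <- evaluate_sector_aucs(samples$sample_A, outc, scheme, covars)
      emit(sprintf("auc_by_sector_%s.csv", outc), sm, wcsv)
      # permutation calibration at the best and worst locations
      fitted_loc <- which(!res$unfit)
      if (length(fitted_loc)) {
        extremes <- c(best = fitted_loc[which.max(res$auc[fitted_loc])],
                      worst = fitted_loc[which.min(res$auc[fitted_loc])])
        for (lbl in names(extremes)) {
          which_loc <- extremes[[lbl]]
          pr <- location_permutation_test(samples$sample_A, outc,
                                          which_loc, covars,
                                          n_perm = config$n_perm,
                                          seed = config$seed)
          emit(sprintf("roc_%s_%s.csv", outc, lbl), pr$roc, wcsv)
          manifest$stages$discriminate[[paste(outc, lbl, sep = "_")]] <- list(
            location_index = which_loc - 1L,
            observed_auc = pr$test$observed_auc,
            null_auc_mean = mean(pr$test$null_aucs),
            p_empirical = pr$test$p_empirical,
            n_perm = pr$test$n_perm, seed = config$seed)
        }
      }
    }
  })

  # --- sector-combination models ----------------------------------------
  stage("sectors", {
    models <- list()
    for (outc in config$amnestic_outcomes) {
      p <- samples$sample_A$participants
      n_cases <- sum(isTRUE_vec(p[[outc]]))
      if (n_cases < config$min_cases) {
        manifest$notes[[outc]] <- sprintf("skipped: only %d cases", n_cases)
        next
      }
      bm <- best_sector_subset(samples$sample_A, outc, scheme,
                               criterion = "AIC", search = "forward",
                               covariates = covars)
      models[[outc]] <- list(selected = bm$selected,
                             signs = as.list(bm$signs),
                             coefficients = as.list(bm$coefficients),
                             auc = bm$auc, aic = bm$aic, bic = bm$bic,
                             loglik = bm$loglik, k = bm$k, n = bm$n,
                             trace = bm$trace)
    }
    if (length(models)) emit("sector_model.json", models, wjson)
  })

  # --- brain markers -----------------------------------------------------
  stage("brain", {
    vols <- simulate_brain_volumes(samples$sample_A,
                                   seed = config$seed + 11L)
    emit("brain_volumes.csv", vols, wcsv)
    adj <- adjust_hcv_for_icv(vols)
    p <- samples$sample_A$participants
    rows <- list()
    for (outc in config$outcomes) {
      g <- isTRUE_vec(p[[outc]])[match(adj$subject_id, p$subject_id)]
      if (sum(g) < 2 || sum(!g) < 2) next
      for (marker in c("hcv_left_adj_mm3", "hcv_right_adj_mm3",
                       "wm_lesion_mm3")) {
        gc <- group_compare(adj[[marker]], g)
        rows[[paste(outc, marker)]] <- data.frame(
          outcome = outc, marker = marker,
          n_case = gc$n[["case"]], n_control = gc$n[["control"]],
          mean_case = gc$means[["case"]],
          mean_control = gc$means[["control"]],
          t = gc$t, df = gc$df, p_value = gc$p_value)
      }
    }
    if (length(rows)) emit("group_comparisons.csv", do.call(rbind, rows), wcsv)
  })

  manifest$stages$done <- TRUE
  finish()
  invisible(manifest)
}

# AUC of the covariate-adjusted logistic model per sector mean
evaluate_sector_aucs <- function(cohort, outcome, scheme, covariates) {
  frame <- sector_model_frame(cohort, outcome, scheme, covariates)
  labels <- attr(frame, "sector_labels")
  rows <- lapply(labels, function(lb) {
    fit <- fit_sector_glm(frame, lb)
    if (is.null(fit)) return(NULL)
    data.frame(label = lb, auc = auc_score(fitted(fit), fit$y),
               coefficient = unname(coef(fit)[length(coef(fit))]),
               n = length(fit$y))
  })
  do.call(rbind, rows)
}

# permutation AUC test of the logistic model at one location (1-based index)
location_permutation_test <- function(cohort, outcome, location, covariates,
                                      n_perm, seed) {
  cm <- covariate_matrix(cohort, covariates)
  idx <- match(cohort$eyes$subject_id, cohort$participants$subject_id)
  y <- cohort$participants[[outcome]][idx]
  th <- masked_thickness(cohort)[, location]
  df <- data.frame(y = as.numeric(y), thickness = th, cm$X,
                   check.names = TRUE)
  df <- df[complete.cases(df), ]
  test <- permutation_auc_pvalue(y ~ ., df, n_perm = n_perm, seed = seed,
                                 label = sprintf("%s@loc%d", outcome,
                                                 location - 1L))
  fit <- glm(y ~ ., data = df, family = binomial())
  list(test = test, roc = roc_curve(fitted(fit), df$y))
}
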