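#' Write a cohort to delimited text files
#'
#' `eyes.csv` holds one row per eye (metadata plus thickness columns
#' `p000`...`p767`, empty where the point is acquisition-missing);
#' `participants.csv` holds covariates, raw scores and flags. If the cohort
#' was simulated, `simconfig.yaml` round-trips the full generator
#' configuration.
#'
#' @param cohort a [cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  th <- cohort$thickness
  th[cohort$missing] <- NA
  pcols <- as.data.frame(th)
  names(pcols) <- sprintf("p%03d", 0:(N_LOCATIONS - 1))
  eyes <- cbind(cohort$eyes, pcols)
  rownames(eyes) <- NULL
  paths <- c(eyes = file.path(dir, "eyes.csv"),
             participants = file.path(dir, "participants.csv"))
  write.csv(eyes, paths["eyes"], row.names = FALSE)
  write.csv(cohort$participants, paths["participants"], row.names = FALSE)
  if (inherits(cohort$provenance, "sim_config")) {
    paths["simconfig"] <- file.path(dir, "simconfig.yaml")
    write_sim_config(cohort$provenance, paths["simconfig"])
  }
  invisible(paths)
}

#' Read a cohort from delimited text files
#'
#' Counterpart of [write_cohort()]: empty thickness cells become missing
#' points. Percentile-based unreliability flags are not persisted; rerun
#' [flag_unreliable()] after reading.
#'
#' @param dir directory containing `eyes.csv` and `participants.csv`.
#' @return a [cohort()].
#' @export
read_cohort <- function(dir) {
  eyes <- read.csv(file.path(dir, "eyes.csv"), stringsAsFactors = FALSE)
  part <- read.csv(file.path(dir, "participants.csv"),
                   stringsAsFactors = FALSE)
  pnames <- sprintf("p%03d", 0:(N_LOCATIONS - 1))
  miss <- setdiff(pnames, names(eyes))
  if (length(miss)) stop("eyes.csv lacks thickness columns, e.g. ", miss[1])
  th <- as.matrix(eyes[, pnames])
  meta <- eyes[, setdiff(names(eyes), pnames), drop = FALSE]
  prov <- sprintf("read from %s", normalizePath(dir))
  cfg_path <- file.path(dir, "simconfig.yaml")
  if (file.exists(cfg_path)) prov <- read_sim_config(cfg_path)
  cohort(part, meta, th, missing = is.na(th), provenance = prov)
}

#' Round-trip a simulation configuration through YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_sim_config` returns the path invisibly; `read_sim_config`
#'   returns a validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  # named atomic vectors must become maps, or YAML drops their names
  to_map <- function(x) {
    if (is.list(x)) lapply(x, to_map)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(to_map(unclass(config)), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vecf <- c("age_range", "education_probs")
  for (f in vecf) raw[[f]] <- unlist(raw[[f]])
  raw$baseline_shape_params <- lapply(raw$baseline_shape_params, unlist)
  for (f in c("effect_map", "dx_effect_map"))
    raw[[f]] <- lapply(raw[[f]], function(entries)
      lapply(entries, function(e) {
        out <- list(interval = unlist(e$interval))
        if (!is.null(e$beta)) out$beta <- e$beta
        if (!is.null(e$delta)) out$delta <- e$delta
        out
      }))
  raw$tmt_params <- lapply(raw$tmt_params, unlist)
  raw$score_params <- lapply(raw$score_params, unlist)
  raw$diagnosis_params <- lapply(raw$diagnosis_params, unlist)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}
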