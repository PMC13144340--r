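#' End-to-end run configuration
#'
#' A single document describing an entire analysis: either a dataset
#' directory or a simulation configuration, the preprocessing settings, the
#' condition grouping, the contrasts, the permutation/TFCE settings, the
#' covariates for the dyadic regression, a mandatory seed and an output
#' directory. Can be given as a list or as a path to a YAML or JSON file.
#'
#' @param x list, or path to a `.yaml`/`.yml`/`.json` config file.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.ya?ml$", x)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the yaml package is needed to read YAML configs")
      x <- yaml::read_yaml(x)
    } else if (grepl("\\.json$", x)) {
      x <- jsonlite::read_json(x, simplifyVector = TRUE)
    } else stop("config file must be .yaml, .yml or .json")
  }
  stopifnot(is.list(x))
  if (is.null(x$seed)) stop("config must set a seed")
  if (is.null(x$out_dir)) stop("config must set out_dir")
  if (is.null(x$dataset) && is.null(x$sim))
    stop("config needs either a dataset directory or a sim block")
  defaults <- list(exclude_volumes = 8, detrend = 2, grouping = "frame",
                   baseline = "none", n_permutations = 1000,
                   tfce = list(), contrasts = NULL,
                   covariate_variables = NULL,
                   regression_conditions = NULL,
                   survey = NULL, behavior_outcomes = NULL)
  for (nm in names(defaults))
    if (is.null(x[[nm]])) x[[nm]] <- defaults[[nm]]
  if (!x$baseline %in% c("none", "subtract"))
    stop("baseline must be 'none' or 'subtract'")
  if (!x$grouping %in% c("frame", "frame_topic"))
    stop("grouping must be 'frame' or 'frame_topic'")
  x$seed <- as.integer(x$seed)
  class(x) <- "run_config"
  x
}

# deterministic per-stage seed derived from the single global seed
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, isc = 307L,
               contrast = 401L, regress = 503L, behavior = 601L)
  (as.integer(seed) * 7919L + offsets[[stage]]) %% 2147483647L
}

#' Parse a contrast given as "a-b" or "a>b" into a contrast vector
#' @param x character like `"neutral-blame"`, or an already-named numeric
#'   vector (returned unchanged).
#' @return named numeric contrast vector.
#' @export
parse_contrast <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(x, "[->]")[[1]]
  if (length(parts) != 2) stop("cannot parse contrast: ", x)
  setNames(c(1, -1), trimws(parts))
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate (optional) -> preprocess -> ISC -> condition contrasts ->
#' proximity regression (optional) -> behavioral models (optional) and writes
#' every stage's outputs plus a JSON + plain-text report with per-stage
#' parameters, derived seeds, file hashes and headline tables. A simulated
#' dataset already on disk with matching manifest hashes is reused rather
#' than regenerated. The report carries no timestamps, so identical
#' configurations produce byte-identical reports.
#'
#' @param config a [run_config()] (or list / file path coercible to one).
#' @return the report, invisibly (also written to `out_dir/report.json` and
#'   `out_dir/report.txt`).
#' @export
run_pipeline <- function(config) {
  config <- run_config(unclass(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "iscpipe",
                 version = as.character(utils::packageVersion("iscpipe")),
                 seed = config$seed, stages = list())

  # --- simulate / load -------------------------------------------------------
  if (!is.null(config$sim)) {
    sim_args <- config$sim
    sim_args$seed <- derive_seed(config$seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    dataset_dir <- config$dataset %||% file.path(config$out_dir, "dataset")
    reuse <- dataset_matches(dataset_dir)
    if (reuse) {
      cohort <- read_cohort(dataset_dir)
      cohort$config <- cfg
    } else {
      cohort <- simulate_cohort(cfg)
      write_cohort(cohort, dataset_dir)
    }
    report$stages$simulate <- list(params = sim_args, dir = dataset_dir,
                                   reused = reuse,
                                   files = dir_hashes(dataset_dir))
  } else {
    dataset_dir <- config$dataset
    cohort <- read_cohort(dataset_dir)
    report$stages$simulate <- list(dir = dataset_dir, reused = TRUE,
                                   files = dir_hashes(dataset_dir))
  }

  # --- preprocess ------------------------------------------------------------
  pre <- preprocess_cohort(cohort, n_exclude_volumes = config$exclude_volumes,
                           detrend = config$detrend)
  report$stages$preprocess <- list(exclude_volumes = config$exclude_volumes,
                                   detrend = config$detrend,
                                   n_segments = nrow(pre$segments),
                                   n_voxels = length(pre$voxel_ids))

  # --- ISC -------------------------------------------------------------------
  isc_seed <- derive_seed(config$seed, "isc")
  pm_seg <- all_pair_maps(pre$series_by_participant, pre$segments,
                          pre$voxel_ids)
  baseline <- NULL
  if (config$baseline == "subtract") {
    baseline <- all_baseline_maps(pre$series_by_participant, seed = isc_seed)
    pm_seg <- subtract_baseline(pm_seg, baseline)
  }
  pm <- average_by_condition(pm_seg, config$grouping)
  isc_dir <- file.path(config$out_dir, "isc")
  files <- write_pair_maps(pm, cohort$mask, isc_dir,
                           cohort$config$voxel_size_mm %||% 1)
  report$stages$isc <- list(grouping = config$grouping,
                            baseline = config$baseline, seed = isc_seed,
                            n_pairs = nrow(pm$pairs),
                            files = file_hashes(files))

  # --- contrasts -------------------------------------------------------------
  if (!is.null(config$contrasts)) {
    contrasts <- lapply(config$contrasts, parse_contrast)
    if (is.null(names(contrasts)))
      names(contrasts) <- vapply(config$contrasts, function(x)
        if (is.character(x)) x else "contrast", "")
    tp <- do.call(tfce_params, config$tfce)
    samples <- condition_samples(pm)
    prs <- permute_and_correct(samples, cohort$mask, contrasts, params = tp,
                               n_perm = config$n_permutations,
                               seed = derive_seed(config$seed, "contrast"))
    con_dir <- file.path(config$out_dir, "contrast")
    files <- character(0)
    headline <- data.frame(contrast = names(prs$results),
                           max_tfce = NA_real_, min_p_fwe = NA_real_,
                           n_sig_fwe05 = NA_integer_)
    for (k in seq_along(prs$results)) {
      r <- prs$results[[k]]
      files <- c(files, write_stat_maps(r, cohort$mask, con_dir,
                                        cohort$config$voxel_size_mm %||% 1))
      headline$max_tfce[k] <- max(r$observed_tfce)
      headline$min_p_fwe[k] <- min(r$p_fwe)
      headline$n_sig_fwe05[k] <- sum(r$p_fwe <= 0.05)
    }
    report$stages$contrast <- list(contrasts = names(prs$results),
                                   n_permutations = prs$n_permutations,
                                   seed = derive_seed(config$seed, "contrast"),
                                   tfce = unclass(tp),
                                   headline = headline,
                                   files = file_hashes(files))
  }

  # --- proximity regression --------------------------------------------------
  if (!is.null(config$covariate_variables)) {
    if (pm$baseline_subtracted) {
      pm_reg <- pm
    } else {
      if (is.null(baseline))
        baseline <- all_baseline_maps(pre$series_by_participant,
                                      seed = isc_seed)
      pm_reg <- average_by_condition(subtract_baseline(pm_seg, baseline),
                                     config$grouping)
    }
    design <- build_proximity_design(cohort$covariates, pm_reg$pairs,
                                     config$covariate_variables)
    conds <- config$regression_conditions %||%
      setdiff(pm_reg$scope$condition, "neutral")
    reg <- isc_proximity_regression(
      pm_reg, design, cohort$mask, conditions = conds,
      params = do.call(tfce_params, config$tfce),
      n_perm = config$n_permutations,
      seed = derive_seed(config$seed, "regress"))
    summ <- do.call(rbind, lapply(names(reg), function(cond) {
      do.call(rbind, lapply(names(reg[[cond]]), function(v) {
        r <- reg[[cond]][[v]]
        data.frame(condition = cond, regressor = v,
                   max_tfce = max(r$observed_tfce), min_p_fwe = min(r$p_fwe),
                   n_sig_fwe05 = sum(r$p_fwe <= 0.05))
      }))
    }))
    reg_dir <- file.path(config$out_dir, "regress")
    dir.create(reg_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(reg_dir, "proximity_summary.tsv")
    write.table(summ, f, sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$regress <- list(variables = config$covariate_variables,
                                  conditions = conds,
                                  seed = derive_seed(config$seed, "regress"),
                                  headline = summ, files = file_hashes(f))
  }

  # --- behavior --------------------------------------------------------------
  if (!is.null(config$survey)) {
    survey <- if (is.character(config$survey)) {
      read.csv(config$survey, stringsAsFactors = FALSE)
    } else config$survey
    survey <- composite_scores(survey)
    outcomes <- config$behavior_outcomes %||%
      c("negative_affect", "anger", "fear", "sharing")
    beh <- lapply(outcomes, function(oc)
      fit_framing_model(survey, oc, covariates = c("age", "gender")))
    names(beh) <- outcomes
    beh_dir <- file.path(config$out_dir, "behavior")
    dir.create(beh_dir, recursive = TRUE, showWarnings = FALSE)
    coefs <- do.call(rbind, lapply(outcomes, function(oc)
      cbind(outcome = oc, beh[[oc]]$coefficients)))
    f <- file.path(beh_dir, "framing_models.tsv")
    write.table(coefs, f, sep = "\t", row.names = FALSE, quote = FALSE)
    report$stages$behavior <- list(outcomes = outcomes, headline = coefs,
                                   files = file_hashes(f))
  }

  # --- report ----------------------------------------------------------------
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(sprintf("iscpipe run (seed %d)", config$seed),
           sprintf("stages: %s", paste(names(report$stages), collapse = ", ")))
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    if (!is.null(st$headline)) {
      txt <- c(txt, "", paste0("[", nm, "]"),
               utils::capture.output(print(st$headline, row.names = FALSE)))
    }
  }
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dataset_matches <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) return(FALSE)
  manifest <- try(jsonlite::read_json(mf, simplifyVector = TRUE),
                  silent = TRUE)
  if (inherits(manifest, "try-error")) return(FALSE)
  files <- file.path(dir, names(manifest$files))
  if (!all(file.exists(files))) return(FALSE)
  all(unname(tools::md5sum(files)) == unlist(manifest$files))
}

file_hashes <- function(files) {
  as.list(setNames(unname(tools::md5sum(files)), basename(files)))
}

dir_hashes <- function(dir) {
  file_hashes(list.files(dir, full.names = TRUE))
}

# write condition pair maps as one 4D NIfTI stack (4th axis = pair x condition
# index) plus a CSV index
write_pair_maps <- function(pm, mask, dir, voxel_size_mm) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- dim(mask)
  n_pair <- dim(pm$z)[2]; n_cond <- dim(pm$z)[3]
  stack <- array(0, c(dims, n_pair * n_cond))
  index <- data.frame(volume_index = seq_len(n_pair * n_cond) - 1L,
                      pair_i = rep(pm$pairs$i, each = n_cond),
                      pair_j = rep(pm$pairs$j, each = n_cond),
                      scope = rep(pm$scope$condition, times = n_pair))
  vol <- 1L
  flat <- matrix(stack, prod(dims), n_pair * n_cond)
  for (k in seq_len(n_pair)) for (g in seq_len(n_cond)) {
    flat[pm$voxel_ids, vol] <- pm$z[, k, g]
    vol <- vol + 1L
  }
  stack <- array(flat, c(dims, n_pair * n_cond))
  f1 <- file.path(dir, "pair_maps.nii")
  RNifti::writeNifti(nifti_from_array(stack, voxel_size_mm, 1), f1,
                     datatype = "double")
  f2 <- file.path(dir, "pair_maps_index.csv")
  write.csv(index, f2, row.names = FALSE)
  c(f1, f2)
}

# write observed stat, TFCE and 1 - p_FWE maps for one contrast
write_stat_maps <- function(r, mask, dir, voxel_size_mm) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- which(mask != 0)
  tag <- gsub("[^a-zA-Z0-9_]+", "_", r$name)
  out <- character(0)
  for (what in c("stat", "tfce", "fwep")) {
    a <- array(0, dim(mask))
    a[ids] <- switch(what, stat = r$observed_stat, tfce = r$observed_tfce,
                     fwep = 1 - r$p_fwe)
    f <- file.path(dir, sprintf("%s_%s.nii", tag, what))
    RNifti::writeNifti(nifti_from_array(a, voxel_size_mm), f,
                       datatype = "double")
    out <- c(out, f)
  }
  sidecar <- file.path(dir, paste0(tag, ".json"))
  jsonlite::write_json(list(contrast = as.list(r$contrast),
                            n_permutations = r$n_permutations,
                            seed = r$seed, exhaustive = r$exhaustive,
                            max_null = list(min = min(r$max_null),
                                            median = stats::median(r$max_null),
                                            max = max(r$max_null))),
                       sidecar, auto_unbox = TRUE, digits = NA)
  c(out, sidecar)
}
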