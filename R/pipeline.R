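# End-to-end orchestration: simulate -> networks -> metrics -> tau
# composites -> associations -> mediation, with a reproducibility
# manifest.  Every stage seed is recorded and every output table carries
# the configuration hash in a header comment, so two runs with the same
# configuration are file-identical.

GLOBAL_OUTCOMES <- c("size", "degree", "density", "clustering",
                     "path_length", "gamma", "lambda", "sigma")

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or
#'   `NULL` when `cohort_dir` points at an existing cohort written by
#'   [write_cohort()]).
#' @param cohort_dir Optional directory with a previously written cohort.
#' @param alpha Spurious-edge risk for threshold calibration.
#' @param n_permutations Null sample size per subject.
#' @param n_reference Randomised reference networks for gamma/lambda.
#' @param min_gm_fraction Cube inclusion criterion.
#' @param threshold_seed,reference_seed,mediation_seed Stage seeds.
#' @param n_boot Mediation bootstrap replicates.
#' @param regional Run regional analyses (default `TRUE`).
#' @param mediation Run the mediation analysis (default `TRUE`).
#' @return `gmnet_pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), cohort_dir = NULL,
                            alpha = 0.05, n_permutations = 1000L,
                            n_reference = 5L, min_gm_fraction = 0,
                            threshold_seed = 11L, reference_seed = 21L,
                            mediation_seed = 31L, n_boot = 1000L,
                            regional = TRUE, mediation = TRUE) {
  structure(list(cohort = cohort, cohort_dir = cohort_dir, alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 n_reference = as.integer(n_reference),
                 min_gm_fraction = min_gm_fraction,
                 threshold_seed = as.integer(threshold_seed),
                 reference_seed = as.integer(reference_seed),
                 mediation_seed = as.integer(mediation_seed),
                 n_boot = as.integer(n_boot),
                 regional = isTRUE(regional), mediation = isTRUE(mediation)),
            class = "gmnet_pipeline_config")
}

write_stamped_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gmnet config_hash=%s stage_seed=%d", hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> per-subject network extraction ->
#' global and regional graph metrics -> tau composites -> covariate-
#' adjusted association suite -> bootstrap mediation, writing all result
#' tables and a manifest into `output_dir`.  The run is deterministic
#' given the configuration: repeating it yields byte-identical outputs.
#' Subjects whose images yield fewer than 2 grey-matter cubes are
#' excluded with a warning and listed in the manifest.
#'
#' @param config `gmnet_pipeline_config`.
#' @param output_dir Output directory (created if needed).
#' @param verbose Print per-stage progress (default `FALSE`).
#' @return Invisibly, a list with the merged subject table, the
#'   association results, the mediation result, and `output_dir`.
#' @export
run_pipeline <- function(config, output_dir, verbose = FALSE) {
  stopifnot(inherits(config, "gmnet_pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage: simulate")
  cohort <- simulate_cohort(config$cohort)
  cfg_path <- file.path(output_dir, "config.yaml")
  write_cohort_config(config$cohort, cfg_path)
  hash <- unname(tools::md5sum(cfg_path))

  say("stage: networks + metrics (%d subjects)", length(cohort$subjects))
  excluded <- character()
  glob_rows <- list(); reg_rows <- list()
  for (s in cohort$subjects) {
    net <- tryCatch(
      gmnet(s$gm_image, cohort$atlas, alpha = config$alpha,
            n_permutations = config$n_permutations,
            min_gm_fraction = config$min_gm_fraction,
            seed = config$threshold_seed, keep_similarity = FALSE),
      error = function(e) e)
    if (inherits(net, "error")) {
      warning(sprintf("subject %s excluded: %s", s$subject_id,
                      conditionMessage(net)), call. = FALSE)
      excluded <- c(excluded, s$subject_id)
      next
    }
    gm <- compute_global_metrics(net$adjacency,
                                 n_reference = config$n_reference,
                                 seed = config$reference_seed)
    glob_rows[[s$subject_id]] <- data.frame(
      subject_id = s$subject_id, size = gm$size, degree = gm$degree,
      n_edges = gm$n_edges, density = gm$density, clustering = gm$clustering,
      path_length = gm$path_length, gamma = gm$gamma, lambda = gm$lambda,
      sigma = gm$sigma)
    if (config$regional) {
      rm_ <- compute_regional_metrics(net$adjacency, net$cubes$label,
                                      net$cubes$gm_volume,
                                      regions = cohort$region_table$region_id)
      reg_rows[[s$subject_id]] <- cbind(subject_id = s$subject_id, rm_)
    }
  }
  global_tab <- do.call(rbind, glob_rows)
  merged <- merge(cohort$table, global_tab, by = "subject_id")
  merged <- merged[order(merged$subject_id), ]

  say("stage: associations")
  # non-finite measures (degenerate networks) count as missing, echoing the
  # network-calculation-failure exclusion pathway
  n_bad <- 0L
  for (oc in GLOBAL_OUTCOMES) {
    bad <- !is.finite(merged[[oc]])
    n_bad <- n_bad + sum(bad)
    merged[[oc]][bad] <- NA
  }
  if (n_bad > 0)
    warning(sprintf("%d non-finite network measure value(s) set to missing",
                    n_bad), call. = FALSE)
  # outcomes with no spread in the reference group cannot be z-scored
  # (e.g. network size when every cube contains grey matter)
  ref_mask <- merged$group == "control"
  usable <- GLOBAL_OUTCOMES[vapply(GLOBAL_OUTCOMES, function(oc) {
    s <- sd(merged[[oc]][ref_mask], na.rm = TRUE)
    is.finite(s) && s > 0
  }, logical(1))]
  dropped <- setdiff(GLOBAL_OUTCOMES, usable)
  if (length(dropped))
    warning("outcome(s) constant in the reference group, excluded from ",
            "associations: ", paste(dropped, collapse = ", "), call. = FALSE)
  assoc <- run_association_suite(merged, usable, "tau_meta", by_group = TRUE)

  med <- NULL
  if (config$mediation) {
    say("stage: mediation")
    tab <- merged
    tab$sigma_z <- zscore_to_reference(tab$sigma, tab$group == "control")
    med <- mediation_analysis(tab, "tau_meta", "sigma_z", "cognition_global",
                              covariates = c("age", "sex", "tiv"),
                              n_boot = config$n_boot,
                              seed = config$mediation_seed)
  }

  write_stamped_tsv(merged, file.path(output_dir, "subjects.tsv"), hash,
                    config$cohort$seed)
  write_stamped_tsv(global_tab, file.path(output_dir, "global_metrics.tsv"),
                    hash, config$reference_seed)
  if (config$regional && length(reg_rows))
    write_stamped_tsv(do.call(rbind, reg_rows),
                      file.path(output_dir, "regional_metrics.tsv"),
                      hash, config$reference_seed)
  write_stamped_tsv(assoc, file.path(output_dir, "associations.tsv"), hash,
                    config$cohort$seed)
  if (!is.null(med))
    write_stamped_tsv(summary(med), file.path(output_dir, "mediation.tsv"),
                      hash, config$mediation_seed)

  manifest <- list(
    config_hash = hash,
    seeds = list(cohort = config$cohort$seed,
                 threshold = config$threshold_seed,
                 reference = config$reference_seed,
                 mediation = config$mediation_seed),
    alpha = config$alpha, n_permutations = config$n_permutations,
    n_reference = config$n_reference, n_boot = config$n_boot,
    n_subjects = nrow(merged), excluded_subjects = as.list(excluded),
    stages = c("simulate", "network", "metrics", "tau", "associate",
               if (config$mediation) "mediate"))
  yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))

  invisible(list(table = merged, associations = assoc, mediation = med,
                 excluded = excluded, output_dir = output_dir))
}
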