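# Seeded synthetic cohorts: grey-matter images with controllable
# within-image texture covariance, a toy atlas, per-region tau-PET SUVR
# rising with disease stage, covariates, and cognition generated with a
# direct tau effect plus a network-mediated effect.
#
# The generative chain mirrors the causal structure the analysis assumes:
#   tau (by stage)  ->  texture degradation  ->  network integrity
#   cognition = intercept + direct * tau + mediated * integrity + noise
# Degradation enters the image as a noise-mixing weight m = 1 - exp(-d),
# bounded in [0, 1); the analytic network-integrity mediator used for
# cognition is exp(-d) = 1 - m, so generation never needs to run the
# network extractor itself.

GROUPS <- c("control", "preclinical", "prodromal", "dementia")

SYNTHETIC_REGION_NAMES <- c(
  "hippocampus", "parahippocampus", "amygdala", "fusiform",
  "inferior_temporal", "orbitofrontal", "precentral", "superior_parietal",
  "precuneus", "lateral_occipital")

#' Synthetic cohort configuration
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The defaults define a toy cohort that runs through the full pipeline in
#' minutes on one CPU: 30x30x30-voxel images at 2 mm (1000 cube nodes),
#' a 10-region atlas, 25 subjects per diagnostic group, and tau SUVR means
#' rising from 1.2 (amyloid-negative controls) to 2.5 (dementia).
#'
#' @param n_per_group Named counts for the four diagnostic groups
#'   (control, preclinical, prodromal, dementia).
#' @param image_shape Three integers, each a multiple of 3.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param n_regions Atlas region count (must not exceed
#'   `image_shape[3]/3`, the number of cube slabs).
#' @param n_prototypes Size of the texture-prototype library; regions
#'   cycle through it, so fewer prototypes than regions makes some region
#'   pairs share a texture.
#' @param base_noise_sd Within-cube noise standard deviation (> 0).
#' @param base_degradation Degradation floor common to all subjects.
#' @param degradation_slope Increase in degradation per unit of meta-ROI
#'   SUVR above the control mean.
#' @param tau_group_means Named per-group mean meta-ROI SUVR,
#'   non-decreasing across disease stages.
#' @param tau_sd Between-subject SUVR standard deviation.
#' @param tau_region_sd Within-subject between-region SUVR jitter.
#' @param age_mean,age_sd Per-group age means (named) and common sd, years.
#' @param sex_prop_female Proportion of female subjects.
#' @param tiv_mean,tiv_sd Total intracranial volume, mL.
#' @param cog_intercept,cog_direct,cog_mediated,cog_sd Global-cognition
#'   (MMSE-like) generating coefficients: intercept, direct tau effect
#'   (per SUVR), mediator (network-integrity) effect, residual sd.
#' @param mem_intercept,mem_direct,mem_mediated,mem_sd The same for the
#'   memory score (recall-error-like: errors rise with tau, fall with
#'   integrity).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Validated `gmnet_cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(control = 25, preclinical = 25,
                                          prodromal = 25, dementia = 25),
                          image_shape = c(30L, 30L, 30L),
                          voxel_size_mm = 2,
                          n_regions = 10L,
                          n_prototypes = 5L,
                          base_noise_sd = 1,
                          base_degradation = 0.2,
                          degradation_slope = 0.2,
                          tau_group_means = c(control = 1.2, preclinical = 1.5,
                                              prodromal = 1.9, dementia = 2.5),
                          tau_sd = 0.15,
                          tau_region_sd = 0.05,
                          age_mean = c(control = 66, preclinical = 72,
                                       prodromal = 72, dementia = 72),
                          age_sd = 8,
                          sex_prop_female = 0.5,
                          tiv_mean = 1450, tiv_sd = 120,
                          cog_intercept = 29, cog_direct = -1.5,
                          cog_mediated = 4, cog_sd = 1,
                          mem_intercept = 1, mem_direct = 1,
                          mem_mediated = -2, mem_sd = 0.8,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (!all(GROUPS %in% names(cfg$n_per_group)))
    stop("'n_per_group' must name all groups: ",
         paste(GROUPS, collapse = ", "), call. = FALSE)
  cfg$n_per_group <- cfg$n_per_group[GROUPS]
  if (any(cfg$n_per_group < 1)) stop("all group counts must be >= 1", call. = FALSE)
  if (length(cfg$image_shape) != 3L || any(cfg$image_shape < 3))
    stop("'image_shape' must be 3 positive integers", call. = FALSE)
  if (any(cfg$image_shape %% 3 != 0))
    stop("'image_shape' must be divisible by 3 in each axis (whole cubes)",
         call. = FALSE)
  cfg$image_shape <- as.integer(cfg$image_shape)
  for (f in c("voxel_size_mm", "base_noise_sd", "tau_sd", "age_sd", "tiv_sd",
              "cog_sd", "mem_sd"))
    stopifnot_scalar_number(cfg[[f]], f, 0, strict_lower = TRUE)
  for (f in c("base_degradation", "degradation_slope", "tau_region_sd"))
    stopifnot_scalar_number(cfg[[f]], f, 0)
  if (cfg$n_regions < 1 || cfg$n_prototypes < 1)
    stop("'n_regions' and 'n_prototypes' must be >= 1", call. = FALSE)
  if (cfg$n_regions > cfg$image_shape[3] %/% 3L)
    stop("'n_regions' cannot exceed image_shape[3]/3 (one cube slab per region)",
         call. = FALSE)
  if (!all(GROUPS %in% names(cfg$tau_group_means)))
    stop("'tau_group_means' must name all groups", call. = FALSE)
  cfg$tau_group_means <- cfg$tau_group_means[GROUPS]
  if (is.unsorted(cfg$tau_group_means))
    stop("'tau_group_means' must be non-decreasing across disease stages",
         call. = FALSE)
  if (!all(GROUPS %in% names(cfg$age_mean)))
    stop("'age_mean' must name all groups", call. = FALSE)
  cfg$age_mean <- cfg$age_mean[GROUPS]
  stopifnot_scalar_number(cfg$sex_prop_female, "sex_prop_female", 0, 1)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "gmnet_cohort_config")
}

#' @export
print.gmnet_cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  subjects: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "), sum(x$n_per_group)))
  cat(sprintf("  image: %s voxels at %g mm, %d regions, %d prototypes\n",
              paste(x$image_shape, collapse = "x"), x$voxel_size_mm,
              x$n_regions, x$n_prototypes))
  cat(sprintf("  tau means: %s\n",
              paste(sprintf("%.2f", x$tau_group_means), collapse = " -> ")))
  cat(sprintf("  degradation: base %.2f + %.2f per SUVR above control mean\n",
              x$base_degradation, x$degradation_slope))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Synthetic atlas labelling
#'
#' Labels the volume in `n_regions` contiguous slabs along the third axis,
#' aligned to the 3-voxel cube grid so that every cube falls entirely
#' within one region.
#'
#' @param shape Image dimensions (multiples of 3).
#' @param n_regions Number of regions.
#' @return 3D integer array of labels 1..n_regions.
#' @export
synthetic_atlas <- function(shape, n_regions) {
  n_slabs <- shape[3] %/% 3L
  if (n_regions > n_slabs) stop("too many regions for this shape", call. = FALSE)
  slab_region <- as.integer(ceiling(seq_len(n_slabs) * n_regions / n_slabs))
  lab <- array(0L, shape)
  for (s in seq_len(n_slabs))
    lab[, , (s - 1L) * 3L + 1:3] <- slab_region[s]
  lab
}

# mixing weight: monotone in degradation, bounded in [0, 1)
degradation_mixing <- function(degradation) 1 - exp(-degradation)

#' Synthesise one subject's grey-matter image
#'
#' Each 3x3x3 cube of the image is a mixture
#' `(1 - m) * prototype(region) + m * noise`, where `m` is a bounded
#' monotone function of the degradation value (`m = 1 - exp(-d)`), the
#' prototype is the 27-voxel texture assigned to the cube's atlas region,
#' and the noise is independent Gaussian.  Intensities are clipped at 0.
#' Cubes in regions sharing a prototype correlate strongly when `m` is
#' small and decorrelate as degradation rises.
#'
#' Draws from the current RNG stream; seed externally for reproducibility.
#'
#' @param shape Image dimensions, multiples of 3.
#' @param atlas_labels 3D label array (one region per cube).
#' @param prototypes 27 x K matrix of texture prototypes.
#' @param region_prototype Integer vector mapping region id to prototype
#'   column (defaults to cycling through the library).
#' @param degradation Non-negative noise-mixing driver.
#' @param noise_sd Noise standard deviation.
#' @return 3D non-negative intensity array.
#' @export
simulate_subject_image <- function(shape, atlas_labels, prototypes,
                                   region_prototype = NULL,
                                   degradation = 0, noise_sd = 1) {
  if (degradation < 0) stop("'degradation' must be >= 0", call. = FALSE)
  if (any(shape %% 3 != 0)) stop("'shape' must be divisible by 3", call. = FALSE)
  n_regions <- max(atlas_labels)
  if (is.null(region_prototype))
    region_prototype <- rep_len(seq_len(ncol(prototypes)), n_regions)
  m <- degradation_mixing(degradation)
  img <- array(0, shape)
  nb <- shape %/% 3L
  for (bz in seq_len(nb[3])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[1])) {
    xs <- (bx - 1L) * 3L + 1:3; ys <- (by - 1L) * 3L + 1:3; zs <- (bz - 1L) * 3L + 1:3
    lab <- atlas_labels[xs[1], ys[1], zs[1]]
    proto <- prototypes[, region_prototype[lab]]
    vals <- (1 - m) * proto + m * rnorm(27L, 0, noise_sd)
    img[xs, ys, zs] <- array(pmax(vals, 0), c(3L, 3L, 3L))
  }
  img
}

#' Pure-noise image
#'
#' An i.i.d. non-negative intensity volume (folded standard normal) with
#' no spatial structure: every apparent connection in a network built from
#' it is spurious.  Used to check the calibration of the binarisation
#' threshold.
#'
#' @param shape Image dimensions.
#' @param seed Optional seed (draws from the current stream when `NULL`).
#' @return 3D non-negative array.
#' @export
simulate_noise_image <- function(shape, seed = NULL) {
  draw <- function() array(abs(rnorm(prod(shape))), shape)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort under a [cohort_config()]: a shared atlas and
#' texture-prototype library, then per subject a meta-ROI tau level around
#' the group mean, per-region SUVR, covariates (age, sex, TIV), a latent
#' degradation value `base + slope * max(0, tau_meta - control mean)`, a
#' grey-matter image synthesised at that degradation, and cognition scores
#' with a direct tau effect plus an effect of the analytic network
#' integrity `exp(-degradation)`.  Identical configurations (including the
#' seed) produce bit-identical cohorts.
#'
#' @param config A `gmnet_cohort_config`.
#' @param images Generate grey-matter images (default `TRUE`; `FALSE`
#'   returns the subject table and tau data only, for purely tabular
#'   simulations).
#' @return A `gmnet_cohort` list: `subjects` (per-subject list with
#'   `gm_image`, `region_suvr`, scalars), `atlas`, `region_table`,
#'   `prototypes`, `table` (one row per subject with all scalars), and
#'   `config`.
#' @export
simulate_cohort <- function(config, images = TRUE) {
  stopifnot(inherits(config, "gmnet_cohort_config"))
  shape <- config$image_shape
  atlas <- synthetic_atlas(shape, config$n_regions)
  region_names <- if (config$n_regions == 10L) SYNTHETIC_REGION_NAMES else
    sprintf("region%02d", seq_len(config$n_regions))
  region_table <- data.frame(region_id = seq_len(config$n_regions),
                             region_name = region_names)
  vox_vol <- config$voxel_size_mm^3
  region_volume <- as.numeric(table(factor(atlas[atlas > 0],
                                           levels = seq_len(config$n_regions)))) * vox_vol
  names(region_volume) <- seq_len(config$n_regions)

  defs <- if (config$n_regions == 10L)
    default_braak_definitions(region_table) else NULL
  meta_ids <- if (!is.null(defs)) defs$temporal_meta$member_region_ids else
    seq_len(config$n_regions)

  groups <- rep(GROUPS, times = config$n_per_group)
  n <- length(groups)

  with_seed(config$seed, {
    prototypes <- matrix(rnorm(27L * config$n_prototypes), 27L)
    region_prototype <- rep_len(seq_len(config$n_prototypes), config$n_regions)

    subjects <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- groups[i]
      tau_subject <- max(0.1, rnorm(1, config$tau_group_means[[g]], config$tau_sd))
      region_suvr <- pmax(0.1, tau_subject + rnorm(config$n_regions, 0,
                                                   config$tau_region_sd))
      names(region_suvr) <- seq_len(config$n_regions)
      tau_meta <- sum(region_suvr[meta_ids] * region_volume[meta_ids]) /
        sum(region_volume[meta_ids])
      degradation <- config$base_degradation + config$degradation_slope *
        max(0, tau_meta - config$tau_group_means[["control"]])
      integrity <- exp(-degradation)

      age <- rnorm(1, config$age_mean[[g]], config$age_sd)
      sex <- rbinom(1, 1, config$sex_prop_female)
      tiv <- rnorm(1, config$tiv_mean, config$tiv_sd)
      cog <- config$cog_intercept + config$cog_direct * tau_meta +
        config$cog_mediated * integrity + rnorm(1, 0, config$cog_sd)
      mem <- config$mem_intercept + config$mem_direct * tau_meta +
        config$mem_mediated * integrity + rnorm(1, 0, config$mem_sd)

      img <- if (images)
        simulate_subject_image(shape, atlas, prototypes, region_prototype,
                               degradation, config$base_noise_sd) else NULL

      subjects[[i]] <- list(subject_id = sprintf("sub%03d", i), group = g,
                            gm_image = img, region_suvr = region_suvr,
                            age = age, sex = sex, tiv = tiv,
                            cognition_global = cog, cognition_memory = mem,
                            latent_degradation = degradation,
                            expected_integrity = integrity)
      row <- data.frame(subject_id = sprintf("sub%03d", i), group = g,
                        age = age, sex = sex, tiv = tiv, tau_meta = tau_meta,
                        cognition_global = cog, cognition_memory = mem,
                        latent_degradation = degradation,
                        expected_integrity = integrity)
      if (!is.null(defs)) {
        comp <- braak_composites(matrix(region_suvr, 1,
                                        dimnames = list(NULL, names(region_suvr))),
                                 region_volume, defs)
        row <- cbind(row, comp)
      }
      rows[[i]] <- row
    }
    table <- do.call(rbind, rows)
    table$group <- factor(table$group, levels = GROUPS)
    structure(list(subjects = subjects, atlas = atlas,
                   region_table = region_table,
                   region_volume = region_volume,
                   prototypes = prototypes, table = table, config = config),
              class = "gmnet_cohort")
  })
}

#' @export
print.gmnet_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n", nrow(x$table),
              paste(sprintf("%s=%d", levels(x$table$group),
                            as.integer(table(x$table$group))), collapse = ", ")))
  cat(sprintf("  image: %s voxels, atlas of %d regions\n",
              paste(x$config$image_shape, collapse = "x"),
              x$config$n_regions))
  cat(sprintf("  images generated: %s\n",
              !is.null(x$subjects[[1]]$gm_image)))
  invisible(x)
}
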