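small_cfg <- function(...) {
  cohort_config(n_per_group = c(control = 3, preclinical = 3, prodromal = 3,
                                dementia = 3),
                image_shape = c(12, 12, 12), n_regions = 4, ...)
}

test_that("identical configurations produce bit-identical cohorts", {
  c1 <- simulate_cohort(small_cfg(seed = 5))
  c2 <- simulate_cohort(small_cfg(seed = 5))
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[7]]$gm_image, c2$subjects[[7]]$gm_image)
  expect_identical(c1$prototypes, c2$prototypes)
  c3 <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(c1$table$tau_meta, c3$table$tau_meta))
})

test_that("the cohort RNG does not disturb the caller's stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_cohort(small_cfg(seed = 5))); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero degradation slope makes degradation identical across groups", {
  coh <- simulate_cohort(small_cfg(degradation_slope = 0, seed = 2),
                         images = FALSE)
  expect_equal(unique(coh$table$latent_degradation), 0.2)
  expect_equal(length(unique(coh$table$expected_integrity)), 1L)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(image_shape = c(10, 12, 12)), "divisible by 3")
  expect_error(cohort_config(tau_group_means = c(control = 2, preclinical = 1.5,
                                                 prodromal = 1.9, dementia = 2.5)),
               "non-decreasing")
  expect_error(cohort_config(n_per_group = c(control = 0, preclinical = 1,
                                             prodromal = 1, dementia = 1)),
               ">= 1")
  expect_error(cohort_config(base_noise_sd = 0), "> 0")
  expect_error(cohort_config(n_regions = 20, image_shape = c(12, 12, 12)),
               "cannot exceed")
  expect_error(simulate_subject_image(c(12, 12, 12),
                                      synthetic_atlas(c(12, 12, 12), 2),
                                      matrix(rnorm(27), 27), degradation = -1),
               ">= 0")
})

test_that("zero degradation reproduces the prototype exactly within regions", {
  shape <- c(9, 9, 9)
  atlas <- synthetic_atlas(shape, 3)
  protos <- matrix(rnorm(27 * 3), 27)
  set.seed(1)
  img <- simulate_subject_image(shape, atlas, protos, 1:3, degradation = 0)
  cubes <- partition_into_cubes(img, atlas)
  rots <- rotation_set()
  same_region <- which(cubes$label == 1)
  for (j in same_region[-1])
    expect_equal(max_rotated_correlation(cubes$values[, same_region[1]],
                                         cubes$values[, j], rots), 1,
                 tolerance = 1e-12)
})

test_that("noise mixing saturates below 1 and rises with degradation", {
  m <- gmnet:::degradation_mixing(c(0, 0.5, 2, 10, 1e6))
  expect_equal(m[1], 0)
  expect_true(all(diff(m) >= 0))
  expect_true(all(m <= 1))
})

test_that("within-region cube correlation decreases monotonically with degradation", {
  shape <- c(9, 9, 9)
  atlas <- synthetic_atlas(shape, 1)
  protos <- matrix(rnorm(27), 27)
  mean_cor <- vapply(c(0, 0.6, 1.8), function(d) {
    set.seed(500 + round(d * 10))
    cors <- replicate(40, {
      img <- simulate_subject_image(shape, atlas, protos, 1L, degradation = d)
      cubes <- partition_into_cubes(img, atlas)
      sim <- build_similarity_matrix(cubes)
      mean(sim[upper.tri(sim)])
    })
    mean(cors)
  }, numeric(1))
  expect_true(all(diff(mean_cor) < 0))
})

test_that("degraded cohorts produce sparser networks than intact ones", {
  shape <- c(9, 9, 9)
  atlas <- synthetic_atlas(shape, 3)
  set.seed(77)
  protos <- matrix(rnorm(27 * 3), 27)
  density_at <- function(d, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      img <- simulate_subject_image(shape, atlas, protos, 1:3, degradation = d)
      net <- gmnet(img, atlas, n_permutations = 150, seed = 1,
                   keep_similarity = FALSE)
      sum(net$adjacency) / (nrow(net$adjacency) * (nrow(net$adjacency) - 1))
    }, numeric(1))
  }
  dense0 <- density_at(0, 1:20)
  dense2 <- density_at(2.5, 21:40)
  expect_gt(mean(dense0), mean(dense2))
})

test_that("the subject table carries all scalars and Braak composites", {
  coh <- simulate_cohort(cohort_config(
    n_per_group = c(control = 2, preclinical = 2, prodromal = 2, dementia = 2),
    image_shape = c(30, 30, 30), seed = 3), images = FALSE)
  expect_true(all(c("subject_id", "group", "age", "sex", "tiv", "tau_meta",
                    "cognition_global", "cognition_memory",
                    "latent_degradation", "expected_integrity",
                    "braak_I_II", "braak_III_IV", "braak_V_VI",
                    "temporal_meta") %in% names(coh$table)))
  expect_true(all(coh$table$latent_degradation >= 0))
  # group tau means rise with stage in expectation (weak check at n = 8)
  agg <- tapply(coh$table$tau_meta, coh$table$group, mean)
  expect_gt(agg[["dementia"]], agg[["control"]])
})

test_that("mediation structure holds by construction in the generator", {
  # with no direct effect the mediated proportion approaches 1; with no
  # mediator effect it approaches 0 (ground-truth mediator, low noise)
  base_cfg <- function(...) cohort_config(
    n_per_group = c(control = 250, preclinical = 250, prodromal = 250,
                    dementia = 250),
    tau_sd = 0.3, cog_sd = 0.2, ...)
  prop_for <- function(cfg) {
    tab <- simulate_cohort(cfg, images = FALSE)$table
    unname(gmnet:::mediation_paths(tab, "tau_meta", "expected_integrity",
                                   "cognition_global",
                                   character())["prop_mediated"])
  }
  full <- mean(vapply(1:6, function(s) prop_for(base_cfg(cog_direct = 0,
                                                         seed = s)),
                      numeric(1)))
  none <- mean(vapply(1:6, function(s) prop_for(base_cfg(cog_mediated = 0,
                                                         seed = 100 + s)),
                      numeric(1)))
  expect_lt(abs(full - 1), 0.15)
  expect_lt(abs(none), 0.08)
})
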