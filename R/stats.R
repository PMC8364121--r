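# Statistical layer: z-scoring to a reference group, covariate-adjusted
# linear associations with two-tier multiplicity correction, group
# comparisons, and bootstrap mediation.

#' Z-score values to a reference group
#'
#' Standardises a measure using the mean and standard deviation of a
#' reference subgroup (typically the amyloid-negative control group), so
#' that effect sizes are comparable across network measures.
#'
#' @param values Numeric vector over all subjects.
#' @param reference_mask Logical vector marking the reference subjects
#'   (>= 2, with non-zero spread).
#' @return `(values - mean_ref) / sd_ref`.
#' @export
zscore_to_reference <- function(values, reference_mask) {
  if (length(reference_mask) != length(values))
    stop("'reference_mask' must match 'values' in length", call. = FALSE)
  ref <- values[reference_mask & !is.na(values)]
  if (length(ref) < 2L)
    stop("reference group must contain at least 2 observations", call. = FALSE)
  s <- sd(ref)
  if (!is.finite(s) || s == 0)
    stop("reference group has zero standard deviation", call. = FALSE)
  (values - mean(ref)) / s
}

#' Covariate-adjusted linear association
#'
#' Ordinary-least-squares association between one outcome and one
#' predictor with optional covariate adjustment.  When `interaction_with`
#' is supplied, the model adds that variable and its product with the
#' predictor, and the reported test is for the product term.
#'
#' @param table Data frame with all named columns.
#' @param outcome,predictor Column names.
#' @param covariates Character vector of covariate column names.
#' @param interaction_with Optional column name for an interaction test.
#' @return A one-row data frame: `outcome`, `predictor`, `term`, `beta`,
#'   `se`, `t`, `p`, `n`, `covariates`.
#' @export
fit_linear_association <- function(table, outcome, predictor,
                                   covariates = character(),
                                   interaction_with = NULL) {
  vars <- c(outcome, predictor, covariates, interaction_with)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- table[vars]
  for (v in vars)                       # non-finite measures count as missing
    if (is.numeric(dat[[v]])) dat[[v]][!is.finite(dat[[v]])] <- NA
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  bt <- function(v) sprintf("`%s`", v)
  rhs <- c(bt(predictor), if (length(covariates)) bt(covariates))
  if (!is.null(interaction_with))
    rhs <- c(rhs, bt(interaction_with),
             paste0(bt(predictor), ":", bt(interaction_with)))
  fml <- stats::as.formula(paste(bt(outcome), "~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (fit$df.residual < 10L)
    stop("fewer than 10 residual degrees of freedom", call. = FALSE)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear column(s): ",
         paste(gsub("`", "", names(cf)[is.na(cf)]), collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(sm))
  term <- if (is.null(interaction_with)) predictor else
    paste0(predictor, ":", interaction_with)
  est <- sm[match(term, rn), ]
  data.frame(outcome = outcome, predictor = predictor,
             term = gsub("`", "", term),
             beta = unname(est[1]), se = unname(est[2]), t = unname(est[3]),
             p = unname(est[4]), n = nrow(dat),
             covariates = paste(covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param method `"fdr_bh"` (Benjamini-Hochberg step-up) or
#'   `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(pvals, method = c("fdr_bh", "bonferroni")) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  method <- match.arg(method)
  stats::p.adjust(pvals, method = switch(method, fdr_bh = "BH",
                                         bonferroni = "bonferroni"))
}

# higher-order measures whose models additionally adjust for density
DENSITY_ADJUSTED <- c("clustering", "path_length", "gamma", "lambda", "sigma")

#' Association suite across network outcomes
#'
#' Fits one covariate-adjusted linear model per outcome (and, when
#' `by_group = TRUE`, additionally within each diagnostic group), with the
#' two-tier multiplicity scheme: each tier of related outcomes is adjusted
#' jointly (`"fdr_bh"` for global network measures, `"bonferroni"` for
#' regional analyses).  Outcomes are z-scored to the reference group
#' before fitting so that betas are comparable effect sizes.
#'
#' @param table Subject table.
#' @param outcomes Character vector of outcome columns (one tier).
#' @param predictor Predictor column (e.g. meta-ROI tau SUVR).
#' @param covariates Baseline covariates for every model (default age,
#'   sex, tiv).
#' @param density_adjusted Outcomes whose models also adjust for
#'   `density_col` (default: the higher-order measures clustering,
#'   path_length, gamma, lambda, sigma present in `outcomes`).
#' @param density_col Connectivity-density column name (default
#'   `"density"`).
#' @param extra_covariates Optional named list mapping an outcome to
#'   additional covariate columns (used for regional models: local volume
#'   and, for clustering/path length, local degree).
#' @param group_col,reference_group Grouping column and reference level
#'   used for z-scoring (default `"group"` / `"control"`).
#' @param by_group Also fit within each diagnostic group (default
#'   `FALSE`).
#' @param zscore Z-score outcomes to the reference group (default
#'   `TRUE`).
#' @param adjust_method Multiplicity correction across the tier.
#' @return Data frame with one row per model, including `p_adjusted`
#'   (adjusted within each whole-sample/per-group stratum).
#' @export
run_association_suite <- function(table, outcomes, predictor,
                                  covariates = c("age", "sex", "tiv"),
                                  density_adjusted = intersect(DENSITY_ADJUSTED,
                                                               outcomes),
                                  density_col = "density",
                                  extra_covariates = list(),
                                  group_col = "group",
                                  reference_group = "control",
                                  by_group = FALSE,
                                  zscore = TRUE,
                                  adjust_method = c("fdr_bh", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  tab <- table
  if (zscore) {
    ref_mask <- tab[[group_col]] == reference_group
    for (oc in outcomes)
      tab[[oc]] <- zscore_to_reference(tab[[oc]], ref_mask)
  }
  fit_tier <- function(dat, stratum) {
    rows <- lapply(outcomes, function(oc) {
      covs <- covariates
      if (oc %in% density_adjusted) covs <- c(covs, density_col)
      if (oc %in% names(extra_covariates))
        covs <- c(covs, extra_covariates[[oc]])
      cbind(stratum = stratum,
            fit_linear_association(dat, oc, predictor, covs))
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- adjust_pvalues(out$p, adjust_method)
    out
  }
  res <- fit_tier(tab, "whole_sample")
  if (by_group) {
    for (g in levels(factor(tab[[group_col]]))) {
      res <- rbind(res, fit_tier(tab[tab[[group_col]] == g, , drop = FALSE], g))
    }
  }
  rownames(res) <- NULL
  res
}

#' Group comparison
#'
#' One-way ANOVA for continuous variables, Pearson chi-squared for
#' categorical ones.
#'
#' @param table Data frame.
#' @param variable Column to compare.
#' @param group Grouping column (>= 2 groups).
#' @return `gmnet_group_comparison` list: `variable`, `test`,
#'   `statistic`, `p`, `summaries`.
#' @export
compare_groups <- function(table, variable, group = "group") {
  x <- table[[variable]]
  g <- factor(table[[group]])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.numeric(x)) {
    sizes <- tapply(!is.na(x), g, sum)
    if (any(sizes < 2))
      stop("every group needs >= 2 observations for ANOVA", call. = FALSE)
    fit <- stats::aov(x ~ g)
    an <- anova(fit)
    out <- list(variable = variable, test = "anova",
                statistic = an$`F value`[1], p = an$`Pr(>F)`[1],
                summaries = tapply(x, g, mean, na.rm = TRUE))
  } else {
    ct <- suppressWarnings(stats::chisq.test(table(g, x), correct = FALSE))
    out <- list(variable = variable, test = "chi-squared",
                statistic = unname(ct$statistic), p = ct$p.value,
                summaries = table(g, x))
  }
  structure(out, class = "gmnet_group_comparison")
}

#' @export
print.gmnet_group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s statistic = %.4g, p = %.3g\n", x$variable, x$test,
              x$statistic, x$p))
  invisible(x)
}

mediation_paths <- function(dat, treatment, mediator, outcome, covariates) {
  bt <- function(v) sprintf("`%s`", v)
  rhs <- function(v) paste(vapply(v, bt, ""), collapse = " + ")
  f_med <- stats::as.formula(paste(bt(mediator), "~",
                                   rhs(c(treatment, covariates))))
  f_out <- stats::as.formula(paste(bt(outcome), "~",
                                   rhs(c(treatment, mediator, covariates))))
  f_tot <- stats::as.formula(paste(bt(outcome), "~",
                                   rhs(c(treatment, covariates))))
  m_med <- stats::lm(f_med, data = dat)
  m_out <- stats::lm(f_out, data = dat)
  m_tot <- stats::lm(f_tot, data = dat)
  pick <- function(fit, var) {
    cf <- coef(fit)
    unname(cf[match(var, gsub("`", "", names(cf)))])
  }
  a <- pick(m_med, treatment)
  b <- pick(m_out, mediator)
  c_prime <- pick(m_out, treatment)
  c_tot <- pick(m_tot, treatment)
  c(a = a, b = b, c = c_tot, c_prime = c_prime, acme = a * b,
    prop_mediated = (a * b) / c_tot)
}

#' Bootstrap mediation analysis
#'
#' Linear-model product-of-coefficients mediation: path `a` from
#' `mediator ~ treatment + covariates`, paths `b` and `c'` from
#' `outcome ~ treatment + mediator + covariates`, and the total effect `c`
#' from `outcome ~ treatment + covariates`.  The average causal mediation
#' effect is `acme = a * b` — which in nested linear models on the same
#' sample equals `c - c'` exactly — and the proportion mediated is
#' `acme / c`.  Confidence intervals are nonparametric percentile
#' bootstrap over subjects, deterministic given the seed.
#'
#' @param table Data frame (complete cases on the named columns are
#'   used).
#' @param treatment,mediator,outcome Column names (e.g. meta-ROI tau
#'   SUVR, small-world coefficient, cognition).
#' @param covariates Covariate column names.
#' @param n_boot Bootstrap replicates (>= 100; default 1000; fewer than
#'   500 draws a warning).
#' @param seed Integer seed.
#' @param conf_level Confidence level (default 0.95).
#' @return `gmnet_mediation` object with point estimates, percentile CIs,
#'   the bootstrap draws, and a flag when the proportion mediated is
#'   unstable (total effect near zero or proportion outside `[0, 1]`).
#' @export
mediation_analysis <- function(table, treatment, mediator, outcome,
                               covariates = character(), n_boot = 1000L,
                               seed = 1L, conf_level = 0.95) {
  if (n_boot < 100L) stop("'n_boot' must be >= 100", call. = FALSE)
  if (n_boot < 500L) warning("fewer than 500 bootstrap replicates")
  vars <- c(treatment, mediator, outcome, covariates)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop("column(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dat <- table[stats::complete.cases(table[vars]), vars, drop = FALSE]
  n <- nrow(dat)
  est <- mediation_paths(dat, treatment, mediator, outcome, covariates)

  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(est),
                  dimnames = list(NULL, names(est)))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[bi, ] <- mediation_paths(dat[idx, , drop = FALSE], treatment,
                                   mediator, outcome, covariates)
    }
    out
  })
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- apply(draws, 2L, quantile, probs = probs, na.rm = TRUE)
  unstable <- abs(est[["c"]]) < 1e-8 || est[["prop_mediated"]] < 0 ||
    est[["prop_mediated"]] > 1
  structure(list(
    a = est[["a"]], b = est[["b"]], c = est[["c"]],
    c_prime = est[["c_prime"]], acme = est[["acme"]],
    prop_mediated = est[["prop_mediated"]],
    prop_mediated_flag = unstable,
    ci = ci, draws = draws, n = n, n_boot = as.integer(n_boot),
    seed = as.integer(seed), conf_level = conf_level,
    treatment = treatment, mediator = mediator, outcome = outcome,
    covariates = covariates
  ), class = "gmnet_mediation")
}

#' @export
print.gmnet_mediation <- function(x, digits = 3, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d, %d bootstraps)\n",
              x$treatment, x$mediator, x$outcome, x$n, x$n_boot))
  fmt <- function(label, key, val) sprintf(
    "  %-14s %8.*f  [%.*f, %.*f]\n", label, digits, val,
    digits, x$ci[1, key], digits, x$ci[2, key])
  cat(fmt("a (T->M)", "a", x$a)); cat(fmt("b (M->Y|T)", "b", x$b))
  cat(fmt("c (total)", "c", x$c)); cat(fmt("c' (direct)", "c_prime", x$c_prime))
  cat(fmt("acme (a*b)", "acme", x$acme))
  cat(fmt("prop_mediated", "prop_mediated", x$prop_mediated))
  if (x$prop_mediated_flag)
    cat("  note: proportion mediated unstable (total effect near zero or outside [0, 1])\n")
  invisible(x)
}

#' @export
summary.gmnet_mediation <- function(object, ...) {
  est <- c(a = object$a, b = object$b, c = object$c,
           c_prime = object$c_prime, acme = object$acme,
           prop_mediated = object$prop_mediated)
  data.frame(quantity = names(est), estimate = unname(est),
             ci_low = object$ci[1, names(est)],
             ci_high = object$ci[2, names(est)], row.names = NULL)
}
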