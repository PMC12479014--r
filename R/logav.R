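#' Per-draw log-ratio of the two ancestral-variance estimates
#'
#' @param post a [fit_model()] posterior.
#' @return numeric vector `log(V_B / V_W)`, one value per posterior draw.
#' @export
compute_logav <- function(post) {
  stopifnot(inherits(post, "model_posterior"))
  vb <- post$draws$v_b; vw <- post$draws$v_w
  if (any(vb <= 0) || any(vw <= 0)) stop("variance draws must be positive")
  log(vb / vw)
}

#' Two-tailed Bayesian p-value for a posterior of log-ratios
#'
#' Monte-Carlo tail probability of the null that the log-ratio is 0:
#' `p = 2 * min(#\{draws <= 0\} + 1, #\{draws >= 0\} + 1) / (S + 1)`, capped
#' at 1. The add-one continuity correction follows the standard Monte-Carlo
#' p-value convention and guarantees p > 0 from finite draws; draws exactly
#' at 0 count toward both tails.
#'
#' @param logratios numeric vector of posterior log-ratio draws (>= 100).
#' @return two-tailed p-value in (0, 1].
#' @export
bayes_p <- function(logratios) {
  s <- length(logratios)
  if (s < 100) stop("need at least 100 draws for a stable tail estimate")
  lo <- sum(logratios <= 0) + 1
  hi <- sum(logratios >= 0) + 1
  min(1, 2 * min(lo, hi) / (s + 1))
}

#' The LogAV test of local adaptation
#'
#' Summarizes a fitted two-variance model into the log-ratio statistic
#' `log(V_B / V_W)` and its two-tailed Bayesian p-value for the null
#' hypothesis that both ancestral-variance estimates are equal. A positive
#' mean log-ratio is compatible with local adaptation (excess
#' between-population divergence), a negative one with spatially homogeneous
#' selection.
#'
#' @param post a [fit_model()] posterior.
#' @param alpha significance threshold recorded in the result.
#' @param probs quantiles of the log-ratio to report.
#' @return object of class `logav_result` with `logav_mean`, `p_value`,
#'   `direction`, `significant`, log-ratio `quantiles` and the draw count.
#' @export
logav_test <- function(post, alpha = 0.05,
                       probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  lr <- compute_logav(post)
  p <- bayes_p(lr)
  mean_lr <- mean(lr)
  structure(list(
    logav_mean = mean_lr,
    p_value = p,
    direction = if (mean_lr >= 0) "local-adaptation-compatible"
                else "homogeneous-selection-compatible",
    significant = p < alpha, alpha = alpha,
    quantiles = stats::quantile(lr, probs),
    n_draws = length(lr),
    converged = post$converged), class = "logav_result")
}

#' @export
print.logav_result <- function(x, ...) {
  cat("LogAV test: mean log(V_B/V_W) =", format(x$logav_mean, digits = 4),
      "(", x$direction, ")\n",
      "two-tailed Bayesian p =", format(x$p_value, digits = 4),
      if (x$significant) paste0("< alpha = ", x$alpha) else "", "\n")
  if (!x$converged) cat("warning: underlying MCMC flagged as not converged\n")
  invisible(x)
}

#' Run the full LogAV pipeline on a common-garden dataset
#'
#' Chains the estimation steps on one dataset: population coancestries from
#' parental neutral markers, within-population F1 kinships and the M matrix
#' from F1 neutral markers (or from the pedigree), the Bayesian two-variance
#' fit, and the log-ratio test.
#'
#' @param data a [common_garden()] dataset, or any list with elements
#'   `parents_neutral`, `f1_neutral` (or `pedigree`) and `phenotypes`.
#' @param mcmc a [mcmc_control()].
#' @param use_pedigree build M from the pedigree instead of F1 genotypes.
#' @param kinship_reference which pairs define the mean allele sharing that
#'   anchors the within-population kinship (Abar): `"parents"` (default)
#'   uses the deme's parental sample — the gene pool the population
#'   coancestry matrix describes, so the F1's family structure and the
#'   finite-parent sampling contribution are retained in M —
#'   `"offspring"` uses the F1 themselves (centring their mean relatedness
#'   at zero), and `"combined"` uses all parent and F1 pairs.
#' @param alpha significance threshold.
#' @return a `logav_result` with the fitted `posterior`, `theta` and `m`
#'   attached.
#' @export
logav_pipeline <- function(data, mcmc = mcmc_control(),
                           use_pedigree = FALSE,
                           kinship_reference = c("parents", "offspring",
                                                 "combined"),
                           alpha = 0.05) {
  kinship_reference <- match.arg(kinship_reference)
  abar <- population_allele_sharing(data$parents_neutral)
  theta <- estimate_theta_p(abar)
  pheno <- data$phenotypes
  ord <- order(match(pheno$pop, theta$labels))
  pheno <- pheno[ord, , drop = FALSE]
  if (use_pedigree) {
    m <- build_m_from_pedigree(data$pedigree, theta, keep = pheno$id)
  } else {
    kin <- lapply(theta$labels, function(x) {
      f1 <- subset_individuals(data$f1_neutral, which(data$f1_neutral$pop == x))
      ids_x <- pheno$id[pheno$pop == x]
      if (kinship_reference == "offspring") {
        k <- estimate_kinship_within(f1)
      } else {
        par_x <- subset_individuals(data$parents_neutral,
                                    which(data$parents_neutral$pop == x))
        both <- genotype_matrix(
          rbind(f1$dosages, par_x$dosages),
          pop = rep(x, nrow(f1$dosages) + nrow(par_x$dosages)),
          ids = c(f1$ids, par_x$ids))
        ref <- if (kinship_reference == "parents") par_x$ids else both$ids
        k <- estimate_kinship_within(both, reference_ids = ref)
      }
      k[ids_x, ids_x, drop = FALSE]
    })
    names(kin) <- theta$labels
    m <- build_m(kin, theta)
  }
  # align phenotypes to the row order of M
  pheno <- pheno[match(m$ids, pheno$id), , drop = FALSE]
  post <- fit_model(pheno, theta, m, mcmc = mcmc)
  res <- logav_test(post, alpha = alpha)
  res$posterior <- post
  res$theta <- theta
  res$m <- m
  res
}
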