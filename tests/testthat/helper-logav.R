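# Shared fixtures and oracles for the test suite.

# Reduced-scale study conditions used by the simulation-heavy tests: the
# published scenario layouts (deme counts, chain/island/hierarchical
# structure, Fst anchors, NC II design, optima, heritability) with deme
# sizes shrunk and migration / selection rescaled by the diffusion scaling
# (N/k, m*k, omega^2/k). Neutral calibration scenarios keep the full 2000
# neutral markers (coancestry precision is part of the published study
# conditions; see the methods vignette); selection scenarios use 1000
# markers (power is driven by the trait, not by marker precision).
# Trait loci: 50.
test_scenarios <- function() {
  list(
    island_neutral = sim_config(
      "island", n_subpops = 8, deme_size = 25, migration_rate = 0.02,
      n_neutral_loci = 2000, n_qtl = 50, fst_target = 0.13,
      max_generations = 2000),
    ss_neutral_fst037 = sim_config(
      "stepping_stones_1d", n_subpops = 20, deme_size = 20,
      migration_rate = 0.05, n_neutral_loci = 2000, n_qtl = 50,
      fst_target = 0.37, max_generations = 4000),
    ss_neutral_fst02 = sim_config(
      "stepping_stones_1d", n_subpops = 20, deme_size = 20,
      migration_rate = 0.25, n_neutral_loci = 2000, n_qtl = 50,
      fst_target = 0.2, max_generations = 4000),
    hier_139 = sim_config(
      "hierarchical_139", n_subpops = 9, deme_size = 45,
      migration_rate = 0, n_neutral_loci = 2000, n_qtl = 50,
      fst_target = 0.2, max_generations = 2000),
    ss_sel_w10 = sim_config(
      "stepping_stones_1d", n_subpops = 20, deme_size = 20,
      migration_rate = 0.045, n_neutral_loci = 1000, n_qtl = 50,
      selection = "stabilizing", omega = 10 / sqrt(50),
      fst_target = 0.18, max_generations = 4000),
    ss_sel_w22 = sim_config(
      "stepping_stones_1d", n_subpops = 20, deme_size = 20,
      migration_rate = 0.045, n_neutral_loci = 1000, n_qtl = 50,
      selection = "stabilizing", omega = 22 / sqrt(50),
      fst_target = 0.18, max_generations = 4000),
    ss_sel_w50 = sim_config(
      "stepping_stones_1d", n_subpops = 20, deme_size = 20,
      migration_rate = 0.045, n_neutral_loci = 1000, n_qtl = 50,
      selection = "stabilizing", omega = 50 / sqrt(50),
      fst_target = 0.18, max_generations = 4000),
    island_sel_w50 = sim_config(
      "island", n_subpops = 8, deme_size = 25, migration_rate = 0.02,
      n_neutral_loci = 1000, n_qtl = 50,
      selection = "stabilizing", omega = 50 / sqrt(20),
      fst_target = 0.15, max_generations = 2000))
}

# fast MCMC settings for replicated runs
test_mcmc <- function(seed = NULL) {
  mcmc_control(chains = 2, warmup = 200, iter = 400, seed = seed)
}

# brute-force allele-sharing oracle: direct loops over pairs and loci
oracle_allele_sharing <- function(G) {
  n <- nrow(G)
  A <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- c()
    for (l in seq_len(ncol(G))) {
      gi <- G[i, l]; gj <- G[j, l]
      if (is.na(gi) || is.na(gj)) next
      s <- c(s, if (gi == 1 || gj == 1) 0.5 else if (gi == gj) 1 else 0)
    }
    A[i, j] <- mean(s)
  }
  A
}

# small exact-model dataset simulated directly from the mixed model:
# z = mu + a_p[pop] + a_i + e with a_p ~ MVN(0, 2 theta V_B),
# a_i ~ MVN(0, M V_W). Uses an island-like theta and an NC II pedigree M.
exact_model_data <- function(r = 8, n_per = 50, v_b = 1, v_w = 1, v_e = 1,
                             theta_diag = 0.15, mu = 0, seed = 1) {
  set.seed(seed)
  labels <- paste0("pop", seq_len(r))
  tp <- diag(theta_diag, r)
  dimnames(tp) <- list(labels, labels)
  theta <- structure(list(theta_p = tp, reference_value = 0,
                          labels = labels), class = "pop_coancestry")
  # NC II 5x5x2 additive-relationship block, shared across demes
  s <- rep(rep(1:5, each = 5), each = 2)
  d <- rep(rep(1:5, times = 5), each = 2)
  blk <- 0.5 * outer(s, s, "==") + 0.5 * outer(d, d, "==")
  diag(blk) <- 1
  blk <- blk[seq_len(n_per), seq_len(n_per), drop = FALSE]
  kin <- lapply(labels, function(x) blk / 2)  # so block = 2k(1-theta)
  names(kin) <- labels
  m <- build_m(kin, theta)
  n <- r * n_per
  chol_t <- chol(2 * tp * v_b + diag(1e-10, r))
  a_p <- as.numeric(t(chol_t) %*% rnorm(r))
  a_i <- as.numeric(t(chol(m$m * v_w + diag(1e-10, n))) %*% rnorm(n))
  pop <- m$pop
  z <- mu + a_p[as.integer(pop)] + a_i + rnorm(n, 0, sqrt(v_e))
  list(pheno = data.frame(id = m$ids, pop = as.character(pop), z = z),
       theta = theta, m = m, truth = list(v_b = v_b, v_w = v_w, v_e = v_e))
}

# log restricted posterior density of the three variances on a grid, with
# the intercept integrated out analytically under its flat prior: used as
# the quadrature oracle for the Gibbs sampler on tiny instances.
log_marginal_variances <- function(z, Kb, Kw, v_b, v_w, v_e, nu, A2) {
  n <- length(z)
  Sigma <- v_b * Kb + v_w * Kw + diag(v_e, n)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  one <- rep(1, n)
  Si_one <- backsolve(ch, forwardsolve(t(ch), one))
  Si_z <- backsolve(ch, forwardsolve(t(ch), z))
  xvx <- sum(one * Si_one)
  beta <- sum(one * Si_z) / xvx
  quad <- sum(z * Si_z) - beta^2 * xvx
  loglik <- -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + quad)
  # half-t(nu, sqrt(A2)) prior on each sd, transformed to the variance scale
  lp <- function(v) -0.5 * (nu + 1) * log1p(v / (nu * A2)) - 0.5 * log(v)
  loglik + lp(v_b) + lp(v_w) + lp(v_e)
}
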