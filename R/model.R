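#' MCMC settings for the ancestral-variance model
#'
#' @param chains number of independent chains.
#' @param warmup discarded burn-in iterations per chain.
#' @param iter kept iterations per chain.
#' @param seed master seed; per-chain streams are derived deterministically.
#' @param keep_effects keep per-draw population and individual effects
#'   (memory grows with n; posterior means are always kept).
#' @param prior_nu,prior_scale_mult half-t prior on each standard deviation:
#'   `sd ~ half-t(prior_nu, prior_scale_mult * sd(z))`.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000,
                         seed = NULL, keep_effects = FALSE,
                         prior_nu = 3, prior_scale_mult = 2.5) {
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = seed,
                 keep_effects = keep_effects, prior_nu = prior_nu,
                 prior_scale_mult = prior_scale_mult),
            class = "mcmc_control")
}

#' Fit the two-variance ancestral animal model
#'
#' Bayesian fit of the mixed model `z = mu + a_p[pop] + a_i + e` with
#' `a_p ~ MVN(0, 2 * theta_p * V_B)`, `a_i ~ MVN(0, M * V_W)` and iid
#' Gaussian residuals, where `theta_p` is the population coancestry matrix
#' and `M` the block-diagonal within-population relatedness. `V_B` and
#' `V_W` are two estimates of the same ancestral additive genetic variance
#' (from between-population divergence and within-population resemblance);
#' under neutrality they coincide.
#'
#' The sampler is a blocked Gibbs scheme: the effects have
#' Gaussian-conjugate full conditionals sampled in the eigenbasis of their
#' covariance matrices (so rank-deficient, PSD-repaired matrices are handled
#' without inversion), and each standard deviation carries a half-t prior
#' implemented by inverse-gamma parameter expansion, making every variance
#' update conjugate as well. The prior on `mu` is improper flat.
#'
#' @param pheno data frame with columns `id`, `pop`, `z`; row order must
#'   match the individual order of `m`.
#' @param theta a [estimate_theta_p()] result (PSD repair is applied to
#'   `2 * theta_p` internally).
#' @param m a [build_m()] result.
#' @param mcmc a [mcmc_control()].
#' @return object of class `model_posterior`: matrices of draws (rows =
#'   chains x iter) for `mu`, `v_b`, `v_w`, `v_e`; posterior means of the
#'   random effects; convergence diagnostics (split R-hat and effective
#'   sample size per scalar parameter, with a `converged` flag at
#'   R-hat <= 1.05).
#' @export
fit_model <- function(pheno, theta, m, mcmc = mcmc_control()) {
  stopifnot(inherits(theta, "pop_coancestry"),
            inherits(m, "within_relatedness"),
            inherits(mcmc, "mcmc_control"))
  if (!all(c("pop", "z") %in% names(pheno))) {
    stop("`pheno` needs columns pop and z")
  }
  z <- as.numeric(pheno$z)
  n <- length(z)
  if (n != nrow(m$m)) stop("phenotype table and M disagree on n")
  if (stats::var(z) == 0) stop("phenotype has zero variance; nothing to partition")
  pop <- factor(as.character(pheno$pop), levels = theta$labels)
  if (anyNA(pop)) stop("phenotype pop labels not all present in theta")
  if (!identical(as.character(pop), as.character(m$pop))) {
    stop("phenotype and M must share the same individual (pop) ordering")
  }
  r <- length(theta$labels)

  # eigen-structure of the two covariance matrices
  G2 <- psd_repair(2 * theta$theta_p, jitter = 0)
  et <- eigen(G2, symmetric = TRUE)
  pos_t <- et$values > max(et$values) * 1e-10
  Ut <- et$vectors[, pos_t, drop = FALSE]
  dt <- et$values[pos_t]
  blocks <- m$blocks
  eb <- lapply(blocks, function(B) {
    e <- eigen(B, symmetric = TRUE)
    keep <- e$values > max(e$values, 0) * 1e-10
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  })
  block_rows <- split(seq_len(n), m$pop)
  n_x <- as.numeric(table(pop))
  pop_int <- as.integer(pop)
  nu <- mcmc$prior_nu
  A2 <- (mcmc$prior_scale_mult * stats::sd(z))^2

  kB <- length(dt)
  kW <- sum(vapply(eb, function(e) length(e$d), numeric(1)))
  # fixed cross-product blocks of the joint (mu, population-effect) update:
  # design W = [1, Zp %*% Ut], so W'W = [[n, nU], [nU', UtnU]]
  nU <- as.numeric(t(Ut) %*% n_x)
  UtnU <- t(Ut) %*% (n_x * Ut)
  WtW <- rbind(c(n, nU), cbind(nU, UtnU))
  # stack the per-block eigenbases into one sparse block-diagonal rotation
  # so the individual-effect update is two sparse matrix-vector products
  ij <- do.call(rbind, lapply(seq_along(eb), function(x) {
    kx <- length(eb[[x]]$d)
    if (!kx) return(NULL)
    cbind(rep(block_rows[[x]], kx),
          rep(seq_len(kx), each = length(block_rows[[x]])),
          as.numeric(eb[[x]]$U))
  }))
  col_off <- cumsum(c(0, utils::head(vapply(eb, function(e) length(e$d),
                                            numeric(1)), -1)))
  ij[, 2] <- ij[, 2] + rep(col_off, vapply(seq_along(eb), function(x) {
    length(eb[[x]]$d) * length(block_rows[[x]])
  }, numeric(1)))
  Ubig <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                               dims = c(n, kW))
  dW <- unlist(lapply(eb, `[[`, "d"), use.names = FALSE)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    vz <- stats::var(z)
    mu <- mean(z); v_b <- vz / 3; v_w <- vz / 3; v_e <- vz / 3
    a_b <- a_w <- a_e <- 1
    cvec <- rep(0, kB)
    bvec <- rep(0, kW)
    ai <- rep(0, n); ap <- rep(0, r)
    tot <- mcmc$warmup + mcmc$iter
    keep <- mcmc$iter
    out <- matrix(NA_real_, keep, 4,
                  dimnames = list(NULL, c("mu", "v_b", "v_w", "v_e")))
    ap_draws <- if (mcmc$keep_effects) matrix(NA_real_, keep, r) else NULL
    ai_draws <- if (mcmc$keep_effects) matrix(NA_real_, keep, n) else NULL
    ap_sum <- rep(0, r); ai_sum <- rep(0, n)
    for (s in seq_len(tot)) {
      # joint (mu, population effects) draw: flat prior on mu, Gaussian on
      # the coefficients in the eigenbasis of 2*theta_p; sampling the
      # intercept together with the population effects removes their
      # strong posterior coupling. The block is swept twice per iteration
      # (it costs O(r^2) and the (a_p, V_B) pair is the slow direction in
      # strongly clustered coancestry structures).
      for (sweep in 1:2) {
        rp <- z - ai
        y_p <- as.numeric(rowsum(rp, pop_int))
        prec <- WtW / v_e + diag(c(0, 1 / (dt * v_b)), kB + 1)
        ch <- chol(prec)
        wr <- c(sum(rp), as.numeric(t(Ut) %*% y_p)) / v_e
        gam <- backsolve(ch, forwardsolve(t(ch), wr) + stats::rnorm(kB + 1))
        mu <- gam[1]
        cvec <- gam[-1]
        ap <- as.numeric(Ut %*% cvec)
        ss_b <- sum(cvec^2 / dt)
        v_b <- rinvgamma((nu + kB) / 2, nu / a_b + ss_b / 2)
        a_b <- rinvgamma((nu + 1) / 2, nu / v_b + 1 / A2)
        if (kB > 0 && sum(ap^2) > 0) {
          u_x <- ap / sqrt(v_b)
          y0 <- as.numeric(rowsum(z - mu - ai, pop_int))
          s_new <- asis_scale_draw(sqrt(v_b), sum(u_x * y0),
                                   sum(n_x * u_x^2), v_e, nu, a_b)
          if (s_new != sqrt(v_b)) {
            ap <- u_x * s_new
            cvec <- cvec * (s_new / sqrt(v_b))
            v_b <- s_new^2
          }
        }
      }
      # individual effects, all blocks at once in the stacked eigenbasis
      ri <- z - mu - ap[pop_int]
      rt <- as.numeric(Matrix::crossprod(Ubig, ri))
      vcond <- 1 / (1 / (dW * v_w) + 1 / v_e)
      bvec <- stats::rnorm(kW, vcond * rt / v_e, sqrt(vcond))
      ai <- as.numeric(Ubig %*% bvec)
      # variances: half-t via inverse-gamma parameter expansion
      ss_w <- sum(bvec^2 / dW)
      v_w <- rinvgamma((nu + kW) / 2, nu / a_w + ss_w / 2)
      a_w <- rinvgamma((nu + 1) / 2, nu / v_w + 1 / A2)
      # interweaving (ASIS) rescaling moves: re-express each effect vector
      # in its non-centred form and update the corresponding standard
      # deviation against the data; breaks the slow variance-effect
      # random walk of the purely centred sampler
      if (kW > 0 && sum(ai^2) > 0) {
        u <- ai / sqrt(v_w)
        res0 <- z - mu - ap[pop_int]
        s_new <- asis_scale_draw(sqrt(v_w), sum(u * res0), sum(u^2), v_e,
                                 nu, a_w)
        if (s_new != sqrt(v_w)) {
          ai <- u * s_new
          bvec <- bvec * (s_new / sqrt(v_w))
          v_w <- s_new^2
        }
      }
      res <- z - mu - ap[pop_int] - ai
      v_e <- rinvgamma((nu + n) / 2, nu / a_e + sum(res^2) / 2)
      a_e <- rinvgamma((nu + 1) / 2, nu / v_e + 1 / A2)
      if (s > mcmc$warmup) {
        j <- s - mcmc$warmup
        out[j, ] <- c(mu, v_b, v_w, v_e)
        ap_sum <- ap_sum + ap; ai_sum <- ai_sum + ai
        if (mcmc$keep_effects) { ap_draws[j, ] <- ap; ai_draws[j, ] <- ai }
      }
    }
    list(out = out, ap_mean = ap_sum / keep, ai_mean = ai_sum / keep,
         ap_draws = ap_draws, ai_draws = ai_draws)
  }

  master <- if (is.null(mcmc$seed)) sample.int(.Machine$integer.max, 1) else mcmc$seed
  chain_seeds <- derive_seeds(master, mcmc$chains)
  chains <- lapply(chain_seeds, run_chain)
  draws <- lapply(c(mu = "mu", v_b = "v_b", v_w = "v_w", v_e = "v_e"),
                  function(p) sapply(chains, function(ch) ch$out[, p]))
  diag_tab <- data.frame(
    parameter = names(draws),
    rhat = vapply(draws, split_rhat, numeric(1)),
    ess = vapply(draws, ess_bulk, numeric(1)))
  converged <- all(is.na(diag_tab$rhat) | diag_tab$rhat <= 1.05)
  if (!converged) {
    warning("MCMC may not have converged: max split R-hat = ",
            round(max(diag_tab$rhat, na.rm = TRUE), 3))
  }
  structure(list(
    draws = lapply(draws, as.numeric),
    n_draws = mcmc$chains * mcmc$iter,
    chains = mcmc$chains, iter = mcmc$iter,
    ap_mean = rowMeans(sapply(chains, `[[`, "ap_mean")),
    ai_mean = rowMeans(sapply(chains, `[[`, "ai_mean")),
    ap_draws = if (mcmc$keep_effects)
      do.call(rbind, lapply(chains, `[[`, "ap_draws")) else NULL,
    ai_draws = if (mcmc$keep_effects)
      do.call(rbind, lapply(chains, `[[`, "ai_draws")) else NULL,
    labels = theta$labels, diagnostics = diag_tab, converged = converged,
    seed = master), class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("model_posterior:", x$n_draws, "draws (", x$chains, "chains )\n")
  s <- t(vapply(x$draws[c("v_b", "v_w", "v_e")], function(d) {
    c(mean = mean(d), stats::quantile(d, c(0.025, 0.975)))
  }, numeric(3)))
  print(round(s, 4))
  cat("max split R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# Deterministic per-chain / per-replicate seed streams from one master seed.
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

rinvgamma <- function(shape, rate) 1 / stats::rgamma(1, shape = shape, rate = rate)

# Independence Metropolis-Hastings draw of a scale parameter in its
# non-centred parameterization: the Gaussian likelihood in s (truncated to
# s > 0) proposes, and the half-t prior (conditional on its inverse-gamma
# auxiliary `a_aux`) corrects through the acceptance ratio.
asis_scale_draw <- function(s_cur, u_dot_res, u_norm2, v_e, nu, a_aux) {
  if (u_norm2 <= 0) return(s_cur)
  m0 <- u_dot_res / u_norm2
  sd0 <- sqrt(v_e / u_norm2)
  p0 <- stats::pnorm(0, m0, sd0)
  if (p0 > 1 - 1e-12) return(s_cur)  # proposal mass entirely below 0
  s_prop <- stats::qnorm(stats::runif(1, p0, 1), m0, sd0)
  if (!is.finite(s_prop) || s_prop <= 0) return(s_cur)
  lp <- function(s) -(nu + 1) * log(s) - nu / (a_aux * s^2)
  if (log(stats::runif(1)) < lp(s_prop) - lp(s_cur)) s_prop else s_cur
}

# Split R-hat (Gelman-Rubin on split half-chains), draws as iter x chain matrix.
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  if (m < 2 || nn < 4) return(NA_real_)
  mu_j <- colMeans(sp); s2_j <- apply(sp, 2, stats::var)
  B <- nn * stats::var(mu_j); W <- mean(s2_j)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Bulk effective sample size from pooled autocorrelations (Geyer initial
# positive sequence, per chain then combined).
ess_bulk <- function(x) {
  x <- as.matrix(x)
  nn <- nrow(x); m <- ncol(x)
  if (nn < 10) return(NA_real_)
  rho <- rowMeans(sapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    a <- stats::acf(v, lag.max = min(nn - 1, 200), plot = FALSE)$acf[, 1, 1]
    a
  }))
  tau <- 1; k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  m * nn / tau
}

#' REML point estimates of the three variance components
#'
#' Maximizes the restricted likelihood of the ancestral-variance model over
#' `(V_B, V_W, V_e)` by direct optimization on the log-variance scale, using
#' the dense phenotypic covariance `Sigma = 2 * theta_p (expanded) * V_B +
#' M * V_W + V_e * I` and profiling out the intercept. Intended as a fast
#' frequentist cross-check of the posterior location, not as the primary
#' fit.
#'
#' @inheritParams fit_model
#' @return list with `v_b`, `v_w`, `v_e`, the restricted log-likelihood and
#'   a `converged` flag.
#' @export
reml_point_fit <- function(pheno, theta, m) {
  stopifnot(inherits(theta, "pop_coancestry"),
            inherits(m, "within_relatedness"))
  z <- as.numeric(pheno$z)
  n <- length(z)
  pop <- factor(as.character(pheno$pop), levels = theta$labels)
  Zp <- outer(pop, theta$labels, "==")
  storage.mode(Zp) <- "double"
  G2 <- psd_repair(2 * theta$theta_p, jitter = 0)
  Kb <- Zp %*% G2 %*% t(Zp)
  Kw <- m$m
  one <- rep(1, n)
  nll <- function(par) {
    v <- exp(par)
    Sigma <- v[1] * Kb + v[2] * Kw + diag(v[3], n)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdet <- 2 * sum(log(diag(ch)))
    Si_one <- backsolve(ch, forwardsolve(t(ch), one))
    Si_z <- backsolve(ch, forwardsolve(t(ch), z))
    xvx <- sum(one * Si_one)
    beta <- sum(one * Si_z) / xvx
    resid_q <- sum(z * Si_z) - beta^2 * xvx
    0.5 * (logdet + log(xvx) + resid_q)
  }
  v0 <- stats::var(z) / 3
  opt <- stats::optim(log(c(v0, v0, v0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  v <- exp(opt$par)
  list(v_b = v[1], v_w = v[2], v_e = v[3],
       logLik = -opt$value, converged = opt$convergence == 0)
}
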