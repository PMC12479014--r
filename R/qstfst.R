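#' Variance components and Qst from a balanced common-garden design
#'
#' Method-of-moments (balanced ANOVA) estimation of the between-population
#' variance and the within-population additive variance from a North
#' Carolina II common-garden experiment, followed by
#' `Qst = V_B / (V_B + 2 * V_W)`.
#'
#' Mean squares are taken from the balanced nested-factorial ANOVA
#' (population, sire and dam within population, sire x dam, residual). The
#' additive within-population variance is mapped from the parental
#' components as `4 * sire variance` by default (paternal half-sib mapping)
#' or `2 * (sire + dam)` with `mapping = "sire_dam"`; both are standard for
#' this design.
#'
#' @param pheno data frame with columns `z`, `pop`.
#' @param families data frame aligned with `pheno` rows, columns `sire`,
#'   `dam` (family labels within population).
#' @param mapping additive-variance mapping, `"sire"` (default) or
#'   `"sire_dam"`.
#' @return list with `v_b`, `v_w`, `qst`, the component estimates and the
#'   design degrees of freedom used by [wg_bootstrap_test()].
#' @export
estimate_qst_components <- function(pheno, families, mapping = c("sire", "sire_dam")) {
  mapping <- match.arg(mapping)
  if (!all(c("z", "pop") %in% names(pheno))) stop("`pheno` needs z and pop")
  if (!all(c("sire", "dam") %in% names(families))) {
    stop("`families` needs sire and dam labels")
  }
  if (nrow(families) != nrow(pheno)) stop("pheno and families must align")
  if (anyNA(families$sire) || anyNA(families$dam)) {
    stop("missing family labels")
  }
  d <- data.frame(z = as.numeric(pheno$z),
                  pop = factor(pheno$pop),
                  sire = factor(paste(pheno$pop, families$sire, sep = ":")),
                  dam = factor(paste(pheno$pop, families$dam, sep = ":")))
  r <- nlevels(d$pop)
  s <- length(unique(families$sire[d$pop == levels(d$pop)[1]]))
  dn <- length(unique(families$dam[d$pop == levels(d$pop)[1]]))
  o <- nrow(d) / (r * s * dn)
  if (abs(o - round(o)) > 1e-8) {
    stop("design is not balanced: offspring per cross is not constant")
  }
  o <- round(o)
  # balanced nested-factorial decomposition from cell means (orthogonal
  # under balance, identical to the sequential ANOVA but O(n))
  gm <- mean(d$z)
  m_pop <- tapply(d$z, d$pop, mean)          # per deme
  m_sire <- tapply(d$z, d$sire, mean)        # per sire (nested in deme)
  m_dam <- tapply(d$z, d$dam, mean)
  m_cell <- tapply(d$z, list(d$sire, d$dam), mean)  # NA for cross-deme cells
  pop_of_sire <- as.character(tapply(as.character(d$pop), d$sire, `[`, 1))
  ss_pop <- s * dn * o * sum((m_pop - gm)^2)
  ss_s <- dn * o * sum((m_sire - m_pop[pop_of_sire])^2)
  pop_of_dam <- as.character(tapply(as.character(d$pop), d$dam, `[`, 1))
  ss_d <- s * o * sum((m_dam - m_pop[pop_of_dam])^2)
  cell_fit <- outer(m_sire - m_pop[pop_of_sire], m_dam, "+")
  ss_sd <- o * sum((m_cell - cell_fit)^2, na.rm = TRUE)
  ss_e <- sum((d$z - m_cell[cbind(as.integer(d$sire), as.integer(d$dam))])^2)
  df_v <- c(r - 1, r * (s - 1), r * (dn - 1), r * (s - 1) * (dn - 1),
            r * s * dn * (o - 1))
  ms <- c(ss_pop, ss_s, ss_d, ss_sd, ss_e) / df_v
  names(ms) <- c("pop", "sire", "dam", "sire:dam", "Residuals")
  ms_pop <- ms[["pop"]]; ms_s <- ms[["sire"]]; ms_d <- ms[["dam"]]
  ms_sd <- ms[["sire:dam"]]; ms_e <- ms[["Residuals"]]
  sig_sd <- max(0, (ms_sd - ms_e) / o)
  sig_s <- max(0, (ms_s - ms_sd) / (o * dn))
  sig_d <- max(0, (ms_d - ms_sd) / (o * s))
  # E[MS_pop] = s*d*o*sig_pop + d*o*sig_s + s*o*sig_d + o*sig_sd + sig_e
  sig_pop <- max(0, (ms_pop - dn * o * sig_s - s * o * sig_d - o * sig_sd -
                       ms_e) / (s * dn * o))
  v_w <- if (mapping == "sire") 4 * sig_s else 2 * (sig_s + sig_d)
  v_b <- sig_pop
  qst <- if (v_b + 2 * v_w > 0) v_b / (v_b + 2 * v_w) else 0
  list(v_b = v_b, v_w = v_w, qst = qst,
       components = c(pop = sig_pop, sire = sig_s, dam = sig_d,
                      sire_dam = sig_sd, residual = ms_e),
       mean_squares = ms,
       df = c(pop = r - 1, sire = r * (s - 1), dam = r * (dn - 1),
              sire_dam = r * (s - 1) * (dn - 1),
              residual = r * s * dn * (o - 1)),
       design = c(r = r, s = s, d = dn, o = o), mapping = mapping)
}

#' Parametric-bootstrap Qst-Fst test
#'
#' Classic chi-square parametric bootstrap of the neutral `Qst - Fst`
#' distribution. Under neutrality the expected between-population variance
#' is `2 * Fst / (1 - Fst) * V_W`; the between-population mean square is
#' resampled from a scaled chi-square centred on that neutral expectation,
#' every within-population mean square from a scaled chi-square centred on
#' its observed value, each with its design degrees of freedom, and a
#' neutral `Qst*` is recomputed from every draw through the same
#' method-of-moments pipeline as the observed value. The observed
#' `Qst - Fst` is then referred to the simulated `Qst* - Fst` distribution
#' with a two-tailed Monte-Carlo p-value. Resampling the mean squares
#' (rather than the variance components directly) reproduces the sampling
#' noise that the component subtraction itself carries. The test is
#' calibrated under the island model's assumption of independent, equally
#' related demes — and anticonservative when that assumption fails.
#'
#' @param comp an [estimate_qst_components()] result (carries the observed
#'   Qst, mean squares, design and degrees of freedom).
#' @param fst_obs neutral-marker Fst.
#' @param n_boot bootstrap draws (>= 1000).
#' @param seed integer seed; the p-value is reproducible given the seed.
#' @return list of class `qstfst_result`: `qst`, `fst`, `observed_diff`,
#'   `null_draws`, `p_value`.
#' @export
wg_bootstrap_test <- function(comp, fst_obs, n_boot = 2000, seed = NULL) {
  if (n_boot < 1000) stop("n_boot must be at least 1000")
  if (is.null(comp$mean_squares) || is.null(comp$df) || is.null(comp$design)) {
    stop("`comp` must be an estimate_qst_components() result")
  }
  df <- comp$df
  if (any(df < 1)) stop("invalid degrees of freedom: ", paste(df, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  des <- comp$design
  s <- des[["s"]]; dn <- des[["d"]]; o <- des[["o"]]
  ms <- comp$mean_squares
  # neutral expectation of the between-population mean square, from the
  # observed within components and the marker Fst
  v_b_neutral <- 2 * fst_obs / (1 - fst_obs) * comp$v_w
  ems_pop_neutral <- s * dn * o * v_b_neutral +
    dn * o * comp$components[["sire"]] + s * o * comp$components[["dam"]] +
    o * comp$components[["sire_dam"]] + comp$components[["residual"]]
  rchi <- function(center, d) center * stats::rchisq(n_boot, d) / d
  ms_pop <- rchi(ems_pop_neutral, df[["pop"]])
  ms_s <- rchi(ms[["sire"]], df[["sire"]])
  ms_d <- rchi(ms[["dam"]], df[["dam"]])
  ms_sd <- rchi(ms[["sire:dam"]], df[["sire_dam"]])
  ms_e <- rchi(ms[["Residuals"]], df[["residual"]])
  sig_s <- pmax(0, (ms_s - ms_sd) / (o * dn))
  sig_d <- pmax(0, (ms_d - ms_sd) / (o * s))
  sig_sd <- pmax(0, (ms_sd - ms_e) / o)
  sig_pop <- pmax(0, (ms_pop - dn * o * sig_s - s * o * sig_d - o * sig_sd -
                        ms_e) / (s * dn * o))
  v_w_star <- if (comp$mapping == "sire") 4 * sig_s else 2 * (sig_s + sig_d)
  qst_star <- ifelse(sig_pop + 2 * v_w_star > 0,
                     sig_pop / (sig_pop + 2 * v_w_star), 0)
  null_draws <- qst_star - fst_obs
  obs <- comp$qst - fst_obs
  lo <- sum(null_draws <= obs) + 1
  hi <- sum(null_draws >= obs) + 1
  p <- min(1, 2 * min(lo, hi) / (n_boot + 1))
  structure(list(qst = comp$qst, fst = fst_obs, observed_diff = obs,
                 null_draws = null_draws, p_value = p, n_boot = n_boot),
            class = "qstfst_result")
}

#' @export
print.qstfst_result <- function(x, ...) {
  cat("Qst-Fst parametric bootstrap: Qst =", format(x$qst, digits = 4),
      " Fst =", format(x$fst, digits = 4),
      " p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Qst-Fst baseline on a common-garden dataset
#'
#' Convenience wrapper chaining [estimate_qst_components()] on the F1
#' phenotypes (family labels parsed from the pedigree),
#' [fst_weir_cockerham()] on the parental neutral markers, and
#' [wg_bootstrap_test()].
#'
#' @param data a [common_garden()] dataset.
#' @param n_boot,seed,mapping passed through.
#' @return a `qstfst_result` with the component estimates attached.
#' @export
qstfst_pipeline <- function(data, n_boot = 2000, seed = NULL,
                            mapping = "sire") {
  pheno <- data$phenotypes
  ped <- data$pedigree
  fam <- ped[match(pheno$id, ped$id), c("sire", "dam")]
  comp <- estimate_qst_components(pheno, fam, mapping = mapping)
  fst <- fst_weir_cockerham(data$parents_neutral)
  res <- wg_bootstrap_test(comp, fst, n_boot = n_boot, seed = seed)
  res$components <- comp
  res
}
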