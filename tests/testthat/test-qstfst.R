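# balanced NC II phenotypes simulated directly from known variance
# components: z = pop + sire + dam + sire:dam + e
ncii_dataset <- function(r = 20, s = 5, d = 5, o = 2, v_pop = 0.3,
                         v_s = 0.2, v_d = 0.2, v_sd = 0.05, v_e = 1,
                         seed = 1) {
  set.seed(seed)
  pop <- rep(seq_len(r), each = s * d * o)
  sire <- rep(rep(seq_len(s), each = d * o), times = r)
  dam <- rep(rep(seq_len(d), each = o), times = r * s)
  u_pop <- rnorm(r, 0, sqrt(v_pop))
  u_s <- matrix(rnorm(r * s, 0, sqrt(v_s)), r, s)
  u_d <- matrix(rnorm(r * d, 0, sqrt(v_d)), r, d)
  u_sd <- array(rnorm(r * s * d, 0, sqrt(v_sd)), c(r, s, d))
  z <- u_pop[pop] + u_s[cbind(pop, sire)] + u_d[cbind(pop, dam)] +
    u_sd[cbind(pop, sire, dam)] + rnorm(length(pop), 0, sqrt(v_e))
  list(pheno = data.frame(id = seq_along(z), pop = paste0("p", pop), z = z),
       families = data.frame(sire = sire, dam = dam))
}

test_that("closed-form mean squares equal the sequential ANOVA", {
  d <- ncii_dataset(r = 4, seed = 2)
  comp <- estimate_qst_components(d$pheno, d$families)
  dd <- data.frame(z = d$pheno$z, pop = factor(d$pheno$pop),
                   sire = factor(paste(d$pheno$pop, d$families$sire)),
                   dam = factor(paste(d$pheno$pop, d$families$dam)))
  an <- stats::anova(stats::lm(z ~ pop + sire + dam + sire:dam, data = dd))
  expect_equal(unname(comp$mean_squares),
               unname(an[["Mean Sq"]]), tolerance = 1e-10)
})

test_that("balanced ANOVA recovers the simulated variance components", {
  d <- ncii_dataset(r = 40, seed = 10)
  comp <- estimate_qst_components(d$pheno, d$families)
  expect_equal(unname(comp$components["sire"]), 0.2, tolerance = 0.35)
  expect_equal(unname(comp$components["dam"]), 0.2, tolerance = 0.35)
  expect_equal(unname(comp$components["pop"]), 0.3, tolerance = 0.4)
  expect_equal(comp$v_w, 4 * comp$components[["sire"]])
  comp2 <- estimate_qst_components(d$pheno, d$families, mapping = "sire_dam")
  expect_equal(comp2$v_w,
               2 * (comp$components[["sire"]] + comp$components[["dam"]]))
  expect_equal(unname(comp$df),
               c(39, 40 * 4, 40 * 4, 40 * 16, 40 * 25))
  bad <- d$families; bad$sire[1] <- NA
  expect_error(estimate_qst_components(d$pheno, bad), "missing family")
})

test_that("Qst algebra: equal components, zero divergence, neutral identity", {
  qst <- function(v_b, v_w) v_b / (v_b + 2 * v_w)
  expect_equal(qst(1, 1), 1 / 3)
  expect_equal(qst(0, 2), 0)
  # components at the neutral expectation give Qst = Fst exactly
  for (fst in c(0.05, 0.13, 0.37)) {
    v_a <- 1.7
    expect_equal(qst(2 * v_a * fst, v_a * (1 - fst)), fst)
  }
})

test_that("the parametric bootstrap is seeded, centred and two-tailed", {
  d <- ncii_dataset(r = 20, v_pop = 2 * 0.2 / (1 - 0.2) * 0.8,
                    v_s = 0.2, v_d = 0.2, seed = 4)
  comp <- estimate_qst_components(d$pheno, d$families)
  b1 <- wg_bootstrap_test(comp, fst_obs = 0.2, n_boot = 2000, seed = 9)
  b2 <- wg_bootstrap_test(comp, fst_obs = 0.2, n_boot = 2000, seed = 9)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$null_draws, b2$null_draws)
  expect_equal(length(b1$null_draws), 2000)
  # an observation at the null median cannot be significant
  med <- stats::median(b1$null_draws)
  comp_med <- comp
  comp_med$qst <- med + 0.2
  b_med <- wg_bootstrap_test(comp_med, fst_obs = 0.2, n_boot = 2000, seed = 9)
  expect_gt(b_med$p_value, 0.9)
  expect_error(wg_bootstrap_test(comp, 0.2, n_boot = 10), "at least 1000")
})

test_that("null Qst draws track the anchoring Fst", {
  d <- ncii_dataset(r = 20, v_pop = 2 * 0.15 / (1 - 0.15) * 0.8,
                    v_s = 0.2, v_d = 0.2, seed = 6)
  comp <- estimate_qst_components(d$pheno, d$families)
  b <- wg_bootstrap_test(comp, fst_obs = 0.15, n_boot = 5000, seed = 2)
  # mean of the neutral Qst* distribution sits near Fst (ratio skew allowed)
  expect_equal(mean(b$null_draws + 0.15), 0.15, tolerance = 0.05)
})

test_that("the baseline pipeline runs end to end on simulator output", {
  cfg <- sim_config("island", n_subpops = 4, deme_size = 25,
                    migration_rate = 0.02, n_neutral_loci = 150, n_qtl = 30,
                    fst_target = 0.12, max_generations = 1500)
  cg <- logav:::simulate_garden(cfg, 8)
  res <- qstfst_pipeline(cg, n_boot = 1500, seed = 8)
  expect_s3_class(res, "qstfst_result")
  expect_true(res$qst >= 0 && res$qst <= 1)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$observed_diff, res$qst - res$fst)
})
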