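test_that("stabilizing fitness reproduces the foreign-fitness anchor values", {
  # home phenotype 10 trait units from the foreign optimum
  expect_equal(round(stabilizing_fitness(5, -5, 10), 1), 0.6)
  expect_equal(stabilizing_fitness(5, -5, 10), exp(-0.5), tolerance = 1e-12)
  expect_equal(round(stabilizing_fitness(5, -5, 22), 1), 0.9)
  expect_equal(stabilizing_fitness(5, -5, 22), exp(-100 / 968),
               tolerance = 1e-12)
  expect_equal(stabilizing_fitness(0, 0, 3), 1)
  expect_equal(stabilizing_fitness(2, 0, Inf), 1)  # flat peak = neutrality
  expect_error(stabilizing_fitness(1, 0, 0), "positive")
})

test_that("configuration validation and allele-effect scaling", {
  cfg <- sim_config("island", fst_target = 0.13)
  # ancestral additive variance identity: n_qtl * 2 * p * q * a^2 = V_A
  expect_equal(cfg$n_qtl * 2 * 0.25 * cfg$allele_effect^2, 1)
  cfg2 <- sim_config("island", v_a_ancestral = 4, n_qtl = 50,
                     fst_target = 0.1)
  expect_equal(50 * 0.5 * cfg2$allele_effect^2, 4)
  expect_error(sim_config("island", migration_rate = 2, fst_target = 0.1),
               "migration_rate")
  expect_error(sim_config("hierarchical_139", n_subpops = 8, fst_target = 0.1),
               "9 demes")
  expect_error(sim_config("island", selection = "stabilizing",
                          fst_target = 0.1), "omega")
  expect_error(sim_config("island"), "fst_target")
  # default optima split demes in half at -5 / +5
  sel <- sim_config("stepping_stones_1d", n_subpops = 20,
                    selection = "stabilizing", omega = 10, fst_target = 0.18)
  expect_equal(sel$optima, c(rep(-5, 10), rep(5, 10)))
})

test_that("diffusion rescaling preserves Nm and N-scaled selection", {
  cfg <- sim_config("stepping_stones_1d", n_subpops = 20, deme_size = 1000,
                    migration_rate = 0.01, selection = "stabilizing",
                    omega = 22, fst_target = 0.18)
  sc <- rescale_config(cfg, 20)
  expect_equal(sc$deme_size * sc$migration_rate,
               cfg$deme_size * cfg$migration_rate)
  expect_equal(sc$omega^2, cfg$omega^2 / 20)
  expect_equal(sc$fst_target, cfg$fst_target)
})

test_that("initialization is deterministic and splits one ancestral pool", {
  cfg <- sim_config("island", n_subpops = 4, deme_size = 50,
                    migration_rate = 0.01, n_neutral_loci = 300, n_qtl = 20,
                    fst_target = 0.1)
  set.seed(5); s1 <- init_metapop(cfg)
  set.seed(5); s2 <- init_metapop(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$G), 4 * 50)
  expect_true(all(s1$G %in% 0:2))
  # trait loci start at frequency 1/2
  expect_equal(mean(s1$G[, s1$qtl_cols]) / 2, 0.5, tolerance = 0.03)
  # uncorrected between-deme differentiation at the split is ~1/(2N)
  p_xd <- apply(s1$G[, -s1$qtl_cols], 2, function(g) {
    tapply(g, s1$deme, mean) / 2
  })
  ratio <- mean(apply(p_xd, 2, var)) /
    mean(colMeans(p_xd) * (1 - colMeans(p_xd)))
  expect_equal(ratio, 1 / (2 * 50), tolerance = 0.25)
  # hierarchical structure starts from the three first-level demes
  h <- sim_config("hierarchical_139", n_subpops = 9, deme_size = 30,
                  n_neutral_loci = 100, n_qtl = 10, fst_target = 0.1)
  set.seed(1)
  sh <- init_metapop(h)
  expect_equal(sh$active_demes, 1:3)
  expect_equal(nrow(sh$G), 3 * 30)
})

test_that("drift erodes heterozygosity at rate 1 - 1/(2N) without migration", {
  cfg <- sim_config("island", n_subpops = 2, deme_size = 20,
                    migration_rate = 0, n_neutral_loci = 600, n_qtl = 5,
                    generations = 30)
  set.seed(8)
  st <- init_metapop(cfg)
  het0 <- mean(st$G[, -st$qtl_cols] == 1)
  for (i in 1:30) st <- step_generation(st, cfg)
  het30 <- mean(st$G[, -st$qtl_cols] == 1)
  expect_equal(het30 / het0, (1 - 1 / (2 * 20))^30, tolerance = 0.12)
  # deme sizes conserved by the Wright-Fisher cycle
  expect_equal(as.numeric(table(st$deme)), c(20, 20))
  expect_true(all(st$G %in% 0:2))
})

test_that("Fst-targeted runs stop inside the target band", {
  cfg <- sim_config("island", n_subpops = 4, deme_size = 30,
                    migration_rate = 0.02, n_neutral_loci = 300, n_qtl = 10,
                    fst_target = 0.15, max_generations = 1500)
  st <- run_scenario(cfg, seed = 31)
  fst <- tail(attr(st, "fst_history")$fst, 1)
  expect_gte(fst, 0.15)
  expect_lte(fst, 0.20)
  # unreachable target errors out
  cfg_bad <- sim_config("island", n_subpops = 4, deme_size = 30,
                        migration_rate = 0.4, n_neutral_loci = 100,
                        n_qtl = 10, fst_target = 0.6, max_generations = 30)
  expect_error(run_scenario(cfg_bad, seed = 1), "not reached")
})

test_that("hierarchical runs produce three blocks of elevated coancestry", {
  cfg <- sim_config("hierarchical_139", n_subpops = 9, deme_size = 45,
                    migration_rate = 0, n_neutral_loci = 200, n_qtl = 20,
                    fst_target = 0.2, max_generations = 1500)
  st <- run_scenario(cfg, seed = 14)
  expect_equal(st$active_demes, 1:9)
  g <- genotype_matrix(st$G[, -st$qtl_cols], pop = st$deme)
  th <- estimate_theta_p(population_allele_sharing(g))$theta_p
  cluster <- rep(1:3, each = 3)
  same <- outer(cluster, cluster, "==") & upper.tri(th)
  diff <- !outer(cluster, cluster, "==") & upper.tri(th)
  expect_gt(mean(th[same]), mean(th[diff]) + 0.05)
})

test_that("common garden implements the 5x5x2 North Carolina II design", {
  cfg <- sim_config("island", n_subpops = 3, deme_size = 25,
                    migration_rate = 0.05, n_neutral_loci = 150, n_qtl = 20,
                    generations = 5)
  st <- run_scenario(cfg, seed = 2)
  cg <- common_garden(st, cfg, seed = 3)
  ped <- cg$pedigree[!is.na(cg$pedigree$sire), ]
  for (p in unique(ped$pop)) {
    sub <- ped[ped$pop == p, ]
    expect_equal(nrow(sub), 50)
    expect_equal(nrow(unique(sub[, c("sire", "dam")])), 25)
    expect_equal(length(unique(sub$sire)), 5)
    expect_equal(length(unique(sub$dam)), 5)
  }
  expect_equal(nrow(cg$phenotypes), 150)
  expect_identical(cg$phenotypes$id, cg$f1_neutral$ids)

  # family mean offspring breeding value tracks the mid-parent value
  bv <- stats::setNames(cg$truth$parent_bv, cg$parents_neutral$ids)
  mid <- (bv[ped$sire] + bv[ped$dam]) / 2
  fam_mean <- tapply(cg$truth$f1_bv, paste(ped$sire, ped$dam), mean)
  mid_fam <- tapply(mid, paste(ped$sire, ped$dam), mean)
  fit <- stats::lm(fam_mean ~ mid_fam[names(fam_mean)])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.2)

  # degenerate garden: monomorphic trait loci and no environmental noise
  st0 <- st
  st0$G[, st0$qtl_cols] <- 2L
  cfg0 <- cfg; cfg0$env_variance <- 0
  cg0 <- common_garden(st0, cfg0, seed = 3)
  expect_equal(stats::var(cg0$phenotypes$z), 0)
  expect_true(all(cg0$phenotypes$z == cfg$allele_effect * cfg$n_qtl))
})

test_that("selection moves deme trait means toward their optima", {
  cfg <- sim_config("island", n_subpops = 4, deme_size = 40,
                    migration_rate = 0.01, n_neutral_loci = 50, n_qtl = 30,
                    selection = "stabilizing", omega = 2,
                    optima = c(-3, -3, 3, 3), generations = 25)
  st <- run_scenario(cfg, seed = 77)
  bv <- breeding_values(st, cfg)
  dm <- tapply(bv, st$deme, mean)
  expect_lt(mean(dm[1:2]), -1)
  expect_gt(mean(dm[3:4]), 1)
})
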