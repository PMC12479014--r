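test_that("pairwise allele sharing follows the homozygote/heterozygote scoring", {
  expect_equal(allele_sharing_pair(c(2), c(2)), 1)
  expect_equal(allele_sharing_pair(c(0), c(0)), 1)
  expect_equal(allele_sharing_pair(c(2), c(0)), 0)
  expect_equal(allele_sharing_pair(c(1), c(2)), 0.5)
  expect_equal(allele_sharing_pair(c(1), c(1)), 0.5)
  # identical all-heterozygote individuals over 10 loci
  expect_equal(allele_sharing_pair(rep(1, 10), rep(1, 10)), 0.5)
  # missing loci are dropped pairwise
  expect_equal(allele_sharing_pair(c(2, NA, 0), c(2, 1, NA)), 1)
  expect_error(allele_sharing_pair(c(NA, 1), c(1, NA)), "no locus")
  expect_error(allele_sharing_pair(c(1, 1), c(1)), "same length")
})

test_that("allele-sharing matrix matches the brute-force pair oracle", {
  set.seed(42)
  G <- matrix(sample(c(0:2, NA), 8 * 20, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 8, 20)
  A <- allele_sharing_matrix(G)$values
  expect_equal(unname(A), oracle_allele_sharing(G), tolerance = 1e-12)
  expect_true(isSymmetric(A))
  expect_true(all(A >= 0 & A <= 1, na.rm = TRUE))
})

test_that("population-level allele sharing averages over the right pairs", {
  # 3-individual toy panel (2 pops, 2 loci), hand-enumerated pair means
  g <- genotype_matrix(rbind(c(2, 2), c(2, 0), c(0, 1)),
                       pop = c("A", "A", "B"),
                       ids = c("a1", "a2", "b1"))
  expect_error(population_allele_sharing(g), ">= 2 individuals")
  g4 <- genotype_matrix(rbind(c(2, 2), c(2, 0), c(0, 1), c(0, 0)),
                        pop = c("A", "A", "B", "B"))
  ab <- population_allele_sharing(g4)
  # within A: pair (1,2): (1 + 0)/2 = 0.5
  # within B: pair (3,4): (1 + 0.5)/2 = 0.75
  # A-B: pairs (1,3)=(0+.5)/2, (1,4)=0, (2,3)=(0+.5)/2... wait by hand:
  # (1,3): loci (2,0)=0,(2,1)=.5 -> .25 ; (1,4): (2,0)=0,(2,0)=0 -> 0
  # (2,3): (2,0)=0,(0,1)=.5 -> .25 ; (2,4): (2,0)=0,(0,0)=1 -> .5
  expect_equal(unname(ab), rbind(c(0.5, 0.25), c(0.25, 0.75)))

  # two pops fixed for opposite alleles: off-diagonal 0, diagonals 1
  fixed <- genotype_matrix(rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0)),
                           pop = c("A", "A", "B", "B"))
  expect_equal(unname(population_allele_sharing(fixed)),
               rbind(c(1, 0), c(0, 1)))

  # genetically identical homozygotes: all entries 1
  same <- genotype_matrix(matrix(2, 4, 3), pop = c("A", "A", "B", "B"))
  expect_equal(unname(population_allele_sharing(same)), matrix(1, 2, 2))
})

test_that("theta_p estimation anchors the least related pair at zero", {
  ab <- rbind(c(0.8, 0.6), c(0.6, 0.8))
  th <- estimate_theta_p(ab)
  expect_equal(unname(th$theta_p), rbind(c(0.5, 0), c(0, 0.5)))
  expect_equal(th$reference_value, 0.6)

  # all-equal allele sharing gives an all-zero coancestry matrix
  th0 <- estimate_theta_p(matrix(0.4, 3, 3))
  expect_equal(unname(th0$theta_p), matrix(0, 3, 3))

  # the minimum off-diagonal is exactly 0 whatever the input scale
  set.seed(7)
  for (i in 1:5) {
    ab <- matrix(runif(16, 0.2, 0.8), 4, 4)
    ab <- (ab + t(ab)) / 2
    shift <- runif(1, -0.1, 0.1)
    th <- estimate_theta_p(pmin(pmax(ab + shift, 0), 1))
    expect_equal(min(th$theta_p[upper.tri(th$theta_p)]), 0)
  }
  expect_error(estimate_theta_p(matrix(1, 2, 2)), "undifferentiated")
})

test_that("within-population kinship is centred and scaled by its reference", {
  set.seed(11)
  G <- matrix(rbinom(12 * 50, 2, 0.5), 12, 50)
  k <- estimate_kinship_within(G)
  # mean off-diagonal kinship is 0 by construction
  expect_equal(mean(k[upper.tri(k)]), 0, tolerance = 1e-12)
  # A_ij = Abar maps to 0; arithmetic identity (A=1, Abar=0.5 -> k=1)
  expect_equal((1 - 0.5) / (1 - 0.5), 1)
  abar <- attr(k, "abar")
  A <- allele_sharing_matrix(G)$values
  expect_equal(unname(k), unname((A - abar) / (1 - abar)),
               ignore_attr = TRUE)
  expect_error(estimate_kinship_within(matrix(2, 3, 4)), "no within-population")
})

test_that("marker kinship among simulated full sibs is close to pedigree expectation", {
  set.seed(5)
  n_par <- 10; L <- 2000
  P <- matrix(rbinom(n_par * L, 2, runif(L, 0.2, 0.8)[col(matrix(0, n_par, L))]),
              n_par, L)
  gam <- function(x) (x == 2) + (x == 1) * rbinom(length(x), 1, 0.5)
  # NC II 5x5, 2 offspring per cross
  cross <- expand.grid(s = 1:5, d = 6:10)
  off <- do.call(rbind, lapply(seq_len(nrow(cross)), function(i) {
    rbind(gam(P[cross$s[i], ]) + gam(P[cross$d[i], ]),
          gam(P[cross$s[i], ]) + gam(P[cross$d[i], ]))
  }))
  k <- estimate_kinship_within(off)
  fam <- rep(seq_len(nrow(cross)), each = 2)
  fullsib <- outer(fam, fam, "==") & upper.tri(k)
  halfsib <- (outer(cross$s[fam], cross$s[fam], "==") |
                outer(cross$d[fam], cross$d[fam], "==")) &
    !outer(fam, fam, "==") & upper.tri(k)
  # relatedness = 2 * kinship: full sibs ~0.5, half sibs ~0.25 relative to
  # the in-sample reference (which subtracts the mean, ~0.085 here)
  baseline <- mean(2 * k[!fullsib & !halfsib & upper.tri(k)])
  expect_equal(mean(2 * k[fullsib]) - baseline, 0.5, tolerance = 0.16)
  expect_equal(mean(2 * k[halfsib]) - baseline, 0.25, tolerance = 0.16)
})

test_that("M assembly scales, zeroes cross-population entries and stays PSD", {
  labels <- c("A", "B")
  tp <- rbind(c(0.2, 0), c(0, 0.4))
  dimnames(tp) <- list(labels, labels)
  theta <- structure(list(theta_p = tp, reference_value = 0.1,
                          labels = labels), class = "pop_coancestry")
  kA <- rbind(c(0.55, 0.25), c(0.25, 0.55))
  kB <- rbind(c(0.5, 0.1), c(0.1, 0.5))
  m <- build_m(list(A = kA, B = kB), theta)
  # relatedness 0.5 (= 2 * 0.25) scaled by (1 - 0.2) -> 0.4
  expect_equal(m$m[1, 2], 0.5 * (1 - 0.2), tolerance = 1e-6)
  # theta_x = 0 leaves the block unchanged (up to jitter)
  theta0 <- theta; theta0$theta_p <- matrix(0, 2, 2, dimnames = dimnames(tp))
  m0 <- build_m(list(A = kA, B = kB), theta0)
  expect_equal(m0$blocks$A, 2 * kA, tolerance = 1e-6, ignore_attr = TRUE)
  # cross-population entries exactly zero
  expect_true(all(m$m[m$pop[row(m$m)] != m$pop[col(m$m)]] == 0))
  expect_true(isSymmetric(m$m))
  expect_gte(min(eigen(m$m, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(build_m(list(A = kA), theta), "no kinship block")
})

test_that("PSD repair clips negative eigenvalues and only those", {
  x <- rbind(c(1, 0.99, 0), c(0.99, 1, 0.99), c(0, 0.99, 1))
  expect_lt(min(eigen(x, only.values = TRUE)$values), 0)
  y <- psd_repair(x)
  expect_gte(min(eigen(y, symmetric = TRUE, only.values = TRUE)$values), 0)
  z <- diag(2)
  expect_equal(psd_repair(z, jitter = 0), z)
})

test_that("pedigree-based M gives classic additive relationships", {
  ped <- data.frame(
    id = c("s1", "s2", "d1", "o1", "o2", "o3"),
    sire = c(NA, NA, NA, "s1", "s1", "s2"),
    dam = c(NA, NA, NA, "d1", "d1", "d1"),
    pop = "A", stringsAsFactors = FALSE)
  A <- logav:::additive_relationship(ped)
  expect_equal(A["o1", "o2"], 0.5)   # full sibs
  expect_equal(A["o1", "o3"], 0.25)  # maternal half sibs
  expect_equal(A["o1", "o1"], 1)     # non-inbred
  labels <- "A"
  tp <- matrix(0.2, 1, 1, dimnames = list(labels, labels))
  theta <- structure(list(theta_p = tp, reference_value = 0,
                          labels = labels), class = "pop_coancestry")
  m <- build_m_from_pedigree(ped, theta)
  expect_equal(m$m["o1", "o2"], 0.5 * (1 - 0.2), tolerance = 1e-6)
  bad <- ped; bad$pop <- c("A", "B", "A", "A", "A", "B")
  expect_error(build_m_from_pedigree(bad, theta), "cross-population")
})

test_that("marker-based and pedigree-based M agree on simulated NC II data", {
  set.seed(9)
  cfg <- sim_config("island", n_subpops = 3, deme_size = 30,
                    migration_rate = 0.05, n_neutral_loci = 1200, n_qtl = 10,
                    generations = 10)
  cg <- common_garden(run_scenario(cfg, seed = 9), cfg)
  theta <- estimate_theta_p(population_allele_sharing(cg$parents_neutral))
  kin <- lapply(theta$labels, function(x) {
    estimate_kinship_within(subset_individuals(
      cg$f1_neutral, which(cg$f1_neutral$pop == x)))
  })
  names(kin) <- theta$labels
  m_marker <- build_m(kin, theta)
  m_ped <- build_m_from_pedigree(cg$pedigree, theta,
                                 keep = cg$phenotypes$id)
  idx <- m_marker$ids
  off <- upper.tri(m_marker$m)
  dif <- m_marker$m[idx, idx][off] - m_ped$m[idx, idx][off]
  expect_lt(mean(abs(dif)), 0.05)
  expect_lt(max(abs(dif)), 0.35)
})

test_that("Fst from theta follows the coancestry identity", {
  tp <- diag(0.2, 3)
  expect_equal(fst_from_theta(tp)$fst, 0.2)
  expect_equal(fst_from_theta(matrix(0, 3, 3))$fst, 0)
  expect_equal(fst_from_theta(matrix(0.5, 3, 3))$fst, 0)
  mixed <- matrix(0.1, 4, 4); diag(mixed) <- c(0.3, 0.4, 0.2, 0.3)
  expect_equal(fst_from_theta(mixed)$fst, (0.3 - 0.1) / (1 - 0.1))
  expect_equal(fst_from_theta(mixed)$theta_b, 0.1)
})

test_that("coancestry-based Fst tracks the Weir-Cockerham estimator", {
  cfg <- sim_config("island", n_subpops = 6, deme_size = 30,
                    migration_rate = 0.02, n_neutral_loci = 2000, n_qtl = 10,
                    fst_target = 0.15, max_generations = 1000)
  st <- run_scenario(cfg, seed = 21)
  g <- genotype_matrix(st$G[, -st$qtl_cols], pop = st$deme)
  fst_wc <- fst_weir_cockerham(g)
  fst_theta <- fst_from_theta(
    estimate_theta_p(population_allele_sharing(g)))$fst
  expect_lt(abs(fst_wc - fst_theta), 0.02)
})

test_that("matrices permute consistently with individual order", {
  set.seed(3)
  G <- matrix(rbinom(10 * 80, 2, 0.4), 10, 80)
  pop <- rep(c("A", "B"), each = 5)
  g <- genotype_matrix(G, pop)
  perm <- sample(10)
  gp <- genotype_matrix(G[perm, ], pop[perm], ids = g$ids[perm])
  A1 <- allele_sharing_matrix(g)$values
  A2 <- allele_sharing_matrix(gp)$values
  expect_equal(A2[g$ids, g$ids], A1)
  expect_equal(population_allele_sharing(gp)[c("A", "B"), c("A", "B")],
               population_allele_sharing(g))
})
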