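#' Metapopulation simulation configuration
#'
#' Parameters of a forward-in-time Wright-Fisher metapopulation with an
#' additive quantitative trait, optional Gaussian stabilizing selection with
#' deme-specific optima, and a common-garden North Carolina II breeding
#' design. Defaults follow the published verification scenarios: 2000
#' neutral markers, 100 fully additive biallelic trait loci, ancestral
#' additive variance 1, optima at -5/+5 in the selected half of the demes.
#'
#' The per-locus allele effect is derived from `v_a_ancestral`: with `n_qtl`
#' biallelic loci at ancestral frequency 1/2, `V_A = n_qtl * 2 * 0.25 * a^2`,
#' so `a = sqrt(v_a_ancestral / (n_qtl / 2))`.
#'
#' @param structure metapopulation layout: `"island"` (uniform migration),
#'   `"stepping_stones_1d"` (migration split between adjacent demes,
#'   reflecting ends) or `"hierarchical_139"` (one root deme splitting into
#'   three, each splitting into three, no migration).
#' @param n_subpops number of demes `r` at sampling time.
#' @param deme_size diploid individuals per deme `N` (constant over time).
#' @param migration_rate total per-generation emigration probability `m`.
#' @param n_neutral_loci,n_qtl numbers of neutral markers and trait loci.
#' @param v_a_ancestral ancestral additive genetic variance of the trait.
#' @param selection `"neutral"` or `"stabilizing"`.
#' @param omega width of the Gaussian fitness peak (larger = weaker
#'   selection); required when `selection = "stabilizing"`.
#' @param optima per-deme trait optima; default splits the demes into two
#'   equal groups with optima -5 and +5 (adjacent demes grouped).
#' @param fst_target neutral-marker Fst at which the forward simulation
#'   stops (burn-in is run until the target is reached).
#' @param generations fixed number of generations, used instead of
#'   `fst_target` when given.
#' @param max_generations safety cap for Fst-targeted runs.
#' @param env_variance environmental variance added to trait values, both
#'   for in-simulation fitness and for common-garden phenotypes.
#' @param maf_range range of ancestral neutral-marker allele frequencies
#'   (uniform draw); trait loci start at frequency 1/2.
#' @param n_sires,n_dams,n_offspring_per_cross common-garden North Carolina
#'   II design: each of `n_sires` males is crossed with each of `n_dams`
#'   females, `n_offspring_per_cross` offspring per cross (defaults 5 x 5
#'   x 2 = 50 offspring per deme).
#' @param mutation_rate per-locus per-allele mutation probability; 0 by
#'   default (drift-migration-selection only).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(structure = c("island", "stepping_stones_1d",
                                     "hierarchical_139"),
                       n_subpops = 8, deme_size = 500,
                       migration_rate = 0.001,
                       n_neutral_loci = 2000, n_qtl = 100,
                       v_a_ancestral = 1,
                       selection = c("neutral", "stabilizing"),
                       omega = NULL, optima = NULL,
                       fst_target = NULL, generations = NULL,
                       max_generations = 5000,
                       env_variance = 1,
                       maf_range = c(0.1, 0.9),
                       n_sires = 5, n_dams = 5, n_offspring_per_cross = 2,
                       mutation_rate = 0) {
  structure <- match.arg(structure)
  selection <- match.arg(selection)
  if (structure == "hierarchical_139") {
    if (n_subpops != 9) stop("the hierarchical 1-3-9 structure has 9 demes")
    migration_rate <- 0
  }
  if (migration_rate < 0 || migration_rate > 1) stop("migration_rate must be in [0, 1]")
  if (n_neutral_loci < 1 || n_qtl < 1) stop("need at least one locus of each kind")
  if (selection == "stabilizing") {
    if (is.null(omega) || omega <= 0) stop("stabilizing selection needs omega > 0")
    if (is.null(optima)) {
      half <- floor(n_subpops / 2)
      optima <- c(rep(-5, half), rep(5, n_subpops - half))
    }
    if (length(optima) != n_subpops) stop("`optima` needs one value per deme")
  } else {
    optima <- rep(0, n_subpops)
    omega <- Inf
  }
  if (is.null(fst_target) && is.null(generations)) {
    stop("give either `fst_target` or `generations`")
  }
  structure(list(
    structure = structure, n_subpops = as.integer(n_subpops),
    deme_size = as.integer(deme_size), migration_rate = migration_rate,
    n_neutral_loci = as.integer(n_neutral_loci), n_qtl = as.integer(n_qtl),
    v_a_ancestral = v_a_ancestral,
    allele_effect = sqrt(v_a_ancestral / (n_qtl / 2)),
    selection = selection, omega = omega, optima = optima,
    fst_target = fst_target, generations = generations,
    max_generations = as.integer(max_generations),
    env_variance = env_variance, maf_range = maf_range,
    n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
    n_offspring_per_cross = as.integer(n_offspring_per_cross),
    mutation_rate = mutation_rate), class = "sim_config")
}

#' Rescale a simulation configuration for faster runs
#'
#' Applies the standard population-genetic diffusion rescaling by a factor
#' `k`: deme size is divided by `k` while the migration rate is multiplied
#' by `k` (preserving `N * m` and therefore the equilibrium differentiation
#' and its spatial pattern) and the squared fitness-peak width is divided by
#' `k` (preserving the product of population size and selection intensity).
#' Time contracts by `k`, so Fst targets are reached in proportionally fewer
#' generations with the same drift-migration-selection balance.
#'
#' @param cfg a [sim_config()].
#' @param k rescaling factor (> 1 accelerates).
#' @param n_neutral_loci,n_qtl optionally also reduce marker and trait-locus
#'   counts (a sampling-precision choice, independent of the dynamics).
#' @return a rescaled `sim_config`.
#' @export
rescale_config <- function(cfg, k, n_neutral_loci = NULL, n_qtl = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  new_n <- max(10L, as.integer(round(cfg$deme_size / k)))
  sim_config(structure = cfg$structure, n_subpops = cfg$n_subpops,
             deme_size = new_n,
             migration_rate = min(1, cfg$migration_rate * k),
             n_neutral_loci = n_neutral_loci %||% cfg$n_neutral_loci,
             n_qtl = n_qtl %||% cfg$n_qtl,
             v_a_ancestral = cfg$v_a_ancestral,
             selection = cfg$selection,
             omega = if (is.finite(cfg$omega)) cfg$omega / sqrt(k) else NULL,
             optima = if (cfg$selection == "stabilizing") cfg$optima else NULL,
             fst_target = cfg$fst_target, generations = cfg$generations,
             max_generations = cfg$max_generations,
             env_variance = cfg$env_variance, maf_range = cfg$maf_range,
             n_sires = cfg$n_sires, n_dams = cfg$n_dams,
             n_offspring_per_cross = cfg$n_offspring_per_cross,
             mutation_rate = cfg$mutation_rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gaussian stabilizing fitness
#'
#' `w(z) = exp(-(z - optimum)^2 / (2 * omega^2))`: relative fitness of
#' phenotype `z` under a Gaussian peak of width `omega` centred at
#' `optimum`. An individual at its home optimum evaluated against a foreign
#' optimum 10 trait units away has fitness 0.61 at `omega = 10` and 0.90 at
#' `omega = 22`.
#'
#' @param z phenotype value(s).
#' @param optimum peak location.
#' @param omega peak width; `Inf` gives flat fitness 1.
#' @return relative fitness in (0, 1].
#' @export
stabilizing_fitness <- function(z, optimum, omega) {
  if (any(omega <= 0)) stop("omega must be positive")
  exp(-(z - optimum)^2 / (2 * omega^2))
}

#' Initialize a metapopulation
#'
#' Draws ancestral allele frequencies once (uniform on `maf_range` for
#' neutral markers, 1/2 for trait loci) and populates each starting deme as
#' an independent Hardy-Weinberg sample from those frequencies — an
#' instantaneous split from one panmictic ancestral pool. For the
#' hierarchical 1-3-9 structure only the first three demes are populated at
#' the root split; the remaining six are filled when the second split is
#' scheduled by [run_scenario()].
#'
#' @param cfg a [sim_config()]. Uses the current RNG state; seed with
#'   `set.seed()` or via [run_scenario()].
#' @return object of class `metapop_state`: dosage matrix `G` (individuals
#'   x loci, trait loci last), deme assignment factor, `qtl_cols`,
#'   `generation` counter and the ancestral frequencies.
#' @export
init_metapop <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$n_neutral_loci + cfg$n_qtl
  p_anc <- c(stats::runif(cfg$n_neutral_loci, cfg$maf_range[1], cfg$maf_range[2]),
             rep(0.5, cfg$n_qtl))
  demes <- if (cfg$structure == "hierarchical_139") 1:3 else seq_len(cfg$n_subpops)
  n <- cfg$deme_size * length(demes)
  G <- matrix(stats::rbinom(n * L, 2, rep(p_anc, each = n)), n, L)
  storage.mode(G) <- "integer"
  structure(list(
    G = G, deme = rep(demes, each = cfg$deme_size),
    qtl_cols = cfg$n_neutral_loci + seq_len(cfg$n_qtl),
    generation = 0L, p_ancestral = p_anc,
    active_demes = demes), class = "metapop_state")
}

#' @export
print.metapop_state <- function(x, ...) {
  cat("metapop_state: generation", x$generation, "-",
      length(x$active_demes), "demes,", nrow(x$G), "individuals,",
      ncol(x$G), "loci\n")
  invisible(x)
}

#' Breeding values of the current individuals
#'
#' Sum of allele effects over trait loci, centred so that the ancestral
#' population mean is 0.
#'
#' @param state a [init_metapop()] state.
#' @param cfg the matching [sim_config()].
#' @return numeric vector of additive genetic values.
#' @export
breeding_values <- function(state, cfg) {
  cfg$allele_effect * (rowSums(state$G[, state$qtl_cols, drop = FALSE]) -
                         cfg$n_qtl)
}

# Gamete transmission: one allele per locus from each parent genotype row.
# Homozygotes transmit deterministically, heterozygotes a fair coin; coins
# are drawn only at heterozygous positions (the simulator hot path).
mendelian_gametes <- function(P) {
  H <- (P == 2L) + 0L
  het <- which(P == 1L)
  if (length(het)) H[het] <- as.integer(stats::runif(length(het)) > 0.5)
  H
}

#' Advance the metapopulation by one generation
#'
#' One Wright-Fisher cycle: (i) migration — island: each individual
#' emigrates with probability `m` to a uniformly chosen other deme;
#' stepping stones: `m/2` to each adjacent deme with reflecting ends (moves
#' off the chain are cancelled); hierarchical: no migration — then (ii)
#' fitness-weighted random mating within each deme (Gaussian stabilizing
#' fitness on phenotype = breeding value + environmental noise; flat under
#' neutrality; no selfing), and (iii) multinomial resampling to the constant
#' deme size.
#'
#' @param state a `metapop_state`.
#' @param cfg the matching [sim_config()].
#' @return the updated `metapop_state`.
#' @export
step_generation <- function(state, cfg) {
  stopifnot(inherits(state, "metapop_state"), inherits(cfg, "sim_config"))
  deme <- state$deme
  n <- length(deme)
  m <- cfg$migration_rate
  if (m > 0 && length(state$active_demes) > 1) {
    if (cfg$structure == "island") {
      move <- stats::runif(n) < m
      k <- length(state$active_demes)
      shift <- sample.int(k - 1, sum(move), replace = TRUE)
      cur <- match(deme[move], state$active_demes)
      deme[move] <- state$active_demes[1 + (cur - 1 + shift) %% k]
    } else if (cfg$structure == "stepping_stones_1d") {
      u <- stats::runif(n)
      step <- ifelse(u < m / 2, -1L, ifelse(u < m, 1L, 0L))
      dest <- deme + step
      # reflecting ends: moves off the chain are cancelled
      dest[dest < 1L | dest > cfg$n_subpops] <-
        deme[dest < 1L | dest > cfg$n_subpops]
      deme <- dest
    }
  }
  # fitness weights on wild phenotypes
  if (cfg$selection == "stabilizing") {
    z <- breeding_values(state, cfg) +
      stats::rnorm(n, 0, sqrt(cfg$env_variance))
    w <- stabilizing_fitness(z, cfg$optima[deme], cfg$omega)
  } else {
    w <- rep(1, n)
  }
  N <- cfg$deme_size
  p1 <- integer(0); p2 <- integer(0); child_deme <- integer(0)
  for (d in state$active_demes) {
    idx <- which(deme == d)
    if (length(idx) < 2) {
      stop("deme ", d, " has fewer than 2 members after migration")
    }
    wd <- w[idx]
    if (sum(wd) <= 0) wd <- rep(1, length(idx))
    a <- sample(idx, N, replace = TRUE, prob = wd)
    b <- sample(idx, N, replace = TRUE, prob = wd)
    clash <- which(a == b)
    while (length(clash)) {  # no selfing
      b[clash] <- sample(idx, length(clash), replace = TRUE, prob = wd)
      clash <- clash[a[clash] == b[clash]]
    }
    p1 <- c(p1, a); p2 <- c(p2, b)
    child_deme <- c(child_deme, rep(d, N))
  }
  G_new <- mendelian_gametes(state$G[p1, , drop = FALSE]) +
    mendelian_gametes(state$G[p2, , drop = FALSE])
  if (cfg$mutation_rate > 0) {
    flips <- matrix(stats::rbinom(length(G_new), 2 - abs(G_new - 1),
                                  cfg$mutation_rate) -
                      stats::rbinom(length(G_new), abs(G_new - 1) + G_new %/% 2,
                                    cfg$mutation_rate),
                    nrow(G_new), ncol(G_new))
    G_new <- pmin(2, pmax(0, G_new + flips))
  }
  state$G <- G_new
  state$deme <- child_deme
  state$generation <- state$generation + 1L
  state
}

# Fast neutral-marker Fst from current deme allele frequencies
# (Weir-Cockerham on the full census of every deme).
state_fst <- function(state, cfg) {
  # counts-based fast path: the simulator has no missing genotypes
  G <- state$G[, -state$qtl_cols, drop = FALSE]
  deme <- match(state$deme, state$active_demes)
  counts <- rowsum(G, deme)
  het <- rowsum((G == 1) + 0, deme)
  n_d <- as.numeric(table(deme))
  n_il <- matrix(n_d, length(n_d), ncol(G))
  wc_theta_core(n_il, counts / (2 * n_il), het / n_il)
}

# Split a deme into `into` new demes, each founded by resampling N
# individuals with replacement from the parent deme.
split_deme <- function(state, parent, into, cfg) {
  idx <- which(state$deme == parent)
  N <- cfg$deme_size
  rows <- lapply(into, function(d) sample(idx, N, replace = TRUE))
  keep <- state$deme != parent
  state$G <- rbind(state$G[keep, , drop = FALSE],
                   state$G[unlist(rows), , drop = FALSE])
  state$deme <- c(state$deme[keep], rep(into, each = N))
  state$active_demes <- sort(c(setdiff(state$active_demes, parent), into))
  state
}

#' Run a full metapopulation scenario
#'
#' Initializes the metapopulation and advances Wright-Fisher generations
#' until the neutral-marker Fst reaches `cfg$fst_target` (checked every
#' `check_every` generations) or, when `cfg$generations` is set, for that
#' fixed number of generations. For the hierarchical 1-3-9 structure the
#' root pool splits into three demes at initialization and each of the
#' three splits into three further demes when Fst first exceeds half the
#' target, giving the nested two-level divergence pattern.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the run is fully reproducible given the seed.
#' @param check_every generations between Fst checks (default 2).
#' @return the final `metapop_state` with an `fst_history` attribute
#'   (generation, fst) of all checkpoints.
#' @export
run_scenario <- function(cfg, seed = NULL, check_every = 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- init_metapop(cfg)
  hist <- data.frame(generation = integer(0), fst = numeric(0))
  split2_done <- cfg$structure != "hierarchical_139"
  if (!is.null(cfg$generations)) {
    for (i in seq_len(cfg$generations)) {
      state <- step_generation(state, cfg)
      if (!split2_done && state$generation >= ceiling(cfg$generations / 2)) {
        for (p in 3:1) state <- split_deme(state, p, p * 3 - (2:0), cfg)
        split2_done <- TRUE
      }
    }
    attr(state, "fst_history") <- hist
    return(state)
  }
  repeat {
    for (i in seq_len(check_every)) state <- step_generation(state, cfg)
    fst <- state_fst(state, cfg)
    hist <- rbind(hist, data.frame(generation = state$generation, fst = fst))
    if (!split2_done && fst >= cfg$fst_target / 2) {
      for (p in 3:1) state <- split_deme(state, p, p * 3 - (2:0), cfg)
      split2_done <- TRUE
    }
    if (split2_done && fst >= cfg$fst_target) break
    if (state$generation >= cfg$max_generations) {
      stop("Fst target ", cfg$fst_target, " not reached within ",
           cfg$max_generations, " generations (last Fst = ",
           round(fst, 4), ")")
    }
  }
  attr(state, "fst_history") <- hist
  state
}

#' Common-garden North Carolina II breeding design
#'
#' Samples sires and dams from every deme of the final generation, performs
#' the full factorial cross (each sire with each dam) with a fixed number of
#' offspring per cross, and phenotypes the offspring in a common garden:
#' phenotype = breeding value + independent environmental noise, with no
#' selection. With the default 5 x 5 design and 2 offspring per cross this
#' yields 25 families and 50 phenotyped offspring per deme.
#'
#' @param state final `metapop_state` from [run_scenario()].
#' @param cfg the matching [sim_config()].
#' @param seed optional integer seed for the sampling, crossing and
#'   phenotyping step.
#' @return object of class `common_garden_data`: parental and F1 neutral
#'   genotypes ([genotype_matrix()]), F1 pedigree (`id`, `sire`, `dam`,
#'   `pop`), F1 phenotype table (`id`, `pop`, `z`), and a `truth` list
#'   (allele effect, parental and F1 breeding values) for oracle checks.
#' @export
common_garden <- function(state, cfg, seed = NULL) {
  stopifnot(inherits(state, "metapop_state"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_par <- cfg$n_sires + cfg$n_dams
  demes <- state$active_demes
  sizes <- table(factor(state$deme, levels = demes))
  if (any(sizes < n_par)) {
    stop("every deme needs at least ", n_par, " individuals to sample parents")
  }
  bv_all <- breeding_values(state, cfg)
  par_rows <- integer(0); par_ids <- character(0); par_pop <- character(0)
  ped <- list(); f1_rows_p1 <- integer(0); f1_rows_p2 <- integer(0)
  f1_ids <- character(0); f1_pop <- character(0)
  for (d in demes) {
    lab <- paste0("pop", d)
    idx <- sample(which(state$deme == d), n_par)
    sires <- idx[seq_len(cfg$n_sires)]
    dams <- idx[cfg$n_sires + seq_len(cfg$n_dams)]
    sire_ids <- paste0(lab, "_S", seq_len(cfg$n_sires))
    dam_ids <- paste0(lab, "_D", seq_len(cfg$n_dams))
    par_rows <- c(par_rows, sires, dams)
    par_ids <- c(par_ids, sire_ids, dam_ids)
    par_pop <- c(par_pop, rep(lab, n_par))
    cross <- expand.grid(s = seq_len(cfg$n_sires), dd = seq_len(cfg$n_dams))
    for (ci in seq_len(nrow(cross))) {
      for (o in seq_len(cfg$n_offspring_per_cross)) {
        f1_rows_p1 <- c(f1_rows_p1, sires[cross$s[ci]])
        f1_rows_p2 <- c(f1_rows_p2, dams[cross$dd[ci]])
        f1_ids <- c(f1_ids, paste0(lab, "_F", cross$s[ci], ".",
                                   cross$dd[ci], ".", o))
        f1_pop <- c(f1_pop, lab)
        ped[[length(ped) + 1L]] <- data.frame(
          id = f1_ids[length(f1_ids)],
          sire = sire_ids[cross$s[ci]], dam = dam_ids[cross$dd[ci]],
          pop = lab, stringsAsFactors = FALSE)
      }
    }
  }
  F1 <- mendelian_gametes(state$G[f1_rows_p1, , drop = FALSE]) +
    mendelian_gametes(state$G[f1_rows_p2, , drop = FALSE])
  qtl <- state$qtl_cols
  f1_bv <- cfg$allele_effect * (rowSums(F1[, qtl, drop = FALSE]) - cfg$n_qtl)
  z <- f1_bv + stats::rnorm(length(f1_bv), 0, sqrt(cfg$env_variance))
  pedigree <- do.call(rbind, ped)
  founders <- data.frame(id = par_ids, sire = NA_character_,
                         dam = NA_character_, pop = par_pop,
                         stringsAsFactors = FALSE)
  structure(list(
    parents_neutral = genotype_matrix(
      state$G[par_rows, -qtl, drop = FALSE], pop = par_pop, ids = par_ids),
    f1_neutral = genotype_matrix(F1[, -qtl, drop = FALSE],
                                 pop = f1_pop, ids = f1_ids),
    pedigree = rbind(founders, pedigree),
    phenotypes = data.frame(id = f1_ids, pop = f1_pop, z = z,
                            stringsAsFactors = FALSE),
    truth = list(allele_effect = cfg$allele_effect,
                 parent_bv = bv_all[par_rows], f1_bv = f1_bv)),
    class = "common_garden_data")
}

#' @export
print.common_garden_data <- function(x, ...) {
  cat("common_garden_data:", nrow(x$phenotypes), "phenotyped F1 from",
      nlevels(x$f1_neutral$pop), "demes;",
      ncol(x$parents_neutral$dosages), "neutral markers\n")
  invisible(x)
}
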