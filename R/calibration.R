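#' Built-in simulation scenarios
#'
#' Registry of the verification scenarios (island, 1-D stepping stones and
#' the hierarchical 1-3-9 structure, neutral and under divergent stabilizing
#' selection) with their published parameters: deme counts and sizes,
#' migration rates, fitness-peak widths and neutral-marker Fst anchors.
#' Scenario definitions are shipped as YAML under
#' `system.file("extdata", "scenarios", package = "logav")`.
#'
#' @param name scenario name; call with no arguments to list all names.
#' @return a [sim_config()] (or a character vector of names).
#' @export
logav_scenario <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "logav")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  names(files) <- sub("\\.yaml$", "", basename(files))
  if (is.null(name)) return(sort(names(files)))
  if (!name %in% names(files)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(sort(names(files)), collapse = ", "))
  }
  y <- yaml::read_yaml(files[[name]])
  do.call(sim_config, y)
}

#' Replicated calibration runs of a test under neutrality
#'
#' Runs `n_reps` independent seeded replicates of the full pipeline —
#' simulate a metapopulation, sample the common garden, estimate
#' coancestries, fit, test — for either the LogAV test or the Qst-Fst
#' parametric bootstrap, and aggregates the p-values into a calibration
#' report: false positive rate at `alpha`, an exact binomial test of the
#' FPR against `alpha`, and a Kolmogorov-Smirnov statistic against the
#' uniform distribution.
#'
#' Replicate seeds are derived deterministically from `master_seed`, so a
#' report is fully reproducible. Replicates whose model fit errors or
#' clearly diverges (split R-hat above 1.2) are recorded and excluded,
#' never silently dropped; the report is flagged invalid when more than 5%
#' are excluded. Fits with R-hat between 1.05 and 1.2 keep their per-fit
#' warning flag but are retained, since short-chain R-hat noise must not
#' censor the replicate set.
#'
#' @param cfg a [sim_config()] (use a neutral one for calibration).
#' @param method `"logav"` or `"qstfst"`.
#' @param n_reps number of replicates (>= 50 for a reported FPR).
#' @param master_seed integer master seed.
#' @param alpha significance threshold.
#' @param mcmc [mcmc_control()] used per replicate (LogAV only).
#' @param n_boot bootstrap draws per replicate (Qst-Fst only).
#' @param datasets optional list of pre-simulated [common_garden()]
#'   datasets to analyze instead of simulating (its length overrides
#'   `n_reps`); used to compare methods on identical data.
#' @return object of class `calibration_report`.
#' @export
run_replicates <- function(cfg, method = c("logav", "qstfst"), n_reps = 100,
                           master_seed = 1, alpha = 0.05,
                           mcmc = mcmc_control(chains = 2, warmup = 400,
                                               iter = 800),
                           n_boot = 2000, datasets = NULL) {
  method <- match.arg(method)
  if (is.null(datasets) && n_reps < 50) {
    stop("at least 50 replicates are required for a reported FPR")
  }
  if (!is.null(datasets)) n_reps <- length(datasets)
  seeds <- derive_seeds(master_seed, n_reps)
  p_values <- rep(NA_real_, n_reps)
  logratios <- rep(NA_real_, n_reps)
  failures <- character(0)
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      data <- if (is.null(datasets)) {
        simulate_garden(cfg, seeds[i])
      } else {
        datasets[[i]]
      }
      if (method == "logav") {
        mc <- mcmc
        mc$seed <- seeds[i]
        out <- suppressWarnings(logav_pipeline(data, mcmc = mc,
                                               alpha = alpha))
        rh <- suppressWarnings(max(out$posterior$diagnostics$rhat,
                                   na.rm = TRUE))
        # drop only clearly diverged fits; R-hat in (1.05, 1.2] keeps the
        # per-fit warning flag but the replicate is retained (short-chain
        # R-hat noise must not censor the replicate set)
        list(p = out$p_value, lr = out$logav_mean,
             ok = !is.finite(rh) || rh <= 1.2)
      } else {
        out <- qstfst_pipeline(data, n_boot = n_boot, seed = seeds[i])
        list(p = out$p_value, lr = NA_real_, ok = TRUE)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("rep ", i, ": ", conditionMessage(res)))
    } else if (!res$ok) {
      failures <- c(failures, paste0("rep ", i, ": not converged"))
    } else {
      p_values[i] <- res$p
      logratios[i] <- res$lr
    }
  }
  used <- !is.na(p_values)
  fpr <- mean(p_values[used] < alpha)
  bt <- stats::binom.test(sum(p_values[used] < alpha), sum(used), p = alpha)
  ks <- suppressWarnings(stats::ks.test(p_values[used], "punif"))
  structure(list(
    scenario = cfg, method = method, alpha = alpha,
    p_values = p_values, logratios = logratios, seeds = seeds,
    fpr = fpr, n_used = sum(used),
    binom_p = bt$p.value, binom_conf = as.numeric(bt$conf.int),
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    failures = failures,
    valid = length(failures) <= 0.05 * n_reps), class = "calibration_report")
}

# simulate + common garden with one seed (single RNG stream)
simulate_garden <- function(cfg, seed) {
  state <- run_scenario(cfg, seed = seed)
  common_garden(state, cfg)
}

#' Power study under a selection scenario
#'
#' Same machinery as [run_replicates()] with a selection configuration:
#' reports power (the fraction of replicates with p below `alpha`) and
#' retains the per-replicate mean log-ratios.
#'
#' @inheritParams run_replicates
#' @return a `calibration_report` whose `fpr` slot holds the power.
#' @export
run_power <- function(cfg, n_reps = 20, master_seed = 1, alpha = 0.05,
                      mcmc = mcmc_control(chains = 2, warmup = 400,
                                          iter = 800)) {
  if (cfg$selection != "stabilizing") {
    stop("`run_power` expects a selection scenario")
  }
  rep_floor <- 10
  if (n_reps < rep_floor) stop("need at least ", rep_floor, " replicates")
  out <- run_replicates(cfg, method = "logav",
                        n_reps = max(n_reps, 50), master_seed = master_seed,
                        alpha = alpha, mcmc = mcmc,
                        datasets = replicate_datasets(cfg, n_reps, master_seed))
  out$power <- out$fpr
  out
}

# pre-simulate n datasets with derived seeds (shared helper so power runs
# can use fewer than 50 replicates while run_replicates keeps its floor)
#' Simulate a batch of independent common-garden datasets
#'
#' @param cfg a [sim_config()].
#' @param n number of datasets.
#' @param master_seed integer; per-dataset seeds are derived from it.
#' @return list of [common_garden()] datasets.
#' @export
replicate_datasets <- function(cfg, n, master_seed = 1) {
  seeds <- derive_seeds(master_seed, n)
  lapply(seeds, function(s) simulate_garden(cfg, s))
}

#' @export
print.calibration_report <- function(x, ...) {
  lab <- if (!is.null(x$power)) "power" else "FPR"
  cat("calibration_report [", x$method, "]: ", lab, " at alpha = ",
      x$alpha, ": ", format(x$fpr, digits = 3),
      " (", sum(x$p_values < x$alpha, na.rm = TRUE), "/", x$n_used, ")\n",
      "binomial test vs alpha: p = ", format(x$binom_p, digits = 3),
      "; KS vs uniform: p = ", format(x$ks_p, digits = 3), "\n", sep = "")
  if (length(x$failures)) {
    cat(length(x$failures), "replicate(s) excluded",
        if (!x$valid) "- REPORT INVALID (>5% excluded)", "\n")
  }
  invisible(x)
}
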