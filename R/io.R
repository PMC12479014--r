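#' Read genotypes from VCF or dosage CSV
#'
#' VCF input keeps biallelic SNPs only (multiallelic sites are skipped with
#' a message) and codes each genotype as the count of the ALT allele; allele
#' sharing is polarity-invariant, so this convention does not affect any
#' coancestry estimate. CSV input expects a header row of locus names, one
#' row per individual with the individual id in the first column, and
#' dosage values 0/1/2 or empty/NA.
#'
#' @param path file path.
#' @param popmap path to a two-column tab-separated file (individual id,
#'   subpopulation label), or a data frame with those two columns. Order of
#'   first appearance fixes the subpopulation order. When `NULL`, all
#'   individuals get the label `"pop1"`.
#' @param format `"auto"` (by extension), `"vcf"` or `"csv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, popmap = NULL, format = c("auto", "vcf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    biallelic <- vcfR::is.biallelic(v)
    if (any(!biallelic)) {
      message("skipping ", sum(!biallelic), " multiallelic site(s)")
      v <- v[biallelic, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(x, "[/|]"), function(a) {
               a <- suppressWarnings(as.numeric(a))
               if (anyNA(a)) NA_real_ else sum(a > 0)
             }, numeric(1)))
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1, dimnames = list(NULL, colnames(gt)))
    dos <- t(dos)
    colnames(dos) <- rownames(gt)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    dos <- as.matrix(tab)
  }
  if (any(rowSums(!is.na(dos)) == 0)) {
    stop("individual(s) with all genotypes missing: ",
         paste(rownames(dos)[rowSums(!is.na(dos)) == 0], collapse = ", "))
  }
  ids <- rownames(dos)
  if (is.null(popmap)) {
    pop <- rep("pop1", nrow(dos))
  } else {
    pm <- if (is.data.frame(popmap)) popmap else read_popmap(popmap)
    pop <- pm[[2]][match(ids, pm[[1]])]
    if (anyNA(pop)) {
      stop("individual(s) missing from popmap: ",
           paste(ids[is.na(pop)], collapse = ", "))
    }
    pop <- factor(pop, levels = unique(pm[[2]]))
  }
  genotype_matrix(dos, pop = pop, ids = ids)
}

#' Read a two-column popmap (individual id, subpopulation label)
#' @param path tab-separated file, no header required.
#' @return data frame with columns `id`, `pop`.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("id", "pop"),
                          colClasses = "character")
  if (ncol(pm) < 2) stop("popmap needs two tab-separated columns")
  pm
}

#' Read a pedigree CSV (id, sire, dam, pop)
#' @param path CSV path; empty/NA parents mark founders.
#' @return data frame with character columns `id`, `sire`, `dam`, `pop`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, colClasses = "character")
  need <- c("id", "sire", "dam", "pop")
  if (!all(need %in% names(ped))) stop("pedigree CSV needs columns id, sire, dam, pop")
  for (cc in c("sire", "dam")) ped[[cc]][ped[[cc]] %in% c("", "0", "NA")] <- NA
  ped[need]
}

#' Read a phenotype table (id, pop, z)
#' @param path tab- or comma-separated file with a header.
#' @return data frame with columns `id`, `pop`, `z`.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ph <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("id", "pop", "z") %in% names(ph))) {
    stop("phenotype table needs columns id, pop, z")
  }
  ph$z <- as.numeric(ph$z)
  ph
}

#' Write genotypes as a dosage CSV
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_csv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  utils::write.csv(g$dosages, path, na = "")
  invisible(path)
}

#' Write genotypes as an uncompressed VCF
#'
#' Minimal VCF 4.2 with GT fields reconstructed from dosages (0/0, 0/1,
#' 1/1, ./.). Loci become synthetic SNPs `snp_1 ...` on contig `sim`.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  gt <- matrix(c("0/0", "0/1", "1/1")[G + 1], nrow(G), ncol(G))
  gt[is.na(G)] <- "./."
  L <- ncol(G)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=sim>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$ids), collapse = "\t"))
  body <- vapply(seq_len(L), function(l) {
    paste(c("sim", l, paste0("snp_", l), "A", "T", ".", ".", ".", "GT",
            gt[, l]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a popmap TSV for a genotype matrix
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(g, path) {
  utils::write.table(data.frame(g$ids, as.character(g$pop)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a labelled matrix as TSV with a JSON sidecar
#'
#' @param x matrix (or `pop_coancestry` / `within_relatedness`).
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, meta = list()) {
  if (inherits(x, "pop_coancestry")) {
    meta <- c(meta, list(reference_value = x$reference_value,
                         labels = x$labels, kind = "pop_coancestry"))
    x <- x$theta_p
  } else if (inherits(x, "within_relatedness")) {
    meta <- c(meta, list(labels = levels(x$pop), kind = "within_relatedness"))
    x <- x$m
  }
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE)
  meta$tool <- paste0("logav ", as.character(utils::packageVersion("logav")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `coancestry`, `fit`, `test`,
#' `calibrate` and `full` over the package functions; see
#' `inst/exec/logav` for the installed launcher. Errors return exit code 1,
#' usage problems exit code 2.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: logav <simulate|coancestry|fit|test|calibrate|full> [options]",
    "  simulate  --scenario NAME --seed S --out DIR [--rescale K]",
    "  coancestry --geno-p FILE --popmap FILE [--geno-f1 FILE] --out DIR",
    "  full      --scenario NAME --seed S --out DIR [--rescale K]",
    "             [--chains N --iter N --warmup N --alpha A]",
    "  calibrate --scenario NAME --method logav|qstfst --reps N --seed S --out DIR",
    sep = "\n")
  if (!length(argv) || argv[1] %in% c("-h", "--help")) {
    message(usage); return(invisible(2L))
  }
  cmd <- argv[1]
  opts <- parse_cli_options(argv[-1])
  if (inherits(opts, "error")) {
    message("error: ", conditionMessage(opts), "\n", usage)
    return(invisible(2L))
  }
  res <- tryCatch(switch(
    cmd,
    simulate = cli_simulate(opts),
    coancestry = cli_coancestry(opts),
    full = cli_full(opts),
    calibrate = cli_calibrate(opts),
    {
      message("unknown subcommand '", cmd, "'\n", usage)
      return(invisible(2L))
    }), error = function(e) e)
  if (inherits(res, "logav_usage_error")) {
    message("error: ", conditionMessage(res), "\n", usage)
    return(invisible(2L))
  }
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(1L))
  }
  invisible(0L)
}

parse_cli_options <- function(args) {
  tryCatch({
    opts <- list()
    i <- 1
    while (i <= length(args)) {
      key <- args[i]
      if (!startsWith(key, "--")) stop("unexpected argument '", key, "'")
      if (i + 1 > length(args)) stop("missing value for ", key)
      opts[[sub("^--", "", key)]] <- args[i + 1]
      i <- i + 2
    }
    opts
  }, error = function(e) e)
}

cli_need <- function(opts, keys) {
  missing <- setdiff(keys, names(opts))
  if (length(missing)) {
    stop(errorCondition(
      paste0("missing required option(s): ",
             paste0("--", missing, collapse = ", ")),
      class = "logav_usage_error"))
  }
}

cli_cfg <- function(opts) {
  cfg <- logav_scenario(opts$scenario)
  if (!is.null(opts$rescale)) cfg <- rescale_config(cfg, as.numeric(opts$rescale))
  cfg
}

cli_simulate <- function(opts) {
  cli_need(opts, c("scenario", "seed", "out"))
  cfg <- cli_cfg(opts)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  data <- simulate_garden(cfg, as.integer(opts$seed))
  write_vcf(data$parents_neutral, file.path(opts$out, "parents.vcf"))
  write_popmap(data$parents_neutral, file.path(opts$out, "popmap.tsv"))
  write_vcf(data$f1_neutral, file.path(opts$out, "f1.vcf"))
  utils::write.csv(data$pedigree, file.path(opts$out, "pedigree.csv"),
                   row.names = FALSE, na = "")
  utils::write.table(data$phenotypes, file.path(opts$out, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(scenario = opts$scenario,
                            seed = as.integer(opts$seed),
                            allele_effect = data$truth$allele_effect),
                       file.path(opts$out, "truth.json"), auto_unbox = TRUE)
  invisible(0L)
}

cli_coancestry <- function(opts) {
  cli_need(opts, c("geno-p", "popmap", "out"))
  g <- read_genotypes(opts[["geno-p"]], popmap = opts$popmap)
  theta <- estimate_theta_p(population_allele_sharing(g))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(theta, file.path(opts$out, "theta_p.tsv"))
  if (!is.null(opts[["geno-f1"]])) {
    f1 <- read_genotypes(opts[["geno-f1"]], popmap = opts[["popmap-f1"]] %||% opts$popmap)
    kin <- lapply(stats::setNames(theta$labels, theta$labels), function(x) {
      estimate_kinship_within(subset_individuals(f1, which(f1$pop == x)))
    })
    write_matrix_tsv(build_m(kin, theta), file.path(opts$out, "m.tsv"))
  }
  invisible(0L)
}

cli_full <- function(opts) {
  cli_need(opts, c("scenario", "seed", "out"))
  cfg <- cli_cfg(opts)
  seed <- as.integer(opts$seed)
  data <- simulate_garden(cfg, seed)
  mc <- mcmc_control(chains = as.integer(opts$chains %||% 2),
                     warmup = as.integer(opts$warmup %||% 400),
                     iter = as.integer(opts$iter %||% 800),
                     seed = seed)
  res <- logav_pipeline(data, mcmc = mc,
                        alpha = as.numeric(opts$alpha %||% 0.05))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    logav_mean = res$logav_mean, p_value = res$p_value,
    direction = res$direction, significant = res$significant,
    quantiles = as.list(res$quantiles), seed = seed,
    scenario = opts$scenario, converged = res$converged),
    file.path(opts$out, "result.json"), auto_unbox = TRUE, digits = NA)
  invisible(0L)
}

cli_calibrate <- function(opts) {
  cli_need(opts, c("scenario", "method", "reps", "seed", "out"))
  cfg <- cli_cfg(opts)
  rep_out <- run_replicates(cfg, method = opts$method,
                            n_reps = as.integer(opts$reps),
                            master_seed = as.integer(opts$seed))
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(
    method = opts$method, scenario = opts$scenario,
    fpr = rep_out$fpr, binom_p = rep_out$binom_p, ks_p = rep_out$ks_p,
    n_used = rep_out$n_used, failures = rep_out$failures),
    file.path(opts$out, "report.json"), auto_unbox = TRUE)
  utils::write.table(data.frame(seed = rep_out$seeds, p = rep_out$p_values,
                                logratio = rep_out$logratios),
                     file.path(opts$out, "p_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(0L)
}
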