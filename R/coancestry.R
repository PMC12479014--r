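#' Allele sharing between two individuals
#'
#' Per-locus allele sharing for diploid biallelic genotypes: 1 when both
#' individuals are homozygous for the same allele, 0 when homozygous for
#' opposite alleles, and 1/2 when at least one of the two is heterozygous.
#' The returned value is the mean over loci where both genotypes are
#' observed.
#'
#' @param geno_i,geno_j dosage vectors (0/1/2/`NA`) of the same length.
#' @return mean allele sharing in `[0, 1]`.
#' @examples
#' allele_sharing_pair(c(2, 2), c(2, 0))  # (1 + 0) / 2
#' @export
allele_sharing_pair <- function(geno_i, geno_j) {
  if (length(geno_i) != length(geno_j)) {
    stop("genotype vectors must have the same length")
  }
  use <- !is.na(geno_i) & !is.na(geno_j)
  if (!any(use)) stop("no locus observed in both individuals; allele sharing is undefined")
  # |d| in {0,1,2}: 2 = opposite homozygotes, 1 = exactly one heterozygote,
  # 0 = same genotype; score = 1 - |d|/2 except het/het which also scores 1/2
  gi <- geno_i[use]; gj <- geno_j[use]
  score <- 1 - abs(gi - gj) / 2
  score[gi == 1 & gj == 1] <- 0.5
  mean(score)
}

#' Pairwise allele-sharing matrix
#'
#' Computes the full symmetric matrix of pairwise mean allele sharing using
#' pairwise-complete loci (each pair is averaged over the loci observed in
#' both of its members). Diagonal entries are self-sharing, `1 - h_i / 2`
#' where `h_i` is the individual's observed heterozygosity; they are used for
#' the diagonal of kinship matrices, never for between-individual statistics.
#'
#' @param g a [genotype_matrix()] or a bare dosage matrix.
#' @return a list of class `allele_sharing` with `values` (n x n symmetric
#'   matrix) and `n_loci_used` (per-pair count of jointly observed loci).
#' @export
allele_sharing_matrix <- function(g) {
  G <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  n <- nrow(G)
  W <- !is.na(G)
  storage.mode(W) <- "double"
  H0 <- (G == 0) & W; H1 <- (G == 1) & W; H2 <- (G == 2) & W
  H0[is.na(H0)] <- FALSE; H1[is.na(H1)] <- FALSE; H2[is.na(H2)] <- FALSE
  storage.mode(H0) <- "double"; storage.mode(H1) <- "double"
  storage.mode(H2) <- "double"
  n_joint <- W %*% t(W)
  # summed |dosage difference| over jointly observed loci; a heterozygote
  # paired with anything contributes exactly 1 (score 1/2), which the
  # |difference| decomposition reproduces once het/het (difference 0) is
  # counted through the H1 (1 - H1) cross terms
  opp_hom <- H2 %*% t(H0)
  one_het <- H1 %*% t(H0 + H2)
  het_het <- H1 %*% t(H1)
  d_sum <- 2 * (opp_hom + t(opp_hom)) + (one_het + t(one_het)) + het_het
  diag(d_sum) <- rowSums(H1)  # self-sharing: each het locus scores 1/2
  if (any(n_joint == 0)) {
    warning("some pairs share no observed locus; their allele sharing is NA")
  }
  A <- 1 - d_sum / (2 * n_joint)
  A[n_joint == 0] <- NA_real_
  A <- (A + t(A)) / 2
  ids <- if (inherits(g, "genotype_matrix")) g$ids else rownames(G)
  dimnames(A) <- dimnames(n_joint) <- list(ids, ids)
  structure(list(values = A, n_loci_used = n_joint), class = "allele_sharing")
}

#' Population-level mean allele sharing
#'
#' Averages pairwise allele sharing over all distinct pairs of individuals
#' for every ordered pair of subpopulations: entry (x, y) with x != y is the
#' mean over pairs with one member in each, and entry (x, x) is the mean over
#' distinct pairs within x (self-pairs excluded).
#'
#' @param g a [genotype_matrix()] with at least 2 subpopulations, each of
#'   size at least 2.
#' @return symmetric r x r matrix with subpopulation labels as dimnames.
#' @export
population_allele_sharing <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  r <- nlevels(g$pop)
  if (r < 2) stop("at least 2 subpopulations are required")
  sizes <- table(g$pop)
  if (any(sizes < 2)) {
    stop("every subpopulation needs >= 2 individuals; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  A <- allele_sharing_matrix(g)$values
  pops <- levels(g$pop)
  Z <- outer(g$pop, pops, "==")
  storage.mode(Z) <- "double"
  pair_sum <- t(Z) %*% A %*% Z
  n_x <- as.numeric(sizes[pops])
  pair_n <- outer(n_x, n_x)
  # within-population entries: drop self-pairs from both sum and count
  diag(pair_sum) <- diag(pair_sum) - diag(t(Z) %*% diag(diag(A)) %*% Z)
  diag(pair_n) <- n_x * (n_x - 1)
  abar <- pair_sum / pair_n
  abar <- (abar + t(abar)) / 2
  dimnames(abar) <- list(pops, pops)
  abar
}

#' Estimate the population coancestry matrix
#'
#' Rescales the population-level mean allele-sharing matrix so that the least
#' related pair of subpopulations — the best available proxy for the
#' ancestral population — has coancestry exactly 0:
#' `theta_p = (abar - min) / (1 - min)`, with the minimum taken over
#' off-diagonal entries only.
#'
#' @param abar symmetric r x r matrix of mean allele sharing, e.g. from
#'   [population_allele_sharing()].
#' @param labels subpopulation labels; default taken from `dimnames(abar)`.
#' @return an object of class `pop_coancestry` with elements `theta_p`
#'   (r x r matrix), `reference_value` (the minimum off-diagonal allele
#'   sharing used as the ancestral reference) and `labels`.
#' @export
estimate_theta_p <- function(abar, labels = NULL) {
  abar <- as.matrix(abar)
  r <- nrow(abar)
  if (r < 2 || ncol(abar) != r) stop("`abar` must be a square matrix, r >= 2")
  if (max(abs(abar - t(abar))) > 1e-8) stop("`abar` must be symmetric")
  if (any(abar < -1e-12 | abar > 1 + 1e-12, na.rm = TRUE)) {
    stop("allele-sharing entries must lie in [0, 1]")
  }
  off <- abar[upper.tri(abar)]
  amin <- min(off)
  if (1 - amin < 1e-12) {
    stop("minimum off-diagonal allele sharing is 1: subpopulations are ",
         "undifferentiated and no ancestral reference exists")
  }
  theta <- (abar - amin) / (1 - amin)
  if (is.null(labels)) labels <- rownames(abar)
  if (is.null(labels)) labels <- paste0("pop_", seq_len(r))
  dimnames(theta) <- list(labels, labels)
  structure(list(theta_p = theta, reference_value = amin, labels = labels),
            class = "pop_coancestry")
}

#' @export
print.pop_coancestry <- function(x, ...) {
  cat("pop_coancestry:", nrow(x$theta_p), "subpopulations;",
      "ancestral reference allele sharing =",
      format(x$reference_value, digits = 4), "\n")
  print(round(x$theta_p, 4))
  invisible(x)
}

#' Within-subpopulation kinship from allele sharing
#'
#' Moment estimator of kinship among individuals of one subpopulation:
#' `k_ij = (A_ij - Abar) / (1 - Abar)` where `Abar` is the mean allele
#' sharing over distinct pairs used as the reference. By construction the
#' mean off-diagonal kinship is 0. The diagonal uses self-sharing, so
#' `2 * k_ii` estimates the usual self-relatedness `1 + F_i`.
#'
#' @param g_x a [genotype_matrix()] (or dosage matrix) holding the
#'   individuals of one subpopulation.
#' @param reference_ids optional subset of ids (or row indices) over whose
#'   distinct pairs `Abar` is computed; defaults to all individuals in
#'   `g_x`. This supports using parents plus offspring for the reference
#'   while reporting kinship among a subset.
#' @return symmetric kinship matrix with attribute `abar` (the reference
#'   mean allele sharing).
#' @export
estimate_kinship_within <- function(g_x, reference_ids = NULL) {
  A <- allele_sharing_matrix(g_x)
  V <- A$values
  n <- nrow(V)
  if (n < 2) stop("kinship needs >= 2 individuals")
  if (is.null(reference_ids)) {
    ref <- seq_len(n)
  } else if (is.character(reference_ids)) {
    ref <- match(reference_ids, rownames(V))
    if (anyNA(ref)) stop("unknown reference ids")
  } else {
    ref <- reference_ids
  }
  Vr <- V[ref, ref, drop = FALSE]
  abar <- mean(Vr[upper.tri(Vr)])
  if (1 - abar < 1e-12) {
    stop("mean allele sharing is 1: no within-population variation")
  }
  k <- (V - abar) / (1 - abar)
  attr(k, "abar") <- abar
  k
}

#' Project a symmetric matrix onto the positive semi-definite cone
#'
#' Moment estimates of coancestry and relatedness are not guaranteed
#' positive semi-definite, while the multivariate-normal random effects that
#' consume them require it. Negative eigenvalues are clipped at zero and a
#' small jitter is added to the diagonal.
#'
#' @param x symmetric matrix.
#' @param jitter value added to the diagonal after clipping (default 1e-8).
#' @return the repaired symmetric matrix.
#' @export
psd_repair <- function(x, jitter = 1e-8) {
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (min(e$values) >= 0 && jitter == 0) return(x)
  d <- pmax(e$values, 0)
  y <- e$vectors %*% (d * t(e$vectors))
  y <- (y + t(y)) / 2
  diag(y) <- diag(y) + jitter
  dimnames(y) <- dimnames(x)
  y
}

#' Build the within-population relatedness matrix M
#'
#' Assembles the block-diagonal relatedness matrix over phenotyped (F1)
#' individuals: within each subpopulation x the kinship matrix is doubled to
#' give relatedness and multiplied by `(1 - theta_x)` to discount the
#' ancestry already carried by the population coancestry matrix; all
#' cross-subpopulation entries are exactly 0. Each block is PSD-repaired.
#'
#' @param kinships named list of within-subpopulation kinship matrices (one
#'   per subpopulation, names matching `theta$labels`), e.g. from
#'   [estimate_kinship_within()].
#' @param theta a [estimate_theta_p()] result.
#' @param order optional character vector giving the subpopulation order of
#'   the phenotype table; defaults to `theta$labels`.
#' @return object of class `within_relatedness`: list with the full matrix
#'   `m`, the per-population `blocks`, the individual `ids` and the `pop`
#'   factor (individuals grouped by subpopulation in `order`).
#' @export
build_m <- function(kinships, theta, order = NULL) {
  stopifnot(inherits(theta, "pop_coancestry"))
  if (is.null(order)) order <- theta$labels
  if (!all(order %in% theta$labels)) {
    stop("`order` contains labels absent from `theta`")
  }
  missing_k <- setdiff(order, names(kinships))
  if (length(missing_k)) {
    stop("no kinship block for subpopulation(s): ",
         paste(missing_k, collapse = ", "))
  }
  theta_diag <- diag(theta$theta_p)
  names(theta_diag) <- theta$labels
  blocks <- lapply(order, function(x) {
    k <- as.matrix(kinships[[x]])
    if (nrow(k) != ncol(k)) stop("kinship block for ", x, " is not square")
    psd_repair(2 * k * (1 - theta_diag[[x]]))
  })
  names(blocks) <- order
  sizes <- vapply(blocks, nrow, integer(1))
  n <- sum(sizes)
  m <- matrix(0, n, n)
  ids <- character(n)
  at <- 0L
  for (x in order) {
    idx <- at + seq_len(sizes[[x]])
    m[idx, idx] <- blocks[[x]]
    bid <- rownames(blocks[[x]])
    ids[idx] <- if (is.null(bid)) paste0(x, "_", seq_along(idx)) else bid
    at <- at + sizes[[x]]
  }
  dimnames(m) <- list(ids, ids)
  structure(list(m = m, blocks = blocks, ids = ids,
                 pop = factor(rep(order, sizes), levels = order)),
            class = "within_relatedness")
}

#' @export
print.within_relatedness <- function(x, ...) {
  cat("within_relatedness: block-diagonal", nrow(x$m), "x", ncol(x$m),
      "matrix,", length(x$blocks), "subpopulation blocks\n")
  invisible(x)
}

#' Build M from pedigree information
#'
#' When F1 genotypes are unavailable, within-subpopulation relatedness can be
#' taken from the pedigree: the additive (numerator) relationship matrix is
#' computed per subpopulation by the tabular method, halved to kinship, and
#' then assembled exactly as in [build_m()]. Cross-population matings are not
#' supported (the model assumes no cross-population breeding).
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam`, `pop`;
#'   founders have `NA` parents. Parents must either appear as rows of the
#'   same subpopulation or be founders.
#' @param theta a [estimate_theta_p()] result.
#' @param keep optional ids to retain in the blocks (e.g. phenotyped F1
#'   only); default keeps non-founder individuals.
#' @return a `within_relatedness` object.
#' @export
build_m_from_pedigree <- function(pedigree, theta, keep = NULL) {
  stopifnot(inherits(theta, "pop_coancestry"))
  need <- c("id", "sire", "dam", "pop")
  if (!all(need %in% names(pedigree))) {
    stop("pedigree needs columns id, sire, dam, pop")
  }
  ped <- pedigree
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped$pop <- as.character(ped$pop)
  pop_of <- stats::setNames(ped$pop, ped$id)
  for (p in c("sire", "dam")) {
    known <- !is.na(ped[[p]]) & ped[[p]] %in% names(pop_of)
    bad <- known & pop_of[ped[[p]]] != ped$pop
    if (any(bad)) {
      stop("cross-population mating detected (offspring ",
           paste(ped$id[bad], collapse = ", "),
           "); the model assumes no cross-population breeding")
    }
  }
  kin <- lapply(split(ped, ped$pop), function(sub) {
    a <- additive_relationship(sub)
    if (!is.null(keep)) {
      keep_x <- intersect(keep, rownames(a))
    } else {
      keep_x <- sub$id[!(is.na(sub$sire) & is.na(sub$dam))]
      if (!length(keep_x)) keep_x <- sub$id
    }
    a[keep_x, keep_x, drop = FALSE] / 2
  })
  build_m(kin, theta, order = intersect(theta$labels, names(kin)))
}

# Additive relationship matrix by the tabular method; founders (NA parents
# or parents absent from `id`) are assumed unrelated and non-inbred.
additive_relationship <- function(ped) {
  ids <- ped$id
  sire <- ifelse(ped$sire %in% ids, ped$sire, NA)
  dam <- ifelse(ped$dam %in% ids, ped$dam, NA)
  # order parents before offspring
  ord <- character(0)
  remaining <- seq_along(ids)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(sire[i]) || sire[i] %in% ord) &&
        (is.na(dam[i]) || dam[i] %in% ord)
    }, logical(1))]
    if (!length(ready)) stop("pedigree contains a cycle")
    ord <- c(ord, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  si <- stats::setNames(sire, ids)[ord]
  da <- stats::setNames(dam, ids)[ord]
  for (i in seq_len(n)) {
    s <- si[i]; d <- da[i]
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) A[s, d] / 2 else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      a_s <- if (!is.na(s)) A[j, s] else rep(0, i - 1)
      a_d <- if (!is.na(d)) A[j, d] else rep(0, i - 1)
      A[j, i] <- A[i, j] <- (a_s + a_d) / 2
    }
  }
  A[ids, ids]
}

#' Fst from a population coancestry matrix
#'
#' Computes the fixation index implied by the population coancestry matrix:
#' `Fst = (mean(diag(theta_p)) - theta_b) / (1 - theta_b)` with `theta_b`
#' the mean off-diagonal coancestry.
#'
#' @param theta a [estimate_theta_p()] result or a bare r x r matrix.
#' @return list with `fst` and the intermediate `theta_b`.
#' @export
fst_from_theta <- function(theta) {
  tp <- if (inherits(theta, "pop_coancestry")) theta$theta_p else as.matrix(theta)
  r <- nrow(tp)
  if (r < 2) stop("at least 2 subpopulations required")
  theta_b <- mean(tp[upper.tri(tp)])
  if (1 - theta_b < 1e-12) stop("mean between-population coancestry is 1")
  list(fst = (mean(diag(tp)) - theta_b) / (1 - theta_b), theta_b = theta_b)
}

#' Multilocus Weir-Cockerham Fst
#'
#' Standard variance-components (theta) estimator of Fst from genotype
#' dosages and subpopulation labels, combined over loci as the ratio of
#' summed components. Used by the Qst-Fst baseline as its neutral-marker
#' anchor.
#'
#' @param g a [genotype_matrix()].
#' @return multilocus Fst estimate (scalar).
#' @export
fst_weir_cockerham <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  G <- g$dosages
  pop <- g$pop
  r <- nlevels(pop)
  if (r < 2) stop("at least 2 subpopulations required")
  obs <- !is.na(G)
  storage.mode(obs) <- "double"
  G0 <- G; G0[!obs] <- 0
  pop_int <- as.integer(pop)
  n_il <- rowsum(obs, pop_int)              # r x L sample sizes
  p_il <- rowsum(G0, pop_int) / (2 * n_il)  # r x L allele frequencies
  het <- (G == 1) & obs
  storage.mode(het) <- "double"
  h_il <- rowsum(het, pop_int) / n_il       # observed heterozygosity
  wc_theta_core(n_il, p_il, h_il)
}

# Weir-Cockerham theta from per-population sample sizes, allele frequencies
# and observed heterozygosities (r x L each), combined over loci as the
# ratio of summed variance components.
wc_theta_core <- function(n_il, p_il, h_il) {
  r <- nrow(n_il)
  nbar <- colMeans(n_il)
  pbar <- colSums(n_il * p_il) / (r * nbar)
  s2 <- colSums(n_il * (p_il - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_il * h_il) / (r * nbar)
  nc <- (r * nbar - colSums(n_il^2) / (r * nbar)) / (r - 1)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- is.finite(a) & is.finite(b) & is.finite(cc)
  denom <- sum(a[keep] + b[keep] + cc[keep])
  if (denom <= 0) return(0)
  sum(a[keep]) / denom
}
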