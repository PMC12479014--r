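#' Genotype matrix with subpopulation labels
#'
#' Container for biallelic diploid genotypes stored as ALT-allele dosages
#' (0, 1, 2, or `NA` for missing), together with one subpopulation label per
#' individual. All coancestry estimators in the package operate on this
#' object. Allele sharing is invariant to which allele is counted, so the
#' REF/ALT polarity of the dosage convention does not affect any estimate.
#'
#' @param dosages numeric or integer matrix, individuals in rows and loci in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param pop character or factor vector of subpopulation labels, one per
#'   individual. Factor level order fixes the subpopulation order used by all
#'   derived matrices.
#' @param ids individual identifiers; defaults to the rownames of `dosages`
#'   or `ind_1 ... ind_n`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `pop` (factor) and `ids`.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 2), c(1, 2), c(2, 0)),
#'                      pop = c("A", "A", "B"))
#' n_pops(g)
#' @export
genotype_matrix <- function(dosages, pop, ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) {
    stop("dosages must be 0, 1, 2 or NA; found other values")
  }
  n <- nrow(dosages)
  if (length(pop) != n) {
    stop("`pop` must have one label per individual (", n, " rows)")
  }
  if (is.null(ids)) {
    ids <- rownames(dosages)
    if (is.null(ids)) ids <- paste0("ind_", seq_len(n))
  }
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(pop))
  pop <- droplevels(pop)
  if (anyNA(pop)) stop("every individual needs a subpopulation label")
  rownames(dosages) <- ids
  structure(list(dosages = dosages, pop = pop, ids = ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "loci,", nlevels(x$pop), "subpopulation(s)\n")
  invisible(x)
}

#' Number of subpopulations in a genotype matrix
#' @param g a [genotype_matrix()]
#' @return integer count of distinct subpopulation labels
#' @export
n_pops <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nlevels(g$pop)
}

#' Subset a genotype matrix by individuals
#' @param g a [genotype_matrix()]
#' @param keep logical, integer or character index of individuals to keep
#' @return a [genotype_matrix()] restricted to the selected individuals
#' @export
subset_individuals <- function(g, keep) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.character(keep)) keep <- match(keep, g$ids)
  genotype_matrix(g$dosages[keep, , drop = FALSE],
                  pop = as.character(g$pop)[keep],
                  ids = g$ids[keep])
}
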