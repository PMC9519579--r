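#' Assemble a multi-context expression study
#'
#' The central container of the package: per-gene expression measured on a
#' common pool of individuals across contexts, with the matching per-gene cis
#' genotype matrices. Individuals need not be observed in every context;
#' unobserved entries are `NA`.
#'
#' @param expr named list (one element per gene) of individuals x contexts
#'   matrices; `NA` marks an unobserved individual-context pair. All genes
#'   must share row (individual) and column (context) names.
#' @param geno named list (same gene names) of individuals x SNPs dosage
#'   matrices in 0/1/2, rows aligned with `expr`.
#' @param covariates optional named list (one element per context) of
#'   individuals x covariates matrices/data.frames, rownames = individual ids.
#' @param groups optional named character vector mapping every context to a
#'   context group (e.g. brain vs non-brain tissues).
#' @return an object of class `content_study`.
#' @export
content_study <- function(expr, geno, covariates = NULL, groups = NULL) {
  stopifnot(is.list(expr), is.list(geno), length(expr) >= 1)
  genes <- names(expr)
  if (is.null(genes) || any(genes == "")) stop("expr must be a named list of genes")
  if (!setequal(genes, names(geno))) stop("expr and geno must cover the same genes")
  geno <- geno[genes]
  contexts <- colnames(expr[[1]])
  inds <- rownames(expr[[1]])
  if (is.null(contexts) || is.null(inds)) stop("expression matrices need dimnames")
  for (g in genes) {
    E <- expr[[g]]; G <- geno[[g]]
    if (!identical(colnames(E), contexts) || !identical(rownames(E), inds))
      stop("gene ", g, ": expression dimnames differ from the first gene")
    if (!identical(rownames(G), inds))
      stop("gene ", g, ": genotype rows do not align with expression rows")
    if (any(!is.finite(E[!is.na(E)]))) stop("gene ", g, ": non-finite expression")
    vals <- G[is.finite(G)]
    if (!all(vals %in% 0:2)) stop("gene ", g, ": dosages must be 0/1/2")
  }
  if (!is.null(groups)) {
    if (!setequal(names(groups), contexts))
      stop("groups must name every context exactly once")
    groups <- groups[contexts]
  }
  if (!is.null(covariates)) {
    if (!all(names(covariates) %in% contexts)) stop("covariates name unknown contexts")
  }
  structure(
    list(expr = expr, geno = geno, covariates = covariates, groups = groups,
         genes = genes, contexts = contexts, individuals = inds),
    class = "content_study")
}

#' @export
print.content_study <- function(x, ...) {
  nobs <- sum(vapply(x$expr, function(E) sum(!is.na(E)), numeric(1)))
  cat("content_study:", length(x$genes), "genes,",
      length(x$contexts), "contexts,", length(x$individuals),
      "individuals in pool\n")
  cat("  observed gene-context-individual values:", nobs, "\n")
  cat("  SNPs per gene:",
      paste(range(vapply(x$geno, ncol, numeric(1))), collapse = "-"), "\n")
  if (!is.null(x$covariates)) cat("  covariates supplied\n")
  if (!is.null(x$groups))
    cat("  context groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

# Observed-individual indices for one gene-context
observed_idx <- function(E, c) which(!is.na(E[, c]))
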