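#' Simes combination of p-values
#'
#' `min_k p_(k) * K / k` over the sorted p-values; valid under positive
#' dependence, which is the typical regime for tests sharing genotypes.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return combined p-value.
#' @export
simes_aggregate <- function(p) {
  if (!length(p)) stop("empty p-value set")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]")
  k <- length(p)
  min(sort(p) * k / seq_len(k))
}

#' Build a gene / context / model hypothesis tree
#'
#' Leaves are (gene, context, model) p-values; internal gene-context nodes
#' aggregate their leaves by Simes, and gene roots aggregate their
#' gene-context nodes by Simes.
#'
#' @param leaves data.frame with columns `gene`, `context`, `model` (or
#'   `method`), `p`.
#' @return `hypothesis_tree` with `leaves`, `contexts` (gene-context Simes
#'   p) and `genes` (gene Simes p) tables.
#' @export
hypothesis_tree <- function(leaves) {
  leaves <- as.data.frame(leaves)
  if ("method" %in% names(leaves) && !"model" %in% names(leaves))
    names(leaves)[names(leaves) == "method"] <- "model"
  req <- c("gene", "context", "model", "p")
  if (!all(req %in% names(leaves)))
    stop("leaves need columns gene, context, model, p")
  if (anyDuplicated(leaves[, c("gene", "context", "model")]))
    stop("duplicate (gene, context, model) leaves")
  dt <- data.table::as.data.table(leaves[, req])
  ctx <- dt[, list(p = simes_aggregate(p)), by = c("gene", "context")]
  gen <- ctx[, list(p = simes_aggregate(p)), by = c("gene")]
  structure(list(leaves = as.data.frame(dt),
                 contexts = as.data.frame(ctx),
                 genes = as.data.frame(gen)),
            class = "hypothesis_tree")
}

#' Pool leaves from several methods into one tree
#'
#' @param ... `hypothesis_tree` objects or leaf data.frames from different
#'   methods; (gene, context, model) keys must be disjoint.
#' @return a combined [hypothesis_tree()].
#' @export
pool_methods <- function(...) {
  parts <- lapply(list(...), function(x) {
    if (inherits(x, "hypothesis_tree")) x$leaves else as.data.frame(x)
  })
  hypothesis_tree(do.call(rbind, parts))
}

# step-up BH selection; returns logical vector
bh_select <- function(p, q) {
  n <- length(p)
  if (!n) return(logical(0))
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  passed <- which(p[ord] <= thresh)
  sel <- logical(n)
  if (length(passed)) sel[ord[seq_len(max(passed))]] <- TRUE
  sel
}

#' Hierarchical FDR control over the hypothesis tree
#'
#' Benjamini-Hochberg at level `q` on the gene-level Simes p-values;
#' within each selected gene, BH on its gene-context Simes p-values at the
#' Benjamini-Bogomolov adjusted level `q * R_genes / G`; within each
#' selected gene-context, BH on the leaf p-values at that level further
#' multiplied by the gene's context selection fraction. The output is
#' tree-consistent by construction: a selected child's parent is selected.
#'
#' @param tree a [hypothesis_tree()] (or leaf data.frame).
#' @param q target FDR level (default 0.05).
#' @return `content_hfdr` with selected `genes`, `contexts`, `leaves`
#'   tables (each with the p-values and a `selected` flag) and the
#'   level-wise adjusted q values.
#' @export
hierarchical_fdr <- function(tree, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (!inherits(tree, "hypothesis_tree")) tree <- hypothesis_tree(tree)
  genes <- tree$genes
  genes$selected <- bh_select(genes$p, q)
  G <- nrow(genes)
  R1 <- sum(genes$selected)
  q2 <- q * R1 / G
  ctx <- tree$contexts
  ctx$selected <- FALSE
  leaves <- tree$leaves
  leaves$selected <- FALSE
  if (R1 > 0) {
    for (g in genes$gene[genes$selected]) {
      ic <- which(ctx$gene == g)
      sel2 <- bh_select(ctx$p[ic], q2)
      ctx$selected[ic] <- sel2
      R2 <- sum(sel2)
      if (R2 > 0) {
        q3 <- q2 * R2 / length(ic)
        for (cc in ctx$context[ic][sel2]) {
          il <- which(leaves$gene == g & leaves$context == cc)
          leaves$selected[il] <- bh_select(leaves$p[il], q3)
        }
      }
    }
  }
  structure(list(genes = genes, contexts = ctx, leaves = leaves,
                 q = c(gene = q, context = q2)),
            class = "content_hfdr")
}

#' @export
print.content_hfdr <- function(x, ...) {
  cat("hierarchical FDR at q =", x$q[["gene"]], "\n")
  cat("  genes selected:", sum(x$genes$selected), "/", nrow(x$genes), "\n")
  cat("  gene-contexts selected:", sum(x$contexts$selected), "/",
      nrow(x$contexts), "\n")
  cat("  leaves selected:", sum(x$leaves$selected), "/", nrow(x$leaves), "\n")
  invisible(x)
}
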