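# Small fixtures built in code; kept deliberately tiny so the suite stays fast.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 3, n_contexts = 6, n_snps = 60,
                   sample_size = c(40, 80), h2_shared = 0.3,
                   h2_specific = 0.1, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# hand-built study: expression matrices given as a named list of I x C
# matrices; genotypes filled with arbitrary valid dosages
manual_study <- function(expr, n_snps = 5, seed = 1, ...) {
  set.seed(seed)
  geno <- lapply(names(expr), function(g) {
    G <- matrix(rbinom(nrow(expr[[g]]) * n_snps, 2, 0.4),
                nrow(expr[[g]]), n_snps,
                dimnames = list(rownames(expr[[g]]),
                                paste0(g, "_snp", seq_len(n_snps))))
    G
  })
  names(geno) <- names(expr)
  content_study(expr, geno, ...)
}

expr_mat <- function(values, inds, ctxs) {
  matrix(values, length(inds), length(ctxs),
         dimnames = list(inds, ctxs))
}
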