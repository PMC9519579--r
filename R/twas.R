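#' Impute genetic expression into a cohort from a weight table
#'
#' Matrix product of cohort dosages with exported SNP weights, one imputed
#' vector per (gene, context, model) row group. Intercepts are omitted:
#' downstream association is scale- and shift-invariant.
#'
#' @param weights weight table as produced by [export_weights()].
#' @param geno named per-gene list of dosage matrices; every SNP named in
#'   the weight table must be present (missing SNPs are an error, never
#'   silently dropped).
#' @return data.frame-backed list: `imputed` matrix (individuals x
#'   model instances) and `index` data.frame (gene, context, model) for its
#'   columns; constant imputations are flagged in `index$constant`.
#' @export
impute_expression <- function(weights, geno) {
  req <- c("gene", "context", "model", "snp", "weight")
  if (!all(req %in% names(weights))) stop("malformed weight table")
  key <- interaction(weights$gene, weights$context, weights$model, drop = TRUE)
  groups <- split(weights, key)
  n <- nrow(geno[[1]])
  imputed <- matrix(NA_real_, n, length(groups))
  idx <- data.frame(gene = character(length(groups)),
                    context = character(length(groups)),
                    model = character(length(groups)),
                    constant = logical(length(groups)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    w <- groups[[i]]
    g <- w$gene[1]
    G <- geno[[g]]
    if (is.null(G)) stop("no genotypes for gene ", g)
    missing_snps <- setdiff(w$snp, colnames(G))
    if (length(missing_snps))
      stop("cohort lacks SNPs: ", paste(missing_snps, collapse = ", "))
    x <- drop(G[, w$snp, drop = FALSE] %*% w$weight)
    imputed[, i] <- x
    idx$gene[i] <- g; idx$context[i] <- w$context[1]; idx$model[i] <- w$model[1]
    idx$constant[i] <- sd(x) < 1e-12
  }
  rownames(imputed) <- rownames(geno[[1]])
  list(imputed = imputed, index = idx)
}

#' Association of imputed expression with a phenotype
#'
#' Simple linear regression of the phenotype on the standardized imputed
#' expression; the t-statistic is reported as a Z-score (capped at |40|)
#' with a two-sided normal p-value. Constant imputations are excluded with
#' `NA` statistics.
#'
#' @param imputation result of [impute_expression()], or a numeric matrix.
#' @param y phenotype vector aligned to the cohort.
#' @param zmax numeric cap on |Z| (default 40; association ranking is
#'   unaffected).
#' @return data.frame of gene, context, model, z, p.
#' @export
associate <- function(imputation, y, zmax = 40) {
  if (is.matrix(imputation)) {
    X <- imputation
    idx <- data.frame(gene = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                      context = NA, model = NA,
                      constant = apply(X, 2, sd) < 1e-12)
  } else {
    X <- imputation$imputed
    idx <- imputation$index
  }
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n < 10) stop("associate requires at least 10 individuals")
  z <- rep(NA_real_, ncol(X))
  ok <- !idx$constant
  if (any(ok)) {
    r <- suppressWarnings(as.numeric(cor(X[, ok, drop = FALSE], y)))
    r <- pmin(pmax(r, -1), 1)
    t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
    z[ok] <- pmin(pmax(t, -zmax), zmax)
  }
  data.frame(gene = idx$gene, context = idx$context, model = idx$model,
             z = z, p = 2 * pnorm(-abs(z)))
}

#' Gene-level discovery AUC from association statistics
#'
#' Scores each gene by its maximum absolute association statistic across
#' contexts (and across models, when several are supplied) and computes
#' the area under the ROC curve for separating causal from non-causal
#' genes by the Mann-Whitney formulation (rank-based, so invariant to
#' monotone transforms of the scores).
#'
#' @param ztab association table from [associate()] (optionally
#'   pre-filtered to one method/model).
#' @param causal_genes character vector of truly causal genes.
#' @param all_genes optional full gene universe (genes without any
#'   statistic receive score `-Inf`, i.e. are never discovered).
#' @return scalar AUC.
#' @export
gene_auc <- function(ztab, causal_genes, all_genes = NULL) {
  sc <- tapply(abs(ztab$z), ztab$gene, max, na.rm = TRUE)
  sc[!is.finite(sc)] <- -Inf
  if (!is.null(all_genes)) {
    miss <- setdiff(all_genes, names(sc))
    sc <- c(sc, setNames(rep(-Inf, length(miss)), miss))
  }
  lab <- names(sc) %in% causal_genes
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: single-class labels")
  r <- rank(sc)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' TWAS power study over simulated phenotypes
#'
#' For each expression-heritability setting and replicate: simulate a
#' multi-context study, train the requested methods, export weights at the
#' nominal forwarding threshold, impute expression into an independent
#' external cohort, simulate a phenotype from the true genetic expression
#' of randomly selected causal gene-context pairs, test every forwarded
#' model, and score gene discovery by AUC of the per-gene maximum |Z|.
#'
#' @param config a [sim_config()] template; per-gene heritability is
#'   redrawn per replicate with the shared proportion sampled from
#'   Unif(0, 1) at total heritability `h2_settings[s]`.
#' @param pcfg a [phenotype_config()].
#' @param h2_settings numeric vector of total expression heritabilities.
#' @param reps replicates per setting.
#' @param methods subset of `c("content", "cbc", "grouplasso")`.
#' @param p_forward nominal forwarding p-value (default 0.1).
#' @param cv,nfolds,nlambda,lambda.min.ratio training controls.
#' @param seed integer seed.
#' @return data.frame of AUC by setting, replicate and method/model
#'   (CONTENT contributes `content_full`, `content_specific`,
#'   `content_shared` and the pooled `content_all`).
#' @export
run_twas_power_study <- function(config, pcfg = phenotype_config(),
                                 h2_settings = c(0.1, 0.3), reps = 1,
                                 methods = c("content", "cbc", "grouplasso"),
                                 p_forward = 0.1, cv = "preval", nfolds = 10,
                                 nlambda = 50, lambda.min.ratio = 0.05,
                                 seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  for (s in seq_along(h2_settings)) {
    for (r in seq_len(reps)) {
      rseed <- derive_seed(seed, paste0("twas-", s, "-", r))
      set.seed(rseed)
      u <- runif(config$n_genes)
      cfg <- config
      cfg$h2_shared <- u * h2_settings[s]
      cfg$h2_specific <- (1 - u) * h2_settings[s]
      cfg$seed <- derive_seed(rseed, "sim")
      panel <- simulate_genotypes(cfg)
      truth <- simulate_effects(cfg, panel)
      train <- simulate_expression(cfg, panel, truth)
      wtabs <- list()
      if ("content" %in% methods) {
        cm <- content_train(train, cv = cv, nfolds = nfolds,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda.min.ratio,
                            seed = derive_seed(rseed, "content"))
        wt <- export_weights(cm, threshold = p_forward)
        for (mod in c("full", "specific", "shared"))
          wtabs[[paste0("content_", mod)]] <- wt[wt$model == mod, ]
        wtabs$content_all <- wt
      }
      if ("cbc" %in% methods) {
        bm <- cbc_train(train, cv = cv, nfolds = nfolds, nlambda = nlambda,
                        lambda.min.ratio = lambda.min.ratio,
                        seed = derive_seed(rseed, "cbc"))
        wtabs$cbc <- export_weights(bm, threshold = p_forward)
      }
      if ("grouplasso" %in% methods) {
        gm <- group_lasso_train(train, seed = derive_seed(rseed, "gl"))
        wtabs$grouplasso <- export_weights(gm, threshold = p_forward)
      }
      rm(train); gc(verbose = FALSE)
      z <- twas_replicate_scores(wtabs, truth, panel$maf, pcfg,
                                 seed = derive_seed(rseed, "external"))
      genes <- names(panel$geno)
      res <- lapply(names(wtabs), function(lab) {
        za <- z$assoc[z$assoc$label == lab, ]
        if (!nrow(za)) return(NULL)
        data.frame(setting = h2_settings[s], rep = r, method = lab,
                   auc = gene_auc(za, z$causal_genes, all_genes = genes))
      })
      out[[length(out) + 1]] <- do.call(rbind, res)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Stream the external cohort gene by gene: simulate each gene's external
# genotypes from the training MAFs, collect the causal pairs' true genetic
# expression and every forwarded model's imputed expression, then build the
# phenotype and test all models. Keeps memory at one gene's genotypes.
twas_replicate_scores <- function(wtabs, truth, maf, pcfg, seed) {
  set.seed(seed)
  genes <- names(truth$genes)
  elig_ctx <- lapply(genes, function(g) {
    tg <- truth$genes[[g]]
    truth$contexts[any(tg$beta_shared != 0) |
                     colSums(tg$beta_specific != 0) > 0]
  })
  names(elig_ctx) <- genes
  heritable <- genes[lengths(elig_ctx) >= pcfg$contexts_per_gene]
  if (pcfg$n_causal_genes > length(heritable))
    stop("fewer heritable genes available than requested causal genes")
  causal_genes <- sample(heritable, pcfg$n_causal_genes)
  causal_ctx <- lapply(causal_genes, function(g)
    sample(elig_ctx[[g]], pcfg$contexts_per_gene))
  names(causal_ctx) <- causal_genes
  n_pairs <- pcfg$n_causal_genes * pcfg$contexts_per_gene
  n <- pcfg$n_external
  X <- matrix(0, n, n_pairs)
  k <- 0
  imp <- list()
  gene_seeds <- sapply(genes, function(g) derive_seed(seed, g))
  for (g in genes) {
    wg <- lapply(wtabs, function(w) w[w$gene == g, , drop = FALSE])
    nw <- sum(vapply(wg, nrow, numeric(1)))
    is_causal <- g %in% causal_genes
    if (!is_causal && nw == 0) next
    set.seed(gene_seeds[[g]])
    M <- length(maf[[g]])
    G <- matrix(rbinom(n * M, 2L, rep(maf[[g]], each = n)), nrow = n,
                dimnames = list(NULL, names(truth$genes[[g]]$beta_shared)))
    if (is_causal) {
      Gs <- standardize_cols(G)$x
      tg <- truth$genes[[g]]
      shared <- drop(Gs %*% tg$beta_shared)
      for (cc in causal_ctx[[g]]) {
        k <- k + 1
        x <- shared + drop(Gs %*% tg$beta_specific[, cc])
        if (pop_sd(x) < 1e-12)
          stop("causal pair without heritable component: ", g, "/", cc)
        X[, k] <- (x - mean(x)) / pop_sd(x)
      }
    }
    for (lab in names(wg)) {
      w <- wg[[lab]]
      if (!nrow(w)) next
      ii <- impute_expression(w, setNames(list(G), g))
      cn <- paste(lab, ii$index$context, ii$index$model, sep = "|")
      keep <- !ii$index$constant
      if (any(keep))
        imp[[length(imp) + 1]] <- list(label = lab, gene = g,
                                       context = ii$index$context[keep],
                                       model = ii$index$model[keep],
                                       x = ii$imputed[, keep, drop = FALSE])
    }
  }
  delta <- rnorm(n_pairs, 0, sqrt(pcfg$var_explained / n_pairs))
  noise_var <- if (pcfg$literal_noise) 1 - pcfg$var_explained / n_pairs
               else 1 - pcfg$var_explained
  y <- drop(X %*% delta) + rnorm(n, 0, sqrt(noise_var))
  assoc <- do.call(rbind, lapply(imp, function(e) {
    za <- associate(e$x, y)
    data.frame(label = e$label, gene = e$gene, context = e$context,
               model = e$model, z = za$z, p = za$p)
  }))
  list(assoc = assoc, causal_genes = causal_genes, y = y, delta = delta)
}
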