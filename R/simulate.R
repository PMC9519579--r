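#' Simulation configuration
#'
#' Describes the generative model for a multi-context expression study:
#' independent cis SNPs with MAF ~ Unif(0.05, 0.50), Bernoulli(pi)-sparse
#' normal genetic effects with a context-shared vector and per-context
#' deviations, Poisson(lambda) truly context-specific eQTLs placed on SNPs
#' without a shared effect, and equicorrelated intra-individual noise across
#' contexts. Defaults follow a GTEx-like design: 20 contexts, 500 cis SNPs,
#' per-context sample sizes 75-410, shared/specific heritability 0.3/0.1,
#' pi = 0.05, lambda = 1.
#'
#' @param n_genes number of genes.
#' @param n_contexts number of contexts `C`.
#' @param n_snps cis SNPs per gene `M`.
#' @param sample_size length-2 range; each context's sample size is drawn
#'   uniformly from it and individuals are sampled from a common pool of
#'   size `max(sample_size)`, so individuals are not observed in every
#'   context.
#' @param h2_shared,h2_specific context-shared and context-specific
#'   heritability of expression; scalar or per-gene vector.
#' @param causal_prob Bernoulli probability pi that a SNP carries a shared
#'   effect.
#' @param frac_contexts_specific fraction of contexts (per gene) that carry
#'   context-specific heritability.
#' @param lambda Poisson rate of truly context-specific eQTLs (placed on
#'   SNPs with no shared effect) per context with specific effects; it also
#'   enters the specific effect-size variance `h2_specific/(lambda*M*pi)`.
#'   `lambda = 0` disables the truly specific additions (the variance then
#'   falls back to `h2_specific/(M*pi)`).
#' @param rho intra-individual noise correlation across contexts
#'   (equicorrelated), `0 <= rho < 1`.
#' @param brain_contexts optional integer/character vector of contexts that
#'   share an additional group-level genetic component.
#' @param h2_group heritability of the group-level component (only used
#'   with `brain_contexts`).
#' @param seed integer seed; all draws are deterministic given the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 100, n_contexts = 20, n_snps = 500,
                       sample_size = c(75, 410),
                       h2_shared = 0.3, h2_specific = 0.1,
                       causal_prob = 0.05, frac_contexts_specific = 1,
                       lambda = 1, rho = 0,
                       brain_contexts = NULL, h2_group = 0, seed = 1L) {
  stopifnot(n_genes >= 1, n_contexts >= 2, n_snps >= 1,
            length(sample_size) == 2, sample_size[1] >= 2,
            sample_size[2] >= sample_size[1],
            causal_prob > 0, causal_prob <= 1,
            frac_contexts_specific >= 0, frac_contexts_specific <= 1,
            lambda >= 0, rho >= 0, rho < 1, h2_group >= 0)
  h2_shared <- rep_len(h2_shared, n_genes)
  h2_specific <- rep_len(h2_specific, n_genes)
  tot <- h2_shared + h2_specific + if (length(brain_contexts)) h2_group else 0
  if (any(tot >= 1)) stop("h2_shared + h2_specific (+ h2_group) must be < 1")
  structure(list(
    n_genes = as.integer(n_genes), n_contexts = as.integer(n_contexts),
    n_snps = as.integer(n_snps), sample_size = as.integer(sample_size),
    h2_shared = h2_shared, h2_specific = h2_specific,
    causal_prob = causal_prob,
    frac_contexts_specific = frac_contexts_specific,
    lambda = lambda, rho = rho,
    brain_contexts = brain_contexts, h2_group = h2_group,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate cis genotype panels
#'
#' Each SNP is an independent Binomial(2, p) dosage with
#' p ~ Unif(0.05, 0.50); no linkage disequilibrium and no rare variants.
#'
#' @param config a [sim_config()].
#' @param n number of individuals (default `max(config$sample_size)`, the
#'   study pool).
#' @param maf optional list of per-gene MAF vectors; when supplied (e.g. to
#'   generate a test set or an external TWAS cohort matched to a training
#'   panel) the MAFs are reused instead of redrawn.
#' @param seed integer seed; defaults to a seed derived from the config.
#' @param prefix prefix for individual ids.
#' @return `content_panel`: list with `geno` (per-gene dosage matrices) and
#'   `maf` (per-gene MAF vectors).
#' @export
simulate_genotypes <- function(config, n = NULL, maf = NULL, seed = NULL,
                               prefix = "ind") {
  n <- n %||% max(config$sample_size)
  if (n < 1 || config$n_snps < 1) stop("non-positive simulation dimensions")
  set.seed(seed %||% derive_seed(config$seed, "genotypes"))
  genes <- paste0("gene", seq_len(config$n_genes))
  inds <- paste0(prefix, seq_len(n))
  M <- config$n_snps
  out <- list(geno = list(), maf = list())
  for (j in seq_len(config$n_genes)) {
    p <- if (is.null(maf)) runif(M, 0.05, 0.50) else maf[[j]]
    G <- matrix(rbinom(n * M, 2L, rep(p, each = n)), nrow = n, ncol = M,
                dimnames = list(inds, paste0(genes[j], "_snp", seq_len(M))))
    out$geno[[genes[j]]] <- G
    out$maf[[genes[j]]] <- p
  }
  structure(out, class = "content_panel")
}

#' Simulate shared, specific and group genetic effects
#'
#' Shared effects are `N(0, h2/(M*pi))` on a Bernoulli(pi) causal mask.
#' Every shared-causal SNP also receives a context-specific deviation
#' `N(0, h2_c/(lambda*M*pi))` in each context carrying specific effects;
#' additionally `Poisson(lambda)` truly specific eQTLs per such context are
#' placed on SNPs without a shared effect (same effect-size law).
#'
#' @param config a [sim_config()].
#' @param panel a [simulate_genotypes()] panel (defines genes and M).
#' @param seed integer seed (derived from config when `NULL`).
#' @return `content_truth`: per-gene effect vectors and causal masks.
#' @export
simulate_effects <- function(config, panel, seed = NULL) {
  set.seed(seed %||% derive_seed(config$seed, "effects"))
  genes <- names(panel$geno)
  C <- config$n_contexts
  M <- config$n_snps
  pi0 <- config$causal_prob
  lam <- config$lambda
  lam_var <- if (lam > 0) lam else 1
  contexts <- paste0("context", seq_len(C))
  n_spec <- round(config$frac_contexts_specific * C)
  truth <- list()
  for (j in seq_along(genes)) {
    h2 <- config$h2_shared[j]; h2c <- config$h2_specific[j]
    mask <- runif(M) < pi0
    beta <- rnorm(M, 0, sqrt(h2 / (M * pi0))) * mask
    spec_ctx <- sort(sample.int(C, n_spec))
    bspec <- matrix(0, M, C, dimnames = list(colnames(panel$geno[[j]]), contexts))
    truly <- vector("list", C)
    sd_spec <- sqrt(h2c / (lam_var * M * pi0))
    for (c in spec_ctx) {
      bspec[, c] <- rnorm(M, 0, sd_spec) * mask
      if (lam > 0) {
        k <- rpois(1, lam)
        pool <- which(!mask)
        if (k > length(pool))
          stop("requested truly-specific eQTL count exceeds available non-causal SNPs")
        if (k > 0) {
          snps <- pool[sample.int(length(pool), k)]
          bspec[snps, c] <- rnorm(k, 0, sd_spec)
          truly[[c]] <- snps
        }
      }
    }
    bgroup <- NULL
    if (length(config$brain_contexts)) {
      bgroup <- rnorm(M, 0, sqrt(config$h2_group / (lam_var * M * pi0))) * mask
    }
    truth[[genes[j]]] <- list(
      beta_shared = setNames(beta, colnames(panel$geno[[j]])),
      beta_specific = bspec,
      beta_group = bgroup,
      causal_shared = which(mask),
      specific_contexts = contexts[spec_ctx],
      truly_specific = truly,
      maf = panel$maf[[j]])
  }
  structure(list(genes = truth, contexts = contexts, config = config),
            class = "content_truth")
}

#' True genetic expression components for a genotype panel
#'
#' Computes, per gene, the context-shared component `G beta`, the
#' context-specific components `G gamma_c` (including truly specific and
#' group-level effects) and their per-context totals, with genotype columns
#' standardized so that component variances match the configured
#' heritabilities.
#'
#' @param panel a `content_panel`.
#' @param truth a `content_truth`.
#' @return list per gene with `shared` (vector), `specific` (I x C),
#'   `group` (vector or NULL) and `total` (I x C).
#' @export
true_components <- function(panel, truth) {
  cfg <- truth$config
  brain <- context_ids(cfg$brain_contexts, truth$contexts)
  out <- list()
  for (g in names(truth$genes)) {
    tg <- truth$genes[[g]]
    Gs <- standardize_cols(panel$geno[[g]])$x
    shared <- drop(Gs %*% tg$beta_shared)
    specific <- Gs %*% tg$beta_specific
    total <- specific + shared
    grp <- NULL
    if (!is.null(tg$beta_group)) {
      grp <- drop(Gs %*% tg$beta_group)
      total[, brain] <- total[, brain] + grp
    }
    out[[g]] <- list(shared = shared, specific = specific, group = grp,
                     total = total)
  }
  out
}

context_ids <- function(x, contexts) {
  if (is.null(x)) return(character(0))
  if (is.numeric(x)) contexts[x] else intersect(x, contexts)
}

#' Simulate observed multi-context expression
#'
#' Observed expression is the true genetic component plus a C-dimensional
#' Gaussian noise draw per individual with per-context variance
#' `1 - h2_shared - h2_specific` (minus `h2_group` in group contexts; the
#' specific share is only subtracted in contexts that carry specific
#' effects) and equicorrelated off-diagonals `rho * sigma_c1 * sigma_c2`.
#' Each context observes a subset of the pool: its sample size is drawn
#' uniformly from `config$sample_size` and individuals are sampled without
#' replacement; every individual is kept in at least one context.
#'
#' @inheritParams simulate_effects
#' @param truth a [simulate_effects()] result.
#' @param seed integer seed (derived from config when `NULL`).
#' @param complete if `TRUE`, no missingness (all pool individuals observed
#'   in every context).
#' @return a [content_study()] with an extra `components` field holding the
#'   true genetic components ([true_components()]) for oracle scoring.
#' @export
simulate_expression <- function(config, panel, truth, seed = NULL,
                                complete = FALSE) {
  set.seed(seed %||% derive_seed(config$seed, "expression"))
  genes <- names(panel$geno)
  C <- config$n_contexts
  contexts <- truth$contexts
  inds <- rownames(panel$geno[[1]])
  I <- length(inds)
  brain <- context_ids(config$brain_contexts, contexts)
  comps <- true_components(panel, truth)

  # one missingness pattern for the whole study, as in a real multi-tissue design
  if (complete) {
    obs <- matrix(TRUE, I, C, dimnames = list(inds, contexts))
  } else {
    obs <- matrix(FALSE, I, C, dimnames = list(inds, contexts))
    sizes <- seq(config$sample_size[1], min(config$sample_size[2], I))
    for (c in seq_len(C)) {
      nc <- sizes[sample.int(length(sizes), 1)]
      obs[sample.int(I, nc), c] <- TRUE
    }
    orphan <- which(rowSums(obs) == 0)
    for (i in orphan) {
      open <- which(colSums(obs) < I)  # nonempty: an orphan implies no full context
      obs[i, open[sample.int(length(open), 1)]] <- TRUE
    }
  }

  expr <- list()
  for (j in seq_along(genes)) {
    g <- genes[j]
    tg <- truth$genes[[g]]
    s2 <- rep(1 - config$h2_shared[j], C)
    s2[contexts %in% tg$specific_contexts] <-
      s2[contexts %in% tg$specific_contexts] - config$h2_specific[j]
    if (length(brain)) s2[contexts %in% brain] <-
      s2[contexts %in% brain] - config$h2_group
    if (any(s2 <= 0)) stop("noise variance not positive; lower heritabilities")
    sdv <- sqrt(s2)
    Sigma <- (config$rho * tcrossprod(sdv)) + diag(s2 - config$rho * s2)
    R <- tryCatch(chol(Sigma),
                  error = function(e) stop("noise covariance not positive definite"))
    eps <- matrix(rnorm(I * C), I, C) %*% R
    E <- comps[[g]]$total + eps
    E[!obs] <- NA
    dimnames(E) <- list(inds, contexts)
    expr[[g]] <- E
  }
  groups <- NULL
  if (length(brain)) {
    groups <- setNames(ifelse(contexts %in% brain, "group", "rest"), contexts)
  }
  study <- content_study(expr, panel$geno, groups = groups)
  study$components <- comps
  study
}

#' Simulate a complete train/test study
#'
#' Draws effects once, then generates a training study and (optionally) an
#' independent test study from the same MAFs and effect sizes, mirroring the
#' one-train/one-test evaluation design.
#'
#' @inheritParams simulate_genotypes
#' @param test generate an independent test study (default `TRUE`).
#' @param n_test test pool size (default: same as training pool).
#' @return list of class `content_sim` with `train`, `test` (or `NULL`),
#'   `truth`, `panel` (training genotypes) and `config`.
#' @export
simulate_study <- function(config, test = TRUE, n_test = NULL) {
  panel <- simulate_genotypes(config)
  truth <- simulate_effects(config, panel)
  train <- simulate_expression(config, panel, truth)
  tst <- NULL
  if (test) {
    panel_t <- simulate_genotypes(config, n = n_test %||% max(config$sample_size),
                                  maf = panel$maf,
                                  seed = derive_seed(config$seed, "genotypes-test"),
                                  prefix = "test")
    tst <- simulate_expression(config, panel_t, truth,
                               seed = derive_seed(config$seed, "expression-test"))
    tst$panel <- panel_t
  }
  structure(list(train = train, test = tst, truth = truth, panel = panel,
                 config = config), class = "content_sim")
}

#' Phenotype simulation configuration
#'
#' @param n_causal_genes number of causal genes (default 100).
#' @param contexts_per_gene causal contexts per gene (default 3), giving
#'   `n_causal_genes * contexts_per_gene` causal gene-context pairs.
#' @param var_explained variance in the phenotype explained by genetic gene
#'   expression, sigma_ge^2 (default 0.2).
#' @param n_external external cohort size for imputation (default 10000).
#' @param literal_noise if `TRUE`, the noise variance uses the literal
#'   `1 - sigma_ge^2/n_pairs` parametrization; default `FALSE` targets a
#'   total phenotypic variance of 1 with genetic share sigma_ge^2.
#' @export
phenotype_config <- function(n_causal_genes = 100, contexts_per_gene = 3,
                             var_explained = 0.2, n_external = 10000,
                             literal_noise = FALSE) {
  stopifnot(var_explained >= 0, var_explained < 1,
            n_causal_genes >= 1, contexts_per_gene >= 1)
  structure(list(n_causal_genes = as.integer(n_causal_genes),
                 contexts_per_gene = as.integer(contexts_per_gene),
                 var_explained = var_explained,
                 n_external = as.integer(n_external),
                 literal_noise = literal_noise), class = "phenotype_config")
}

#' Simulate a phenotype from genetic gene expression
#'
#' Selects causal gene-context pairs at random, standardizes their true
#' genetic expression in the supplied cohort, draws per-pair effect sizes
#' `delta ~ N(0, sigma_ge^2 / n_pairs)` and adds Gaussian noise.
#'
#' @param pcfg a [phenotype_config()].
#' @param panel genotype panel of the cohort the phenotype is generated for
#'   (e.g. an external imputation cohort).
#' @param truth the `content_truth` the expression architecture was drawn
#'   from.
#' @param seed integer seed.
#' @return list with `y` (named phenotype vector), `pairs` (data.frame of
#'   causal gene, context, delta) and `delta`.
#' @export
simulate_phenotype <- function(pcfg, panel, truth, seed = 1L) {
  set.seed(seed)
  genes <- names(truth$genes)
  n_pairs <- pcfg$n_causal_genes * pcfg$contexts_per_gene
  elig_ctx <- lapply(genes, function(g) {
    tg <- truth$genes[[g]]
    truth$contexts[any(tg$beta_shared != 0) |
                     colSums(tg$beta_specific != 0) > 0]
  })
  names(elig_ctx) <- genes
  heritable <- genes[lengths(elig_ctx) >= pcfg$contexts_per_gene]
  if (pcfg$n_causal_genes > length(heritable))
    stop("fewer heritable genes available than requested causal genes")
  comps <- true_components(panel, truth)
  causal_genes <- sample(heritable, pcfg$n_causal_genes)
  C <- length(truth$contexts)
  if (pcfg$contexts_per_gene > C) stop("more causal contexts than contexts")
  X <- matrix(0, nrow(panel$geno[[1]]), n_pairs)
  pairs <- data.frame(gene = rep(causal_genes, each = pcfg$contexts_per_gene),
                      context = NA_character_, stringsAsFactors = FALSE)
  k <- 0
  for (g in causal_genes) {
    ctx <- sample(elig_ctx[[g]], pcfg$contexts_per_gene)
    for (cc in ctx) {
      k <- k + 1
      x <- comps[[g]]$total[, cc]
      if (pop_sd(x) < 1e-12)
        stop("selected gene-context pair has no heritable component: ", g, "/", cc)
      X[, k] <- (x - mean(x)) / pop_sd(x)
      pairs$context[k] <- cc
    }
  }
  delta <- rnorm(n_pairs, 0, sqrt(pcfg$var_explained / n_pairs))
  noise_var <- if (pcfg$literal_noise) 1 - pcfg$var_explained / n_pairs
               else 1 - pcfg$var_explained
  y <- drop(X %*% delta) + rnorm(nrow(X), 0, sqrt(noise_var))
  names(y) <- rownames(panel$geno[[1]])
  pairs$delta <- delta
  list(y = y, pairs = pairs, delta = delta)
}
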