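#' Train context-shared, context-specific and full predictors
#'
#' The main per-gene training driver. Expression is residualized (if
#' covariates are present), centered/scaled and decomposed; an elastic net
#' is then fit to the shared component (over all individuals with at least
#' one observed context) and to each context's specific component, and the
#' per-context full model recombines the two out-of-fold component
#' predictions by linear regression. When the study carries context groups,
#' a predictor is additionally fit to each group-shared component.
#'
#' @param study a [content_study()].
#' @param alpha,nfolds,cv,nlambda,lambda.min.ratio passed to
#'   [fit_component()].
#' @param seed integer seed (fold assignments are derived per gene and
#'   component).
#' @param min_n minimum observations to fit a specific/full model for a
#'   context (default 20).
#' @return `content_models`: per-gene fits, plus a `summary` data.frame
#'   with one row per fitted model (gene, context, model, n, cv_r2,
#'   cv_adj_r2, lrt_p). The shared model is reported with context `"all"`.
#' @export
content_train <- function(study, alpha = 0.5, nfolds = 10,
                          cv = c("preval", "nested"), nlambda = 50,
                          lambda.min.ratio = 0.05, seed = 1L, min_n = 20) {
  cv <- match.arg(cv)
  prep <- prepare_and_decompose(study)
  dec <- prep$decomposition
  study <- prep$study
  genes <- study$genes
  rows <- list()
  fits <- list()
  for (g in genes) {
    d <- dec$genes[[g]]
    G <- study$geno[[g]]
    ids_sh <- names(d$shared)
    sh <- fit_component(d$shared, G[ids_sh, , drop = FALSE], alpha = alpha,
                        nfolds = nfolds, cv = cv, nlambda = nlambda,
                        lambda.min.ratio = lambda.min.ratio,
                        seed = derive_seed(seed, paste0(g, "-shared")),
                        component = "shared")
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, context = "all", model = "shared", n = sh$n,
      cv_r2 = sh$cv_r2, cv_adj_r2 = sh$cv_adj_r2, lrt_p = sh$lrt_p)
    spec <- list(); full <- list(); grp <- list()
    if (!is.null(d$group_shared)) {
      for (gr in colnames(d$group_shared)) {
        v <- d$group_shared[, gr]
        idx <- which(!is.na(v))
        if (length(idx) < min_n) next
        gf <- fit_component(v[idx], G[names(v)[idx], , drop = FALSE],
                            alpha = alpha, nfolds = nfolds, cv = cv,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda.min.ratio,
                            seed = derive_seed(seed, paste0(g, "-group-", gr)),
                            component = paste0("group:", gr))
        grp[[gr]] <- gf
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, context = gr, model = "group", n = gf$n,
          cv_r2 = gf$cv_r2, cv_adj_r2 = gf$cv_adj_r2, lrt_p = gf$lrt_p)
      }
    }
    for (ctx in study$contexts) {
      v <- d$specific[, ctx]
      idx <- which(!is.na(v))
      if (length(idx) < min_n) next
      ids <- rownames(d$specific)[idx]
      sp <- fit_component(v[idx], G[ids, , drop = FALSE], alpha = alpha,
                          nfolds = nfolds, cv = cv, nlambda = nlambda,
                          lambda.min.ratio = lambda.min.ratio,
                          seed = derive_seed(seed, paste0(g, "-", ctx)),
                          component = paste0("specific:", ctx))
      spec[[ctx]] <- sp
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, context = ctx, model = "specific", n = sp$n,
        cv_r2 = sp$cv_r2, cv_adj_r2 = sp$cv_adj_r2, lrt_p = sp$lrt_p)
      # full model on out-of-fold component predictions
      yobs <- study$expr[[g]][ids, ctx]
      fl <- fit_full(yobs, sh$preval[ids], sp$preval[ids])
      full[[ctx]] <- fl
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, context = ctx, model = "full", n = fl$n,
        cv_r2 = fl$cv_r2, cv_adj_r2 = fl$cv_adj_r2, lrt_p = fl$lrt_p)
    }
    fits[[g]] <- list(shared = sh, specific = spec, full = full, group = grp)
  }
  structure(list(method = "content", genes = fits,
                 contexts = study$contexts,
                 summary = do.call(rbind, rows)),
            class = "content_models")
}

#' @export
print.content_models <- function(x, ...) {
  cat("content_models [", x$method, "]:", length(x$genes), "genes,",
      nrow(x$summary), "fitted models\n")
  invisible(x)
}

#' Predict expression components on new genotypes
#'
#' @param models a `content_models` object from [content_train()].
#' @param geno named list of dosage matrices (per gene) for the target
#'   cohort.
#' @return list per gene with `shared` (vector), `specific` and `full`
#'   (individuals x contexts matrices; `NA` columns where no model was
#'   fitted).
#' @export
predict_components <- function(models, geno) {
  stopifnot(inherits(models, "content_models"), models$method == "content")
  out <- list()
  for (g in names(models$genes)) {
    mg <- models$genes[[g]]
    G <- geno[[g]]
    if (is.null(G)) stop("no genotypes for gene ", g)
    n <- nrow(G)
    shared <- predict(mg$shared, G)
    specific <- matrix(NA_real_, n, length(models$contexts),
                       dimnames = list(rownames(G), models$contexts))
    full <- specific
    for (ctx in names(mg$specific)) {
      sp <- predict(mg$specific[[ctx]], G)
      specific[, ctx] <- sp
      fl <- mg$full[[ctx]]
      full[, ctx] <- fl$intercept + fl$w_shared * shared + fl$w_specific * sp
    }
    out[[g]] <- list(shared = shared, specific = specific, full = full)
  }
  out
}

#' Best model per gene-context by cross-validated adjusted R-squared
#'
#' Selects, for every gene-context pair, the model (shared, specific or
#' full) with the greatest cross-validated adjusted R-squared. Ties are
#' broken in favour of fewer predictors (shared/specific before full),
#' then lexicographically.
#'
#' @param models a `content_models` object.
#' @return data.frame with gene, context, best model label and its score.
#' @export
select_best_model <- function(models) {
  s <- models$summary
  s <- s[s$model %in% c("shared", "specific", "full") & is.finite(s$cv_adj_r2), ]
  out <- list()
  for (g in unique(s$gene)) {
    sg <- s[s$gene == g, ]
    shared_row <- sg[sg$model == "shared", ]
    ctxs <- unique(sg$context[sg$context != "all"])
    for (ctx in ctxs) {
      cand <- sg[sg$context == ctx, ]
      if (nrow(shared_row)) {
        sr <- shared_row
        sr$context <- ctx
        cand <- rbind(cand, sr)
      }
      npred <- ifelse(cand$model == "full", 2L, 1L)
      ord <- order(-cand$cv_adj_r2, npred, cand$model)
      best <- cand[ord[1], ]
      out[[length(out) + 1]] <- data.frame(
        gene = g, context = ctx, model = best$model,
        cv_adj_r2 = best$cv_adj_r2)
    }
  }
  do.call(rbind, out)
}

#' Export per-context SNP weight tables
#'
#' Emits one row per nonzero SNP weight for every model whose expression
#' was predicted at a nominal LRT p-value below `threshold` (the
#' weight-forwarding rule; default 0.1). Full-model weights are the
#' combined vector `w_shared * beta_hat + w_specific * gamma_hat_c`. The
#' shared model is exported once per gene with context `"all"`.
#'
#' @param models a `content_models` (or baseline) object.
#' @param threshold nominal p-value threshold (default 0.1; use 1 to export
#'   everything).
#' @param a1,a2 allele labels carried into the table (simulated SNPs use
#'   "A"/"B").
#' @return data.frame with columns gene, context, model, snp, a1, a2,
#'   weight.
#' @export
export_weights <- function(models, threshold = 0.1, a1 = "A", a2 = "B") {
  rows <- list()
  emit <- function(g, ctx, model, w) {
    nz <- which(w != 0)
    if (!length(nz)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      gene = g, context = ctx, model = model,
      snp = names(w)[nz], a1 = a1, a2 = a2, weight = unname(w[nz]))
  }
  if (inherits(models, "content_models") && models$method == "content") {
    for (g in names(models$genes)) {
      mg <- models$genes[[g]]
      if (mg$shared$lrt_p < threshold) emit(g, "all", "shared", mg$shared$weights)
      for (ctx in names(mg$specific)) {
        sp <- mg$specific[[ctx]]
        if (sp$lrt_p < threshold) emit(g, ctx, "specific", sp$weights)
        fl <- mg$full[[ctx]]
        if (fl$lrt_p < threshold)
          emit(g, ctx, "full", combine_weights(fl, mg$shared, sp))
      }
    }
  } else if (inherits(models, "content_models") && models$method == "cbc") {
    for (g in names(models$genes)) {
      for (ctx in names(models$genes[[g]]$fits)) {
        f <- models$genes[[g]]$fits[[ctx]]
        if (f$lrt_p < threshold) emit(g, ctx, "cbc", f$weights)
      }
    }
  } else if (inherits(models, "grouplasso_models")) {
    for (g in names(models$genes)) {
      mg <- models$genes[[g]]
      for (ctx in colnames(mg$weights)) {
        if (is.na(mg$lrt_p[ctx]) || mg$lrt_p[ctx] >= threshold) next
        emit(g, ctx, "grouplasso", setNames(mg$weights[, ctx], rownames(mg$weights)))
      }
    }
  } else stop("unsupported model object")
  if (!length(rows))
    return(data.frame(gene = character(), context = character(),
                      model = character(), snp = character(),
                      a1 = character(), a2 = character(), weight = numeric()))
  do.call(rbind, rows)
}
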