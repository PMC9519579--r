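#' Context-by-context elastic net baseline
#'
#' The traditional TWAS training scheme: an independent elastic-net fit of
#' each context's observed (residualized, centered/scaled, *not*
#' decomposed) expression on cis genotypes, with the same cross-validation
#' and testing machinery as the component fits.
#'
#' @inheritParams content_train
#' @return a `content_models` object with `method = "cbc"`; per gene a
#'   list of per-context `content_fit`s.
#' @export
cbc_train <- function(study, alpha = 0.5, nfolds = 10,
                      cv = c("preval", "nested"), nlambda = 50,
                      lambda.min.ratio = 0.05, seed = 1L, min_n = 20) {
  cv <- match.arg(cv)
  study <- center_scale(residualize(study))
  rows <- list(); fits <- list()
  for (g in study$genes) {
    E <- study$expr[[g]]
    G <- study$geno[[g]]
    gf <- list()
    for (ctx in study$contexts) {
      idx <- observed_idx(E, ctx)
      if (length(idx) < min_n) next
      f <- fit_component(E[idx, ctx], G[idx, , drop = FALSE], alpha = alpha,
                         nfolds = nfolds, cv = cv, nlambda = nlambda,
                         lambda.min.ratio = lambda.min.ratio,
                         seed = derive_seed(seed, paste0(g, "-cbc-", ctx)),
                         component = paste0("cbc:", ctx))
      gf[[ctx]] <- f
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, context = ctx, model = "cbc", n = f$n,
        cv_r2 = f$cv_r2, cv_adj_r2 = f$cv_adj_r2, lrt_p = f$lrt_p)
    }
    fits[[g]] <- list(fits = gf)
  }
  structure(list(method = "cbc", genes = fits, contexts = study$contexts,
                 summary = do.call(rbind, rows)),
            class = "content_models")
}

#' Joint group-LASSO fit across contexts
#'
#' Minimizes \deqn{\sum_c RSS_c/(2 n_c) + \lambda \sum_m \|B_{m\cdot}\|_2}
#' over a SNPs x contexts coefficient matrix by block coordinate descent
#' (each SNP's row is jointly zero or nonzero across contexts), with the
#' penalty selected by cross-validation over a log-spaced path. Folds are
#' assigned at the individual level so that an individual is held out of
#' every context simultaneously. Per-context loss weights `1/(2 n_c)`
#' balance unequal sample sizes; individuals missing from a context simply
#' drop from that context's loss term.
#'
#' @param y_list list of per-context outcome vectors.
#' @param X_list list of per-context design matrices (columns = shared
#'   SNPs, pre-scaled to a common per-SNP scale).
#' @param lambda penalty value(s); a decreasing path is fit with warm
#'   starts.
#' @param tol convergence tolerance on the maximum coefficient change
#'   (default 1e-6).
#' @param maxit maximum coordinate-descent passes per penalty (default
#'   10000); non-convergence returns the best iterate, flagged.
#' @return list with `beta` (SNPs x contexts x length(lambda) array) and
#'   `converged` flags.
#' @export
group_lasso <- function(X_list, y_list, lambda, tol = 1e-6, maxit = 10000) {
  stopifnot(length(X_list) == length(y_list), length(X_list) >= 1)
  for (c in seq_along(X_list)) {
    stopifnot(nrow(X_list[[c]]) == length(y_list[[c]]))
  }
  res <- gl_path_cpp(X_list, y_list, as.numeric(lambda), tol, as.integer(maxit))
  if (!all(res$converged))
    warning("group LASSO did not converge at ",
            sum(!res$converged), " penalty value(s); best iterate returned")
  res
}

# largest penalty with any active group
gl_lambda_max <- function(X_list, y_list) {
  C <- length(X_list)
  M <- ncol(X_list[[1]])
  acc <- numeric(M)
  for (c in seq_len(C)) {
    acc <- acc + (crossprod(X_list[[c]], y_list[[c]]) / nrow(X_list[[c]]))^2
  }
  sqrt(max(acc))
}

#' Train the group-LASSO baseline on a study
#'
#' Per gene: residualized, centered/scaled expression of every context is
#' jointly regressed on the gene's cis genotypes (pooled-scale SNP columns,
#' per-context centering) under the group-LASSO penalty of
#' [group_lasso()], with `nfolds`-fold CV (default 5) choosing the penalty
#' that minimizes the pooled held-out squared error. Held-out predictions
#' at the chosen penalty provide per-context CV statistics.
#'
#' @inheritParams content_train
#' @param nfolds CV folds (default 5).
#' @param nlambda,lambda.min.ratio penalty path resolution.
#' @param tol,maxit solver controls (see [group_lasso()]).
#' @return `grouplasso_models`: per gene dosage-scale `weights`
#'   (SNPs x contexts), per-context `intercepts`, CV statistics, and a
#'   `summary` data.frame.
#' @export
group_lasso_train <- function(study, nfolds = 5, nlambda = 15,
                              lambda.min.ratio = 0.05, tol = 1e-6,
                              maxit = 10000, seed = 1L, min_n = 20) {
  study <- center_scale(residualize(study))
  rows <- list(); fits <- list()
  for (g in study$genes) {
    E <- study$expr[[g]]
    G <- study$geno[[g]]
    std <- standardize_cols(G)
    ctxs <- study$contexts[vapply(study$contexts,
                                  function(ctx) length(observed_idx(E, ctx)) >= min_n,
                                  logical(1))]
    if (length(ctxs) < 1) next
    idx_list <- lapply(ctxs, function(ctx) observed_idx(E, ctx))
    names(idx_list) <- ctxs
    center_ctx <- function(rowsidx, ctx, train = NULL) {
      # context design on pooled SNP scale, centered within (training) rows
      Xc <- std$x[rowsidx, , drop = FALSE]
      mu <- colMeans(if (is.null(train)) Xc else std$x[train, , drop = FALSE])
      sweep(Xc, 2, mu, "-")
    }
    X_all <- lapply(ctxs, function(ctx) center_ctx(idx_list[[ctx]], ctx))
    y_all <- lapply(ctxs, function(ctx) {
      v <- E[idx_list[[ctx]], ctx]; v - mean(v)
    })
    lmax <- gl_lambda_max(X_all, y_all)
    if (lmax <= 0) next
    lambdas <- exp(seq(log(lmax), log(lmax * lambda.min.ratio),
                       length.out = nlambda))
    set.seed(derive_seed(seed, paste0(g, "-gl")))
    foldid <- setNames(sample(rep_len(seq_len(nfolds), length(study$individuals))),
                       study$individuals)
    cv_sse <- matrix(0, nfolds, nlambda)
    cv_n <- numeric(nfolds)
    preval <- lapply(ctxs, function(ctx)
      matrix(NA_real_, length(idx_list[[ctx]]), nlambda))
    names(preval) <- ctxs
    for (f in seq_len(nfolds)) {
      Xtr <- list(); ytr <- list(); info <- list()
      for (ctx in ctxs) {
        ids <- rownames(E)[idx_list[[ctx]]]
        tr <- which(foldid[ids] != f)
        te <- which(foldid[ids] == f)
        if (length(tr) < 5) { tr <- seq_along(ids); te <- integer(0) }
        ridx <- idx_list[[ctx]]
        Xc <- std$x[ridx, , drop = FALSE]
        mu <- colMeans(Xc[tr, , drop = FALSE])
        ybar <- mean(E[ridx, ctx][tr])
        Xtr[[ctx]] <- sweep(Xc[tr, , drop = FALSE], 2, mu, "-")
        ytr[[ctx]] <- E[ridx, ctx][tr] - ybar
        info[[ctx]] <- list(te = te, mu = mu, ybar = ybar, Xc = Xc, ridx = ridx)
      }
      # looser tolerance inside CV; the final fit uses the full tolerance
      fit <- suppressWarnings(
        gl_path_cpp(Xtr, ytr, lambdas, max(tol, 1e-4), as.integer(maxit)))
      for (ci in seq_along(ctxs)) {
        ctx <- ctxs[ci]
        te <- info[[ctx]]$te
        if (!length(te)) next
        yte <- E[info[[ctx]]$ridx, ctx][te]
        for (l in seq_len(nlambda)) {
          pred <- info[[ctx]]$ybar +
            drop(sweep(info[[ctx]]$Xc[te, , drop = FALSE], 2,
                       info[[ctx]]$mu, "-") %*% fit$beta[, ci, l])
          cv_sse[f, l] <- cv_sse[f, l] + sum((yte - pred)^2)
          preval[[ctx]][te, l] <- pred
        }
        cv_n[f] <- cv_n[f] + length(te)
      }
    }
    mse <- colSums(cv_sse) / sum(cv_n)
    lbest <- which.min(mse)
    final <- suppressWarnings(
      gl_path_cpp(X_all, y_all, lambdas[seq_len(lbest)], tol,
                  as.integer(maxit)))
    bstd <- final$beta[, , lbest, drop = TRUE]
    if (is.null(dim(bstd))) bstd <- matrix(bstd, ncol = length(ctxs))
    # back-transform to dosage scale
    bdos <- bstd / std$sd
    dimnames(bdos) <- list(colnames(G), ctxs)
    intercepts <- cv_r2 <- cv_adj_r2 <- lrt_p <-
      setNames(rep(NA_real_, length(ctxs)), ctxs)
    for (ci in seq_along(ctxs)) {
      ctx <- ctxs[ci]
      ridx <- idx_list[[ctx]]
      intercepts[ctx] <- mean(E[ridx, ctx]) -
        sum(bdos[, ci] * colMeans(G[ridx, , drop = FALSE]))
      pv <- preval[[ctx]][, lbest]
      ok <- is.finite(pv)
      yv <- E[ridx, ctx][ok]
      cv_r2[ctx] <- if (sum(ok) > 3 && sd(pv[ok]) > 1e-12) cor(yv, pv[ok])^2 else 0
      cv_adj_r2[ctx] <- if (sum(ok) > 3) adjusted_r2(yv, pv[ok], p = 1L) else NA
      lrt <- if (sum(ok) > 3) lrt_significance(yv, pv[ok]) else list(p = NA)
      lrt_p[ctx] <- lrt$p
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, context = ctx, model = "grouplasso", n = length(ridx),
        cv_r2 = cv_r2[ctx], cv_adj_r2 = cv_adj_r2[ctx], lrt_p = lrt_p[ctx])
    }
    fits[[g]] <- list(weights = bdos, intercepts = intercepts,
                      lambda = lambdas[lbest], lambda_path = lambdas,
                      cv_mse = mse, cv_r2 = cv_r2, cv_adj_r2 = cv_adj_r2,
                      lrt_p = lrt_p,
                      converged = all(final$converged))
  }
  structure(list(method = "grouplasso", genes = fits,
                 contexts = study$contexts,
                 summary = do.call(rbind, rows)),
            class = "grouplasso_models")
}

#' @export
print.grouplasso_models <- function(x, ...) {
  cat("grouplasso_models:", length(x$genes), "genes\n")
  invisible(x)
}

#' Per-context expression predictions on new genotypes
#'
#' Dispatches over the trained-model classes of the package: the CONTENT
#' full model, the context-by-context elastic net, or the joint
#' group-LASSO fit. Returns, per gene, an individuals x contexts matrix of
#' predicted expression (`NA` where no model was fitted).
#'
#' @param models a trained model object.
#' @param geno named per-gene list of dosage matrices.
#' @export
predict_contexts <- function(models, geno) UseMethod("predict_contexts")

#' @export
predict_contexts.content_models <- function(models, geno) {
  if (models$method == "content") {
    comps <- predict_components(models, geno)
    return(lapply(comps, `[[`, "full"))
  }
  out <- list()
  for (g in names(models$genes)) {
    G <- geno[[g]]
    pred <- matrix(NA_real_, nrow(G), length(models$contexts),
                   dimnames = list(rownames(G), models$contexts))
    for (ctx in names(models$genes[[g]]$fits))
      pred[, ctx] <- predict(models$genes[[g]]$fits[[ctx]], G)
    out[[g]] <- pred
  }
  out
}

#' @export
predict_contexts.grouplasso_models <- function(models, geno) {
  out <- list()
  for (g in names(models$genes)) {
    G <- geno[[g]]
    mg <- models$genes[[g]]
    pred <- matrix(NA_real_, nrow(G), length(models$contexts),
                   dimnames = list(rownames(G), models$contexts))
    for (ctx in colnames(mg$weights))
      pred[, ctx] <- mg$intercepts[ctx] + drop(G %*% mg$weights[, ctx])
    out[[g]] <- pred
  }
  out
}
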