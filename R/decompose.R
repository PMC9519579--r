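#' Residualize expression on per-context covariates
#'
#' Replaces each gene-context expression vector by its ordinary least
#' squares residuals on that context's covariates (plus an intercept),
#' dropping constant and collinear covariate columns with a warning.
#'
#' @param study a [content_study()] with a `covariates` list.
#' @return the study with residualized expression (covariates removed).
#' @export
residualize <- function(study) {
  if (is.null(study$covariates)) return(study)
  for (ctx in names(study$covariates)) {
    Z <- as.matrix(study$covariates[[ctx]])
    storage.mode(Z) <- "double"
    for (g in study$genes) {
      E <- study$expr[[g]]
      idx <- observed_idx(E, ctx)
      if (!length(idx)) next
      ids <- rownames(E)[idx]
      if (!all(ids %in% rownames(Z)))
        stop("covariates for context ", ctx, " are missing individuals")
      Zi <- Z[ids, , drop = FALSE]
      keep <- apply(Zi, 2, sd) > 1e-12
      Zi <- Zi[, keep, drop = FALSE]
      if (ncol(Zi)) {
        q <- qr(cbind(1, Zi))
        if (q$rank < ncol(Zi) + 1) {
          warning("context ", ctx, ": collinear covariates dropped")
          pick <- q$pivot[seq_len(q$rank)]
          q <- qr(cbind(1, Zi)[, pick, drop = FALSE])
        }
        if (length(idx) <= q$rank)
          stop("context ", ctx, ": more covariates than observations")
        study$expr[[g]][idx, ctx] <- qr.resid(q, E[idx, ctx])
      } else {
        study$expr[[g]][idx, ctx] <- E[idx, ctx] - mean(E[idx, ctx])
      }
    }
  }
  study$covariates <- NULL
  study
}

#' Center and scale expression per gene-context
#'
#' Standardizes each gene-context vector over its observed individuals to
#' mean 0 and *population* variance 1 (1/n denominator). Gene-contexts with
#' fewer than 2 observations or zero variance are excluded (set to `NA`)
#' and recorded in the `"excluded"` attribute.
#'
#' @param study a [content_study()].
#' @return the standardized study.
#' @export
center_scale <- function(study) {
  excluded <- data.frame(gene = character(), context = character(),
                         reason = character())
  for (g in study$genes) {
    E <- study$expr[[g]]
    for (ctx in study$contexts) {
      idx <- observed_idx(E, ctx)
      if (length(idx) < 2) {
        if (length(idx)) study$expr[[g]][idx, ctx] <- NA
        excluded <- rbind(excluded, data.frame(gene = g, context = ctx,
                                               reason = "fewer than 2 observations"))
        next
      }
      v <- E[idx, ctx]
      s <- pop_sd(v)
      if (s < 1e-12) {
        study$expr[[g]][idx, ctx] <- NA
        excluded <- rbind(excluded, data.frame(gene = g, context = ctx,
                                               reason = "zero variance"))
        next
      }
      study$expr[[g]][idx, ctx] <- (v - mean(v)) / s
    }
  }
  attr(study, "excluded") <- excluded
  attr(study, "scaled") <- TRUE
  study
}

#' Decompose expression into context-shared and context-specific components
#'
#' For each individual, the shared component is the mean of the (centered,
#' scaled) expression over that individual's observed contexts; each
#' specific component is the deviation of the observed context value from
#' this mean. Individuals observed in a single context have a specific
#' component of exactly zero. When `study$groups` assigns contexts to
#' groups (or `groups` is supplied), an intermediate group-shared component
#' is extracted: the individual's mean over observed contexts of the group
#' minus the overall shared component, with the specific component then
#' taken relative to shared + group-shared. Groups with fewer than 2
#' contexts are collapsed (flagged) since their group component would be
#' indistinguishable from a specific component.
#'
#' @param study a centered/scaled [content_study()].
#' @param groups optional named character vector (context -> group)
#'   overriding `study$groups`.
#' @return `content_decomposition`: per gene, `shared` (named vector over
#'   individuals with at least one observation), `specific` (individuals x
#'   contexts, `NA` when unobserved) and optionally `group_shared`
#'   (individuals x groups).
#' @export
decompose_expression <- function(study, groups = NULL) {
  groups <- groups %||% study$groups
  if (!is.null(groups)) {
    tab <- table(groups)
    singleton <- names(tab)[tab < 2]
    if (length(singleton)) {
      warning("singleton context group(s) collapsed: ",
              paste(singleton, collapse = ", "))
      groups <- groups[!groups %in% singleton]
      if (!length(unique(groups))) groups <- NULL
    }
  }
  out <- list()
  for (g in study$genes) {
    E <- study$expr[[g]]
    obs <- !is.na(E)
    keep <- rowSums(obs) > 0
    Em <- E[keep, , drop = FALSE]
    shared <- rowMeans(Em, na.rm = TRUE)
    specific <- Em - shared
    gs <- NULL
    if (!is.null(groups)) {
      gnames <- unique(groups)
      gs <- matrix(NA_real_, nrow(Em), length(gnames),
                   dimnames = list(rownames(Em), gnames))
      for (gr in gnames) {
        ctx <- names(groups)[groups == gr]
        sub <- Em[, ctx, drop = FALSE]
        any_obs <- rowSums(!is.na(sub)) > 0
        gmean <- rowMeans(sub, na.rm = TRUE)
        gs[any_obs, gr] <- gmean[any_obs] - shared[any_obs]
        specific[any_obs, ctx] <- sub[any_obs, , drop = FALSE] -
          shared[any_obs] - gs[any_obs, gr]
      }
    }
    out[[g]] <- list(shared = shared, specific = specific, group_shared = gs)
  }
  structure(list(genes = out, contexts = study$contexts, groups = groups),
            class = "content_decomposition")
}

#' Residualize, scale and decompose in one step
#'
#' Convenience pipeline: [residualize()] (if covariates are present), then
#' [center_scale()], then [decompose_expression()].
#'
#' @inheritParams decompose_expression
#' @return list with the prepared `study` and its `decomposition`.
#' @export
prepare_and_decompose <- function(study, groups = NULL) {
  study <- residualize(study)
  study <- center_scale(study)
  list(study = study, decomposition = decompose_expression(study, groups))
}
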