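#' @name io_tables
#' @title Tab-separated readers and writers
#'
#' @description All external tables are TSV with fixed lowercase headers.
#' Expression is long format (`gene  context  individual  value`);
#' genotypes are one file per gene (`individual` column plus one 0/1/2
#' column per SNP id); weight tables have the header
#' `gene context model snp a1 a2 weight`; model summaries have
#' `gene context model n cv_r2 cv_adj_r2 lrt_p`. Write-then-read
#' round-trips are exact for integers and strings and within 1e-12 for
#' floats.
NULL

MODEL_LABELS <- c("shared", "specific", "full", "group", "cbc", "grouplasso")

fread_checked <- function(file, required) {
  if (!file.exists(file)) stop("no such file: ", file)
  dt <- tryCatch(
    data.table::fread(file, sep = "\t", header = TRUE, data.table = FALSE),
    error = function(e) stop("parse error in ", file, ": ", conditionMessage(e)))
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop("malformed header in ", file, ": missing column(s) ",
         paste(miss, collapse = ", "))
  dt
}

#' @rdname io_tables
#' @param study a [content_study()].
#' @param file path of the TSV to read or write.
#' @export
write_expression_tsv <- function(study, file) {
  rows <- list()
  for (g in study$genes) {
    E <- study$expr[[g]]
    obs <- which(!is.na(E), arr.ind = TRUE)
    rows[[g]] <- data.frame(gene = g,
                            context = colnames(E)[obs[, 2]],
                            individual = rownames(E)[obs[, 1]],
                            value = E[obs])
  }
  data.table::fwrite(do.call(rbind, rows), file, sep = "\t")
  invisible(file)
}

#' @rdname io_tables
#' @export
read_expression_tsv <- function(file) {
  fread_checked(file, c("gene", "context", "individual", "value"))
}

#' @rdname io_tables
#' @param geno named per-gene list of dosage matrices.
#' @param dir output directory (one `<gene>.geno.tsv` per gene).
#' @export
write_genotypes_tsv <- function(geno, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(geno)) {
    df <- data.frame(individual = rownames(geno[[g]]), geno[[g]],
                     check.names = FALSE)
    data.table::fwrite(df, file.path(dir, paste0(g, ".geno.tsv")), sep = "\t")
  }
  invisible(dir)
}

#' @rdname io_tables
#' @export
read_genotypes_tsv <- function(file) {
  df <- fread_checked(file, "individual")
  G <- as.matrix(df[, setdiff(names(df), "individual"), drop = FALSE])
  rownames(G) <- df$individual
  if (any(!G[is.finite(G)] %in% 0:2))
    stop("parse error in ", file, ": dosages must be 0/1/2")
  storage.mode(G) <- "double"
  G
}

#' Read genotype dosages from a VCF
#'
#' Converts diploid GT fields to 0/1/2 dosages (count of ALT alleles).
#' Individuals with any missing genotype in the file are excluded.
#'
#' @param file VCF path (uncompressed or gzipped).
#' @return dosage matrix individuals x SNPs.
#' @export
read_genotypes_vcf <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- apply(gt, c(1, 2), function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  G <- t(dosage)
  keep <- rowSums(is.na(G)) == 0
  G[keep, , drop = FALSE]
}

#' @rdname io_tables
#' @param weights weight table from [export_weights()].
#' @export
write_weights_tsv <- function(weights, file) {
  stopifnot(identical(names(weights),
                      c("gene", "context", "model", "snp", "a1", "a2", "weight")))
  data.table::fwrite(weights, file, sep = "\t")
  invisible(file)
}

#' @rdname io_tables
#' @export
read_weights_tsv <- function(file) {
  w <- fread_checked(file, c("gene", "context", "model", "snp", "a1", "a2",
                             "weight"))
  bad <- setdiff(unique(w$model), MODEL_LABELS)
  if (length(bad))
    stop("parse error in ", file, ": unknown model label(s) ",
         paste(bad, collapse = ", "))
  w
}

#' @rdname io_tables
#' @param models a trained model object with a `summary` component.
#' @export
write_summary_tsv <- function(models, file) {
  data.table::fwrite(models$summary, file, sep = "\t")
  invisible(file)
}

#' @rdname io_tables
#' @param truth a `content_truth`.
#' @export
write_truth_tsv <- function(truth, file) {
  rows <- list()
  for (g in names(truth$genes)) {
    tg <- truth$genes[[g]]
    nz <- which(tg$beta_shared != 0)
    if (length(nz))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, component = "shared", snp = names(tg$beta_shared)[nz],
        effect = unname(tg$beta_shared[nz]))
    for (ctx in colnames(tg$beta_specific)) {
      nz <- which(tg$beta_specific[, ctx] != 0)
      if (length(nz))
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, component = ctx,
          snp = rownames(tg$beta_specific)[nz],
          effect = unname(tg$beta_specific[nz, ctx]))
    }
  }
  data.table::fwrite(do.call(rbind, rows), file, sep = "\t")
  invisible(file)
}

#' @rdname io_tables
#' @param expr_long long-format expression data.frame
#'   ([read_expression_tsv()]).
#' @param covariates optional per-context covariate list.
#' @export
assemble_study <- function(expr_long, geno, covariates = NULL) {
  genes <- unique(expr_long$gene)
  contexts <- unique(expr_long$context)
  inds <- rownames(geno[[genes[1]]])
  expr <- list()
  for (g in genes) {
    sub <- expr_long[expr_long$gene == g, ]
    E <- matrix(NA_real_, length(inds), length(contexts),
                dimnames = list(inds, contexts))
    E[cbind(match(sub$individual, inds), match(sub$context, contexts))] <-
      sub$value
    expr[[g]] <- E
  }
  content_study(expr, geno, covariates = covariates)
}

#' @rdname io_tables
#' @param phenotype result of [simulate_phenotype()].
#' @export
write_phenotype_tsv <- function(phenotype, file) {
  data.table::fwrite(data.frame(individual = names(phenotype$y),
                                value = unname(phenotype$y)),
                     file, sep = "\t")
  invisible(file)
}
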