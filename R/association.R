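## Module-trait association: eigengene correlation with the quantitative
## trait, per-gene quantitative-trait-transcript (QTT) analysis, and module
## enrichment for QTT genes.

## Vectorized Spearman correlation + two-sided p of each row of `m` against
## `trait`, using the t approximation on the rank correlation (the same
## approximation cor.test uses for tied/large samples).
.spearmanVsTrait <- function(m, trait) {
  n <- length(trait)
  rt <- rank(trait, ties.method = "average")
  rm_ <- .rowRanks(m)
  rho <- as.numeric(cor(t(rm_), rt))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = pmin(p, 1))
}

.traitSamples <- function(expr, samples = NULL, useCondition = "case") {
  m <- .asExprMatrix(expr)
  if (is.null(samples)) {
    if (!is(expr, "SummarizedExperiment"))
      stop("supply a sample table or a SummarizedExperiment with colData")
    samples <- as.data.frame(SummarizedExperiment::colData(expr))
    samples$sample_id <- colnames(m)
  }
  samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  keep <- !is.na(samples$trait)
  if (!is.null(useCondition) && !is.null(samples$condition))
    keep <- keep & samples$condition %in% useCondition
  if (sum(keep) < 4) stop("need >= 4 samples with a defined trait")
  trait <- samples$trait[keep]
  if (length(unique(trait)) == 1L) stop("trait is constant")
  list(m = m[, keep, drop = FALSE], trait = trait,
       ids = samples$sample_id[keep])
}

#' Eigengene-trait association
#'
#' Spearman correlation of each module eigengene with the quantitative
#' trait, with a two-sided p, BH adjustment across modules, and the
#' fraction of trait variance explained by an ordinary least-squares fit of
#' trait on eigengene (R2_trait; squared Spearman rho is reported alongside
#' since the two summaries answer subtly different questions).
#'
#' @param eigengenes Named list: module label -> result of
#'   [moduleEigengene()] (or a plain numeric vector of per-sample scores).
#' @param samples Sample table with sample_id, condition, trait; or NULL if
#'   the eigengene names align with a SummarizedExperiment passed earlier.
#' @param useCondition Conditions contributing samples (default "case":
#'   the trait is a disease phenotype the controls lack); NULL for all.
#' @return data.frame(module, rho, p, q, R2_trait, rho2, n).
#' @export
eigengeneTrait <- function(eigengenes, samples, useCondition = "case") {
  stopifnot(length(eigengenes) > 0, !is.null(names(eigengenes)))
  vals <- lapply(eigengenes, function(e) if (is.list(e)) e$values else e)
  ids <- names(vals[[1]])
  if (is.null(ids)) stop("eigengene values must be named by sample id")
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  keep <- !is.na(samples$trait)
  if (!is.null(useCondition) && !is.null(samples$condition))
    keep <- keep & samples$condition %in% useCondition
  if (sum(keep) < 4) stop("need >= 4 samples with a defined trait")
  trait <- samples$trait[keep]
  if (length(unique(trait)) == 1L) stop("trait is constant")
  rows <- lapply(names(vals), function(mod) {
    e <- vals[[mod]][keep]
    st <- .spearmanVsTrait(matrix(e, 1), trait)
    r2 <- summary(lm(trait ~ e))$r.squared
    data.frame(module = mod, rho = st$rho, p = st$p, R2_trait = r2,
               rho2 = st$rho^2, n = length(e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjustBH(out$p)
  out[, c("module", "rho", "p", "q", "R2_trait", "rho2", "n")]
}

#' Quantitative-trait-transcript (QTT) analysis
#'
#' Spearman correlation of every gene's expression with the trait, BH
#' adjustment across all tested genes (genome-wide family), and the set of
#' QTT genes at q < threshold.
#'
#' @param expr SummarizedExperiment (condition/trait in colData) or matrix.
#' @param samples Sample table if \code{expr} is a matrix.
#' @param threshold FDR threshold for calling a QTT gene (default 0.05).
#' @param useCondition As in [eigengeneTrait()].
#' @return list(table = data.frame(gene_id, rho, p, q),
#'   qttGenes = character vector, n = samples used).
#' @export
qttAnalysis <- function(expr, samples = NULL, threshold = 0.05,
                        useCondition = "case") {
  ts <- .traitSamples(expr, samples, useCondition)
  st <- .spearmanVsTrait(ts$m, ts$trait)
  tab <- data.frame(gene_id = rownames(ts$m), rho = st$rho, p = st$p,
                    q = adjustBH(st$p), stringsAsFactors = FALSE)
  list(table = tab, qttGenes = tab$gene_id[tab$q < threshold],
       n = length(ts$trait))
}

#' Module enrichment for QTT genes
#'
#' One-sided hypergeometric upper-tail test of the overlap between a
#' module's genes and the QTT gene set within the expressed-gene universe,
#' plus the module's mean gene-level trait correlation.
#'
#' @param moduleGenes Module gene ids (subset of universe).
#' @param qttGenes QTT gene ids (subset of universe).
#' @param universe Expressed-gene universe.
#' @param geneRho Optional named vector of gene-level rho for meanRho.
#' @return list(p, k, n, K, N, meanRho).
#' @export
qttEnrichment <- function(moduleGenes, qttGenes, universe, geneRho = NULL) {
  if (!length(universe)) stop("empty universe")
  moduleGenes <- intersect(moduleGenes, universe)
  qttGenes <- intersect(qttGenes, universe)
  k <- length(intersect(moduleGenes, qttGenes))
  p <- .hyperUpper(k, K = length(qttGenes), N = length(universe),
                   n = length(moduleGenes))
  meanRho <- if (!is.null(geneRho))
    mean(geneRho[intersect(moduleGenes, names(geneRho))]) else NA_real_
  list(p = p, k = k, n = length(moduleGenes), K = length(qttGenes),
       N = length(universe), meanRho = meanRho)
}

#' Module-level trait association report
#'
#' Runs [qttAnalysis()] once and [qttEnrichment()] for every module,
#' BH-adjusting enrichment p across modules — the table behind a
#' volcano-style display of mean gene-trait correlation against enrichment
#' significance.
#'
#' @param expr Expression (case samples carry the trait).
#' @param partition \linkS4class{ModulePartition} or named list.
#' @param samples Sample table if \code{expr} is a matrix.
#' @param threshold QTT FDR threshold.
#' @return list(modules = data.frame(module, size, k, meanRho, enrich_p,
#'   enrich_q), qtt = the gene-level result).
#' @export
moduleTraitEnrichment <- function(expr, partition, samples = NULL,
                                  threshold = 0.05) {
  mods <- if (is(partition, "ModulePartition")) moduleList(partition) else partition
  qtt <- qttAnalysis(expr, samples, threshold)
  universe <- qtt$table$gene_id
  rho <- setNames(qtt$table$rho, qtt$table$gene_id)
  rows <- lapply(names(mods), function(mod) {
    e <- qttEnrichment(mods[[mod]], qtt$qttGenes, universe, rho)
    data.frame(module = mod, size = length(mods[[mod]]), k = e$k,
               meanRho = e$meanRho, enrich_p = e$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enrich_q <- adjustBH(out$enrich_p)
  list(modules = out, qtt = qtt)
}
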