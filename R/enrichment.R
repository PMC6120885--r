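## Gene-set enrichment used across the pipeline: Fisher/hypergeometric
## over-representation for cell-type marker signatures, and the
## literature co-citation test that defines disease-associated genes.

#' Over-representation of annotations in a query gene set
#'
#' One-sided Fisher exact (equivalently hypergeometric upper-tail) test of
#' the overlap between a query set and each annotation set within a
#' universe, BH-adjusted across the annotations. The odds ratio is the
#' sample odds ratio of the 2x2 table; a 0.5 continuity correction is
#' applied only when a margin is zero and only for the reported ratio,
#' never for the p-value.
#'
#' @param query Gene ids (restricted to the universe).
#' @param annotations Named list of annotation gene sets (e.g. cell-type
#'   markers from [readGMT()]).
#' @param universe Background gene ids (e.g. all expressed genes).
#' @return data.frame(annotation, k, n, K, N, oddsRatio, p, q).
#' @export
fisherEnrich <- function(query, annotations, universe) {
  if (!length(universe)) stop("empty universe")
  stopifnot(length(annotations) > 0, !is.null(names(annotations)))
  query <- intersect(query, universe)
  rows <- lapply(names(annotations), function(a) {
    ann <- intersect(annotations[[a]], universe)
    k <- length(intersect(query, ann))
    n <- length(query); K <- length(ann); N <- length(universe)
    tab <- c(k, n - k, K - k, N - n - K + k)
    or <- if (any(tab == 0)) ((tab[1] + 0.5) * (tab[4] + 0.5)) /
      ((tab[2] + 0.5) * (tab[3] + 0.5)) else (tab[1] * tab[4]) / (tab[2] * tab[3])
    data.frame(annotation = a, k = k, n = n, K = K, N = N, oddsRatio = or,
               p = .hyperUpper(k, K, N, n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjustBH(out$p)
  out
}

#' Cell-type enrichment of modules
#'
#' Runs [fisherEnrich()] for every module against a marker-signature
#' collection; BH is applied per module across the cell types (one family
#' per query, stated in the output).
#'
#' @param partition \linkS4class{ModulePartition} or named list of modules.
#' @param markers Named list of cell-type marker sets.
#' @param universe Expressed-gene universe.
#' @return data.frame with a \code{module} column prepended.
#' @export
cellTypeEnrichment <- function(partition, markers, universe) {
  mods <- if (is(partition, "ModulePartition")) moduleList(partition) else partition
  out <- do.call(rbind, lapply(names(mods), function(mod)
    cbind(module = mod, fisherEnrich(mods[[mod]], markers, universe))))
  rownames(out) <- NULL
  out
}

#' Literature co-citation test for disease-associated genes
#'
#' For each gene, an upper-tail hypergeometric test of k_gene gene-disease
#' co-citation abstracts among n_gene gene-citing abstracts, drawn from a
#' corpus of N_total abstracts of which K_disease co-cite any gene with the
#' disease. Genes at BH q < threshold form the disease gene set.
#'
#' @param cites Citation table from [readCitationTable()] /
#'   [citationTable()].
#' @param threshold FDR threshold (default 0.05).
#' @return list(table = data.frame(gene_id, n_gene, k_gene, p, q),
#'   diseaseGenes = character vector).
#' @export
literatureGeneTest <- function(cites, threshold = 0.05) {
  g <- cites$genes
  p <- .hyperUpper(g$k_gene, K = cites$K_disease, N = cites$N_total,
                   n = g$n_gene)
  tab <- data.frame(g, p = p, q = adjustBH(p), stringsAsFactors = FALSE)
  list(table = tab, diseaseGenes = tab$gene_id[tab$q < threshold])
}

#' Module enrichment for literature disease genes
#'
#' Ranks modules by hypergeometric enrichment of the disease gene set
#' (single annotation, BH across modules).
#'
#' @param partition \linkS4class{ModulePartition} or named list.
#' @param diseaseGenes Disease-associated genes from [literatureGeneTest()].
#' @param universe Universe (expressed genes with at least one abstract).
#' @return data.frame(module, k, n, K, N, oddsRatio, p, q) ordered by p.
#' @export
literatureModuleEnrichment <- function(partition, diseaseGenes, universe) {
  mods <- if (is(partition, "ModulePartition")) moduleList(partition) else partition
  rows <- lapply(names(mods), function(mod) {
    r <- fisherEnrich(mods[[mod]], list(disease = diseaseGenes), universe)
    data.frame(module = mod, r[, c("k", "n", "K", "N", "oddsRatio", "p")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjustBH(out$p)
  out[order(out$p), ]
}
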