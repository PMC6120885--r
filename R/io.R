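## Readers/writers for the plain-text formats the pipeline consumes, plus the
## expression filter. Expression lives in a SummarizedExperiment (assay
## "exprs", genes as rows); sample metadata in colData. Gene ids are opaque,
## case-sensitive strings throughout.

.asExprMatrix <- function(expr) {
  if (is(expr, "SummarizedExperiment"))
    expr <- SummarizedExperiment::assay(expr, 1)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene rownames and sample colnames")
  expr
}

.validateExprMatrix <- function(m, where = "expression") {
  dupg <- rownames(m)[duplicated(rownames(m))]
  if (length(dupg))
    stop(sprintf("duplicate gene id(s) in %s: %s", where,
                 paste(unique(dupg), collapse = ", ")))
  dups <- colnames(m)[duplicated(colnames(m))]
  if (length(dups))
    stop(sprintf("duplicate sample id(s) in %s: %s", where,
                 paste(unique(dups), collapse = ", ")))
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value in %s at gene '%s', sample '%s'", where,
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  invisible(m)
}

#' Read a log-expression matrix
#'
#' Reads a TSV (or CSV) with a header row of sample ids and gene ids in the
#' first column, and returns a validated
#' \linkS4class{SummarizedExperiment} with one assay \code{"exprs"}.
#' Values are expected to be on a log scale (e.g. log2 FPKM); the package
#' never re-normalizes.
#'
#' @param path File path.
#' @param sep Field separator, default tab.
#' @return SummarizedExperiment, genes as rows.
#' @export
readExpression <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene-id column plus samples")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric expression value at row %d, column '%s' of %s",
                   bad[1, 1], colnames(df)[-1][bad[1, 2]], path))
    stop("non-numeric expression values in ", path)
  }
  rownames(m) <- genes
  .validateExprMatrix(m, path)
  SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
}

#' Write an expression matrix as TSV
#'
#' @param expr SummarizedExperiment or matrix.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeExpression <- function(expr, path) {
  m <- .asExprMatrix(expr)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table
#'
#' TSV with columns \code{sample_id}, \code{condition} (\code{case} or
#' \code{control}) and optional \code{trait} (a non-negative quantitative
#' phenotype such as daily seizure frequency; may be missing for samples
#' never used in trait association).
#'
#' @param path File path.
#' @return data.frame with columns sample_id, condition, trait.
#' @export
readSampleTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("sample table needs columns sample_id, condition")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad))
    stop("condition must be 'case' or 'control'; got: ",
         paste(bad, collapse = ", "))
  if (is.null(df$trait)) df$trait <- NA_real_
  df$trait <- as.numeric(df$trait)
  if (any(df$trait < 0, na.rm = TRUE)) stop("trait values must be non-negative")
  df[, c("sample_id", "condition", "trait")]
}

#' Attach sample metadata to an expression container
#'
#' @param expr SummarizedExperiment from [readExpression()].
#' @param samples data.frame from [readSampleTable()].
#' @return SummarizedExperiment with condition/trait in colData; samples are
#'   matched by id and must cover all expression columns.
#' @export
attachSamples <- function(expr, samples) {
  m <- .asExprMatrix(expr)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from sample table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    colData = S4Vectors::DataFrame(samples[idx, , drop = FALSE],
                                   row.names = colnames(m)))
}

#' Filter to expressed genes
#'
#' Retains genes whose value exceeds \code{threshold} (strictly) in at least
#' \code{ceiling(minFraction * n_samples)} samples — the "expressed in at
#' least 5\% of samples" rule with \code{threshold = 0},
#' \code{minFraction = 0.05} on log2 FPKM data.
#'
#' @param expr SummarizedExperiment or matrix.
#' @param threshold Expression must be strictly greater than this.
#' @param minFraction Fraction of samples required, in \[0, 1\].
#' @return Same container type, rows subset; warns if nothing survives.
#' @examples
#' m <- matrix(c(0, 0, 1, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rownames(filterExpressed(m, 0, 0.5))
#' @export
filterExpressed <- function(expr, threshold = 0, minFraction = 0.05) {
  stopifnot(minFraction >= 0, minFraction <= 1)
  m <- .asExprMatrix(expr)
  need <- ceiling(minFraction * ncol(m))
  keep <- rowSums(m > threshold) >= need
  if (!any(keep)) warning("no genes pass the expression filter")
  if (is(expr, "SummarizedExperiment")) expr[keep, ] else m[keep, , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated name, description, gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors; names unique, sets non-empty.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path)
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  sets
}

#' Write a GMT gene-set collection
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @export
writeGMT <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[[(i - 1) %% length(description) + 1]],
            sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed regulome edge list
#'
#' TSV with columns \code{source}, \code{target}, \code{layer}
#' (\code{receptor_tf} or \code{tf_target}) and \code{sign} (\code{act},
#' \code{inh}, \code{unk}). Exact duplicate rows collapse to one edge; a
#' pair carrying both act and inh keeps both signed edges so the causal
#' engine sees the conflict.
#'
#' @param path File path.
#' @return A \linkS4class{Regulome}.
#' @export
readRegulome <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "layer", "sign")
  if (!all(need %in% names(df)))
    stop("regulome file needs columns source, target, layer, sign")
  badl <- setdiff(unique(df$layer), REG_LAYERS)
  if (length(badl))
    stop("unknown layer token(s): ", paste(badl, collapse = ", "),
         "; allowed: ", paste(REG_LAYERS, collapse = ", "))
  bads <- setdiff(unique(df$sign), REG_SIGNS)
  if (length(bads))
    stop("unknown sign token(s): ", paste(bads, collapse = ", "),
         "; allowed: ", paste(REG_SIGNS, collapse = ", "))
  Regulome(receptorTF = df[df$layer == "receptor_tf", c("source", "target", "sign")],
           tfTarget   = df[df$layer == "tf_target",  c("source", "target", "sign")])
}

#' Write a Regulome as a 4-column TSV
#' @param reg A Regulome.
#' @param path Output path.
#' @export
writeRegulome <- function(reg, path) {
  stopifnot(is(reg, "Regulome"))
  a <- regulomeEdges(reg, "receptor_tf"); b <- regulomeEdges(reg, "tf_target")
  df <- rbind(if (nrow(a)) cbind(a, layer = "receptor_tf") else NULL,
              if (nrow(b)) cbind(b, layer = "tf_target") else NULL)
  df <- df[, c("source", "target", "layer", "sign")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with columns \code{gene_id}, \code{direction} (\code{over},
#' \code{under} or \code{none}), \code{q} (BH-adjusted significance) and
#' optional \code{effect} (signed log fold change). One row per gene.
#'
#' @param path File path.
#' @return data.frame(gene_id, direction, q, effect).
#' @export
readDETable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction", "q") %in% names(df)))
    stop("DE table needs columns gene_id, direction, q")
  if (anyDuplicated(df$gene_id))
    stop("DE table has more than one row for gene(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- setdiff(unique(df$direction), c("over", "under", "none"))
  if (length(bad))
    stop("direction must be over/under/none; got: ", paste(bad, collapse = ", "))
  df$q <- as.numeric(df$q)
  if (any(df$q < 0 | df$q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]")
  if (is.null(df$effect)) df$effect <- NA_real_
  df[, c("gene_id", "direction", "q", "effect")]
}

#' Write a DE table
#' @param de data.frame as returned by [readDETable()] or [rankSumDE()].
#' @param path Output path.
#' @export
writeDETable <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Nonparametric stand-in differential expression
#'
#' Two-sided Wilcoxon rank-sum test per gene between case and control
#' columns, BH-adjusted, calling direction over/under at \code{q <= alpha}.
#' A documented stand-in for model-based DE fitting, used when no external
#' DE table is supplied.
#'
#' @param expr SummarizedExperiment with condition in colData, or matrix.
#' @param condition Condition labels if \code{expr} is a matrix.
#' @param alpha FDR threshold for calling a direction (default 0.05).
#' @return data.frame(gene_id, direction, q, effect); effect is the
#'   case-minus-control difference of means (log-scale).
#' @export
rankSumDE <- function(expr, condition = NULL, alpha = 0.05) {
  m <- .asExprMatrix(expr)
  if (is.null(condition)) {
    if (!is(expr, "SummarizedExperiment") ||
        is.null(SummarizedExperiment::colData(expr)$condition))
      stop("supply condition labels or a SummarizedExperiment with colData$condition")
    condition <- SummarizedExperiment::colData(expr)$condition
  }
  stopifnot(length(condition) == ncol(m))
  isCase <- condition == "case"
  if (!any(isCase) || all(isCase)) stop("need both case and control samples")
  p <- apply(m, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[isCase], x[!isCase])$p.value))
  q <- adjustBH(p)
  eff <- rowMeans(m[, isCase, drop = FALSE]) - rowMeans(m[, !isCase, drop = FALSE])
  dir <- ifelse(q <= alpha, ifelse(eff > 0, "over", "under"), "none")
  data.frame(gene_id = rownames(m), direction = dir, q = q, effect = eff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a one-to-one ortholog map
#'
#' Two-column TSV (source gene id, target gene id). The mapping must be
#' one-to-one on the mapped subset: no source and no target appears twice.
#'
#' @param path File path.
#' @return Named character vector, names = source ids, values = target ids.
#' @export
readOrthologMap <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  src <- as.character(df[[1]]); tgt <- as.character(df[[2]])
  if (anyDuplicated(src))
    stop("ortholog map is not one-to-one: duplicated source id(s): ",
         paste(unique(src[duplicated(src)]), collapse = ", "))
  if (anyDuplicated(tgt))
    stop("ortholog map is not one-to-one: duplicated target id(s): ",
         paste(unique(tgt[duplicated(tgt)]), collapse = ", "))
  setNames(tgt, src)
}

#' Map a gene set through a one-to-one ortholog map
#'
#' Unmapped genes are dropped; the number dropped is attached as attribute
#' \code{"n_dropped"}.
#'
#' @param genes Character vector of gene ids.
#' @param map Named character vector from [readOrthologMap()].
#' @return Character vector of mapped target ids.
#' @examples
#' applyOrthologMap(c("a", "b"), c(a = "A"))
#' @export
applyOrthologMap <- function(genes, map) {
  hit <- genes %in% names(map)
  out <- unname(map[genes[hit]])
  attr(out, "n_dropped") <- sum(!hit)
  out
}

#' Read a citation-count table
#'
#' TSV with per-gene columns \code{gene_id}, \code{n_gene} (abstracts citing
#' the gene) and \code{k_gene} (abstracts co-citing the gene and the
#' disease). The corpus-wide totals are supplied as arguments or as
#' columns \code{N_total} / \code{K_disease} (constant across rows).
#'
#' @param path File path.
#' @param nTotal Abstracts with at least one gene citation (corpus size).
#' @param kDisease Abstracts with at least one gene-disease co-citation.
#' @return list(genes = data.frame(gene_id, n_gene, k_gene),
#'   N_total, K_disease).
#' @export
readCitationTable <- function(path, nTotal = NULL, kDisease = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "n_gene", "k_gene") %in% names(df)))
    stop("citation table needs columns gene_id, n_gene, k_gene")
  if (is.null(nTotal)) nTotal <- unique(df$N_total)
  if (is.null(kDisease)) kDisease <- unique(df$K_disease)
  if (length(nTotal) != 1 || length(kDisease) != 1 || is.null(nTotal))
    stop("supply scalar N_total and K_disease (argument or constant column)")
  citationTable(df[, c("gene_id", "n_gene", "k_gene")], nTotal, kDisease)
}

#' Assemble and validate a citation table
#' @param genes data.frame(gene_id, n_gene, k_gene).
#' @param nTotal,kDisease Corpus-wide totals.
#' @return list(genes, N_total, K_disease), validated.
#' @export
citationTable <- function(genes, nTotal, kDisease) {
  stopifnot(all(c("gene_id", "n_gene", "k_gene") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene id in citation table")
  with(genes, {
    if (any(k_gene < 0 | k_gene > n_gene))
      stop("need 0 <= k_gene <= n_gene for every gene")
    if (any(n_gene > nTotal)) stop("n_gene exceeds N_total")
  })
  if (kDisease > nTotal) stop("K_disease exceeds N_total")
  list(genes = genes[, c("gene_id", "n_gene", "k_gene")],
       N_total = as.numeric(nTotal), K_disease = as.numeric(kDisease))
}
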