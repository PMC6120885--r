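## Module discovery: Spearman distance -> Ward dendrogram -> scan of nested
## cuts scored by the distance-based R^2 = BSS/(BSS+WSS) and the
## Calinski-Harabasz pseudo F-index -> K selection by elbow / pseudo-F ->
## module eigengenes.

#' Spearman distance matrix between genes
#'
#' d_ij = 1 - rho_ij where rho is the Spearman rank correlation of the two
#' genes' expression across samples (average ranks on ties). d is symmetric
#' with zero diagonal and values in \[0, 2\].
#'
#' @param expr SummarizedExperiment or genes-by-samples matrix; >= 3 samples.
#' @return Symmetric numeric matrix with gene dimnames.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 3, 2, 4))
#' colnames(m) <- paste0("s", 1:4)
#' spearmanDistance(m)["g1", "g2"]  # 1 - 0.8
#' @export
spearmanDistance <- function(expr) {
  m <- .asExprMatrix(expr)
  if (ncol(m) < 3) stop("need at least 3 samples for rank correlation")
  const <- apply(m, 1, function(x) length(unique(x)) == 1L)
  if (any(const))
    stop("constant gene(s) have no rank variance: ",
         paste(rownames(m)[const], collapse = ", "))
  d <- 1 - cor(t(.rowRanks(m)))
  d[d < 0] <- 0           # clip numerical noise at the rho = 1 boundary
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a gene distance matrix
#'
#' Agglomerates genes under Ward's minimum-variance criterion applied to the
#' supplied distances (squared internally, i.e. \code{hclust} method
#' \code{"ward.D2"}), so the objective being greedily minimized is the same
#' sum-of-squared-distances quantity the partition scan scores.
#'
#' @param dist Symmetric distance matrix from [spearmanDistance()].
#' @return An \code{hclust} merge tree.
#' @export
wardCluster <- function(dist) {
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(dist) < 2) stop("need at least 2 genes to cluster")
  hclust(as.dist(dist), method = "ward.D2")
}

#' Cut a merge tree into a ModulePartition
#'
#' @param tree hclust tree from [wardCluster()].
#' @param k Number of modules.
#' @param prefix Module label prefix (labels are prefix + integer).
#' @return A \linkS4class{ModulePartition}.
#' @export
cutPartition <- function(tree, k, prefix = "M") {
  cl <- cutree(tree, k = k)
  ModulePartition(setNames(paste0(prefix, cl), names(cl)))
}

## Within-cluster sum of squares from distances only:
##   WSS_c = sum_{i<j in c} d_ij^2 / n_c
## which equals the centroid sum of squares when d is Euclidean-embeddable.
.wssFromD2 <- function(d2, membership) {
  vapply(split(seq_along(membership), membership), function(idx) {
    if (length(idx) < 2) return(0)
    sum(d2[idx, idx]) / (2 * length(idx))
  }, 0)
}

#' Score nested partitions of a merge tree
#'
#' For each K in \code{kMin:kMax}, cuts the tree and computes the
#' within-group sum of squares from the distance matrix alone via
#' WSS_c = (1/n_c) * sum over pairs in c of d^2, the total sum of squares
#' TSS the same way over all genes, BSS = TSS - WSS, the percentage of
#' variance explained R^2 = BSS/(BSS+WSS) and the Calinski-Harabasz pseudo
#' F-index (BSS/(K-1)) / (WSS/(n-K)).
#'
#' @param tree hclust tree.
#' @param dist Distance matrix the tree was built from.
#' @param kMin,kMax Range of cluster counts (2 <= kMin <= kMax <= n genes).
#' @return data.frame(K, R2, BSS, WSS, pseudoF).
#' @export
scanPartitions <- function(tree, dist, kMin = 2, kMax = min(300, nrow(dist))) {
  n <- nrow(dist)
  if (kMax > n) stop("kMax exceeds the number of genes")
  stopifnot(kMin >= 2, kMin <= kMax)
  d2 <- dist^2
  tss <- sum(d2) / (2 * n)
  cuts <- cutree(tree, k = kMin:kMax)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  res <- lapply(seq_len(ncol(cuts)), function(j) {
    wss <- sum(.wssFromD2(d2, cuts[, j]))
    k <- (kMin:kMax)[j]
    bss <- tss - wss
    data.frame(K = k, R2 = bss / tss, BSS = bss, WSS = wss,
               pseudoF = if (k < n) (bss / (k - 1)) / (wss / (n - k)) else NA_real_)
  })
  do.call(rbind, res)
}

#' Select the number of modules from partition scores
#'
#' \code{"pseudoF"} takes the K maximizing the pseudo F-index.
#' \code{"elbow"} takes the smallest K after which the marginal gain in R^2
#' stays below \code{elbowFraction} of the total R^2 range for
#' \code{elbowWindow} consecutive steps (the plateau of the variance-
#' explained curve). \code{"consensus"} requires the two to agree within
#' \code{tolerance}; on agreement it returns the elbow K, otherwise it
#' errors carrying both candidates (or returns the elbow K when
#' \code{force = TRUE}).
#'
#' @param scores data.frame from [scanPartitions()] over a contiguous K range.
#' @param method "elbow", "pseudoF" or "consensus".
#' @param elbowFraction Plateau threshold as a fraction of the R^2 range.
#' @param elbowWindow Consecutive sub-threshold steps required.
#' @param tolerance Maximum |K_elbow - K_pseudoF| for consensus.
#' @param force Return the elbow K on consensus disagreement instead of
#'   erroring.
#' @return Selected K (integer), with attribute \code{"candidates"}.
#' @export
selectK <- function(scores, method = c("consensus", "elbow", "pseudoF"),
                    elbowFraction = 0.01, elbowWindow = 3, tolerance = 2,
                    force = FALSE) {
  method <- match.arg(method)
  stopifnot(all(diff(scores$K) == 1))
  if (nrow(scores) == 1) {
    warning("degenerate K range; returning its single value")
    return(structure(scores$K, candidates = c(elbow = scores$K,
                                              pseudoF = scores$K)))
  }
  kF <- scores$K[which.max(scores$pseudoF)]
  gain <- diff(scores$R2)
  rng <- max(scores$R2) - min(scores$R2)
  thr <- elbowFraction * if (rng > 0) rng else 1
  below <- gain < thr
  kE <- scores$K[nrow(scores)]   # fall back to the last K if no plateau
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= min(elbowWindow, length(below))) {
      kE <- scores$K[i - run + 1L]  # first K whose following gains plateau
      break
    }
  }
  cand <- c(elbow = kE, pseudoF = kF)
  k <- switch(method,
    pseudoF = kF,
    elbow = kE,
    consensus = {
      if (abs(kE - kF) > tolerance && !force)
        stop(sprintf(paste0("elbow (K = %d) and pseudo-F (K = %d) disagree ",
                            "beyond tolerance %d; inspect the score curve or ",
                            "rerun with force = TRUE"), kE, kF, tolerance))
      kE
    })
  if (k == min(scores$K) || k == max(scores$K))
    warning("selected K lies on the scan boundary; selection may be unstable")
  structure(as.integer(k), candidates = cand)
}

#' Module eigengene
#'
#' The first principal component of the module's standardized expression:
#' each member gene is centred and scaled to unit variance across samples,
#' and the first right singular vector of the resulting genes-by-samples
#' matrix gives one score per sample. The sign is oriented so that the
#' eigengene correlates non-negatively with the module's mean standardized
#' expression profile.
#'
#' @param expr SummarizedExperiment or matrix containing the module genes.
#' @param genes Character vector of module gene ids (>= 2).
#' @return list(values = named numeric per sample, varianceExplained =
#'   fraction of module variance carried by the first component).
#' @export
moduleEigengene <- function(expr, genes) {
  m <- .asExprMatrix(expr)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("module gene(s) absent from expression: ",
         paste(missing, collapse = ", "))
  if (length(genes) < 2) stop("a module needs at least 2 genes")
  x <- m[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  if (any(sds == 0))
    stop("constant gene(s) in module: ",
         paste(genes[sds == 0], collapse = ", "))
  z <- (x - rowMeans(x)) / sds
  sv <- svd(z, nu = 1, nv = 1)
  e <- sv$v[, 1]
  ref <- colMeans(z)
  flip <- if (sd(ref) > 0) cor(e, ref) < 0 else sum(sv$u[, 1]) < 0
  if (isTRUE(flip)) e <- -e
  list(values = setNames(e, colnames(m)),
       varianceExplained = sv$d[1]^2 / sum(sv$d^2))
}
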