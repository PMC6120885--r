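## Differential co-expression: the statistic D is the Euclidean distance
## between the vectors of within-module pairwise Spearman correlations
## computed in each condition separately; its null distribution is built by
## redrawing random same-size gene sets from the expressed-gene pool.

#' Within-set pairwise Spearman correlation profile
#'
#' Correlations for all gene pairs i < j of \code{genes} in the fixed
#' column-major upper-triangle order (1,2), (1,3), (2,3), (1,4), ...
#'
#' @param expr SummarizedExperiment or matrix.
#' @param genes Ordered character vector of gene ids (>= 2).
#' @return Numeric vector of length choose(|genes|, 2), named "g_i|g_j".
#' @export
coexprProfile <- function(expr, genes) {
  m <- .asExprMatrix(expr)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("gene(s) absent from expression: ", paste(missing, collapse = ", "))
  if (length(genes) < 2) stop("need at least 2 genes")
  r <- cor(t(.rowRanks(m[genes, , drop = FALSE])))
  pr <- .upperPairs(length(genes))
  setNames(r[upper.tri(r)], paste(genes[pr[, 1]], genes[pr[, 2]], sep = "|"))
}

#' Differential co-expression statistic D
#'
#' D = sqrt(sum over pairs of (r_A - r_B)^2): the Euclidean distance between
#' the two conditions' pairwise-correlation profiles on an identical pair
#' ordering.
#'
#' @param exprA,exprB Expression for the two conditions (same genes present).
#' @param genes Module gene ids.
#' @return Non-negative scalar D.
#' @export
diffCoexprStat <- function(exprA, exprB, genes) {
  a <- coexprProfile(exprA, genes)
  b <- coexprProfile(exprB, genes)
  sqrt(sum((a - b)^2))
}

## Shared engine: observed D plus B null Ds from random same-size gene sets
## drawn (without replacement) from `pool`. Correlation matrices over the
## pool are precomputed once when the pool is small enough, making each
## null draw an O(|genes|^2) lookup.
.nullD <- function(rankedA, rankedB, genes, pool, B, precomputeLimit = 4000L) {
  mA <- rankedA[pool, , drop = FALSE]; mB <- rankedB[pool, , drop = FALSE]
  k <- length(genes)
  if (length(pool) <= precomputeLimit) {
    cA <- cor(t(mA)); cB <- cor(t(mB))
    dOf <- function(sel) {
      da <- cA[sel, sel]; db <- cB[sel, sel]
      sqrt(sum((da[upper.tri(da)] - db[upper.tri(db)])^2))
    }
  } else {
    dOf <- function(sel) {
      da <- cor(t(mA[sel, , drop = FALSE])); db <- cor(t(mB[sel, , drop = FALSE]))
      sqrt(sum((da[upper.tri(da)] - db[upper.tri(db)])^2))
    }
  }
  obs <- dOf(match(genes, pool))
  nulls <- vapply(seq_len(B), function(i) dOf(sample.int(length(pool), k)), 0)
  list(observed = obs, nulls = nulls)
}

#' Permutation test for differential co-expression of a module
#'
#' Computes the observed D between conditions and compares it with a null
#' distribution of D recomputed for \code{B} random gene sets of the same
#' size drawn without replacement from the expressed-gene pool (a
#' competitive null). The empirical p-value uses the add-one estimator
#' p = (1 + #\{D_null >= D_obs\}) / (B + 1), which never returns zero.
#'
#' @param exprA,exprB Expression matrices for the two conditions (rows must
#'   cover \code{pool}).
#' @param genes Module gene ids (all in \code{pool}).
#' @param pool Eligible gene pool to redraw from (default: all genes shared
#'   by the two matrices); must be strictly larger than the module.
#' @param B Number of null draws (default 1000; the framework's reference
#'   setting is 10000).
#' @param seed Integer seed for reproducibility.
#' @param nullModel \code{"redraw"} (default, random same-size gene sets) or
#'   \code{"label"} (shuffle condition labels across samples), exposed for
#'   comparison.
#' @return list(module D, p_emp, B, nulls).
#' @export
diffCoexprTest <- function(exprA, exprB, genes, pool = NULL, B = 1000,
                           seed = 1, nullModel = c("redraw", "label")) {
  nullModel <- match.arg(nullModel)
  mA <- .asExprMatrix(exprA); mB <- .asExprMatrix(exprB)
  if (is.null(pool)) pool <- intersect(rownames(mA), rownames(mB))
  missing <- setdiff(genes, pool)
  if (length(missing))
    stop("module gene(s) not in the expressed pool: ",
         paste(missing, collapse = ", "))
  stopifnot(B >= 1)
  if (nullModel == "redraw" && length(pool) <= length(genes))
    stop("expressed-gene pool must be strictly larger than the module")
  set.seed(seed)
  rA <- .rowRanks(mA[pool, , drop = FALSE])
  rB <- .rowRanks(mB[pool, , drop = FALSE])
  if (nullModel == "redraw") {
    res <- .nullD(rA, rB, genes, pool, B)
  } else {
    ## label-shuffling null: permute sample-to-condition assignment
    sel <- match(genes, pool)
    joint <- cbind(mA[pool, , drop = FALSE], mB[pool, , drop = FALSE])
    nA <- ncol(mA)
    dOf <- function(colsA) {
      a <- .rowRanks(joint[sel, colsA, drop = FALSE])
      b <- .rowRanks(joint[sel, -colsA, drop = FALSE])
      da <- cor(t(a)); db <- cor(t(b))
      sqrt(sum((da[upper.tri(da)] - db[upper.tri(db)])^2))
    }
    obs <- dOf(seq_len(nA))
    nulls <- vapply(seq_len(B), function(i)
      dOf(sample.int(ncol(joint), nA)), 0)
    res <- list(observed = obs, nulls = nulls)
  }
  list(D = res$observed,
       p_emp = (1 + sum(res$nulls >= res$observed)) / (B + 1),
       B = B, nulls = res$nulls)
}

#' Test every module of a partition for differential co-expression
#'
#' @param exprA,exprB Condition-wise expression.
#' @param partition \linkS4class{ModulePartition} or named list of gene sets.
#' @param pool,B,seed As in [diffCoexprTest()]; each module gets its own
#'   derived seed stream.
#' @param minSize Modules below this size are skipped with a note.
#' @return data.frame(module, size, D, p_emp, q, B), BH-adjusted across the
#'   tested modules.
#' @export
diffCoexprModules <- function(exprA, exprB, partition, pool = NULL, B = 1000,
                              seed = 1, minSize = 3) {
  mods <- if (is(partition, "ModulePartition")) moduleList(partition) else partition
  mods <- mods[lengths(mods) >= minSize]
  if (!length(mods)) stop("no modules of size >= ", minSize)
  rows <- lapply(seq_along(mods), function(i) {
    t <- diffCoexprTest(exprA, exprB, mods[[i]], pool = pool, B = B,
                        seed = .childSeed(seed, i))
    data.frame(module = names(mods)[i], size = length(mods[[i]]),
               D = t$D, p_emp = t$p_emp, B = B, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- adjustBH(out$p_emp)
  out[, c("module", "size", "D", "p_emp", "q", "B")]
}

#' Cross-dataset conservation test of a module
#'
#' Maps the module's genes into an external dataset through a one-to-one
#' ortholog map and asks whether they remain coherently co-expressed there:
#' the statistic is the mean absolute pairwise Spearman correlation of the
#' mapped genes, and the null redraws B equal-size gene sets from the
#' external expressed genes (one-sided exceedance p).
#'
#' @param genes Module gene ids in the source dataset's id space.
#' @param externalExpr External expression (SummarizedExperiment or matrix).
#' @param map Ortholog map ([readOrthologMap()]); use an identity map for a
#'   same-species external dataset.
#' @param B,seed As in [diffCoexprTest()].
#' @return list(statistic, p_emp, nMapped, nDropped, B).
#' @export
conservationTest <- function(genes, externalExpr, map, B = 1000, seed = 1) {
  m <- .asExprMatrix(externalExpr)
  mapped <- applyOrthologMap(genes, map)
  dropped <- attr(mapped, "n_dropped")
  mapped <- intersect(mapped, rownames(m))
  if (length(mapped) < 2)
    stop(sprintf(paste0("fewer than 2 module genes map into the external ",
                        "data (%d of %d mapped by orthology, %d present)"),
                 length(genes) - dropped, length(genes), length(mapped)))
  set.seed(seed)
  ranked <- .rowRanks(m)
  meanAbsCor <- function(sel) {
    r <- cor(t(ranked[sel, , drop = FALSE]))
    mean(abs(r[upper.tri(r)]))
  }
  obs <- meanAbsCor(match(mapped, rownames(m)))
  nulls <- vapply(seq_len(B), function(i)
    meanAbsCor(sample.int(nrow(m), length(mapped))), 0)
  list(statistic = obs, p_emp = (1 + sum(nulls >= obs)) / (B + 1),
       nMapped = length(mapped), nDropped = length(genes) - length(mapped),
       B = B)
}

#' Subsampling power grid for differential co-expression
#'
#' For each sampling fraction and repetition, draws a stratified random
#' subset of samples per condition, reruns [diffCoexprTest()] and records
#' the empirical p-value — the post hoc sample-size framework: reduce the
#' sample size in steps, repeat to assess sampling variation.
#'
#' @param exprA,exprB Condition-wise expression.
#' @param genes Module gene ids.
#' @param fractions Sampling fractions in (0, 1\].
#' @param reps Repetitions per fraction (reference setting: 50).
#' @param pool,B As in [diffCoexprTest()].
#' @param seed Master seed; each (fraction, rep) cell gets a derived stream.
#' @param minPerCondition Cells leaving fewer samples than this per
#'   condition are skipped with a warning.
#' @return data.frame(fraction, rep, nA, nB, D, p_emp) in long format.
#' @export
subsamplePower <- function(exprA, exprB, genes,
                           fractions = seq(0.1, 1, by = 0.1), reps = 50,
                           pool = NULL, B = 1000, seed = 1,
                           minPerCondition = 4) {
  mA <- .asExprMatrix(exprA); mB <- .asExprMatrix(exprB)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  grid <- expand.grid(rep = seq_len(reps), fraction = fractions)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$fraction[i]
    nA <- round(f * ncol(mA)); nB <- round(f * ncol(mB))
    if (nA < minPerCondition || nB < minPerCondition) {
      warning(sprintf("fraction %.2f leaves < %d samples; skipped", f,
                      minPerCondition))
      return(NULL)
    }
    s <- .childSeed(seed, i)
    set.seed(s)
    sA <- sample.int(ncol(mA), nA); sB <- sample.int(ncol(mB), nB)
    t <- diffCoexprTest(mA[, sA, drop = FALSE], mB[, sB, drop = FALSE],
                        genes, pool = pool, B = B, seed = .childSeed(s, 1L))
    data.frame(fraction = f, rep = grid$rep[i], nA = nA, nB = nB,
               D = t$D, p_emp = t$p_emp)
  })
  do.call(rbind, rows)
}
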