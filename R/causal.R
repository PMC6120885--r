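## The causal reasoning core: compose signed receptor->TF->target paths,
## test direction-specified target sets against disease sub-modules,
## classify regulators as activators/inhibitors, and rank them absolutely
## and by residual sub-module coverage.

#' Restrict a regulome to expressed entities
#'
#' Drops every edge with an endpoint outside the expressed-gene set, so the
#' causal analysis only reasons over receptors, TFs and targets actually
#' expressed in the tissue. Entity counts before/after are attached as
#' attribute \code{"report"}.
#'
#' @param reg A \linkS4class{Regulome}.
#' @param expressed Character vector of expressed gene ids.
#' @return Filtered Regulome.
#' @export
filterToExpressed <- function(reg, expressed) {
  stopifnot(is(reg, "Regulome"))
  a <- regulomeEdges(reg, "receptor_tf")
  b <- regulomeEdges(reg, "tf_target")
  a2 <- a[a$source %in% expressed & a$target %in% expressed, , drop = FALSE]
  b2 <- b[b$source %in% expressed & b$target %in% expressed, , drop = FALSE]
  out <- Regulome(a2, b2)
  if (length(expressed) == 0 || (nrow(a2) == 0 && nrow(b2) == 0))
    warning("no regulome edges survive the expression filter")
  attr(out, "report") <- c(receptors_before = length(receptors(reg)),
                           receptors_after = length(receptors(out)),
                           tfs_before = length(transcriptionFactors(reg)),
                           tfs_after = length(transcriptionFactors(out)),
                           targets_before = length(regulomeTargets(reg)),
                           targets_after = length(regulomeTargets(out)))
  out
}

#' Compose two interaction signs along a receptor->TF->target path
#'
#' \code{"multiplicative"} (default) is the sign group with \code{unk}
#' absorbing: act.act = act, act.inh = inh.act = inh, inh.inh = act.
#' \code{"as_printed"} reproduces the published rule table literally,
#' whose (inh, act) row reads "Activated"; both behaviours are selectable
#' and neither is silently corrected.
#'
#' @param s1 Receptor-on-TF sign(s): "act", "inh" or "unk" (vectorized).
#' @param s2 TF-on-target sign(s).
#' @param mode "multiplicative" or "as_printed".
#' @return Composed sign vector in \{"act", "inh", "unk"\}.
#' @examples
#' composeSigns("inh", "inh")                      # "act"
#' composeSigns("inh", "act")                      # "inh"
#' composeSigns("inh", "act", mode = "as_printed") # "act"
#' @export
composeSigns <- function(s1, s2, mode = c("multiplicative", "as_printed")) {
  mode <- match.arg(mode)
  bad <- setdiff(unique(c(s1, s2)), REG_SIGNS)
  if (length(bad))
    stop("invalid sign token(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(REG_SIGNS, collapse = ", "))
  out <- ifelse(s1 == "unk" | s2 == "unk", "unk",
                ifelse(s1 == s2, "act", "inh"))
  if (mode == "as_printed")
    out[s1 == "inh" & s2 == "act"] <- "act"
  out
}

#' Direction-specified target sets of a receptor
#'
#' Enumerates every two-hop path receptor -> TF -> gene in the regulome and
#' composes the two signs. A gene with at least one activating path enters
#' the activated set, one with at least one inhibiting path the inhibited
#' set (membership in both records a path conflict); genes reachable only
#' through unknown-composed paths form the unknown set.
#'
#' @param reg Filtered \linkS4class{Regulome}.
#' @param receptor Receptor id (must be present).
#' @param mode Sign-composition mode, see [composeSigns()].
#' @return list(regulator, activated, inhibited, unknown) of gene-id sets.
#' @export
receptorTargetSets <- function(reg, receptor,
                               mode = c("multiplicative", "as_printed")) {
  mode <- match.arg(mode)
  a <- regulomeEdges(reg, "receptor_tf")
  a <- a[a$source == receptor, , drop = FALSE]
  if (nrow(a) == 0) stop("receptor not present in regulome: ", receptor)
  b <- regulomeEdges(reg, "tf_target")
  hops <- merge(a, b, by.x = "target", by.y = "source",
                suffixes = c("_rt", "_tt"))
  if (nrow(hops) == 0)
    return(list(regulator = receptor, activated = character(),
                inhibited = character(), unknown = character()))
  sign <- composeSigns(hops$sign_rt, hops$sign_tt, mode = mode)
  gene <- hops$target_tt
  activated <- sort(unique(gene[sign == "act"]))
  inhibited <- sort(unique(gene[sign == "inh"]))
  unknown <- sort(setdiff(unique(gene[sign == "unk"]),
                          c(activated, inhibited)))
  list(regulator = receptor, activated = activated, inhibited = inhibited,
       unknown = unknown)
}

#' Direction-specified target sets of a TF (single hop)
#'
#' @param reg Filtered Regulome.
#' @param tf TF id with outgoing tf_target edges.
#' @return As [receptorTargetSets()].
#' @export
tfTargetSets <- function(reg, tf) {
  b <- regulomeEdges(reg, "tf_target")
  b <- b[b$source == tf, , drop = FALSE]
  if (nrow(b) == 0) stop("TF has no target edges: ", tf)
  activated <- sort(unique(b$target[b$sign == "act"]))
  inhibited <- sort(unique(b$target[b$sign == "inh"]))
  unknown <- sort(setdiff(unique(b$target[b$sign == "unk"]),
                          c(activated, inhibited)))
  list(regulator = tf, activated = activated, inhibited = inhibited,
       unknown = unknown)
}

#' Split modules into over/under-expressed sub-modules
#'
#' A sub-module is the subset of a module's genes called over-expressed
#' ("o") or under-expressed ("u") in disease; genes absent from the DE
#' table count as direction "none". Empty sub-modules are dropped.
#'
#' @param partition \linkS4class{ModulePartition} or named list.
#' @param de DE table ([readDETable()] / [rankSumDE()]).
#' @return data.frame(submodule, module, direction) with a list-column
#'   \code{genes}; label convention "<module>_o" / "<module>_u".
#' @export
buildSubmodules <- function(partition, de) {
  mods <- if (is(partition, "ModulePartition")) moduleList(partition) else partition
  dir <- setNames(de$direction, de$gene_id)
  rows <- list()
  for (mod in names(mods)) {
    g <- mods[[mod]]
    gd <- dir[g]; gd[is.na(gd)] <- "none"
    for (d in c("o", "u")) {
      sel <- g[gd == c(o = "over", u = "under")[d]]
      if (length(sel))
        rows[[paste(mod, d, sep = "_")]] <-
          data.frame(submodule = paste(mod, d, sep = "_"), module = mod,
                     direction = d, stringsAsFactors = FALSE)
      if (length(sel))
        rows[[paste(mod, d, sep = "_")]]$genes <- list(sel)
    }
  }
  if (!length(rows))
    return(data.frame(submodule = character(), module = character(),
                      direction = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired direction-specified enrichment of a regulator on a sub-module
#'
#' Upper-tail hypergeometric tests of the overlap between the regulator's
#' activated (positive effect) and inhibited (negative effect) target sets
#' and the sub-module's genes. Empty target sets yield no row (untested,
#' not p = 1). q-values are left NA here; BH is applied across the whole
#' test family by [craftCausal()].
#'
#' @param targets list from [receptorTargetSets()] / [tfTargetSets()].
#' @param subGenes Sub-module gene ids.
#' @param universe Universe gene ids (see [craftCausal()] for the options).
#' @return data.frame(regulator, effect_sign, k, n, K, N, p), 0-2 rows.
#' @export
effectEnrichment <- function(targets, subGenes, universe) {
  if (!length(universe)) stop("empty universe")
  K <- length(intersect(subGenes, universe))
  rows <- lapply(c(positive = "activated", negative = "inhibited"),
                 function(slot) {
    ts <- intersect(targets[[slot]], universe)
    if (!length(ts)) return(NULL)
    k <- length(intersect(ts, subGenes))
    data.frame(regulator = targets$regulator,
               effect_sign = if (slot == "activated") "positive" else "negative",
               k = k, n = length(ts), K = K, N = length(universe),
               p = .hyperUpper(k, K, length(universe), length(ts)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(regulator = character(), effect_sign = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Classify a regulator's effect on a sub-module
#'
#' act: significant positive effect (q < alpha) and no significant negative
#' effect (untested counts as not significant); inh: the mirror image;
#' uns: both effects significant; ns: neither.
#'
#' @param posQ,negQ Family-adjusted q of the positive/negative effect test
#'   (NA if untested).
#' @param alpha FDR threshold (default 0.05).
#' @return "act", "inh", "uns" or "ns".
#' @export
classifyRegulator <- function(posQ, negQ, alpha = 0.05) {
  sp <- !is.na(posQ) && posQ < alpha
  sn <- !is.na(negQ) && negQ < alpha
  if (sp && sn) "uns" else if (sp) "act" else if (sn) "inh" else "ns"
}

#' Predicted therapeutic intervention on a receptor
#'
#' Signature-reversion logic: a receptor activating an over-expressed
#' sub-module (or inhibiting an under-expressed one) is a disease
#' "activator" whose blockade should restore the signature toward health;
#' the two mirror combinations call for receptor activation.
#'
#' @param class Regulator class, "act" or "inh" ("uns"/"ns" give NA).
#' @param direction Sub-module direction, "o" or "u".
#' @return "blockade", "activation" or NA (vectorized).
#' @export
therapeuticDirection <- function(class, direction) {
  stopifnot(all(direction %in% c("o", "u")))
  out <- rep(NA_character_, length(class))
  out[class == "act" & direction == "o"] <- "blockade"
  out[class == "inh" & direction == "o"] <- "activation"
  out[class == "act" & direction == "u"] <- "activation"
  out[class == "inh" & direction == "u"] <- "blockade"
  out
}

## within-stratum rank-sum ordering used by both rankings
.rankWithin <- function(df) {
  if (!nrow(df)) return(df)
  df$stratum <- ifelse(df$class %in% c("act", "inh"), 1L, 2L)
  parts <- split(df, df$stratum)
  parts <- lapply(parts, function(p) {
    p$ranksum <- rank(-p$activity, ties.method = "average") +
      rank(-p$weight, ties.method = "average")
    p
  })
  df <- do.call(rbind, parts)
  df <- df[order(df$stratum, df$ranksum, df$q, df$regulator), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Absolute ranking of regulators on one sub-module
#'
#' Regulators with a defined direction (act/inh) outrank unspecified (uns)
#' ones; ns regulators are excluded. Within a stratum, regulators are
#' ordered by the ascending sum of their activity rank and weight rank
#' (rank 1 = largest value), with ties broken by the smaller classifying q
#' and then lexicographic id.
#'
#' @param calls data.frame with columns regulator, class, activity, weight,
#'   q for a single sub-module (see [craftCausal()]).
#' @return The calls ordered and augmented with stratum, ranksum, rank.
#' @export
absoluteRanking <- function(calls) {
  calls <- calls[calls$class %in% c("act", "inh", "uns"), , drop = FALSE]
  if (!nrow(calls)) return(cbind(calls, stratum = integer(),
                                 ranksum = numeric(), rank = integer()))
  .rankWithin(calls)
}

#' Relative (coverage-maximizing) ranking of regulators
#'
#' Greedy re-ranking: take the absolute-rank-1 regulator, remove the
#' sub-module genes it covers, recompute each remaining regulator's
#' activity (residual overlap / its direction-specified target count) and
#' weight (residual overlap / residual sub-module size), re-apply the
#' absolute ranking rule, and repeat until the residual is empty or no
#' regulator covers a residual gene. Regulators never picked are appended
#' in absolute order with zero gain.
#'
#' @param calls As [absoluteRanking()].
#' @param targetSets Named list (by regulator) from [receptorTargetSets()].
#' @param subGenes Sub-module gene ids.
#' @param universe Universe used for the tests.
#' @return data.frame(rank, regulator, class, gained, covered,
#'   cumulativeCoverage) where coverage is a fraction of the sub-module.
#' @export
relativeRanking <- function(calls, targetSets, subGenes, universe) {
  calls <- calls[calls$class %in% c("act", "inh", "uns"), , drop = FALSE]
  if (!nrow(calls))
    return(data.frame(rank = integer(), regulator = character(),
                      class = character(), gained = integer(),
                      covered = integer(), cumulativeCoverage = numeric()))
  ## each regulator covers through its classifying direction's target set
  dirSet <- function(i) {
    ts <- targetSets[[calls$regulator[i]]]
    slot <- switch(calls$class[i], act = "activated", inh = "inhibited",
                   uns = if (identical(calls$classifyingSign[i], "negative"))
                     "inhibited" else "activated")
    intersect(intersect(ts[[slot]], universe), subGenes)
  }
  cov <- lapply(seq_len(nrow(calls)), dirSet)
  names(cov) <- calls$regulator
  nDir <- vapply(seq_len(nrow(calls)), function(i) {
    ts <- targetSets[[calls$regulator[i]]]
    slot <- switch(calls$class[i], act = "activated", inh = "inhibited",
                   uns = if (identical(calls$classifyingSign[i], "negative"))
                     "inhibited" else "activated")
    length(intersect(ts[[slot]], universe))
  }, 0L)
  residual <- subGenes
  remaining <- calls$regulator
  picked <- character(); gained <- integer()
  absOrder <- absoluteRanking(calls)$regulator
  current <- absOrder
  while (length(residual) && length(current)) {
    idx <- match(current, calls$regulator)
    res <- data.frame(regulator = current,
                      class = calls$class[idx],
                      activity = vapply(current, function(r)
                        length(intersect(cov[[r]], residual)), 0L) /
                        pmax(nDir[idx], 1L),
                      weight = vapply(current, function(r)
                        length(intersect(cov[[r]], residual)), 0L) /
                        length(residual),
                      q = calls$q[idx], stringsAsFactors = FALSE)
    res <- res[res$activity > 0, , drop = FALSE]
    if (!nrow(res)) break
    top <- .rankWithin(res)$regulator[1]
    g <- length(intersect(cov[[top]], residual))
    picked <- c(picked, top); gained <- c(gained, g)
    residual <- setdiff(residual, cov[[top]])
    current <- setdiff(current, top)
  }
  leftover <- setdiff(absOrder, picked)
  regs <- c(picked, leftover)
  gains <- c(gained, rep(0L, length(leftover)))
  cum <- cumsum(gains)
  data.frame(rank = seq_along(regs), regulator = regs,
             class = calls$class[match(regs, calls$regulator)],
             gained = gains,
             covered = vapply(regs, function(r) length(cov[[r]]), 0L),
             cumulativeCoverage = cum / max(length(subGenes), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

.resolveUniverse <- function(universe, reg, expressed, targets = NULL) {
  switch(universe,
    regulome_targets = intersect(regulomeTargets(reg), expressed),
    expressed_genes = expressed,
    regulator_targets = {
      if (is.null(targets)) stop("regulator_targets universe needs a regulator")
      intersect(unique(c(targets$activated, targets$inhibited,
                         targets$unknown)), expressed)
    },
    stop("unknown universe option: ", universe))
}

#' Run the causal reasoning analysis
#'
#' The full regulator workflow: filter the regulome to expressed entities,
#' build over/under sub-modules from the DE table, compute each regulator's
#' direction-specified target sets, run the paired hypergeometric effect
#' tests against every sub-module, BH-adjust across the whole family
#' (receptors and TFs as separate families), classify each
#' (regulator, sub-module) pair, and produce absolute and relative
#' rankings per sub-module with the predicted intervention direction.
#'
#' @param reg \linkS4class{Regulome}.
#' @param expressed Expressed gene ids.
#' @param partition \linkS4class{ModulePartition} or named module list.
#' @param de DE table.
#' @param universe "regulome_targets" (default: expressed genes appearing
#'   as regulome targets), "expressed_genes", or "regulator_targets" (the
#'   literal per-regulator universe reading).
#' @param signMode See [composeSigns()].
#' @param alpha FDR threshold for classification (default 0.05).
#' @param regulators "receptors" (default) or "tfs".
#' @return list(tests, calls, rankings = per-sub-module list with absolute
#'   and relative tables, submodules, universe, counts).
#' @export
craftCausal <- function(reg, expressed, partition, de,
                        universe = c("regulome_targets", "expressed_genes",
                                     "regulator_targets"),
                        signMode = c("multiplicative", "as_printed"),
                        alpha = 0.05, regulators = c("receptors", "tfs")) {
  universe <- match.arg(universe)
  signMode <- match.arg(signMode)
  regulators <- match.arg(regulators)
  freg <- filterToExpressed(reg, expressed)
  subs <- buildSubmodules(partition, de)
  if (!nrow(subs)) stop("no non-empty sub-modules to test")
  regIds <- if (regulators == "receptors") receptors(freg) else
    sort(unique(regulomeEdges(freg, "tf_target")$source))
  targetSets <- lapply(regIds, function(r)
    if (regulators == "receptors") receptorTargetSets(freg, r, mode = signMode)
    else tfTargetSets(freg, r))
  names(targetSets) <- regIds
  globalUniverse <- if (universe == "regulator_targets") NULL else
    .resolveUniverse(universe, freg, expressed)
  tests <- do.call(rbind, lapply(seq_len(nrow(subs)), function(si) {
    sg <- subs$genes[[si]]
    do.call(rbind, lapply(regIds, function(r) {
      u <- if (is.null(globalUniverse))
        .resolveUniverse(universe, freg, expressed, targetSets[[r]]) else
          globalUniverse
      if (!length(u)) return(NULL)
      t <- effectEnrichment(targetSets[[r]], sg, u)
      if (nrow(t)) cbind(submodule = subs$submodule[si],
                         direction = subs$direction[si], t) else NULL
    }))
  }))
  if (is.null(tests) || !nrow(tests)) stop("no testable regulator effects")
  tests$q <- adjustBH(tests$p)
  ## classification per (regulator, sub-module)
  key <- interaction(tests$regulator, tests$submodule, drop = TRUE)
  calls <- do.call(rbind, lapply(split(tests, key), function(tt) {
    pos <- tt[tt$effect_sign == "positive", , drop = FALSE]
    neg <- tt[tt$effect_sign == "negative", , drop = FALSE]
    pq <- if (nrow(pos)) pos$q else NA_real_
    nq <- if (nrow(neg)) neg$q else NA_real_
    cls <- classifyRegulator(pq, nq, alpha)
    ## the classifying test supplies activity = k/n and weight = k/K
    useNeg <- cls == "inh" ||
      (cls == "uns" && !is.na(nq) && (!is.na(pq) && nq < pq))
    ct <- if (useNeg) neg else if (nrow(pos)) pos else neg
    data.frame(regulator = tt$regulator[1], submodule = tt$submodule[1],
               direction = tt$direction[1], class = cls,
               activity = ct$k / ct$n, weight = if (ct$K > 0) ct$k / ct$K else 0,
               q = ct$q, classifyingSign = ct$effect_sign,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls$intervention <- therapeuticDirection(calls$class, calls$direction)
  rankings <- lapply(split(calls, calls$submodule), function(cc) {
    si <- match(cc$submodule[1], subs$submodule)
    u <- if (is.null(globalUniverse))
      unique(unlist(lapply(targetSets, function(ts)
        c(ts$activated, ts$inhibited, ts$unknown)))) else globalUniverse
    list(absolute = absoluteRanking(cc),
         relative = relativeRanking(cc, targetSets, subs$genes[[si]], u))
  })
  list(tests = tests, calls = calls, rankings = rankings, submodules = subs,
       universe = universe, signMode = signMode, alpha = alpha,
       counts = attr(freg, "report"), targetSets = targetSets)
}
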