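## Seeded generators with planted ground truth. Expression follows a
## latent-factor model: gene g in module m under condition c is
##   x_gs = baseline + lambda_c(m) * f_ms + shift * 1[case, DE gene] + eps,
## with f ~ N(0,1) per sample and eps ~ N(0, noiseSd), so the within-module
## correlation has the closed form lambda^2 / (lambda^2 + noiseSd^2).
## Trait counts for case samples follow a Poisson log-linear model on the
## module factors. One RNG stream per component (expression / regulome /
## citations) is derived from the master seed.

#' Assemble a simulation configuration
#'
#' @param nGenes Total genes (module genes + background noise genes).
#' @param nCase,nControl Samples per condition.
#' @param moduleSpecs data.frame with one row per planted module and
#'   columns size, lambdaCase, lambdaControl (loadings in \[0, 1\]),
#'   traitEffect (log-linear trait coefficient), deFraction (fraction of
#'   the module's genes differentially expressed), deDirection ("over" or
#'   "under").
#' @param noiseSd Residual standard deviation (default 1: loadings are
#'   signal-to-noise ratios).
#' @param deShift Additive log-scale case shift for DE genes (default 1).
#' @param baseline Mean log-expression level (default 5).
#' @param traitIntercept Log baseline trait rate (default log(3), i.e.
#'   about three events per day at factor zero).
#' @param regulomeSpec list(nReceptors = decoy count, nTFs, nTargets =
#'   size of the candidate target pool TF edges are drawn from (the
#'   realized target set is somewhat smaller), coverage = fraction of the
#'   chosen o-sub-module covered by the planted driver, unkFraction =
#'   fraction of edge signs degraded to unknown).
#' @param seed Master seed.
#' @return list of class "craftSimConfig".
#' @export
simulationConfig <- function(nGenes = 1500, nCase = 60, nControl = 60,
                             moduleSpecs = data.frame(
                               size = c(50, 50),
                               lambdaCase = c(0.8, 0.6),
                               lambdaControl = c(0.0, 0.6),
                               traitEffect = c(0.5, 0),
                               deFraction = c(0.6, 0.3),
                               deDirection = c("over", "under")),
                             noiseSd = 1, deShift = 1, baseline = 5,
                             traitIntercept = log(3),
                             regulomeSpec = list(nReceptors = 20, nTFs = 30,
                                                 nTargets = 1000,
                                                 coverage = 0.6,
                                                 unkFraction = 0.1),
                             seed = 1) {
  stopifnot(nGenes >= sum(moduleSpecs$size), all(moduleSpecs$size > 0),
            all(moduleSpecs$lambdaCase >= 0 & moduleSpecs$lambdaCase <= 1),
            all(moduleSpecs$lambdaControl >= 0 & moduleSpecs$lambdaControl <= 1),
            noiseSd > 0)
  structure(list(nGenes = nGenes, nCase = nCase, nControl = nControl,
                 moduleSpecs = moduleSpecs, noiseSd = noiseSd,
                 deShift = deShift, baseline = baseline,
                 traitIntercept = traitIntercept,
                 regulomeSpec = regulomeSpec, seed = as.integer(seed)),
            class = "craftSimConfig")
}

#' Simulate case/control expression, trait and planted truth
#'
#' @param cfg Configuration from [simulationConfig()].
#' @return list(case, control: genes-by-samples matrices; samples: sample
#'   table with trait counts for cases; truth: list with the module
#'   assignment, per-module flags, and per-gene DE direction).
#' @export
simulateExpression <- function(cfg) {
  stopifnot(inherits(cfg, "craftSimConfig"))
  set.seed(.childSeed(cfg$seed, 1L))
  ms <- cfg$moduleSpecs
  nMod <- nrow(ms)
  geneIds <- sprintf("g%05d", seq_len(cfg$nGenes))
  assignment <- rep("background", cfg$nGenes)
  idx <- 0
  for (m in seq_len(nMod)) {
    assignment[idx + seq_len(ms$size[m])] <- paste0("M", m)
    idx <- idx + ms$size[m]
  }
  names(assignment) <- geneIds
  sampleIds <- c(paste0("case_", seq_len(cfg$nCase)),
                 paste0("ctrl_", seq_len(cfg$nControl)))
  fCase <- matrix(rnorm(nMod * cfg$nCase), nMod)
  fCtrl <- matrix(rnorm(nMod * cfg$nControl), nMod)
  deDir <- rep("none", cfg$nGenes); names(deDir) <- geneIds
  build <- function(nS, f, lambda, isCase) {
    x <- matrix(rnorm(cfg$nGenes * nS, sd = cfg$noiseSd), cfg$nGenes) +
      cfg$baseline
    for (m in seq_len(nMod)) {
      rows <- which(assignment == paste0("M", m))
      x[rows, ] <- x[rows, ] + lambda[m] * rep(f[m, ], each = length(rows))
    }
    x
  }
  xCase <- build(cfg$nCase, fCase, ms$lambdaCase, TRUE)
  xCtrl <- build(cfg$nControl, fCtrl, ms$lambdaControl, FALSE)
  for (m in seq_len(nMod)) {
    rows <- which(assignment == paste0("M", m))
    nDE <- round(ms$deFraction[m] * ms$size[m])
    if (nDE > 0) {
      deRows <- rows[seq_len(nDE)]
      deDir[deRows] <- ms$deDirection[m]
      sgn <- if (ms$deDirection[m] == "over") 1 else -1
      xCase[deRows, ] <- xCase[deRows, ] + sgn * cfg$deShift
    }
  }
  dimnames(xCase) <- list(geneIds, sampleIds[seq_len(cfg$nCase)])
  dimnames(xCtrl) <- list(geneIds, sampleIds[cfg$nCase + seq_len(cfg$nControl)])
  beta <- ms$traitEffect
  eta <- cfg$traitIntercept + as.numeric(crossprod(fCase, beta))
  trait <- rpois(cfg$nCase, exp(eta))
  samples <- data.frame(
    sample_id = sampleIds,
    condition = rep(c("case", "control"), c(cfg$nCase, cfg$nControl)),
    trait = c(trait, rep(NA_real_, cfg$nControl)),
    stringsAsFactors = FALSE)
  truth <- list(
    assignment = assignment,
    modules = split(geneIds, assignment),
    moduleFlags = data.frame(
      module = paste0("M", seq_len(nMod)),
      diffCoexpressed = ms$lambdaCase != ms$lambdaControl,
      traitAssociated = beta != 0, stringsAsFactors = FALSE),
    deDirection = deDir)
  list(case = xCase, control = xCtrl, samples = samples, truth = truth)
}

#' DE table from planted truth
#'
#' Converts the generator's per-gene DE direction into the (gene,
#' direction, q) table the causal stage consumes, with q = 0 for planted
#' calls and 1 otherwise.
#'
#' @param truth Truth component of [simulateExpression()] output.
#' @return data.frame(gene_id, direction, q, effect).
#' @export
deTableFromTruth <- function(truth) {
  d <- truth$deDirection
  data.frame(gene_id = names(d), direction = unname(d),
             q = ifelse(d == "none", 1, 0), effect = NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate a signed regulome with a planted driver receptor
#'
#' Builds a two-layer regulome in which one "driver" receptor reaches, via
#' activating receptor-TF and TF-target edges, a configured fraction of the
#' chosen over-expressed sub-module, while decoy receptors connect to a TF
#' pool with uniformly random signed edges. A configured fraction of all
#' edge signs is then degraded to unknown. Receptor and TF ids are drawn
#' from background genes so the whole regulome survives the expression
#' filter.
#'
#' @param cfg Configuration ([simulationConfig()]); uses
#'   \code{cfg$regulomeSpec}.
#' @param truth Truth from [simulateExpression()] (supplies DE directions
#'   and module membership).
#' @param targetModule Module whose over-expressed sub-module the driver
#'   covers (default "M1").
#' @return list(regulome, truth) where truth gains \code{driver} (id),
#'   \code{driverSubmodule}, \code{driverIntendedClass} ("act") and
#'   \code{decoys}.
#' @export
simulateRegulome <- function(cfg, truth, targetModule = "M1") {
  stopifnot(inherits(cfg, "craftSimConfig"))
  rs <- cfg$regulomeSpec
  set.seed(.childSeed(cfg$seed, 2L))
  sub <- names(truth$deDirection)[truth$deDirection == "over" &
                                    truth$assignment == targetModule]
  if (!length(sub))
    stop("module ", targetModule, " has no over-expressed sub-module")
  nCover <- ceiling(rs$coverage * length(sub))
  if (nCover < 1) stop("coverage fraction infeasible for sub-module size ",
                       length(sub))
  background <- names(truth$assignment)[truth$assignment == "background"]
  nEntities <- rs$nReceptors + 1 + rs$nTFs
  if (length(background) < nEntities)
    stop(sprintf(paste0("regulome needs %d background genes for receptor/TF ",
                        "ids but only %d are available; increase nGenes"),
                 nEntities, length(background)))
  entityPool <- sample(background, nEntities)
  driver <- entityPool[1]
  decoys <- entityPool[1 + seq_len(rs$nReceptors)]
  tfs <- entityPool[rs$nReceptors + 1 + seq_len(rs$nTFs)]
  nDriverTFs <- min(3L, rs$nTFs)
  driverTFs <- tfs[seq_len(nDriverTFs)]
  poolTFs <- if (rs$nTFs > nDriverTFs) tfs[-seq_len(nDriverTFs)] else tfs
  ## target universe: the sub-module plus random other genes
  others <- setdiff(names(truth$assignment), c(sub, entityPool))
  targets <- c(sub, sample(others, min(length(others),
                                       max(0, rs$nTargets - length(sub)))))
  covered <- sample(sub, nCover)
  rtf <- data.frame(source = driver, target = driverTFs, sign = "act",
                    stringsAsFactors = FALSE)
  ## split coverage across the driver TFs, each with a few random extras
  splitIdx <- rep(seq_len(nDriverTFs), length.out = nCover)
  tft <- do.call(rbind, lapply(seq_len(nDriverTFs), function(i) {
    extra <- sample(setdiff(targets, sub), 5)
    data.frame(source = driverTFs[i],
               target = c(covered[splitIdx == i], extra), sign = "act",
               stringsAsFactors = FALSE)
  }))
  nTfPer <- min(3L, length(poolTFs))
  for (d in decoys) {
    dtf <- sample(poolTFs, nTfPer)
    rtf <- rbind(rtf, data.frame(source = d, target = dtf,
                                 sign = sample(c("act", "inh"), nTfPer,
                                               replace = TRUE),
                                 stringsAsFactors = FALSE))
  }
  for (tf in poolTFs) {
    tg <- sample(targets, min(20, length(targets)))
    tft <- rbind(tft, data.frame(source = tf, target = tg,
                                 sign = sample(c("act", "inh"), length(tg),
                                               replace = TRUE),
                                 stringsAsFactors = FALSE))
  }
  if (rs$unkFraction > 0) {
    rtf$sign[runif(nrow(rtf)) < rs$unkFraction] <- "unk"
    tft$sign[runif(nrow(tft)) < rs$unkFraction] <- "unk"
  }
  truth$driver <- driver
  truth$driverSubmodule <- paste0(targetModule, "_o")
  truth$driverIntendedClass <- "act"
  truth$decoys <- decoys
  list(regulome = Regulome(rtf, tft), truth = truth)
}

#' Simulate a citation-count table with planted disease genes
#'
#' Every gene receives a number of citing abstracts and a co-citation count
#' drawn binomially at the corpus base rate K_disease/N_total; planted
#' disease genes co-cite at \code{enrichmentFold} times that rate (capped
#' at 1). Corpus-scale defaults are of the order of millions of abstracts.
#'
#' @param genes Gene ids to tabulate.
#' @param diseaseGenes Planted disease-associated genes.
#' @param nTotal,kDisease Corpus totals.
#' @param meanAbstracts Mean abstracts citing a gene (Poisson, default 200).
#' @param enrichmentFold Co-citation rate multiplier for planted genes.
#' @param seed RNG seed.
#' @return Validated citation table (see [citationTable()]).
#' @export
simulateCitations <- function(genes, diseaseGenes = character(),
                              nTotal = 3811179, kDisease = 23092,
                              meanAbstracts = 200, enrichmentFold = 10,
                              seed = 1) {
  set.seed(.childSeed(seed, 3L))
  n <- pmax(1L, rpois(length(genes), meanAbstracts))
  base <- kDisease / nTotal
  rate <- ifelse(genes %in% diseaseGenes, pmin(1, enrichmentFold * base), base)
  k <- rbinom(length(genes), n, rate)
  citationTable(data.frame(gene_id = genes, n_gene = n, k_gene = k,
                           stringsAsFactors = FALSE), nTotal, kDisease)
}
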