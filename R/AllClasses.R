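#' @import methods
#' @importFrom stats cor sd setNames phyper dhyper pt p.adjust rnorm rpois
#'   rbinom runif hclust cutree as.dist prcomp lm quantile median fisher.test
#'   complete.cases
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

REG_SIGNS <- c("act", "inh", "unk")
REG_LAYERS <- c("receptor_tf", "tf_target")

#' ModulePartition: assignment of genes to co-expression modules
#'
#' A hard partition of clustered genes into labelled modules, as produced by
#' [cutPartition()] or carried through the pipeline. Every clustered gene
#' belongs to exactly one module and every module is non-empty.
#'
#' @slot assignment Named character vector mapping gene id to module label.
#'
#' @seealso [wardCluster()], [scanPartitions()], [moduleList()]
#' @export
setClass("ModulePartition", representation(assignment = "character"))

setValidity("ModulePartition", function(object) {
  a <- object@assignment
  if (length(a) == 0L) return("empty assignment")
  if (is.null(names(a)) || anyNA(names(a)) || any(names(a) == ""))
    return("assignment must be named by gene id")
  if (anyDuplicated(names(a)))
    return("duplicate gene ids in assignment")
  if (anyNA(a)) return("NA module labels")
  TRUE
})

#' Construct a ModulePartition
#'
#' @param assignment Named character (or factor/integer) vector: names are
#'   gene ids, values module labels.
#' @return A [ModulePartition-class] object.
#' @examples
#' p <- ModulePartition(c(g1 = "M1", g2 = "M1", g3 = "M2"))
#' nModules(p)
#' @export
ModulePartition <- function(assignment) {
  new("ModulePartition", assignment = setNames(as.character(assignment),
                                               names(assignment)))
}

#' @describeIn ModulePartition Number of modules.
#' @param x,object A ModulePartition.
#' @export
nModules <- function(x) length(unique(x@assignment))

#' Module membership as a named list of gene-id vectors
#'
#' @param x A [ModulePartition-class].
#' @return Named list, one character vector of gene ids per module, ordered
#'   by module label.
#' @export
moduleList <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  split(names(x@assignment), x@assignment)
}

#' @describeIn ModulePartition Gene-to-module assignment vector.
#' @export
moduleAssignment <- function(x) x@assignment

setMethod("show", "ModulePartition", function(object) {
  sizes <- table(object@assignment)
  cat("ModulePartition:", length(object@assignment), "genes in",
      length(sizes), "modules\n")
  cat("  sizes:", paste(utils::head(sort(as.integer(sizes), decreasing = TRUE), 8),
                        collapse = " "),
      if (length(sizes) > 8) "...\n" else "\n")
})

#' Regulome: a signed two-layer regulatory network
#'
#' Holds the two edge layers the causal engine reasons over: membrane
#' receptor to transcription factor (via linear canonical pathways) and
#' transcription factor to target gene. Each edge carries a sign in
#' \code{act} (activating), \code{inh} (inhibitory) or \code{unk} (direction
#' unknown). The same (source, target, layer) pair may legitimately carry
#' both an \code{act} and an \code{inh} edge (conflicting literature
#' evidence); exact duplicate edges are disallowed.
#'
#' @slot receptorTF data.frame with columns source, target, sign.
#' @slot tfTarget data.frame with columns source, target, sign.
#' @seealso [readRegulome()], [receptorTargetSets()], [filterToExpressed()]
#' @export
setClass("Regulome",
         representation(receptorTF = "data.frame", tfTarget = "data.frame"))

.checkEdgeFrame <- function(df, what) {
  need <- c("source", "target", "sign")
  if (!all(need %in% names(df)))
    return(sprintf("%s must have columns source, target, sign", what))
  if (nrow(df) > 0) {
    bad <- setdiff(unique(df$sign), REG_SIGNS)
    if (length(bad))
      return(sprintf("%s has invalid sign token(s) %s; allowed: %s", what,
                     paste(bad, collapse = ", "),
                     paste(REG_SIGNS, collapse = ", ")))
    if (anyDuplicated(df[, need]))
      return(sprintf("%s contains duplicate edges", what))
  }
  TRUE
}

setValidity("Regulome", function(object) {
  v <- .checkEdgeFrame(object@receptorTF, "receptorTF")
  if (!isTRUE(v)) return(v)
  .checkEdgeFrame(object@tfTarget, "tfTarget")
})

#' Construct a Regulome
#'
#' @param receptorTF data.frame (source = receptor, target = TF, sign).
#' @param tfTarget data.frame (source = TF, target = gene, sign).
#' @return A [Regulome-class] object; duplicate edges are collapsed.
#' @examples
#' reg <- Regulome(
#'   data.frame(source = "R1", target = "T1", sign = "act"),
#'   data.frame(source = "T1", target = c("g1", "g2"), sign = c("act", "inh")))
#' receptors(reg)
#' @export
Regulome <- function(receptorTF = NULL, tfTarget = NULL) {
  tidy <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(data.frame(source = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE))
    df <- data.frame(source = as.character(df$source),
                     target = as.character(df$target),
                     sign = as.character(df$sign), stringsAsFactors = FALSE)
    unique(df)
  }
  new("Regulome", receptorTF = tidy(receptorTF), tfTarget = tidy(tfTarget))
}

#' @describeIn Regulome Receptor ids (sources of the receptor-TF layer).
#' @param x,object A Regulome.
#' @export
receptors <- function(x) sort(unique(x@receptorTF$source))

#' @describeIn Regulome Transcription-factor ids (union of receptor-TF
#'   targets and TF-target sources).
#' @export
transcriptionFactors <- function(x)
  sort(unique(c(x@receptorTF$target, x@tfTarget$source)))

#' @describeIn Regulome Target gene ids (targets of the TF-target layer).
#' @export
regulomeTargets <- function(x) sort(unique(x@tfTarget$target))

#' @describeIn Regulome Edge table of one layer.
#' @param layer One of "receptor_tf", "tf_target".
#' @export
regulomeEdges <- function(x, layer = c("receptor_tf", "tf_target")) {
  layer <- match.arg(layer)
  if (layer == "receptor_tf") x@receptorTF else x@tfTarget
}

setMethod("show", "Regulome", function(object) {
  cat("Regulome:", length(receptors(object)), "receptors,",
      length(transcriptionFactors(object)), "TFs,",
      length(regulomeTargets(object)), "target genes\n")
  cat("  edges:", nrow(object@receptorTF), "receptor-TF,",
      nrow(object@tfTarget), "TF-target\n")
})
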