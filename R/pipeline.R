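## End-to-end orchestration: filter -> modules -> differential co-expression
## -> trait association -> (optional enrichments) -> causal reasoning ->
## rankings, with stage outputs written as TSV/JSON and a run manifest last.
## The stage cascade applies an FDR gate (default 0.05) at each decision
## point; any gate can be disabled by setting it to NULL/1.

.defaultConfig <- function() {
  list(seed = 1,
       filter = list(threshold = 0, minFraction = 0.05),
       modules = list(kMin = 2, kMax = 50, select = "consensus",
                      elbowFraction = 0.01, elbowWindow = 3),
       diffcoexpr = list(B = 1000, minSize = 3),
       gates = list(diffcoexpr = 0.05, trait = NULL),
       qtt = list(threshold = 0.05),
       causal = list(universe = "regulome_targets",
                     signMode = "multiplicative", alpha = 0.05))
}

.mergeConfig <- function(user, default = .defaultConfig()) {
  for (k in names(user)) {
    default[[k]] <- if (is.list(user[[k]]) && is.list(default[[k]]))
      .mergeConfig(user[[k]], default[[k]]) else user[[k]]
  }
  default
}

#' Run the full target-discovery pipeline
#'
#' Executes, in order: expression filter, module discovery (Spearman
#' distance, Ward clustering, K selection), per-module differential
#' co-expression testing, eigengene/QTT trait association, and causal
#' reasoning over the regulome for the modules passing the differential
#' co-expression gate. Each stage's tables are written under
#' \code{outDir} before the next stage starts; a JSON run manifest is
#' written last.
#'
#' @param expr Expression: path, matrix or SummarizedExperiment
#'   (genes x samples, both conditions).
#' @param samples Sample table: path or data.frame (sample_id, condition,
#'   trait).
#' @param regulome Regulome: path or \linkS4class{Regulome} (NULL skips the
#'   causal stage).
#' @param de DE table: path or data.frame; NULL computes the built-in
#'   rank-sum stand-in.
#' @param outDir Output directory (created; NULL keeps results in memory
#'   only).
#' @param config Nested list overriding the defaults (see the package
#'   vignette); unset entries keep their defaults.
#' @return list with expressed genes, scores, partition, diffcoexpr,
#'   trait association, causal results and the manifest.
#' @export
runPipeline <- function(expr, samples, regulome = NULL, de = NULL,
                        outDir = NULL, config = list()) {
  cfg <- .mergeConfig(config)
  if (is.character(expr)) expr <- readExpression(expr)
  if (is.character(samples)) samples <- readSampleTable(samples)
  if (is.character(regulome)) regulome <- readRegulome(regulome)
  if (is.character(de)) de <- readDETable(de)
  m <- .asExprMatrix(expr)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) stop("stage io: samples missing from sample table: ",
                       paste(colnames(m)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  emit <- function(name, obj) {
    if (!is.null(outDir)) {
      dir.create(file.path(outDir, name), recursive = TRUE, showWarnings = FALSE)
      for (nm in names(obj))
        if (is.data.frame(obj[[nm]]))
          write.table(obj[[nm]], file.path(outDir, name, paste0(nm, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## filter
  filt <- stage("filter", function()
    filterExpressed(m, cfg$filter$threshold, cfg$filter$minFraction))
  expressed <- rownames(filt)
  isCase <- samples$condition == "case"
  mCase <- filt[, isCase, drop = FALSE]
  mCtrl <- filt[, !isCase, drop = FALSE]

  ## modules (built on case samples, the disease co-expression structure)
  modres <- stage("modules", function() {
    d <- spearmanDistance(mCase)
    tree <- wardCluster(d)
    kMax <- min(cfg$modules$kMax, nrow(d) - 1)
    scores <- scanPartitions(tree, d, cfg$modules$kMin, kMax)
    k <- selectK(scores, cfg$modules$select,
                 elbowFraction = cfg$modules$elbowFraction,
                 elbowWindow = cfg$modules$elbowWindow)
    list(scores = scores, k = k, partition = cutPartition(tree, k))
  })
  emit("modules", list(scores = modres$scores))
  if (!is.null(outDir)) {
    writeGMT(moduleList(modres$partition),
             file.path(outDir, "modules", "modules.gmt"))
    write.table(data.frame(gene_id = names(moduleAssignment(modres$partition)),
                           module = moduleAssignment(modres$partition)),
                file.path(outDir, "modules", "assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## differential co-expression
  dce <- stage("diffcoexpr", function()
    diffCoexprModules(mCase, mCtrl, modres$partition,
                      B = cfg$diffcoexpr$B, seed = cfg$seed,
                      minSize = cfg$diffcoexpr$minSize))
  emit("diffcoexpr", list(diffcoexpr = dce))

  ## trait association (skipped when no sample carries a trait)
  assoc <- NULL
  if (any(!is.na(samples$trait))) {
    assoc <- stage("associate", function() {
      eig <- lapply(moduleList(modres$partition), function(g)
        moduleEigengene(filt, g))
      list(eigengeneTrait = eigengeneTrait(eig, samples),
           enrichment = moduleTraitEnrichment(filt, modres$partition, samples,
                                              cfg$qtt$threshold))
    })
    emit("associate", list(eigengene_trait = assoc$eigengeneTrait,
                           module_qtt = assoc$enrichment$modules,
                           qtt_genes = assoc$enrichment$qtt$table))
  }

  ## causal reasoning on modules passing the differential co-expression gate
  causal <- NULL
  if (!is.null(regulome)) {
    gate <- cfg$gates$diffcoexpr
    keep <- if (is.null(gate)) dce$module else dce$module[dce$q < gate]
    if (length(keep)) {
      if (is.null(de)) de <- stage("de", function()
        rankSumDE(filt, samples$condition))
      causal <- stage("causal", function() {
        mods <- moduleList(modres$partition)[keep]
        craftCausal(regulome, expressed, mods, de,
                    universe = cfg$causal$universe,
                    signMode = cfg$causal$signMode,
                    alpha = cfg$causal$alpha)
      })
      emit("causal", list(effect_tests = causal$tests, calls = causal$calls))
      if (!is.null(outDir)) {
        for (sm in names(causal$rankings)) {
          write.table(causal$rankings[[sm]]$absolute,
                      file.path(outDir, "causal",
                                paste0("absolute_", sm, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          write.table(causal$rankings[[sm]]$relative,
                      file.path(outDir, "causal",
                                paste0("relative_", sm, ".tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
  }

  manifest <- list(
    tool = "craftr", version = as.character(packageVersion("craftr")),
    seed = cfg$seed, config = cfg,
    n_genes_input = nrow(m), n_expressed = length(expressed),
    n_samples = ncol(m), k_selected = as.integer(modres$k),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(expressed = expressed, scores = modres$scores, k = modres$k,
       partition = modres$partition, diffcoexpr = dce, association = assoc,
       causal = causal, manifest = manifest)
}
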