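# End-to-end orchestration: simulate -> normalize -> DE -> GRN -> NCA ->
# validate -> temporal -> enrichment, with a reproducible JSON manifest.

#' Build a pipeline run configuration
#'
#' All thresholds of the analysis with their standard defaults: CPM filter
#' 2 in more than 90 percent of samples, DEG |log2FC| > 1 and p < 0.05,
#' per-ecotype cap 1500, initial |PCC| > 0.70, final |PCC| >= 0.75,
#' semantic-similarity cutoff 0.3, TF split cutoff 0.001, enrichment
#' alpha 0.01. The object round-trips losslessly through YAML.
#'
#' @param outDir output directory for stage files and the manifest.
#' @param seed master seed; per-stage seeds derive from it.
#' @param cpmThreshold,sampleFraction expression-filter parameters.
#' @param fcThreshold,pThreshold DEG thresholds (log2 scale, raw p).
#' @param perEcotypeCap stress-affected cap per ecotype.
#' @param pcc0,pcc1 initial and final |PCC| cutoffs.
#' @param semsimCutoff functional-relevance similarity cutoff.
#' @param nBackground background sets for the similarity test.
#' @param splitCutoff TF split-score cutoff.
#' @param enrichAlpha enrichment p-value threshold.
#' @param dispersion NB dispersion passed to the DE tests (NULL =
#'   estimate).
#' @param simulation a \linkS4class{SimulationConfig} (used when no input
#'   files are supplied to \code{\link{runAll}}).
#' @return a list of class "stressGrnConfig".
#' @export
runConfig <- function(outDir = tempfile("stressgrn_run"), seed = 1L,
                      cpmThreshold = 2, sampleFraction = 0.90,
                      fcThreshold = 1, pThreshold = 0.05,
                      perEcotypeCap = 1500L, pcc0 = 0.70, pcc1 = 0.75,
                      semsimCutoff = 0.3, nBackground = 200L,
                      splitCutoff = 0.001, enrichAlpha = 0.01,
                      dispersion = NULL,
                      simulation = simulationConfig(seed = seed)) {
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              cpmThreshold = cpmThreshold, sampleFraction = sampleFraction,
              fcThreshold = fcThreshold, pThreshold = pThreshold,
              perEcotypeCap = as.integer(perEcotypeCap),
              pcc0 = pcc0, pcc1 = pcc1, semsimCutoff = semsimCutoff,
              nBackground = as.integer(nBackground),
              splitCutoff = splitCutoff, enrichAlpha = enrichAlpha,
              dispersion = dispersion, simulation = simulation)
  class(cfg) <- "stressGrnConfig"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a configuration from \code{\link{runConfig}}.
#' @param path YAML file.
#' @return \code{writeRunConfig}: invisibly, the path;
#'   \code{readRunConfig}: the configuration.
#' @export
writeRunConfig <- function(cfg, path) {
  sim <- cfg$simulation
  lst <- cfg
  class(lst) <- NULL
  lst$simulation <- list(
    nTfs = sim@nTfs, nTgs = sim@nTgs, nTimepoints = sim@nTimepoints,
    nReplicates = sim@nReplicates, nEcotypes = sim@nEcotypes,
    nHousekeeping = sim@nHousekeeping, edgeDensity = sim@edgeDensity,
    dispersion = sim@dispersion,
    librarySizeRange = sim@librarySizeRange,
    bifurcationTime = sim@bifurcationTime, seed = sim@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  sim <- lst$simulation
  simCfg <- simulationConfig(
    nTfs = sim$nTfs, nTgs = sim$nTgs, nTimepoints = sim$nTimepoints,
    nReplicates = sim$nReplicates, nEcotypes = sim$nEcotypes,
    nHousekeeping = sim$nHousekeeping, edgeDensity = sim$edgeDensity,
    dispersion = sim$dispersion,
    librarySizeRange = unlist(sim$librarySizeRange),
    bifurcationTime = if (is.null(sim$bifurcationTime)) NA_integer_ else
      sim$bifurcationTime,
    seed = sim$seed)
  lst$simulation <- simCfg
  do.call(runConfig, lst)
}

.stageCounts <- function(net) {
  e <- edgeTable(net)
  list(tfs = length(unique(e$tf)), targets = length(unique(e$tg)),
       interactions = nrow(e), positive = sum(e$sign == "+"),
       negative = sum(e$sign == "-"))
}

#' Run the full pipeline
#'
#' Executes every stage in order on either supplied input files or (by
#' default) a freshly generated synthetic study, writes each stage's
#' outputs under \code{cfg$outDir}, and returns a manifest (also written
#' as \code{manifest.json}) with versions, seeds, input digests and
#' per-stage record counts: the TF/target/interaction and
#' positive/negative tallies at the initial, NCA and final network
#' stages. Timestamps are deliberately excluded so identical inputs and
#' seeds give byte-identical manifests.
#'
#' @param cfg configuration from \code{\link{runConfig}}.
#' @param inputs optional named list of file paths (counts, meta, tfList,
#'   orthologMap, referenceSets, annotations, obo); when NULL the
#'   configured simulation supplies them.
#' @return the manifest list, invisibly the same as written to
#'   manifest.json. The stage objects are saved on the returned list
#'   under \code{objects} for interactive use.
#' @export
runAll <- function(cfg = runConfig(), inputs = NULL) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "stressGRN",
                   version = as.character(packageVersion("stressGRN")),
                   seed = cfg$seed)
  # --- stage: inputs -------------------------------------------------------
  if (is.null(inputs)) {
    sim <- simulateStudy(cfg$simulation)
    simDir <- file.path(cfg$outDir, "inputs")
    writeSimulation(sim, simDir)
    se <- sim$se
    tfList <- tfIds(sim$network)
    orthologMap <- sim$orthologMap
    referenceSets <- sim$referenceSets
    annotations <- sim$annotations
    dag <- sim$goDag
    truth <- sim$truth
    inputFiles <- list.files(simDir, full.names = TRUE)
  } else {
    se <- readCounts(inputs$counts, inputs$meta)
    tfList <- readTfList(inputs$tfList)
    orthologMap <- readOrthologMap(inputs$orthologMap)
    referenceSets <- readReferenceSets(inputs$referenceSets)
    annotations <- readAnnotations(inputs$annotations)
    dag <- readObo(inputs$obo)
    truth <- NULL
    inputFiles <- unlist(inputs, use.names = FALSE)
  }
  manifest$inputDigests <- as.list(tools::md5sum(sort(inputFiles)))
  names(manifest$inputDigests) <- basename(sort(inputFiles))
  # --- stage: normalization ------------------------------------------------
  nf <- tmmFactors(se)
  kept <- expressionFilter(se, cfg$cpmThreshold, cfg$sampleFraction, nf)
  .writeTsv(data.frame(sample_id = names(nf), factor = as.numeric(nf),
                       reference = names(nf) == attr(nf, "reference")),
            file.path(cfg$outDir, "tmm_factors.tsv"))
  manifest$normalization <- list(
    genesIn = nrow(se), genesKept = nrow(kept),
    referenceSample = attr(nf, "reference"))
  # --- stage: differential expression -------------------------------------
  de <- runDifferentialExpression(kept, normFactors = nf,
                                  dispersion = cfg$dispersion,
                                  fcThreshold = cfg$fcThreshold,
                                  pThreshold = cfg$pThreshold)
  .writeTsv(de, file.path(cfg$outDir, "differential_expression.tsv"))
  sets <- selectStressGenes(de, tfList, cfg$perEcotypeCap)
  manifest$diffexpr <- list(
    contrasts = nrow(unique(de[, c("ecotype", "time")])),
    degCalls = sum(de$is_deg),
    stressResponding = length(sets@stressResponding),
    tfs = length(sets@tfs), tgs = length(sets@tgs))
  # --- stage: GRN ----------------------------------------------------------
  cp <- cpmMatrix(kept, nf)
  expr <- log2(cp + 1)
  net0 <- pccNetwork(expr, sets@tfs, sets@tgs, cfg$pcc0)
  pruned <- pruneForNca(net0, seed = cfg$seed)
  dec <- ncaDecompose(expr, pruned$net, seed = cfg$seed)
  netF <- finalEdges(dec$net, expr, cfg$pcc1)
  writeGrn(net0, file.path(cfg$outDir, "edges_initial.tsv"))
  writeGrn(dec$net, file.path(cfg$outDir, "edges_nca.tsv"))
  writeGrn(netF, file.path(cfg$outDir, "edges_final.tsv"))
  .writeTsv(data.frame(tf = rownames(activities(dec$tfa)),
                       activities(dec$tfa), check.names = FALSE),
            file.path(cfg$outDir, "tfa.tsv"))
  manifest$grn <- list(
    initial = .stageCounts(net0),
    nca = .stageCounts(dec$net),
    final = .stageCounts(netF),
    removedTfs = pruned$removed,
    pRankOk = dec$pRankOk,
    objectiveStart = dec$trace[1], objectiveEnd = dec$trace[length(dec$trace)])
  # --- stage: validation ---------------------------------------------------
  orth <- validateByOrthology(netF, orthologMap, referenceSets)
  background <- sort(unique(annotations$gene))
  fun <- functionalRelevance(netF, annotations, dag,
                             cutoff = cfg$semsimCutoff,
                             nBackground = cfg$nBackground,
                             background = background, seed = cfg$seed)
  val <- orth$edges[, c("tf", "tg", "orthology_validated")]
  val$funct_validated <- fun$validatedEdges$funct_validated[
    match(paste(val$tf, val$tg),
          paste(fun$validatedEdges$tf, fun$validatedEdges$tg))]
  val$either_validated <- val$orthology_validated | val$funct_validated
  .writeTsv(val, file.path(cfg$outDir, "edge_validation.tsv"))
  manifest$validation <- list(
    orthologyValidated = sum(val$orthology_validated),
    functValidated = sum(val$funct_validated),
    eitherValidated = sum(val$either_validated),
    perSource = orth$perSource,
    wilcoxonP = lapply(fun$perTf, `[[`, "wilcoxonP"))
  # --- stage: temporal maps ------------------------------------------------
  temporal <- list()
  for (eco in sort(unique(de$ecotype))) {
    traj <- buildTrajectories(de, eco, genes = tgIds(netF))
    map <- fitTemporalMap(traj, seed = .subSeed(cfg$seed, 7L))
    sc <- if (length(splitNodes(map)))
      scoreSplits(map, netF, cfg$splitCutoff) else NULL
    chains <- chainSummary(map, traj, sc)
    enr <- lapply(chains, function(ch) {
      if (length(ch$members) < 2L) return(NULL)
      goEnrichment(intersect(ch$members, background), annotations, dag,
                   background, alpha = cfg$enrichAlpha)
    })
    chains <- chainSummary(map, traj, sc, enr)
    temporal[[eco]] <- list(map = map, splits = sc, chains = chains)
    jsonlite::write_json(
      list(nodes = map@nodes, edges = map@edges,
           paths = map@paths,
           assignments = as.list(assignments(map)),
           splits = sc),
      file.path(cfg$outDir, sprintf("temporal_map_%s.json", eco)),
      auto_unbox = TRUE, digits = NA, null = "null")
    manifest$temporal[[eco]] <- list(
      chains = length(pathList(map)),
      splits = length(splitNodes(map)),
      reportedTfs = if (is.null(sc)) 0L else
        length(unique(sc$tf[sc$reported])))
  }
  manifest$configuration <- list(
    cpmThreshold = cfg$cpmThreshold, sampleFraction = cfg$sampleFraction,
    fcThreshold = cfg$fcThreshold, pThreshold = cfg$pThreshold,
    perEcotypeCap = cfg$perEcotypeCap, pcc0 = cfg$pcc0, pcc1 = cfg$pcc1,
    semsimCutoff = cfg$semsimCutoff, splitCutoff = cfg$splitCutoff,
    enrichAlpha = cfg$enrichAlpha)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  manifest$objects <- list(se = se, filtered = kept, normFactors = nf,
                           de = de, sets = sets, initial = net0,
                           pruned = pruned, decomposition = dec,
                           final = netF, orthology = orth,
                           functional = fun, temporal = temporal,
                           truth = truth)
  invisible(manifest)
}
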