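#' Pipeline configuration
#'
#' Bundles every stage's thresholds and constants plus the master seed.
#' Validation happens at construction time, before any stage executes.
#'
#' @param outDir run directory (created by \code{\link{runPipeline}}).
#' @param seed master integer seed driving every stochastic step.
#' @param simulation a \code{\link{simulationConfig}} (its seed is set
#'   from \code{seed} unless supplied explicitly).
#' @param detP,detPFraction,beadCount probe-filter thresholds.
#' @param bmiq run beta-mixture quantile normalization (default FALSE:
#'   the synthetic cohorts are emitted on a single common scale, and
#'   remapping an already-harmonized cohort only injects per-sample map
#'   noise; enable for real Infinium cohorts with a type II scale bias).
#' @param kRange,nBoot candidates and bootstrap count for
#'   \code{\link{selectK}}.
#' @param qThresh,dbThresh DMP criterion.
#' @param nPerm colocalization permutations.
#' @param minMethods consensus membership threshold (1..4).
#' @param diamondN DIAMOnD nodes to add.
#' @param vwp MCODE vertex weight percentage.
#' @param ccIter,ccFreq Correlation Clique iterations / frequency
#'   cutoff.
#' @param diseaseSigns named vector of disease effect signs relative to
#'   the pregnancy effects (each -1 or +1).
#' @param vistaMaxRemoved VIStA-style removal budget fraction.
#' @return validated list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir = tempfile("methrun"), seed = 1L,
    simulation = NULL, detP = 0.01, detPFraction = 0, beadCount = 3,
    bmiq = FALSE, kRange = 1:3, nBoot = 16L, qThresh = 0.05,
    dbThresh = 0.05, nPerm = 200L, minMethods = 3L, diamondN = 20L,
    vwp = 0.2, ccIter = 30L, ccFreq = 0.5,
    diseaseSigns = c(diseaseA = -1, diseaseB = -1, diseaseC = 1),
    vistaMaxRemoved = 0.5) {
  if (is.null(simulation)) simulation <- simulationConfig(seed = seed)
  cfg <- list(outDir = outDir, seed = as.integer(seed),
              simulation = simulation, detP = detP,
              detPFraction = detPFraction, beadCount = beadCount,
              bmiq = bmiq, kRange = kRange, nBoot = as.integer(nBoot),
              qThresh = qThresh, dbThresh = dbThresh,
              nPerm = as.integer(nPerm),
              minMethods = as.integer(minMethods),
              diamondN = as.integer(diamondN), vwp = vwp,
              ccIter = as.integer(ccIter), ccFreq = ccFreq,
              diseaseSigns = diseaseSigns,
              vistaMaxRemoved = vistaMaxRemoved)
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  if (cfg$minMethods < 1 || cfg$minMethods > 4)
    stop("minMethods must lie in 1..4")
  if (cfg$qThresh <= 0 || cfg$qThresh >= 1)
    stop("qThresh must lie in (0, 1)")
  if (cfg$dbThresh < 0 || cfg$dbThresh >= 1)
    stop("dbThresh must lie in [0, 1)")
  if (any(!cfg$diseaseSigns %in% c(-1, 1)))
    stop("disease signs must be -1 or +1")
  if (cfg$nPerm < 10) stop("nPerm must be >= 10")
  if (cfg$vistaMaxRemoved < 0 || cfg$vistaMaxRemoved >= 1)
    stop("vistaMaxRemoved must lie in [0, 1)")
  validateSimulationConfig(cfg$simulation)
  invisible(cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes simulate -> probe filtering -> normalization ->
#' deconvolution (with K selection) -> differential methylation (three
#' contrasts) -> network module detection (four methods + consensus +
#' colocalization) -> disease analysis (subgroup selection, CpG
#' enrichment, direction correlation per configured disease), writing
#' every intermediate table, a machine-readable manifest and a summary
#' JSON into the run directory.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, a list with \code{summary} (also written as
#'   \code{summary.json}), the run directory and the key intermediate
#'   objects.
#' @export
runPipeline <- function(config) {
  validatePipelineConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)

  sim <- stage("simulate", simulateCohort(config$simulation))
  ds <- sim$dataset
  writeBetaTsv(ds, out("beta_raw.tsv"))
  writeSampleSheet(ds, out("samples.csv"))
  writeProbeAnnotation(ds, out("probes.tsv"))

  ds <- stage("preprocess", {
    f <- filterProbes(ds, detP = config$detP,
                      detPFraction = config$detPFraction,
                      beadCount = config$beadCount)
    if (config$bmiq) f <- bmiqNormalize(f) else f
  })
  fr <- filterReport(ds)
  jsonlite::write_json(fr[c("counts", "retained", "input", "order")],
                       out("filter_report.json"), auto_unbox = TRUE,
                       digits = NA)
  writeBetaTsv(ds, out("beta_normalized.tsv"))

  dec <- stage("deconvolution", {
    ks <- selectK(ds, kRange = config$kRange, nBoot = config$nBoot,
                  seed = config$seed)
    fit <- refFreeDecompose(ds, ks$k, seed = config$seed)
    write.table(ks$devianceTable, out("k_selection.tsv"), sep = "\t",
                quote = FALSE)
    write.table(data.frame(sample = rownames(cellProportions(fit)),
                           cellProportions(fit)),
                out("omega.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(k = ks$k, fit = fit)
  })
  omega <- cellProportions(dec$fit)

  dmps <- stage("diffmeth", dmpTable(ds, omega, config$qThresh,
                                     config$dbThresh))
  write.table(dmps, out("dmp_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ann <- probeGenes(ds)
  dmgs <- stage("diffmeth", mapDmpsToGenes(dmps, ann))
  write.table(dmgs, out("dmg_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mds <- stage("diffmeth", mdsCoordinates(ds))
  write.table(data.frame(sample = rownames(mds$coords), mds$coords),
              out("mds_coordinates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  seedsT2 <- dmgs$gene[dmgs$contrast == "T2_vs_NP"]
  dirT2 <- setNames(dmgs$direction[dmgs$contrast == "T2_vs_NP"],
                    seedsT2)

  net <- stage("netmodule", {
    sn <- simulateNetwork(config$simulation,
                          effectGenes = unique(sim$truth$effects$gene),
                          seed = config$seed)
    writeStringEdges(sn$network, out("network_edges.tsv"))
    writeSif(sn$network, out("network.sif"))
    coloc <- colocalizationTest(sn$network, seedsT2,
                                nPerm = config$nPerm,
                                seed = config$seed)
    jsonlite::write_json(list(dObs = coloc@dObs,
                              dNullMean = mean(coloc@dNull),
                              p = coloc@p, nSeeds = coloc@nSeeds),
                         out("colocalization.json"), auto_unbox = TRUE,
                         digits = NA)
    mres <- list(
      runMcode(sn$network, seedsT2, vwp = config$vwp),
      runDiamond(sn$network, seedsT2, nAdded = config$diamondN),
      runCliqueSum(sn$network, seedsT2),
      runCorrelationClique(sn$network, seedsT2, nIter = config$ccIter,
                           freqCutoff = config$ccFreq,
                           rngSeed = config$seed))
    for (m in mres)
      write.table(data.frame(gene = m@genes),
                  out(paste0("module_", m@method, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    cons <- buildConsensus(mres, minMethods = config$minMethods,
                           dmgDirections = dirT2)
    write.table(data.frame(gene = cons@genes, cons@membership,
                           seedOrigin = cons@seedOrigin,
                           direction = cons@direction),
                out("module_consensus.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(network = sn$network, truth = sn$truth, coloc = coloc,
         methods = mres, consensus = cons)
  })

  modCpgs <- stage("netmodule",
                   moduleToCpgs(net$consensus, ann, dmps, "T2_vs_NP"))
  write.table(modCpgs, out("module_cpgs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  diseases <- stage("disease", {
    lapply(seq_along(config$diseaseSigns), function(i) {
      dzName <- names(config$diseaseSigns)[i]
      cfgDz <- config$simulation
      cfgDz$disease$effectSign <- unname(config$diseaseSigns[i])
      dz <- simulateDiseaseCohort(cfgDz, sim$truth,
                                  seed = deriveSeed(config$seed,
                                                    900L + i))
      dx <- filterSamples(dz$dataset, sex == "F")
      dx <- dx[rownames(ds), ]          # same probe universe post-filter
      decDz <- refFreeDecompose(dx, dec$k,
                                seed = deriveSeed(config$seed, 950L + i))
      omDz <- cellProportions(decDz)
      sel <- vistaSubgroups(dx, omDz, config$qThresh, config$dbThresh,
                            maxRemovedFraction = config$vistaMaxRemoved)
      kept <- c(sel$caseIds, sel$controlIds)
      dxr <- dx[, kept]
      dmpsDz <- dmpTable(dxr, omDz[kept, , drop = FALSE],
                         config$qThresh, config$dbThresh,
                         refGroup = "control")
      dzDmps <- dmpsDz$probe[dmpsDz$isDMP]
      enr <- tryCatch(cpgEnrichment(modCpgs$probe, dzDmps, rownames(ds)),
                      error = function(e) NULL)
      dzEff <- setNames(dmpsDz$deltaBeta, dmpsDz$probe)
      modEff <- setNames(modCpgs$deltaBeta, modCpgs$probe)
      corRes <- tryCatch(
        directionCorrelation(modEff, dzEff,
                             intersect(modCpgs$probe, dzDmps)),
        error = function(e) NULL)
      write.table(dmpsDz[dmpsDz$isDMP, ],
                  out(paste0("disease_", dzName, "_dmps.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(sel$removed,
                  out(paste0("disease_", dzName, "_removed.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(name = dzName, sign = unname(config$diseaseSigns[i]),
           selection = sel, enrichment = enr, correlation = corRes,
           truth = dz$truth, nDmps = length(dzDmps))
    })
  })

  summary <- list(
    seed = config$seed,
    retainedProbes = fr$retained,
    selectedK = dec$k,
    nDmpT2vsNP = sum(dmps$isDMP & dmps$contrast == "T2_vs_NP"),
    nDmgT2vsNP = length(seedsT2),
    moduleSize = length(net$consensus@genes),
    moduleSeedOrigin = sum(net$consensus@seedOrigin),
    moduleSeedOriginFraction =
      if (length(net$consensus@genes) > 0)
        sum(net$consensus@seedOrigin) / length(net$consensus@genes)
      else NA,
    colocalization = list(dObs = net$coloc@dObs,
                          dNullMean = mean(net$coloc@dNull),
                          p = net$coloc@p),
    diseases = lapply(diseases, function(d) list(
      name = d$name, plantedSign = d$sign,
      removedControls = nrow(d$selection$removed),
      nDiseaseDmps = d$nDmps,
      foldEnrichment = if (is.null(d$enrichment)) NA else d$enrichment@fe,
      enrichmentP = if (is.null(d$enrichment)) NA else d$enrichment@p,
      pearsonR = if (is.null(d$correlation)) NA else d$correlation$pearsonR,
      pearsonP = if (is.null(d$correlation)) NA else d$correlation$pearsonP,
      observedSign = if (is.null(d$correlation)) NA else d$correlation$sign)))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(package = "MethylModule",
                   version = as.character(utils::packageVersion("MethylModule")),
                   rVersion = as.character(getRversion()),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("simulation", "outDir"))])
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(summary = summary, outDir = config$outDir,
                 dataset = ds, truth = sim$truth,
                 decomposition = dec$fit, dmps = dmps, dmgs = dmgs,
                 network = net, moduleCpgs = modCpgs,
                 diseases = diseases))
}
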