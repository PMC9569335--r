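#' @include synthetic-genotypes.R synthetic-peaks.R sldsc.R clumping.R
#' @include comparisons.R pathways.R io.R
NULL

#' Pipeline stage names, in dependency order
#'
#' @return Character vector of the stage names [runPipeline()] accepts.
#' @export
pipelineStages <- function()
  c("simulate", "annotate", "ldscore", "sldsc", "clump", "cheers",
    "compare", "pathways")

#' Read and validate a pipeline configuration
#'
#' A single YAML (or JSON) document drives [runPipeline()].  Recognized
#' top-level keys: `seed`, `stages` (subset of the stage names, default
#' all), `simulation` (arguments to [simulationConfig()]), `plantedTau`
#' (named map annotation -> tau), `disorders` (labels; one summary-stat
#' draw each), `targetState`, `windowBp`, `sldsc` (`nBlocks`, `weights`),
#' `clump` (`pThreshold`, `distanceBp`, `minLoci`), `cheers`
#' (`r2Threshold`), `pathways` (`specificityThreshold`, `maxTssDistance`,
#' `promoterWindow`, `nGenes`, `geneWidth`).  Numeric analysis constants
#' default to the conventional values (P < 5e-8, +/- 500 kb, r^2 > 0.8,
#' MAC >= 10, MAF > 0.01, rank > 0.9, 10 kb TSS cap, 3 minimum loci).
#'
#' @param path YAML/JSON file path, or a list to validate directly.
#' @return Validated config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, stages = pipelineStages(),
    simulation = list(), plantedTau = list(active = 0),
    disorders = c("disorderA", "disorderB"), targetState = "state1",
    windowBp = 100000L,
    sldsc = list(nBlocks = 100L, weights = "ldsc"),
    clump = list(pThreshold = 5e-8, distanceBp = 500000, minLoci = 3,
                 minMac = 10, minMaf = 0.01, mhcBuild = "GRCh38"),
    cheers = list(r2Threshold = 0.8),
    pathways = list(specificityThreshold = 0.9, maxTssDistance = 10000,
                    promoterWindow = 3000, nGenes = 200L,
                    geneWidth = 20000L))
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- modifyList(defaults[[k]], cfg[[k]])
  }
  unknown <- setdiff(cfg$stages, pipelineStages())
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run the whole analysis pipeline on synthetic data
#'
#' Executes the requested stages in dependency order: simulate the
#' genotype panel, segmentation, peak matrix and per-disorder summary
#' statistics; build the active and element-class annotations; compute
#' partitioned LD scores; fit the stratified LD-score regression per
#' disorder; filter and clump each disorder to lead variants; run the
#' specificity-rank enrichment with LD expansion; cross-disorder
#' comparisons; and over-representation analysis.  All outputs are
#' TSV/BED/JSON under `outDir`, and a JSON run manifest records the config
#' snapshot, seeds, per-stage record counts and md5 digests of every
#' output file.
#'
#' @param config a config list or YAML path (see [readPipelineConfig()]).
#' @param outDir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @param resume if `TRUE` and a manifest with an identical config
#'   snapshot exists whose recorded file digests all match the files on
#'   disk, the run is skipped and the recorded manifest returned.
#' @return The manifest (list), invisibly written to
#'   `file.path(outDir, "manifest.json")`.
#' @export
runPipeline <- function(config, outDir, seed = NULL, resume = FALSE) {
  cfg <- readPipelineConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(outDir, "manifest.json")
  cfgDigest <- digestOf(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  if (resume && file.exists(manifestPath)) {
    old <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    digests <- unlist(unname(lapply(old$stages, `[[`, "digests")))
    onDisk <- unname(md5sum(file.path(outDir, names(digests))))
    if (identical(old$configDigest, cfgDigest) &&
        !anyNA(onDisk) && all(onDisk == unname(digests))) {
      message("runPipeline: digests match; resuming from existing outputs")
      return(invisible(old))
    }
  }
  scfg <- do.call(simulationConfig,
                  c(list(seed = cfg$seed), cfg$simulation))
  tau <- unlist(cfg$plantedTau)
  manifest <- list(package = "epienrich",
                   version = as.character(utils::packageVersion("epienrich")),
                   created = format(Sys.time(), tz = "UTC"),
                   seed = cfg$seed, config = cfg, configDigest = cfgDigest,
                   stages = list())
  record <- function(stage, files, counts) {
    ds <- md5sum(file.path(outDir, files))
    names(ds) <- files
    manifest$stages[[stage]] <<- list(digests = as.list(ds), counts = counts)
  }
  want <- function(s) s %in% cfg$stages

  # ---- simulate ----
  panel <- simulateGenotypePanel(scfg)
  seg <- simulateSegmentation(scfg)
  active <- mergeActiveStates(seg)
  classes <- classAnnotations(seg)
  psm <- simulatePeakMatrix(scfg)
  statsList <- lapply(seq_along(cfg$disorders), function(i) {
    di <- scfg; di$seed <- stageSeed(scfg$seed, cfg$disorders[[i]])
    di$plantedTau <- setNames(as.numeric(tau), names(tau))
    simulateSummaryStats(panel, list(active = active)[names(tau)], di,
                         mode = "analytic", windowBp = cfg$windowBp)
  })
  names(statsList) <- cfg$disorders
  if (want("simulate")) {
    writeGenotypePanel(panel, file.path(outDir, "panel"))
    writePeakMatrix(psm, file.path(outDir, "peaks"))
    rtracklayer::export(seg, file.path(outDir, "segmentation.bed"),
                        format = "BED")
    for (d in cfg$disorders)
      writeSummaryStats(statsList[[d]],
                        file.path(outDir, paste0("sumstats_", d, ".tsv")))
    fwrite(data.table::data.table(annotation = names(tau), tau = tau),
           file.path(outDir, "truth_tau.tsv"), sep = "\t")
    record("simulate",
           c("panel.map.tsv", "panel.geno.tsv", "peaks.bed",
             "peaks.signal.tsv", "segmentation.bed", "truth_tau.tsv",
             paste0("sumstats_", cfg$disorders, ".tsv")),
           list(variants = scfg$nVariants, peaks = nrow(psm),
                individuals = scfg$nIndividuals))
  }

  # ---- annotate ----
  if (want("annotate")) {
    writeAnnotationBed(active, file.path(outDir, "active.bed"))
    for (cl in names(classes))
      writeAnnotationBed(classes[[cl]],
                         file.path(outDir, paste0("class_", cl, ".bed")))
    record("annotate",
           c("active.bed", paste0("class_", names(classes), ".bed")),
           list(active_bp = coveredBases(active)))
  }

  # ---- ldscore ----
  annList <- c(list(active = active), classes,
               list(total = annotationSet("total",
                 GRanges("chr1", IRanges(1, genomeLength(scfg))))))
  lds <- partitionedLdScores(panel, annList, windowBp = cfg$windowBp)
  if (want("ldscore")) {
    writeLdScores(lds, file.path(outDir, "ldscores.tsv"))
    record("ldscore", "ldscores.tsv",
           list(variants = nrow(ldScores(lds)),
                annotations = ncol(ldScores(lds))))
  }

  # ---- sldsc ----
  fits <- lapply(statsList, fitSldsc, ldscores = lds,
                 modelAnnotations = "active",
                 nBlocks = cfg$sldsc$nBlocks, weights = cfg$sldsc$weights)
  if (want("sldsc")) {
    tab <- do.call(rbind, lapply(cfg$disorders, function(d) {
      cbind(disorder = d, coefficientTable(fits[[d]]),
            intercept = fits[[d]]@intercept)
    }))
    fwrite(as.data.table(tab), file.path(outDir, "sldsc_results.tsv"),
           sep = "\t")
    record("sldsc", "sldsc_results.tsv", list(models = length(fits)))
  }

  # ---- clump ----
  mhc <- mhcRegion(cfg$clump$mhcBuild)
  leadsList <- lapply(cfg$disorders, function(d) {
    st <- suppressMessages(filterMac(statsList[[d]],
                                     minMac = cfg$clump$minMac))
    st <- suppressMessages(filterMafPanel(st, panel,
                                          minMaf = cfg$clump$minMaf))
    clumpVariants(st, pThreshold = cfg$clump$pThreshold,
                  distanceBp = cfg$clump$distanceBp, mhc = mhc,
                  disorder = d)
  })
  names(leadsList) <- cfg$disorders
  if (want("clump")) {
    all <- do.call(rbind, leadsList)
    fwrite(as.data.table(all), file.path(outDir, "leads.tsv"), sep = "\t")
    record("clump", "leads.tsv",
           lapply(leadsList, nrow) |> setNames(cfg$disorders))
  }

  # ---- cheers ----
  overlapsList <- list(); cheersList <- list()
  for (d in cfg$disorders) {
    leads <- leadsList[[d]]
    if (!checkMinLoci(leads, cfg$clump$minLoci)) {
      message("disorder ", d, " ineligible for specificity-rank analysis")
      next
    }
    nb <- expandLeads(panel, leads$SNP,
                      r2Threshold = cfg$cheers$r2Threshold,
                      windowBp = cfg$windowBp)
    ov <- overlapVariants(psm, neighborhoodRanges(nb))
    if (!nrow(ov)) {
      message("disorder ", d, ": no variant-peak overlap; skipped")
      next
    }
    overlapsList[[d]] <- ov
    cheersList[[d]] <- cheersTest(psm, ov)
  }
  if (want("cheers")) {
    if (length(cheersList)) {
      tab <- do.call(rbind, lapply(names(cheersList), function(d)
        cbind(disorder = d, enrichmentTable(cheersList[[d]]))))
      fwrite(as.data.table(tab), file.path(outDir, "cheers_results.tsv"),
             sep = "\t")
      ovTab <- do.call(rbind, lapply(names(overlapsList), function(d)
        cbind(disorder = d, overlapsList[[d]])))
      fwrite(as.data.table(ovTab), file.path(outDir, "cheers_overlaps.tsv"),
             sep = "\t")
      record("cheers", c("cheers_results.tsv", "cheers_overlaps.tsv"),
             lapply(overlapsList, nrow) |> setNames(names(overlapsList)))
    } else message("cheers stage: no eligible disorder")
  }

  # ---- compare ----
  if (want("compare") && length(overlapsList) >= 2L) {
    sh <- sharingCounts(overlapsList)
    fwrite(as.data.table(sh$cells), file.path(outDir, "sharing_cells.tsv"),
           sep = "\t")
    d1 <- names(overlapsList)[1]; d2 <- names(overlapsList)[2]
    disc <- discordantPeaks(psm, overlapsList[[d1]], overlapsList[[d2]],
                            classes = classes,
                            statsA = statsList[[d1]], statsB = statsList[[d2]])
    discTab <- data.frame(
      peak = c(disc$onlyA, disc$onlyB),
      only_in = c(rep(d1, length(disc$onlyA)), rep(d2, length(disc$onlyB))))
    discTab$classes <- vapply(disc$classes[discTab$peak],
                              paste, character(1), collapse = ";")
    fwrite(as.data.table(discTab), file.path(outDir, "discordant_peaks.tsv"),
           sep = "\t")
    z1 <- enrichmentTable(cheersList[[d1]])$z
    z2 <- enrichmentTable(cheersList[[d2]])$z
    compareFiles <- c("sharing_cells.tsv", "discordant_peaks.tsv")
    if (length(z1) >= 3 && all(is.finite(c(z1, z2)))) {
      corr <- spearmanExact(z1, z2, nBoot = 1000L,
                            seed = stageSeed(cfg$seed, "bootstrap"))
      jsonlite::write_json(
        list(n = corr$n, S = corr$S, rho = corr$rho, p = corr$p,
             method = corr$method, ci = corr$ci),
        file.path(outDir, "correlation.json"), auto_unbox = TRUE,
        digits = NA)
      compareFiles <- c(compareFiles, "correlation.json")
    }
    record("compare", compareFiles,
           list(shared_cells = nrow(sh$cells), discordant = nrow(discTab)))
  }

  # ---- pathways ----
  if (want("pathways") && length(overlapsList)) {
    genes <- simulateGeneModel(scfg, nGenes = cfg$pathways$nGenes,
                               geneWidth = cfg$pathways$geneWidth)
    sets <- simulateGeneSets(scfg, genes)
    writeGeneModel(genes, file.path(outDir, "genes.tsv"))
    writeGmt(sets, file.path(outDir, "genesets.gmt"))
    d <- names(overlapsList)[1]
    testPeaks <- selectTestPeaks(psm, overlapsList[[d]],
      specificityThreshold = cfg$pathways$specificityThreshold)
    geneList <- peaksToGenes(psm, genes,
      maxTssDistance = cfg$pathways$maxTssDistance,
      promoterWindow = cfg$pathways$promoterWindow, peakIds = testPeaks)
    if (length(geneList)) {
      ora <- oraTest(geneList, sets, universe = mcols(genes)$gene_id)
      fwrite(as.data.table(ora), file.path(outDir, "ora_results.tsv"),
             sep = "\t")
      record("pathways", c("genes.tsv", "genesets.gmt", "ora_results.tsv"),
             list(test_peaks = length(testPeaks),
                  test_genes = length(geneList), sets = length(sets)))
    } else {
      message("pathways stage skipped: empty test gene list")
      record("pathways", c("genes.tsv", "genesets.gmt"),
             list(test_peaks = length(testPeaks), test_genes = 0L))
    }
  }

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

digestOf <- function(x) {
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(md5sum(tf))
}
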