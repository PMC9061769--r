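# End-to-end orchestration: simulate -> cluster -> abundance -> link ->
# ecology -> network -> biogeo -> pathfit, with dependency closure, one
# reproducibility seed, and a figure-level summary report.

.stageOrder <- c("simulate", "cluster", "abundance", "link", "ecology",
                 "network", "biogeo", "pathfit")

.stageDeps <- list(
  simulate = character(0),
  cluster = "simulate",
  abundance = c("simulate", "cluster"),
  link = c("simulate", "cluster"),
  ecology = c("abundance", "link"),
  network = c("link", "abundance"),
  biogeo = "abundance",
  pathfit = "simulate")

.stageClosure <- function(stages) {
  out <- character(0)
  add <- function(s) {
    if (s %in% out) return(invisible())
    for (d in .stageDeps[[s]]) add(d)
    out <<- c(out, s)
  }
  for (s in stages) add(s)
  .stageOrder[.stageOrder %in% out]
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order (the closure of their
#' requirements is computed automatically): dataset simulation and
#' serialization, vOTU clustering and host dereplication, depth-track
#' abundance matrices, three-evidence host linkage aggregated to
#' populations, lineage-level VHR/correlation/range/lifestyle summaries,
#' per-sample bipartite network metrics with richness regressions,
#' biogeography (Hellinger/Bray-Curtis, PCoA, Mantel, distance decay), and
#' the recursive path model. Writes per-stage TSV/JSON outputs plus
#' `report.json` under `outDir`; identical config and seed give identical
#' outputs.
#'
#' @param config A [simConfig()] (its `seed` drives every stage through
#'   [deriveSeed()]).
#' @param outDir Output directory.
#' @param stages Character subset of
#'   `c("simulate", "cluster", "abundance", "link", "ecology", "network",
#'   "biogeo", "pathfit")`, or `"all"`.
#' @param datasetDir Optional pre-existing dataset directory (from
#'   [writeDataset()]); when given, the simulate stage is not required.
#' @param homology `"align"` recomputes homology hits with the built-in
#'   aligner; `"dataset"` consumes the dataset's tabular hit file.
#' @param brimRestarts BRIM restarts for per-sample modularity.
#' @return The report (named list), invisibly also written as JSON.
#' @export
runPipeline <- function(config = simConfig(), outDir = tempfile("amdvir_"),
                        stages = "all", datasetDir = NULL,
                        homology = c("align", "dataset"),
                        brimRestarts = 10L) {
  homology <- match.arg(homology)
  stages <- if (identical(stages, "all")) .stageOrder
            else match.arg(stages, .stageOrder, several.ok = TRUE)
  closure <- .stageClosure(stages)
  if (!is.null(datasetDir)) closure <- setdiff(closure, "simulate")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  report <- list(seed = config$seed, stages = closure,
                 thresholds = list(votu_ani = 95, votu_af = 85,
                                   prok_ani = 97, prok_af = 70,
                                   homology = list(evalue = 1e-3, bits = 50,
                                                   length = 2500, id = 70)))
  wTsv <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  loadData <- function() {
    if (is.null(st$data)) {
      dd <- datasetDir %||% file.path(outDir, "dataset")
      if (!file.exists(file.path(dd, "manifest.tsv")))
        stop("dependency error: stage needs a dataset; run 'simulate' or ",
             "supply datasetDir")
      st$data <- readDataset(dd)
    }
    st$data
  }

  for (stage in closure) {
    switch(stage,
      simulate = {
        ds <- simulateDataset(config)
        writeDataset(ds, file.path(outDir, "dataset"))
        st$data <- readDataset(file.path(outDir, "dataset"))
        st$truth <- ds$sequences$truth
        report$simulate <- list(
          n_viral_genomes = length(ds$sequences$viruses),
          n_host_genomes = length(ds$sequences$hosts),
          n_samples = ncol(abundance(ds$ecology$virusAbundance)))
      },
      cluster = {
        d <- loadData()
        st$votus <- clusterViralPopulations(d$viruses)
        hostMeta <- d$genomeMeta[d$genomeMeta$kind == "prokaryotic", ]
        st$hostClusters <- dereplicateProkaryoteGenomes(
          d$hosts,
          completeness = stats::setNames(hostMeta$completeness,
                                         hostMeta$id)[names(d$hosts)],
          contamination = stats::setNames(hostMeta$contamination,
                                          hostMeta$id)[names(d$hosts)])
        wTsv(st$votus, "votu_clusters.tsv")
        wTsv(st$hostClusters, "host_populations.tsv")
        report$cluster <- list(
          n_votus = length(unique(st$votus$representative)),
          n_host_populations =
            length(unique(st$hostClusters$representative)))
      },
      abundance = {
        d <- loadData()
        cov <- coverageFromDepthRuns(d$depthRuns)
        am <- buildAbundanceMatrix(cov, d$librarySizes)
        m <- abundance(am)
        vir <- intersect(rownames(m),
                         d$genomeMeta$id[d$genomeMeta$kind == "viral"])
        hst <- intersect(rownames(m),
                         d$genomeMeta$id[d$genomeMeta$kind == "prokaryotic"])
        st$virusAbund <- AbundanceMatrix(m[vir, , drop = FALSE],
                                         d$librarySizes)
        st$hostAbund <- AbundanceMatrix(m[hst, , drop = FALSE],
                                        d$librarySizes)
        report$abundance <- list(
          n_virus_entities = length(vir), n_host_entities = length(hst))
      },
      link = {
        d <- loadData()
        spacers <- extractSpacers(d$hosts)
        spHits <- matchSpacers(spacers, d$viruses)
        crisprPairs <- if (nrow(spHits)) {
          m <- merge(spHits, d$binning, by.x = "host_scaffold",
                     by.y = "scaffold")
          unique(data.frame(virus = m$virus, host = m$host_genome,
                            evidence = "crispr", stringsAsFactors = FALSE))
        } else data.frame(virus = character(0), host = character(0),
                          evidence = character(0))
        homHits <- if (homology == "align")
          searchHomology(d$viruses, d$hosts) else d$homologyHits
        homPairs <- linkByGenomeHomology(homHits)
        if (nrow(homPairs)) homPairs$evidence <- "homology"
        else homPairs$evidence <- character(0)
        vm <- d$genomeMeta[d$genomeMeta$kind == "viral", ]
        proPairs <- linkByProphageOrigin(
          data.frame(id = vm$id, source_scaffold = vm$source_scaffold,
                     stringsAsFactors = FALSE), d$binning)
        if (nrow(proPairs)) proPairs$evidence <- "prophage"
        else proPairs$evidence <- character(0)
        pairs <- rbind(crisprPairs, homPairs, proPairs)
        st$links <- aggregatePopulationLinks(pairs,
                                             clusterMap(st$votus),
                                             clusterMap(st$hostClusters))
        wTsv(spacers, "crispr_spacers.tsv")
        wTsv(st$links, "virus_host_links.tsv")
        report$link <- list(
          n_spacers = nrow(spacers),
          n_genome_pairs = nrow(unique(pairs[c("virus", "host")])),
          n_population_links = nrow(st$links),
          n_linked_votus = length(unique(st$links$virus_population)),
          n_linked_host_populations =
            length(unique(st$links$host_population)))
      },
      ecology = {
        d <- loadData()
        phylumMap <- stats::setNames(
          d$taxonomy$phylum[match(rownames(abundance(st$hostAbund)),
                                  d$taxonomy$genome)],
          rownames(abundance(st$hostAbund)))
        st$phylumMap <- phylumMap[!is.na(phylumMap)]
        vhr <- lineageVhr(st$virusAbund, st$hostAbund, st$links,
                          st$phylumMap)
        corr <- lineageAbundanceCorrelation(st$virusAbund, st$hostAbund,
                                            st$links, st$phylumMap)
        rng <- hostViralRange(st$links, st$phylumMap)
        vm <- d$genomeMeta[d$genomeMeta$kind == "viral", ]
        lifestyles <- stats::setNames(vm$lifestyle, vm$id)
        trend <- lifestyleRatioTrend(st$virusAbund, lifestyles,
                                     colSums(abundance(st$hostAbund)))
        st$vhr <- vhr
        wTsv(vhr, "lineage_vhr.tsv")
        wTsv(corr, "lineage_correlation.tsv")
        wTsv(rng, "lineage_ranges.tsv")
        wTsv(trend$trend, "lifestyle_trend.tsv")
        report$ecology <- list(
          vhr = stats::setNames(as.list(vhr$mean_log10_vhr), vhr$phylum),
          correlation = stats::setNames(as.list(corr$r), corr$phylum),
          lifestyle_slopes = stats::setNames(as.list(trend$trend$slope),
                                             trend$trend$class))
      },
      network = {
        net <- buildNetwork(st$links)
        va <- abundance(st$virusAbund)
        ha <- abundance(st$hostAbund)
        samples <- colnames(va)
        rows <- lapply(samples, function(s) {
          pv <- intersect(rownames(va)[va[, s] > 0], virusNodes(net))
          ph <- intersect(rownames(ha)[ha[, s] > 0], hostNodes(net))
          sub <- extractSubnetwork(net, pv, ph)
          q <- tryCatch(barberModularity(sub, nRestarts = brimRestarts,
                                         seed = deriveSeed(config$seed, s))$q,
                        error = function(e) NA_real_)
          nd <- tryCatch(nodf(sub)$nodf, error = function(e) NA_real_)
          data.frame(sample = s, modularity = q, nodf = nd,
                     prokaryotic_richness = sum(ha[, s] > 0),
                     viral_richness = sum(va[, s] > 0))
        })
        st$networkMetrics <- do.call(rbind, rows)
        st$structureReg <- richnessStructureRegression(
          st$networkMetrics, st$networkMetrics)
        wTsv(st$networkMetrics, "network_metrics.tsv")
        wTsv(st$structureReg, "network_regressions.tsv")
        report$network <- list(
          meta_edges = sum(incidence(net)),
          regressions = st$structureReg)
      },
      biogeo = {
        d <- loadData()
        va <- t(abundance(st$virusAbund))
        ha <- t(abundance(st$hostAbund))
        vh <- communityTransform(va, "hellinger")
        hh <- communityTransform(ha, "hellinger")
        bcV <- communityDissimilarity(vh, "bray_curtis")
        bcH <- communityDissimilarity(hh, "bray_curtis")
        coords <- d$metadata[, c("lat", "lon")]
        rownames(coords) <- d$metadata$sample
        geo <- geographicDistance(coords)
        st$ddr <- fitDistanceDecay(geo, bcV)
        st$mantel <- mantelTest(bcH, bcV, nPerm = 999,
                                seed = deriveSeed(config$seed, "mantel"))
        pc <- pcoaOrdination(bcV)
        wTsv(st$ddr$fits, "ddr_fits.tsv")
        report$biogeo <- list(
          ddr = st$ddr$fits,
          mantel_r = st$mantel$r, mantel_p = st$mantel$p,
          pcoa_pc1_inertia = pc$relative_inertia[1L])
      },
      pathfit = {
        d <- loadData()
        spec <- config$path_coefficients
        fit <- fitPathModel(d$metadata, spec)
        st$pathFit <- fit
        report$pathfit <- list(
          chi2 = fit$chi2, df = fit$df, p_value = fit$p_value,
          rmsea = fit$rmsea,
          coefficients = fit$coefficients[c("from", "to", "estimate", "p")])
      })
  }
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       dataframe = "rows")
  invisible(report)
}
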