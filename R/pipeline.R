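#' Run the full analysis pipeline on a synthetic atlas
#'
#' Orchestrates every stage end to end: simulate the atlas, classify
#' probes and map structures, compute region profiles and spatial
#' statistics, run the region-wise robust group comparison, build the
#' correlation network, detect expression modules, scan planted
#' interaction pairs and calibrate their p-values against a
#' dinucleotide-shuffled background. Writes tidy TSV/JSON outputs plus a
#' manifest of seeds and per-stage counts when \code{outdir} is given.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param outdir optional output directory (created if missing).
#' @param granularity region granularity for the sweep ("coarse" or "fine").
#' @param alpha adjusted-p cutoff for the region sweep (default 0.25).
#' @param B bootstrap resamples per region (default 2000).
#' @param rhoT correlation-network edge threshold (default 0.8).
#' @param eMin spatial-enrichment energy threshold (default 2).
#' @param nShuffles background shuffles per interaction pair (default 100).
#' @param nPairs,plantedFrac,seqLength interaction-pair geometry passed to
#'   \code{\link{simulateInteractionPairs}}.
#' @return list with every stage's result: atlas, classes, structuredFlag,
#'   counts, profiles, sweep, network, modules, interactions, manifest.
#' @export
runPipeline <- function(config, outdir = NULL,
                        granularity = c("coarse", "fine"),
                        alpha = 0.25, B = 2000L, rhoT = 0.8, eMin = 2,
                        nShuffles = 100L, nPairs = 40L, plantedFrac = 0.5,
                        seqLength = 60L) {
  granularity <- match.arg(granularity)
  stages <- character(0)
  note <- function(s) { stages <<- c(stages, s); message("stage: ", s) }

  note("simulate")
  atlas <- simulateAtlas(config, nPairs = nPairs, plantedFrac = plantedFrac,
                         seqLength = seqLength)
  ve <- atlas$expression

  note("annotate")
  g <- atlas$genome
  classes <- classifyProbes(g$probes, g$geneParts)
  mapped <- mapStructures(g$probes, classes, g$structures, g$geneParts)
  structuredFlag <- lengths(mapped) > 0
  counts <- classificationCounts(classes, structuredFlag)

  note("expression-stats")
  prof <- regionProfile(ve, granularity)
  divergence <- spatialDivergence(regionProfile(ve, "fine"))

  note("region-sweep")
  grp <- SummarizedExperiment::rowData(ve)$structuredGroup
  sweep <- regionSweep(prof[grp, , drop = FALSE],
                       prof[!grp, , drop = FALSE],
                       alpha = alpha, B = B, seed = config@seed + 10L)

  note("correlate")
  pairs <- correlatePairs(ve, "brain")
  network <- buildNetwork(pairs, rhoT = rhoT)

  note("modules")
  modules <- detectModules(regionProfile(ve, "fine"),
                           k = max(2L, length(config@cliqueSpec) + 1L))

  note("interact")
  ip <- atlas$interactionPairs
  hits <- scanInteractions(ip$queries, ip$targets)
  bg <- buildBackground(ip$queries[!ip$truth$planted],
                        ip$targets[!ip$truth$planted],
                        nShuffles = nShuffles, seed = config@seed + 20L)
  evd <- binAndFit(bg)
  ok <- !is.na(hits$mfe)
  hits$p <- NA_real_
  hits$p[ok] <- interactionPvalue(hits$mfe[ok], evd,
                                  siteLength = hits$siteLength[ok],
                                  gcFrac = hits$gcFrac[ok])
  significant <- filterHits(hits)

  note("report")
  manifest <- list(seed = config@seed, stages = stages,
                   nProbes = nrow(ve), nVoxels = ncol(ve),
                   nGenomeProbes = length(g$probes),
                   nPairs = nrow(hits),
                   nSignificantInteractions = nrow(significant),
                   nRegionsFlagged = sum(sweep$significant),
                   alpha = alpha, rhoT = rhoT, eMin = eMin, B = B)

  res <- list(atlas = atlas, classes = classes,
              structuredFlag = structuredFlag, counts = counts,
              profiles = prof, divergence = divergence, sweep = sweep,
              pairs = pairs, network = network, modules = modules,
              interactions = hits, significantInteractions = significant,
              evdBackground = evd, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(sweep, file.path(outdir, "region_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pairs, file.path(outdir, "correlation_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(hits, file.path(outdir, "interaction_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(counts, file.path(outdir, "classification_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    utils::write.table(modules$modules, file.path(outdir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    writeOntology(atlas$ontology, file.path(outdir, "ontology.json"))
  }
  res
}
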