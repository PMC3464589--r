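#' Construct a RegionOntology
#'
#' @param labels integer 3-D array assigning each voxel a fine-region id.
#' @param coarseOf integer vector mapping fine-region ids to coarse ids.
#' @param fineNames,coarseNames optional region names.
#' @return A \linkS4class{RegionOntology}.
#' @export
RegionOntology <- function(labels, coarseOf, fineNames = NULL,
                           coarseNames = NULL) {
  coarseOf <- as.integer(coarseOf)
  nf <- length(coarseOf)
  nc <- max(coarseOf)
  if (is.null(fineNames)) fineNames <- sprintf("fine_%03d", seq_len(nf))
  if (is.null(coarseNames)) coarseNames <- sprintf("coarse_%02d", seq_len(nc))
  storage.mode(labels) <- "integer"
  new("RegionOntology", labels = labels, coarseOf = coarseOf,
      fineNames = fineNames, coarseNames = coarseNames)
}

#' @rdname RegionOntology
#' @param x a RegionOntology.
#' @export
nFineRegions <- function(x) length(x@fineNames)

#' @rdname RegionOntology
#' @export
nCoarseRegions <- function(x) length(x@coarseNames)

#' @rdname RegionOntology
#' @export
latticeShape <- function(x) {
  if (is(x, "VoxelExperiment")) metadata(x)$latticeShape else dim(x@labels)
}

#' Per-voxel region labels at a chosen granularity
#'
#' @param x a RegionOntology.
#' @param granularity "fine" or "coarse".
#' @return integer vector of region ids, one per voxel in array order.
#' @export
voxelRegions <- function(x, granularity = c("fine", "coarse")) {
  granularity <- match.arg(granularity)
  lab <- as.integer(x@labels)
  if (granularity == "coarse") x@coarseOf[lab] else lab
}

#' Construct a VoxelExperiment from an energy matrix and an ontology
#'
#' @param energy numeric matrix, probes x voxels (voxels in array order).
#' @param ontology a \linkS4class{RegionOntology} whose lattice matches.
#' @param probeData optional DataFrame of per-probe annotation.
#' @return A \linkS4class{VoxelExperiment}.
#' @export
VoxelExperiment <- function(energy, ontology, probeData = NULL) {
  stopifnot(is.matrix(energy), is(ontology, "RegionOntology"))
  shape <- dim(ontology@labels)
  if (ncol(energy) != prod(shape))
    stop("energy has ", ncol(energy), " voxels but the lattice has ",
         prod(shape))
  coords <- arrayInd(seq_len(prod(shape)), .dim = shape)
  cd <- DataFrame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                  region = as.integer(ontology@labels))
  se <- SummarizedExperiment(
    assays = list(energy = energy),
    colData = cd,
    rowData = if (is.null(probeData)) NULL else probeData
  )
  metadata(se)$ontology <- ontology
  metadata(se)$latticeShape <- shape
  new("VoxelExperiment", se)
}

#' @rdname VoxelExperiment
#' @param x a VoxelExperiment.
#' @export
energyMatrix <- function(x) SummarizedExperiment::assay(x, "energy")

#' @rdname VoxelExperiment
#' @export
ontology <- function(x) metadata(x)$ontology

#' Configure the synthetic atlas generator
#'
#' Defaults reflect the study design the generator emulates: an 11-coarse /
#' 115-fine region ontology on a 200-um voxel lattice, probe groups of
#' structured and non-structured transcripts with a positive mean energy
#' shift for the structured groups, and GC-rich planted duplex sites.
#'
#' @param seed integer master seed.
#' @param latticeShape integer(3) lattice dimensions.
#' @param nCoarseRegions,nFineRegions region counts.
#' @param probesPerGroup named integer vector of group sizes. Group labels
#'   containing "structured" (and not "non_structured") receive the
#'   `effectSize` mean shift.
#' @param effectSize mean energy shift of structured groups (energy units).
#' @param cliqueSpec list of `c(size, strength)` for planted correlated
#'   cliques; strength is the share of the latent spatial pattern in the
#'   noise budget (pairwise correlation approaches strength^2).
#' @param noiseSd per-voxel Gaussian noise sd (energy units).
#' @param baseline baseline mean energy of every probe.
#' @param exprThreshold brain-wide mean energy above which a probe is
#'   flagged expressed.
#' @param genomeLength,nGenes synthetic genome size.
#' @param interactionSiteLength planted reverse-complement site length (nt).
#' @param interactionSiteGC GC fraction of planted sites (GC-rich sites
#'   model thermodynamically stable duplexes).
#' @return A validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(seed = 1L,
                            latticeShape = c(40L, 30L, 20L),
                            nCoarseRegions = 11L,
                            nFineRegions = 115L,
                            probesPerGroup = c(structured_utr = 200L,
                                               non_structured_utr = 200L),
                            effectSize = 2,
                            cliqueSpec = list(),
                            noiseSd = 1,
                            baseline = 3,
                            exprThreshold = 0.5,
                            genomeLength = 200000L,
                            nGenes = 20L,
                            interactionSiteLength = 15L,
                            interactionSiteGC = 1) {
  new("SyntheticConfig",
      seed = as.integer(seed),
      latticeShape = as.integer(latticeShape),
      nCoarseRegions = as.integer(nCoarseRegions),
      nFineRegions = as.integer(nFineRegions),
      probesPerGroup = stats::setNames(as.integer(probesPerGroup),
                                       names(probesPerGroup)),
      effectSize = effectSize,
      cliqueSpec = cliqueSpec,
      noiseSd = noiseSd,
      baseline = baseline,
      exprThreshold = exprThreshold,
      genomeLength = as.integer(genomeLength),
      nGenes = as.integer(nGenes),
      interactionSiteLength = as.integer(interactionSiteLength),
      interactionSiteGC = interactionSiteGC)
}

#' Construct a pair-additive duplex energy model
#'
#' @param pairEnergies named numeric of per-pair stabilities (kcal/mol).
#' @param bulgePenalty penalty per bulged nucleotide (kcal/mol).
#' @return An \linkS4class{EnergyModel}.
#' @export
energyModel <- function(pairEnergies = c(GC = -3, AU = -2, GU = -1),
                        bulgePenalty = 4) {
  new("EnergyModel", pairEnergies = pairEnergies, bulgePenalty = bulgePenalty)
}

#' Construct a PWMotif
#'
#' @param id motif identifier.
#' @param matrix 4 x L numeric matrix (rows A, C, G, U or unnamed in that
#'   order); columns are normalised to sum to 1. Count matrices are
#'   accepted and normalised.
#' @param background background distribution (default uniform).
#' @return A \linkS4class{PWMotif}.
#' @export
pwMotif <- function(id, matrix, background = rep(0.25, 4)) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "U")
  rownames(m) <- sub("T", "U", toupper(rownames(m)))
  m <- m[c("A", "C", "G", "U"), , drop = FALSE]
  m <- sweep(m, 2, colSums(m), "/")
  new("PWMotif", id = id, matrix = m, background = background / sum(background))
}
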