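#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Two-level region ontology over a voxel lattice
#'
#' Partition of a 3-D voxel lattice into fine regions, each nested inside
#' exactly one coarse region. `labels` assigns every voxel a fine-region id
#' (1..nFine); `coarseOf[f]` gives the coarse region containing fine region f.
#'
#' @slot labels integer 3-D array, voxel to fine-region id.
#' @slot coarseOf integer vector, fine-region id to coarse-region id.
#' @slot fineNames,coarseNames character region names.
#' @export
setClass("RegionOntology",
  representation(
    labels = "array",
    coarseOf = "integer",
    fineNames = "character",
    coarseNames = "character"
  )
)

setValidity("RegionOntology", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3-D array")
  nf <- length(object@fineNames)
  if (length(object@coarseOf) != nf)
    msg <- c(msg, "coarseOf must have one entry per fine region")
  lab <- as.integer(object@labels)
  if (anyNA(lab) || any(lab < 1L) || any(lab > nf))
    msg <- c(msg, "every voxel must carry a fine-region label in 1..nFine")
  if (nf > 0 && !all(seq_len(nf) %in% lab))
    msg <- c(msg, "every fine region must own at least one voxel")
  nc <- length(object@coarseNames)
  if (nf > 0 && (any(object@coarseOf < 1L) || any(object@coarseOf > nc)))
    msg <- c(msg, "coarseOf ids out of range")
  if (length(msg)) msg else TRUE
})

#' Probe-by-voxel expression container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are probes and whose
#' columns are the voxels of a 3-D lattice (in array order). The single
#' assay \code{"energy"} holds non-negative expression energy. Voxel
#' coordinates and fine-region labels live in \code{colData}; the
#' \linkS4class{RegionOntology} is kept in \code{metadata(x)$ontology}.
#'
#' @export
setClass("VoxelExperiment", contains = "SummarizedExperiment")

setValidity("VoxelExperiment", function(object) {
  msg <- character()
  if (!"energy" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'energy' is required")
  else {
    e <- SummarizedExperiment::assay(object, "energy")
    if (any(!is.finite(e)) || any(e < 0))
      msg <- c(msg, "energy must be finite and non-negative")
  }
  cd <- colData(object)
  need <- c("x", "y", "z", "region")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must carry x, y, z, region")
  ont <- metadata(object)$ontology
  if (is.null(ont) || !is(ont, "RegionOntology"))
    msg <- c(msg, "metadata$ontology must be a RegionOntology")
  else if (ncol(object) != length(ont@labels))
    msg <- c(msg, "number of voxels must match the ontology lattice")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic atlas generator
#'
#' Holds every knob of the synthetic data generator: lattice geometry,
#' region counts, per-group probe counts, the mean energy shift applied to
#' "structured" groups, planted correlated cliques, the voxel noise level,
#' and the genome/interaction-sequence geometry.
#'
#' @slot seed integer master seed.
#' @slot latticeShape integer(3), voxels per axis (nominally 200 um cubes).
#' @slot nCoarseRegions,nFineRegions integer region counts (defaults 11/115).
#' @slot probesPerGroup named integer, group label to probe count.
#' @slot effectSize numeric mean energy shift for structured groups.
#' @slot cliqueSpec list of c(size, strength) pairs for planted cliques.
#' @slot noiseSd positive numeric voxel noise standard deviation.
#' @slot baseline numeric baseline energy level.
#' @slot exprThreshold numeric mean-energy cutoff for the expressed flag.
#' @slot genomeLength,nGenes integer synthetic genome geometry.
#' @slot interactionSiteLength integer planted duplex site length (nt).
#' @slot interactionSiteGC numeric GC fraction of planted duplex sites.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    latticeShape = "integer",
    nCoarseRegions = "integer",
    nFineRegions = "integer",
    probesPerGroup = "integer",
    effectSize = "numeric",
    cliqueSpec = "list",
    noiseSd = "numeric",
    baseline = "numeric",
    exprThreshold = "numeric",
    genomeLength = "integer",
    nGenes = "integer",
    interactionSiteLength = "integer",
    interactionSiteGC = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (length(object@latticeShape) != 3L || any(object@latticeShape < 1L))
    msg <- c(msg, "latticeShape must be 3 positive integers")
  if (object@nFineRegions < object@nCoarseRegions || object@nCoarseRegions < 1L)
    msg <- c(msg, "need nFineRegions >= nCoarseRegions >= 1")
  if (prod(object@latticeShape) < object@nFineRegions)
    msg <- c(msg, "lattice has fewer voxels than fine regions")
  if (is.null(names(object@probesPerGroup)) || any(object@probesPerGroup < 1L))
    msg <- c(msg, "probesPerGroup must be a named positive integer vector")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (object@genomeLength < 1L || object@nGenes < 1L)
    msg <- c(msg, "genomeLength and nGenes must be positive")
  if (object@interactionSiteLength < 2L)
    msg <- c(msg, "interactionSiteLength must be >= 2")
  for (cl in object@cliqueSpec) {
    if (length(cl) != 2L || cl[1] < 2 || cl[2] < 0 || cl[2] > 1)
      msg <- c(msg, "each cliqueSpec entry is c(size >= 2, strength in [0,1])")
  }
  if (length(msg)) msg else TRUE
})

#' Censored extreme-value background for duplex MFEs
#'
#' Per (site length, GC fraction) bin Gumbel-type parameters (lambda, mu)
#' for the law P(S <= s) = 1 - exp(-exp(lambda * (s - mu))), fitted by
#' maximum likelihood with right-censoring at `censorCutoff` (MFEs above
#' the cutoff only contribute the censored tail mass). Bin edges are
#' empirical quantiles; outer edges extend to +/- Inf so every covariate
#' pair maps to exactly one bin.
#'
#' @slot lenBreaks,gcBreaks numeric bin edges (half-open, outer = +/-Inf).
#' @slot lambda,mu numeric matrices (length bins x GC bins).
#' @slot counts integer matrix of background samples per bin.
#' @slot censorCutoff numeric censoring point (kcal/mol).
#' @export
setClass("EvdBackground",
  representation(
    lenBreaks = "numeric",
    gcBreaks = "numeric",
    lambda = "matrix",
    mu = "matrix",
    counts = "matrix",
    censorCutoff = "numeric"
  )
)

setValidity("EvdBackground", function(object) {
  msg <- character()
  dl <- dim(object@lambda)
  if (!identical(dl, dim(object@mu)) || !identical(dl, dim(object@counts)))
    msg <- c(msg, "lambda, mu, counts must share dimensions")
  if (length(object@lenBreaks) != dl[1] + 1L ||
      length(object@gcBreaks) != dl[2] + 1L)
    msg <- c(msg, "bin edges must be one longer than the bin grid")
  if (any(is.finite(object@lambda) & object@lambda <= 0))
    msg <- c(msg, "fitted lambda must be > 0")
  if (length(msg)) msg else TRUE
})

#' Pair-additive duplex energy model
#'
#' Toy intermolecular energy model: each base pair contributes a fixed
#' stability (kcal/mol, <= 0) and every unpaired bulged nucleotide inside
#' the duplex costs a fixed penalty. A named, swappable engine: nearest-
#' neighbour engines can be adapted in without touching the statistics.
#'
#' @slot pairEnergies named numeric, pair type to energy (GC, AU, GU).
#' @slot bulgePenalty numeric penalty per bulged nucleotide (>= 0).
#' @export
setClass("EnergyModel",
  representation(pairEnergies = "numeric", bulgePenalty = "numeric")
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  if (!all(c("GC", "AU", "GU") %in% names(object@pairEnergies)))
    msg <- c(msg, "pairEnergies must name GC, AU and GU")
  if (any(object@pairEnergies > 0))
    msg <- c(msg, "pair energies must be <= 0")
  if (object@bulgePenalty < 0)
    msg <- c(msg, "bulgePenalty must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Position weight matrix over the RNA alphabet
#'
#' Column-stochastic 4 x L probability matrix (rows A, C, G, U) with a
#' background distribution, scored as log2 odds after pseudocount
#' regularisation.
#'
#' @slot id character identifier.
#' @slot matrix numeric 4 x L matrix, rows named A, C, G, U.
#' @slot background numeric(4) background probabilities.
#' @export
setClass("PWMotif",
  representation(id = "character", matrix = "matrix", background = "numeric")
)

setValidity("PWMotif", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != 4L || !identical(rownames(m), c("A", "C", "G", "U")))
    msg <- c(msg, "matrix must have 4 rows named A, C, G, U")
  if (ncol(m) < 1L) msg <- c(msg, "matrix must have >= 1 column")
  if (any(abs(colSums(m) - 1) > 1e-6))
    msg <- c(msg, "each column must sum to 1 (tolerance 1e-6)")
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegionOntology", function(object) {
  d <- dim(object@labels)
  cat("RegionOntology:", d[1], "x", d[2], "x", d[3], "lattice,",
      length(object@fineNames), "fine regions in",
      length(object@coarseNames), "coarse regions\n")
})

setMethod("show", "VoxelExperiment", function(object) {
  cat("VoxelExperiment:", nrow(object), "probes x", ncol(object), "voxels\n")
  callNextMethod()
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: lattice",
      paste(object@latticeShape, collapse = "x"), "|",
      object@nCoarseRegions, "coarse /", object@nFineRegions, "fine regions |",
      sum(object@probesPerGroup), "probes in",
      length(object@probesPerGroup), "groups | effect",
      object@effectSize, "| noise sd", object@noiseSd,
      "| seed", object@seed, "\n")
})

setMethod("show", "EvdBackground", function(object) {
  cat("EvdBackground:", nrow(object@lambda), "x", ncol(object@lambda),
      "(length x GC) bins, censored at", object@censorCutoff, "kcal/mol\n")
  cat("  fitted bins:", sum(is.finite(object@lambda)), "of",
      length(object@lambda), "| samples:", sum(object@counts), "\n")
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel: pair energies [",
      paste(names(object@pairEnergies), object@pairEnergies,
            sep = "=", collapse = ", "),
      "] kcal/mol; bulge penalty", object@bulgePenalty, "kcal/mol/nt\n")
})

setMethod("show", "PWMotif", function(object) {
  cat("PWMotif", object@id, "of width", ncol(object@matrix), "\n")
})
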