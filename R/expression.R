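#' Expression energy from intensity and cell density
#'
#' Expression energy is the per-voxel product of ISH signal intensity and
#' the density of expressing cells.
#'
#' @param intensity,density numeric arrays/matrices of identical shape;
#'   density in [0, 1], intensity >= 0.
#' @return numeric array of the same shape.
#' @export
expressionEnergy <- function(intensity, density) {
  if (!identical(dim(intensity), dim(density)) ||
      length(intensity) != length(density))
    stop("intensity and density shapes differ")
  if (any(density < 0 | density > 1, na.rm = TRUE))
    stop("density must lie in [0, 1]")
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensity must be >= 0")
  intensity * density
}

# voxel column indices of a region at the requested granularity
.regionVoxels <- function(ont, regionId, granularity = c("fine", "coarse")) {
  granularity <- match.arg(granularity)
  which(voxelRegions(ont, granularity) == regionId)
}

#' Mean expression energy over a region
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param regionId region id, or "brain" for the whole lattice.
#' @param granularity "fine" or "coarse".
#' @return numeric vector, one mean per probe.
#' @export
regionMean <- function(x, regionId, granularity = c("fine", "coarse")) {
  e <- energyMatrix(x)
  if (identical(regionId, "brain")) return(rowMeans(e))
  vox <- .regionVoxels(ontology(x), regionId, granularity)
  if (length(vox) == 0L) stop("region ", regionId, " is empty")
  rowMeans(e[, vox, drop = FALSE])
}

#' Probe-by-region matrix of mean energies
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param granularity "fine" or "coarse".
#' @return numeric matrix, probes x regions.
#' @export
regionProfile <- function(x, granularity = c("fine", "coarse")) {
  granularity <- match.arg(granularity)
  ont <- ontology(x)
  lab <- voxelRegions(ont, granularity)
  ids <- seq_len(if (granularity == "fine") nFineRegions(ont)
                 else nCoarseRegions(ont))
  e <- energyMatrix(x)
  # rowsum over voxels grouped by region, then divide by voxel counts
  sums <- t(rowsum(t(e), group = lab))
  nv <- as.vector(table(factor(lab, levels = ids)))
  prof <- sweep(sums[, as.character(ids), drop = FALSE], 2, nv, "/")
  colnames(prof) <- if (granularity == "fine") ont@fineNames
                    else ont@coarseNames
  prof
}

#' Spatial enrichment score of a region
#'
#' Ratio of the region's fraction of voxels with energy >= \code{eMin} to
#' the brain-wide fraction. Values > 1 flag high spatial expression in the
#' region. Returns \code{NaN} with a warning when no voxel brain-wide
#' reaches \code{eMin}.
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param regionId region id, or "brain" (score exactly 1 by definition).
#' @param eMin energy threshold (default 2).
#' @param granularity "fine" or "coarse".
#' @return numeric vector, one score per probe.
#' @export
spatialEnrichment <- function(x, regionId, eMin = 2,
                              granularity = c("fine", "coarse")) {
  e <- energyMatrix(x)
  vb <- ncol(e)
  nb <- rowSums(e >= eMin)
  if (identical(regionId, "brain")) {
    vox <- seq_len(vb)
  } else {
    vox <- .regionVoxels(ontology(x), regionId, granularity)
    if (length(vox) == 0L) stop("region ", regionId, " is empty")
  }
  vd <- length(vox)
  nd <- rowSums(e[, vox, drop = FALSE] >= eMin)
  out <- (nd / vd) / (nb / vb)
  if (any(nb == 0)) {
    warning("no voxel above eMin brain-wide for ", sum(nb == 0),
            " probe(s); returning NaN")
    out[nb == 0] <- NaN
  }
  out
}

#' Spatial expression divergence
#'
#' Sample standard deviation of per-region mean energies; a probe whose
#' expression concentrates in few regions has a high divergence.
#'
#' @param regionMeans numeric vector (or probes x regions matrix) of
#'   per-region mean energies.
#' @return numeric scalar (or vector, one per probe/row).
#' @export
spatialDivergence <- function(regionMeans) {
  if (is.matrix(regionMeans)) {
    if (ncol(regionMeans) < 2L) stop("need >= 2 regions")
    return(apply(regionMeans, 1, stats::sd))
  }
  if (length(regionMeans) < 2L) stop("need >= 2 regions")
  stats::sd(regionMeans)
}

#' Flag-driven quality-control filter
#'
#' Drops probes whose QC flag is set (processing artifacts, missing data,
#' widespread expression, ...), reporting how many were removed.
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param flags named logical vector covering every probe; TRUE = exclude.
#' @return the filtered VoxelExperiment; attribute \code{"removed"} holds
#'   the dropped probe ids.
#' @export
qcFilter <- function(x, flags) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (!all(ids %in% names(flags)))
    stop("flags missing for ", sum(!(ids %in% names(flags))), " probe(s)")
  drop <- flags[ids]
  out <- x[!drop, ]
  message(sum(drop), " of ", length(ids), " probes removed by QC filter")
  attr(out, "removed") <- ids[drop]
  out
}
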