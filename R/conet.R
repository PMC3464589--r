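#' Pearson correlation of two voxel vectors
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return the product-moment correlation, or NA (with a warning) when
#'   either vector has zero variance.
#' @export
pearson <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    warning("zero-variance vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(u, v)
}

#' All pairwise voxel correlations within a domain
#'
#' Computes the Pearson correlation of every unordered probe pair over the
#' voxels of one brain domain (a region id, or "brain" for the whole
#' lattice). Pairs with undefined correlation (a constant probe within the
#' domain) are dropped with a message.
#'
#' @param x a \linkS4class{VoxelExperiment}.
#' @param domain region id or "brain".
#' @param granularity "fine" or "coarse" (ignored for "brain").
#' @return data.frame (probeA, probeB, rho, domain), probeA < probeB.
#' @export
correlatePairs <- function(x, domain = "brain",
                           granularity = c("fine", "coarse")) {
  e <- energyMatrix(x)
  if (nrow(e) < 2L) stop("need at least 2 probes")
  if (!identical(domain, "brain")) {
    vox <- .regionVoxels(ontology(x), domain, granularity)
    if (length(vox) == 0L) stop("domain ", domain, " is empty")
    e <- e[, vox, drop = FALSE]
  }
  ids <- rownames(e)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(e)))
  cm <- suppressWarnings(stats::cor(t(e)))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  rho <- cm[ut]
  bad <- is.na(rho)
  if (any(bad))
    message(sum(bad), " pair(s) dropped: undefined correlation")
  data.frame(probeA = ids[ut[!bad, 1]], probeB = ids[ut[!bad, 2]],
             rho = rho[!bad],
             domain = if (identical(domain, "brain")) "brain"
                      else as.character(domain),
             stringsAsFactors = FALSE)
}

#' Correlation-threshold selection from the pair-frequency curve
#'
#' The cumulative fraction of pairs above rho typically follows a negative
#' sigmoid; the threshold is placed in its right flattened area. This
#' formalises the choice as the smallest grid multiple \code{rhoT >= floor}
#' at which the surviving pair fraction drops to \code{qTarget} or below.
#'
#' @param rhos numeric vector of pair correlations.
#' @param qTarget maximum surviving fraction of pairs (default 0.01).
#' @param gridStep grid spacing for candidate thresholds (default 0.05).
#' @param floor smallest admissible threshold (default 0.8).
#' @return list with \code{rhoT} and \code{curve} (data.frame of grid
#'   value and surviving fraction) for inspection.
#' @export
selectThreshold <- function(rhos, qTarget = 0.01, gridStep = 0.05,
                            floor = 0.8) {
  stopifnot(length(rhos) > 0, qTarget > 0, qTarget < 1)
  grid <- seq(floor, 1 - gridStep, by = gridStep)
  frac <- vapply(grid, function(g) mean(rhos >= g), numeric(1))
  ok <- which(frac <= qTarget)
  if (length(ok) == 0L) {
    warning("no grid value reaches the target fraction; using ",
            1 - gridStep)
    rhoT <- 1 - gridStep
  } else rhoT <- grid[ok[1]]
  list(rhoT = rhoT, curve = data.frame(rho = grid, fracAbove = frac))
}

#' Correlation network from thresholded pairs
#'
#' Builds the graph whose edges are pairs with rho strictly above
#' \code{rhoT}, and reports connected components and maximal cliques of
#' size >= 3.
#'
#' @param pairs data.frame from \code{\link{correlatePairs}}.
#' @param rhoT correlation threshold (edges require rho > rhoT).
#' @return list with the igraph \code{graph}, \code{components} (list of
#'   probe-id vectors) and \code{cliques} (maximal cliques, size >= 3).
#' @export
buildNetwork <- function(pairs, rhoT = 0.8) {
  keep <- pairs$rho > rhoT
  edges <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("probeA", "probeB", "rho")], directed = FALSE)
  comps <- igraph::components(g)
  compList <- split(names(comps$membership), comps$membership)
  cl <- igraph::max_cliques(g, min = 3)
  list(graph = g,
       components = unname(compList),
       cliques = lapply(cl, function(v) sort(names(v))))
}

#' Expression-module detection from region profiles
#'
#' Average-linkage agglomerative clustering of probes on the correlation
#' distance 1 - rho between their region-level expression profiles, cut
#' into \code{k} modules (or at height \code{h}). Each module's focal
#' region is the region with the highest module-mean energy. Probes with
#' constant profiles are excluded with a warning.
#'
#' @param profiles numeric matrix, probes x regions (region means).
#' @param k number of modules (default 2); ignored when \code{h} given.
#' @param h optional dendrogram cut height on the 1 - rho scale.
#' @return list with \code{modules} (data.frame probe, module),
#'   \code{focalRegions} (per-module focal region name) and the
#'   \code{hclust} object.
#' @export
detectModules <- function(profiles, k = 2L, h = NULL) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2)
  ids <- rownames(profiles)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(profiles)))
  const <- apply(profiles, 1, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning(sum(const), " constant-profile probe(s) excluded")
    profiles <- profiles[!const, , drop = FALSE]
    ids <- ids[!const]
  }
  if (nrow(profiles) < 2L) stop("fewer than 2 usable probes")
  d <- stats::as.dist(1 - stats::cor(t(profiles)))
  hc <- stats::hclust(d, method = "average")
  cut <- if (is.null(h)) stats::cutree(hc, k = k)
         else stats::cutree(hc, h = h)
  mods <- sort(unique(cut))
  rn <- colnames(profiles)
  if (is.null(rn)) rn <- as.character(seq_len(ncol(profiles)))
  focal <- vapply(mods, function(m) {
    rn[which.max(colMeans(profiles[cut == m, , drop = FALSE]))]
  }, character(1))
  list(modules = data.frame(probe = ids, module = unname(cut),
                            stringsAsFactors = FALSE),
       focalRegions = stats::setNames(focal, mods),
       hclust = hc)
}
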