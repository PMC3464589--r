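#' Simulate a nested two-level region ontology
#'
#' Grows \code{nFineRegions} contiguous fine regions on the voxel lattice
#' by seeded multi-source accretion (every voxel joins the nearest growing
#' region front), then groups fine regions into coarse regions by sorting
#' their centroids along a seeded random direction and chunking, so each
#' fine region nests inside exactly one coarse region and every voxel
#' carries exactly one fine label. Deterministic for a fixed seed.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{RegionOntology}.
#' @export
simulateOntology <- function(config) {
  shape <- config@latticeShape
  nF <- config@nFineRegions
  nC <- config@nCoarseRegions
  nVox <- prod(shape)
  if (nVox < nF) stop("lattice has fewer voxels than fine regions")
  .withSeed(config@seed, {
    lab <- integer(nVox)
    seeds <- sample.int(nVox, nF)
    lab[seeds] <- seq_len(nF)
    coords <- arrayInd(seq_len(nVox), .dim = shape)
    # multi-source breadth-first accretion over the 6-neighbourhood
    frontier <- seeds
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        nb <- coords[frontier, , drop = FALSE] +
          matrix(offs[o, ], length(frontier), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
          nb[, 2] >= 1 & nb[, 2] <= shape[2] &
          nb[, 3] >= 1 & nb[, 3] <= shape[3]
        if (!any(ok)) next
        nbIdx <- (nb[ok, 3] - 1L) * shape[1] * shape[2] +
          (nb[ok, 2] - 1L) * shape[1] + nb[ok, 1]
        src <- frontier[ok]
        free <- lab[nbIdx] == 0L
        if (!any(free)) next
        # first writer wins within a wave; order randomized per wave
        ord <- sample.int(sum(free))
        tgt <- nbIdx[free][ord]
        from <- src[free][ord]
        newly <- !duplicated(tgt)
        tgt <- tgt[newly]; from <- from[newly]
        still <- lab[tgt] == 0L
        lab[tgt[still]] <- lab[from[still]]
        nxt <- c(nxt, tgt[still])
      }
      frontier <- nxt
    }
    # isolated leftovers (none expected on a connected lattice)
    if (any(lab == 0L)) lab[lab == 0L] <- lab[seeds[1]]
    # group fine regions into coarse by centroid projection
    cent <- rowsum(coords, lab) / as.vector(table(lab))
    dirv <- stats::rnorm(3)
    proj <- as.vector(cent %*% dirv)
    ord <- order(proj)
    sizes <- rep(nF %/% nC, nC)
    if (nF %% nC > 0) sizes[seq_len(nF %% nC)] <- sizes[seq_len(nF %% nC)] + 1L
    coarseOf <- integer(nF)
    coarseOf[ord] <- rep(seq_len(nC), times = sizes)
    RegionOntology(array(lab, dim = shape), coarseOf)
  })
}

#' Simulate per-probe expression volumes
#'
#' Per-probe energy = baseline + group effect (added for groups whose
#' label contains "structured" but not "non_structured") + planted clique
#' latent pattern + i.i.d. Gaussian voxel noise, clipped at 0. Within a
#' clique the noise budget is split between a shared latent spatial field
#' (weight = strength) and private noise (weight = sqrt(1 - strength^2)),
#' so pairwise correlations approach strength^2. Probes are flagged
#' expressed when their brain-wide mean energy exceeds the configured
#' threshold.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param ont a \linkS4class{RegionOntology} (from
#'   \code{\link{simulateOntology}}).
#' @return a \linkS4class{VoxelExperiment} with rowData columns
#'   \code{group}, \code{structuredGroup}, \code{clique} (0 = none) and
#'   \code{expressed}.
#' @export
simulateExpression <- function(config, ont) {
  stopifnot(is(ont, "RegionOntology"))
  nVox <- prod(config@latticeShape)
  groups <- rep(names(config@probesPerGroup), config@probesPerGroup)
  n <- length(groups)
  structuredGroup <- grepl("structured", groups) &
    !grepl("non_structured", groups)
  cliqueOf <- integer(n)
  .withSeed(config@seed + 1L, {
    # assign cliques to the first probes of the first group, disjointly
    at <- 1L
    for (ci in seq_along(config@cliqueSpec)) {
      sz <- as.integer(config@cliqueSpec[[ci]][1])
      cliqueOf[at:(at + sz - 1L)] <- ci
      at <- at + sz
    }
    e <- matrix(config@baseline, n, nVox)
    e <- e + config@effectSize * structuredGroup
    noise <- matrix(stats::rnorm(n * nVox, sd = config@noiseSd), n, nVox)
    for (ci in seq_along(config@cliqueSpec)) {
      s <- config@cliqueSpec[[ci]][2]
      members <- which(cliqueOf == ci)
      latent <- stats::rnorm(nVox, sd = config@noiseSd)
      noise[members, ] <- s * matrix(latent, length(members), nVox,
                                     byrow = TRUE) +
        sqrt(1 - s^2) * noise[members, , drop = FALSE]
    }
    e <- pmax(e + noise, 0)
    rownames(e) <- sprintf("probe_%04d", seq_len(n))
    rd <- DataFrame(group = groups, structuredGroup = structuredGroup,
                    clique = cliqueOf,
                    expressed = rowMeans(e) > config@exprThreshold)
    VoxelExperiment(e, ont, probeData = rd)
  })
}

# random RNA sequence as a character scalar
.randSeq <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(RNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

#' Simulate gene models, probes and structure predictions
#'
#' Lays out genes on a single synthetic chromosome, each with
#' 5'UTR / intron / CDS / intron / 3'UTR parts separated by intergenic
#' gaps, then plants probes so every classification category is
#' represented (intergenic, intronic, 5'UTR overlap, 3'UTR overlap,
#' CDS-only) and plants structure intervals inside a known subset of
#' probes (or their mapped gene parts) and decoys elsewhere. Returns the
#' planted ground truth for oracle testing.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param probeLength planted probe length in nt (default 400, within the
#'   400-1200 nt riboprobe range).
#' @return list with GRanges \code{geneParts} (mcols gene, part),
#'   \code{probes}, \code{structures}, a character vector
#'   \code{transcripts} (per-gene spliced sequence) and a data.frame
#'   \code{truth} (probe, class, structured).
#' @export
simulateGenome <- function(config, probeLength = 400L) {
  nGenes <- config@nGenes
  partLens <- c(five_utr = 300L, intron1 = 500L, cds = 900L,
                intron2 = 500L, three_utr = 600L)
  geneSpan <- sum(partLens)
  gap <- 1000L
  need <- nGenes * (geneSpan + gap) + gap
  if (config@genomeLength < need)
    stop("genomeLength ", config@genomeLength, " too small; need >= ", need)
  .withSeed(config@seed + 2L, {
    partKind <- c("five_utr", "intron", "cds", "intron", "three_utr")
    gp <- list(); probes <- list(); structs <- list(); truth <- list()
    transcripts <- character(nGenes)
    classes <- c("three_utr", "five_utr", "intronic", "intergenic", "cds")
    pi <- 0L; si <- 0L
    for (g in seq_len(nGenes)) {
      strand <- if (g %% 2L == 0L) "-" else "+"
      gStart <- gap + (g - 1L) * (geneSpan + gap) + 1L
      offs <- cumsum(c(0L, partLens[-length(partLens)]))
      starts <- gStart + offs
      ends <- starts + partLens - 1L
      gp[[g]] <- GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(starts, ends), strand = strand,
        gene = sprintf("gene_%03d", g), part = partKind)
      exLen <- sum(partLens[c("five_utr", "cds", "three_utr")])
      transcripts[g] <- .randSeq(exLen)
      # one probe per gene, class rotating through the categories
      cls <- classes[(g - 1L) %% length(classes) + 1L]
      pStart <- switch(cls,
        three_utr = starts[5] + 50L,
        five_utr = starts[1] - 100L,   # 100 nt intergenic + 300 nt 5'UTR
        intronic = starts[2] + 50L,
        intergenic = gStart - gap + 100L,
        cds = starts[3] + 100L)
      pLen <- switch(cls,
        three_utr = min(probeLength, partLens["three_utr"] - 100L),
        five_utr = 400L,
        intronic = min(probeLength, partLens["intron1"] - 100L),
        intergenic = min(probeLength, gap - 200L),
        cds = min(probeLength, partLens["cds"] - 200L))
      pi <- pi + 1L
      probes[[pi]] <- GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(pStart, pStart + pLen - 1L),
        probe = sprintf("probe_%04d", pi))
      # every even probe gets a planted structure overlapping it 1+ nt;
      # decoy structures sit in gaps untouched by any probe
      structured <- (pi %% 2L == 0L)
      if (structured) {
        si <- si + 1L
        structs[[si]] <- GenomicRanges::GRanges(
          "chrS", IRanges::IRanges(pStart + pLen - 1L, pStart + pLen + 58L),
          strand = "*", source = sprintf("struct_%04d", si))
      } else {
        si <- si + 1L
        structs[[si]] <- GenomicRanges::GRanges(
          "chrS", IRanges::IRanges(gStart + geneSpan + 200L,
                                   gStart + geneSpan + 260L),
          strand = "*", source = sprintf("struct_%04d", si))
      }
      truth[[pi]] <- data.frame(probe = sprintf("probe_%04d", pi),
                                class = cls, structured = structured,
                                stringsAsFactors = FALSE)
    }
    list(geneParts = do.call(c, gp),
         probes = do.call(c, probes),
         structures = do.call(c, structs),
         transcripts = stats::setNames(transcripts,
                                       sprintf("gene_%03d", seq_len(nGenes))),
         truth = do.call(rbind, truth))
  })
}

#' Simulate query-target interaction pairs
#'
#' Random-composition sequence pairs; in a planted fraction the target
#' carries the reverse complement of a query subsequence of the configured
#' length and GC content at recorded coordinates. The remaining pairs are
#' unrelated nulls. Sequences default to AU-rich composition (as real
#' untranslated regions are) and to short, accessible-window lengths on
#' which the pair-additive energy model's chance-duplex distribution
#' peaks near the censored-fit regime; planted sites default to pure GC,
#' modelling thermodynamically stable functional duplexes.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param nPairs number of pairs (default 50).
#' @param plantedFrac fraction with a planted site (default 0.5).
#' @param seqLength sequence length in nt (default 60).
#' @param seqGC background GC fraction of the sequences (default 0.35).
#' @return list with character vectors \code{queries}, \code{targets} and
#'   a data.frame \code{truth} (pair, planted, queryStart, targetStart;
#'   1-based).
#' @export
simulateInteractionPairs <- function(config, nPairs = 50L,
                                     plantedFrac = 0.5, seqLength = 60L,
                                     seqGC = 0.35) {
  L <- config@interactionSiteLength
  if (L > seqLength) stop("interaction site longer than the sequences")
  .withSeed(config@seed + 3L, {
    nPlant <- round(nPairs * plantedFrac)
    queries <- targets <- character(nPairs)
    qs <- ts <- rep(NA_integer_, nPairs)
    for (i in seq_len(nPairs)) {
      queries[i] <- .randSeq(seqLength, gc = seqGC)
      targets[i] <- .randSeq(seqLength, gc = seqGC)
      if (i <= nPlant) {
        site <- .randSeq(L, gc = config@interactionSiteGC)
        qPos <- sample.int(seqLength - L + 1L, 1L)
        tPos <- sample.int(seqLength - L + 1L, 1L)
        substr(queries[i], qPos, qPos + L - 1L) <- site
        rc <- .collapseChars(.revCompChars(strsplit(site, "")[[1]]))
        substr(targets[i], tPos, tPos + L - 1L) <- rc
        qs[i] <- qPos; ts[i] <- tPos
      }
    }
    names(queries) <- sprintf("q%04d", seq_len(nPairs))
    names(targets) <- sprintf("t%04d", seq_len(nPairs))
    list(queries = queries, targets = targets,
         truth = data.frame(pair = seq_len(nPairs),
                            planted = seq_len(nPairs) <= nPlant,
                            queryStart = qs, targetStart = ts))
  })
}

#' Generate the full synthetic atlas
#'
#' Convenience wrapper running \code{\link{simulateOntology}},
#' \code{\link{simulateExpression}}, \code{\link{simulateGenome}} and
#' \code{\link{simulateInteractionPairs}} from one config.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param ... passed to \code{\link{simulateInteractionPairs}}.
#' @return list with ontology, expression (VoxelExperiment), genome and
#'   interactionPairs components.
#' @export
simulateAtlas <- function(config, ...) {
  ont <- simulateOntology(config)
  list(ontology = ont,
       expression = simulateExpression(config, ont),
       genome = simulateGenome(config),
       interactionPairs = simulateInteractionPairs(config, ...))
}
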