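#' @importFrom GenomicRanges GRanges findOverlaps ranges seqnames strand width
#'   start end mcols mcols<- reduce
#' @importFrom IRanges IRanges pintersect subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
NULL

EXONIC_KINDS <- c("five_utr", "cds", "three_utr")
PART_KINDS <- c(EXONIC_KINDS, "intron")

# Per-probe union overlap width with a reduced (disjoint) set of ranges,
# strand-blind, per chromosome.
.unionOverlapWidth <- function(probes, features) {
  out <- integer(length(probes))
  if (length(features) == 0L || length(probes) == 0L) return(out)
  red <- reduce(features, ignore.strand = TRUE)
  hits <- findOverlaps(probes, red, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  w <- width(pintersect(probes[queryHits(hits)], red[subjectHits(hits)],
                        ignore.strand = TRUE))
  agg <- tapply(w, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Classify probes against gene models
#'
#' Assigns each probe the set of gene-part classes it maps to. A probe gets
#' every exonic class (\code{five_utr}, \code{cds}, \code{three_utr}) whose
#' per-base union overlap with the probe covers at least \code{minFrac} of
#' the probe length. A probe with zero exonic overlap is classified
#' \code{intergenic} (some bases outside all gene parts) and/or
#' \code{intronic} (some bases inside introns). A probe with exonic overlap
#' that nowhere reaches \code{minFrac} receives no class and is excluded
#' downstream. Probes whose only exonic class is \code{cds} are retained
#' here but excluded from the analysis sets by \code{\link{analysisSets}}.
#'
#' Gene parts and probes are ordinary \code{GRanges} (1-based closed, the
#' Bioconductor convention; BED files imported through
#' \code{rtracklayer} arrive correctly converted from 0-based half-open).
#' Strand is ignored throughout: probe strand is not trusted.
#'
#' @param probes GRanges of probes.
#' @param geneParts GRanges of gene parts with a metadata column
#'   \code{part} in \code{five_utr}, \code{cds}, \code{intron},
#'   \code{three_utr}; may be empty (all probes intergenic).
#' @param minFrac minimum overlap as a fraction of probe length
#'   (default 0.10).
#' @return A \code{CharacterList}-like list of class vectors, one per probe.
#' @export
classifyProbes <- function(probes, geneParts, minFrac = 0.10) {
  stopifnot(minFrac > 0, minFrac <= 1)
  n <- length(probes)
  if (n == 0L) return(list())
  if (length(geneParts) > 0 &&
      !all(geneParts$part %in% PART_KINDS))
    stop("geneParts$part must be one of ", paste(PART_KINDS, collapse = ", "))
  plen <- width(probes)
  kindW <- sapply(PART_KINDS, function(k)
    .unionOverlapWidth(probes, geneParts[geneParts$part == k]))
  kindW <- matrix(kindW, nrow = n,
                  dimnames = list(NULL, PART_KINDS))
  exonW <- .unionOverlapWidth(
    probes, geneParts[geneParts$part %in% EXONIC_KINDS])
  anyW <- .unionOverlapWidth(probes, geneParts)
  lapply(seq_len(n), function(i) {
    ex <- EXONIC_KINDS[kindW[i, EXONIC_KINDS] >= minFrac * plen[i]]
    if (length(ex) > 0) return(ex)
    if (exonW[i] > 0) return(character(0))  # sub-threshold exonic contact
    cls <- character(0)
    if (anyW[i] < plen[i]) cls <- c(cls, "intergenic")
    if (kindW[i, "intron"] > 0) cls <- c(cls, "intronic")
    cls
  })
}

#' Map strandless structure predictions onto probes
#'
#' A structure maps to an intergenic probe when it overlaps the probe
#' itself by at least 1 nt; it maps to a gene-mapped probe when it overlaps
#' by at least 1 nt any gene part (UTR exon, coding exon or intron) that
#' itself touches the probe. Strand is ignored on both sides: structure
#' predictions are strandless.
#'
#' @param probes GRanges of probes.
#' @param probeClasses list of class vectors from \code{\link{classifyProbes}}.
#' @param structures GRanges of structure predictions (strand ignored).
#' @param geneParts GRanges of gene parts as in \code{\link{classifyProbes}}.
#' @return list (one entry per probe) of integer indices into
#'   \code{structures} that map to the probe. \code{lengths() > 0} gives
#'   the structured flag.
#' @export
mapStructures <- function(probes, probeClasses, structures, geneParts) {
  n <- length(probes)
  stopifnot(length(probeClasses) == n)
  if (n == 0L) return(list())
  geneMapped <- vapply(probeClasses, function(cl)
    any(cl %in% c(EXONIC_KINDS, "intronic")) && !identical(cl, "intergenic"),
    logical(1))
  # parts touching each probe (>= 1 nt)
  partHits <- if (length(geneParts))
    findOverlaps(probes, geneParts, ignore.strand = TRUE) else NULL
  structProbe <- if (length(structures))
    findOverlaps(probes, structures, ignore.strand = TRUE) else NULL
  structPart <- if (length(structures) && length(geneParts))
    findOverlaps(geneParts, structures, ignore.strand = TRUE) else NULL
  lapply(seq_len(n), function(i) {
    if (geneMapped[i]) {
      if (is.null(partHits)) return(integer(0))
      myParts <- subjectHits(partHits)[queryHits(partHits) == i]
      if (length(myParts) == 0L || is.null(structPart)) return(integer(0))
      sort(unique(subjectHits(structPart)[queryHits(structPart) %in% myParts]))
    } else {
      if (is.null(structProbe)) return(integer(0))
      sort(unique(subjectHits(structProbe)[queryHits(structProbe) == i]))
    }
  })
}

#' Protein-coding potential of a transcript sequence
#'
#' TRUE when some reading frame, on either strand, contains an open reading
#' frame (ATG to stop) longer than \code{minCodons} codons whose nucleotide
#' length covers at least one third of the transcript. Both strands are
#' scanned because probe and structure strands are not trusted.
#'
#' @param transcript character scalar or XString over ACGU/ACGT.
#' @param minCodons ORF length threshold in codons, exclusive (default 120).
#' @param minFracLen minimum ORF share of transcript length (default 1/3).
#' @return logical scalar.
#' @export
codingPotential <- function(transcript, minCodons = 120L, minFracLen = 1 / 3) {
  v <- .asRnaChars(transcript)
  n <- length(v)
  if (n < 3L) stop("transcript must be at least 3 nt")
  best <- .longestOrfCodons(v)
  bestRc <- .longestOrfCodons(.revCompChars(v))
  ncod <- max(best, bestRc)
  ncod > minCodons && (3 * ncod) >= n * minFracLen
}

# Longest forward ORF (ATG..stop, stop excluded from the count), in codons.
.longestOrfCodons <- function(v) {
  n <- length(v)
  stops <- c("UAA", "UAG", "UGA")
  best <- 0L
  for (frame in 0:2) {
    idx <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(idx) == 0L) next
    cod <- paste0(v[idx], v[idx + 1L], v[idx + 2L])
    open <- NA_integer_
    for (j in seq_along(cod)) {
      if (cod[j] %in% stops) {
        if (!is.na(open)) best <- max(best, j - open)
        open <- NA_integer_
      } else if (is.na(open) && cod[j] == "AUG") {
        open <- j
      }
    }
  }
  best
}

#' Annotate probes with known RNA labels
#'
#' A probe receives a known-RNA label when it covers at least
#' \code{minFrac} of the reference feature's length (note the denominator
#' is the known RNA, not the probe).
#'
#' @param probes GRanges of probes.
#' @param known GRanges of known RNAs with a metadata column \code{label}.
#' @param minFrac minimum covered fraction of the reference (default 0.10).
#' @return list of label character vectors, one per probe.
#' @export
annotateKnown <- function(probes, known, minFrac = 0.10) {
  n <- length(probes)
  out <- replicate(n, character(0), simplify = FALSE)
  if (length(known) == 0L || n == 0L) return(out)
  hits <- findOverlaps(probes, known, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  w <- width(pintersect(probes[queryHits(hits)], known[subjectHits(hits)],
                        ignore.strand = TRUE))
  keep <- w >= minFrac * width(known)[subjectHits(hits)]
  for (k in which(keep)) {
    i <- queryHits(hits)[k]
    out[[i]] <- c(out[[i]], known$label[subjectHits(hits)[k]])
  }
  lapply(out, unique)
}

#' Relative position of a structure within a UTR
#'
#' Midpoint of the structure/UTR overlap as a fraction of UTR length,
#' measured from the UTR's 5' end (0 = 5' end, 1 = 3' end, strand-aware).
#'
#' @param structure,utr GRanges of length 1 (or start/end pairs).
#' @param strand "+" or "-" strand of the UTR's gene.
#' @return numeric in [0, 1].
#' @export
utrRelativePosition <- function(structure, utr, strand = "+") {
  s0 <- start(structure) - 1L; e0 <- end(structure)
  us0 <- start(utr) - 1L; ue0 <- end(utr)
  ovS <- max(s0, us0); ovE <- min(e0, ue0)
  if (ovE <= ovS) stop("structure does not overlap the UTR")
  mid <- (ovS + ovE) / 2
  len <- ue0 - us0
  if (identical(as.character(strand), "-")) (ue0 - mid) / len
  else (mid - us0) / len
}

#' Analysis sets in the style of the probe summary table
#'
#' Splits classified probes into the two analysis categories: putative
#' ncRNAs (entirely intergenic or intronic, without coding potential) and
#' UTR probes (overlapping a 5' or 3' UTR). Probes whose only exonic class
#' is CDS are excluded.
#'
#' @param probeClasses list from \code{\link{classifyProbes}}.
#' @param codingFlags logical vector of per-probe coding potential
#'   (only consulted for intergenic/intronic probes).
#' @return list with integer index vectors \code{ncrna} and \code{utr},
#'   plus \code{excluded}.
#' @export
analysisSets <- function(probeClasses, codingFlags) {
  stopifnot(length(probeClasses) == length(codingFlags))
  isUtr <- vapply(probeClasses, function(cl)
    any(cl %in% c("five_utr", "three_utr")), logical(1))
  isNc <- vapply(probeClasses, function(cl)
    length(cl) > 0 && all(cl %in% c("intergenic", "intronic")), logical(1)) &
    !codingFlags
  list(ncrna = which(isNc), utr = which(isUtr),
       excluded = which(!isUtr & !isNc))
}

#' Tabulate probe classifications
#'
#' Counts probes per class column, reporting each class independently
#' (a probe overlapping both UTRs is counted in both columns), split by
#' the structured flag.
#'
#' @param probeClasses list from \code{\link{classifyProbes}}.
#' @param structured logical vector of per-probe structured flags.
#' @return data.frame of counts: rows structured/non_structured/total,
#'   columns the class labels.
#' @export
classificationCounts <- function(probeClasses, structured) {
  stopifnot(length(probeClasses) == length(structured))
  labs <- c("intergenic", "intronic", "five_utr", "three_utr", "cds")
  cnt <- function(idx) vapply(labs, function(l)
    sum(vapply(probeClasses[idx], function(cl) l %in% cl, logical(1))),
    integer(1))
  out <- rbind(structured = cnt(which(structured)),
               non_structured = cnt(which(!structured)),
               total = cnt(seq_along(structured)))
  as.data.frame(out)
}
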