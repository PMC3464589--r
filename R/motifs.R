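#' Extract a structure neighbourhood from a UTR sequence
#'
#' Subsequence covering a structure interval plus flanking nucleotides on
#' both sides, clipped at the UTR boundaries.
#'
#' @param utrSeq UTR sequence (character or XString).
#' @param start,end 1-based inclusive structure coordinates on the UTR.
#' @param flank flank width in nt (default 50).
#' @return character subsequence; attributes \code{start}/\code{end} give
#'   the extracted 1-based window.
#' @export
extractFlanked <- function(utrSeq, start, end, flank = 50L) {
  s <- as.character(utrSeq)
  n <- nchar(s)
  if (start < 1L || end > n || start > end)
    stop("structure [", start, ", ", end, "] outside the UTR (length ", n, ")")
  ws <- max(1L, start - flank)
  we <- min(n, end + flank)
  if (ws > start - flank || we < end + flank)
    message("flank clipped at UTR boundary")
  out <- substr(s, ws, we)
  attr(out, "start") <- ws
  attr(out, "end") <- we
  out
}

# log2-odds score matrix after pseudocount regularisation
.pwmLogOdds <- function(pwm, pseudocount = 0.01) {
  m <- pwm@matrix + pseudocount
  m <- sweep(m, 2, colSums(m), "/")
  log2(m / pwm@background)
}

#' Scan a sequence with a position weight matrix
#'
#' Log2-odds scoring of every window on the sense strand (RNA is
#' single-stranded); windows whose relative score — (score - min) /
#' (max - min) over the PWM's score range — reaches \code{relThreshold}
#' are reported.
#'
#' @param seq sequence (ACGU; T read as U).
#' @param pwm a \linkS4class{PWMotif}.
#' @param relThreshold relative-score cutoff in [0, 1] (default 0.8).
#' @param pseudocount added to matrix cells before log-odds (default 0.01).
#' @return data.frame with pwm, position (1-based offset), score (bits),
#'   relScore.
#' @export
pwmScan <- function(seq, pwm, relThreshold = 0.8, pseudocount = 0.01) {
  v <- .asRnaChars(seq)
  lo <- .pwmLogOdds(pwm, pseudocount)
  L <- ncol(lo)
  if (length(v) < L) stop("sequence shorter than the PWM")
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  idx <- match(v, RNA_BASES)
  nW <- length(v) - L + 1L
  scores <- vapply(seq_len(nW), function(p)
    sum(lo[cbind(idx[p:(p + L - 1L)], seq_len(L))]), numeric(1))
  rel <- (scores - smin) / (smax - smin)
  keep <- which(rel >= relThreshold)
  data.frame(pwm = rep(pwm@id, length(keep)), position = keep,
             score = scores[keep], relScore = rel[keep],
             stringsAsFactors = FALSE)
}

#' Motif enrichment against dinucleotide-shuffled backgrounds
#'
#' Observed statistic: the number of sequences with at least one PWM hit.
#' Null: the same statistic on dinucleotide-shuffled copies of every
#' sequence; the empirical p-value is (1 + #{null >= observed}) /
#' (nShuffles + 1). Adjust across PWMs with \code{\link{bhAdjust}}.
#'
#' @param sequences character vector (or XStringSet) of sequences.
#' @param pwm a \linkS4class{PWMotif}.
#' @param nShuffles shuffle rounds (default 100).
#' @param relThreshold passed to \code{\link{pwmScan}}.
#' @param seed integer seed.
#' @return list with \code{p.value}, \code{observed} (sequences with a
#'   hit) and \code{null} (the null statistics).
#' @export
motifEnrichment <- function(sequences, pwm, nShuffles = 100L,
                            relThreshold = 0.8, seed = 1L) {
  sequences <- vapply(as.list(sequences), as.character, character(1))
  stopifnot(length(sequences) > 0)
  nHit <- function(seqs) sum(vapply(seqs, function(s) {
    if (nchar(s) < ncol(pwm@matrix)) return(FALSE)
    nrow(pwmScan(s, pwm, relThreshold)) > 0
  }, logical(1)))
  obs <- nHit(sequences)
  if (obs == 0)
    return(list(p.value = 1, observed = 0L, null = integer(0)))
  null <- vapply(seq_len(nShuffles), function(r) {
    shuf <- vapply(seq_along(sequences), function(i)
      dinucShuffle(sequences[[i]],
                   seed = (seed + 7919L * r + i) %% .Machine$integer.max),
      character(1))
    nHit(shuf)
  }, numeric(1))
  list(p.value = (1 + sum(null >= obs)) / (nShuffles + 1),
       observed = obs, null = null)
}

#' Near-exact substring match of bound sequences
#'
#' Reduced sequence-level matching against experimentally bound RNA
#' sequences: a bound sequence matches a target when it occurs as a
#' substring with at most \code{maxMismatch} mismatches.
#'
#' @param boundSeqs character vector of experimentally bound sequences.
#' @param targetSeq target sequence.
#' @param maxMismatch maximum mismatches (default 1).
#' @return logical vector, one per bound sequence.
#' @export
matchBoundSequences <- function(boundSeqs, targetSeq, maxMismatch = 1L) {
  t <- Biostrings::RNAString(chartr("T", "U", toupper(as.character(targetSeq))))
  vapply(boundSeqs, function(b) {
    p <- Biostrings::RNAString(chartr("T", "U", toupper(as.character(b))))
    length(Biostrings::matchPattern(p, t,
                                    max.mismatch = maxMismatch)) > 0
  }, logical(1))
}
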