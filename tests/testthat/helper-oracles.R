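# Independent brute-force oracles used across the suite. All work on
# explicit base-position sets or exhaustive enumeration, never on the
# package's vectorised code paths.

# ---- interval oracles (1-based closed coordinates, position sets) ----

.posSet <- function(start, end) seq.int(start, end)

# per-base classification oracle mirroring the documented rule
oracleClassify <- function(pStart, pEnd, parts, minFrac = 0.10) {
  # parts: data.frame(start, end, part)
  pPos <- .posSet(pStart, pEnd)
  plen <- length(pPos)
  kinds <- c("five_utr", "cds", "three_utr", "intron")
  cov <- lapply(kinds, function(k) {
    rows <- parts[parts$part == k, , drop = FALSE]
    covered <- unique(unlist(lapply(seq_len(nrow(rows)), function(r)
      intersect(pPos, .posSet(rows$start[r], rows$end[r])))))
    covered
  })
  names(cov) <- kinds
  exonic <- kinds[1:3][vapply(kinds[1:3], function(k)
    length(cov[[k]]) >= minFrac * plen, logical(1))]
  if (length(exonic) > 0) return(sort(exonic))
  nExonBases <- length(unique(unlist(cov[kinds[1:3]])))
  if (nExonBases > 0) return(character(0))
  allCov <- unique(unlist(cov))
  out <- character(0)
  if (length(allCov) < plen) out <- c(out, "intergenic")
  if (length(cov$intron) > 0) out <- c(out, "intronic")
  sort(out)
}

# per-base structure-mapping oracle
oracleMapStructure <- function(pStart, pEnd, cls, sStart, sEnd, parts) {
  pPos <- .posSet(pStart, pEnd)
  sPos <- .posSet(sStart, sEnd)
  geneMapped <- any(cls %in% c("five_utr", "cds", "three_utr", "intronic")) &&
    !identical(cls, "intergenic")
  if (!geneMapped) return(length(intersect(pPos, sPos)) >= 1)
  for (r in seq_len(nrow(parts))) {
    partPos <- .posSet(parts$start[r], parts$end[r])
    if (length(intersect(pPos, partPos)) >= 1 &&
        length(intersect(sPos, partPos)) >= 1) return(TRUE)
  }
  FALSE
}

oracleAnnotateKnown <- function(pStart, pEnd, kStart, kEnd, minFrac = 0.10) {
  shared <- length(intersect(.posSet(pStart, pEnd), .posSet(kStart, kEnd)))
  shared >= minFrac * (kEnd - kStart + 1)
}

# ---- statistics oracles ----

oracleBH <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i)
    min(1, min(vapply(which(p >= p[i] - 1e-15), function(j)
      m * p[j] / sum(p <= p[j] + 1e-15), numeric(1)))), numeric(1))
}

oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  pObs <- probs[a - lo + 1]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# ---- sequence oracles ----

# longest forward ORF via anchored regular expressions, per AUG occurrence
oracleOrfCodons <- function(seq) {
  best <- 0L
  for (s in c(seq, oracleRevComp(seq))) {
    starts <- gregexpr("AUG", s, fixed = TRUE)[[1]]
    if (starts[1] == -1) next
    for (p in starts) {
      tail <- substring(s, p)
      m <- regmatches(tail,
        regexpr("^AUG(?:[ACGU]{3})*?(?:UAA|UAG|UGA)", tail))
      if (length(m) > 0) best <- max(best, (nchar(m) - 3L) %/% 3L)
    }
  }
  best
}

oracleRevComp <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

oracleDinucCounts <- function(s) {
  v <- strsplit(s, "")[[1]]
  if (length(v) < 2) return(table(character(0)))
  table(paste0(v[-length(v)], v[-1]))
}

# ---- PWM window oracle: plain per-window log-odds loop ----
oraclePwmScores <- function(seq, probMat, background = rep(0.25, 4),
                            pseudocount = 0.01) {
  v <- strsplit(seq, "")[[1]]
  L <- ncol(probMat)
  bases <- c("A", "C", "G", "U")
  reg <- apply(probMat + pseudocount, 2, function(col) col / sum(col))
  vapply(seq_len(length(v) - L + 1), function(p) {
    sc <- 0
    for (j in seq_len(L)) {
      b <- match(v[p + j - 1], bases)
      sc <- sc + log2(reg[b, j] / background[b])
    }
    sc
  }, numeric(1))
}

# ---- duplex oracle: memoized top-down search over arbitrary monotone
# pairings (any number of bulges), independent of the row-scan DP ----
oracleDuplexMfe <- function(q, t, pair = c(GC = -3, AU = -2, GU = -1),
                            bulge = 4) {
  qv <- strsplit(q, "")[[1]]
  tv <- rev(strsplit(t, "")[[1]])   # 3'->5'
  n <- length(qv); m <- length(tv)
  eP <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = pair[["GC"]], "AU" = pair[["AU"]],
           "GU" = pair[["GU"]], Inf)
  }
  memo <- new.env()
  f <- function(i, k) {   # best energy of a duplex STARTING with pair (i,k)
    key <- paste(i, k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    e0 <- eP(qv[i], tv[k])
    if (!is.finite(e0)) { memo[[key]] <- Inf; return(Inf) }
    best <- e0
    if (i < n && k < m) {
      for (i2 in (i + 1):n) for (k2 in (k + 1):m) {
        cont <- f(i2, k2)
        if (is.finite(cont)) {
          cost <- e0 + bulge * ((i2 - i - 1) + (k2 - k - 1)) + cont
          if (cost < best) best <- cost
        }
      }
    }
    memo[[key]] <- best
    best
  }
  best <- Inf
  for (i in seq_len(n)) for (k in seq_len(m)) best <- min(best, f(i, k))
  if (best >= 0) NA_real_ else best
}

# random helpers
randomRna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

randomParts <- function(nGenes, chromLen = 10000) {
  rows <- list()
  kinds <- c("five_utr", "intron", "cds", "intron", "three_utr")
  for (g in seq_len(nGenes)) {
    at <- sample.int(chromLen - 600, 1)
    lens <- sample(20:120, 5, replace = TRUE)
    for (j in seq_along(kinds)) {
      rows[[length(rows) + 1]] <- data.frame(
        start = at, end = at + lens[j] - 1, part = kinds[j],
        gene = paste0("g", g))
      at <- at + lens[j]
    }
  }
  do.call(rbind, rows)
}

partsToGRanges <- function(parts) {
  GenomicRanges::GRanges("chrT",
    IRanges::IRanges(parts$start, parts$end),
    part = parts$part)
}

smallOntology <- function(shape = c(6, 5, 4), nFine = 8, nCoarse = 2,
                          seed = 1) {
  cfg <- syntheticConfig(seed = seed, latticeShape = shape,
                         nCoarseRegions = nCoarse, nFineRegions = nFine,
                         probesPerGroup = c(structured_utr = 5L,
                                            non_structured_utr = 5L))
  simulateOntology(cfg)
}
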