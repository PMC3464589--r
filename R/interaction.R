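#' Dinucleotide shuffle
#'
#' Uniform random permutation of a sequence that preserves the exact
#' multiset of dinucleotides (hence also mononucleotide counts) and the
#' first and last nucleotide, via the Eulerian-path construction of
#' Altschul and Erickson: the sequence is a walk on the 4-vertex
#' nucleotide graph; a random arborescence toward the terminal vertex
#' fixes each vertex's last exit edge, the remaining out-edges are
#' permuted uniformly, and the walk is replayed.
#'
#' @param seq character scalar or XString over ACGU (T accepted, read as U).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return shuffled sequence as a character scalar.
#' @export
dinucShuffle <- function(seq, seed = NULL) {
  v <- .asRnaChars(seq)
  n <- length(v)
  if (n < 2L) stop("sequence must be at least 2 nt")
  .withSeed(seed, .dinucShuffleChars(v)) |> .collapseChars()
}

.dinucShuffleChars <- function(v) {
  n <- length(v)
  from <- v[-n]; to <- v[-1L]
  verts <- unique(v)
  term <- v[n]
  outEdges <- split(to, factor(from, levels = verts))
  nonTerm <- setdiff(verts[vapply(outEdges, length, 1L) > 0L], term)
  # sample last-exit edges until they form an arborescence into `term`
  repeat {
    last <- vapply(nonTerm, function(u) {
      e <- outEdges[[u]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    ok <- TRUE
    for (u in nonTerm) {
      cur <- u; steps <- 0L
      while (cur != term) {
        if (!(cur %in% nonTerm) || steps > length(verts)) { ok <- FALSE; break }
        cur <- last[[cur]]
        steps <- steps + 1L
      }
      if (!ok) break
    }
    if (ok) break
  }
  lists <- lapply(verts, function(u) {
    e <- outEdges[[u]]
    if (u %in% nonTerm) {
      # remove one copy of the designated last edge, permute, re-append
      i <- match(last[[u]], e)
      rest <- e[-i]
      if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
      c(rest, last[[u]])
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })
  names(lists) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- v[1L]
  cur <- v[1L]
  for (i in 2:n) {
    nxt <- lists[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

# duplexMfe with the optional accessibility heuristic applied to both sides
.scanOne <- function(q, t, model, accessWeight) {
  if (is.null(accessWeight)) return(duplexMfe(q, t, model))
  duplexMfe(q, t, model,
            accessQuery = accessibilityProfile(q, weight = accessWeight),
            accessTarget = accessibilityProfile(t, weight = accessWeight))
}

# pair energy lookup table over (query base, target base); +Inf = no pair
.pairEnergyTable <- function(model) {
  pe <- model@pairEnergies
  m <- matrix(Inf, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["G", "C"] <- m["C", "G"] <- pe[["GC"]]
  m["A", "U"] <- m["U", "A"] <- pe[["AU"]]
  m["G", "U"] <- m["U", "G"] <- pe[["GU"]]
  m
}

#' Minimum-free-energy local duplex between two sequences
#'
#' Dynamic program over antiparallel intermolecular duplexes under a
#' pair-additive energy model with per-nucleotide bulge penalties. The
#' duplex must start and end in a base pair; bulges of any length are
#' allowed on either side at \code{bulgePenalty} per unpaired nucleotide.
#' Optional accessibility profiles add a per-position opening penalty for
#' every covered position. Returns the single best (most negative) site,
#' or NULL when no duplex with negative energy exists.
#'
#' @param query,target sequences (character or XString, ACGU; T read as U).
#' @param model an \linkS4class{EnergyModel}.
#' @param accessQuery,accessTarget optional numeric opening-penalty
#'   profiles (one value per position, >= 0).
#' @return list with \code{mfe} (kcal/mol), 1-based inclusive site
#'   coordinates \code{queryStart/queryEnd/targetStart/targetEnd},
#'   \code{siteLength} (query side) and \code{gcFrac} (GC fraction of the
#'   query site); or NULL.
#' @export
duplexMfe <- function(query, target, model = energyModel(),
                      accessQuery = NULL, accessTarget = NULL) {
  q <- .asRnaChars(query)
  tRev <- rev(.asRnaChars(target))   # align against 3'->5' target
  n <- length(q); m <- length(tRev)
  pe <- .pairEnergyTable(model)
  bp <- model@bulgePenalty
  aq <- if (is.null(accessQuery)) numeric(n) else as.numeric(accessQuery)
  atF <- if (is.null(accessTarget)) numeric(m)
         else rev(as.numeric(accessTarget))
  stopifnot(length(aq) == n, length(atF) == m)
  qi <- match(q, RNA_BASES); ti <- match(tRev, RNA_BASES)
  E <- matrix(Inf, n, m)
  D <- matrix(Inf, n, m)
  inc <- bp + atF                     # per-column bulge increments
  cumInc <- cumsum(inc)
  for (i in seq_len(n)) {
    pairRow <- pe[qi[i], ti] + aq[i] + atF
    prevD <- if (i > 1L) c(Inf, D[i - 1L, -m]) else rep(Inf, m)
    Erow <- pairRow + pmin(0, prevD)
    A <- Erow
    if (i > 1L) A <- pmin(A, D[i - 1L, ] + bp + aq[i])
    # D[k] = min_{k' <= k} A[k'] + sum_{k'+1..k} inc  (running-min scan)
    Drow <- cummin(A - cumInc) + cumInc
    E[i, ] <- Erow
    D[i, ] <- Drow
  }
  best <- min(E)
  if (!is.finite(best) || best >= 0) return(NULL)
  idx <- which(E == best, arr.ind = TRUE)[1L, ]
  iEnd <- idx[[1]]; kEnd <- idx[[2]]
  # traceback for the site start
  i <- iEnd; k <- kEnd
  tol <- 1e-9
  repeat {
    # currently at a paired cell (i, k)
    prev <- if (i > 1L && k > 1L) D[i - 1L, k - 1L] else Inf
    if (!is.finite(prev) || prev >= -tol) break
    i <- i - 1L; k <- k - 1L
    # descend through bulges in D until we land on a paired cell
    while (abs(D[i, k] - E[i, k]) > tol) {
      if (i > 1L &&
          abs(D[i, k] - (D[i - 1L, k] + bp + aq[i])) <= tol) {
        i <- i - 1L
      } else {
        k <- k - 1L
      }
    }
  }
  qs <- i; qe <- iEnd
  siteChars <- q[qs:qe]
  list(mfe = best,
       queryStart = qs, queryEnd = qe,
       targetStart = m - kEnd + 1L, targetEnd = m - k + 1L,
       siteLength = qe - qs + 1L,
       gcFrac = .gcFrac(siteChars))
}

#' Score all query-target pairs
#'
#' Runs \code{\link{duplexMfe}} on every supplied pair and assembles a hit
#' table; pairs without a negative-energy duplex are reported with NA.
#'
#' @param queries,targets named character vectors (or XStringSets) of
#'   equal length; element i of each forms pair i.
#' @param model an \linkS4class{EnergyModel}.
#' @param accessWeight weight of the GC-based accessibility heuristic
#'   applied to both sequences (\code{\link{accessibilityProfile}});
#'   NULL disables accessibility (default 0.1).
#' @return data.frame with query, target, mfe, site coordinates,
#'   siteLength, gcFrac.
#' @export
scanInteractions <- function(queries, targets, model = energyModel(),
                             accessWeight = 0.1) {
  queries <- vapply(as.list(queries), as.character, character(1))
  targets <- vapply(as.list(targets), as.character, character(1))
  stopifnot(length(queries) == length(targets))
  qn <- names(queries); tn <- names(targets)
  if (is.null(qn)) qn <- sprintf("q%04d", seq_along(queries))
  if (is.null(tn)) tn <- sprintf("t%04d", seq_along(targets))
  rows <- lapply(seq_along(queries), function(i) {
    h <- .scanOne(queries[[i]], targets[[i]], model, accessWeight)
    if (is.null(h))
      return(data.frame(query = qn[i], target = tn[i], mfe = NA_real_,
                        queryStart = NA, queryEnd = NA, targetStart = NA,
                        targetEnd = NA, siteLength = NA, gcFrac = NA))
    data.frame(query = qn[i], target = tn[i], mfe = h$mfe,
               queryStart = h$queryStart, queryEnd = h$queryEnd,
               targetStart = h$targetStart, targetEnd = h$targetEnd,
               siteLength = h$siteLength, gcFrac = h$gcFrac)
  })
  do.call(rbind, rows)
}

#' Dinucleotide-shuffled background of duplex MFEs
#'
#' For each pair and shuffle replicate, both sequences are dinucleotide
#' shuffled and rescored, recording the MFE and the site covariates
#' (length, GC). This is the null sample on which the censored EVD
#' background is fitted.
#'
#' @param queries,targets paired sequences as in \code{\link{scanInteractions}}.
#' @param nShuffles shuffle replicates per pair (default 100).
#' @param model an \linkS4class{EnergyModel}.
#' @param seed integer seed (replicates use derived sub-seeds).
#' @param accessWeight accessibility heuristic weight as in
#'   \code{\link{scanInteractions}} (must match the observed scan).
#' @return data.frame with mfe, siteLength, gcFrac (hits only).
#' @export
buildBackground <- function(queries, targets, nShuffles = 100L,
                            model = energyModel(), seed = 1L,
                            accessWeight = 0.1) {
  stopifnot(nShuffles >= 1L)
  queries <- vapply(as.list(queries), as.character, character(1))
  targets <- vapply(as.list(targets), as.character, character(1))
  res <- vector("list", length(queries) * nShuffles)
  k <- 0L
  for (i in seq_along(queries)) {
    for (r in seq_len(nShuffles)) {
      k <- k + 1L
      sub <- (seed + 7919L * (k %% 262139L)) %% .Machine$integer.max
      qs <- dinucShuffle(queries[[i]], seed = sub)
      ts <- dinucShuffle(targets[[i]], seed = sub + 1L)
      h <- .scanOne(qs, ts, model, accessWeight)
      if (!is.null(h))
        res[[k]] <- c(h$mfe, h$siteLength, h$gcFrac)
    }
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  out <- as.data.frame(res)
  names(out) <- c("mfe", "siteLength", "gcFrac")
  out
}

#' Censored maximum-likelihood fit of the extreme-value law
#'
#' Fits (lambda, mu) of P(S <= s) = 1 - exp(-exp(lambda (s - mu))) — the
#' minimum-Gumbel law governing best-of-many duplex MFEs — by maximum
#' likelihood, treating every sample at or above \code{censorCutoff} as
#' right-censored there: near-zero MFEs pile up around the cutoff for
#' reasons unrelated to the extreme tail, so only the tail shape below the
#' cutoff is trusted.
#'
#' @param samples numeric vector of background MFEs.
#' @param censorCutoff censoring point (default -10 kcal/mol);
#'   \code{Inf} gives the ordinary uncensored fit.
#' @param minUncensored minimum samples below the cutoff (default 30).
#' @return named numeric c(lambda, mu).
#' @export
fitCensoredEvd <- function(samples, censorCutoff = -10, minUncensored = 30L) {
  unc <- samples[samples < censorCutoff]
  nCens <- sum(samples >= censorCutoff)
  if (length(unc) < minUncensored)
    stop("only ", length(unc), " uncensored samples below ", censorCutoff,
         "; need >= ", minUncensored)
  if (stats::sd(unc) == 0) stop("degenerate sample: zero variance")
  eulerGamma <- 0.5772156649015329
  lam0 <- pi / (stats::sd(unc) * sqrt(6))
  mu0 <- mean(unc) + eulerGamma / lam0
  negll <- function(par) {
    lam <- exp(par[1]); mu <- par[2]
    z <- lam * (unc - mu)
    ll <- sum(log(lam) + z - exp(z))
    if (nCens > 0 && is.finite(censorCutoff))
      ll <- ll - nCens * exp(lam * (censorCutoff - mu))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  fit <- stats::optim(c(log(lam0), mu0), negll, method = "BFGS")
  c(lambda = exp(fit$par[1]), mu = fit$par[2])
}

#' Sample from the extreme-value law
#'
#' Inverse-CDF draws from P(S <= s) = 1 - exp(-exp(lambda (s - mu))).
#'
#' @param n sample size.
#' @param lambda,mu law parameters (lambda > 0).
#' @param seed optional integer seed.
#' @return numeric vector of length n.
#' @export
rEvd <- function(n, lambda, mu, seed = NULL) {
  stopifnot(lambda > 0)
  .withSeed(seed, mu + log(-log(1 - stats::runif(n))) / lambda)
}

#' Fit the binned EVD background
#'
#' Bins the background samples into a grid over (site length, GC fraction)
#' at empirical quantile edges (outer edges open to +/- Inf, so every
#' covariate pair maps to exactly one bin) and fits the censored EVD in
#' each bin. Duplicate quantile edges collapse (discrete site lengths),
#' which merges neighbouring bins; bins with too few uncensored samples
#' borrow the parameters of the nearest fitted bin.
#'
#' @param background data.frame from \code{\link{buildBackground}}.
#' @param nLenBins,nGcBins requested bin counts (defaults 7 and 7, i.e.
#'   49 covariate combinations).
#' @param censorCutoff censoring point (default -10).
#' @param minPerBin minimum samples per bin before borrowing (default 50).
#' @return an \linkS4class{EvdBackground}.
#' @export
binAndFit <- function(background, nLenBins = 7L, nGcBins = 7L,
                      censorCutoff = -10, minPerBin = 50L) {
  stopifnot(nrow(background) > 0)
  qEdges <- function(v, k) {
    e <- unique(stats::quantile(v, probs = seq(0, 1, length.out = k + 1),
                                names = FALSE, type = 7))
    if (length(e) < 2) e <- c(e, e + 1)
    e[1] <- -Inf; e[length(e)] <- Inf
    e
  }
  lenB <- qEdges(background$siteLength, nLenBins)
  gcB <- qEdges(background$gcFrac, nGcBins)
  nL <- length(lenB) - 1L; nG <- length(gcB) - 1L
  if (nL < nLenBins || nG < nGcBins)
    message("duplicate quantile edges: grid reduced to ", nL, " x ", nG)
  li <- findInterval(background$siteLength, lenB, rightmost.closed = FALSE)
  gi <- findInterval(background$gcFrac, gcB, rightmost.closed = FALSE)
  lambda <- mu <- matrix(NA_real_, nL, nG)
  counts <- matrix(0L, nL, nG)
  for (a in seq_len(nL)) for (b in seq_len(nG)) {
    s <- background$mfe[li == a & gi == b]
    counts[a, b] <- length(s)
    if (length(s) >= minPerBin &&
        sum(s < censorCutoff) >= 30L &&
        stats::sd(s[s < censorCutoff]) > 0) {
      fit <- tryCatch(fitCensoredEvd(s, censorCutoff), error = function(e) NULL)
      if (!is.null(fit)) { lambda[a, b] <- fit[1]; mu[a, b] <- fit[2] }
    }
  }
  if (all(is.na(lambda))) {
    glob <- fitCensoredEvd(background$mfe, censorCutoff)
    lambda[] <- glob[1]; mu[] <- glob[2]
  } else if (any(is.na(lambda))) {
    # borrow from the nearest fitted bin (grid distance)
    fitted <- which(!is.na(lambda), arr.ind = TRUE)
    for (idx in which(is.na(lambda))) {
      a <- (idx - 1L) %% nL + 1L; b <- (idx - 1L) %/% nL + 1L
      d <- (fitted[, 1] - a)^2 + (fitted[, 2] - b)^2
      near <- fitted[which.min(d), , drop = FALSE]
      lambda[a, b] <- lambda[near]; mu[a, b] <- mu[near]
    }
    message("some bins borrowed parameters from their nearest fitted bin")
  }
  new("EvdBackground", lenBreaks = lenB, gcBreaks = gcB,
      lambda = lambda, mu = mu, counts = counts,
      censorCutoff = censorCutoff)
}

#' Extreme-value interaction p-value
#'
#' p = 1 - exp(-exp(lambda (MFE - mu))): the probability of a chance MFE
#' at least as stable as the observed one, strictly increasing in MFE.
#'
#' @param mfe observed MFE (kcal/mol).
#' @param lambda,mu law parameters, or an \linkS4class{EvdBackground} as
#'   \code{lambda} with the hit covariates in \code{siteLength}, \code{gcFrac}.
#' @param siteLength,gcFrac hit covariates (used with a background object).
#' @return numeric p-value(s) in [0, 1].
#' @export
interactionPvalue <- function(mfe, lambda, mu = NULL,
                              siteLength = NULL, gcFrac = NULL) {
  if (is(lambda, "EvdBackground")) {
    bg <- lambda
    stopifnot(!is.null(siteLength), !is.null(gcFrac))
    a <- findInterval(siteLength, bg@lenBreaks)
    b <- findInterval(gcFrac, bg@gcBreaks)
    lam <- bg@lambda[cbind(a, b)]
    m <- bg@mu[cbind(a, b)]
  } else {
    lam <- lambda; m <- mu
  }
  if (any(lam <= 0, na.rm = TRUE)) stop("lambda must be > 0")
  1 - exp(-exp(lam * (mfe - m)))
}

#' Filter interaction hits on the reporting thresholds
#'
#' Keeps hits with site length strictly greater than \code{minLen} nt, MFE
#' strictly below \code{maxMfe} kcal/mol and p-value strictly below
#' \code{maxP}.
#'
#' @param hits data.frame with siteLength, mfe, p columns.
#' @param minLen exclusive site-length threshold (default 9 nt).
#' @param maxMfe exclusive MFE threshold (default -40 kcal/mol).
#' @param maxP exclusive p-value threshold (default 1e-5).
#' @return the surviving rows.
#' @export
filterHits <- function(hits, minLen = 9L, maxMfe = -40, maxP = 1e-5) {
  if (nrow(hits) == 0L) return(hits)
  keep <- !is.na(hits$mfe) & hits$siteLength > minLen &
    hits$mfe < maxMfe & hits$p < maxP
  hits[keep, , drop = FALSE]
}

#' Heuristic accessibility profile
#'
#' Per-position duplex opening penalty proportional to local GC content:
#' GC-rich neighbourhoods tend to be locked in stable intramolecular
#' structure and cost more to open. A coarse single-strandedness heuristic;
#' thermodynamic opening energies from a folding engine can be supplied to
#' \code{\link{duplexMfe}} instead.
#'
#' @param seq sequence (ACGU).
#' @param window smoothing window in nt (default 11).
#' @param weight penalty at 100% local GC (kcal/mol, default 0.5).
#' @return numeric penalty per position.
#' @export
accessibilityProfile <- function(seq, window = 11L, weight = 0.5) {
  v <- .asRnaChars(seq)
  isGC <- as.numeric(v %in% c("G", "C"))
  half <- window %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- isGC[max(1L, i - half):min(n, i + half)]
    weight * mean(w)
  }, numeric(1))
}
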