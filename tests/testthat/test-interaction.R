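test_that("dinucleotide shuffle preserves counts and terminals exactly", {
  expect_identical(dinucShuffle("AAAA", seed = 1), "AAAA")
  expect_identical(dinucShuffle("ACGU", seed = 1), "ACGU")  # unique path
  set.seed(2)
  for (i in 1:40) {
    s <- randomRna(sample(c(5:30, 200), 1), gc = runif(1, 0.2, 0.8))
    sh <- dinucShuffle(s, seed = 100 + i)
    expect_identical(oracleDinucCounts(sh), oracleDinucCounts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, nchar(s), nchar(s)),
                     substr(s, nchar(s), nchar(s)))
  }
  # deterministic given the seed, and actually permutes
  s <- randomRna(200)
  expect_identical(dinucShuffle(s, seed = 9), dinucShuffle(s, seed = 9))
  expect_false(identical(dinucShuffle(s, seed = 9), s))
  expect_error(dinucShuffle("ACGX"), "non-nucleotide")
})

test_that("duplex MFE reproduces closed-form and degenerate cases", {
  expect_null(duplexMfe("AAAA", "AAAA"))       # A-A cannot pair
  h <- duplexMfe("GGGGG", "CCCCC")
  expect_equal(h$mfe, -15)                     # 5 GC pairs at -3
  expect_equal(h$siteLength, 5L)
  expect_equal(h$gcFrac, 1)
  # GU wobble only
  expect_equal(duplexMfe("GGG", "UUU")$mfe, -3)
  # antiparallel orientation: site coordinates come back 5'->3' on both
  h2 <- duplexMfe("AAGGGGAA", "UUCCCCUU")
  expect_equal(h2$mfe, -3 * 4 - 2 * 4)         # GC core plus AU flanks
  expect_equal(c(h2$queryStart, h2$queryEnd), c(1, 8))
})

test_that("duplex MFE equals the exhaustive monotone-pairing oracle", {
  set.seed(31)
  for (i in 1:120) {
    q <- randomRna(sample(6:11, 1), gc = runif(1, 0.3, 0.7))
    t <- randomRna(sample(6:11, 1), gc = runif(1, 0.3, 0.7))
    got <- duplexMfe(q, t)
    exp <- oracleDuplexMfe(q, t)
    if (is.na(exp)) expect_null(got, label = paste(q, t))
    else expect_equal(got$mfe, exp, label = paste(q, t))
  }
})

test_that("duplex MFE is symmetric in its arguments", {
  set.seed(37)
  for (i in 1:40) {
    q <- randomRna(30); t <- randomRna(30)
    hq <- duplexMfe(q, t); ht <- duplexMfe(t, q)
    if (is.null(hq)) expect_null(ht)
    else expect_equal(hq$mfe, ht$mfe)
  }
})

test_that("accessibility penalties raise duplex energies", {
  q <- randomRna(50, gc = 0.6); t <- randomRna(50, gc = 0.6)
  set.seed(41)
  h0 <- duplexMfe(q, t)
  h1 <- duplexMfe(q, t, accessQuery = accessibilityProfile(q),
                  accessTarget = accessibilityProfile(t))
  if (!is.null(h0) && !is.null(h1)) expect_gte(h1$mfe, h0$mfe)
  prof <- accessibilityProfile(strrep("G", 20), weight = 0.5)
  expect_equal(prof, rep(0.5, 20))
})

test_that("interaction p-value follows the extreme-value formula", {
  expect_equal(interactionPvalue(-20, 1, -20), 1 - exp(-1))
  expect_equal(interactionPvalue(-25, 1, -20), 1 - exp(-exp(-5)))
  expect_equal(interactionPvalue(-25, 1, -20), 0.006715, tolerance = 1e-4)
  expect_lt(interactionPvalue(-1e3, 0.5, -15), 1e-200)
  expect_equal(interactionPvalue(1e3, 0.5, -15), 1)
  # monotone in MFE and in mu (strictly, until numerical saturation at 1)
  m <- seq(-60, -10, by = 0.5)
  pm <- interactionPvalue(m, 0.7, -18)
  expect_true(all(diff(pm) > 0 | pm[-1] == 1))
  mus <- seq(-40, -16, by = 0.5)
  pu <- vapply(mus, function(u) interactionPvalue(-25, 0.7, u), numeric(1))
  expect_true(all(diff(pu) < 0 | pu[-1] == 1))
  expect_error(interactionPvalue(-20, -1, -20), "lambda")
})

test_that("censored EVD fitting recovers known parameters", {
  x <- rEvd(5000, lambda = 0.5, mu = -15, seed = 51)
  fit <- fitCensoredEvd(x, censorCutoff = -10)
  expect_lt(abs(fit[["lambda"]] - 0.5) / 0.5, 0.10)
  expect_lt(abs(fit[["mu"]] - (-15)) / 15, 0.10)
  # heavy censoring: censor inside the bulk, tail still identifies the law
  xc <- rEvd(20000, lambda = 0.8, mu = -8, seed = 53)
  fitc <- fitCensoredEvd(xc, censorCutoff = -10)
  expect_lt(abs(fitc[["lambda"]] - 0.8) / 0.8, 0.15)
  # uncensored limit agrees with the plain ML fit
  fitu <- fitCensoredEvd(x, censorCutoff = Inf)
  fitn <- fitCensoredEvd(x, censorCutoff = max(x) + 1)
  expect_equal(fitu[["lambda"]], fitn[["lambda"]], tolerance = 1e-4)
  expect_error(fitCensoredEvd(rep(-20, 100), -10), "degenerate")
  expect_error(fitCensoredEvd(rEvd(20, 0.5, -15, seed = 1), -10), "uncensored")
})

test_that("binned background partitions the covariate space", {
  set.seed(61)
  n <- 4000
  bg <- data.frame(mfe = rEvd(n, 0.5, -18),
                   siteLength = sample(5:40, n, TRUE),
                   gcFrac = runif(n))
  evd <- suppressMessages(binAndFit(bg, minPerBin = 40))
  expect_s4_class(evd, "EvdBackground")
  expect_lte(nrow(evd@lambda) * ncol(evd@lambda), 49)
  expect_true(all(is.finite(evd@lambda)) && all(evd@lambda > 0))
  # arbitrary covariates map into exactly one bin
  for (sl in c(0, 5, 12, 40, 1000)) for (gc in c(0, 0.33, 0.5, 1)) {
    a <- findInterval(sl, evd@lenBreaks)
    b <- findInterval(gc, evd@gcBreaks)
    expect_true(a >= 1 && a <= nrow(evd@lambda))
    expect_true(b >= 1 && b <= ncol(evd@lambda))
  }
  # homogeneous law: bin parameters agree within sampling error
  expect_lt(stats::sd(evd@lambda) / mean(evd@lambda), 0.25)
  expect_lt(stats::sd(evd@mu), 1.5)
})

test_that("background construction is deterministic and counts replicates", {
  cfg <- syntheticConfig(seed = 71)
  ip <- simulateInteractionPairs(cfg, nPairs = 3, plantedFrac = 0,
                                 seqLength = 40)
  b1 <- buildBackground(ip$queries, ip$targets, nShuffles = 4, seed = 5)
  b2 <- buildBackground(ip$queries, ip$targets, nShuffles = 4, seed = 5)
  expect_identical(b1, b2)
  expect_lte(nrow(b1), 12)
  b3 <- buildBackground(ip$queries[1], ip$targets[1], nShuffles = 1, seed = 5)
  expect_lte(nrow(b3), 1)
})

test_that("hit filtering applies all three strict thresholds", {
  hits <- data.frame(
    query = paste0("q", 1:6), target = paste0("t", 1:6),
    siteLength = c(9, 10, 15, 20, 12, 14),
    mfe = c(-60, -40, -55, -39, -70, -45),
    p = c(1e-7, 1e-7, 1e-6, 1e-8, 2e-5, 1e-9))
  out <- filterHits(hits)
  expect_identical(out$query, c("q3", "q6"))   # 9 nt and -40 both rejected
  expect_equal(nrow(filterHits(hits[0, ])), 0)
})

test_that("planted interaction sites are found at the planted coordinates", {
  cfg <- syntheticConfig(seed = 81)
  ip <- simulateInteractionPairs(cfg, nPairs = 12, plantedFrac = 1,
                                 seqLength = 60)
  h <- scanInteractions(ip$queries, ip$targets)
  for (i in 1:12) {
    lo <- ip$truth$queryStart[i]; hi <- lo + 14
    expect_lte(h$queryStart[i], hi)
    expect_gte(h$queryEnd[i], lo)
    expect_lte(h$mfe[i], -40)
  }
  # planted pairs rank above nulls by p-value
  ip2 <- simulateInteractionPairs(cfg, nPairs = 40, plantedFrac = 0.25)
  h2 <- scanInteractions(ip2$queries, ip2$targets)
  bg <- buildBackground(ip2$queries[!ip2$truth$planted],
                        ip2$targets[!ip2$truth$planted],
                        nShuffles = 25, seed = 83)
  evd <- suppressMessages(binAndFit(bg, minPerBin = 30))
  p <- interactionPvalue(h2$mfe, evd, siteLength = h2$siteLength,
                         gcFrac = h2$gcFrac)
  planted <- ip2$truth$planted
  expect_gte(mean(max(p[planted]) < min(p[!planted], na.rm = TRUE)), 0.95)
})

test_that("null interaction p-values are a valid, non-anticonservative test", {
  cfg <- syntheticConfig(seed = 91)
  ip <- simulateInteractionPairs(cfg, nPairs = 200, plantedFrac = 0)
  h <- scanInteractions(ip$queries, ip$targets)
  bg <- buildBackground(ip$queries[1:120], ip$targets[1:120],
                        nShuffles = 25L, seed = 92)
  evd <- suppressMessages(binAndFit(bg))
  ok <- !is.na(h$mfe)
  p <- interactionPvalue(h$mfe[ok], evd, siteLength = h$siteLength[ok],
                         gcFrac = h$gcFrac[ok])
  for (al in c(0.01, 0.05, 0.2))
    expect_lte(mean(p <= al), al + 2 * sqrt(al * (1 - al) / length(p)))
})
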