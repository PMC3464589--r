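test_that("probe classification handles the canonical cases", {
  parts <- partsToGRanges(data.frame(
    start = c(101, 401, 901, 1801, 2301),
    end = c(400, 900, 1800, 2300, 2900),
    part = c("five_utr", "intron", "cds", "intron", "three_utr")))

  # fully inside the 3'UTR exon
  p <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2400, 2499))
  expect_identical(classifyProbes(p, parts)[[1]], "three_utr")

  # 10 nt of a 100 nt probe on the 5'UTR: kept at 0.10, dropped at 0.101
  p <- GenomicRanges::GRanges("chrT", IRanges::IRanges(391, 490))
  expect_identical(classifyProbes(p, parts, minFrac = 0.10)[[1]], "five_utr")
  expect_false("five_utr" %in% classifyProbes(p, parts, minFrac = 0.101)[[1]])

  # probe entirely in the intron
  p <- GenomicRanges::GRanges("chrT", IRanges::IRanges(500, 700))
  expect_identical(classifyProbes(p, parts)[[1]], "intronic")

  # no gene models: everything intergenic
  p <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 50))
  expect_identical(classifyProbes(p, parts[0])[[1]], "intergenic")

  # probe spanning gap and intron start with zero exonic contact
  p <- GenomicRanges::GRanges("chrT", IRanges::IRanges(3000, 3200))
  expect_identical(sort(classifyProbes(p, parts)[[1]]), "intergenic")
})

test_that("probe classification equals the per-base oracle on random inputs", {
  set.seed(101)
  parts <- randomParts(25, chromLen = 20000)
  gr <- partsToGRanges(parts)
  n <- 400
  starts <- sample.int(19500, n)
  lens <- sample(20:300, n, replace = TRUE)
  probes <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(starts, pmin(starts + lens - 1, 20000)))
  got <- classifyProbes(probes, gr)
  for (i in seq_len(n)) {
    exp <- oracleClassify(GenomicRanges::start(probes)[i],
                          GenomicRanges::end(probes)[i], parts)
    expect_identical(sort(got[[i]]), exp, label = paste("probe", i))
  }
})

test_that("structure mapping follows the 1-nt rule and half-open exclusions", {
  parts <- partsToGRanges(data.frame(
    start = c(101, 401, 901), end = c(400, 900, 1800),
    part = c("five_utr", "intron", "cds")))
  probes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    c(150, 2500), c(350, 2700)))  # utr probe; intergenic probe
  cls <- classifyProbes(probes, parts)

  # structure abutting the intergenic probe start: zero overlap, unmapped
  s0 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2400, 2499),
                               strand = "*")
  # structure overlapping 1 nt of the mapped 5'UTR exon (not the probe)
  s1 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(400, 460),
                               strand = "*")
  mp <- mapStructures(probes, cls, c(s0, s1), parts)
  expect_identical(mp[[1]], 2L)          # via the UTR exon, 1 nt
  expect_identical(mp[[2]], integer(0))  # abutting, no overlap
})

test_that("structure mapping equals the per-base oracle and ignores strand", {
  set.seed(202)
  parts <- randomParts(12, chromLen = 8000)
  gr <- partsToGRanges(parts)
  starts <- sample.int(7500, 120)
  probes <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(starts, starts + sample(30:200, 120, TRUE)))
  sStarts <- sample.int(7800, 150)
  strands <- sample(c("+", "-", "*"), 150, TRUE)
  structures <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(sStarts, sStarts + sample(20:120, 150, TRUE)),
    strand = strands)
  cls <- classifyProbes(probes, gr)
  got <- mapStructures(probes, cls, structures, gr)
  flipped <- structures
  GenomicRanges::strand(flipped) <- ifelse(strands == "+", "-",
                                           ifelse(strands == "-", "+", "*"))
  expect_identical(got, mapStructures(probes, cls, flipped, gr))
  for (i in seq_along(probes)) {
    exp <- which(vapply(seq_along(structures), function(s)
      oracleMapStructure(GenomicRanges::start(probes)[i],
                         GenomicRanges::end(probes)[i], cls[[i]],
                         GenomicRanges::start(structures)[s],
                         GenomicRanges::end(structures)[s], parts),
      logical(1)))
    expect_identical(got[[i]], as.integer(exp), label = paste("probe", i))
  }
})

test_that("coding potential applies the >120-codon and one-third rules", {
  set.seed(7)
  noAtg <- paste(sample(c("C", "G", "U"), 300, TRUE), collapse = "")
  expect_false(codingPotential(noAtg))

  orf <- paste0("AUG", strrep("GCU", 120), "UAA")   # 121 codons, 363+3 nt
  pad <- function(k) paste(sample(c("C", "G"), k, TRUE), collapse = "")
  tx900 <- paste0(pad(300), orf, pad(900 - 300 - nchar(orf)))
  expect_true(codingPotential(tx900))
  tx1200 <- paste0(pad(400), orf, pad(1200 - 400 - nchar(orf)))
  expect_false(codingPotential(tx1200))  # 363/1200 < 1/3

  shortOrf <- paste0("AUG", strrep("GCU", 119), "UAA")  # 120 codons
  tx <- paste0(pad(10), shortOrf, pad(20))
  expect_false(codingPotential(tx))
})

test_that("coding potential matches the regex ORF oracle and is strand-symmetric", {
  set.seed(303)
  for (i in 1:60) {
    s <- randomRna(sample(60:400, 1), gc = runif(1, 0.3, 0.7))
    ours <- codingPotential(s, minCodons = 5L)
    orc <- oracleOrfCodons(s)
    expect_identical(ours, orc > 5 && 3 * orc >= nchar(s) / 3,
                     label = paste("seq", i))
    expect_identical(ours, codingPotential(oracleRevComp(s), minCodons = 5L))
  }
})

test_that("known-RNA annotation uses the reference length as denominator", {
  known <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 1100),
                                  label = "mir-1")
  hit10 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(991, 1010))
  hit9 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(991, 1009))
  expect_identical(annotateKnown(hit10, known)[[1]], "mir-1")
  expect_identical(annotateKnown(hit9, known)[[1]], character(0))

  set.seed(404)
  kStarts <- sample.int(5000, 60)
  known <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(kStarts, kStarts + sample(20:90, 60, TRUE)),
    label = paste0("rna", 1:60))
  pStarts <- sample.int(5000, 200)
  probes <- GenomicRanges::GRanges("chrT",
    IRanges::IRanges(pStarts, pStarts + sample(30:400, 200, TRUE)))
  got <- annotateKnown(probes, known)
  for (i in seq_len(200)) {
    exp <- known$label[vapply(seq_along(known), function(k)
      oracleAnnotateKnown(pStarts[i], GenomicRanges::end(probes)[i],
                          kStarts[k], GenomicRanges::end(known)[k]),
      logical(1))]
    expect_setequal(got[[i]], exp)
  }
})

test_that("relative UTR position is strand-aware", {
  utr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 200))
  mid <- GenomicRanges::GRanges("chrT", IRanges::IRanges(141, 160))
  expect_equal(utrRelativePosition(mid, utr, "+"), 0.5)
  expect_equal(utrRelativePosition(mid, utr, "-"), 0.5)
  # minus-strand UTR [100,200) 0-based; overlap midpoint at genomic 190
  hi <- GenomicRanges::GRanges("chrT", IRanges::IRanges(186, 195))
  expect_equal(utrRelativePosition(hi, utr, "-"), 0.1)
  expect_equal(utrRelativePosition(hi, utr, "+"), 0.9)
  lo <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 110))
  expect_equal(utrRelativePosition(lo, utr, "+"), 0.05)
  away <- GenomicRanges::GRanges("chrT", IRanges::IRanges(300, 310))
  expect_error(utrRelativePosition(away, utr, "+"), "overlap")
})

test_that("analysis sets exclude CDS-only probes and coding ncRNA candidates", {
  cls <- list("three_utr", "cds", c("intergenic"), "intronic",
              c("five_utr", "cds"), character(0))
  coding <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  s <- analysisSets(cls, coding)
  expect_identical(s$utr, c(1L, 5L))
  expect_identical(s$ncrna, 3L)
  expect_identical(s$excluded, c(2L, 4L, 6L))
})
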