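test_that("ontology simulation covers the lattice with nested regions", {
  # degenerate single region
  cfg1 <- syntheticConfig(seed = 1, latticeShape = c(2, 2, 2),
                          nCoarseRegions = 1, nFineRegions = 1,
                          probesPerGroup = c(structured_utr = 2L))
  o1 <- simulateOntology(cfg1)
  expect_equal(unique(as.integer(o1@labels)), 1L)
  expect_equal(length(as.integer(o1@labels)), 8L)

  # full default granularity: exhaustive coverage and nesting
  cfg <- syntheticConfig(seed = 2)
  ont <- simulateOntology(cfg)
  lab <- as.integer(ont@labels)
  expect_equal(length(lab), prod(cfg@latticeShape))
  expect_setequal(unique(lab), 1:115)
  expect_equal(length(ont@coarseOf), 115L)
  expect_setequal(unique(ont@coarseOf), 1:11)
  # nesting: every voxel's coarse label derives from its unique fine label
  expect_equal(length(voxelRegions(ont, "coarse")), prod(cfg@latticeShape))

  # determinism: identical config => identical ontology
  expect_identical(simulateOntology(cfg)@labels, ont@labels)
  expect_identical(simulateOntology(cfg)@coarseOf, ont@coarseOf)

  # impossible partition rejected at configuration time
  expect_error(
    syntheticConfig(seed = 1, latticeShape = c(2, 2, 2),
                    nCoarseRegions = 1, nFineRegions = 9,
                    probesPerGroup = c(structured_utr = 2L)),
    "fewer voxels")
})

test_that("expression simulation applies effect, cliques and noise as documented", {
  # zero effect, zero noise, no cliques: constant baseline volumes
  cfg0 <- syntheticConfig(seed = 3, latticeShape = c(6, 5, 4),
                          nCoarseRegions = 2, nFineRegions = 6,
                          probesPerGroup = c(structured_utr = 3L,
                                             non_structured_utr = 3L),
                          effectSize = 0, noiseSd = 0)
  ve0 <- simulateExpression(cfg0, simulateOntology(cfg0))
  expect_true(all(energyMatrix(ve0) == cfg0@baseline))

  # effect size recovered within 3 standard errors at n = 200/group
  cfg <- syntheticConfig(seed = 4, latticeShape = c(8, 6, 4),
                         nCoarseRegions = 2, nFineRegions = 8)
  ve <- simulateExpression(cfg, simulateOntology(cfg))
  grp <- SummarizedExperiment::rowData(ve)$structuredGroup
  m <- rowMeans(energyMatrix(ve))
  d <- mean(m[grp]) - mean(m[!grp])
  se <- sqrt(var(m[grp]) / sum(grp) + var(m[!grp]) / sum(!grp))
  expect_lt(abs(d - 2), 3 * se)

  # planted clique correlations
  cfgC <- syntheticConfig(seed = 5, latticeShape = c(8, 6, 4),
                          nCoarseRegions = 2, nFineRegions = 8,
                          probesPerGroup = c(structured_utr = 10L,
                                             non_structured_utr = 10L),
                          cliqueSpec = list(c(5, 0.95)))
  veC <- simulateExpression(cfgC, simulateOntology(cfgC))
  e <- energyMatrix(veC)
  cc <- cor(t(e))
  within <- cc[1:5, 1:5][upper.tri(diag(5))]
  expect_true(all(within > 0.8))
  expect_lt(max(abs(cc[1:5, 8:20])), 0.4)

  # expressed flag honours the threshold
  expect_true(all(SummarizedExperiment::rowData(ve)$expressed))
  cfgLo <- syntheticConfig(seed = 6, latticeShape = c(6, 5, 4),
                           nCoarseRegions = 2, nFineRegions = 6,
                           probesPerGroup = c(structured_utr = 4L,
                                              non_structured_utr = 4L),
                           baseline = 0, effectSize = 3, noiseSd = 0.01)
  veLo <- simulateExpression(cfgLo, simulateOntology(cfgLo))
  expressed <- SummarizedExperiment::rowData(veLo)$expressed
  expect_true(all(expressed ==
    SummarizedExperiment::rowData(veLo)$structuredGroup))

  # determinism
  expect_identical(energyMatrix(simulateExpression(cfgC, simulateOntology(cfgC))),
                   energyMatrix(veC))
})

test_that("genome simulation plants classifiable probes with exact truth", {
  cfg <- syntheticConfig(seed = 7, nGenes = 25L, genomeLength = 200000L)
  g <- simulateGenome(cfg)
  expect_setequal(unique(g$truth$class),
                  c("three_utr", "five_utr", "intronic", "intergenic", "cds"))
  cl <- classifyProbes(g$probes, g$geneParts)
  for (i in seq_along(cl)) {
    expect_true(g$truth$class[i] %in%
      c(cl[[i]], if (g$truth$class[i] == "intronic") "intronic"),
      label = paste("probe", i))
  }
  got <- vapply(cl, paste, character(1), collapse = ",")
  expect_identical(unname(got), g$truth$class)
  mp <- mapStructures(g$probes, cl, g$structures, g$geneParts)
  expect_identical(unname(lengths(mp) > 0), g$truth$structured)
  # classification counts see every category
  cc <- classificationCounts(cl, lengths(mp) > 0)
  expect_true(all(cc["total", ] > 0))
  # capacity guard
  tiny <- syntheticConfig(seed = 1, genomeLength = 5000L, nGenes = 10L)
  expect_error(simulateGenome(tiny), "too small")
})

test_that("interaction-pair simulation plants reverse-complement sites", {
  cfg <- syntheticConfig(seed = 8)
  ip <- simulateInteractionPairs(cfg, nPairs = 10, plantedFrac = 0.4,
                                 seqLength = 80)
  expect_equal(sum(ip$truth$planted), 4)
  rc <- function(s) paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]),
                          collapse = "")
  for (i in which(ip$truth$planted)) {
    site <- substr(ip$queries[i], ip$truth$queryStart[i],
                   ip$truth$queryStart[i] + 14)
    expect_identical(
      unname(substr(ip$targets[i], ip$truth$targetStart[i],
                    ip$truth$targetStart[i] + 14)), unname(rc(site)))
    # pure-GC planted site: toy-model MFE of the site alone is -3 * 15
    expect_equal(duplexMfe(site, rc(site))$mfe, -45)
  }
  expect_true(all(is.na(ip$truth$queryStart[!ip$truth$planted])))
  expect_error(simulateInteractionPairs(cfg, seqLength = 10), "longer")
  # determinism
  ip2 <- simulateInteractionPairs(cfg, nPairs = 10, plantedFrac = 0.4,
                                  seqLength = 80)
  expect_identical(ip, ip2)
})

test_that("generated artefacts round-trip through their file formats", {
  cfg <- syntheticConfig(seed = 9, latticeShape = c(5, 4, 3),
                         nCoarseRegions = 2, nFineRegions = 5,
                         probesPerGroup = c(structured_utr = 3L,
                                            non_structured_utr = 3L),
                         nGenes = 5L, genomeLength = 30000L)
  ont <- simulateOntology(cfg)
  tf <- tempfile(fileext = ".json")
  writeOntology(ont, tf)
  back <- readOntology(tf)
  expect_identical(back@labels, ont@labels)
  expect_identical(back@coarseOf, ont@coarseOf)

  g <- simulateGenome(cfg)
  fa <- tempfile(fileext = ".fa")
  writeFasta(g$transcripts, fa)
  expect_identical(readFasta(fa), g$transcripts)

  bed <- tempfile(fileext = ".bed")
  writeBed(g$probes, bed)
  back <- readBed(bed)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(g$probes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(g$probes))
})
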