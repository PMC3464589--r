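# StructExpr

Spatial expression analysis of RNA-structure-annotated transcripts in a
voxelized 3-D brain atlas.

## The problem

Large in situ hybridization atlases quantify where each transcript is
expressed in the adult brain as *expression energy* — the per-voxel
product of ISH signal intensity and the density of expressing cells — on
a lattice of 200 µm voxels organised into a nested neuroanatomical
ontology (11 coarse regions subdivided into 115 fine regions). Genome
screens for conserved RNA secondary structure independently annotate
probes as "structured" (overlapping a predicted structure) or not. The
scientific question is whether structured transcripts — putative ncRNAs
and mRNAs with structured UTRs — form a spatially and statistically
distinct population: higher regional expression, higher spatial
divergence, coherent co-expression modules, RNA-binding-protein motifs
near their UTR structures, and statistically significant RNA–RNA
interaction sites.

StructExpr implements that whole analysis as a tested, reusable
Bioconductor-style pipeline, together with a synthetic atlas generator
that produces every input with known ground truth, so each stage is
verifiable without any external data.

## What it computes

* **Probe classification** (`classifyProbes`, `mapStructures`,
  `annotateKnown`, `codingPotential`): probes are mapped to gene parts
  when they overlap a 5'UTR/CDS/3'UTR exon by ≥ 10 % of the probe
  length; probes with no exonic contact are intergenic/intronic;
  strandless structure predictions map to a probe via ≥ 1 nt overlap
  with the probe (intergenic) or any gene part touching it; a transcript
  has coding potential when an ORF of > 120 codons covers ≥ 1/3 of its
  length; known-RNA labels require covering ≥ 10 % of the reference.
* **Spatial statistics** (`regionMean`, `spatialEnrichment`,
  `spatialDivergence`): region means of expression energy *E*; the
  spatial-enrichment score

      [ v_d(E ≥ 2) / v_d ] / [ v_b(E ≥ 2) / v_b ]

  (fraction of domain voxels above threshold over the brain-wide
  fraction; > 1 flags high spatial expression); and the standard
  deviation of the 115 fine-region means as spatial divergence.
* **Robust group comparison** (`trimmedMean`, `percentileTBootstrap`,
  `regionSweep`): per-region two-sample tests of 20 %-trimmed means via
  the percentile-t bootstrap of the Yuen-studentized statistic,
  Benjamini–Hochberg adjusted across regions, significant at adjusted
  p < 0.25; `fisherExact2x2`/`categoryEnrichment` for category counts.
* **Correlation networks** (`correlatePairs`, `selectThreshold`,
  `buildNetwork`, `detectModules`): Pearson ρ of voxel vectors per
  domain, a survivor-fraction rule that formalises choosing ρ_T on the
  flattened right end of the pair-frequency curve, graphs with strict
  ρ > ρ_T edges plus components and maximal cliques, and
  average-linkage modules on the 1 − ρ distance between region
  profiles with per-module focal regions.
* **RNA–RNA interactions** (`dinucShuffle`, `duplexMfe`,
  `buildBackground`, `binAndFit`, `interactionPvalue`, `filterHits`):
  minimum-free-energy duplex sites under a pluggable pair-additive
  energy model with bulge penalties and optional accessibility
  profiles; Eulerian-path dinucleotide shuffling; per (site length ×
  GC) bin censored maximum-likelihood Gumbel fits
  (P(S ≤ s) = 1 − exp(−e^{λ(s−μ)}), right-censored at −10 kcal/mol, 49
  bins); p-values from that law; reporting filters > 9 nt, < −40
  kcal/mol, p < 1e−5.
* **Motifs** (`extractFlanked`, `pwmScan`, `motifEnrichment`): PWM
  log-odds scans of UTR structures ± 50 nt and shuffle-based enrichment.
* **Synthetic atlas** (`syntheticConfig`, `simulateAtlas`,
  `runPipeline`): nested region ontologies, probe volumes with planted
  group effects and correlated cliques, synthetic gene models with
  planted probe classes and structures, and interaction pairs with
  planted reverse-complement sites — all deterministic given a seed.

## Worked example

```r
library(StructExpr)

cfg <- syntheticConfig(seed = 42, cliqueSpec = list(c(5, 0.95)))
ont <- simulateOntology(cfg)
ve  <- simulateExpression(cfg, ont)
ve
#> VoxelExperiment: 400 probes x 24000 voxels

prof <- regionProfile(ve, "coarse")
grp  <- SummarizedExperiment::rowData(ve)$structuredGroup
sw   <- regionSweep(prof[grp, ], prof[!grp, ], B = 1000, seed = 43)
head(sw, 4)
#>      region  nA  nB statistic estimate p pAdj significant direction
#> 1 coarse_01 200 200       862        2 0    0        TRUE       A>B
#> 2 coarse_02 200 200       943        2 0    0        TRUE       A>B
#> 3 coarse_03 200 200      1006        2 0    0        TRUE       A>B
#> 4 coarse_04 200 200       881        2 0    0        TRUE       A>B
sum(sw$significant)
#> [1] 11

net <- buildNetwork(correlatePairs(ve, "brain"), rhoT = 0.8)
net$cliques[[1]]
#> [1] "probe_0001" "probe_0002" "probe_0003" "probe_0004" "probe_0005"
```

The structured group was simulated with a +2 mean energy shift, and the
sweep recovers it in all 11 coarse regions with adjusted p below 0.25
and direction `A>B` (structured > non-structured); the five-probe
planted clique (pattern strength 0.95) comes back as a maximal clique
at ρ > 0.8. `runPipeline(cfg, outdir = "out")` runs every stage —
simulate, annotate, expression stats, region sweep, correlation,
modules, interaction scan — and writes tidy TSV/JSON outputs plus a
manifest of seeds and counts.

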