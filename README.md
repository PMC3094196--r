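# immunoGrade

Quantify how relevant every gene is to immunity (or any other context)
from literature co-citation counts, and use that score to benchmark
curated immune gene resources, analyse protein-interaction networks,
and grade the immune component of tumour expression profiles.

## Who this is for

Computational biologists working on tumour immunology who need a
*ranked, genome-wide* notion of "immune gene" rather than a flat curated
list — for benchmarking gene-set resources, for annotating interactome
analyses, or for stratifying patient cohorts by the immunological
content of their expression profiles.

## The score

The input is a gene × term table of **co-citations**: joint mentions of
a gene and a GO/MeSH vocabulary term in article titles/abstracts,
together with a curated dictionary of context terms (e.g. immune terms).
For gene *x* and context term *i*:

```
p_i = g_i / iT_g          (gene's share of the term's co-citations)
q   = g_T / GS_T          (gene's overall literature popularity)

H(x)  = − Σ_i p_i log2 p_i            Shannon information, bits
KL(x) = Σ_i p_i log2 (p_i / q)        popularity-corrected relevance, bits
```

`H` measures the size of the gene's contextual message; `KL` corrects
for the bias that heavily studied genes co-occur with everything. Genes
are ranked by descending `KL` (ties by symbol). On top of the score sit
three layers: curated gene-set benchmarking
(`overlapDistribution`, `meanRelevanceBySet`, `noncuratedCandidates`),
interactome analysis (`buildInteractome`, `centralityProfile`,
`clusterTissues`, `compareToRandom`, `landscapeSurface`) and expression
grading (`quantileNormalize`, `detectionFilter`, `foldChangeDE`,
`compositeGeneScore`, `patientScore`, `phenotypeAssociation`).
Seeded generators (`simulateCocitationCorpus`, `simulateInteractome`,
`simulateExpressionCohort`) produce every input with planted ground
truth.

## Worked example

Score a synthetic corpus with 50 planted immune-enriched genes among
1000, benchmark two curated sets against the score, then grade a
40-patient cohort in which the top-100 relevance genes are upregulated
in one group:

```r
library(immunoGrade)

sim <- simulateCocitationCorpus(nGenes = 1000, nPlanted = 50, seed = 1)
rel <- scoreGenome(sim$table, sim$dictionary)
head(relevanceScores(rel), 5)
#>    gene shannon_bits   kl_bits rank never_cocited
#> 1 G0191     3.986396 1.4254372    1         FALSE
#> 2 G0426     3.691935 1.2990500    2         FALSE
#> 3 G0615     2.904529 1.2169908    3         FALSE
#> 4 G0829     2.654906 1.1160825    4         FALSE
#> 5 G0117     1.488618 0.6300632    5         FALSE

rocAuc(klBits(rel), sim$planted)
#> [1] 0.98976

gc <- GeneSetCollection(list(curatedA = sim$planted[1:30],
                             curatedB = sim$planted[15:40]))
meanRelevanceBySet(gc, rel)
#>           set n_genes mean_kl_bits
#> 1    curatedA      30    0.4419064
#> 2    curatedB      26    0.4198288
#> 3        core      16    0.4176526
#> 4 non_curated     960    0.1032349

co <- simulateExpressionCohort(rel, nPerGroup = c(20, 20),
                               effectSize = 1, nTop = 100, seed = 1)
st <- detectionFilter(quantileNormalize(co$study))
#> detection filter: keeping 708 of 1000 genes (detected at p < 0.01
#> in more than 36 samples)
wp <- patientScore(compositeGeneScore(st, rel))
phenotypeAssociation(wp, conditionLabels(st), nDraws = 10000, seed = 1)
#> $statistic   18.42...     # mean W_p difference, group B − group A
#> $p.raw       0            # no permutation beat the observed split
#> $p.smoothed  1e-04        # (k+1)/(n+1) with 10,000 draws
#> $direction   "up_in_groupB"
```

Reading the numbers: the planted genes occupy the top of the KL ranking
(AUROC 0.99); curated sets average ~0.43 bits against ~0.10 for
non-curated genes, the score recovering the curation; and the patient
immune grade `W_p` — the sum over genes of log2 expression change
weighted by relevance — separates the affected group with a permutation
p of 1e-04 in the expected direction.

A command-line front end with the same pipeline is installed as
`exec/immunograde` (subcommands `simulate`, `score`, `network`,
`grade`); each run writes a `run_manifest.json` with the configuration,
seed and input checksums.

## Acceptance script

`scripts/acceptance.R` re-runs the main computation from scratch on
seeded synthetic data — corpus scoring with planted-signal recovery,
interactome centralities and landscape, and cohort grading with the
permutation phenotype test — and writes its result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                  implementation (S4 classes + methods)
tests/testthat/     unit, property and acceptance tests (with
                    independent brute-force oracles in helper-oracles.R)
exec/immunograde    command-line entry point
scripts/acceptance.R
vignettes/          methods vignette: model, conventions, generator
                    design, limitations
```
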