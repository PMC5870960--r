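---
title: "Codon usage bias: methods and conventions in codonBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias: methods and conventions in codonBias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonBias)
```

## The problem

Most amino acids are encoded by several synonymous codons, and genomes use
these synonyms unevenly. The strength and direction of this synonymous codon
usage bias (CUB) carries information about directional mutation pressure
(e.g. genome-wide AT richness), translational selection (preference for
codons matching abundant tRNAs, strongest in highly expressed genes), and
their balance. `codonBias` implements the classical index battery used to
dissect these forces in nuclear genomes — composition indices, RSCU, ENC and
the ENC-plot, PR2-bias, P2, optimal-codon detection — together with
cross-genome comparison machinery and a generative simulator that provides
ground truth for every stage.

All statistics are computed from a single container, `CodonCounts` (a
`SummarizedExperiment` of in-frame codon counts, 64 codons × genes), built
by `countCodons()` from validated CDS. Stop codons are excluded from every
index (a terminal stop occurs once per CDS and carries no usage signal;
`countCodons()` drops it at tally time), and the single-codon amino acids
Met and Trp are excluded from all synonymous-usage statistics. This leaves
the familiar 59 synonymous codons of the standard nuclear code.

## Definitions and conventions

**RSCU.** For codon $c$ of an amino acid with family size $k$ and observed
family total $n$, $\mathrm{RSCU}(c) = k\,\mathrm{obs}(c)/n$. Values sum to
$k$ within each used family; a family with zero usage yields *undefined*
(`NA`) entries, never zero — a short gene that happens to lack histidine
tells us nothing about its histidine codon preference.

**ENC.** Wright-style effective number of codons. Within each family with
usage $n \ge 2$, codon homozygosity is estimated as
$F = (n\sum_i p_i^2 - 1)/(n-1)$; $F$ is averaged within each degeneracy
class $k \in \{2,3,4,6\}$ and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Conventions, chosen where tools differ and exposed via
`enc(..., details = TRUE)`:

* Six-fold families (Leu, Ser, Arg) are single six-membered families, not
  2+4 splits — consistent with the RSCU multiplier and the class-6 term.
* A family with $n < 2$ contributes no $F$. If the three-fold class (Ile
  alone) is empty, $\bar F_3$ is imputed as $(\bar F_2 + \bar F_4)/2$, a
  standard fallback; if a two-, four- or six-fold class is empty, or a class
  mean is exactly 0 (possible in tiny perfectly balanced samples), ENC is
  returned `NA` with a reason rather than a fabricated number.
* Finite-sample estimates above 61 are reported as 61, preserving the
  index's defining range $[20, 61]$; 20 is attained exactly when one codon
  per amino acid carries all usage, 61 under even synonymous usage.

**Composition indices.** X3s (X ∈ {A, T, G, C}) uses the CodonW
"family-potential" denominator: codons of families offering at least one
X-ending synonym. The four denominators differ, so X3s values routinely sum
to more than 1 — they are propensities, not a composition vector. GC3s by
contrast uses all 59 synonymous codons as denominator, and GC1/GC2/GC3/GC12
are plain positional G+C fractions over all sense codons (Cusp-style); GC3
and GC3s are therefore related but distinct, and both are reported.

**Pooled vs averaged.** Genome-level tables can be computed two ways: from
pooled counts (`compositionProfile(pooledCounts(x))` — long genes weigh
more) or as unweighted means of per-gene profiles (`colMeans` over
`indexTable()` columns). These differ, sometimes visibly (a pooled ENC of
~54 can coexist with a gene-mean ENC of ~52). Both are exposed; pooled
values feed genome summary tables, per-gene values feed distributions,
multiple comparisons and correlations.

**PR2 and P2.** PR2 coordinates are $x = G3s/(G3s+C3s)$,
$y = A3s/(A3s+T3s)$; a coordinate with zero pair sum is `NA`. P2 sums RSCU
over the eight codon pairs whose first two bases are both weak (A/T) or
both strong (G/C) and whose family contains both the C- and the T-ending
synonym: AAC/AAT (Asn), ATC/ATT (Ile), TAC/TAT (Tyr), TTC/TTT (Phe),
CCC/CCT (Pro), CGC/CGT (Arg), GCC/GCT (Ala), GGC/GGT (Gly). The membership
is derived from the code table at run time (`p2Index()$codonPairs`), since
published analyses rarely print the list; one P2 is reported per gene set,
from pooled RSCU.

**Optimal codons.** Genes are ranked by ENC; the lowest 5% form the
high-bias dataset (low ENC = strong bias, the usual proxy for high
expression) and the highest 5% the low-bias dataset (`partitionByEnc()`,
ties broken by gene id for determinism). ΔRSCU is the difference of
*dataset-pooled* RSCU values — genome reports print one High/Low value per
codon — while the significance test is a two-sample Welch t-test on
*per-gene* RSCU values, the unit of replication. Unequal variances are the
safe default for tail datasets of different dispersion. The flag rule is
ΔRSCU ≥ 0.08 (inclusive) and two-sided $P < 0.01$ with
$\mathrm{RSCU_{high}} > \mathrm{RSCU_{low}}$; no multiplicity correction is
applied (the historical rule), and raw p-values are reported so users can
apply their own. The 5% is read as a fraction of *genes*, not codons.

**Correlations, Duncan letters, clustering.** Index correlations are
Pearson product-moment with pairwise-complete observations (undefined
per-gene indices dropped pair by pair); pairs with fewer than 5 complete
observations trigger a small-sample warning — whole-genome correlations over
4–8 genomes are supported but intrinsically fragile. `anovaDuncan()` fits a
one-way ANOVA and applies Duncan's multiple range test: means sorted
descending, span-$p$ ranges compared against
$R_p = q_{1-\alpha_p}(p, \nu)\sqrt{\mathrm{MSE}/n_h}$ with Duncan's
protection level $\alpha_p = 1-(1-\alpha)^{p-1}$, $n_h$ the harmonic mean
group size, and the stepwise protocol (an insignificant span protects its
sub-spans) feeding the standard letter sweep. With two groups this reduces
exactly to the pooled-variance t-test, which the test suite checks.
`rscuCluster()` performs agglomerative clustering of labelled RSCU vectors,
Euclidean distance with average linkage by default (the typical HCA-tool
default; both are configurable since published pipelines rarely state
them). Undefined RSCU entries are imputed at 1 — the no-bias value, the
least informative completion. Labels are sorted before clustering so the
tree and its Newick serialisation are invariant under input order.

## The simulator

`generateCdsSet()` draws equilibrium snapshots from an explicit
mutation–selection model. Per gene: a length (gamma with mean
`lengthMean` = 360 codons — a typical plant nuclear CDS — and CV
`lengthCv` = 0.3, floored at 10); per codon: an amino acid from
`aaFrequencies` (default uniform over the 18 multi-codon amino acids,
isolating synonymous effects from amino-acid composition), then

* with probability $s_g$ (`selectionStrength`, per gene, default 0): the
  family's designated preferred codon — translational selection as
  probabilistic replacement, a single interpretable knob;
* otherwise: a family codon weighted by the mutational probability of its
  third base (`mutationThirdBaseProbs`, default uniform), renormalised
  within the family. Under uniform third-base probabilities every family is
  used uniformly, so the neutral limit reproduces RSCU = 1, ENC near 61 and
  genes on the expected-ENC curve; under GC-biased probabilities the
  neutral stratum's GC3s tracks the mutational G+C setting.

An ATG start and a uniform random stop flank the body. The default
preferred-codon set is the alphabetically first T-ending codon per family
(A-ending for Lys/Gln/Glu, which lack T-ending synonyms), mirroring the
T/A-ending optimal codons of AT-rich plant genomes. Output is deterministic
given `seed`, and the caller's RNG state is restored.

What the generator does *not* emulate: amino-acid composition differences
between genes, position effects along the CDS, isochore/length
correlations, mutation–selection–drift dynamics over generations, or any
dependence between neighbouring codons. Passing recovery tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to every property of real genomes.

## Verification strategy and problem sizes

Every index (ENC, RSCU, X3s/GC3s, GC, P2) is tested against an independent
brute-force oracle that walks the plain codon table with explicit loops, on
batches of random count tables (agreement to 1e-9 on 100 tables). Model
properties are tested at simulation scales chosen to keep the full suite
under ~20 s while leaving comfortable statistical margins: 200 neutral
genes of 1,000 codons for the expected-ENC band (mean absolute deviation
< 2 ENC units), 400 genes with 50 selected at $s_g = 0.8$ for
optimal-codon recovery (≥ 90% of the 18 designated codons, no family-level
false positives), 200 genes per stratum for ENC monotonicity across
$s_g \in \{0, 0.4, 0.8\}$, and 400 replicates for the Duncan type-I
probe.

## Known limitations

* ENC-tail selection of gene datasets induces mild selection bias even under
  the null; with ΔRSCU relaxed to 0 a handful of codons can reach $P < 0.01$
  by chance. The 0.08 ΔRSCU floor is what keeps the published rule
  conservative.
* X3s denominators make cross-base comparisons of X3s values subtle; use
  GC3s or the PR2 coordinates for composition summaries.
* P2's codon membership follows the both-pyrimidine-endings reading of the
  weak/strong prefix rule; tools that include additional NNC/NNU codons will
  give slightly different aggregates.
* The cap at ENC = 61 makes the index uninformative between "unbiased" and
  "slightly over-dispersed" usage in short genes.
* Duncan's MRT controls comparisonwise, not familywise, error — that is the
  method's definition, not an implementation choice.
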