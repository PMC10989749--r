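---
title: "Methods and design of the ampliflow pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the ampliflow pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliflow)
```

ampliflow is a scriptable, fully seeded re-implementation of the classic
marker-gene (16S rRNA amplicon) analysis workflow: read assignment against a
reference database, copy-number-corrected taxonomic profiles, predicted
KEGG-Orthology (KO) function with a prediction-reliability index, alpha and
beta diversity with permutation statistics, biomarker selection, and
co-occurrence networks, orchestrated by a deterministic parallel scheduler
and rendered into a static HTML viewer. This vignette explains the models
and the design decisions; the README shows a worked run.

## The reference pack

Every stage reads from one *reference pack*: a rooted phylogeny with branch
lengths, a 7-rank lineage string per leaf (`k__;p__;...;s__`), 16S gene copy
numbers, per-taxon KO gene counts, a 3-level pathway hierarchy above the
KOs, per-taxon distances to the nearest sequenced relative, and
representative sequences. Real database builds (GreenGenes/SILVA scale) are
out of scope; the pack interface is small and text-based, and
`simulate_reference_pack()` generates statistically reasonable packs for
development and testing.

## Read assignment

Reads are matched to representative sequences by cosine similarity of
8-mer count vectors, computed for both strands, which is fast and
alignment-free. Because a single substitution in a 200-bp read disturbs
about $k$ of its $k$-mers, the cosine $c$ understates sequence identity by
roughly a factor $k$; we therefore report the identity estimate
$\hat{\imath} = 1 - (1-c)/k$ and apply the classical 97% OTU-radius
threshold on that scale. Reads tied between several references (identical
best score) are assigned to the lowest taxonomic rank the tied leaves
share, and their count is split equally among the tied leaves — the
taxonomy stays honest at the rank the data can actually resolve. A
precomputed `read_id<TAB>leaf_id<TAB>identity` table can be imported
instead (`read_assignments()`), so external aligners slot in unchanged.
ASV denoising and chimera removal are deliberately not implemented; the
profiling entry point is a no-op-compatible hook for pre-cleaned reads.

With defaults ($k = 8$, 200-bp references, per-base error 0.5%), read-level
assignment accuracy on simulated 16-taxon packs is above 95% (measured by
`scripts/acceptance.R`).

## Copy-number correction and level collapsing

A taxon with four 16S copies yields four times the reads per organism, so
counts are divided by the pack's copy numbers before normalization:
$a_i = (n_i / c_i) / \sum_j (n_j / c_j)$. Correction is scale-invariant and
reduces to plain relative counts when all copy numbers are one. Collapsing
to a taxonomy level sums leaf abundances over shared lineage prefixes;
leaves with an empty rank (`g__`) pool into `Unclassified_<parent>`, so
mass is conserved at every level.

## Functional prediction and NSTI

KO abundance is predicted as the copy-number-weighted sum of the reference
taxa's KO gene counts, $KO_k \propto \sum_i w_i \cdot g_{ik}$ with
$w_i = n_i / c_i$ — integer gene counts, not presence/absence, so predicted
magnitudes are meaningful. The Nearest Sequenced Taxon Index is the
abundance-weighted mean of each taxon's phylogenetic distance to its
nearest sequenced relative, $\mathrm{NSTI} = \sum_i a_i d_i$; since the
$a_i$ sum to one this weighted form is bounded by the largest $d_i$ and
equals a pure sample's own distance. We use the weighted-mean form (the
original definition of the index) rather than an unnormalized sum, which
would grow with community richness rather than prediction difficulty.
Pathway profiles aggregate KOs through the 3-level hierarchy; a KO with
several hierarchy paths splits its mass equally across them, and KOs
missing from the hierarchy pool under `Unannotated`, so mass is conserved.

## Alpha diversity

Shannon ($H = -\sum p_i \ln p_i$, natural log), Gini–Simpson
($D = 1 - \sum p_i^2$) and bias-corrected Chao1
($S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))$). Chao1 models unseen taxa from
singleton/doubleton counts, which only makes sense on raw sampling counts —
the function rejects relative abundances, and the pipeline feeds it
uncorrected classified-read counts while Shannon/Simpson use the
copy-number-corrected profile.

Association with discrete metadata uses the two-sided Mann–Whitney rank-sum
test (exact by full enumeration of rank splits when both groups have at
most 8 samples — the enumeration handles ties through mid-ranks, which the
standard exact algorithm cannot — otherwise the tie- and
continuity-corrected normal approximation) or Kruskal–Wallis for more than
two groups. Numeric metadata gets ordinary least squares with a two-sided
t-test on the slope. Missing metadata is dropped pairwise per test, with
the drop count reported.

## Beta diversity

The taxonomic distance matches abundance mass bottom-up along the
reference tree. At each leaf the shared mass $\min(a_i, b_i)$ is credited
to similarity; residuals propagate to the parent attenuated by
$e^{-\ell}$ for branch length $\ell$, are matched again where lineages
meet, and mass that passes the root unmatched is lost. The distance is
$1 - S \in [0, 1]$: identical communities score 0, communities confined to
distant clades approach 1, and sibling taxa separated by zero-length
branches are indistinguishable. The *weighted* flavour uses
copy-number-corrected abundances; the *unweighted* flavour puts mass $1/n$
on each present leaf, making it invariant to abundance rescaling. The
functional distance runs the same recursion on the 4-level pathway
hierarchy (root–L1–L2–L3–KO) with a fixed attenuation of 0.5 per edge,
since hierarchy edges carry no lengths; 0.5 makes each extra level of
disagreement halve the recoverable similarity, giving the hand-checkable
anchors 0.5 (shared L3) and $1 - 0.5^4 = 0.9375$ (shared root only).
These two constants — $e^{-\ell}$ and 0.5/level — are this package's
declared choices; the contracts the tests enforce are the metric
properties, not the constants.

Ordination uses classical scaling (Gower double-centering
$B = -\tfrac12 J D^2 J$, eigendecomposition, coordinates
$v_i\sqrt{\lambda_i}$ over positive eigenvalues) and mean-centered,
unscaled PCA via SVD; on Euclidean distance matrices the two agree
to machine precision, which the tests exploit. Axis signs are fixed by
making each axis's largest-magnitude loading positive, so outputs are
reproducible.

Group structure is tested with PERMANOVA
($F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(N-g)}$ on squared distances) and
ANOSIM ($R = (\bar r_B - \bar r_W)/(M/2)$ on mid-ranked distances);
numeric variables with pairwise regression of $d_{ij}$ on $|x_i - x_j|$
and a Mantel-style permutation of sample labels. All permutation p-values
use the add-one convention $(b+1)/(m+1)$ with 999 permutations by default
and a mandatory seed.

## Biomarkers

Features below 10% prevalence are removed (rank tests on near-constant
sparse taxa are uninformative), each survivor is tested with the same
rank-sum machinery as alpha diversity, p-values are Benjamini–Hochberg
corrected, and features with $q \le 0.05$ proceed to a Random-Forest
classifier (500 trees, fixed seed) whose out-of-bag permutation importance
— mean decrease in accuracy — ranks them. The OOB error rate is reported as
the model's internal cross-validation estimate. Screening before the
forest keeps the model small and the importances interpretable; the order
(screen, then forest) is this package's choice. Numeric variables use a
Spearman screen with BH correction, ranked by $|\rho|$.

## Co-occurrence networks

Edges are Spearman correlations between features (mid-rank ties, t
approximation for p, BH across all pairs) passing $|\rho| \ge 0.6$ and
$q \le 0.05$, over features with at least 20% prevalence; constant
features have no rank variance and are excluded. Isolated nodes are kept.
Summary statistics: density $2E/(V(V-1))$ over all nodes; diameter and
radius as extreme unweighted eccentricities on the largest connected
component (finite by construction); Freeman degree centralization
$\sum_i (d_{max} - d_i)/((V-1)(V-2))$, which is 1 for a star and 0 for any
regular graph. The thresholds and the centralization variant are declared
package choices.

## The synthetic cohort model

`simulate_reference_pack()` grows a bifurcating tree by successive random
pair joins (branch lengths Exponential, mean 0.1), derives nested
taxonomy labels from root-to-leaf ancestor paths, draws copy numbers
uniformly from 1–10, KO gene counts Poisson(2) over a 2/4/8-label 3-level
hierarchy, nearest-relative distances Exponential(mean 0.03), and evolves
200-bp representative sequences down the tree with per-base substitution
probability proportional to branch length.

`simulate_cohort()` is a Dirichlet–multinomial: each sample's proportions
are drawn from a symmetric Dirichlet(0.5) and counts from a Multinomial at
10,000 reads per sample by default. The Dirichlet draw per *sample* is the
important property: between-sample biological overdispersion dominates
counting noise, as in real cohorts. Group B multiplies the effect taxa's
Dirichlet weights by the fold change (proportions renormalize by
construction). Because abundances are compositional, planting a fold
change necessarily deflects every other taxon slightly; with per-sample
overdispersion this bleed stays well below the planted signal, which is
what makes recovery experiments meaningful. The cohort metadata includes a
numeric covariate drawn independently of the communities, so
numeric-association tests have a true null to be calibrated against.
`simulate_reads()` turns counts into per-sample FASTA files (i.i.d.
substitutions at the chosen error rate) plus the `seqs.list`/`meta.txt`
dialects the readers expect.

What the generator does *not* emulate: chimeras, length variation,
quality-score structure, phylogenetically correlated gene content, or
realistic database scale. Passing tests therefore demonstrate correctness
of the algorithms under a clean, well-specified model — not performance on
real sequencing artifacts.

## Calibration and recovery studies

The test suite and `scripts/acceptance.R` run two simulation studies, with
sizes chosen to be informative at desk scale:

* **Null calibration** — 500 replicate cohorts with no planted effect
  (32-taxon pack, 15 samples per group, 10,000 reads per sample, 199
  permutations per test so the 0.05 level is exactly attainable at
  granularity 1/200). The rejection rates of PERMANOVA, ANOSIM, the alpha
  rank-sum test and the per-feature screen must all lie in [0.03, 0.07]
  at the 0.05 level.
* **Recovery** — 10 cohorts with a fold change of 8 planted on 5 taxa
  (30 samples per group). The screen must retain at least 4 of 5 planted
  taxa, and the *strongest* planted taxon — the one with the largest
  rank separability $|AUC - \tfrac12|$ between groups, i.e. the strongest
  signal on the scale the rank tests and the forest actually use — must
  appear in the forest's top 3 importances in at least 8 of 10 seeds with
  OOB error at most 0.1.

## Scheduling and determinism

`schedule()` executes a declared task graph (cycle-checked with Kahn's
algorithm) with dynamic dispatch over forked workers: the next ready task
goes to the next free worker, failures cancel only their dependents. Every
task is a pure function of its declared inputs — stages communicate
exclusively through files under the output directory — and every random
step derives its seed from the pipeline seed, never from scheduling, so
all result tables are byte-identical for any thread count, which the test
suite asserts by hashing two full runs. The per-stage file protocol also
yields the emitted `script.sh`: a step-by-step shell script that re-runs
any stage stand-alone against the same output directory.

Numerical conventions worth knowing: reductions run in fixed manifest
order (floating-point sums are order-stable); tables are written with 8
significant digits so relative rows still re-sum to 1 within $10^{-6}$
after a round trip; empty samples (no classified reads) are kept, flagged,
and score distance 1 to non-empty samples and 0 (flagged degenerate) to
each other; eigenvalues below $10^{-10}$ of the spectral radius are
treated as zero in ordination.

## Known limitations

The k-mer matcher is a deliberately simple stand-in for a full aligner and
is not suitable for real reference databases; the import path for external
assignments is the production route. Chao1 on tie-split fractional counts
rounds to integers. The HTML viewer embeds static PNG figures only. The
scheduler's parallel speedup requires a fork-capable OS and really
available cores; its *correctness* contract (identical outputs) holds
everywhere, and that is the property the tests enforce.
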