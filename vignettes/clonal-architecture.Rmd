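---
title: "Reconstructing clonal architecture from single-cell amplicon resequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal architecture from single-cell amplicon resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

## The problem

A tumor is a mosaic of clones: cell populations that share a set of somatic
mutations inherited from a common ancestor. Bulk sequencing averages over
that mosaic; single-cell sequencing can segregate each mutation into the
cells that carry it, at the cost of the noise introduced by whole-genome
amplification of a single DNA molecule. clonotrace implements the
computational half of a design in which all bulk-confirmed variants — both
single-nucleotide variants (SNVs) and structural-variant (SV) breakpoints —
are genotyped in every amplified single cell by targeted amplicon
resequencing, and the resulting binary cell-by-mutation matrix is used to
infer the clonal populations and their genealogy.

The key idea for SVs is that a rearrangement creates a *novel junction
sequence* at the point where two genomic segments join. A short window
spanning that junction (30 nt here) occurs in a read if and only if the read
crosses the breakpoint, so SVs of every class and size — deletions,
insertions, inversions, translocations — can be genotyped by exact substring
matching in the raw reads, without alignment and without relying on read
depth. SNVs and SVs then enter the same binary matrix as equivalent
markers of clonal identity.

## Genotyping rules and quality control

All thresholds are fixed, auditable rules applied to read counts; they are
exposed as configuration but their defaults are the package's operating
point:

| stage | rule | default |
|---|---|---|
| SV presence | exactly-matching reads strictly greater than `min_reads` | 40 |
| SNV presence | variant reads at least `min_alt_reads` **and** variant fraction strictly above `min_vaf` of all reads at the position | 3 reads, 1% |
| cell QC | visually confirmed single cell **and** at least `min_fraction` of target SNV sites covered at `min_depth` or more | 80%, 10X |

Conventions worth stating precisely:

* The SV rule is a strict inequality: 41 matching reads is a present call,
  40 is absent. The high bar guards against cross-contamination between
  samples and index hopping, both of which leak reads at low counts.
* The SNV read minimum is inclusive (3 reads suffice) while the
  variant-allele-fraction bound is strict (exactly 1% fails). The VAF
  denominator is the total depth at the position, not ref+alt.
* Junction matching is unstranded by default: a read containing the reverse
  complement of the junction counts. Raw reads carry no strand information,
  so ignoring the reverse strand would halve sensitivity on average;
  `both_strands = FALSE` is available for library preparations that preserve
  strand. Each read counts at most once per junction, duplicate reads are all
  counted (amplicon libraries are duplicates by construction), and reads with
  ambiguous bases simply never match.
* QC counts only SNV sites in its coverage fraction; SV assays have no
  per-site depth in the same sense.

Missing data (a site with no counts row for a cell) becomes a 0 in the
binary matrix, with a companion mask recording that the 0 carries no
evidence. The default treatment — scoring masked entries as 0 — matches a
binary matrix with no missing state; `use_mask = TRUE` makes the mixture
model skip those entries in both the E-step products and the M-step sums.
No imputation is performed.

## The mixture model

Cells are clustered with a mixture of multivariate Bernoulli distributions.
Cell $i$ with binary call vector $x_i \in \{0,1\}^J$ belongs to a latent
cluster $z_i$ with $P(z_i = k) = \pi_k$, and

$$P(x_i \mid z_i = k) = \prod_{j=1}^{J} \theta_{kj}^{x_{ij}}
  (1-\theta_{kj})^{1-x_{ij}},$$

where $\theta_{kj}$ is the probability that assay $j$ is called present in a
cell of cluster $k$. The model is deliberately simple: conditional on the
clone, calls are independent, which is a reasonable approximation when the
dominant noise (allelic dropout, amplification failure) acts per amplicon.

Fitting is by expectation–maximization with these numerical choices:

* **Smoothing.** M-step estimates of $\theta$ use Jeffreys-style
  pseudocounts $a = b = 0.5$, i.e. the posterior mode under a
  Beta$(1.5, 1.5)$ prior. This keeps $\theta$ off $\{0,1\}$ so
  log-likelihoods stay finite even for clusters whose members agree on every
  assay. A consequence worth being explicit about: the quantity EM then
  increases monotonically is the log-posterior (log-likelihood plus the Beta
  log-prior kernel), and that is what `loglik_trace` records and what
  convergence is tested on; the final observed-data log-likelihood is
  reported separately as `loglik`. With `smooth = c(0, 0)` the two coincide.
* **Initialization.** `n_restarts` (default 20) random responsibility
  matrices drawn from a flat Dirichlet, plus one deterministic restart from
  the average-linkage hierarchical-clustering cut at $K$ — an anchor that
  makes the common case reproducible while the random restarts guard against
  local optima. Arbitrary extra initializations (hard labelings or
  responsibility matrices) can be supplied via `init`; EM ascends
  monotonically from each, so seeding with a candidate partition guarantees
  the fit scores at least as well as that partition.
* **Convergence.** Relative change of the objective below `tol` (default
  `1e-6`), capped at `max_iter` (500). The best restart by final objective
  wins. All randomness flows from `seed`; the same seed reproduces the fit
  exactly.
* **E-step in log space** with row-wise log-sum-exp, so long assay panels do
  not underflow.
* **Degenerate inputs.** $K$ larger than the number of cells is an error; an
  all-identical matrix with $K > 1$ warns and lets the surplus clusters empty
  out ($\pi_k \to 0$). $K = 1$ is computed in closed form (smoothed column
  means).

### Choosing the number of clusters

The number of cell clusters is estimated before the EM by agglomerative
hierarchical clustering (average linkage on Hamming distances between cell
rows), scoring each cut at $K = 2..k_{\max}$ by mean silhouette width and
taking the best; if no cut reaches a mean silhouette of 0.1 the matrix is
declared unclustered ($K = 1$). Linkage, distance, silhouette criterion and
the 0.1 floor are package choices — reasonable defaults for binary genotype
data, all exposed as arguments. At the simulator's default regime the
silhouette selects $K = 2$: the doublet population (~10% of cells) is real
structure but too small and too dispersed to win the cut, so doublet
detection is run at an explicitly enlarged $K$ (below).

### Mutation clusters, poor assays, doublets

Thresholding $\theta_{\cdot j}$ at 0.5 (inclusive) gives each assay a
presence pattern over clusters; assays with identical patterns form a
mutation cluster. The all-ones pattern is the *ancestral* cluster (present
in every clone); the all-zeros pattern collects *poor* assays — assays that
fail in enough cells that no cluster reaches 50% presence. Poor assays can
also be excluded up front by their missing-data fraction
(`flag_poor_assays`, off by default); both routes are reported, and the
post-hoc cluster route is the default because it requires no extra
threshold.

A chamber that received two cells produces the *union* of two clones'
mutation profiles. A cluster $d$ is flagged as a doublet cluster when its
profile is within `tolerance` (default 0.15 mean absolute deviation) of
$\max(\theta_a, \theta_b)$ elementwise for some pair of other clusters, and
that union fits strictly better than any single other cluster's profile.
The second condition matters: a cluster that merely duplicates an existing
clone is also "within tolerance of a union" trivially, but duplication is a
model-selection problem, not doublet detection, so it is never flagged.
Doublet flagging needs $K \ge 3$ — with two clusters there is no third
profile to test — so the pipeline's doublet check is meaningful when run at
the estimated $K$ plus room for one union cluster.

## The clone tree

Clone consensus genotypes are $\theta_{kj}$ thresholded at 0.5 (inclusive),
with doublet and poor clusters excluded, plus an all-zero germline root so
the tree is rootable. The clonal architecture is the minimum spanning tree
of the complete graph over these genotypes with genetic-distance edge
weights — Hamming distance by default, Jaccard as an alternative for panels
where shared absences are uninformative. Kruskal's algorithm is implemented
with lexicographic tie-breaking on node labels, so the tree is fully
deterministic; duplicate genotypes are legal (weight-0 edges). On instances
small enough to enumerate every spanning tree, the result provably attains
the minimum total weight (this is tested).

## The simulator

Every stage is testable at desk scale against
known truth. `simulate_truth()` builds a clone tree rooted at the germline —
one ancestral edge shared by all clones, one private edge per clone, each
mutation on exactly one edge (infinite sites) — and draws cells from the
clone proportions, with doublet chambers taking the union of two distinct
clones' genotypes. `simulate_observations()` applies the error model and
draws read-count evidence.

Defaults mirror the observed regime of the study design the package models:
128 cells, 41 SNV + 36 SV assays, two clones, doublet rate 0.096,
poor-assay fraction 0.063, allelic dropout 0.1 and false-positive rate 0.01
per cell-assay. Where no value was dictated, the package fixes one and
documents it here:

* clone proportions 50/50; the ancestral edge carries 60% of the SV assays
  when `ancestral_sv_only = TRUE` (the default), emulating an ancestral
  mutation cluster composed entirely of structural variants, with the
  remaining assays split evenly between the clone edges;
* SNV depth $\sim$ NB(mean 100, size 5); variant allele fraction 0.5 for a
  present heterozygous variant and an error floor of 0.002 otherwise —
  values at which the 3-read/1% filter is discriminative at realistic
  amplicon depths;
* SV junction-matching reads $\sim$ Poisson(100) when present, Poisson(1)
  when absent, so the 40-read rule separates the two regimes by a wide
  margin;
* poor assays yield no usable data in a cell with probability 0.8;
* allelic dropout is applied at the genotype level, before counts are drawn,
  which is how amplification dropout manifests in amplicon data;
* materialized reads embed the junction 30-mer at a uniform offset in a
  150-mer, reverse-complemented with probability 1/2 (reads are unstranded);
  junctions are rejection-sampled to be unique and background reads are
  rejection-sampled to contain no junction on either strand, so the
  exact-match counter has no structural false positives in synthetic data.

What the simulator does *not* emulate: base-level sequencing error beyond
the flat error floor, chimeric amplicons and primer artifacts, coverage
correlation between neighboring amplicons, copy-number-dependent allele
fractions, or any real genome sequence. Tests passing on simulated data
therefore demonstrate that the inference machinery is correct under its own
noise model, not that the noise model captures everything real
amplification does.

## What the tests and defaults were sized to

The test suite runs the recovery study at the default regime over 100
simulation replicates (counts-level, which is distributionally identical to
genotyping the materialized reads and much faster); end-to-end runs from
FASTQ use 24–128 cells. Exhaustive oracles (all 2-colorings for the EM
bound, all spanning trees for the MST) run at $n \le 8$ cells and $\le 6$
nodes respectively, where enumeration is exact and fast. On one CPU the
whole suite completes in a few minutes.

## Known limitations

* The mixture model treats assays as conditionally independent within a
  clone; linked amplicons (e.g. two junctions of one complex rearrangement)
  violate this mildly.
* Model selection by silhouette is a heuristic; it will merge clones
  separated by very few assays and, by design, does not count a small
  doublet population as a clone.
* The doublet rule only detects *clusters* of doublets; a lone doublet cell
  is absorbed into whichever clone fits better.
* The MST over consensus genotypes is a genealogy summary, not a
  phylogeny: no mutation ordering within an edge, no recurrent-mutation or
  loss modeling, and duplicated consensus genotypes collapse to weight-0
  edges.
* A YAML configuration layer is not provided; `run_config()` plus CLI flags
  cover the same surface with one less format.
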