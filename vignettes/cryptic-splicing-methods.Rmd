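---
title: "Models and methods behind crypticsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crypticsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticsplice)
library(dplyr)
```

# The problem

When TDP-43 loses its nuclear splicing-repressor function — as in
frontotemporal lobar degeneration with TDP-43 pathology (FTLD-TDP) and
related proteinopathies — normally silent *cryptic exons* are aberrantly
included in mRNAs and constitutive exons are skipped. Bulk brain RNA-seq
captures these events as shifts in the relative usage of splice junctions.
`crypticsplice` implements the full analysis chain for such data: intron
clustering, overdispersed differential-usage testing with covariate and
cell-composition adjustment, annotation-based novelty and event-type
classification, in-silico cryptic peptide prediction, and cross-study
event harmonization — together with a synthetic-data generator that
emulates each layer so every component can be validated against known
truth.

# Junction clustering

Split reads define junctions as 1-based, fully closed intronic intervals
(the first and last intronic base), the same convention used when event
coordinates are printed in papers, so printed coordinates can be pasted
into code directly. BED-dialect input (0-based half-open) is converted on
read. Junctions are filtered on intron length (default cap 500 kb) and
total split-read support across samples (default minimum 50 reads; the
threshold's scope — per junction rather than per cluster — is ambiguous
in common usage, so it is configurable and documented as per-junction).
An 8 bp anchor requirement is a property of upstream junction extraction
from alignments; it is recorded in the filter configuration for
provenance but cannot be re-checked without read-level data.

Clusters are connected components of the graph linking junctions on the
same chromosome and strand that share a start or an end coordinate —
intron-excision clusters in the Leafcutter sense. Mere interval overlap
does not link junctions by default (`by = "overlap"` enables it), because
shared splice sites are what make junction counts compositionally
comparable. Singleton components carry no relative-usage information and
are dropped. Cluster identifiers are assigned in coordinate order so that
re-running on reordered input yields identical results.

# The Dirichlet-multinomial model

Within a cluster with $J$ junctions, the counts $y_i$ of sample $i$
(total $n_i$) are modelled as Dirichlet-multinomial with parameters
$\alpha\, p_i$, where $\alpha > 0$ is a shared concentration and the
usage proportions follow a softmax link,

$$ p_{ij} = \frac{\exp(x_i^\top \beta_j)}{\sum_k \exp(x_i^\top \beta_k)},
   \qquad \beta_J = 0, $$

with covariates $x_i$ comprising an intercept, the group indicator
(case = 1), sex (0/1), standardized age at death and RIN, and optionally
cell-proportion principal components. The reference-junction constraint
makes the model identifiable; the shared $\alpha$ captures biological
overdispersion relative to a pure multinomial (the generator's default
$\alpha = 30$ gives realistic between-sample PSI spread at sequencing
depths around 100 spliced reads per cluster).

Fitting maximizes the log-likelihood over $(\beta, \log\alpha)$ by
bounded quasi-Newton (L-BFGS-B) with analytic gradients. Intercepts are
initialized at pooled empirical logit proportions with pseudocount 0.5,
other coefficients at zero, and $\log\alpha$ at $\log 10$; convergence
uses a relative-tolerance criterion with at most 500 iterations. Two
numerical guards matter in practice: linear predictors are bounded at
$\pm 30$ (beyond which softmax saturates), and $\alpha$ is capped at
$10^6$. The cap marks the effectively-multinomial limit — past it,
differences of log-gamma functions of nearly equal huge arguments lose
all floating-point precision and the likelihood surface turns into
noise, so unbounded optimizers wander to meaningless optima. Within the
bounds the likelihood is computed directly from log-gamma terms; a
sample with zero cluster total contributes zero.

Each cluster is tested by a likelihood-ratio test of the full model
against the group-free null, with $\chi^2$ degrees of freedom $J - 1$
(one free usage dimension per non-reference junction; the originating
analysis does not state its statistic, and this is the natural choice
for the parameterization). Two finite-sample refinements keep the null
distribution honest at cohort-scale sample sizes, where the naive
statistic runs measurably hot (about 7% of null clusters below
$p = 0.05$ at twenty samples per group). First, the concentration is
treated as a profiled nuisance: it is estimated in the null fit and held
fixed in the full fit, so the compared models differ only in the $J - 1$
group coefficients. Second, the residual multiplicative inflation —
a classical Bartlett-type $O(1/N)$ effect, empirically uniform across
cluster sizes — is estimated from the data by parametric bootstrap:
every tested cluster re-simulates counts from its fitted null model
(fitted proportions, profiled concentration, observed totals), the test
is re-run, and the family-wide mean of bootstrap LRT/df becomes the
factor by which each observed statistic is deflated before the
chi-square tail is taken (three replicates per cluster by default; the
correction is skipped when the family yields fewer than 50 bootstrap
draws, where the factor itself would be too noisy). Clusters where
either fit fails to converge, or with fewer than three informative
samples in a group, are excluded from testing *and* from the
Benjamini-Hochberg family, which is formed per comparison. On 500
synthetic null clusters the corrected p-values are uniform (the
acceptance suite checks a Kolmogorov-Smirnov p above 0.01) and the
empirical FDR at $q < 0.05$ with planted signal stays at or below 0.10.

Per-junction effect sizes are the fitted group coefficients in the
centred, sum-zero representation: the implicit zero of the reference
junction is appended and the mean subtracted. Raw reference-relative
coefficients leave every non-shifted junction near zero with arbitrary
sign; centring restores the property that a junction's sign carries its
usage direction (it agrees with the sign of its empirical
$\Delta\mathrm{PSI}$ in at least 95% of significant junctions on
synthetic data), which the cassette-direction rule depends on.

PSI values are empirical: per sample, each junction's share of the
cluster total (samples with zero total excluded); group PSIs are plain
group means, and $\Delta\mathrm{PSI}$ is case minus control, reported
unrounded. Fitted rather than empirical group PSIs would also be
defensible; empirical means were chosen because they are what the
headline arithmetic of published event tables reproduces. An event is
differentially spliced when its cluster has $q < 0.05$ and its own
$|\Delta\mathrm{PSI}| > 0.1$ (both thresholds configurable).

# Annotation, event types, and cryptic events

The splice-site index derives annotated introns as gaps between
consecutive exons per transcript; donors and acceptors are strand-aware
(the donor is the 5' intron end in transcription direction). Junction
status is `annotated` when the exact intron pair is annotated, otherwise
`novel_acceptor`, `novel_donor`, or `novel_pair` when one or both
positions are unknown. A junction whose two positions are both known
splice sites that are never paired gets the separate status
`novel_combination` rather than inflating the genuinely novel-site
categories — these are typically exon-skipping junctions. Genes are
assigned by containment of both junction ends within a gene span, ties
resolved by the largest overlap, otherwise `intergenic`.

Event types follow a small rule set: junctions fully containing an
annotated exon are exon skipping (ES); a single novel position within
`alt_ss_window` (default 100 bp, configurable) of the annotated site it
replaces is an alternative 5' or 3' splice site (A5SS/A3SS); a novel
position strictly inside an annotated intron and farther than the window
from the replaced site — or a pair of cluster junctions flanking a novel
exonic island — marks cryptic exon inclusion (EI); anything else is
`complex`. The window rule is a documented surrogate: the boundary
between a "shifted splice site" and a "new exon" is not defined
operationally in the literature this package follows, and 100 bp
separates the two regimes cleanly on both synthetic data and the printed
examples (splice-site shifts of tens of bases versus cryptic exons
kilobases inside introns).

Cassette-exon directionality applies only to three-junction clusters in
parent/child geometry (the parent spanning both children, children
sharing the parent's outer boundaries, separated by the cassette exon).
A positive parent effect with negative child effects means the exon is
skipped in cases; the reverse means included; all other sign patterns
are complex. The classifier is tested against the exhaustive 27-pattern
truth table.

Cryptic events are junctions that are not annotated, lie in a
significant cluster, and are elevated in cases: the strict mode
($\Delta\mathrm{PSI} > 0.1$) yields the headline event list; the relaxed
mode ($\Delta\mathrm{PSI} > 0$) yields the longer list used for
cross-study comparison. Binding-site proximity labels an event `close`
when the gap between the event interval and the nearest site is at most
500 bp (overlap counts as zero); distance is measured from the event
interval, as the measurement base is unstated in the source methods.

# Cell-type deconvolution and composition adjustment

Bulk brain expression is deconvolved into five cell-type proportions
(neurons, oligodendrocytes, astrocytes, microglia, endothelial cells)
from marker genes: counts are CPM-normalized (no log — the mixing model
is linear), each type is summarized by its marker-mean signal
$y_{st} \approx c_t\, p_{st}$, and the sum-to-one constraint across
types yields the non-negative least-squares problem
$\min_{w \ge 0} \lVert Y w - 1 \rVert^2$ in the inverse scales
$w_t = 1/c_t$, after which $p_{st} = y_{st} w_t$ is clamped and
renormalized. This is a deliberate approximation to published
digital-sorting deconvolution — downstream use needs only relative
proportions with simplex structure, and the marker-mean constrained
solve recovers synthetic mixtures with mean absolute error well under
0.05 at 10% multiplicative noise. It identifies the scales only when
composition varies across samples; a cohort of identical mixtures is
degenerate (and also useless for adjustment).

A PCA of the centered proportions supplies adjustment covariates: the
smallest number of leading components reaching 80% cumulative variance,
capped at four because five proportions summing to one span a
four-dimensional subspace. On data generated with group-correlated
composition (cases with a lower neuronal share driving junction usage of
composition-sensitive clusters), adding these PCs to the design removes
essentially all spurious significance, mirroring the sharp drop in
significant clusters that motivates the adjustment.

# Cryptic transcript surgery and peptide prediction

For each cryptic event the representative transcript is the MANE-tagged
one, else the longest CDS, ties broken by identifier. Exon-chain surgery
is performed in genomic coordinates — EI inserts the cryptic exon
between its flanks, ES removes exons contained in the skipping
junction's intron, A5SS/A3SS move the affected exon boundary to the
novel site (extensions pull intronic sequence in; truncations cut exonic
sequence) — and the chain is re-validated before the cDNA is assembled
(reverse-complemented for minus-strand genes). A null event reproduces
the reference cDNA byte-identically, and mirrored minus-strand
constructions yield identical peptides; both properties are tested.

Translation starts at the reference start codon when its three bases are
untouched by the modification (mapped through the length change when the
modification is upstream); otherwise the longest ATG-initiated open
reading frame of at least 30 codons is used, and if none exists the
consequence is `NA` — which also covers non-coding genes, matching the
"not applicable" rows of published event tables. A premature termination
codon (PTC) is flagged when the new stop lies 5' of the position
homologous to the reference stop.

Protein consequences compare predicted and reference peptides:
`no_change` (identical — events confined to untranslated regions),
`truncated_proteoform` (stop inside the novel sequence),
`sequence_missing` (termini preserved around an internal deletion; one
junction-hybrid residue from a codon straddling the splice is
tolerated), `alt_N_terminal` / `alt_C_terminal` (one terminus replaced),
plus `sequence_inserted` for in-frame internal insertions with both
termini preserved. The last label is a package extension: the published
consequence vocabulary has no value for the neoepitope-bearing in-frame
cryptic peptides, and folding them into any other category would violate
the rule that `no_change` means byte-identical peptides. Structural
categories follow the six-way scheme for cryptic events: in-frame exons
(length divisible by three, no in-register stop), out-of-frame exons
(which provably carry a PTC — asserted on every synthetic case),
terminal exons (an entering junction with no exit junction in the
cluster; their 3' extent is unknowable without 3'-end data, so no
peptide is predicted), initial exons, alternative splice sites, and exon
skipping. Terminal-exon detection uses cluster topology, not
polyadenylation signals.

# Cross-study matching

Event lists from different studies are harmonized at two levels. Gene
level is a case-insensitive intersection. Coordinate level compares
junction-end pairs exactly: both positions equal is a perfect match,
exactly one is partial. Lists whose coordinates mark the outer ends of
the whole event rather than one junction's ends (span semantics) are
compared by membership of each span end in the pooled coordinate
positions of the other list's events for that gene. Exact integer
equality after normalizing to 1-based closed intron ends is assumed —
no tolerance window, since none is documented — and a per-study
coordinate offset is available at ingestion for dialect differences;
genome-build harmonization is the caller's responsibility (a guard warns
on differing chromosome naming styles). A gene's pairwise level is the
maximum over its event pairs, and a gene counts as a multi-study perfect
match when every pairwise comparison is perfect.

# The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions for all validation: twenty samples per group, negative
binomial cluster totals with mean 100 and size 5, concentration
$\alpha = 30$, planted inclusion differences on the 0.1/0.2/0.3 grid
(matching the effect sizes of headline cryptic events), covariates (age
at death, sex, RIN) drawn at demographically plausible values, cell
mixtures from group-specific Dirichlet distributions (concentration 50)
with cases centered on a lower neuronal and higher endothelial/microglial
share, and study lists planted with the published overlap structure
(three triple-perfect events, thirteen pair-unique perfect matches, nine
and five partials, 52 and 24 shared genes). The toy annotation writes
real coding sequence into a synthetic genome — ATG...stop CDS, GT..AG
introns, strand-aware — and reserves cryptic exons strictly inside
introns with proper splice dinucleotides, in-frame exons built from
stop-free codons, and out-of-frame exons with a stop written at the
insertion phase, so classifier and translation checks have exact ground
truth. In confounded mode, null clusters respond to each sample's
neuronal share, coupling composition to apparent splicing.

What the generator does not emulate bounds what green tests mean for
real data: no read-level artifacts (alignment errors, anchor-length
effects, multimapping), no annotation incompleteness beyond the planted
events, no correlated noise across clusters, no library-size or batch
structure, and single-transcript genes only. Passing tests certify the
statistical machinery and the classification logic, not robustness to
upstream data pathologies.

# Problem sizes and determinism

The test and acceptance workloads use 500 null plus 100 signal clusters
for calibration, 50 clusters for recovery, 150 clusters for the
confounding experiment, and 12–18 genes for annotation-linked checks —
sizes at which every check is stable across seeds while the whole suite
runs in minutes on one core. All generators draw from seed-derived
streams (distinct fixed offsets per generator), making every emitted
file byte-reproducible; the pipeline writes a manifest with input hashes
so reruns can be verified hash-equal.

# Known limitations

The deconvolution is a marker-mean approximation, not a reimplementation
of the published digital-sorting algorithm. The EI-versus-alternative-
splice-site window is a surrogate for an undocumented rule. Group PSIs
are empirical means, not model-fitted values. Terminal exons get no
peptide. The degrees of freedom of the cluster test are assumed, not
taken from the original implementation, and exact numerical
compatibility with Leafcutter is a non-goal. Cross-study matching is
exact-coordinate only; fuzzy or liftover-based matching is out of scope.
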