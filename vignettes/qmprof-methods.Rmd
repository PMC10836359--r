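---
title: "Quantitative microbiome profiling of preclinical RA cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative microbiome profiling of preclinical RA cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmprof)
```

# The scientific problem

Gut microbes — *Prevotellaceae* in particular — have repeatedly been
associated with rheumatoid arthritis (RA) and with the asymptomatic
"preclinical" phases that precede it. Testing that association in an at-risk
population requires (i) a reproducible assignment of cohort participants to
preclinical stages, (ii) microbiome profiles expressed on an absolute scale
(cells per gram of stool) rather than as sequencing proportions, and (iii)
statistics that respect the compositional, non-normal character of microbiome
data. `qmprof` implements that full analysis stack for cohorts of
first-degree relatives of RA patients, together with a synthetic-cohort
generator so that every stage can be exercised and validated without access
to restricted cohort data.

# Cohort classification

Participants are assigned to one of four preclinical stages:

* **control** — asymptomatic, without clinically significant autoantibodies
  (ACPA below the upper limit of normal, ULN; rheumatoid factor (RF) and
  anti-Ra33 below 3× ULN);
* **high genetic risk** — asymptomatic carriers of two copies of the
  HLA-DRB1 shared epitope;
* **autoimmunity** — asymptomatic but with clinically significant serology
  (ACPA ≥ 1× ULN, or RF / anti-Ra33 ≥ 3× ULN);
* **symptomatic** — clinically suspect arthralgia (CSA, 7-item EULAR
  checklist, score ≥ 4) or untreated new-onset RA.

Rules fire in precedence order (diagnosis → symptoms → serology → genotype →
control). Two cutoffs exist for the CSA score: when one or two checklist
items are missing, or when autoimmunity is concomitant, the lowered cutoff
applies. The package adopts **score ≥ 3** as the lowered cutoff — the
explicit operationalisation "at least 3" — and exposes it as an argument
(`lowered_cutoff`) so the alternative strict reading (> 3) remains one
keystroke away. Two missing-data decisions matter downstream and are recorded
in each assignment's `rationale`:

* a missing anti-Ra33 titre is treated as non-significant — it can neither
  trigger the autoimmunity rule nor veto the control rule;
* a missing shared-epitope genotype with no earlier rule fired yields
  `control`, flagged, rather than an error — genotype missingness occurs in
  real cohorts and must not crash classification.

For sensitivity analyses the package selects the *k* most pronounced
phenotypes per non-control group (default 20), ranking by RA diagnosis, then
CSA score, then the maximum titre-to-threshold ratio over the three analytes
(ACPA relative to 1× ULN; RF and anti-Ra33 relative to 3× ULN, so
"significance" is scale-free across assays). The composite is not uniquely
defined by the study design; this ordering is the package's choice and each
element of it is overridable. Controls are matched to the symptomatic
subgroup by exact sex and greedy nearest age with deterministic tie-breaking
(participant-id order); optimal matching is deliberately out of scope.

# Quantitative microbiome profiling (QMP)

Sequencing yields compositional counts; flow cytometry yields the total
microbial load $L_i$ (cells per gram). The QMP transform reconciles the two:

1. divide each taxon's counts by its predicted 16S rRNA gene copy number
   $c_j$, giving copy-number-corrected depths $D_i = \sum_j x_{ji}/c_j$;
2. define each sample's *sampling depth* $s_i = D_i / L_i$ — the fraction of
   the community that was sequenced — and the even depth
   $s^\* = \min_i s_i$;
3. rarefy each sample without replacement to $T_i = \mathrm{round}(s^\* L_i)$
   reads, so all samples describe the same fraction of their community;
4. exclude samples whose rarefied count would fall below 150 reads and
   iterate the even depth on the remainder to a fixed point;
5. scale the rarefied counts by $L_i / T_i$, giving estimated cells per gram;
   columns then sum to the loads exactly.

Numerical choices: corrected counts are real-valued and are rounded half to
even immediately before rarefaction (the urn needs integers); a sample whose
own corrected depth is already below the read threshold can never survive
and is excluded up front, which prevents one ultra-shallow sample from
dragging $s^\*$ below usability for everyone else; rarefaction is a single
seeded multivariate-hypergeometric draw (sequential conditional
hypergeometric sampling), not an average over repeated rarefactions. The
threshold reading — "samples whose rarefied read count would be below 150
are excluded" — and the threshold value itself are arguments.

# Community ecology

Alpha diversity uses the Shannon index in nats (base configurable).
Between-sample dissimilarity is Bray–Curtis,
$d_{ij} = 1 - 2\sum_k \min(x_{ki},x_{kj})/(\sum_k x_{ki} + \sum_k x_{kj})$,
computed through `vegan`. Ordination is classical PCoA: Gower
double-centering $B = -\tfrac12 J D^2 J$, eigendecomposition, coordinates
scaled by the square roots of positive eigenvalues. Negative eigenvalues
(Bray–Curtis is non-Euclidean) are reported but not corrected — no
Lingoes/Cailliez adjustment — matching common practice for this analysis.

The one-factor PERMANOVA is implemented in the package from first
principles: $SS_{total} = \tfrac1n \sum_{i<j} d_{ij}^2$, within-group sums
analogously per group, pseudo-$F$ from the usual degrees of freedom, and a
permutation p-value under seeded label shuffling. The observed statistic is
included in the null set ($p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$),
which guarantees a valid test under exchangeability; consequently the
smallest attainable p is $1/(n_{perm}+1)$. The default 999 permutations are
recorded in the output. `vegan::adonis2` is used in the test suite as an
independent cross-check of pseudo-$F$ and $R^2$, never as the
implementation.

# Enterotyping by Dirichlet-multinomial mixtures

Genus-level counts (rarefied to 10 000 reads, the same preprocessing used
for rarefied genus richness) are modelled as a finite mixture of
Dirichlet-multinomial components. Fitting is EM: responsibilities from
component DM log-densities in log-gamma form (including the multinomial
coefficient, so the reported log-likelihood is the true one), weights from
responsibility totals, and concentration vectors by responsibility-weighted
fixed-point iteration. Because the fixed-point update is not guaranteed
monotone, it is damped by step-halving in log space whenever the likelihood
would decrease, keeping EM monotone to numerical tolerance. Initialisation
is k-means on sample proportions, with jittered restarts; the best restart
wins.

The number of components is selected by BIC, $-2\log L + \nu \log n$ with
$\nu = (K-1) + K S$ for $S$ genera. Popular software for this model
family scores a Laplace approximation instead; BIC was chosen here for
transparency and the criterion enters through `glance()`, so it is pluggable.
Components are mapped to the four canonical enterotype names by their
dominant genera: *Prevotella*-dominated → `Prev`,
Ruminococcaceae-dominated → `Rum`, and the *Bacteroides*-dominated
components → `Bact1`/`Bact2`, with `Bact2` the lower-entropy (dominated)
community type, following the usual convention that Bact2 is the
low-richness Bacteroides configuration. Samples with zero counts cannot be
assigned and are reported as `unassigned`. Enterotyping studies commonly fit the
mixture on the cohort pooled with a large external reference panel; the
package preserves that workflow by letting callers concatenate a synthetic
four-enterotype reference panel, since real reference collections are not
redistributable. A caveat recorded here on purpose: the mixture model needs
counts, so rarefied counts — not relative abundances — enter the fit.

# Differential abundance

The differential-abundance engine follows the CLR Monte-Carlo mechanism:
taxa are first prevalence-filtered (retained if observed ≥ 10 times in ≥ 5%
of samples, with `ceiling` on the sample count), counts are optionally
aggregated to family or genus, and `n_mc` posterior compositions per sample
are drawn from Dirichlet(counts + 0.5). Each instance is mapped to centred
log-ratio coordinates and tested per taxon with a rank test (Wilcoxon
rank-sum for two groups, Kruskal–Wallis otherwise); the reported raw p is
the expectation over instances (the median is available), and
Benjamini–Hochberg correction is applied across taxa on a single shared
code path. The defaults `n_mc = 128` and `prior = 0.5` follow the cited
tool-family's conventions; both are arguments. A property worth knowing:
averaging p over posterior instances shrinks small p-values upward, so the
expected-p procedure is deliberately *conservative* — on exchangeable null
panels its false-positive fraction falls well below the nominal level, while
the underlying single-instance rank test is calibrated (it reproduces
`wilcox.test` exactly). The test suite checks both facts: two-sided
calibration at one instance, and strict non-anticonservativeness under
instance averaging. The calprotectin association
analysis is the same engine under a binary grouping at 100 µg/g. Effect
sizes are the median over instances of the between-group difference in
median CLR.

# Resampling inference

The pronounced-subgroup comparison uses a bespoke permutation test: the
observed statistic is the difference in median taxon abundance between two
selected subgroups of size $k$; the null is built by redrawing two disjoint
random size-$k$ subsets from the whole cohort 10 000 times, exactly as the
procedure is described — not by permuting labels within the selected $2k$
individuals, though that mode is provided (`null = "labels"`). The p-value
is one-sided (alternative: later stage exceeds control, matching the
direction of the prior literature on *Prevotellaceae*; the direction is an
argument) and uses the same $+1/+1$ convention as every other resampling
procedure in the package.

Group-level univariate comparisons use the unpaired Wilcoxon rank-sum test
against the control group with BH correction. Calprotectin protocols of this
kind are sometimes written up with the signed-rank test, but the groups are
independent samples — there is no pairing — so the unpaired test is the
correct choice and is what the package implements. Contingency tables
(enterotype × group) are tested either by Pearson's χ² or by a Monte-Carlo
Fisher-type exact test that samples tables with fixed margins (Patefield
algorithm via `r2dtable`) and counts tables at most as probable as the
observed one.

# The synthetic-cohort generator

The generator emulates the study design the analysis assumes: 226 controls,
50 high-genetic-risk, 49 autoimmunity and 46 symptomatic participants
(8 of the symptomatic carrying a new-onset RA diagnosis), a genus universe
of 120 taxa spanning the common gut families, four enterotype-structured
Dirichlet composition profiles (Bact1/Bact2/Prev/Rum), negative-binomial
read depths (mean 20 000), log-normal microbial loads with median
$10^{11}$ cells/g (a typical faecal order of magnitude; the study reports no
load values), per-ASV 16S copy numbers uniform on [1, 12] (copy-number
predictions are non-integer), and log-normal calprotectin with median
30 µg/g so that most participants fall below the 100 µg/g elevation
threshold. Each genus is split into 1–5 ASVs with Dirichlet-distributed
proportions so ASV-level code paths (prevalence filter, QMP) are genuinely
exercised.

Serology only matters through threshold relationships, so titres are drawn
log-normally around 0.3× ULN for negatives and uniformly on [1, 10]× ULN
(ACPA) or [3, 10]× ULN (RF/anti-Ra33) for positives; per-group
distributions of true cohorts are not published, and these defaults are
placeholders with the right threshold behaviour, not estimates. Anti-Ra33
is set missing with probability 0.2 and each CSA item with probability 0.03,
exercising both missing-data paths of the classifier. The generator
round-trips every participant through `classify_participant()` and fails if
any intended label is not recovered, so label fidelity is an enforced
invariant, not a hope. The default configuration injects **no group effect**
— the null cohort, matching the design's primary finding — and effects are
added explicitly via `effect_spec` (e.g. a 3-fold *Prevotellaceae*
enrichment in the symptomatic group) for power experiments.

What the generator does **not** emulate: raw reads, chimeras, PCR bias,
taxon-taxon correlations beyond the Dirichlet covariance, longitudinal
structure, or realistic serology distributions. Green tests therefore show
that the algorithms are correct under the stated generative assumptions;
they do not certify performance on real cohort data.

# Validation strategy and problem sizes

The test suite validates against independent oracles wherever one exists:
hand-computed arithmetic for the QMP building blocks; exhaustive
multivariate-hypergeometric probabilities (χ² goodness of fit over 10 000
seeded draws) for rarefaction; exhaustive enumeration of all 720 label
permutations at $n = 6$ and a naive double-loop pseudo-$F$ (agreement to
1e-12) for PERMANOVA, plus `vegan::adonis2` as a cross-check; a direct BFGS
optimiser of the one-component DM likelihood for the mixture model; and the
step-up definition for BH. Calibration properties are checked by
simulation: PERMANOVA type-I error within [0.03, 0.07] at α = 0.05 over 500
null replicates (99 permutations each, at which the rejection rule
$p \le 0.05$ is exact under exchangeability); uniformity of the
subgroup-permutation p over 500 null replicates (Kolmogorov–Smirnov,
α = 0.01); differential-abundance false-positive fraction within
0.05 ± 0.02 over 200-taxon null panels; and a 3-fold injected taxon winning
the BH ranking in ≥ 90% of 50 replicates at $n = 50/50$.

Simulation sizes in the suite are chosen as the smallest that make each
property statistically decisive: the model-selection experiment uses
$n = 600$ samples over a 24-genus panel at 5 000 reads with a single
k-means-initialised restart per candidate $K \in \{2,\dots,6\}$, recovering
the generating $K = 4$ in well over 80% of 20 runs; the parameter-recovery
experiment uses $n = 300$ over three disjoint 10-genus blocks. Classifier
fidelity is checked on twenty full 371-participant cohorts. The end-to-end
pipeline is verified byte-identical across repeated runs at a fixed seed.

# Known limitations

* PERMANOVA is one-factor only; no covariates, strata or interactions.
* No phylogeny-aware distances (UniFrac) — no tree is in scope.
* The DMM fit is EM with restarts; a multimodal likelihood can in principle
  retain a local optimum, which the BIC experiment quantifies but does not
  eliminate.
* Copy numbers are consumed as given; their prediction, and any moisture
  correction of microbial loads, happen upstream of this package.
* The enterotype naming heuristic keys on genus names; fitted on a taxon
  universe without recognisable genera it falls back to `component_<k>`.
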