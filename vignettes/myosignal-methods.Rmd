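---
title: "Methods: kinase activity, substrate prediction and temporal event ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinase activity, substrate prediction and temporal event ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myosignal` analyses time-resolved and inhibitor-perturbed phosphoproteome
and proteome quantification matrices: label-free (LFQ-style) log2
intensities of phosphosites and proteins measured over a differentiation
time course (e.g. C2C12 myoblasts at 0 h, 30 min, 24 h and day 5, four
replicates in two batches) and under kinase inhibition (control vs the
MEK/ERK inhibitor PD0325901 and the JNK inhibitor SP600125). This vignette
is the package's own account of its models, parameters and design
decisions.

```{r setup}
library(myosignal)
```

## The data model

All quantification enters as a `QuantMatrix`: a features x samples matrix
of log2 values with a per-sample design (condition, replicate, batch) and a
scale flag (`intensity` or `ratio`). Missing cells are `NA` and explicit.
The declared order of conditions in the design is the time order; adjacency
filters and event ordering rely on it rather than on parsing labels.

The generative model assumed throughout (and implemented literally by the
synthetic generator) is additive on the log2 scale:

    y[site, sample] = baseline[site] + activity[kinase(site), condition]
                      + batch_shift[site, batch] + noise,

with left-censored missingness (low-abundance cells are more likely to be
unobserved) plus a completely-at-random component. These are the standard
working assumptions behind location-based batch correction, down-shifted
normal imputation and ratio conversion for LFQ data.

## Preprocessing

**Coverage filters.** A feature is retained iff its total quantified count
reaches `min_total_quantified` and at least `min_conditions` conditions
(adjacent in time order if required) each have at least
`min_reps_within_condition` quantified replicates. The presets mirror the
four designs the package targets: phospho time course 4-of-16 with 3-of-4
in some time point; phospho inhibition 3-of-12 with 3-of-4; proteome time
course 2-of-4 in two adjacent time points; inhibition proteome 4-of-15 with
3-of-4.

**Two-stage imputation.** Stage one is condition-specific: a (feature,
condition) group with at least three observed replicates ("more than two")
has its missing replicates drawn from the normal with the observed mean and
sd -- this preserves within-condition variance; a deterministic `mean` mode
is available. Stage two is random-tail imputation for everything left:
each missing cell in sample *s* is drawn from
N(mean_s - shift * sd_s, (width * sd_s)^2) with defaults shift = 1.8 and
width = 0.3 sample sds, the standard down-shifted-normal parameters for
left-censored LFQ data; both are arguments. Observed cells are never
modified -- tests assert bit identity. A practical consequence worth
knowing: purely random missing cells that fall through to stage two are
imputed as if censored, which biases them low; with the default 5% MCAR
rate this is the dominant loss of end-to-end ratio fidelity in the
synthetic benchmark.

**Ratios and batch.** Intensities are converted to log2 ratios against the
mean of the reference condition *within each batch*, so reference structure
cannot re-introduce batch effects; for the inhibition design the control
condition plays the reference role, likewise per batch. Batch correction is
location-only (additive shifts are what the generative model and typical
log2 LFQ batch effects look like): `center` subtracts each feature's batch
mean deviation exactly, `eb_location` shrinks the deviations with an
empirical-Bayes weight n_b * tau^2 / (n_b * tau^2 + sigma^2) where tau^2 is
a method-of-moments estimate across features -- useful when batches are
small and the raw deviations are noisy. No scale adjustment is attempted.

**Control-feature normalisation.** `select_stable_features()` ranks
features by the variance of their condition means (ties: total variance,
then id) to provide "stably expressed" negative controls;
`ruv_normalize()` estimates k unwanted sample-space factors as the top
right singular vectors of the row-centered controls submatrix and removes
each feature's fitted component. k defaults to 1; it must stay below the
rank of the controls submatrix.

**Proteome correction.** Site ratios are corrected by subtracting the host
protein's ratio at the matched condition so phosphorylation changes are
read net of protein abundance. Replicate-level site values are corrected by
the protein's *condition mean* (the protein replicate pairing is not
assumed meaningful); sites with unmapped proteins pass through and are
flagged.

## Kinase activity on standardized contrasts

Per contrast (a non-reference condition), each feature's value is its mean
log2 ratio over replicates; the column is then centered and scaled to unit
*sample* sd (the n-1 convention, asserted by direct formula in the tests).
Kinase activity at a contrast is the Stouffer combination over the
kinase's known substrates, Z = sum(z_i)/sqrt(n), with a two-sided normal
p-value; the signed Z is the reported activity. For paired inhibitor
contrasts the z-matrix is first projected onto unit directions in the
(PD, SP) plane -- eight canonical directions at 45-degree steps, with
"inhibited by PD only" = (-1, 0) since contrasts are log2(treated/control)
-- and the same set test is applied to the projected scores. BH adjustment
is across kinases within each direction or contrast. `min_substrates`
defaults to 3; kinases below it are excluded and reported, and substrates
annotated but not quantified are silently skipped (the reported `n` counts
those used).

## Kinase-substrate scoring

Motif evidence: a PSSM is estimated from the kinase's known-substrate
15-mer windows with pseudocount alpha = 0.01 per residue, padding symbols
excluded position-wise; at least 5 known substrates are required, kinases
below are skipped. A window's raw score (mean log probability over
non-padding positions) is min-max normalized by the best and worst windows
achievable under that PSSM, giving S_motif in [0, 1]; a fully uniform PSSM
makes every window score 0.5 by convention. Profile evidence: S_profile =
(r + 1)/2 where r is the Pearson correlation between the site's
standardized temporal profile and the centroid of the kinase's known
substrates; zero-variance profiles are undefined and recorded as missing.
The combined score is the weighted geometric mean
S_motif^w * S_profile^(1-w) with w = 0.5 -- one of several defensible
combination rules; the recovery benchmarks are designed to be
combination-rule-agnostic, and w is an argument. Held-out-recovery AUROCs
exclude each kinase's own known substrates from the evaluation set
(leakage control), though they appear flagged in the emitted table.

The signalome assigns each site to its argmax-scoring kinase when that
score reaches 0.5 (ties broken lexicographically and logged); a
kinase-kinase edge weight counts the distinct proteins shared by the two
kinases' top-scoring above-threshold site sets. Inhibitor-specificity
dissection takes sites whose group score (max over member kinases, e.g.
MAPK1/3 = max(MAPK1, MAPK3)) exceeds 0.7 -- the threshold applies to the
combined prediction score -- and partitions them by inhibition profile:
z_PD < z_SP means more inhibited under PD, hence MAPK1/3-specific, and
vice versa; exact ties are left unassigned.

## Temporal clustering and event ordering

Fold-change profiles of dynamically regulated features are z-transformed
across time points (flat profiles dropped) and clustered by k-means with
seeded restarts (best within-SS kept; plain k-means is used for determinism
and speed -- fuzzy alternatives are out of scope). For each candidate k the
enrichment score E(k) sums, over clusters, -log10 p of annotation terms
reaching BH q <= 0.05 within the cluster (Fisher one-sided hypergeometric
p; Haldane-corrected odds ratio on zero cells); this rewards both strength
and breadth of enrichment, and a `count` mode is available. The optimal k
maximizes E(k), ties to the smallest k; if nothing is enriched at any k a
warning says the choice is not meaningful. The candidate range defaults to
[2, 12], bounded above by n/5.

Event ordering is deliberately simpler than interval-testing formulations:
a cluster's direction is up if its mean profile's maximum comes after its
minimum, and its event time is the first half-amplitude crossing of the
mean profile, linearly interpolated between time points. On monotone
step-like profiles this yields the same ordering as model-based event
detection with far fewer knobs; it is a documented simplification, and
non-monotone profiles get the time of their first half-crossing only.

## Differential and dynamic statistics

The moderated t-test shrinks each feature's pooled variance toward an
empirical-Bayes prior: with e = log(s^2) - digamma(d/2) + log(d/2), the
excess of var(e) over trigamma(d/2) determines the prior df d0 through the
trigamma inverse and mean(e) determines s0^2; at or below the sampling
floor d0 = Inf and all variances shrink to the common value (constant
variances return that value exactly). The statistic is
t = log2FC / sqrt(s2_post * (1/n1 + 1/n2)) with s2_post =
(d0 s0^2 + d s^2)/(d0 + d) on d + d0 degrees of freedom; d0 = 0 reproduces
the ordinary pooled t exactly (a test asserts 1e-10 agreement) and
unequal group sizes use pooled variance (no Welch correction). DE calls
follow the literal rule wording: |log2FC| >= 1 (inclusive) and q < 0.05
(strict); the dynamic-regulation rule is |log2FC| > 1 (strict) in at least
two time points and ANOVA q <= 0.05 (inclusive). Both thresholds are
arguments. The two-stage overexpression contrast first normalizes both
treatment conditions to the shared reference condition's mean, then
applies the moderated test between the two ratio sets.

## Cross-omics concordance and morphology indices

Cells are gated as (any positive marker > 0) AND (all negative markers
<= 0 counts), i.e. "(Myf5+ or Myod1+) and Myog-" with the parenthesization
taken as written -- note this reads like a progenitor gate even though it
is used to extract myotube-like cells; the marker sets and threshold are
arguments. Genes with more than 95% zeros are dropped (exactly 95% is
kept), the top 100 highly variable genes are ranked by variance of log1p
counts (a scale-robust criterion chosen here since the ranking statistic
is otherwise unspecified; coefficient of variation is a drop-in
alternative), and each cell is Pearson-correlated with each proteome time
point over the shared genes, dropping missing pairs pairwise. Gene matching
is by exact symbol; no ortholog mapping. Morphology indices are pure count
arithmetic: differentiation index = nuclei in MHC+ cells / total nuclei,
%MHC+ = MHC+ cells / total nuclei, fusion index = nuclei in multinucleated
(>= 4 nuclei) myotubes / total nuclei -- tubes with 3 or fewer nuclei
contribute nothing, by definition of the input counts.

## The synthetic generator, and what passing tests do not show

The generator plants everything downstream stages claim to recover:
kinase PSSMs over 15-mer windows whose informativeness is a single mixture
weight (0 = uniform columns, KL from uniform grows monotonically),
per-condition log2 activities (sd 2 at non-reference conditions),
substrate windows drawn from the assigned kinase's PSSM against uniform
background windows, additive N(0, batch_sd) batch shifts, per-sample
left-censoring at the `mnar_quantile` of the latent matrix followed by
MCAR deletion, staggered step-profile proteome clusters with one pathway
term each, and a marker-gated cell population recoverable with recall 1 in
the noise-free limit. Benchmark defaults: 10 kinases x 20 substrates + 200
background sites, 4 conditions x 4 replicates x 2 batches, noise_sd 0.5,
batch_sd 0.5, mnar_quantile 0.1, mcar_rate 0.05, half of true substrates
annotated as known; the clustering scenario uses 8 time points, 200
proteins, 4 planted clusters; the DE scenario 500 proteins with 50 planted
at effect 2 and 4 replicates. These sizes keep every benchmark comfortably
in CPU-seconds.

What the generator does **not** emulate -- and hence what green tests do
not certify about real data: peptide-to-site rollup and shared peptides,
nonlinear or scale batch effects, intensity-dependent variance,
correlated substrate noise beyond the shared kinase activity, motif
overlap between biologically related kinases, incomplete or wrong
annotation databases, and any raw-MS artifacts (identification FDR,
match-between-runs). The benchmarks validate the statistical machinery
under its own model assumptions, not the assumptions themselves.

## Numerical conventions

Ties are broken lexicographically by feature/kinase id everywhere a choice
is arbitrary, for determinism. Degenerate cases have documented fixed
behaviours: uniform PSSM -> motif score 0.5; zero-variance profile ->
missing profile score; flat cluster profile -> excluded from events; zero
within-group ANOVA variance -> F = Inf, p = 0, flagged; single batch ->
warning and no-op; constant contrast column -> error. All generators and
the clustering sweep are exactly reproducible from their seed arguments.

```{r example, eval = FALSE}
# a complete run on synthetic data with planted truth
tc <- run_timecourse_scenario(seed = 1)
round(tc$metrics, 3)     # activity rho, substrate AUROC, ratio recovery
inh <- run_inhibition_scenario(seed = 1)
cl <- run_proteome_clustering_scenario(seed = 1)
```

## Known limitations

Location-only batch correction cannot remove multiplicative batch effects;
RUV with k factors assumes the controls actually span the unwanted
variation; the half-amplitude event time is ill-defined for strongly
non-monotone cluster profiles (the first crossing is reported); the
profile score degenerates to {0, 1} with only two contrasts; and the
moderated test's FDR control inherits BH's independence/PRDS assumptions.
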