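---
title: "Methods: temporal transcriptomics of the estrogen response"
author: "estromir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal transcriptomics of the estrogen response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estromir)
```

# Overview

`estromir` implements an integrative analysis of matched mRNA and miRNA
count time series after estrogen (E2) stimulation of ER-positive breast
cancer cells. The design it targets is a dense time course — ten timepoints
(0, 1, 2, 3, 4, 5, 6, 8, 12, 24 h) with three biological replicates each —
profiled by RNA-seq and small RNA-seq. Five analysis stages are chained:

1. **Estrogen-responsive genes.** Median-of-ratios normalization, a
   negative-binomial (NB) Wald test of every timepoint against time zero,
   and the responsiveness filters: mean normalized expression of at least
   500 across the series, and a significant (BH-adjusted p < 0.05) at least
   twofold change at one or more timepoints.
2. **Temporal classes.** Responsive-gene trajectories are interpolated with
   a piecewise cubic Hermite interpolating polynomial (PCHIP), decomposed
   with a Daubechies-3 discrete wavelet transform, and the coefficient
   vectors are hierarchically clustered and cut into three classes:
   *transient*, *induced*, *repressed*.
3. **Responsive miRNAs.** Reads-per-million-mapped (RPMM) normalization, a
   50-RPMM mean-expression filter, and per-timepoint fold change versus the
   time-zero replicate mean with an uncorrected Welch t-test
   (fold change ≥ 1.5, p ≤ 0.05).
4. **Characteristic genes per interval.** For each pair of consecutive
   timepoints, the characteristic-direction vector — a shrunken-covariance
   weighted mean difference — ranks genes by their contribution to
   separating the two timepoints; a prefix of the ranking forms the
   interval's characteristic gene set.
5. **Candidate master-regulator miRNA families.** miRNAs are grouped into
   families by their extended seed (mature nt 2–8); canonical seed sites
   (8mer, 7mer-m8, 7mer-1A) are scanned in 3′-UTRs; a Monte-Carlo
   permutation test asks whether a family's predicted targets are
   over-represented in each characteristic gene set; families are ranked by
   summed −log10 p across intervals.

Every stage is exercised end to end on a bundled ground-truthed synthetic
data generator, so the whole pipeline is testable without any external
download.

# The synthetic-data generator

The generator emulates the study design, not any particular dataset: it
plants known temporal structure and known miRNA targeting, then asks the
pipeline to recover it.

## Latent temporal archetypes

Each gene is assigned (deterministically, by largest-remainder
apportionment of the configured fractions; default 25% each) to one of four
archetypes with baseline mean $b$ and effect size $E$ (default 2):

* **Null**: $\mu(t) = b$.
* **Transient**: $\mu(t) = b\,(1 + E\,e^{-(t-p)^2 / 2w^2})$, a Gaussian
  pulse with peak time $p \sim U(3, 6)$ h and width $w \sim U(0.8, 1.3)$ h.
  The pulse effectively vanishes at $t = 0$ and $t = 24$ h.
* **Induced**: $\mu(t) = b\,(1 + E\,s(t))$, with $s$ a Hill rise
  (coefficient 2, half-time $\sim U(2, 8)$ h) normalized so $s(24) = 1$:
  the latent relative change at the final timepoint equals $E$ exactly.
* **Repressed**: a fast exponential drop (time constant 0.6 h) toward
  $b/(1+E)$ — log-symmetric with the induced maximum — followed, after a
  2 h lag, by partial recovery of a fraction $r$ of the drop. A fraction of
  repressed genes (default 30%) receives $r$ such that the trajectory
  settles at a new lower plateau (a "GATA3-like" drop-then-recover
  profile, e.g. recovering to 60% of time-zero expression); the remainder
  are monotone ($r = 0$).

Two interpretation choices deserve a note. First, *effect size* is the
maximum **relative change**, so an induced gene tops out at $(1+E)\,b$;
the planted master miRNA instead uses a **ratio** parameter (default 6: its
latent 24 h level is exactly six times baseline), because that is the
natural scale on which an induced miRNA's fold change is read. Second, the
repressed archetype is written with an explicit drop term so that
$\mu(0) = b$ exactly (a trajectory discontinuous at $t=0$ would be
unphysical) while keeping the plateau at $b\,(1 - a(1-r))$ for amplitude
$a$.

Baselines default to 2000 expected counts. This is deliberate: the
abundance filter operates on the *series mean*, and a twofold-repressed
gene spends most of the time course near half its baseline, so responsive
genes must be abundant for the filter to behave as intended — which matches
the biology the design emulates, where the canonical repressed genes
(*ESR1*, *GATA3*, *ZNF217*) are highly expressed.

## Counts, library depth, and miRNAs

Counts are drawn independently per gene and sample from an NB distribution
with $\mathrm{Var} = \mu + \alpha\mu^2$ ($\alpha = 0.05$ by default, a
typical bulk RNA-seq scale; $\alpha = 0$ falls back to Poisson). Per-sample
library size factors are log-normal(0, 0.15) multipliers so that size-factor
estimation is non-trivially exercised. All draws descend from a single
master seed through labelled stream derivation (`derive_seed()`), so a
configuration reproduces its dataset bit for bit.

miRNA baselines are log-normal around the configured mean; the first
`n_master_mirnas` follow the induced archetype. Note that observed RPMM
fold changes of the master sit somewhat **below** the latent ratio (about
5 rather than 6 with 30 miRNAs): RPMM is compositional, and the master's own
rise inflates the library total it is normalized by. This is a property of
the normalization, not a bug, and affects real small-RNA data equally.

## UTRs and planted seed sites

Background 3′-UTRs are i.i.d. uniform ACGT, rejection-sampled so that *no*
8mer, 7mer-m8 or 7mer-1A match to *any* configured family occurs anywhere
(scrubbing the two 7-mer patterns suffices, since an 8mer contains a
7mer-m8). Each planted target gene then receives 8mer sites of the master
family at recorded positions; planting is redone if the insertion creates a
junction artifact. A Markov-model background was considered and rejected:
uniform composition is sufficient for recovery tests and keeps the
rejection sampler simple. Unscrubbed backgrounds (`random_utrs()`) are used
where natural site frequencies are wanted, e.g. null calibration of the
permutation test.

Planted target genes also carry a larger effect amplitude (default boost
1.5×). The generator must plant the phenomenon the enrichment stage is
meant to detect — master-miRNA targets over-represented among the genes
that *drive* interval-to-interval expression change — and with equal
amplitudes a target would be no more likely than any other responsive gene
to enter a characteristic set.

# Stage-by-stage notes and numerical choices

## Differential expression

The DE backend is deliberately self-contained rather than delegated to a
heavyweight framework: size factors are the classical median-of-ratios over
genes positive in all samples (rescaled to geometric mean 1), dispersion is
a per-gene method-of-moments estimate
$\hat\alpha = \max(10^{-8}, (s^2_{\text{within}} - \bar x)/\bar x^2)$
pooled across all timepoint groups, and each timepoint is compared with
time zero by a Wald statistic whose standard error uses the NB variance
function at the pooled (null) group mean. Two small-sample choices matter
at $n = 3$ replicates:

* the variance is evaluated at the **pooled** mean of the two groups (a
  score-test flavour), which removes most of the plug-in noise a
  per-group evaluation would add;
* inside `de_table()` the per-gene dispersions are moderated toward the
  across-gene median with weight 0.3. Simulation at the default design
  (2000 null genes) puts the null fraction of $p_{\text{raw}} < 0.05$
  within three binomial standard deviations of 0.05, whereas raw per-gene
  estimates are mildly anticonservative.

Fold changes use a pseudocount of 0.5 normalized counts; all-zero genes
return the degenerate contract ($p = 1$, log2 fold change 0) rather than
being dropped, so matrix shapes are stable. BH adjustment is applied within
each timepoint contrast, not across contrasts. The abundance filter's mean
is taken over all 30 samples (the plausible alternative — per-condition
means — is configurable via the threshold argument but not the default).

## Temporal clustering

The clustered signal is the per-gene log2 fold-change trajectory versus
time zero (replicate means, pseudocount 0.5), standardized to unit maximum
absolute value per gene — the classes are defined by *shape*, not
amplitude. Trajectories are PCHIP-interpolated onto a uniform hourly grid
(25 points, 0–24 h); PCHIP is shape-preserving, so no overshoot between
knots. The wavelet transform is a hand-implemented periodized orthonormal
Daubechies-3 DWT taken to the conventional maximum depth
$\lfloor \log_2(n/5) \rfloor$; on even-length inputs it is exactly
orthonormal (Parseval to $10^{-9}$), and odd lengths at any level are
handled by repeating the last sample, which preserves exact
reconstruction. Coefficients are concatenated coarsest-first into a
fixed-length feature vector; Ward linkage (`ward.D2`) on Euclidean
distances is cut at $k = 3$. Cluster numbering is canonicalized by each
cluster's lexicographically smallest gene id, making the partition
invariant to input row order.

Cluster labels come from centroids on the *fold-change* scale (baseline 1
at $t = 0$): with start $b$, end $f$ and maximum $m$, a centroid is
repressed if $f < b(1-\delta)$, transient if $m > \max(b,f)(1+\delta)$,
induced otherwise ($\delta = 0.1$); a ranking fallback guarantees that the
three labels are always a bijection. The GATA3-like/anti analysis
correlates standardized trajectories against a drop-then-recover template
(default: the recovering subcentroid of the repressed class, obtained by a
2-way subcut) at $|r| \ge 0.7$.

## Characteristic directions

For consecutive timepoints the direction is
$b \propto (\gamma S + \lambda I)^{-1}(\mu_2 - \mu_1)$ on
$\log_2(\text{normalized} + 1)$ data, with $S$ the pooled within-group
covariance, $\lambda = (1-\gamma)\,\mathrm{tr}(S)/d$, $d$ the rank of the
within-group-centered data, and $\gamma = 0.5$ by default. The solve is
carried out in the sample-spanned subspace plus an explicit orthogonal
complement term, so it is *exactly* the dense gene-space solution at
$O(\text{samples}^3)$ cost; a dense brute-force oracle in the test suite
confirms cosine agreement beyond 0.999. The vector is unit-norm and
oriented along the mean change, which makes it antisymmetric under group
swap. Characteristic sets default to the smallest b²-ranked prefix holding
half the coefficient energy ($\theta = 0.5$); a fixed-size `top_n` rule is
available and is the natural choice when comparing against a planted set of
known size. A per-interval low-signal flag marks
$\max_g b_g^2 < 3/n$; note this is conservative — under pure noise the
maximum normalized squared coefficient concentrates near $2\ln(n)/n$, which
exceeds $3/n$ for realistic $n$, so the flag fires only for coefficient
spectra much flatter than noise itself produces.

## Target enrichment

Families are keyed by mature nt 2–8; family expression is the best member's
mean RPMM (sum optional) with a 50-RPMM floor. The scanner recognizes the
three canonical site classes on the UTR (5′→3′, DNA alphabet; RNA/DNA
conversion happens at the scanner boundary): 7mer-m8 = reverse complement
of nt 2–8, 7mer-1A = reverse complement of nt 2–7 followed by A, 8mer =
7mer-m8 followed by A. An 8mer is reported once and suppresses the two
7mers it contains; overlapping distinct sites are all reported; 6mer sites
are excluded as a weak class. Scores are either the number of set genes
with ≥ 1 site (binary, default) or the total site count.

The null model draws `n_perm` random gene sets of the observed size from
the expressed-gene background (optionally stratified by UTR-length decile;
off by default) and uses the add-one estimate
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$, so $p > 0$ always
and $-\log_{10} p$ is finite. Null sets are drawn once per interval and
scored against every family simultaneously, which keeps the matrix
computation linear in `n_perm`. Conservation weighting and the
network-hub component of the original master-regulator algorithm are
**not** re-implemented — they require multi-species alignments and
interaction networks — so the score here is a site-presence statistic that
preserves the decision structure (observed score versus size-matched
random-set null, summed significance across intervals) but not the full
original scoring. Rankings sum $-\log_{10} p$ across intervals with
lexicographic tie-breaking.

# What the synthetic tests do and do not show

The generator produces independent NB noise, a single condition, equal
class sizes, and scrubbed UTR backgrounds. Passing recovery tests
demonstrates that the *logic* of each stage is correct — filters implement
their definitions, clustering separates the planted shapes, the direction
matches its dense definition, the permutation test is calibrated on
natural-frequency backgrounds and detects planted targets. It does not
demonstrate robustness to features real data have and the generator lacks:
correlated genes, batch effects, isomiR complexity, GC/length-biased
counting, overlapping or ambiguous temporal shapes, and UTR sequence
composition structure. Printed gene counts from any particular real
dataset (how many genes pass the filters, how many targets a family has)
are data-dependent and are not reproduced by construction.

# Problem sizes used in the checks

The bundled checks run at the design scale the package targets: 600 genes
(150 per archetype) × 30 samples for filter and clustering recovery; 50
repeated designs with 21 families and 30 planted targets at 1000
permutations for master-regulator recovery; 200 null simulations at 300
permutations for calibration; 1000 random 200-nt UTRs × 50 families for
scanner/oracle equality. These sizes give stable pass/fail behaviour for
the thresholds quoted in the tests while remaining comfortably runnable on
a laptop.

# Known limitations

* The NB test is a two-group Wald test per timepoint; it shares information
  across genes only through the dispersion moderation, not through a trend
  or shrinkage of fold changes.
* The characteristic-set threshold ($\theta$) has no principled default;
  0.5 is a convention, and downstream target lists change with it.
* RPMM fold changes are compositional (see above); strongly induced miRNAs
  depress the apparent fold of everything else.
* The enrichment null controls set size (and optionally UTR-length decile)
  but not sequence composition; on composition-biased UTR sets the
  empirical p-values inherit that bias.
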