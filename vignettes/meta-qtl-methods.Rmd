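---
title: "Methods: meta-QTL condensation and the candidate-gene funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-QTL condensation and the candidate-gene funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical model behind `mqtlkit`, the
choices made where the method leaves room, and what the synthetic-data
generator does and does not emulate.

## 1. Confidence-interval standardization

Published QTLs rarely report comparable intervals, so the package
derives each QTL's 95% CI width from the mapping design. With
population size $N$ and the QTL's phenotypic variance explained $R^2$:

$$CI = \frac{530}{N R^2} \;\; (\mathrm{F2,\ F2{:}3,\ BC}), \qquad
  CI = \frac{163}{N R^2} \;\; (\mathrm{RIL,\ BIL}), \qquad
  CI = \frac{97.462}{(N R^2)^{0.835}} \;\; (\mathrm{DH}).$$

The assignment of population types to the three formulas follows the
population-specific CI literature (early-generation crosses have the
widest intervals at a given $NR^2$, doubled haploids a sub-linear
decay); it is exposed through `ci_formula_map()` so users can remap
types. Reported intervals are kept when present
(`policy = "prefer_reported"`); formula-derived intervals are placed
symmetrically about the peak. Rows without $R^2$ are rejected (the
standardization cannot proceed without it); rows without LOD are kept,
as LOD enters no downstream computation.

## 2. Consensus map and projection

Maps are merged chromosome-wise. The map with the most markers anchors
the frame; every other map is rescaled onto the accumulating consensus
by a **Theil–Sen** line through the shared markers, and each marker's
consensus position is the running mean of its rescaled observations.
The robust fit matters: a least-squares line through shared markers
would let a single discordant marker tilt the whole frame, whereas the
median-slope fit reproduces the identity transform whenever a majority
of shared markers agree. Order conflicts are resolved by majority: the
largest order-consistent subset (longest increasing subsequence) of the
incoming map's markers is kept and the conflicting observations are
dropped with a warning. This rescaled-mean merge deliberately replaces
the linear-programming consensus used by dedicated map-merging tools —
it is deterministic, dependency-free, and honours the same contract
(order-valid consensus positions, averaged coordinates); it is a
deviation in mechanism, not in contract.

Projection maps a QTL's peak and CI bounds through the affine transform
of the nearest pair of shared markers bracketing the peak,
$x' = L' + (x - L)\frac{R' - L'}{R - L}$. Peaks outside the shared span
extrapolate with the nearest interval's slope up to 5 cM (configurable)
beyond it; farther peaks are excluded with a warning, because silent
long-range extrapolation would corrupt the mixture input. The projected
positional standard deviation is $s = CI_{95}/3.92$, the two-sided
Gaussian convention; the method sources never state the CI-to-variance
conversion, and this is the standard reading for a 95% interval.

## 3. The mixture model

On each chromosome the projected peaks $x_i$ are modeled as draws from
$K$ consensus loci:

$$\ln L = \sum_i \ln \sum_{k=1}^{K} \pi_k\,\phi(x_i;\,\mu_k,\,s_i^2),$$

with the per-observation variances $s_i^2$ **known** from the projected
intervals. Only the means and proportions are free, so $p = 2K - 1$.
EM alternates the posterior responsibilities
$r_{ik} \propto \pi_k \phi(x_i; \mu_k, s_i^2)$ with the weighted
updates $\mu_k = \sum_i r_{ik} x_i / s_i^2 \big/ \sum_i r_{ik}/s_i^2$
and $\pi_k = \frac1n \sum_i r_{ik}$. Numerical choices: the E-step is
computed in log space with log-sum-exp; responsibilities are floored at
$10^{-300}$; convergence is $|\Delta \ln L| < 10^{-8}$ with a 2000
iteration cap; 20 initializations per $K$ start from quantile-spread
means with Gaussian jitter (the first start unjittered; $K=1$ needs a
single start, its fixed point being the closed-form inverse-variance
mean). The best-likelihood run is kept and the log-likelihood is
monotone within $10^{-10}$ every iteration — this is asserted by tests
on every fitted trace.

### Model selection

For candidate counts $K = 1..K_{max}$ the five criteria are, with
$D = -2\ln L$ and $n$ observations:

* $AIC = D + 2p$
* $AICc = AIC + 2p(p+1)/(n-p-1)$ (reported $+\infty$ with a warning
  when $n \le p+1$)
* $AIC3 = D + 3p$
* $BIC = D + p\ln n$
* $AWE = -2\ln L_c + 2p(3/2 + \ln n)$, where
  $\ln L_c = \ln L + \sum_{ik} r_{ik}\ln r_{ik}$ is the completed-data
  log-likelihood ($0\ln 0 \equiv 0$). AWE is named without a formula in
  the meta-QTL literature we follow; the classification-likelihood form
  used here is Banfield–Raftery's.

Each criterion votes for its minimizing $K$; a $K$ holding at least
three of the five minima wins. When no $K$ reaches three, the most
minima win, and remaining ties go to the smallest $K$ — parsimony is
the natural tie-break for a locus count. Chromosomes with $n \le 10$
QTLs search $K \in \{1,\dots,\min(4, n)\}$; larger ones
$K \in \{1,\dots,\min(\lceil n/2 \rceil, 12)\}$. The small-$n$ regime
unifies what older two-algorithm implementations treat separately: the
same mixture with a conservative $K_{max}$, still under multi-criterion
selection.

### Membership and MQTL summaries

A QTL joins a component only if (i) its membership probability exceeds
0.60 strictly and (ii) its peak lies inside the component's pooled 95%
CI. The sources state both rules without saying whether both must hold;
the package takes the stricter conjunctive reading, and reports — never
drops — unassigned QTLs. The peak-in-CI check is iterated to a
fixpoint, trimming the farthest outlier one at a time before re-pooling
so that a distant peak cannot drag the consensus CI off every genuine
member. An MQTL's peak is the responsibility-weighted inverse-variance
mean, its variance $1/\sum_i r_i/s_i^2$, its CI peak $\pm 1.96$ sd;
with $m$ comparable members the MQTL CI shrinks like $1/\sqrt m$, which
is the CI-reduction property the tests assert on every simulated
chromosome. MQTLs are named `MQTL<chr>.<rank>` by position, a format
choice (the convention in the literature is "named by chromosomal
location" without a printed format).

The QTL-overview index tiles each chromosome into 0.5 cM bins; QTL $i$
contributes $\Phi((b-x_i)/s_i) - \Phi((a-x_i)/s_i)$ to bin $[a,b)$ and
the bin index is the mean contribution, so each QTL carries at most
unit mass.

## 4. GWAS validation

MQTL windows are peak ± 0.5 Mbp in physical coordinates (1-based,
inclusive). The anchor is the member flanking marker with a known
physical position whose consensus genetic position is nearest the MQTL
peak, preferring higher-membership members — the sources do not say
which marker realizes "the peak position" in bp, and the nearest
anchorable flanking marker is the least-extrapolated choice. An MQTL is
validated when at least one association with $-\log_{10}(p) \ge 5.0$
(inclusive, matching the printed "≥") falls inside the window
(boundaries inclusive). The production overlap uses interval trees
(`GenomicRanges`); tests verify exact agreement with a brute-force
double loop including boundary and threshold-equal cases.

## 5. The candidate funnel

Genes overlap a window under an any-overlap rule (`containment =
"any"`; "located within" is not defined for partial overlap in the
sources, and any-overlap is the inclusive reading — `"full"` is
available). DEGs require $|\log_2 FC| \ge 1$ (inclusive) and
$FDR < 0.05$ (strict), with the union taken over contrasts. Expression
profiles (replicate-averaged FPKM per genotype × timepoint,
standardized per gene to zero mean and unit variance, zero-variance
genes removed) are clustered by fuzzy c-means with fuzzifier $m = 2$;
memberships follow the classic update
$u_{ij} = 1/\sum_l (d_{ij}/d_{il})^{2/(m-1)}$, a profile coincident
with a center takes membership 1 there, and centers are seeded from a
k-means pass (10 restarts) — random-membership starts are available,
but the k-means seeding is far more reliable for well-separated
temporal shapes. The per-iteration objective is non-increasing and the
implementation is cross-checked against `e1071::cmeans` in the tests.
The default cluster count is 9 (the value used on the real 3851-gene
set this workflow mirrors); it is a parameter, and the desk-scale
simulations in the tests use the number of planted profile shapes
(4–5), since forcing more clusters than shapes onto a few dozen genes
splits the signature group arbitrarily.

The signature cluster maximizes (mutant slope − wild-type slope) with
mutant slope > 0 and wild-type slope < 0, slopes being least-squares
trends of the cluster's per-genotype mean profile over the 0/3/6-day
timepoints; genes are attributed to clusters by maximum membership
≥ 0.5. Promoters follow the annotation rule: 2000 bp upstream of the
ATG down to the TSS, or 1500 bp upstream of the ATG down to the 5'UTR
start when the 5'UTR exceeds 100 bp; minus-strand promoters are
reverse-complemented, and regions are clipped at chromosome ends with a
warning. Motif scanning is exact IUPAC-degenerate matching on both
strands, with subject `N` never matching. The motif catalog (ABRE
`ACGTG`, DRE core `RCCGAC`, MBS `CAACTG`, MYC `CANNTG`, ARE `AAACCA`,
W-box `TTGACC`, as-1 `TGACG`, G-box `CACGTG`) ships as an editable
table: only the G-box core is printed in the sources; the others follow
standard plant CRE catalogs. A gene becomes a DECG iff it sits in the
signature cluster and its promoter carries at least one ABRE hit.
`cre_enrichment()` additionally reports a one-sided binomial presence
test against a shuffled-promoter background; the sources name
"significantly enriched" elements without a test, so this screen is a
stand-in, not a reproduction.

## 6. What the generator emulates — and what it does not

The generator plants true loci and draws each study's re-detection of
them: peak $\sim N(\text{locus}, s^2)$ where $s$ is drawn from
`s_range` (default 0.5–2 cM) and the QTL's $(N, R^2)$ are back-solved
from the population-class formula so the compendium is exactly
formula-consistent. Study maps share anchor markers (5 cM spacing,
jitter sd 0.25 cM, 10% interior dropout); physical coordinates couple
to genetic ones at 250 kb/cM so windows and genes co-locate
predictably. GWAS panels plant 1–2 significant SNPs in a configured
fraction of true windows over sub-threshold background. Gene decoys
each violate exactly one funnel condition (in-window non-DEG;
out-of-window DEG; signature without ABRE, with the element scrubbed
from the promoter; ABRE without signature), giving every stage an
independent discriminating test; expression shapes are linear genotype
× time trends with Gaussian noise (default sd 0.3 FPKM).

What passing tests therefore show: the estimator recovers planted
component counts and positions, shrinks CIs, and the funnel's stages
discriminate their intended conditions. What they do not show: realism
of linkage-map error structure (only jitter and dropout are modeled),
LD structure in the GWAS panels (background SNPs are uniform),
sequence composition (genomes are i.i.d. uniform DNA), or
distributional realism of expression (no overdispersion, no
library-size effects). Headline counts from any real compendium
(numbers of QTLs, MQTLs, validated fractions, intersection sizes)
depend on that compendium and are outside what the simulations can
certify.

## 7. Problem sizes used by the tests

Mixture recovery runs one 120 cM chromosome with 3 loci × 20 QTLs over
20 replicate panels; funnel recovery uses one 40 cM chromosome (10 Mb
at 250 kb/cM) with two loci, six planted candidates and three decoys
per class, noiseless once and over 10 replicates at noise sd 0.3.
These sizes were chosen as the smallest at which the selection and
recovery behavior is stable and clearly interpretable.

## 8. Known limitations

* The consensus merge is order-majority based; with fewer than two
  shared markers per chromosome a map cannot be placed and is skipped.
* Membership trimming is greedy (one outlier at a time); pathological
  bimodal components could in principle stabilize on either mode.
* The AWE definition relies on the classification likelihood; other
  software may implement AWE variants, so criterion values are
  comparable within this package, not across tools.
* The CRE screen is presence-based; it does not model motif affinity
  or positional bias within the promoter.
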