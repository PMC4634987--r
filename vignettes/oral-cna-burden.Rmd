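---
title: "Methods: copy-number aberration burden in oral lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number aberration burden in oral lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralcna)
```

# Scope and model

`oralcna` implements an array-CGH copy-number workflow for cohorts of oral
potentially malignant disorders (OPMDs) and oral squamous cell carcinomas
(OSCCs), in which each patient contributes one or more involved oral mucosa
subsites, each subsite one or more biopsies, and each biopsy a probe-level
log2-ratio profile plus a flow-cytometric DNA-index (DI) label. The pipeline
runs from probe-level ratios to segment calls, focal/broad event
classification, cohort-level recurrent CNAs, patient-by-subsite burden
scores, and association tests against ploidy, histology and subsite.

The signal model is the standard clonality dilution of a two-color aCGH
ratio. If a fraction $\alpha$ of cells in a biopsy carries $q_t$ total
copies of a region on a background ploidy $D$, the expected ratio is

$$\log_2 \frac{\alpha q_t + 2(1-\alpha)}{\alpha D + 2(1-\alpha)}.$$

At $\alpha = 0.5$, $D = 2$, a hemizygous deletion ($q_t = 1$) gives
$-0.415$ and a single copy gain ($q_t = 3$) gives $0.322$; this motivates
the symmetric calling thresholds of $\pm 0.3$ used throughout
(`expected_log2()`, `call_segments()`). Comparisons with the thresholds are
inclusive ($\ge +0.3$, $\le -0.3$); the boundary convention is a package
decision, recorded here because the threshold sentence alone does not fix
it.

# Preprocessing

**Replicate averaging.** One value per probe, the arithmetic mean over
replicates (`average_replicates()`).

**Array QC.** The derivative log-ratio spread,
$\mathrm{dLRs} = \mathrm{IQR}(\Delta) / (1.349\sqrt{2})$ over consecutive
same-chromosome probe differences $\Delta$, estimates the per-probe noise SD
for iid Gaussian probes. Arrays with dLRs strictly above 0.35 are discarded;
an allowlist emulates the visual-inspection override used in practice for
borderline arrays (`qc_filter()`).

**Winsorization.** Per chromosome, residuals from the chromosome median are
clamped at $\pm k \cdot 1.4826 \cdot \mathrm{MAD}$ with $k = 2.5$
(configurable; the method names MAD winsorization but not $k$). On exactly
noiseless profiles the MAD can be zero and the clamp collapses to the
median, so noiseless segmentation fixtures in the test suite bypass this
step deliberately. On realistic noise levels the clamp tames single-probe
outliers while leaving event-level signal (which spans many probes) largely
intact.

**Segmentation.** The piecewise-constant fit minimizing
$\sum_i (y_i - \mu_{s(i)})^2 + \gamma B$, with $B$ the number of
breakpoints, solved *exactly* per chromosome by an $O(n^2)$ dynamic program
(`segment_pcf()`). The reference penalty is $\gamma = 40$. The scale on
which a penalty of that magnitude applies is ambiguous — raw log2 residuals
or noise-normalized ones — so both are supported; the default divides the
profile by its dLRs estimate first (floored at $10^{-3}$ to keep noiseless
synthetic profiles finite), which makes $\gamma$ noise-scale-free and
matches common practice for penalties of this magnitude. The DP is
validated against an independent exhaustive search over all breakpoint
subsets (`pcf_exhaustive()`, compiled); both must agree on every fixture.

# Event classification and recurrence

Called regions are split at the centromere; an arm piece covering more than
half its arm is a *broad* event, labelled at arm resolution ("8q gain"),
otherwise a *focal* event annotated with every cytoband it overlaps. A
region is either broad or focal by this length rule — never both. This is a
declared simplification of GISTIC2.0, whose arbitrated ziggurat
deconstruction can assign a region to both analyses; the divergence is
intentional and documented here.

Cohort-level recurrence (`recurrent_cnas()`) is a frequency-and-amplitude
G-score in the GISTIC spirit without the full model: per marker (cytoband
for the focal analysis, arm for the broad analysis) and direction,
$G = \sum_s \max(0, |A_{ms}| - 0.3)$ over sample amplitudes $A$ projected
from segment means. The null preserves each sample's spatial
autocorrelation by cyclic shifts of its marker amplitudes (within
chromosome for bands, genome-wide for arms); independent shuffling is a
config option. Empirical p-values receive Benjamini-Hochberg q-values per
analysis; focal markers are retained at $q < 0.25$ and broad at $q < 0.3$,
the retention cutoffs of the original selection.

# Statistical units and burden scores

All biopsies of one subsite of one patient form a statistical unit:
histology collapses to the most severe diagnosis
(ND-OPMD $<$ D-OPMD $<$ OSCC; graded dysplasia collapses to D-OPMD), and a
single aneuploid biopsy suffices to label the unit aneuploid. DI values are
continuous, so "DI $\ne$ 1" is operationalized as $|DI - 1| \ge 0.05$
(configurable). Burden scores count each affected unit once: TFG/TFL are
the numbers of distinct cytobands hit by at least one focal gain/loss in
any biopsy; TBG/TBL count distinct broad arm-regions, keyed by (arm,
direction) — partial-arm broad events on the same arm and direction are the
same region, matching arm-level labels such as "8q gain".

# Association machinery

* `fisher_2x2()` — two-sided p by the sum-of-smaller-or-equal-probabilities
  convention (this convention, and not e.g. the doubling rule, reproduces
  the published contingency rows to 4 decimals). The odds ratio is $ad/bc$
  with Haldane-Anscombe $+0.5$ on all cells when any cell is zero, CI by the
  Woolf logit method; the upstream report prints OR/CI without naming a
  method, so this is a package decision.
* `breslow_day()` — classic homogeneity statistic against the
  Mantel-Haenszel common OR, optional Tarone correction.
* `mann_whitney()` — exact by enumeration for small untied groups, else
  normal approximation with tie and continuity corrections.
* `cohens_kappa()` — marginal-product expected agreement.
* `bh_qvalues()` — step-up with an explicit family size $m$ that may exceed
  the number of supplied p-values. Family sizes are always explicit plan
  parameters: the published aneuploidy-by-histology legend states $n = 4$
  while its printed q-values reconstruct exactly under $m = 3$, so nothing
  is inferred from the data.
* `carlson_fdr()` — discrete FDR for families of 2x2 tables: expected null
  discoveries are summed from each table's own hypergeometric null, and
  tables whose minimum attainable p exceeds `alpha_cap` (default 0.05; the
  original cap is unpublished) are provably irrelevant and filtered from
  the family. Discrete q-values may legitimately fall below their p-values;
  they are never above the corresponding BH q-values.

`run_association_suite()` composes these into the study's table layout:
CNA presence vs ploidy within histology strata, vs histology group, vs
TNG/BM subsite (each a discrete-FDR family), and Mann-Whitney comparisons
of TFG/TBG/TFL/TBL (BH families of size 4), flagged at $q < 0.1$.

# The synthetic cohort: what it emulates

No per-sample raw arrays are shipped; `generate_cohort()` provides a stated
world with known ground truth. Its defaults are fixed once from the
published cohort structure and are not tuned:

* subsite mix and per-subsite histology frequencies from the cohort's
  biopsy table (522 biopsies over 7 subsites);
* biopsies per subsite $1 + \mathrm{Pois}(0.58)$ (522 biopsies / 331
  subsites) and extra involved subsites per patient at rate 0.13 (331/292);
* aneuploidy probability by histology 0.15 / 0.40 / 0.60 (ND-OPMD /
  D-OPMD / OSCC), with a tongue-subsite odds multiplier of 4 reflecting the
  reported TNG enrichment (ORs near 5);
* somatic event rates 0.4 / 1.5 / 3 per biopsy by histology, tripled in
  aneuploid biopsies; 60% focal (1-3 contiguous cytobands), 40% broad
  (whole arm or 55-95% of an arm);
* integer copy states: gains $q_t \in \{3,4,5\}$ w.p. $\{.5,.35,.15\}$,
  losses $q_t \in \{1,0\}$ w.p. $\{.85,.15\}$ — single-copy changes
  dominate, with occasional amplification/homozygous loss;
* cancer cell fraction $\alpha \sim U(0.4, 0.8)$ per biopsy, constant
  across that biopsy's events (one dominant clone; subclonal mixtures are
  out of scope);
* DI labels are drawn from the histology-conditioned probabilities, not
  computed from simulated histograms (flow cytometry itself is out of
  scope); aneuploid magnitudes are $U(1.1, 2.2)$ — the true DI values of
  the aneuploid sublines are unpublished, so these magnitudes are
  arbitrary by necessity;
* probe noise $N(0, 0.15^2)$ per probe with 1% outliers at SD 1.

What the generator does **not** emulate: hybridization chemistry, dye bias,
GC waves, replicate feature-level files, and germline CNVs. A green test on
synthetic data therefore establishes correctness of the computational
pipeline under the dilution model, not robustness to array artifacts the
model excludes.

# Numerical choices and degenerate inputs

* dLRs divisor floored at $10^{-3}$ before segmentation normalization.
* DP tie-breaks favour the earliest minimizing segment start (strict `<`
  update); cost equality with the exhaustive reference is the invariant,
  not breakpoint identity.
* Permutation p-values use the add-one estimator $(1 + \#\{G^* \ge G\}) /
  (n_{perm} + 1)$, so no p is ever zero.
* Empty margins make a 2x2 test undefined: such tables are skipped and
  reported with `NA` rather than silently dropped; a fully discarded cohort
  propagates empty tables through the pipeline without error.
* A fully clonal homozygous deletion returns $-\infty$ from
  `expected_log2()` as a sentinel.

# Known limitations

* The recurrence stage is deliberately simpler than GISTIC2.0; absolute
  G-scores are not comparable to GISTIC scores, only the retention logic
  (separate focal/broad analyses with q cutoffs 0.25/0.3) mirrors it.
* Winsorization against the chromosome median can shrink genuine
  high-amplitude focal events on otherwise quiet chromosomes; running-median
  alternatives are not implemented.
* Mixed 105K/180K designs are represented only through their shared-probe
  intersection; design-specific effects are not modelled.
* Headline cohort results that depend on the unreleased per-sample raw data
  (e.g. the exact set of 80 recurrent CNAs) are not reproducible at desk
  scale; the package reproduces every printed self-contained statistic and
  validates the machinery by simulation instead.
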