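---
title: "Estimating linkage disequilibrium from non-random samples: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating linkage disequilibrium from non-random samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldnr)
```

## The problem

The coefficient of linkage disequilibrium between two biallelic loci — a
marker with alleles $M/m$ at frequency $p$ and a disease locus with alleles
$A/a$ at frequency $q$ — is defined on the gamete scale as
$D = g_{11} - pq$, where $g_{11}$ is the population frequency of the $M\!A$
gamete. Feasibility of the four gamete frequencies constrains $D$ to

$$\max(-pq,\,-(1-p)(1-q)) \;\le\; D \;\le\; \min(p(1-q),\,(1-p)q),$$

implemented in `d_bounds()` (and, shifted by $pq$, `g11_bounds()`).

The classical estimator for unphased genotype data (here *Method H*, for
Hill) maximizes the likelihood of the full $3\times 3$ marker-by-disease
genotype table under random union of gametes, resolving the phase ambiguity
of double heterozygotes by EM "chromosome counting" (`em_g11()`), or
equivalently by solving a cubic score equation (`cubic_g11()`). It assumes
the individuals are a random sample of the population. Real samples rarely
are: genotype classes get excluded by design, and case-control panels fix
the number of disease-allele carriers a priori.

This package implements a conditional-likelihood estimator (*Method L*)
that instead models the distribution of the disease genotype **given** each
marker genotype. Writing $Q = P(A \mid M\text{ gamete}) = (pq+D)/p$ and
$R = P(A \mid m\text{ gamete}) = ((1-p)q - D)/(1-p)$, random mating gives
row-wise conditional probabilities

| | $AA$ | $Aa$ | $aa$ |
|---|---|---|---|
| $MM$ | $Q^2$ | $2Q(1-Q)$ | $(1-Q)^2$ |
| $Mm$ | $QR$ | $Q+R-2QR$ | $(1-Q)(1-R)$ |
| $mm$ | $R^2$ | $2R(1-R)$ | $(1-R)^2$ |

(`conditional_probs()`; the identities $pQ + (1-p)R = q$ and
$D = p(1-p)(Q-R)$ are enforced as tested invariants). The log-likelihood is
$\ell(D) = \sum_{ij} n_{ij}\log f_{ij}$ with $p,q$ supplied externally, and
`mle_D_conditional()` maximizes it over the feasibility interval. Because
each row's contribution is invariant to how many individuals of that row
were sampled, excluding (or enriching) whole marker classes does not move
the maximizer — the core robustness property.

Significance is assessed by $\Lambda = 2\{\ell(\hat D) - \ell(0)\}$,
asymptotically $\chi^2_1$, with `lod = lambda / (2 ln 10)` (`lrt_lod()`).

## A structural fact that shapes the whole package

With the *same* plug-in $(p, q)$, the joint likelihood factorizes exactly as

$$ P_{ij} = w_i(p)\, f_{ij}, \qquad w(p) = (p^2,\, 2p(1-p),\, (1-p)^2), $$

so joint and conditional log-likelihoods differ by the marker-margin term
$\sum_i n_{i\cdot}\log w_i(p)$, which does not involve $D$. Consequently
**Methods L and H coincide whenever the maximizer is interior and in
bounds**. (This factorization is itself a tested cross-module invariant.)
The two methods genuinely diverge only through

1. **frequency sources** — which $(p, q)$ each method is given, and
2. **boundary behavior** — the joint EM fixed point can leave the feasible
   interval when the supplied $(p,q)$ are inconsistent with the sample (the
   hallmark failure on case-control data), while the conditional estimator
   is constrained to the bounds by construction.

This fact drives several reproduction choices below; it also means the
"robustness" of the conditional route is inseparable from supplying
frequencies that are themselves undistorted (survey values, or control-only
counting for $p$).

## Sampling designs emulated by the simulator

* **Scheme I** (`sample_scheme1()`): $n$ individuals multinomial on the
  joint table. Emulates a true random sample.
* **Scheme II** (`sample_scheme2()`): one marker genotype row
  (`"n1." / "n2." / "n3."`) or one diagonal marker-disease cell
  (`"n11" / "n22" / "n33"`) is excluded and sampling continues to quota.
  Implemented as a multinomial on the renormalized table, which is
  distributionally identical to rejection sampling (a rejection-mode
  implementation is kept and the equivalence is tested by chi-square
  agreement). Emulates genotype-class ascertainment.
* **Scheme III** (`sample_scheme3()`): fixed numbers of cases (disease
  genotype $AA$ or $Aa$, split $q^2 : 2q(1-q)$) and controls ($aa$); marker
  genotypes are drawn per gamete with $P(M\mid A) = g_{11}/q$ and
  $P(M \mid a) = g_{12}/(1-q)$ — exact conditional sampling with no
  rejection even for rare diseases. Emulates case-control designs.

Frequency estimation follows the design (`estimate_freqs()`): allele
counting on the full sample for Schemes I/II; for Scheme III, $p$ from the
controls only and $q$ either fixed at the population ("survey") value or
counted from the pooled sample. `replicate_study()` repeats
sample–estimate–test cycles with per-replicate seeds derived once from a
base seed, so studies are exactly reproducible.

What the generator does **not** emulate: genotyping error, population
stratification, missing data, multi-locus haplotype structure. A green
simulation test therefore establishes correctness of the estimator under
the stated sampling model, not robustness to those additional realities.

## Choices made where the design was open

**Frequency recipe for the bias tables.** Because of the factorization fact,
the published Scheme I/II contrast between the methods is reproducible only
if Method L is given the *survey* (true simulated) frequencies while Method
H uses sample allele counting; with a common $(p,q)$ the two estimators are
identical. `replicate_study(l_freqs = "survey")` selects that recipe (the
default `"scheme"` keeps the allele-counting contract for both). Under the
survey recipe our replications match the published Scheme II table cell by
cell at print precision, including the directional biases of Method H
(underestimation when marker heterozygotes are missing, severe
underestimation for diagonal-cell exclusions) and of Method L under
cell exclusions (which distort the conditional rows themselves — the
conditional estimator is provably unbiased only for whole-row exclusion).

**LOD units.** The package reports the standard
$\mathrm{LOD} = \Lambda / (2\ln 10)$. The power tables we reproduce print
values exactly a factor $\ln 10$ smaller — consistent with a likelihood
ratio computed in $\log_{10}$ units being divided by $2\ln 10$ once more.
The identification is numerical: across an 8-fold range of sample sizes
and five case:control ratios, our means divided by $\ln 10$ agree with the
printed ones to about 1% (e.g. 9.58 vs 9.560 at $n=400$; 18.96 vs 18.948 at
$n=800$). Functions therefore expose `lambda` (in nats, $\chi^2_1$
calibrated — use this for p-values) alongside `lod`; the acceptance script
converts to the printed scale via $\Lambda/(2\ln^2 10)$ where a printed
value is the comparison target.

**Case:control ratios.** The printed power-versus-proportion table labels
columns "c:c" without defining the order. Matching our simulations to the
printed values identifies the "1/4:3/4" column as 150 cases : 50 controls
(2.25 vs printed 2.275 for 50 cases; 7.36–7.62 vs printed 7.616 for 150
cases, with matching standard deviations), i.e. the ratio reads
control:case and the LOD *increases* with the case proportion under
survey-$q$. The surrounding prose claims the opposite direction; we follow
the numbers.

**MLE algorithm.** The conditional score equation is a degree-5 polynomial
in $D$ whose coefficients are not available to us; rather than trusting a
transcription, `mle_D_conditional()` scans a 2001-point grid over the
(slightly shrunken, $\varepsilon = 10^{-9}$) feasibility interval, refines
every grid local maximum by bounded scalar optimization, and polishes
interior optima to a root of the analytic score via `uniroot`. The test
suite reconstructs the quintic numerator by exact polynomial interpolation
and checks the returned maximizer is a root. Ties within $10^{-10}$
log-likelihood are broken toward the smallest $|D|$ (conservative toward
the null). Cells with $f_{ij}=0$ but $n_{ij}>0$ make that $D$ infeasible
($\ell = -\infty$) rather than being clamped.

**Joint MLE.** The EM update is started at linkage equilibrium ($g_{11} =
pq$), tolerance $10^{-10}$, cap $10^4$ iterations. The cubic derived from
the fixed-point equation has leading coefficient $4n$ (the printed version
of this equation is internally inconsistent and was not used); its roots
coincide with likelihood stationary points exactly when $(p,q)$ are the
sample frequencies, so `mle_D_joint(mode = "strict")` additionally scans
the feasible interval and always returns the in-bounds maximizer.
`mode = "replication"` instead reports the raw EM fixed point with an
`out_of_bounds` flag — the behavior needed to reproduce (and demonstrate)
the joint method's failure on case-control data, where it can overestimate
a $D$ of 0.004 as ≈ 0.28, seventy-fold outside its bounds.

**Degenerate inputs.** Monomorphic loci ($p$ or $q \in \{0,1\}$) collapse
the bounds to $\{0\}$; estimators return $\hat D = 0$ with a `degenerate`
flag instead of erroring, because monomorphic sites occur in scans.

**Profiling over $q$.** When no survey estimate of $q$ exists,
`q_profile()` evaluates $(\hat D, \mathrm{LOD})$ over a user grid and
recommends the LOD argmax. On noiseless (expectation) data the profile
peaks at the generating $q$; on sampled case-control data it is nearly
flat — $q$ and $D$ are weakly separated, and the argmax often drifts to
the low edge of the grid. The profile should be read as a sensitivity
display, not as a reliable point estimator of $q$.

## Worked example

```{r example}
set.seed(1)
pop <- ld_params(p = 0.5, q = 0.01, D = 0.004)   # rare disease allele
cc <- sample_scheme3(pop, n_case = 100, n_control = 100)
p_hat <- allele_freqs(cc$controls)[["p"]]

# conditional estimator, survey q
estimate_ld(cc$combined, p_hat, q = 0.01, method = "L")

# joint estimator in replication mode: escapes the theoretical bounds
estimate_ld(cc$combined, p_hat, q = 0.01, method = "H",
            h_mode = "replication")
```

## Known limitations

* Biallelic loci only; no $D'$ or other scaled measures beyond $r^2$.
* $p$ and $q$ are plug-ins, never jointly estimated with $D$; with
  case-control data the data alone identify only $(Q, R)$, so a wrong $p$
  rescales $\hat D$ by $p(1-p)$ — accurate external frequencies are a
  prerequisite, not a convenience.
* The $\chi^2_1$ calibration of $\Lambda$ is asymptotic and assumes $D=0$
  is interior to the parameter space; it is tested at the nominal level
  under Scheme I but is not exact for boundary-adjacent truths.
* No multiple-testing machinery in `ld_scan()` beyond a Bonferroni column.
* TSV input only; convert VCF upstream (genotype classes, not calls, are
  consumed).
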