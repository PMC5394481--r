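---
title: "Models and methods: fluctuation-assay inference and mutation-accumulation spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutassay)
```

# The mutant-count model

A fluctuation assay grows many replica cultures from small inocula to
$N_t$ cells and counts selection-resistant mutant colonies per culture.
Mutations arise at rate $\mu$ per cell division; a culture experiences
$D \approx N_t$ divisions, so the expected number of mutational events per
culture is $m = \mu D$. Each event founds a clone that keeps expanding
until plating, which produces the model's famous heavy tail.

**Clone sizes.** In an asynchronously, exponentially growing population a
mutation arising when the population has $n$ cells founds a clone whose
final size is geometric with mean $N_t/n$; since founding divisions are
uniform over growth, the founding fraction $u = n/N_t$ is uniform on
$(0,1]$ and the marginal clone-size law is the Lea–Coulson distribution
$P(S = s) = \int_0^1 u(1-u)^{s-1}\,du = \frac{1}{s(s+1)}$. With plating
efficiency $\varepsilon$ (the fraction of each culture actually assayed),
every mutant cell is plated independently, thinning each clone binomially:
$$q_j \;=\; \sum_{s \ge \max(j,1)} \frac{1}{s(s+1)}\binom{s}{j}
\varepsilon^j (1-\varepsilon)^{s-j}, \qquad
q_0 = 1 + \frac{\varepsilon \ln \varepsilon}{1-\varepsilon}.$$

**Counts.** The number of events is Poisson($m$) and clones contribute
independently, so the mutant count is compound-Poisson over $q$ and obeys
the Panjer recursion
$$p_0 = e^{-m(1-q_0)}, \qquad
p_n = \frac{m}{n}\sum_{j=1}^{n} j\,q_j\,p_{n-j}.$$
At $\varepsilon = 1$, $j q_j = 1/(j+1)$ and this is exactly the
Ma–Sandri–Sarkar recursion $p_n = (m/n)\sum_{k<n} p_k/(n-k+1)$; the test
suite checks term-by-term agreement to $10^{-12}$ up to $n = 100$.

**Assumptions** (classical Lea–Coulson): mutants grow at wild-type rate,
no phenotypic lag, no death, no post-plating growth, no back mutation, and
a single mean $N_t$ per strain. None of these corrections is applied
anywhere in the pipeline.

## Numerical choices

- The infinite clone-size sum for $q_j$ is truncated adaptively; summation
  stops when a geometric bound on every remaining coefficient drops below
  `tail_tol` (default $10^{-9}$), and $q_0$ is checked against its closed
  form. The recorded `mass_deficit` of the truncated distribution is
  bounded by $1/(J+1)$ — the clone-size tail itself — because a plated
  count never exceeds its clone size. Truncation at $J = n_{\max}$ is
  exact for the pmf up to $n_{\max}$: $p_n$ consumes only $q_0 \dots q_n$.
- The recursion runs in linear space (stable for the $m \lesssim 10^2$
  range of real assays) in compiled code, together with its first and two
  derivatives in $m$, so likelihood, score and Hessian come from one pass.
- `estimate_m()` runs safeguarded Newton on the analytic score inside a
  sign-change bracket, with bisection fallback; convergence at relative
  step $10^{-8}$. All-zero counts give the boundary MLE $\hat m = 0$. A
  non-finite score (pmf underflow at absurdly large trial $m$) contracts
  the bracket instead of failing.
- `profile_ci()` inverts the likelihood-ratio statistic
  $2[\ell(\hat m) - \ell(m)] = \chi^2_{1,\text{level}}$ by bisection
  (relative tolerance $10^{-6}$). For all-zero counts the log-likelihood
  is linear, $\ell(m) = -n_c m (1-q_0)$, so the upper bound has the closed
  form $\chi^2_{1}/(2 n_c (1-q_0))$ and the lower bound is clamped to 0.
- `lrt_compare()` maximizes the one-parameter null (shared per-division
  rate, $m_i = \mu N_{t,i}$) on the analytic score between the two
  per-arm rate MLEs, then takes the best of the root and both endpoints;
  with identical inputs this makes the statistic exactly 0. Statistics are
  clamped at 0; both-arms-all-zero returns stat 0, $p = 1$.
- Fold effects are reported at full precision alongside a 2-decimal
  rounding, the display convention of antimutator effect columns; rates
  render as "2.2 (1.3, 3.4)" in units of $10^{-7}$ per division.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `epsilon` | fraction of culture plated | user input, no default in experiments | the selective-plating efficiency of an assay is protocol-specific and is not published for the canavanine assay; it must be supplied |
| `n_t` | mean CFU per culture (= divisions) | user input | inoculum is assumed negligible, so divisions $\approx N_t$ |
| `level` | CI confidence level | 0.95 | convention of the rate tables |
| `n_cultures` | replica cultures (simulator) | 24 | common bench practice; the estimator accepts any $n \ge 2$ |
| `min_depth` | depth must exceed this | 20 | ">20-fold coverage" read strictly: depth 21 passes |
| `vaf_low`, `vaf_high` | heterozygous window | 0.40, 0.60 | inclusive bounds; replaces manual heterozygosity review with a deterministic rule |
| `indel_denominator` | indel frequency denominator | `"scored"` | consistent with the substitution denominators; `"sequenced"` is available because the two published descriptions of the indel denominator disagree, and the choice is surfaced rather than silently reconciled |

# The synthetic generators

`simulate_cultures()` draws, per culture, $K \sim \mathrm{Binomial}(D,
\mu)$ mutational events, a uniform founding division for each, a geometric
clone size with mean $N_t/n_{\text{found}}$, and binomial plating. This is
the generative model above, simulated directly — it never touches the pmf
recursion, so it serves as an independent oracle for it.

A generation-synchronous doubling simulator was considered and rejected:
synchronous division forces clone sizes onto powers of two, giving
$q_0 = \sum_k 2^{-(k+1)}(1-\varepsilon)^{2^k} \approx 0.506$ at
$\varepsilon = 0.3$ versus the Lea–Coulson $0.484$ — a discrepancy around
ten Monte-Carlo standard errors at $10^5$ cultures, which would make the
simulator disagree with the distribution the inference assumes. Real
cultures divide asynchronously, which is the regime the Lea–Coulson law
describes, so the asynchronous simulator is both the faithful and the
testable choice.

`simulate_variant_table()` emulates the MA sequencing layer: a random
genome at specified composition (defaults: 12 Mb, 38% GC — yeast scale),
1-kb low-complexity mask windows (4%), per-class mutation counts Poisson
in rate × eligible unmasked bases, heterozygous records with
Poisson-distributed depth (default mean 200, within the 100–300× range of
the study design) and binomial read sampling around allele fraction 0.5,
plus planted strain-SNP and in-mask decoy records that the filter must
remove. Default class rates are calibrated so one
ultramutator-heterozygote genome accumulates ~1.7–1.8 thousand scored
mutations over ~20 generations, dominated by C→T/G→A with A→G/T→C and
C→A/G→T at roughly half that frequency. Ground truth (planted class
counts, decoy counts) always accompanies the output.

**What the generators do not emulate:** real sequencing reads (alignment
artifacts, strand bias, mapping error), context-dependent mutation rates
(trinucleotide signatures), clustered mutations, copy-number changes,
aneuploidy, mitotic recombination, or selection during colony growth.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated model, not robustness to upstream calling
artifacts.

# Filtering and classification

Filters apply in a fixed precedence — strain SNP, low coverage, masked,
VAF out of range, pass — so each record gets exactly one terminal flag and
re-filtering is idempotent. VCF positions are 1-based; BED masks are
0-based half-open; the conversion is internal and covered by tests.
Multi-allelic VCF lines are decomposed into biallelic records before
filtering. Substitutions collapse to pyrimidine-anchored pair labels
(G→A ≡ C→T/G→A), an involution under strand complement; insertions and
deletions are distinguished by allele-length difference with a shared
leading base; equal-length multi-base substitutions are reported and
excluded.

# Known limitations

- **CI coverage at very low $m$.** When $m \approx 0.1$ with 24 cultures,
  $e^{-24m} \approx 8\%$ of experiments see no mutants at all, and the
  all-zero 95% upper bound $\chi^2_{1,0.95}/48 = 0.080$ lies below such an
  $m$; those experiments can never cover. Profile-CI coverage at that
  operating point is therefore a little under 90% (the acceptance run
  reports it), although conditional on observing any mutant it is
  ~97%. This is a discreteness limit of the assay design, not of the
  estimator; at $m \gtrsim 1$ the effect vanishes.
- **LRT power at extreme rate contrast but tiny $m$.** Comparing
  $\mu = 10^{-7}$ against $5 \times 10^{-9}$-scale rates at $N_t = 2^{20}$
  with 24 cultures leaves only a couple of positive cultures of
  information; the median likelihood-ratio statistic sits below the 3.84
  threshold and power is ~40–50% (reported by the acceptance run). Power
  against such contrasts requires larger $m$ (bigger cultures) or more
  replicas, not a different test.
- Mutant fitness effects, phenotypic lag, and culture-to-culture $N_t$
  variation are outside the model (matching the published analysis, which
  uses one mean CFU per strain).

# Problem sizes used by tests and acceptance

Unit tests run clone-law and pmf checks up to $n = 10^4$, a $10^6$-draw
clone-size Monte Carlo, and $4 \times 10^4$-culture simulator
cross-checks. The acceptance suite uses the study-scale operating points:
$10^5$ cultures for the pmf-versus-simulator comparison, 200 experiments
of 24 cultures for estimator bias and coverage, 500 null and 200
alternative pairs for test calibration and power, and 50 genomes of
$\ge 500$ mutations for the spectrum round-trip. The acceptance script
reports the same quantities at up to 1000 replicates for tighter
Monte-Carlo error, and runs the MA pipeline at the full default genome
scale. The spectrum drivers in `analysis/` use a 4 Mb genome so a full
run stays in seconds; the statistical behaviour is identical up to
denominators.
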