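---
title: "Immunogenetic scoring of HLA alleles for melanoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogenetic scoring of HLA alleles for melanoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaims)
```

## The model

The package works at the ecological (country) level. For each 4-digit HLA
allele $a$ it correlates the allele's population frequency $f_{a,c}$ with
melanoma prevalence $p_c$ (cases divided by total population) across
countries $c$, and transforms the Pearson correlation $r_a$ with Fisher's
variance-stabilising z-transform:

$$ r'_a = \operatorname{atanh}(r_a) = \tfrac{1}{2}\ln\frac{1+r_a}{1-r_a}. $$

$r'$ is the immunogenetic melanoma score (IMS). A negative score means the
allele is more common where melanoma is rarer — *protective* in the
ecological sense — and a positive score marks a *susceptibility* allele.
The mechanistic reading is that protective alleles bind and present
melanoma neoantigens efficiently enough to aid immune elimination.

Assumptions worth keeping in view:

- **Ecological inference.** The correlation is across country aggregates;
  it does not follow automatically that the same allele protects an
  individual carrier (the classical ecological fallacy). The congruence of
  the score's sign with published per-patient immunotherapy outcomes for
  six alleles (`check_cbi_congruence()`) is evidence, not proof, that the
  population signal carries to individuals.
- **Small $n$.** With at most 14 countries per correlation, individual
  scores are noisy; the analysis therefore leans on the *proportion* of
  protective alleles within strata rather than on single correlations.
- **No confounder adjustment.** UV exposure, skin phototype, ancestry
  structure and registry quality all vary by country and are not modelled;
  scores are raw bivariate associations (no partial correlations, no
  multiplicity correction — deliberately matching the source analysis).

## Data contracts and bundled reference tables

Frequencies are proportions in $[0,1]$ (an input flag rescales percentage
files); missing country/allele cells are explicit `NA`s, never imputed
zeros — absence of data is not absence of the allele. The bundled fixtures
(`hla_fixtures()`) carry the 127-allele registry (class, gene, supertype),
the published IMS values (79 protective, 48 susceptibility) and the
published expected scores, with md5 checksums and count invariants checked
at load. Two typographical gene cells in the source score tables (a blank
gene for DQB1\*05:02; DRB1\*04:08 listed under DQB1) are corrected from
the allele name, which is authoritative for the gene; this keeps the
per-gene counts (A 20, B 36, C 13, DPB1 15, DQB1 14, DRB1 29) consistent.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `min_countries` | `filter_alleles()`, `compute_ims()` | 9 | the inclusion rule that defines the 127-allele reference panel out of 14 countries; at least 3 is enforced for a correlation to exist |
| `conf` | interval functions | 0.95 | conventional level; the normal quantile is used at full precision (1.959964), not 1.96 |
| `min_stratum_size` | `group_proportions()` | 6 | supertype strata with more than 5 alleles are the reported ones; smaller strata are still computed but flagged `below_threshold` |
| `n_replicates` | expected-score functions | 1000 | the published Monte Carlo depth; see error analysis below |
| `include_self` | expected-score functions | `TRUE` | the extra own-gene draw comes from the full gene pool, including the target allele; exclusion is available and shifts expectations by less than ~0.01 |
| `policy` | `overall_risk_score()` | `"strict"` | `"available_mean"` scores real genotypes containing alleles outside the 127-allele panel and reports how many alleles were used |
| `seed` | all stochastic functions | none | always explicit; stochastic functions refuse to run without one, so no result depends on hidden RNG state |

## Proportion inference

Whether protective alleles predominate in a stratum is tested against
$p_0 = 1/2$ with the Wald single-proportion z-test, with the standard
error evaluated at the **sample** proportion,
$z = (\hat p - p_0)/\sqrt{\hat p(1-\hat p)/n}$. This choice matters: it is
the form that reproduces the published stratum statistics exactly at three
decimals (the score test, with SE at $p_0$, does not). The statistic is
kept signed — negative when protective alleles are in the minority —
whereas the published tables print its magnitude. Intervals are
Agresti–Coull: add $z^{*2}$ pseudo-observations, then apply the normal
approximation and clamp to $[0,1]$; unlike the Wald interval it behaves at
$k \in \{0, n\}$, which occurs in small supertype strata (e.g. B58, 3/3
protective). For such boundary strata the Wald statistic is reported as
`NA` rather than infinity.

Two cells of the published supertype table are treated as errata: the B44
row's counts (printed 7/7 against its own N = 11; the allele-level
assignments give 7/4, which the package reports) and three interval bounds
(A01 lower, A03 upper, B44 both) that are inconsistent with the
Agresti–Coull formula that reproduces every other interval in both tables.

## The expected genotype-context score R′

A carried allele acts alongside 11 others (two per classical gene). The
expected score embeds allele $a$ in random genotype contexts: each
replicate keeps $r'_a$, draws one more score from $a$'s own gene pool and
two from each of the other five pools (uniform, with replacement), and
averages the 12; $R'_a$ is the mean over replicates. The estimator has the
closed-form expectation

$$ E[R'_a] = \tfrac{1}{12}\Big(r'_a + \overline{r'}_{g(a)} +
   2\sum_{g \ne g(a)} \overline{r'}_g\Big), $$

implemented as `closed_form_expectation()` and used as the oracle in the
tests. Because five of the six gene-pool means are negative, $R'$ is
negative for most alleles even when their own score is positive —
B\*44:02 (IMS +0.108, $R'$ −0.077) is the canonical example, and exactly
this sign structure makes the six CBI-reference alleles fully congruent
with their published outcomes.

**Monte Carlo error.** A replicate average has standard deviation
$\approx 0.14$ on the bundled scores, so the standard error of $R'$ is
about $0.0045$ at 1000 replicates and $4.5\times10^{-4}$ at 100{,}000.
Self-consistency is therefore asserted probabilistically
($|R' - E[R']| \le 4\,\mathrm{SE}$), and agreement with the published
$R'$ column is assessed as a correlation across the 127 alleles
($\ge 0.99$) rather than per-allele equality: the published values
themselves carry Monte Carlo noise of this size, and the exact pool
construction behind them (self-inclusion, any weighting) is not fully
specified. Draws are uniform over alleles, not weighted by population
frequency, and genes are sampled independently — no linkage structure.

Reproducibility: one seeded RNG stream per `compute_all_expected()` call,
alleles processed in registry order, so the full table is bit-identical
given (seed, registry order, replicate count).

## The individual risk score

The overall melanoma P/S risk score of a genotype is the **mean** of its
12 IMS values (homozygous alleles count twice). A summed variant (12× the
mean) is available behind `statistic = "sum"` for comparability with a
summed formulation of the same quantity; the mean is the default because
it keeps the score on the IMS scale and is the form stated in words in
the source analysis. The score is invariant to within-gene allele order
and bounded by the extreme IMS values carried.

## Synthetic panels and what they show

`generate_panel()` plants a chosen correlation $\rho_a$ per allele:
prevalence is uniform on `prevalence_range` (default 0.001–0.006, the
order of magnitude of melanoma prevalence in Western European countries),
and frequencies follow $f = \mu_a + s\rho_a z(p) + \varepsilon$ with
$\mathrm{sd}(\varepsilon) = s\sqrt{1-\rho_a^2}$, $\mu_a$ uniform on
`freq_mean_range` (default 0.01–0.15, typical 4-digit allele frequencies)
and $s$ = `noise_sd` (default 0.02). If a draw would leave $[0,1]$ the
scale $s$ is shrunk and the column redrawn — re-parameterisation, never
clipping, so the realised correlation stays near target. Per-allele
coverage defaults to uniform on 9–14 reporting countries, mirroring the
reference panel's footprint. The default planted panel reuses the 127
bundled alleles with $\rho = \mp 0.8$ according to their published labels.

The linear-Gaussian form was chosen over Beta-distributed frequencies for
analytic control of the planted correlation; the generator consequently
does **not** emulate the skewness of real allele-frequency distributions,
linkage between genes, or database sampling error. Passing sign-recovery
tests therefore demonstrates that the pipeline's statistics behave
correctly under known correlation structure — not that real AFND/GBD data
would yield these recovery rates.

`sign_recovery_experiment()` quantifies recovery: at $|\rho| = 0.7$–$0.8$
and full 14-country coverage the expected sign-recovery probability is
$\Phi(|\operatorname{atanh}\rho|\sqrt{11}) > 0.99$, and the null
($\rho = 0$) protective fraction sits at 0.5 by symmetry; recovery
degrades as coverage drops to 9 (the Fisher-z SE grows from
$1/\sqrt{11}$ to $1/\sqrt{6}$). The validation suite runs 500 panels per
coverage level with 4 alleles per $\rho$ value — 2000 planted alleles per
cell — which resolves recovery rates to about $\pm 1$ percentage point in
a couple of minutes on one core; these sizes are the package's validation
design, chosen to make the Monte Carlo error small relative to the
thresholds checked.

## Numerical choices and degenerate inputs

- Correlations use pairwise-complete countries per allele. The alternative
  (imputing zero for missing cells) was rejected because missingness in
  frequency databases means "not typed", not "absent".
- $|r| \ge 1 - 10^{-12}$ has no finite score; `fisher_z()` raises rather
  than clamps, and `compute_ims()` converts the condition into a flagged
  `degenerate` row (score `NA`, reason recorded) so a pathological allele
  never aborts a panel run.
- $r' = 0$ is refused a label: it carries no direction, and assigning one
  arbitrarily would silently bias stratum counts. Zero expected scores are
  likewise counted incongruent in the CBI check.
- Frequency tables round-trip bit-identically through CSV (`%.17g`
  formatting), and the missingness mask is preserved by construction.
- Boundary proportions ($k \in \{0, n\}$): Wald statistic undefined
  (`NA`), Agresti–Coull interval still reported, clamped to $[0,1]$.

## Known limitations

- Country-level associations; individual-level transfer is hypothesis,
  not conclusion.
- The 14-country reference footprint is Continental Western European;
  scores need not generalise to other populations, and the 127-allele
  panel is a small slice of HLA diversity.
- No adjustment for environmental or ancestry confounders; no
  multiple-testing correction across the 127 correlations or the strata.
- The expected-score pools are unweighted and gene-independent; real
  genotypes have strong haplotype structure.
- Supertype strata pool alleles with heterogeneous effects (the package
  exposes the confidence-limit ratio precisely to flag such mixing), and
  dual-assigned alleles are kept as their own combined stratum rather
  than double-counted in both parents.
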