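---
title: "Site-component selection analysis of cancer somatic mutations"
author: "selscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-component selection analysis of cancer somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selscape)
```

## The problem

In a tumor cohort, a gene's ratio of nonsynonymous to synonymous somatic
mutation rates — CN/CS, the somatic analog of dN/dS — measures the mean
selection pressure acting on its protein changes. A ratio above 1 indicates
positive selection (classic drivers), below 1 purifying selection. But the
mean is a blunt instrument: a gene in which one or two amino-acid sites are
under strong positive selection while the remainder is conserved can have
CN/CS below 1 and be invisible to a gene-level test. Such genes — weakly
positively selected overall but carrying at least one genuine driver site —
are the *mini-drivers*; when the rest of the protein is additionally under
significant purifying selection they are *conserved mini-drivers*. selscape
implements the full chain from a mutation table to this three-way
classification.

## The model

**Gene level.** For a gene with `N` missense and `S` synonymous mutations,

$$ C_N/C_S = \frac{N / L_N}{S / L_S}, $$

where `L_N` and `L_S` are the expected numbers of nonsynonymous and
synonymous sites: the sum, over every possible single-nucleotide change in
the coding sequence, of the relative mutation rate of that change's
trinucleotide context class. The 96 pyrimidine-centered context classes (6
substitution types times 16 flank combinations) are estimated from the
cohort's synonymous mutations, which are taken as selectively neutral: the
relative rate of a class is its observed synonymous count over its
synonymous opportunity count, shrunk toward the cohort-average rate and
normalized to mean 1. Under a uniform spectrum `L_N / L_S` reduces to the
classic potential-site ratio. Stop-gain and stop-loss changes count toward
neither class, and the terminal stop codon is excluded from site accounting.

**Among-site heterogeneity.** With `z` the per-codon missense counts,

$$ H = \frac{\operatorname{var}(z) - \bar z}{\operatorname{var}(z) +
\bar z (\bar z - 1)}, \qquad 0 \le H \le 1, $$

estimates \(1 - E[\lambda]^2 / E[\lambda^2]\) of the latent per-site rates:
0 when all sites mutate at one rate, near 1 when a few sites absorb most
mutations. The band \(1 - H < C_N/C_S < 1\) flags weak positive selection at
individual sites masked by constraint elsewhere. Both the test against null
ratio 1 and against \(1 - H\) are two-cell Pearson chi-square tests on
`(N, S)` with expectations proportional to the (null-scaled) opportunities.

**Site components.** Per-codon missense counts follow a two-component
mixture: a fraction \(1 - \eta\) of passenger sites is Poisson with rate
\(m_0\) (calibrated from the gene's synonymous count,
\(m_0 = S \cdot (L_N/L_S) / n_\text{codons}\)); a fraction \(\eta\) of
driver sites carries a gamma-distributed excess rate, giving approximately a
negative binomial with mean \(m_1\) and shape \(\alpha\):

$$ f(z) = (1-\eta)\,\text{Pois}(z; m_0) +
\eta\,\text{NB}(z; m_1, \alpha). $$

\(\alpha\) is treated as universal across genes and fitted once per cohort;
\((m_1, \eta)\) are estimated per gene. A likelihood ratio test against a
single-Poisson null, with the boundary-corrected reference distribution
\(\tfrac12\chi^2_0 + \tfrac12\chi^2_1\), asks whether the driver component
is real.

**Component decomposition.** With `S_N`/`S_S` the numbers of distinct
mutated nonsynonymous/synonymous sites,

$$ \Omega_\text{pass} = \frac{S_N / S_S}{L_N / L_S}, \qquad
\Omega_\text{dri} = \frac{[N/S]^*}{L_N / L_S}, \qquad
[N/S]^* = \frac{N/S - (1-\eta) S_N/S_S}{\eta}, $$

which satisfy \((1-\eta)\Omega_\text{pass} + \eta\Omega_\text{dri} =
C_N/C_S\) exactly. Recurrence inflates `N` but not `S_N`, so the site-based
ratio isolates the passenger background while the adjusted count ratio
captures the driver sites. Per site,
\(Q_k = \eta\,\text{NB}(z_k)/f(z_k)\) is the posterior driver probability
and

$$ \Omega_k = (1 - Q_k)\,\Omega_\text{pass} +
Q_k \frac{z_k + \alpha}{m_1 + \alpha}\,\Omega_\text{dri}. $$

**Classification.** Driver: CN/CS > 1 (chi-square p < 0.05) and a
significant driver component (eta > 0, LRT p < 0.05). Mini-driver:
1 − H < CN/CS < 1 (p < 0.05 against 1 − H) and, under the default joint
rule, also a significant driver component; `minidriver_rule =
"methods_only"` drops the mixture requirement. Conserved mini-driver: a
mini-driver with \(\Omega_\text{pass} < 1\) at one-sided p < 0.05. An
optional filter excludes six recurrently false-positive giants (TTN, FLG,
PCLO, CSMD3, CNTN5, LRP1B).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha_level` | 0.05 | raw p-value threshold at every decision point |
| `pseudocount` | 0.5 | substituted for zero `S` or `S_S` denominators (gene flagged) |
| `spectrum_pseudocount` | 0.5 | shrinkage strength of the context spectrum toward the cohort mean rate |
| `mom_method` | `"ml"` | per-gene (m1, eta) estimator; `"printed"`/`"exact"` select the moment inversions |
| `lrt_df` | `"boundary"` | reference distribution of the driver LRT |
| `lrt_null` | `"profiled"` | null Poisson rate: the gene's MLE, or `"m0"` for the fixed passenger rate |
| `alpha_fallback` | 1.51 | gamma shape used when no gene supports the global fit (the published pan-cancer estimate) |

## Numerical and design choices

* **Variance convention.** `compute_H` and the moment equations use the
  population variance (divisor *n*): the moment identities are over all
  sites of the gene, not a sample of them. The sample variance is available
  via `compute_H(variance = "sample")`.
* **Clamping.** Raw H outside [0, 1] is clamped; raw eta outside [0, 1] is
  truncated and flagged; a negative adjusted ratio \([N/S]^*\) (possible by
  sampling noise at small counts) is floored at 0 and flagged rather than
  propagated.
* **Moment inversion.** The closed-form estimator of \(m_1\) is an
  approximation whose relative error is about
  \(m_0(m_1 + u)/(u(\alpha+1))\), \(u = m_1 - m_0\): negligible for
  \(m_1 \gg m_0\) but >5% at \(m_1 = 20 m_0\) when \(\alpha < 1.2\). The
  exact inversion solves the quadratic
  \((\alpha+1)u^2 + (2m_0 - \alpha d - \alpha V/d)u + m_0^2 = 0\)
  (\(d = \bar z - m_0\), \(V = \operatorname{var}(z) - \bar z\)); both roots
  satisfy the moment identities, and the larger is taken as the
  sparse-driver solution — for \(m_1 < m_0(1 + 1/\sqrt{\alpha+1})\) the
  smaller root is the true one and the method cannot distinguish them from
  two moments alone.
* **Why ML is the pipeline default.** With a 1% driver fraction a
  500-codon gene carries ~5 driver sites; the moment ratio \(V/d\) is then
  strongly right-skewed and the median gene underestimates \(m_1\) by
  ~20%. Maximizing the mixture likelihood at fixed \((m_0, \alpha)\),
  initialized from the moments, removes most of that bias (median error a
  few percent in simulation) while keeping the same model. The printed and
  exact moment estimators remain available and verbatim.
* **Why the LRT null is profiled.** \(m_0\) comes from a handful of
  synonymous mutations. Testing the mixture against a Poisson fixed at that
  noisy rate lets the driver component absorb estimation error in \(m_0\):
  empirical type-I error ~12% at nominal 5% in null simulations. Profiling
  the null rate (Poisson at the gene's MLE, \(\bar z\)) makes the test
  conservative (~1%) without changing the alternative. The fixed-m0
  construction is kept as `lrt_null = "m0"`.
* **Why the global alpha fit pools.** Profiling \((m_1, \eta)\) gene by
  gene from their own moments biases \(\alpha\) severely in either
  direction depending on the m0 baseline's noise. The default profiles one
  \((m_1, \eta)\) from the pooled moments of the overdispersed genes
  against a cohort-calibrated baseline rate while still summing the
  likelihood per gene; per-gene profiling is available
  (`profile = "per_gene"`).
* **Spectrum shrinkage.** Synonymous counts are orders of magnitude sparser
  than opportunities, so a symmetric pseudocount would hand never-offered
  classes a huge relative rate after normalization; the estimator instead
  adds pseudo-opportunities carrying events at the cohort-average rate, so
  data-poor classes default to relative rate 1.
* **Hypermutators.** Within each cancer type, samples are excluded only if
  their mutation count exceeds both Q3 + 1.5 IQR (type-7 quantiles) and
  1000; strata with fewer than 4 samples fall back to the whole-cohort
  fence. The filter is idempotent.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws random sense-codon coding sequences, marks each
codon a driver with probability eta, draws driver excess rates from the
gamma, realizes missense counts as Poisson events placed on specific
nucleotide changes (weighted by the context spectrum), and adds synonymous
mutations at the intensity `m0 * n_codons * L_S / L_N`, which makes neutral
genes satisfy E[CN/CS] = 1 by construction. Defaults are the standard
recovery scenario (500 genes x 500 codons, eta 0.01, m0 0.05, m1 5, alpha
1.51 — a sparse-driver regime of the kind seen pan-cancer). It does not
model clonal structure, copy number, per-sample mutational signatures,
indels, or regional mutation-rate covariates; mutations are assigned to
samples independently. A green simulation test therefore establishes
internal consistency of estimation and classification under the stated
generative model, not robustness to those real-data complications.

Two further caveats calibrated by simulation:

* The clamped H estimator is essentially unbiased under equal rates once
  the density reaches about one expected missense mutation per codon, but
  at sparse densities (mean 0.1 per codon) the clamp leaves a positive bias
  around 0.15 — the denominator \(\operatorname{var}(z) + \bar z(\bar z -
  1)\) is then near zero. H-based calls on very sparsely mutated genes
  should be read accordingly.
* The Eq-8 variance identity uses the NBD* term \(\eta m_1^2/\alpha\),
  which matches the generative Poisson(\(m_0 + \lambda\)) variance only
  when \(m_0 \ll m_1\); the simulator and estimators are consistent in that
  regime, which is also the biologically relevant one.

## A small worked run

```{r example, eval = FALSE}
cfg <- simulation_config(n_genes = 30, n_codons = 200, eta = 0.03,
                         m0 = 0.2, m1 = 6, alpha = 1.51,
                         n_samples = 50, seed = 42)
sim <- simulate_cohort(cfg)
res <- run_pipeline(run_config(maf = sim$maf, cds = sim$transcripts))
table(res$classifications$label)
head(res$gene_stats[, c("gene_id", "N", "S", "cncs", "H", "mode")])
```

## Known limitations

1 − H is treated as a known constant in the second gene-level test although
H is estimated; uncertainty in H is not propagated. The exact Poisson-gamma
convolution for driver counts is not implemented (the negative-binomial
form is the working model). Genomic-to-CDS projection, indels, and
multi-allelic sites are out of scope: mutation positions must arrive in CDS
coordinates (a numeric column or HGVSc strings). Confidence intervals on
the component ratios are not provided.
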