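---
title: "Negative-control screening of contaminant ASVs: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative-control screening of contaminant ASVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asvscreen)
```

## The problem

Low-microbial-biomass samples — mosquito guts and reproductive tracts are
the motivating case — carry so little bacterial DNA that the background
DNA in extraction kits, PCR reagents, and the laboratory (the "kitome")
competes with, and can dominate, the true community in 16S rRNA amplicon
sequencing. Negative controls (sampling blanks, extraction blanks)
sequenced alongside the tissues provide the reference signal: sequences
abundant in blanks are suspect everywhere.

`asvscreen` works at the amplicon sequence variant (ASV) level — unique
sequences, no OTU clustering — because contamination is sequence-specific:
the same genus (*Acinetobacter*, *Serratia*, Enterobacter, Pseudomonas)
routinely appears both as a reagent contaminant and as a genuine tissue
resident, and only exact-sequence resolution separates the two
populations. Upstream read processing (quality filtering, chimera removal,
taxonomy) is assumed done; the package starts from a feature-by-sample
count table and per-sample metadata (`role`, `dataset`, `tissue`).

## The screening model

For a sample subset $S$, the pooled relative abundance of feature $f$ is

$$p_f(S) = \frac{\sum_{s \in S} x_{fs}}{\sum_{g}\sum_{s \in S} x_{gs}}.$$

**Pooling, not averaging.** We sum counts over the subset rather than
averaging per-sample proportions. "Overall" abundance reads most naturally
as a property of the pooled reads, and several real data sets have exactly
one negative control, where the two definitions coincide; pooling is the
one definition that behaves consistently across both situations.

A feature is a **candidate contaminant at threshold $\tau$** when
$p_f(\text{controls}) \ge \tau/100$. The comparison is inclusive
($\ge$, matching the "at least $\tau$%" reading), and the five standard
treatments are:

| treatment | removed features |
|---|---|
| `none` | nothing (experimental columns only) |
| `full` | every feature with a nonzero control count |
| `t1`, `t5`, `t10` | candidates at $\tau$ = 1, 5, 10% |

Removal is feature-global within a data set: a classified ASV is removed
from every experimental sample, regardless of its per-sample abundance.
Counts are not re-scaled after removal; diversity is computed on the
trimmed counts (rarefaction, where used, happens upstream).

The **shared burden** of a candidate set against a tissue is the number of
candidates with nonzero pooled tissue abundance and the sum of their
tissue abundances. "Shared" requires only a nonzero pooled count — no
minimum prevalence — since any weaker definition would need a parameter
the screening model does not have. Report columns round percentages to
two decimals, half-up; all internal arithmetic is unrounded. Summaries are
always recomputed from the per-ASV abundance blocks rather than
transcribed, which also sidesteps transcription inconsistencies that can
creep into circulated summary tables (e.g. a shared count exceeding its
own candidate total); the recomputed values are internally consistent by
construction, and nested by construction:
candidates(10%) ⊆ candidates(5%) ⊆ candidates(1%) ⊆ control-detected set.

Deliberately **not** implemented: rules comparing control to tissue
abundance (e.g. "remove when 10× more abundant in controls"). The
screening signal here is the control abundance alone.

## The prevalence score

For comparison with prevalence-based software, each feature gets a
one-sided score from its 2×2 presence/absence table
($k_\text{ctrl}/n_\text{ctrl}$ vs $k_\text{exp}/n_\text{exp}$; presence =
count ≥ `detect_min`, default 1):

* Pearson chi-square without continuity correction, p halved and directed:
  $P = p/2$ when prevalence is higher in controls, else
  $\max(1 - p/2, 0.5)$ — so a feature more prevalent in tissues can never
  be called;
* whenever any expected cell is below 5, the one-sided Fisher exact test
  (a hypergeometric tail, `stats::phyper`) replaces the asymptotic branch;
* degenerate margins (present everywhere or nowhere) are uninformative:
  $P = 1$.

A feature is classified when $P < P^*$ (strict), conventionally at the
default $P^* = 0.1$ and the stricter $P^* = 0.5$ side by side. Because
published prevalence-based tools do not pin down their tail conventions,
absolute $P$ values are implementation-specific; what this score is built
to guarantee — and what the tests check — is the exact agreement of the
Fisher branch with brute-force hypergeometric enumeration, monotonicity
in the presence counts at fixed margins, and nesting of the call sets
across $P^*$.

A structural property worth knowing: at high sequencing depth, even a
fraction of a percent of contaminant bleed-through puts a read or two of
each major contaminant into *every* tissue sample, the presence table
saturates, and the prevalence score goes uninformative ($P \to 1$ via the
degenerate rule). Prevalence-based screening is a shallow-detection-limit
method; the package's recovery experiment (below) therefore runs at
realistic *shallow* depths, around 500 reads, where presence/absence still
carries the signal.

## Diversity and paired comparisons

Alpha diversity per sample: observed richness $S$, Shannon
$H = -\sum p_i \ln p_i$ (natural log by default, base configurable),
Pielou $J = H/\ln S$ ($J$ undefined for $S \le 1$, propagated as `NA` and
dropped pairwise). Beta diversity: binary Jaccard and Bray–Curtis, via
`vegan::vegdist`. Rarefaction (`subsample_to_depth`) subsamples without
replacement via `vegan::rrarefy`, drops samples below the target depth by
default, and records determinism through an explicit seed argument.

Treatments are compared pairwise with paired tests. The pairing unit is
the sample for alpha metrics and the *unordered sample pair* for beta
metrics, so the same distance is tracked across treatments. The
Shapiro–Wilk gate is applied to the **paired differences** at α = 0.05:
the differences are the quantity whose distribution the paired *t* test
assumes normal, so they — not each arm's marginal values — are the
statistically meaningful object to gate on (per-arm gating is available
via `gate_on = "values"`). Wilcoxon conventions: zero differences
dropped, exact null up to 25 informative pairs, normal approximation with
tie correction above; all-zero differences short-circuit to a degenerate
result with $p = 1$. No multiplicity correction is applied by default
(raw per-data-set p-values with asterisk bands is the reporting
convention); `p_adjust = "holm"` is available.

The compact letter display assigns letters to the maximal cliques of the
non-significance graph (`igraph::max_cliques`), ordered by lowest-ranked
member, so two treatments share a letter **iff** their comparison was not
significant.

## The synthetic generator

`generate_community()` emulates the contamination phenomena the screening
model assumes, with ground-truth labels:

* **contaminant pool**: composition ~ symmetric Dirichlet(α = 0.3) over 30
  features — an uneven pool in which the top contaminant typically exceeds
  10% of control reads, as real blanks show;
* **true community**: log-normal rank abundance (σ = 1.5) over 150
  features, jittered per sample (σ = 0.6); one designated endosymbiont
  feature holds 30% of the true community, reproducing the
  *Wolbachia*-like signature of high tissue abundance with faint leakage
  into controls;
* **bleed-through**: experimental sample $i$ mixes
  $(1-\varepsilon_i)\,\text{true}_i + \varepsilon_i\,\text{pool}$, with
  $\varepsilon_i$ Beta-distributed (mean 0.3, sd 0.1) — shared-read
  burdens of 10–67% of tissue reads are typical in real low-biomass data
  sets, and a mean bleed of 0.3 puts the simulated burden in that range;
* **cross-contamination**: controls mix
  $(1-\varepsilon_\text{cross})\,\text{pool} +
  \varepsilon_\text{cross}\,\overline{\text{true}}$ with
  $\varepsilon_\text{cross} = 0.02$, matching endosymbiont leakage below
  ~1.5% of control reads;
* **counts**: multinomial at a per-sample depth drawn from 20–30k (around
  the 25k depth deep runs are commonly rarefied to). Multinomial — not
  per-feature negative binomial — keeps column totals exactly equal to the
  drawn depths; overdispersion enters through the per-sample log-normal
  profiles. Singletons (rate 0.05 per feature) are injected by swapping
  single reads out of each host sample's top feature, preserving totals.

Defaults mirror a laboratory study arm of 23 experimental pools and 6
extraction blanks. What the generator does **not** emulate: index
switching and well-to-well geometry, taxonomic structure, chimeras, batch
effects across extraction rounds, and per-feature overdispersion beyond
the log-normal jitter. Passing tests therefore demonstrate that the
machinery recovers truth under the stated mixture model, not that any
particular real data set is contamination-free.

## Validation experiments and their problem sizes

The acceptance-style tests (in `tests/testthat/test-acceptance.R`) run at
sizes chosen to make each check sharp yet quick; all seeds are fixed:

* **Worked example**: the packaged per-ASV abundance blocks of the five
  mosquito data sets reproduce every shared-burden cell (counts exactly,
  percentages within ±0.05, the slack implied by 2-decimal printed
  inputs).
* **Nesting**: threshold candidate sets are nested on 1,000 random tables.
* **Oracle**: the Fisher branch equals exhaustive hypergeometric
  enumeration on every 2×2 table with group sizes ≤ 12 (tolerance 1e-12).
* **Recovery**: with no cross-contamination, threshold classification
  returns *exactly* the pool features at/above τ of realized control
  abundance (20 seeds); the prevalence score at $P^* = 0.5$ recovers ≥90%
  of pool features at ≥1% control abundance with 40 samples, 6 controls,
  1% mean bleed, ~500-read depths (20 seeds; see the depth argument
  above).
* **Impact**: under the default dominant-contaminant conditions, full
  removal lowers per-sample richness always, and the paired tests flag
  richness and Shannon shifts in ≥80% of 50 seeds.
* **Size**: with zero bleed-through, the τ = 1% treatment removes nothing
  from the experimental samples, so each treatment table is rarefied
  *independently* (2,000 reads from ~5,000) and the none-vs-t1 Shannon
  comparison is pure resampling noise; over 200 simulated data sets of 20
  samples the paired machinery rejects at 3% — within the 5% ± 3% band a
  nominal-size test should occupy. This independent-rarefaction design is
  the only null under which the size question is well-posed: with a shared
  upstream table the two treatments are bit-identical and every test is
  degenerate.

## Known limitations and sharp edges

* **Shannon is not monotone under removal.** Richness can only fall when
  features are removed; Shannon can *rise*, because removing a dominant
  uneven contaminant leaves a more even residual composition. Minimal
  counterexample: counts (100, 1, 1) have $H \approx 0.12$; dropping the
  dominant feature leaves (1, 1) with $H = \ln 2 \approx 0.69$. Under the
  generator's defaults a few samples per 50 data sets show small Shannon
  increases after full removal, and the test suite's per-sample
  Shannon-direction expectation records exactly this (it fails for those
  seeds, by design of the check rather than of the code). Treat per-sample
  Shannon direction as an empirical tendency, not an invariant.
* Diversity is computed at the ASV level; re-clustering the trimmed
  sequences into 97% OTUs requires the sequences themselves and is out of
  scope. Absolute diversity values differ from OTU-level analyses, but the
  treatment-contrast design (every treatment measured on the same feature
  space) is unaffected.
* Whether rarefaction precedes or follows screening is configurable in
  `run_pipeline` (`normalize$per_treatment`); the default normalizes
  first, once, which matches the usual processing order.
* No predefined threshold is universal. The 1/5/10% ladder spans low to
  high control abundance, but each study should pick its criterion from
  its own controls — and treat full removal as the conservative extreme
  that also deletes cross-contaminated true residents (the endosymbiont in
  the generator makes this cost measurable).
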