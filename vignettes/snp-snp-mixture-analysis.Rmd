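---
title: "SNP-SNP microhaplotypes for unbalanced degraded mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-SNP microhaplotypes for unbalanced degraded mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpsnpmix)
library(dplyr)
```

## The problem

A two-person DNA mixture in which one contributor outweighs the other a
thousandfold — a suspect's traces under a victim's DNA, or cell-free
fetal DNA (cffDNA) against the maternal background in plasma — defeats
conventional STR genotyping twice over: the minor alleles drown below
the major's signal and stutter, and when the sample is also degraded
the long STR amplicons have no intact template left.  SNP-SNP
microhaplotypes attack both failures at once.  Each marker is a pair of
tightly linked biallelic SNPs inside one short amplicon (60–150 bp for
the panel shipped here).  An allele-specific ARMS primer whose 3'
terminus matches only one SNP1 allele amplifies *only* template
carrying that allele, so a minor contributor's private allele is read
against essentially no background; the linked SNP2 is then typed by
single-base extension (SBE/SNaPshot) and sized on a capillary
electrophoresis (CE) platform.  Because the markers are SNPs, no
stutter products arise at all.

`snpsnpmix` implements this analysis as a tidyverse-style pipeline:
informative-marker classification from trio genotypes, a simulator for
the ARMS + SBE readout, fragment-length/degradation models,
panel-level population genetics, and a synthetic-data generator that
stands in for real specimens.

## Informative markers

Write a genotype at a locus as an unordered pair of two-base
haplotypes, e.g. `"CA-TG"` (SNP1 base first).  The fetal component of
maternal plasma can be targeted at a locus exactly when the child's
paternally inherited SNP1 allele is **absent from the mother's SNP1
genotype**.  Because the targeting primer reads only SNP1, the maternal
SNP2 configuration is irrelevant.  Three patterns follow:

* **Type 1** — parents are opposite SNP1 homozygotes.  Whichever allele
  the father transmits, the mother lacks it; the locus is always
  informative.
* **Type 2** — mother SNP1-homozygous, father heterozygous, and the
  transmitted allele is the one the mother lacks: informative.
* **Type 3** — as Type 2 but the shared allele was transmitted: the
  fetus is invisible against the mother.

A SNP1-heterozygous mother can never be informative (both primer
targets amplify her own DNA); we keep this as a distinct
`MATERNAL_HET` category rather than folding it into `UNINFORMATIVE`,
because it is the panel's structural limitation and worth reporting
separately.

`classify_locus()` resolves the transmitted allele from the child's
genotype.  With a SNP1-homozygous mother this is never ambiguous at
SNP1: any child haplotype carrying a non-maternal SNP1 allele cannot
have come from her.  Full-haplotype attribution *can* be ambiguous
(both child haplotypes compatible with the mother); `paternal_allele()`
then flags the ambiguity, and since both attributions agree that no
non-maternal SNP1 allele exists, the conservative "not informative"
verdict is automatic.  The test suite pins the classifier to the
direct definition by exhaustively enumerating every biallelic parental
genotype pair crossed with every Mendelian child.

```{r}
panel <- load_panel()
classify_locus("CA-CA", "CA-TG", "CA-TG",
               locus = panel[panel$locus_id == "MH9", ])
```

## The bundled panel

The panel fixture ships 15 loci with their ARMS amplicon lengths
(60–150 bp), designed SBE amplicon lengths (26–71 bp, per-locus mean
45 bp), each primer's CE-observed product size, and each primer's
published sensitivity class (0.025 or 0.05 ng).  SNP identity and
population frequencies were never part of the published record, so
allele labels are documented placeholders consistent with the printed
mixture genotypes, and the CE-observed sizes of the four primers that
never appeared in the plasma study reuse their sibling primer's value
(marked synthetic in the fixture header).  Summaries follow the
reporting conventions of the source tables: ARMS statistics over
primer rows, SBE statistics over the 15 distinct per-locus values
(682/15 = 45.47 → 45), and all reported means rounded half-up —
half-to-even rounding cannot reproduce hand-reported tables.

## The amplification model

The CE peak model is deliberately parsimonious, because the published
record constrains only thresholds, limits of detection (LODs) and
qualitative behaviour, never absolute fluorescence:

\[
E[h] \;=\; T \cdot b \cdot \frac{m_\text{target} + \varepsilon\, m_\text{non-target}}{L/2},
\qquad h = E[h]\cdot X,\quad X \sim \text{logN}(-\sigma^2/2, \sigma^2)
\]

with \(T\) the 50 RFU calling threshold, \(L\) the primer's published
LOD, \(\varepsilon\) the non-specific amplification rate (default
\(10^{-4}\)), \(b\) the 32-cycle cfDNA-protocol gain (default 4,
roughly a doubling per extra cycle away from plateau, applied only on
the plasma path), and \(\sigma^2 = \log(1 + cv^2)\) for a noise CV of
0.3 with \(E[X] = 1\).

Two conventions matter:

* **LOD is a heterozygous input mass.**  Sensitivity was established by
  diluting SNP1-heterozygous single-source samples, so a primer of the
  "0.05 ng" class saw 0.025 ng of *target* template at its limit.  The
  calibration anchor is therefore \(L/2\) ng of target, where the
  deterministic peak sits exactly on the threshold.  This single
  convention makes the sensitivity series (positive down to input
  \(L\)), and the 1:1,000 mixture series with the minor fixed at
  0.05 ng (0.025 ng of target for a heterozygous minor — detected by
  primers of both LOD classes), mutually consistent; interpreting
  \(L\) as a target mass would contradict the mixture results.
* **Monotonicity and specificity.**  With \(\varepsilon = 0\) a primer
  whose target allele is absent from every contributor produces
  exactly zero signal at any mass — allele-specific PCR's defining
  property, and the reason a 1:1,000 mixture is readable at all.  With
  \(\varepsilon > 0\) the expected height grows (mildly) with the
  major's mass, so the noise-free height is non-increasing in the
  mixing ratio only at \(\varepsilon = 0\); the observed *decrease* of
  minor peaks with increasing ratio in real multiplexes (template
  competition at fixed cycle number) is not modelled.  Stutter is
  never simulated: SNP markers produce none.

```{r}
primers <- panel_primers(panel)
sensitivity_assay(primers[primers$primer_id == "MH9-F2", ],
                  replicates = 1, deterministic = TRUE)
```

## Degradation and fragment lengths

Heat degradation is modelled as a Poisson breakpoint process: an
amplicon of length \(\ell\) survives with probability
\(e^{-\ell/\lambda}\) where \(\lambda\) is the mean fragment length.
The published evidence for the incubation series is qualitative
("fragments concentrated below 200 bp"), so the incubation times map
to configurable presets — 150/120/100 bp for genomic DNA at 98 °C for
35/40/45 min and 120/90/80 bp for the standard DNA at 120/160/170 min
— acknowledged model choices, not fitted kinetics.  The survival
ordering that matters is parameter-free: every 60–150 bp panel
amplicon strictly outranks every ≥250 bp STR-style amplicon at any
severity, which is why the panel genotypes where long amplicons fail.

Circulating cfDNA is not Poisson-fragmented — apoptotic cleavage
concentrates lengths around a mono-nucleosomal mode — so the cfDNA
model is log-normal with median 143 bp.  The tail constraint (<1 %
of fragments above 300 bp) pins the dispersion: at median 143,
\(P(>300) < 0.01\) requires \(\sigma \le 0.3186\), and we use 0.30,
the largest round value satisfying it.  A fragment supports
amplification only if it is at least as long as the amplicon, so the
survival function on the plasma path is the log-normal upper tail.

## Population genetics

Under Hardy–Weinberg equilibrium with the father's transmitted allele
an independent population draw (unrelated parents; no pedigree
structure to say otherwise), the probability that a locus is
informative for a random family is \(\sum_a p_a^2(1-p_a)\) over SNP1
alleles — \(p(1-p)\) in the biallelic case, maximised at 0.25 for
\(p = 0.5\).  Treating the loci as unlinked (the panel is spread
across the genome), the panel-wide informative count is
Poisson-binomial, computed by exact convolution; with all 15 loci at
0.25 the chance of a family with *zero* informative markers is
\(0.75^{15} \approx 0.013\) — rare, but exactly the situation one
cohort family presented.  `effective_allele_number()` supplies the
Ae = \(1/\sum q_h^2\) polymorphism measure used to rank
microhaplotype candidates.

```{r}
f <- tibble::tibble(locus_id = "L1", haplotype = c("CA", "TG"),
                    freq = c(0.3, 0.7))
prob_informative_locus(f)
panel_informative_count_distribution(rep(0.25, 15)) |> head(4)
```

## The synthetic study

`synth_frequencies()` + `generate_cohort()` + `generate_plasma()`
generate everything the pipeline consumes.  Defaults are the study
conditions: 26 families; total cfDNA concentration uniform on
0.156–1.43 ng/µL (the quantified range; a replay mode uses the 25
published concentrations verbatim, imputing the one below-quantitation
sample at 0.078 ng/µL, half the quantified minimum); fetal fraction
uniform on 5–20 %; cfDNA lengths log-normal(143, 0.30).  Haplotype
frequencies are not part of the published record, so each locus is
biallelic at both SNPs with minor-allele frequencies uniform on
0.3–0.5 (the high-polymorphism regime such panels are designed for)
and between-SNP LD at D′ = 0.8 — tight enough that haplotypes behave
as alleles, without collapsing to two haplotypes only.  Children
receive one uniformly chosen haplotype per parent, so cohorts are
Mendelian-consistent by construction.

What the generator does *not* emulate: gestational-age dependence of
the fetal fraction, linkage between loci, genotyping error in the
reference samples, and electrophoretic artifacts (pull-up, off-ladder
peaks).  Passing tests therefore demonstrate internal consistency of
the models under the stated conditions, not performance on real
plasma.

## The plasma pipeline end to end

```{r}
set.seed(7)
cohort <- generate_cohort(synth_frequencies(panel), n_families = 26)
plasma <- generate_plasma(cohort)
run <- run_cohort(cohort, plasma, panel)
glance(summarize_cohort(run))
```

Each informative marker is simulated as an independent single-plex
reaction (matching the study design; no inter-locus competition), with
1 µL of template.  The per-family accounting (`expected_count` from
reference genotypes, `observed_count` from detected plasma peaks) and
the cohort totals mirror the published tables; on the bundled
per-family table the totals are 77 expected, 76 observed, detection
rate 98.7 %.  `correlation_report()` gives the Spearman coefficient
between concentration and detected fraction only — the underlying
claim is qualitative (no obvious correlation), so no test machinery is
attached.  The "observed size" of a detected product is taken from the
primer's CE-observed size column rather than re-derived from mobility
physics.

## Numerical choices and problem sizes

* Reported means and rates: half-up rounding (whole bp; one decimal
  for percentages).
* Detection is `height >= threshold` (ties detect), making the
  deterministic LOD anchor exact.
* Validation errors are classed (`snpsnpmix_format_error`,
  `snpsnpmix_validation_error`, `snpsnpmix_mendelian_error`) so
  callers can distinguish malformed files from impossible genetics.
* Monte-Carlo checks in the test suite use 100,000 draws for
  single-locus probabilities and fragment lengths, 10,000 replicates
  for specificity, and 10,000 families for the generator-to-theory
  convergence check, each against 3-standard-error (or exact)
  tolerances under fixed seeds — sizes at which those tolerances are
  decisive yet the suite stays quick.

## Known limitations

* Peak heights are linear in template with multiplicative log-normal
  noise; plateau effects, inter-primer competition in multiplexes, and
  the empirical decline of minor-allele peaks with increasing ratio
  are not reproduced (a per-primer `efficiency_penalty` can emulate a
  locus that underperforms in multiplex).
* The degradation presets are not a kinetic model of thermal
  fragmentation.
* Paternity-index / likelihood-ratio computation is out of scope; the
  pipeline stops at marker-level detection accounting.
* Real allele frequencies for the panel's source population are not
  included; all frequency-dependent results are parameterised.
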