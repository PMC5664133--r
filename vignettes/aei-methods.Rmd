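---
title: "Detecting allelic expression imbalance from RNA-seq allele depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allelic expression imbalance from RNA-seq allele depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeiscan)
```

## The problem and the model

At a transcribed heterozygous SNP, RNA-seq reads sample the two alleles'
transcripts. Without *cis* regulation, the alternative-allele read count
at depth $d$ is approximately binomial with fraction $0.5$ (plus
overdispersion from library and biological noise), so the linear allelic
ratio $r = \text{alt}/\text{ref}$ concentrates near 1 and its natural
log near 0. A *cis*-regulatory allele on one haplotype shifts the
transcript mix to some fraction $f \neq 0.5$ of one haplotype's
transcripts, moving $\ln r$ to $\ln\!\big(f/(1-f)\big)$ in every
heterozygous carrier — with a *direction* set by which marker allele
shares the haplotype with the regulatory allele.

`aeiscan` detects these shifts with an intentionally simple empirical
rule rather than a parametric read-count test:

1. **Record filters.** Keep heterozygous records with site quality
   strictly above 225, total coverage $\ge 20$ reads, each allele
   supported by $\ge 2$ reads, and an rsID (dbSNP membership,
   operationalized as a non-missing `ID`; an allowlist can substitute
   for a local dbSNP copy). The two-reads rule also guarantees $r$ is
   finite and positive.
2. **Outlier rule.** Assuming approximate normality of $\ln r$, a record
   is an outlier when it falls strictly outside
   $\bar{x} \pm k \cdot s$ ($k = 2$) of its reference population — by
   default all passing variants *within the same sample*
   (`outlier_scope = "per_sample"`). A variant is retained when at least
   one sample is an outlier; *single-hit exclusion* additionally
   requires a second outlier sample or one further sample in the
   moderate band.
3. **Moderate band.** $r < 0.666$ or $r > 1.5$, strictly — i.e. one
   allele contributing less than 40% or more than 60% of reads, since
   the allele percentages are $100r/(1+r)$ and $100/(1+r)$.
4. **Cohort summary.** Per retained variant: heterozygote count,
   directional band counts, AEI frequency among heterozygotes and in the
   cohort (an explicit `cohort_size`, never inferred from the table),
   and over the imbalanced samples' oriented ratios
   $a = \min(r, 1/r)$: mean $\pm$ SEM, bias-corrected excess kurtosis
   $G_2$ with its standard error SEK, and the orientation fraction
   $\max(n_{below}, n_{above})/n_{imbalanced}$.

The assumptions worth keeping in mind: genotypes are trusted from the
upstream caller (never re-derived from counts); log ratios within the
reference population are roughly unimodal so that $\bar{x} \pm 2s$ is a
meaningful tail rule; and read mapping is unbiased between alleles
(reference-bias correction is out of scope — orthogonal validation and
region blacklists stand in for it).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_qual` | 225 | Phred-like site QUAL | strict `>`, upstream-caller confidence floor |
| `min_depth` | 20 | reads | below this, $r$ is too noisy to interpret |
| `min_allele_reads` | 2 | reads | excludes genotyping errors and guarantees $r \in (0, \infty)$ |
| `require_rsid` | `TRUE` | — | known-polymorphism filter against private caller artifacts |
| `outlier_scope` | `per_sample` | — | see "Open design choices" |
| `k_sd` | 2 | SD units | $\approx 4.6\%$ two-sided tail under normality |
| `ratio_low`, `ratio_high` | 0.666, 1.5 | ratio | the 40–60% allele-percentage band |
| `min_cohort_freq` | 10 | % of cohort | keeps recurrently imbalanced SNPs (strict `>`) |

All are surfaced in `aei_config()`, in key=value config files
(`read_aei_config()`), and as flags of the command-line wrapper.

## Statistics conventions

**Kurtosis.** `excess_kurtosis()` implements the bias-corrected $G_2$
convention,
$$G_2 = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum_i \left(\frac{a_i - \bar a}{s}\right)^{\!4} - \frac{3(n-1)^2}{(n-2)(n-3)},$$
with $s$ the $n-1$ sample SD. This is the convention paired with the
closed-form standard error implemented in `sek()`:
$$\mathrm{SEK} = 2\,\mathrm{SES}\sqrt{\frac{n^2-1}{(n-3)(n+5)}}, \qquad
\mathrm{SES} = \sqrt{\frac{6n(n-1)}{(n-2)(n+1)(n+3)}}.$$
Alternative conventions (population kurtosis, non-excess) would not
match this SEK and are not offered. $G_2$ requires $n \ge 4$ and
non-zero spread; SEK requires $n \ge 6$; below these the value is
reported missing with a warning rather than extrapolated.

**Which samples enter the ratio statistics.** The report's two
directional columns count *band* membership, and mean/SEM/kurtosis/SEK
are computed over those band-imbalanced samples only; the
mean-$\pm$-2SD outlier flag drives variant *selection*, not per-sample
counting. This is the only reading under which the directional columns
always sum to the imbalanced total and the SEM/SEK values are consistent
with $n$ = the imbalanced count.

## Numerical and boundary choices

- **Strict boundaries everywhere they matter.** QUAL 225 fails; $r$
  exactly 0.666 or 1.5 is balanced; cohort frequency exactly at the
  threshold is dropped; a value exactly on an outlier bound is not
  outside it — so a constant reference population (SD 0) flags nothing.
- **Log base.** Natural log. The outlier rule is equivariant under
  affine maps of the log ratios, so base choice cannot change flags;
  it is fixed for reproducibility of printed models.
- **Degenerate reference populations.** A sample (or variant, under
  `per_variant` scope) with fewer than two passing records cannot
  support a mean/SD estimate; its records are left unflagged with one
  warning. `fit_outlier_model()` itself refuses $n < 2$.
- **Single imbalanced sample.** SEM is 0 by convention, with a warning.
- **Report rounding.** Percentages to one decimal, ratios and SEM to
  three decimals, kurtosis and SEK to four significant figures; the
  written table re-parses to exactly those printed values.
- **Sex chromosomes.** Processed like autosomes but tagged
  (`is_sex_chrom`), since X-inactivation mimics *cis* regulation and
  merits separate interpretation, not separate statistics.
- **Multi-allelic and indel records** are never represented; `read_vcf()`
  drops them (with a count) or refuses the file on request.

## Open design choices

**Outlier-model scope.** A "mean ± 2 SD" rule needs a reference
population, and either axis of the variant × sample matrix is
defensible. The default is per sample — each sample's passing variants
form the population — because variant selection then asks "did any
sample find this variant extreme among everything that sample
expresses?", which composes naturally with the at-least-one-sample
retention rule and is robust to a variant having few heterozygotes. The
per-variant scope (samples within a variant) is available via
`outlier_scope`, and the scope used is recorded in the fitted model and
the run manifest.

**The single-hit rescue.** Retention keeps variants with at least one
outlier sample; the stricter multi-hit tier keeps those with two, *or*
with one outlier plus at least one additional moderately imbalanced
sample. The rescue acknowledges that a second sample just inside the
outlier bounds but clearly outside the 40–60% band is corroborating
evidence, while a lone extreme sample is more likely a private artifact.

**Band value 0.666.** The band is the 40/60 allele-percentage split,
whose exact lower ratio is $2/3$; 0.666 is the conventional printed
value and is used literally (configurable via `ratio_low`).

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the detector
assumes, with defaults fixed at the study conditions the package
targets: 52 samples; marker allele frequency 0.3 under Hardy–Weinberg;
depth $= 20 + \mathrm{NB}(\mu = 60, \text{size} = 8)$, i.e. mean 80
truncated at the 20× filter floor (size 8 gives a realistic
coefficient of variation ≈ 0.28 for per-site RNA-seq depth);
beta-binomial allele counts with intra-class correlation $\rho = 0.01$
(real allelic counts are overdispersed relative to binomial; $\rho$ is a
free parameter, as no empirical cohort estimate exists); 200 balanced
variants at fraction 0.5; and 50 cis-regulated variants where the
haplotype carrying the repressive regulatory allele yields 30% of
transcripts. The regulatory locus is a single biallelic site in LD with
the marker ($r^2 = 1$ by default, so the repressed haplotype always
carries the alternative marker allele and every heterozygote's ratio
tilts the same way). All randomness flows from one seed through
counter-derived per-variant substreams, so adding variants never
perturbs earlier ones and output is bit-identical under a fixed seed.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: read-level artifacts and mapping
bias (the dominant false-positive source in practice, handled in real
cohorts by blacklists and orthogonal validation), expression-level
(total-count) eQTL effects, multi-locus haplotypes, sample-specific
library effects, and genotyping error beyond missing calls.

Test and example problem sizes (tens of samples, a few hundred
variants, single-seed or small seed panels) are chosen so the full suite
exercises every stage at cohort scale while staying quick to run; the
statistical properties asserted are scale-free or averaged over fixed
seeds.

## Behavior under the null, and known limitations

The empirical mean ± 2 SD rule flags, by construction, roughly the
normal two-sided tail (≈ 4.6%) of *records* per reference population.
At the variant level this makes the any-hit retention rule deliberately
liberal: a balanced variant heterozygous in $h$ samples survives with
probability $\approx 1 - (1 - p)^h$, which for cohort-scale $h$ is
substantial. This is a property of the method, not a defect of the
implementation — it is why the pipeline stacks the multi-hit rule, the
recurrence (cohort-frequency) filter, the gene panel, manual region
blacklists, and orthogonal pyrosequencing validation on top of the raw
scan, and the property suite asserts the calibration of the per-sample
flag rate and the strict tightening from the multi-hit rule rather than
a small variant-level false-positive rate.

A second consequence of using an *empirical* reference population:
detection power depends on the prevalence of truly regulated sites. If
regulated variants dominate a sample's transcriptome, they inflate the
sample's own SD and can sit inside the bounds precisely when sequencing
is deep and their ratios concentrate; with regulated sites in the
minority (as in real transcriptomes), sensitivity increases with depth
and with effect size, which is what the monotonicity tests assert.

Further limitations, deliberate per scope: no phasing, no
reference-allele mapping-bias correction, no per-site binomial or
beta-binomial hypothesis test, no LD/annotation retrieval, and no
significance test between pyrosequencing DNA and RNA means (band
membership only, inclusive 40–60%).

## Pyrosequencing validation model

Technical replicates (the assay design uses three DNA-level PCRs and
four cDNA PCRs, but any $n \ge 1$ is accepted and recorded) are
aggregated to mean ± SEM per sample/SNP/level. AEI is *confirmed* when
the DNA level is balanced — ruling out genomic copy imbalance or assay
bias — while the RNA level falls outside the band; an unbalanced DNA
assay is flagged and never confirmed, whatever the RNA shows.
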