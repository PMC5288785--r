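---
title: "Methods: gene-level integration of histone marks and expression"
author: "markexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-level integration of histone marks and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markexpr)
```

## The analysis

`markexpr` implements a gene-level integration of bulk mRNA-seq and
histone-mark ChIP-seq for a two-genotype design — the motivating system is
mouse Sertoli cells from XY testes versus XX testes masculinized by an *Sry*
transgene, profiled for the active promoter mark H3K4me3 and the repressive
mark H3K27me3. The question the statistics answer is whether genes whose
expression differs between the genotypes also differ in mark deposition, in
the expected directions.

The pipeline has four quantitative layers:

1. **Expression.** Per-gene FPKM
   ($\mathrm{FPKM}_g = 10^9 c_g / (\ell_g N)$ for $c_g$ fragments on a
   transcript of $\ell_g$ bp in a library of $N$ fragments), averaged over
   replicates within genotype; the genotype comparison is the plain ratio
   $(\mathrm{FPKM}_{test} + \epsilon)/(\mathrm{FPKM}_{ref} + \epsilon)$ with
   pseudocount $\epsilon = 0.1$, classified `up`/`down`/`unchanged` by a
   strict fold-change cut (default 1.5; the mark association uses a stricter
   3-fold cut). There is no dispersion model or DE testing: the method being
   reproduced defines its gene lists purely by fold change.
2. **Mark enrichment.** Reads are counted in a mark-specific window —
   H3K4me3 in $[\mathrm{TSS} - 2\,\mathrm{kb}, \mathrm{TSS} + 2\,\mathrm{kb})$,
   H3K27me3 from 2 kb upstream of the TSS to the TTS — in both the ChIP and
   the matched input library; each count is RPM-normalized
   ($10^6 (c + 0.5)/N$, pseudocount 0.5 on both fractions) and the per-gene
   enrichment is the ChIP/input RPM ratio.
3. **Class-wise comparison.** For each mark and each expression class, an
   unpaired Welch *t*-test compares per-gene $\log_2$ enrichment between the
   two genotypes. A paired variant (one-sample *t* on per-gene differences)
   is available behind a flag, because the original description does not
   pin down which reading was used.
4. **Reporting.** Joint per-gene table of expression, H3K4me3 and H3K27me3
   $\log_2$ fold changes, and TSS-centered or scaled-gene-body metagene
   profiles (reads per million per bp).

## Coordinate and counting conventions

All tables and files use BED-style 0-based half-open intervals; GTF input is
converted on read. The TSS is the locus start on `+` and the locus end on
`-`, so the promoter window $[\mathrm{TSS} - f, \mathrm{TSS} + f)$ is
symmetric and off-by-one-free on both strands. A read is counted in a
window when it overlaps by at least 1 bp (the default behavior of the
interval-counting tools this rule replaces); duplicates are not collapsed —
the only read filter is uniqueness, carried in the BED score column
(score > 0 = uniquely mapped). One representative transcript per gene is
chosen as the longest (ties by transcript id), a deterministic stand-in for
an unstated choice. Where a chromosome size map is supplied, windows are
clipped at both ends; otherwise only at zero. Metagene profiles assign read
*midpoints* to bins (avoiding double counting across bins) while window
counts use any-overlap; the two conventions serve different purposes and are
deliberately not unified.

## Statistical choices

Enrichment ratios are right-skewed, so class-wise tests operate on
$\log_2$ enrichment (configurable off). Welch's unequal-variance form is
the default; the pooled Student form is available. Degenerate inputs are
defined rather than errors: both groups constant and equal gives $t = 0$,
$p = 1$; constant but different gives $p = 0$. No multiple-testing
correction is applied — the reproduced analysis reports raw p-values across
four class/mark combinations.

The expression fold change inherits FPKM's composition bias: when a few
strongly up-regulated genes inflate the test library's total, ratios of all
other genes deflate. The synthetic studies reproduce this visibly (more
`down` than `up` calls at equal planted numbers). This is a faithful
property of the method, not a defect of the generator.

## The synthetic-data generator

The generator stands in for the deposited mRNA-seq and ChIP-seq libraries
and is first-class, tested code. It emulates: two genotypes; genes with
planted up/down expression changes (half up, half down, default 20% of 200
genes at 4-fold); negative-binomial counts (dispersion 0.05) around
log-normal baselines (median ~30 expression units, `sdlog` 1.2) scaled by
transcript length; H3K4me3 reads Gaussian around the TSS
($\sigma$ = 500 bp); H3K27me3 reads uniform over the gene body; matched
uniform input libraries; and mark–expression coupling in the direction
observed in the motivating study — down-regulated genes lose H3K4me3
($2^{-1}$ by default) and gain H3K27me3 ($2^{+1}$), reversed for
up-regulated genes.

**Planted ratios are exact expected enrichments.** A naive "assign reads to
genes proportionally to weight × ratio" scheme makes the recovered
enrichment proportional to, but not equal to, the planted ratio (the
proportionality constant depends on every other gene's ratio through the
multinomial normalization). Instead each gene's window receives read
probability $p_g = \rho_g L_g / G$ exactly, and the remaining mass
$1 - B$ (with $B = \sum_g \rho_g L_g / G$) is placed uniformly on the
complement of all windows, so the expected window count is
$N \rho_g L_g / G$ against a uniform input expectation of
$N_{in} L_g / G$ — the expected RPM ratio is $\rho_g$ at any pair of
depths, for any positive $\rho_g$ (windows may be depleted as well as
enriched). The only validity condition is $B < 1$; violations raise a
"genome too small" error rather than silently rescaling. The
`background_fraction` knob shrinks planted ratios toward 1
($\rho_{eff} = 1 + (1 - bf)(\rho - 1)$); at `bf = 1` the ChIP library is
distributionally identical to the input.

Defaults not fixed by the emulated design were chosen once, on domain
grounds, and not revisited: chromosomes 2 × 3 Mb (large enough that the
total planted signal mass stays below the library total for both marks at
default couplings), baseline ratios 6 (H3K4me3) and 3 (H3K27me3) with
log-normal gene-to-gene spread `sdlog = 0.25`, 10^5 reads per library
(desk-scale; the real study's ~3 × 10^7 is reachable by config), read
length 50 bp, gene lengths log-uniform in [1, 20] kb with ≥ 4 kb spacing so
±2 kb windows never overlap neighbors.

**What a green test does not establish.** The generator has no mappability
or GC structure, no fragment-length distribution, no peak shape beyond the
Gaussian/uniform placements, no replicate structure for ChIP, and
single-exon gene models. Passing tests establish that the *pipeline's
arithmetic and statistics* behave as specified on data with known truth —
not that the biological conclusions of any particular study are correct.

Two calibration subtleties are worth recording. First, baseline mark
ratios are *shared* between genotypes (they model the same genome), which
makes the two class-wise groups positively correlated across genes; the
unpaired Welch test is conservative in that regime, which is the safe
direction in production. The type-I-error acceptance test therefore sets
`mark_ratio_sdlog = 0`, the regime where group values are iid and the
test's nominal level is the right yardstick; the paired variant
(`paired = TRUE`) is the more powerful choice when between-gene spread is
large. Second, library totals are fixed exactly, so window counts within
one library are multinomially (negatively) correlated; when the windows
jointly hold a large share of the library — as in a deliberately tiny
test genome — this deflates the variance of class means and makes the
test measurably conservative (we observed ~4.6% at signal mass
$B \approx 0.5$). Real libraries are in the opposite regime (one gene's
window holds a vanishing fraction of reads), and at $B \approx 0.05$ the
empirical level is 5.0%; the calibration test runs there.

## Determinism and reproducibility

All randomness flows from one integer seed; sub-generators reseed from
fixed offsets of it, so any library or table can be regenerated standalone.
The pipeline itself is RNG-free, and reruns on the same inputs are
byte-identical (asserted in the acceptance suite). A run manifest records
package and R versions, the seed and a hash of the configuration.

## Known limitations

- FPKM-only normalization; no TMM/median-of-ratios option.
- Welch on ~10–30 genes per class assumes approximate normality of
  $\log_2$ enrichment; heavy-tailed deviations are not handled.
- The metagene profile construction (bin width, midpoint assignment,
  per-gene and per-million normalization) substitutes for an external
  method that the reproduced description cites but does not specify.
- No peak calling, no local background, no input subtraction in profiles.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7)
st <- simulate_study(cfg, outdir = "study")
res <- run_pipeline("study/pipeline_config.txt", "report")
res$test_table
```

On this seed the down-class shows the planted pattern: lower H3K4me3
(t < 0) and higher H3K27me3 (t > 0) in the test genotype, both far below
p = 0.01. The same numbers appear in `report/class_tests.tsv`.
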