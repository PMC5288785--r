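# markexpr

Gene-level integration of bulk expression and histone-mark ChIP-seq in
two-genotype designs.

## The problem

When two genotypes of the same cell type differ in expression — the
motivating system is mouse Sertoli cells from XY testes versus XX testes
carrying an *Sry* transgene — a natural follow-up is whether the
differentially expressed genes also differ in chromatin state. `markexpr`
implements that comparison for the active promoter mark **H3K4me3** and
the repressive mark **H3K27me3**, for analysts who have per-gene fragment
counts (mRNA-seq) and aligned read positions (ChIP-seq + input) and want
the classic gene-level readout rather than peak calling.

## The model

- **Expression**: FPKM per gene,
  `FPKM_g = 1e9 * c_g / (len_g * total)`; fold change between genotypes
  `(FPKM_test + 0.1) / (FPKM_ref + 0.1)`; genes classified `up` / `down` /
  `unchanged` by a strict fold-change cut (1.5× for gene lists, 3× for the
  mark association).
- **Mark enrichment** per gene: reads counted in a mark-specific window —
  H3K4me3 in `[TSS − 2 kb, TSS + 2 kb)`, H3K27me3 from 2 kb upstream of
  the TSS to the TTS — RPM-normalized (`1e6 * (count + 0.5) / total`) in
  ChIP and input, and reported as the ChIP/input RPM ratio.
- **Association**: within each expression class, an unpaired Welch t-test
  compares per-gene log2 enrichment between genotypes
  (`t = (m1 − m2) / sqrt(s1²/n1 + s2²/n2)`, Welch–Satterthwaite df).
- **Profiles**: TSS-centered and scaled-gene-body metagene read densities
  (reads per million per bp).
- **Synthetic studies**: a generator plants expression fold changes and
  per-gene mark enrichment ratios (the planted ratio *is* the expected
  enrichment by construction) with mark–expression coupling, so the whole
  pipeline is testable without sequencing data.

All coordinates are BED-style 0-based half-open; GTF is converted on read.
BAM input is out of scope — convert with `bedtools bamtobed` first.

## Worked example

```r
library(markexpr)

cfg <- simulation_config(seed = 7)           # 200 genes, 1e5 reads/library
st  <- simulate_study(cfg, outdir = "study") # writes BED/GTF/TSV inputs
res <- run_pipeline("study/pipeline_config.txt", "report")
res$test_table
```

This prints (seed 7):

```
       mark de_class n_genes mean_test mean_ref statistic       df      p_value
1:  H3K4me3       up       7 2.9422548 1.877194  6.691769 11.42189 2.837455e-05
2:  H3K4me3     down      28 1.5541853 2.098435 -3.777101 45.12495 4.620174e-04
3: H3K27me3       up       7 0.4101648 1.186003 -5.225801 11.94190 2.160943e-04
4: H3K27me3     down      28 1.8311375 1.189593  5.485420 44.11059 1.900309e-06
```

Reading: among genes ≥3-fold **down** in the test genotype, mean log2
H3K4me3 enrichment drops from 2.10 to 1.55 (t = −3.78, p = 4.6e−4) while
H3K27me3 rises (t = +5.49, p = 1.9e−6) — the planted coupling, recovered
end to end. `report/` also contains the expression table and DE lists,
per-gene enrichment tables and between-genotype enrichment fold changes
for both marks, the joint expression/H3K4me3/H3K27me3 log2 fold-change
table, metagene profile TSVs, and a run manifest.

The same steps are available as a CLI
(`inst/cli/markexpr simulate|run|expression|enrich|profile`), e.g.:

```sh
Rscript -e 'markexpr::markexpr_main()' simulate --outdir study --seed 7
Rscript -e 'markexpr::markexpr_main()' run --config study/pipeline_config.txt --outdir report
```

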