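# RPM, ChIP/input enrichment, per-gene tables, metagene profiles

test_that("RPM and enrichment closed forms", {
  expect_equal(rpm(50, 2e6, 0), 25)
  expect_equal(rpm(0, 2e6, 0), 0)
  expect_equal(rpm(123, 3e7, 0.5), 1e6 * 123.5 / 3e7)
  expect_error(rpm(5, 0), "total_mapped")

  expect_equal(enrichment(25, 5), 5)
  expect_equal(enrichment(7, 7), 1)
  expect_error(enrichment(5, 0), "input_rpm")
  # zero input count with symmetric pseudocount: (10.5)/(0.5) at equal totals
  expect_equal(enrichment(rpm(10, 1e6), rpm(0, 1e6)), 21)
})

test_that("gene enrichment composes counting, RPM and ratio", {
  g <- toy_genes()[1]  # + strand, K4 window [8000, 12000)
  pad <- function(n, offset = 5e5)  # reads far from the window
    data.frame(chrom = "chr1", start = offset + seq_len(n) * 100,
               end = offset + seq_len(n) * 100 + 50)
  chip <- read_set(rbind(
    data.frame(chrom = "chr1", start = rep(9000, 20), end = rep(9050, 20)),
    pad(80)), "chip")
  inp <- read_set(rbind(
    data.frame(chrom = "chr1", start = rep(9000, 10), end = rep(9050, 10)),
    pad(90)), "input")
  tbl <- gene_enrichment_table(g, chip, inp, "H3K4me3", "XY",
                               pseudocount = 0)
  expect_equal(tbl$chip_count, 20)
  expect_equal(tbl$input_count, 10)
  expect_equal(tbl$enrichment, 2)  # equal totals (100 each), ratio 20/10

  same <- gene_enrichment_table(toy_genes(), chip, chip, "H3K4me3", "XY")
  expect_equal(same$enrichment, rep(1, 2))

  empty <- gene_enrichment_table(toy_genes()[0], chip, inp, "H3K4me3")
  expect_equal(nrow(empty), 0)
})

test_that("per-gene counts in the enrichment table match the oracle", {
  set.seed(31)
  n <- 50
  start <- sort(sample(seq(5000, 9e5, by = 15000), n))
  len <- sample(1000:8000, n, replace = TRUE)
  g <- gene_models(data.frame(
    gene_id = sprintf("g%02d", 1:n), chrom = "chr1", start = start,
    end = start + len, strand = sample(c("+", "-"), n, TRUE),
    transcript_length = len))
  chip <- read_set(random_reads(4000), "chip")
  inp <- read_set(random_reads(4000), "input")
  tbl <- gene_enrichment_table(g, chip, inp, "H3K27me3", "XY")
  regions <- mark_regions(g, "H3K27me3")
  expect_equal(tbl$chip_count, oracle_count_overlaps(chip$reads, regions))
  expect_equal(tbl$input_count, oracle_count_overlaps(inp$reads, regions))
})

test_that("enrichment is invariant to common library scaling and reciprocal", {
  expect_equal(enrichment(rpm(30, 1e6), rpm(10, 2e6)),
               enrichment(rpm(30, 1e7 * 0.1), rpm(10, 2e7 * 0.1)))
  # proportional counts and totals
  e1 <- enrichment(rpm(30, 1e6, 0), rpm(10, 2e6, 0))
  e2 <- enrichment(rpm(300, 1e7, 0), rpm(100, 2e7, 0))
  expect_equal(e1, e2)
  expect_equal(enrichment(rpm(30, 1e6), rpm(10, 2e6)) *
                 enrichment(rpm(10, 2e6), rpm(30, 1e6)), 1)
})

test_that("mirror-genome reflection leaves counts and enrichment unchanged", {
  set.seed(32)
  L <- 1e6
  n <- 30
  start <- sort(sample(seq(5000, 9.5e5, by = 20000), n))
  len <- sample(1000:10000, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, TRUE)
  g <- gene_models(data.frame(
    gene_id = sprintf("g%02d", 1:n), chrom = "chr1", start = start,
    end = start + len, strand = strand, transcript_length = len))
  reads <- random_reads(3000, chrom_len = L)
  chip <- read_set(reads, "chip")
  inp <- read_set(random_reads(3000, chrom_len = L), "input")

  flip <- function(df) {
    out <- data.table::copy(data.table::as.data.table(df))
    s <- out$start
    out$start <- L - out$end
    out$end <- L - s
    if (!is.null(out$strand))
      out$strand <- ifelse(out$strand == "+", "-",
                           ifelse(out$strand == "-", "+", "."))
    out
  }
  gf <- gene_models(flip(g)[, c("gene_id", "chrom", "start", "end",
                                "strand", "transcript_length"), with = FALSE])
  chipf <- read_set(flip(chip$reads), "chip")
  inpf <- read_set(flip(inp$reads), "input")
  for (mk in c("H3K4me3", "H3K27me3")) {
    a <- gene_enrichment_table(g, chip, inp, mk)
    b <- gene_enrichment_table(gf, chipf, inpf, mk)
    expect_equal(a$chip_count, b[match(a$gene_id, gene_id), chip_count])
    expect_equal(a$enrichment, b[match(a$gene_id, gene_id), enrichment])
  }
})

test_that("enrichment fold change: ratio, identity, and mark mismatch error", {
  g <- toy_genes()
  chip <- read_set(random_reads(500), "c")
  inp <- read_set(random_reads(500), "i")
  a <- gene_enrichment_table(g, chip, inp, "H3K4me3", "XXSry")
  b <- gene_enrichment_table(g, chip, inp, "H3K4me3", "XY")
  fc <- enrichment_fold_change(a, b)
  expect_equal(fc$fc, rep(1, 2))
  b2 <- data.table::copy(b)[, enrichment := enrichment / 2]
  expect_equal(enrichment_fold_change(a, b2)$fc, rep(2, 2))
  bad <- gene_enrichment_table(g, chip, inp, "H3K27me3", "XY")
  expect_error(enrichment_fold_change(a, bad), "mark mismatch")
})

test_that("planted 2-fold enrichment reduction is recovered on average", {
  cfg <- simulation_config(n_genes = 100, chrom_length = 4e6, n_chroms = 1,
                           reads_per_chip_library = 1e5,
                           reads_per_input_library = 1e5,
                           background_fraction = 0, seed = 51)
  genes <- simulate_genes(cfg)
  ratios_hi <- rep(6, 100)
  chip_hi <- simulate_chip_library(cfg, genes, "H3K4me3", "XY",
                                   ratios = ratios_hi, seed = 52)
  chip_lo <- simulate_chip_library(cfg, genes, "H3K4me3", "XXSry",
                                   ratios = ratios_hi / 2, seed = 53)
  inp1 <- simulate_chip_library(cfg, genes, "H3K4me3", "XY", seed = 54)
  inp2 <- simulate_chip_library(cfg, genes, "H3K4me3", "XXSry", seed = 55)
  hi <- gene_enrichment_table(genes, chip_hi, inp1, "H3K4me3", "XY")
  lo <- gene_enrichment_table(genes, chip_lo, inp2, "H3K4me3", "XXSry")
  fc <- enrichment_fold_change(lo, hi)
  expect_gt(mean(fc$fc), 0.45)
  expect_lt(mean(fc$fc), 0.55)
})

test_that("TSS-centered metagene assigns point masses and flips minus strand", {
  g <- toy_genes()  # geneA + tss 10000; geneB - tss 15000
  # 1-bp reads: one on each gene's first transcribed base (10000 on +,
  # 14999 on -) and one 500 bp upstream of it (9500 on +, 15499 on -);
  # after strand flipping both pairs land in the same bins
  rs <- mk_reads(c(10000, 14999, 9500, 15499),
                 c(10001, 15000, 9501, 15500))
  pr <- metagene_profile(rs, g, "tss_centered", window = 2000, n_bins = 40)
  expect_equal(sum(pr$counts), 4)
  # TSS base maps to relative position 2000 on both strands -> bin 21 of 40
  expect_equal(pr$counts[21], 2)
  # upstream reads: relative 1500 -> bin 16, identical for both strands
  expect_equal(pr$counts[16], 2)
  expect_true(all(pr$density >= 0))
  # density normalization: counts = density * bw * n_genes * total/1e6
  expect_equal(sum(pr$density * pr$bin_width) * pr$n_genes *
                 rs$total_mapped / 1e6, 4)
})

test_that("scaled-body metagene places body and flank reads correctly", {
  g <- toy_genes()[1]  # + strand [10000, 15000), body length 5000
  # 1-bp reads: 1.5 kb upstream, 10% into body, 90% into body, 0.5 kb
  # downstream of the TTS
  rs <- mk_reads(c(8500, 10500, 14500, 15500),
                 c(8501, 10501, 14501, 15501))
  pr <- metagene_profile(rs, g, "scaled_body", window = 2000, n_bins = 10)
  n_flank <- max(1, round(10 / 5))  # 2 flank bins of 1 kb each
  expect_equal(pr$n_bins, 10 + 2 * n_flank)
  expect_equal(sum(pr$counts), 4)
  expect_equal(pr$counts[1], 1)                   # upstream, first flank bin
  expect_equal(pr$counts[n_flank + 2], 1)         # 10% of body -> body bin 2
  expect_equal(pr$counts[n_flank + 10], 1)        # 90% of body -> body bin 10
  expect_equal(pr$counts[n_flank + 10 + 1], 1)    # first downstream bin
  expect_error(metagene_profile(rs, toy_genes()[0], "scaled_body"), "no genes")
})
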