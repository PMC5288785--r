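# synthetic-study generator

test_that("simulated genes are window-disjoint, in-bounds, and deterministic", {
  cfg <- simulation_config(n_genes = 60, seed = 81)
  g1 <- simulate_genes(cfg)
  g2 <- simulate_genes(cfg)
  expect_equal(g1, g2)
  expect_equal(nrow(g1), 60)
  sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                    paste0("chr", 1:cfg$n_chroms))
  expect_true(all(g1$start >= 0 & g1$end <= sizes[g1$chrom]))
  # +/-2 kb windows of neighbors never overlap (>= 4 kb spacing)
  dt <- data.table::as.data.table(g1)
  gaps <- dt[, start[-1] - end[-.N], by = chrom]$V1
  expect_true(all(gaps >= 4000))
  # K4 windows unclipped and pairwise disjoint
  k4 <- mark_regions(g1, "H3K4me3", chrom_sizes = sizes)
  expect_true(all(k4$end - k4$start == 4000))

  expect_error(simulate_genes(simulation_config(n_genes = 500,
                                                chrom_length = 1e6,
                                                n_chroms = 1, seed = 1)),
               "genome too small")
})

test_that("strand assignment is balanced over many genes", {
  cfg <- simulation_config(n_genes = 2000, chrom_length = 4e7, n_chroms = 1,
                           seed = 82)
  g <- simulate_genes(cfg)
  p <- mean(g$strand == "+")
  ci <- 2.576 * sqrt(0.25 / 2000)  # binomial 99% CI around 0.5
  expect_gt(p, 0.5 - ci)
  expect_lt(p, 0.5 + ci)
})

test_that("expression simulation: planted classes, null case, determinism", {
  cfg <- simulation_config(n_genes = 100, seed = 83)
  g <- simulate_genes(cfg)
  ex1 <- simulate_expression(cfg, g)
  ex2 <- simulate_expression(cfg, g)
  expect_equal(ex1$counts, ex2$counts)
  expect_equal(table(ex1$truth$de_class)[["up"]], 10)
  expect_equal(table(ex1$truth$de_class)[["down"]], 10)
  expect_error(simulate_expression(
    simulation_config(n_genes = 100, de_fraction = 0, seed = 1), g),
    "de_fraction")

  null_cfg <- simulation_config(n_genes = 100, expr_log2fc_effect = 0,
                                seed = 84)
  exn <- simulate_expression(null_cfg, g)
  expect_true(all(exn$truth$de_class == "unchanged"))
})

test_that("deep-count planted expression effects are recovered at 3-fold", {
  cfg <- simulation_config(n_genes = 200, expr_log2fc_effect = 2,
                           count_dispersion = 0.005, expr_depth = 30,
                           seed = 85)
  g <- simulate_genes(cfg)
  ex <- simulate_expression(cfg, g)
  fc <- expression_fold_change(ex$counts, ex$samples, "XXSry", "XY",
                               threshold = 3)
  planted <- ex$truth$de_class != "unchanged"
  agree <- fc$de_class[match(ex$truth$gene_id, fc$gene_id)][planted] ==
    ex$truth$de_class[planted]
  expect_gte(mean(agree), 0.95)
})

test_that("library totals, bounds, and determinism of read simulation", {
  cfg <- simulation_config(n_genes = 50, reads_per_chip_library = 2e4,
                           reads_per_input_library = 1.5e4, seed = 86)
  g <- simulate_genes(cfg)
  chip <- simulate_chip_library(cfg, g, "H3K4me3", "XY",
                                ratios = rep(4, 50), seed = 87)
  inp <- simulate_chip_library(cfg, g, "H3K4me3", "XY", seed = 88)
  expect_equal(chip$total_mapped, 2e4)
  expect_equal(inp$total_mapped, 1.5e4)
  sizes <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                    paste0("chr", 1:cfg$n_chroms))
  for (rs in list(chip, inp)) {
    expect_true(all(rs$reads$start >= 0))
    expect_true(all(rs$reads$end <= sizes[rs$reads$chrom]))
    expect_true(all(rs$reads$end - rs$reads$start == cfg$read_length))
  }
  chip2 <- simulate_chip_library(cfg, g, "H3K4me3", "XY",
                                 ratios = rep(4, 50), seed = 87)
  expect_equal(chip$reads, chip2$reads)
})

test_that("background_fraction = 1 collapses ChIP onto the input distribution", {
  cfg <- simulation_config(n_genes = 80, background_fraction = 1,
                           reads_per_chip_library = 1e5,
                           reads_per_input_library = 1e5, seed = 89)
  g <- simulate_genes(cfg)
  chip <- simulate_chip_library(cfg, g, "H3K4me3", "XY",
                                ratios = rep(8, 80), seed = 90)
  inp <- simulate_chip_library(cfg, g, "H3K4me3", "XY", seed = 91)
  e <- gene_enrichment_table(g, chip, inp, "H3K4me3", "XY")
  expect_equal(mean(e$enrichment), 1, tolerance = 0.1)
})

test_that("one strongly weighted gene stands out by about its planted factor", {
  cfg <- simulation_config(n_genes = 100, chrom_length = 6e6, n_chroms = 1,
                           background_fraction = 0,
                           reads_per_chip_library = 1e5,
                           reads_per_input_library = 1e5, seed = 92)
  g <- simulate_genes(cfg)
  ratios <- rep(2, 100)
  ratios[37] <- 16
  chip <- simulate_chip_library(cfg, g, "H3K4me3", "XY", ratios = ratios,
                                seed = 93)
  inp <- simulate_chip_library(cfg, g, "H3K4me3", "XY", seed = 94)
  e <- gene_enrichment_table(g, chip, inp, "H3K4me3", "XY")
  rel <- e$enrichment[37] / median(e$enrichment[-37])
  expect_gt(rel, 8 * 0.8)
  expect_lt(rel, 8 * 1.2)
})

test_that("zero coupling centers between-genotype enrichment changes on 1", {
  cfg <- simulation_config(n_genes = 200, k4_coupling = 0, k27_coupling = 0,
                           seed = 95)
  st <- simulate_study(cfg)
  e_ref <- gene_enrichment_table(st$genes, st$libraries$H3K4me3_chip_XY,
                                 st$libraries$H3K4me3_input_XY,
                                 "H3K4me3", "XY")
  e_test <- gene_enrichment_table(st$genes, st$libraries$H3K4me3_chip_XXSry,
                                  st$libraries$H3K4me3_input_XXSry,
                                  "H3K4me3", "XXSry")
  fc <- enrichment_fold_change(e_test, e_ref)
  expect_lt(abs(mean(fc$log2fc)), 0.05)
})

test_that("written study round-trips through the package readers", {
  cfg <- simulation_config(n_genes = 40, reads_per_chip_library = 5e3,
                           reads_per_input_library = 5e3, seed = 96)
  outdir <- file.path(tempdir(), "study_rt")
  st <- simulate_study(cfg, outdir = outdir)
  g_bed <- read_gene_annotation(st$paths$annotation_bed)
  g_gtf <- read_gene_annotation(st$paths$annotation_gtf)
  for (gg in list(g_bed, g_gtf)) {
    expect_equal(gg$gene_id, st$genes$gene_id)
    expect_equal(gg$start, st$genes$start)
    expect_equal(gg$end, st$genes$end)
    expect_equal(gg$tss, st$genes$tss)
    expect_equal(gg$transcript_length, st$genes$transcript_length)
  }
  lib <- read_alignments_bed(st$paths$reads_H3K4me3_chip_XY)
  expect_equal(lib$total_mapped, 5e3)
  expect_equal(lib$reads$start, st$libraries$H3K4me3_chip_XY$reads$start)
  inp <- read_expression_input(st$paths$counts, st$paths$samples)
  expect_equal(inp$counts$gene_id, st$genes$gene_id)
  unlink(outdir, recursive = TRUE)
})

test_that("stronger coupling lowers the down-class p-value in expectation", {
  # monotone trend of mean log10 p over couplings {0, 1, 2}, 4 seeds each
  mean_logp <- vapply(c(0, 1, 2), function(cpl) {
    mean(vapply(1:4, function(s) {
      cfg <- simulation_config(n_genes = 100, chrom_length = 4e6,
                               k4_coupling = cpl, seed = 100 + 10 * cpl + s,
                               reads_per_chip_library = 3e4,
                               reads_per_input_library = 3e4)
      st <- simulate_study(cfg)
      eA <- gene_enrichment_table(st$genes, st$libraries$H3K4me3_chip_XY,
                                  st$libraries$H3K4me3_input_XY, "H3K4me3")
      eB <- gene_enrichment_table(st$genes, st$libraries$H3K4me3_chip_XXSry,
                                  st$libraries$H3K4me3_input_XXSry, "H3K4me3")
      res <- mark_vs_expression_test(eB, eA, st$truth[, .(gene_id, de_class)],
                                     classes = "down")
      log10(res$down$p_value + 1e-300)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_logp) < 0))
})
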