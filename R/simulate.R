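# Synthetic two-genotype study generator.
#
# The generator plants (i) expression fold changes (negative-binomial counts
# around log-normal baselines), and (ii) per-gene mark enrichment ratios
# whose read libraries are constructed so that the planted ratio IS the
# expected ChIP/input enrichment of the gene's counting window. Read
# allocation: gene g's window (length L_g, genome length G) receives read
# probability p_g = rho_g * L_g / G exactly, and the remaining mass
# p_bg = 1 - B (B = sum(rho_g L_g)/G, must be < 1) is placed uniformly on
# the complement of all windows. Then E[window count] = N * rho_g * L_g / G
# while the matched input library is uniform with E = N_in * L_g / G, so
# the expected RPM ratio is rho_g at any pair of depths and for any
# positive rho (windows may be depleted as well as enriched).
# `background_fraction` shrinks planted ratios toward 1
# (rho_eff = 1 + (1 - bf) * (rho - 1)); bf = 1 gives a library whose
# per-window mass matches the input exactly.

#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic study. Defaults
#' describe a desk-scale study mirroring the real design: two genotypes
#' (reference "XY", test "XXSry"), one ChIP and one input library per mark
#' and genotype, planted expression changes coupled to both marks in the
#' observed direction (down-regulated genes lose H3K4me3 and gain H3K27me3
#' in the test genotype, and vice versa for up-regulated genes).
#'
#' @param n_genes Number of genes (default 200).
#' @param chrom_length,n_chroms Chromosome length in bp and count
#'   (default 3e6 x 2).
#' @param gene_length_min,gene_length_max Gene lengths are log-uniform in
#'   this range (defaults 1e3, 2e4 bp).
#' @param de_fraction Fraction of genes with planted expression change,
#'   half up / half down (default 0.2).
#' @param expr_log2fc_effect Planted |log2| expression effect (default 2,
#'   i.e. 4-fold).
#' @param count_dispersion Negative-binomial dispersion (1/size) of counts
#'   (default 0.05).
#' @param expr_meanlog,expr_sdlog Log-normal baseline of expression levels
#'   (defaults log(30), 1.2).
#' @param expr_depth Multiplier on expected fragment counts (default 1).
#' @param n_replicates mRNA-seq replicates per genotype (default 1,
#'   matching a single-library design).
#' @param reads_per_chip_library,reads_per_input_library Reads per ChIP /
#'   input library (defaults 1e5).
#' @param read_length Read length in bp (default 50).
#' @param k4_sigma Gaussian spread of promoter (H3K4me3) reads around the
#'   TSS in bp (default 500).
#' @param k4_base,k27_base Baseline planted enrichment ratios for the two
#'   marks (defaults 6 and 3: promoter marks concentrate more than
#'   body marks).
#' @param mark_ratio_sdlog Between-gene log-normal spread of baseline
#'   ratios (default 0.25).
#' @param k4_coupling Log2 decrease of H3K4me3 ratio per planted
#'   down-regulation in the test genotype (default 1); up-regulated genes
#'   get the opposite sign.
#' @param k27_coupling Log2 increase of H3K27me3 ratio per planted
#'   down-regulation (default 1), reversed for up genes.
#' @param background_fraction Shrinkage of planted ratios toward 1
#'   (default 0.3); 1 yields input-like ChIP libraries.
#' @param seed Integer seed; all randomness flows from it (default 1).
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_genes = 200, chrom_length = 3e6, n_chroms = 2,
                              gene_length_min = 1e3, gene_length_max = 2e4,
                              de_fraction = 0.2, expr_log2fc_effect = 2,
                              count_dispersion = 0.05,
                              expr_meanlog = log(30), expr_sdlog = 1.2,
                              expr_depth = 1, n_replicates = 1,
                              reads_per_chip_library = 1e5,
                              reads_per_input_library = 1e5,
                              read_length = 50, k4_sigma = 500,
                              k4_base = 6, k27_base = 3,
                              mark_ratio_sdlog = 0.25,
                              k4_coupling = 1, k27_coupling = 1,
                              background_fraction = 0.3, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$chrom_length > 0, cfg$n_chroms >= 1,
            cfg$gene_length_min >= 1,
            cfg$gene_length_max >= cfg$gene_length_min,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$background_fraction >= 0, cfg$background_fraction <= 1,
            cfg$reads_per_chip_library >= 1, cfg$reads_per_input_library >= 1,
            cfg$read_length >= 1, cfg$k4_sigma > 0, cfg$n_replicates >= 1,
            cfg$k4_base > 0, cfg$k27_base > 0, cfg$mark_ratio_sdlog >= 0)
  if (cfg$count_dispersion <= 0)
    stop("simulation_config: count_dispersion must be > 0")
  cfg$seed <- as.integer(cfg$seed) %% 2000000000L
  structure(cfg, class = "simulation_config")
}

.sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

# minimum per-gene footprint: length + 4 kb spacing so +/-2 kb windows of
# neighbors never overlap
.MIN_SPACING <- 4000
.EDGE_MARGIN <- 2500  # keep windows clear of chromosome ends

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` genes with log-uniform lengths and random strands across
#' the configured chromosomes, with at least 4 kb between neighboring genes
#' so that +/-2 kb promoter windows never overlap, and a margin at
#' chromosome ends so windows are never clipped. Genes are single-exon:
#' `transcript_length` equals the locus length.
#'
#' @param config A [simulation_config].
#' @param seed Optional seed override (default `config$seed`).
#' @return A [gene_models] table.
#' @export
simulate_genes <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_genes
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chroms + 1)))
  mean_len <- (config$gene_length_max - config$gene_length_min) /
    max(log(config$gene_length_max / config$gene_length_min), 1e-9)
  need <- max(per_chrom) * (config$gene_length_max + 2 * .MIN_SPACING) +
    2 * .EDGE_MARGIN
  rows <- vector("list", config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    k <- per_chrom[ci]
    if (!k) next
    lens <- round(exp(runif(k, log(config$gene_length_min),
                            log(config$gene_length_max))))
    # required worst-case span on this chromosome
    min_need <- sum(lens) + (k + 1) * .MIN_SPACING + 2 * .EDGE_MARGIN
    if (min_need > config$chrom_length)
      stop("simulate_genes: genome too small; chromosome of ",
           config$chrom_length, " bp cannot hold ", k,
           " genes (needs >= ", min_need, " bp)")
    slack <- config$chrom_length - min_need
    # distribute the slack over the k+1 gaps at random
    extra <- if (slack > 0) {
      u <- sort(runif(k, 0, slack))
      diff(c(0, u, slack))
    } else rep(0, k + 1)
    gaps <- .MIN_SPACING + extra
    starts <- .EDGE_MARGIN + cumsum(gaps[seq_len(k)]) +
      cumsum(c(0, lens[-k]))
    rows[[ci]] <- data.table(
      gene_id = character(k), chrom = paste0("chr", ci),
      start = round(starts), end = round(starts) + lens,
      strand = sample(c("+", "-"), k, replace = TRUE),
      transcript_length = lens)
  }
  g <- rbindlist(rows)
  setorder(g, chrom, start)
  g[, gene_id := sprintf("g%04d", seq_len(.N))]
  gene_models(g)
}

#' Simulate expression counts for two genotypes
#'
#' Baseline expected counts are log-normal (scaled by transcript length so
#' that FPKM-like levels are length-free); a planted fraction of genes gets
#' its test-genotype mean multiplied by `2^(+/- expr_log2fc_effect)` (half
#' up, half down); counts are negative-binomial with the configured
#' dispersion.
#'
#' @param config A [simulation_config].
#' @param genes A [gene_models] table.
#' @param seed Optional seed override.
#' @return List with `counts` (data.table: `gene_id`, `length`, one column
#'   per sample), `samples` (sample sheet), and `truth` (`gene_id`,
#'   `de_class`, `expr_log2fc`).
#' @export
simulate_expression <- function(config, genes, seed = config$seed + 1L) {
  set.seed(seed)
  g <- as.data.table(genes)
  n <- nrow(g)
  n_de <- round(config$de_fraction * n)
  if (config$expr_log2fc_effect != 0 && n_de < 2)
    stop("simulate_expression: de_fraction * n_genes must be >= 2")
  s <- numeric(n)
  if (config$expr_log2fc_effect != 0 && n_de >= 2) {
    de <- sample.int(n, n_de)
    s[de[seq_len(floor(n_de / 2))]] <- 1
    s[de[(floor(n_de / 2) + 1):n_de]] <- -1
  }
  q <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  mu_ref <- q * g$transcript_length / 1000 * config$expr_depth
  mu_test <- mu_ref * 2^(s * config$expr_log2fc_effect)
  size <- 1 / config$count_dispersion
  counts <- data.table(gene_id = g$gene_id, length = g$transcript_length)
  samples <- list()
  for (rep_i in seq_len(config$n_replicates)) {
    ref_col <- sprintf("XY_rep%d", rep_i)
    test_col <- sprintf("XXSry_rep%d", rep_i)
    counts[[ref_col]] <- rnbinom(n, mu = mu_ref, size = size)
    counts[[test_col]] <- rnbinom(n, mu = mu_test, size = size)
    samples[[length(samples) + 1]] <- data.table(
      sample_id = c(ref_col, test_col), genotype = c("XY", "XXSry"))
  }
  truth <- data.table(
    gene_id = g$gene_id,
    de_class = ifelse(s > 0, "up", ifelse(s < 0, "down", "unchanged")),
    expr_log2fc = s * config$expr_log2fc_effect)
  list(counts = counts, samples = rbindlist(samples), truth = truth)
}

# allocation probabilities; see header comment
.chip_allocation <- function(config, regions) {
  G <- config$n_chroms * config$chrom_length
  L <- regions$end - regions$start
  p_gene <- regions$rho_eff * L / G
  B <- sum(p_gene)
  if (B >= 1)
    stop("simulate_chip_library: genome too small for requested enrichment ",
         "(signal mass B = ", round(B, 3), " must be < 1; increase ",
         "chrom_length or lower ratios)")
  list(p_bg = 1 - B, p_gene = p_gene, G = G)
}

# uniform read midpoints over the complement of the (disjoint) windows
.complement_reads <- function(n, config, sizes, regions) {
  if (!n) return(data.table(chrom = character(), start = numeric(),
                            end = numeric()))
  comp <- rbindlist(lapply(names(sizes), function(ch) {
    r <- regions[regions$chrom == ch]
    setorder(r, start)
    bounds <- c(0, as.vector(rbind(r$start, r$end)), sizes[[ch]])
    s <- bounds[seq(1, length(bounds), by = 2)]
    e <- bounds[seq(2, length(bounds), by = 2)]
    data.table(chrom = ch, start = s, end = e)[end > start]
  }))
  len <- comp$end - comp$start
  idx <- sample.int(nrow(comp), n, replace = TRUE, prob = len)
  mid <- comp$start[idx] + floor(runif(n, 0, len[idx]))
  .reads_from_midpoints(comp$chrom[idx], mid, config$read_length, sizes)
}

# uniform read midpoints over the genome -> read table
.uniform_reads <- function(n, config, sizes) {
  if (!n) return(data.table(chrom = character(), start = numeric(),
                            end = numeric()))
  chrom <- sample(names(sizes), n, replace = TRUE,
                  prob = sizes / sum(sizes))
  mid <- floor(runif(n, 0, sizes[chrom]))
  .reads_from_midpoints(chrom, mid, config$read_length, sizes)
}

.reads_from_midpoints <- function(chrom, mid, read_length, sizes) {
  start <- round(mid) - read_length %/% 2
  start <- pmax(0, pmin(start, sizes[chrom] - read_length))
  data.table(chrom = chrom, start = start, end = start + read_length,
             strand = ".")
}

#' Simulate one ChIP or input read library
#'
#' ChIP libraries place each read either in the background (uniform over
#' the complement of all mark windows) or inside a gene's mark window, with
#' window probabilities chosen so that the planted ratio equals the
#' expected ChIP/input enrichment (see the module header). Within a
#' window, H3K4me3 reads are
#' Gaussian around the TSS (`sd = k4_sigma`) and H3K27me3 reads uniform over
#' the gene body. Input libraries (`ratios = NULL`) are uniform over the
#' genome. The library total equals the configured read number exactly.
#'
#' @param config A [simulation_config].
#' @param genes A [gene_models] table.
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param genotype Genotype label (used in the library id).
#' @param ratios Planted per-gene enrichment ratios (> 0), in `genes` order;
#'   `NULL` simulates the matched uniform input library.
#' @param seed Optional seed override.
#' @param apply_background Shrink ratios toward 1 by
#'   `config$background_fraction` (default `TRUE`); the study-level
#'   generator pre-shrinks, tests that plant exact ratios can disable it by
#'   setting `background_fraction = 0`.
#' @return A [read_set] with id `<mark>_<chip|input>_<genotype>`.
#' @export
simulate_chip_library <- function(config, genes,
                                  mark = c("H3K4me3", "H3K27me3"),
                                  genotype = "XY", ratios = NULL,
                                  seed = config$seed + 2L,
                                  apply_background = TRUE) {
  mark <- match.arg(mark)
  set.seed(seed)
  sizes <- .sim_chrom_sizes(config)
  g <- as.data.table(genes)
  if (is.null(ratios)) {
    n <- config$reads_per_input_library
    return(read_set(.uniform_reads(n, config, sizes),
                    paste(mark, "input", genotype, sep = "_")))
  }
  if (length(ratios) != nrow(g) || any(ratios <= 0))
    stop("simulate_chip_library: ratios must be positive, one per gene")
  bf <- if (apply_background) config$background_fraction else 0
  regions <- mark_regions(g, mark, flank = 2000, chrom_sizes = sizes)
  regions[, rho_eff := 1 + (1 - bf) * (ratios - 1)]
  if (any(regions$rho_eff <= 0))
    stop("simulate_chip_library: effective ratio <= 0")
  alloc <- .chip_allocation(config, regions)
  n <- config$reads_per_chip_library
  comp <- sample.int(nrow(g) + 1L, n, replace = TRUE,
                     prob = c(alloc$p_bg, alloc$p_gene)) - 1L
  bg <- comp == 0L
  out <- vector("list", 2)
  out[[1]] <- .complement_reads(sum(bg), config, sizes, regions)
  idx <- comp[!bg]
  if (length(idx)) {
    if (mark == "H3K4me3") {
      mid <- rnorm(length(idx), mean = g$tss[idx], sd = config$k4_sigma)
    } else {
      mid <- runif(length(idx), g$start[idx], g$end[idx])
    }
    mid <- floor(pmax(0, pmin(mid, sizes[g$chrom[idx]] - 1)))
    out[[2]] <- .reads_from_midpoints(g$chrom[idx], mid, config$read_length,
                                      sizes)
  }
  reads <- rbindlist(out)
  read_set(reads, paste(mark, "chip", genotype, sep = "_"))
}

#' Simulate a complete two-genotype study
#'
#' Composes gene, expression and library simulation. Baseline mark ratios
#' are log-normal around `k4_base` / `k27_base` and shared between
#' genotypes; in the test genotype, planted down-regulated genes have their
#' H3K4me3 ratio scaled by `2^-k4_coupling` and their H3K27me3 ratio by
#' `2^+k27_coupling` (reversed for up-regulated genes) — the direction in
#' which an active promoter mark tracks expression loss and a repressive
#' body mark tracks expression gain. When `outdir` is given, all artifacts
#' are written in the pipeline's input formats together with a ready-to-run
#' pipeline configuration.
#'
#' @param config A [simulation_config].
#' @param outdir Optional output directory.
#' @return Object of class `simulated_study`: list with `config`, `genes`,
#'   `counts`, `samples`, `truth` (planted classes, expression log2fc and
#'   per-mark per-genotype ratios), `libraries` (named list of [read_set];
#'   names `<mark>_<chip|input>_<genotype>`), `chrom_sizes`, and `paths`
#'   when written to disk.
#' @export
simulate_study <- function(config = simulation_config(), outdir = NULL) {
  genes <- simulate_genes(config, seed = config$seed)
  expr <- simulate_expression(config, genes, seed = config$seed + 1L)
  n <- nrow(genes)
  set.seed(config$seed + 2L)
  base_k4 <- config$k4_base * rlnorm(n, 0, config$mark_ratio_sdlog)
  base_k27 <- config$k27_base * rlnorm(n, 0, config$mark_ratio_sdlog)
  dir_sign <- ifelse(expr$truth$de_class == "down", -1,
                     ifelse(expr$truth$de_class == "up", 1, 0))
  ratios <- list(
    H3K4me3 = list(XY = base_k4,
                   XXSry = base_k4 * 2^(dir_sign * config$k4_coupling)),
    H3K27me3 = list(XY = base_k27,
                    XXSry = base_k27 * 2^(-dir_sign * config$k27_coupling)))
  libs <- list()
  i <- 0L
  for (mk in c("H3K4me3", "H3K27me3")) {
    for (geno in c("XY", "XXSry")) {
      libs[[paste(mk, "chip", geno, sep = "_")]] <-
        simulate_chip_library(config, genes, mk, geno,
                              ratios = ratios[[mk]][[geno]],
                              seed = config$seed + 10L + i)
      libs[[paste(mk, "input", geno, sep = "_")]] <-
        simulate_chip_library(config, genes, mk, geno, ratios = NULL,
                              seed = config$seed + 20L + i)
      i <- i + 1L
    }
  }
  truth <- copy(expr$truth)
  truth[, `:=`(k4_ratio_XY = ratios$H3K4me3$XY,
               k4_ratio_XXSry = ratios$H3K4me3$XXSry,
               k27_ratio_XY = ratios$H3K27me3$XY,
               k27_ratio_XXSry = ratios$H3K27me3$XXSry)]
  study <- structure(list(config = config, genes = genes,
                          counts = expr$counts, samples = expr$samples,
                          truth = truth, libraries = libs,
                          chrom_sizes = .sim_chrom_sizes(config)),
                     class = "simulated_study")
  if (!is.null(outdir)) study$paths <- write_study(study, outdir)
  study
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("simulated_study: ", nrow(x$genes), " genes on ",
      x$config$n_chroms, " chromosome(s), ",
      length(x$libraries), " read libraries, seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study to disk in pipeline input formats
#'
#' Writes the annotation (BED12 and GTF), per-library BED6 reads, the count
#' table, sample sheet, planted truth, the simulation parameters, and a
#' ready pipeline configuration (`pipeline_config.txt`).
#'
#' @param study A `simulated_study`.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- list()
  g <- study$genes
  bed12 <- data.table(g$chrom, as.integer(g$start), as.integer(g$end),
                      g$gene_id, 0L, g$strand, as.integer(g$start),
                      as.integer(g$end), "0", 1L,
                      paste0(as.integer(g$transcript_length), ","),
                      "0,")
  p$annotation_bed <- file.path(outdir, "genes.bed")
  fwrite(bed12, p$annotation_bed, sep = "\t", col.names = FALSE,
         quote = FALSE, scipen = 50L)
  p$annotation_gtf <- file.path(outdir, "genes.gtf")
  .write_gtf(g, p$annotation_gtf)
  p$counts <- file.path(outdir, "counts.tsv")
  fwrite(study$counts, p$counts, sep = "\t", quote = FALSE)
  p$samples <- file.path(outdir, "samples.tsv")
  fwrite(study$samples, p$samples, sep = "\t", quote = FALSE)
  p$truth <- file.path(outdir, "truth.tsv")
  fwrite(study$truth, p$truth, sep = "\t", quote = FALSE)
  for (nm in names(study$libraries)) {
    p[[paste0("reads_", nm)]] <- file.path(outdir, paste0("reads_", nm, ".bed"))
    write_bed(study$libraries[[nm]], p[[paste0("reads_", nm)]])
  }
  cfg_lines <- c(
    paste("annotation =", p$annotation_bed),
    paste("counts =", p$counts),
    paste("sample_sheet =", p$samples),
    "genotype_ref = XY",
    "genotype_test = XXSry",
    vapply(names(study$libraries), function(nm)
      paste0("reads_", nm, " = ", p[[paste0("reads_", nm)]]), ""),
    paste("seed =", study$config$seed))
  p$pipeline_config <- file.path(outdir, "pipeline_config.txt")
  writeLines(cfg_lines, p$pipeline_config)
  sim_cfg <- unclass(study$config)
  writeLines(paste(names(sim_cfg), unlist(sim_cfg), sep = " = "),
             file.path(outdir, "simulation_config.txt"))
  p$simulation_config <- file.path(outdir, "simulation_config.txt")
  invisible(p)
}

.write_gtf <- function(g, path) {
  attr_of <- function(id) sprintf(
    'gene_id "%s"; transcript_id "%s.t1";', id, id)
  lines <- c(
    sprintf("%s\tmarkexpr\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
            g$gene_id),
    sprintf("%s\tmarkexpr\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
            attr_of(g$gene_id)),
    sprintf("%s\tmarkexpr\texon\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, as.integer(g$start) + 1L, as.integer(g$end), g$strand,
            attr_of(g$gene_id)))
  ord <- order(rep(seq_len(nrow(g)), 3))
  writeLines(lines[ord], path)
}
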