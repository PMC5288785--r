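# Per-gene histone-mark enrichment and metagene profiles.
#
# Enrichment of a mark at a gene is the ratio of RPM in the ChIP library to
# RPM in the matched input library, counted over the mark-specific window
# (promoter +/- flank for H3K4me3; upstream flank to TTS for H3K27me3).
# A symmetric pseudocount on both counts keeps ratios finite at empty
# windows.

#' Reads per million
#'
#' `1e6 * (count + pseudocount) / total_mapped`.
#'
#' @param count Region read count(s).
#' @param total_mapped Library total of retained (unique) reads, >= 1.
#' @param pseudocount Added to the count before scaling (default 0.5).
#' @return RPM value(s).
#' @export
rpm <- function(count, total_mapped, pseudocount = 0.5) {
  if (any(total_mapped < 1))
    stop("rpm: total_mapped must be >= 1")
  if (any(count < 0) || pseudocount < 0)
    stop("rpm: negative count or pseudocount")
  1e6 * (count + pseudocount) / total_mapped
}

#' ChIP/input enrichment
#'
#' @param chip_rpm,input_rpm RPM in the ChIP and input fractions;
#'   `input_rpm` must be > 0 (guaranteed upstream by the pseudocount).
#' @return `chip_rpm / input_rpm`.
#' @export
enrichment <- function(chip_rpm, input_rpm) {
  if (any(input_rpm <= 0)) stop("enrichment: input_rpm must be > 0")
  chip_rpm / input_rpm
}

#' Per-gene enrichment table for one mark and genotype
#'
#' Counts ChIP and input reads over each gene's mark-specific window,
#' normalizes both to RPM (with a shared pseudocount) and reports the
#' ChIP/input ratio.
#'
#' @param genes A [gene_models] table.
#' @param chip,input [read_set] libraries, already filtered to unique reads.
#' @param mark `"H3K4me3"` or `"H3K27me3"` (sets the counting window).
#' @param genotype Genotype label carried into the output.
#' @param flank Window flank in bp (default 2000).
#' @param pseudocount Count pseudocount for RPM (default 0.5).
#' @param chrom_sizes Optional chromosome size map for window clipping.
#' @return `data.table` with `gene_id`, `mark`, `genotype`, `chip_count`,
#'   `input_count`, `chip_rpm`, `input_rpm`, `enrichment`.
#' @export
gene_enrichment_table <- function(genes, chip, input,
                                  mark = c("H3K4me3", "H3K27me3"),
                                  genotype = "NA", flank = 2000,
                                  pseudocount = 0.5, chrom_sizes = NULL) {
  mark <- match.arg(mark)
  g <- as.data.table(genes)
  if (!nrow(g))
    return(data.table(gene_id = character(), mark = character(),
                      genotype = character(), chip_count = integer(),
                      input_count = integer(), chip_rpm = numeric(),
                      input_rpm = numeric(), enrichment = numeric()))
  if (chip$total_mapped < 1 || input$total_mapped < 1)
    stop("gene_enrichment_table: library with zero mapped reads (",
         chip$library_id, " / ", input$library_id, ")")
  regions <- mark_regions(g, mark, flank, chrom_sizes)
  cc <- count_region_overlaps(chip, regions)
  ic <- count_region_overlaps(input, regions)
  crpm <- rpm(cc, chip$total_mapped, pseudocount)
  irpm <- rpm(ic, input$total_mapped, pseudocount)
  data.table(gene_id = g$gene_id, mark = mark, genotype = genotype,
             chip_count = cc, input_count = ic,
             chip_rpm = crpm, input_rpm = irpm,
             enrichment = enrichment(crpm, irpm))
}

#' Enrichment fold change between genotypes
#'
#' Ratio of per-gene enrichment values, test genotype over reference, for
#' one mark. Both tables must cover the same genes and the same mark.
#'
#' @param record_test,record_ref Enrichment tables from
#'   [gene_enrichment_table] for the two genotypes.
#' @return `data.table` with `gene_id`, `mark`, `enrichment_test`,
#'   `enrichment_ref`, `fc`, `log2fc`.
#' @export
enrichment_fold_change <- function(record_test, record_ref) {
  a <- as.data.table(record_test)
  b <- as.data.table(record_ref)
  if (!identical(sort(a$gene_id), sort(b$gene_id)))
    stop("enrichment_fold_change: gene sets differ between genotypes")
  if (!identical(unique(a$mark), unique(b$mark)))
    stop("enrichment_fold_change: mark mismatch (",
         paste(unique(a$mark), collapse = ","), " vs ",
         paste(unique(b$mark), collapse = ","), ")")
  m <- merge(a[, .(gene_id, mark, enrichment_test = enrichment)],
             b[, .(gene_id, enrichment_ref = enrichment)], by = "gene_id")
  m[, fc := enrichment_test / enrichment_ref]
  m[, log2fc := log2(fc)]
  m[]
}

#' Metagene read-density profile
#'
#' Aggregates read midpoints across genes on a common coordinate frame and
#' reports reads-per-million-per-bp densities.
#'
#' In `tss_centered` mode each gene contributes a `[tss - window,
#' tss + window)` frame, flipped for minus-strand genes so that upstream is
#' always left of the TSS; the frame is cut into `n_bins` equal bins.
#' In `scaled_body` mode the gene body is mapped to `n_bins` equal fractions
#' with fixed-width `window`-bp flanks (each flank gets
#' `max(1, round(n_bins/5))` bins).
#'
#' Densities are per-bin midpoint counts divided by
#' `bin_width * n_genes * total_mapped / 1e6`, so profiles are comparable
#' across libraries of different depth.
#'
#' @param reads A [read_set].
#' @param genes A [gene_models] table (must be non-empty).
#' @param mode `"tss_centered"` or `"scaled_body"`.
#' @param window Flank size in bp (default 2000).
#' @param n_bins Number of bins for the frame/body (default 100).
#' @return Object of class `metagene_profile`: list with `mode`,
#'   `bin_edges` (relative coordinates; body fractions are scaled to the
#'   mean body length in `scaled_body` mode), `bin_width`, `counts`,
#'   `density`, `n_genes`, `total_mapped`.
#' @export
metagene_profile <- function(reads, genes,
                             mode = c("tss_centered", "scaled_body"),
                             window = 2000, n_bins = 100) {
  mode <- match.arg(mode)
  if (n_bins < 2) stop("metagene_profile: n_bins must be >= 2")
  g <- as.data.table(genes)
  if (!nrow(g)) stop("metagene_profile: no genes")
  r <- reads$reads
  mids <- if (nrow(r)) .read_midpoints(r) else numeric()

  if (mode == "tss_centered") {
    frames <- data.table(chrom = g$chrom, start = pmax(g$tss - window, 0),
                         end = g$tss + window)
    bw <- 2 * window / n_bins
    hit <- .point_frame_hits(r, mids, frames)
    rel <- ifelse(g$strand[hit$frame] == "+",
                  mids[hit$point] - (g$tss[hit$frame] - window),
                  (g$tss[hit$frame] + window - 1) - mids[hit$point])
    bins <- pmin(floor(rel / bw) + 1L, n_bins)
    counts <- tabulate(bins, nbins = n_bins)
    widths <- rep(bw, n_bins)
    edges <- seq(-window, window, length.out = n_bins + 1)
  } else {
    n_flank <- max(1L, as.integer(round(n_bins / 5)))
    fbw <- window / n_flank
    total_bins <- n_bins + 2L * n_flank
    frames <- data.table(chrom = g$chrom, start = pmax(g$start - window, 0),
                         end = g$end + window)
    len <- g$end - g$start
    hit <- .point_frame_hits(r, mids, frames)
    td <- ifelse(g$strand[hit$frame] == "+",
                 mids[hit$point] - g$start[hit$frame],
                 (g$end[hit$frame] - 1) - mids[hit$point])
    L <- len[hit$frame]
    bins <- integer(length(td))
    up <- td < 0
    body <- td >= 0 & td < L
    down <- td >= L
    bins[up] <- pmax(1L, pmin(n_flank, floor((td[up] + window) / fbw) + 1L))
    bins[body] <- n_flank + pmin(n_bins, floor(td[body] / L[body] * n_bins) + 1L)
    bins[down] <- n_flank + n_bins +
      pmax(1L, pmin(n_flank, floor((td[down] - L[down]) / fbw) + 1L))
    counts <- tabulate(bins, nbins = total_bins)
    mean_len <- mean(len)
    widths <- c(rep(fbw, n_flank), rep(mean_len / n_bins, n_bins),
                rep(fbw, n_flank))
    edges <- cumsum(c(-window, widths)) # relative frame, upstream at -window
    n_bins <- total_bins
  }
  density <- counts / (widths * nrow(g) * reads$total_mapped / 1e6)
  structure(list(mode = mode, bin_edges = edges, bin_width = widths,
                 counts = counts, density = density, n_genes = nrow(g),
                 total_mapped = reads$total_mapped, window = window,
                 n_bins = n_bins),
            class = "metagene_profile")
}

# read-midpoint x gene-frame overlap pairs (frames in 0-based half-open)
.point_frame_hits <- function(r, mids, frames) {
  if (!length(mids))
    return(list(point = integer(), frame = integer()))
  seqlev <- unique(c(frames$chrom, r$chrom))
  pts <- .to_granges(r$chrom, mids, mids + 1, seqlev)
  frg <- .to_granges(frames$chrom, frames$start, frames$end, seqlev)
  ov <- findOverlaps(pts, frg, ignore.strand = TRUE)
  list(point = S4Vectors::queryHits(ov), frame = S4Vectors::subjectHits(ov))
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat("metagene_profile (", x$mode, "): ", x$n_bins, " bins, ",
      x$n_genes, " genes, ", sum(x$counts), " read assignments from ",
      x$total_mapped, " reads\n", sep = "")
  invisible(x)
}

#' Export a metagene profile as a TSV table
#'
#' @param profile A [metagene_profile].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  dt <- data.table(bin_start = head(profile$bin_edges, -1),
                   bin_end = tail(profile$bin_edges, -1),
                   count = profile$counts,
                   density = profile$density)
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
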