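# Expression quantification and differential classification.
#
# Expression is summarized per gene as FPKM (fragments per kilobase of
# transcript per million mapped fragments); genotype comparison is a plain
# fold-change cut ("more than t-fold", strict), not a statistical DE test —
# the pipeline's DE lists are fold-change lists by design.

#' FPKM from fragment counts
#'
#' `FPKM_g = counts_g * 1e9 / (length_g * total_fragments)`.
#'
#' @param counts Non-negative per-gene fragment counts.
#' @param transcript_lengths Per-gene transcript lengths in bp (>= 1).
#' @param total_fragments Total mapped fragments for the sample; defaults to
#'   `sum(counts)`.
#' @return Numeric vector of FPKM values (0 exactly where `counts` is 0).
#' @export
compute_fpkm <- function(counts, transcript_lengths,
                         total_fragments = sum(counts)) {
  if (length(counts) != length(transcript_lengths))
    stop("compute_fpkm: counts and transcript_lengths differ in length")
  if (any(counts < 0)) stop("compute_fpkm: negative counts")
  if (any(transcript_lengths < 1)) stop("compute_fpkm: lengths must be >= 1")
  if (total_fragments < 1)
    stop("compute_fpkm: total_fragments must be >= 1 (got ", total_fragments, ")")
  as.numeric(counts) * 1e9 /
    (as.numeric(transcript_lengths) * as.numeric(total_fragments))
}

#' Expression fold change between genotypes
#'
#' Ratio of test-genotype to reference-genotype FPKM with a small pseudocount
#' keeping ratios finite at unexpressed genes:
#' `(test + pseudocount) / (ref + pseudocount)`.
#'
#' @param test_fpkm,ref_fpkm Non-negative FPKM values (vectorized).
#' @param pseudocount Added to both numerator and denominator (default 0.1).
#' @return Fold change(s), test relative to reference.
#' @export
fold_change <- function(test_fpkm, ref_fpkm, pseudocount = 0.1) {
  if (any(test_fpkm < 0) || any(ref_fpkm < 0) || pseudocount < 0)
    stop("fold_change: inputs must be non-negative")
  (test_fpkm + pseudocount) / (ref_fpkm + pseudocount)
}

#' Classify genes by fold change
#'
#' Strict threshold semantics ("more than t-fold"): `up` when
#' `fc > threshold`, `down` when `fc < 1/threshold`, otherwise `unchanged`.
#'
#' @param fc Fold changes (test/reference, linear scale).
#' @param threshold Fold-change cutoff, must be > 1 (default 1.5).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
classify_de <- function(fc, threshold = 1.5) {
  if (threshold <= 1) stop("classify_de: threshold must be > 1")
  ifelse(fc > threshold, "up", ifelse(fc < 1 / threshold, "down", "unchanged"))
}

#' Log-scale expression correlation between two samples
#'
#' Pearson correlation of `log10(FPKM + pseudocount)` over the genes
#' expressed (FPKM > 0) in at least one of the two samples, the statistic
#' quoted alongside log-scale FPKM scatter plots.
#'
#' @param sample_a,sample_b Per-gene FPKM vectors over the same genes.
#' @param pseudocount Added before the log (default 1).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
log_correlation <- function(sample_a, sample_b, pseudocount = 1) {
  if (length(sample_a) != length(sample_b))
    stop("log_correlation: samples cover different gene sets")
  keep <- sample_a > 0 | sample_b > 0
  if (sum(keep) < 3)
    stop("log_correlation: fewer than 3 genes expressed in either sample")
  la <- log10(sample_a[keep] + pseudocount)
  lb <- log10(sample_b[keep] + pseudocount)
  if (var(la) == 0 || var(lb) == 0)
    stop("log_correlation: zero variance in log expression")
  cor(la, lb)
}

#' Read a count table and sample sheet
#'
#' The count table is a TSV with columns `gene_id`, `length` and one column
#' per sample; the sample sheet a TSV with columns `sample_id`, `genotype`.
#'
#' @param counts_path,samples_path File paths.
#' @return List with `counts` (data.table) and `samples` (data.table).
#' @export
read_expression_input <- function(counts_path, samples_path) {
  counts <- fread(counts_path, sep = "\t")
  if (!all(c("gene_id", "length") %in% names(counts)))
    stop("count table ", counts_path, " must have gene_id and length columns")
  samples <- fread(samples_path, sep = "\t")
  if (!all(c("sample_id", "genotype") %in% names(samples)))
    stop("sample sheet ", samples_path,
         " must have sample_id and genotype columns")
  missing <- setdiff(samples$sample_id, names(counts))
  if (length(missing))
    stop("samples absent from count table ", counts_path, ": ",
         paste(missing, collapse = ", "))
  list(counts = counts, samples = samples)
}

#' Per-genotype FPKM and fold-change table
#'
#' Computes FPKM per sample (library size = column sum), averages replicates
#' within genotype, and derives fold change, log2 fold change and the DE
#' class of the test genotype relative to the reference.
#'
#' @param counts data.table with `gene_id`, `length` and sample columns.
#' @param samples data.table with `sample_id`, `genotype`.
#' @param test_genotype,ref_genotype Genotype labels in `samples$genotype`.
#' @param pseudocount FPKM pseudocount for the ratio (default 0.1).
#' @param threshold DE fold-change threshold (default 1.5).
#' @return `data.table` with `gene_id`, `fpkm_ref`, `fpkm_test`, `fc`,
#'   `log2fc`, `de_class`; threshold and labels stored as attributes.
#' @export
expression_fold_change <- function(counts, samples, test_genotype,
                                   ref_genotype, pseudocount = 0.1,
                                   threshold = 1.5) {
  counts <- as.data.table(counts)
  samples <- as.data.table(samples)
  for (g in c(test_genotype, ref_genotype))
    if (!any(samples$genotype == g))
      stop("expression_fold_change: no samples with genotype ", g)
  fpkm_of <- function(geno) {
    ids <- samples$sample_id[samples$genotype == geno]
    f <- vapply(ids, function(s) {
      compute_fpkm(counts[[s]], counts$length, sum(counts[[s]]))
    }, numeric(nrow(counts)))
    rowMeans(matrix(f, nrow = nrow(counts)))
  }
  ft <- fpkm_of(test_genotype)
  fr <- fpkm_of(ref_genotype)
  fc <- fold_change(ft, fr, pseudocount)
  out <- data.table(gene_id = counts$gene_id, fpkm_ref = fr, fpkm_test = ft,
                    fc = fc, log2fc = log2(fc),
                    de_class = classify_de(fc, threshold))
  setattr(out, "threshold", threshold)
  setattr(out, "test_genotype", test_genotype)
  setattr(out, "ref_genotype", ref_genotype)
  out[]
}
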