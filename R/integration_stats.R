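# Genotype comparison of mark levels within expression classes, joint
# fold-change reporting, and the end-to-end pipeline runner.

#' Two-sample t-test (Welch by default)
#'
#' Welch form: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom; `equal_var = TRUE` gives the
#' pooled-variance Student form. Two-sided p-value. When both variances are
#' zero the test degenerates: p = 1 if the means are equal (by convention),
#' p = 0 otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param equal_var Use the pooled-variance Student form (default `FALSE`).
#' @return Object of class `markexpr_ttest`: list with `statistic`, `df`,
#'   `p_value`, `n1`, `n2`, `means` (a, b), `method`.
#' @export
welch_t <- function(group_a, group_b, equal_var = FALSE) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2 || n2 < 2)
    stop("welch_t: each group needs at least 2 values (got ", n1, ", ", n2, ")")
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- var(group_a); v2 <- var(group_b)
  if (equal_var) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se > 0)
      (v1 / n1 + v2 / n2)^2 /
        ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    else n1 + n2 - 2
  }
  if (se == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / se
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(statistic = t, df = df, p_value = p, n1 = n1, n2 = n2,
                 means = c(a = m1, b = m2),
                 method = if (equal_var) "student" else "welch"),
            class = "markexpr_ttest")
}

#' @export
print.markexpr_ttest <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.3g, p = %.4g (n = %d, %d; means %.4g vs %.4g)\n",
              x$method, x$statistic, x$df, x$p_value, x$n1, x$n2,
              x$means[1], x$means[2]))
  invisible(x)
}

# one-sample t on per-gene differences (paired reading of the comparison)
.paired_t <- function(d) {
  n <- length(d)
  if (n < 2) stop("paired test needs >= 2 genes")
  se <- sd(d) / sqrt(n)
  m <- mean(d)
  if (se == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / se
    p <- 2 * pt(-abs(t), n - 1)
  }
  structure(list(statistic = t, df = n - 1, p_value = p, n1 = n, n2 = n,
                 means = c(a = m, b = 0), method = "paired"),
            class = "markexpr_ttest")
}

#' Compare mark enrichment between genotypes within expression classes
#'
#' For each differential-expression class (by default `up` and `down`), runs
#' a Welch t-test comparing per-gene log2 enrichment of one mark between the
#' test and reference genotypes over the genes of that class. This asks
#' whether, e.g., strongly down-regulated genes carry less H3K4me3 in the
#' test genotype than in the reference.
#'
#' @param enrichment_test,enrichment_ref Enrichment tables from
#'   [gene_enrichment_table] for the test and reference genotypes (same
#'   mark, same gene universe).
#' @param de_class Per-gene classes: a data.frame with `gene_id`,
#'   `de_class`, or a character vector named by gene id.
#' @param classes Classes to test (default `c("up", "down")`).
#' @param log2_transform Test on log2 enrichment (default `TRUE`).
#' @param paired Use the paired reading (one-sample t on per-gene
#'   test - reference differences) instead of the unpaired Welch test.
#' @return Named list of [welch_t] results, one per testable class; classes
#'   with fewer than 2 genes are skipped with a warning and recorded in the
#'   `skipped` attribute.
#' @export
mark_vs_expression_test <- function(enrichment_test, enrichment_ref, de_class,
                                    classes = c("up", "down"),
                                    log2_transform = TRUE, paired = FALSE) {
  a <- as.data.table(enrichment_test)
  b <- as.data.table(enrichment_ref)
  if (is.data.frame(de_class)) {
    cls <- setNames(as.character(de_class$de_class), de_class$gene_id)
  } else cls <- de_class
  if (!all(a$gene_id %in% names(cls)) || !all(b$gene_id %in% names(cls)))
    stop("mark_vs_expression_test: genes missing from de_class")
  m <- merge(a[, .(gene_id, e_test = enrichment)],
             b[, .(gene_id, e_ref = enrichment)], by = "gene_id")
  if (log2_transform) m[, `:=`(e_test = log2(e_test), e_ref = log2(e_ref))]
  m[, de_class := cls[gene_id]]
  out <- list()
  skipped <- character()
  for (cl in classes) {
    sub <- m[de_class == cl]
    if (nrow(sub) < 2) {
      warning("mark_vs_expression_test: class '", cl,
              "' has fewer than 2 genes; skipped")
      skipped <- c(skipped, cl)
      next
    }
    out[[cl]] <- if (paired) .paired_t(sub$e_test - sub$e_ref)
                 else welch_t(sub$e_test, sub$e_ref)
    out[[cl]]$n_genes <- nrow(sub)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Joint expression / mark fold-change table
#'
#' Merges expression and per-mark enrichment fold changes into one per-gene
#' table on the log2 scale, optionally restricted to a gene subset (e.g. a
#' curated metabolic gene list).
#'
#' @param expression_fc Table from [expression_fold_change].
#' @param k4_fc,k27_fc Tables from [enrichment_fold_change] for H3K4me3 and
#'   H3K27me3.
#' @param gene_subset Optional character vector of gene ids.
#' @return `data.table` with `gene_id`, `expr_log2fc`, `k4_log2fc`,
#'   `k27_log2fc`, `de_class`, each requested gene exactly once.
#' @export
joint_fold_change <- function(expression_fc, k4_fc, k27_fc,
                              gene_subset = NULL) {
  e <- as.data.table(expression_fc)[, .(gene_id, expr_log2fc = log2fc, de_class)]
  k4 <- as.data.table(k4_fc)[, .(gene_id, k4_log2fc = log2fc)]
  k27 <- as.data.table(k27_fc)[, .(gene_id, k27_log2fc = log2fc)]
  universe <- Reduce(intersect, list(e$gene_id, k4$gene_id, k27$gene_id))
  ids <- gene_subset %||% universe
  missing <- setdiff(ids, universe)
  if (length(missing))
    stop("joint_fold_change: gene(s) absent from a component table: ",
         paste(missing, collapse = ", "))
  out <- merge(merge(e, k4, by = "gene_id"), k27, by = "gene_id")
  out <- out[match(ids, gene_id)]
  out[, .(gene_id, expr_log2fc, k4_log2fc, k27_log2fc, de_class)]
}
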