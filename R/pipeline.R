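# End-to-end pipeline: annotation + counts + 8 read libraries in,
# TSV report bundle out. The pipeline itself is deterministic; the seed in
# the config is only recorded in the manifest (randomness lives in the
# simulate step).

.PIPELINE_DEFAULTS <- list(
  genotype_ref = "XY", genotype_test = "XXSry",
  de_threshold = 1.5, test_threshold = 3, flank = 2000,
  fpkm_pseudocount = 0.1, rpm_pseudocount = 0.5,
  profile_window = 2000, profile_bins = 50, seed = 0)

#' Read a flat key-value pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' kept (read-library paths are of the form
#' `reads_<mark>_<chip|input>_<genotype>`).
#'
#' @param path Configuration file path.
#' @return Named list of configuration values (numbers coerced).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out <- lapply(seq_along(out), function(i)
    if (is.na(suppressWarnings(as.numeric(vals[i])))) vals[i]
    else as.numeric(vals[i]))
  names(out) <- keys
  out
}

.fill_config <- function(config) {
  for (k in names(.PIPELINE_DEFAULTS))
    if (is.null(config[[k]])) config[[k]] <- .PIPELINE_DEFAULTS[[k]]
  config
}

.lib_key <- function(mark, fraction, genotype)
  paste("reads", mark, fraction, genotype, sep = "_")

#' Run the full integration pipeline
#'
#' Reads the annotation, count table, sample sheet and the eight read
#' libraries (two marks x ChIP/input x two genotypes); computes the
#' expression fold-change table and DE lists, per-gene enrichment tables and
#' between-genotype enrichment fold changes for both marks, Welch tests of
#' mark levels within the up/down classes at the (stricter) test threshold,
#' the joint fold-change table, and TSS-centered metagene profiles; writes
#' everything as TSV plus a run manifest.
#'
#' Config keys: `annotation`, `counts`, `sample_sheet`,
#' `reads_<mark>_<chip|input>_<genotype>` (paths); `genotype_ref`,
#' `genotype_test` (labels, defaults XY / XXSry); `de_threshold` (1.5),
#' `test_threshold` (3), `flank` (2000), `fpkm_pseudocount` (0.1),
#' `rpm_pseudocount` (0.5), `profile_window` (2000), `profile_bins` (50),
#' `seed` (recorded only).
#'
#' @param config Path to a config file or a named list.
#' @param outdir Output directory.
#' @return List with all result tables and `paths` of written files,
#'   invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- .fill_config(config)
  marks <- c("H3K4me3", "H3K27me3")
  genos <- c(config$genotype_ref, config$genotype_test)
  req_files <- c(annotation = config$annotation, counts = config$counts,
                 sample_sheet = config$sample_sheet)
  for (mk in marks) for (fr in c("chip", "input")) for (gn in genos) {
    key <- .lib_key(mk, fr, gn)
    if (is.null(config[[key]]))
      stop("run_pipeline: config key missing: ", key)
    req_files[key] <- config[[key]]
  }
  absent <- !file.exists(unlist(req_files))
  if (any(absent))
    stop("run_pipeline: missing input file(s): ",
         paste(unlist(req_files)[absent], collapse = ", "))

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genes <- read_gene_annotation(config$annotation)
  expr_in <- read_expression_input(config$counts, config$sample_sheet)
  if (!setequal(expr_in$counts$gene_id, genes$gene_id))
    stop("run_pipeline: gene universe of ", config$counts,
         " does not match the annotation ", config$annotation)

  message("pipeline: expression fold change (", config$genotype_test,
          " vs ", config$genotype_ref, ")")
  expr_fc <- expression_fold_change(
    expr_in$counts, expr_in$samples, config$genotype_test,
    config$genotype_ref, config$fpkm_pseudocount, config$de_threshold)
  test_class <- classify_de(expr_fc$fc, config$test_threshold)
  paths <- list()
  w <- function(dt, name) {
    paths[[name]] <<- file.path(outdir, paste0(name, ".tsv"))
    fwrite(dt, paths[[name]], sep = "\t", quote = FALSE)
  }
  w(expr_fc, "expression")
  w(expr_fc[de_class == "up", .(gene_id, fc, log2fc)], "de_up")
  w(expr_fc[de_class == "down", .(gene_id, fc, log2fc)], "de_down")

  enr <- list(); enr_fc <- list(); tests <- list(); profiles <- list()
  for (mk in marks) {
    for (gn in genos) {
      message("pipeline: enrichment ", mk, " / ", gn)
      chip <- read_alignments_bed(config[[.lib_key(mk, "chip", gn)]])
      inp <- read_alignments_bed(config[[.lib_key(mk, "input", gn)]])
      enr[[paste(mk, gn, sep = "_")]] <- gene_enrichment_table(
        genes, chip, inp, mk, gn, config$flank, config$rpm_pseudocount)
      w(enr[[paste(mk, gn, sep = "_")]], paste0("enrichment_", mk, "_", gn))
      pr <- metagene_profile(chip, genes, "tss_centered",
                             config$profile_window, config$profile_bins)
      profiles[[paste(mk, gn, sep = "_")]] <- pr
      paths[[paste0("profile_", mk, "_", gn)]] <-
        file.path(outdir, paste0("profile_", mk, "_", gn, ".tsv"))
      write_profile_tsv(pr, paths[[paste0("profile_", mk, "_", gn)]])
    }
    enr_fc[[mk]] <- enrichment_fold_change(
      enr[[paste(mk, config$genotype_test, sep = "_")]],
      enr[[paste(mk, config$genotype_ref, sep = "_")]])
    w(enr_fc[[mk]], paste0("enrichment_fc_", mk))
    tests[[mk]] <- mark_vs_expression_test(
      enr[[paste(mk, config$genotype_test, sep = "_")]],
      enr[[paste(mk, config$genotype_ref, sep = "_")]],
      data.table(gene_id = expr_fc$gene_id, de_class = test_class))
  }
  test_dt <- rbindlist(lapply(marks, function(mk) {
    rbindlist(lapply(names(tests[[mk]]), function(cl) {
      t <- tests[[mk]][[cl]]
      data.table(mark = mk, de_class = cl, n_genes = t$n_genes,
                 mean_test = t$means[["a"]], mean_ref = t$means[["b"]],
                 statistic = t$statistic, df = t$df, p_value = t$p_value)
    }))
  }))
  w(test_dt, "class_tests")
  joint <- joint_fold_change(expr_fc, enr_fc$H3K4me3, enr_fc$H3K27me3)
  w(joint, "joint_fold_change")

  manifest <- c(
    paste("markexpr_version =", as.character(packageVersion("markexpr"))),
    paste("r_version =", R.version.string),
    paste("seed =", config$seed),
    paste("config_hash =", .config_hash(config)),
    paste("de_threshold =", config$de_threshold),
    paste("test_threshold =", config$test_threshold))
  paths$manifest <- file.path(outdir, "manifest.txt")
  writeLines(manifest, paths$manifest)

  invisible(list(expression = expr_fc, enrichment = enr,
                 enrichment_fc = enr_fc, tests = tests, test_table = test_dt,
                 joint = joint, profiles = profiles, config = config,
                 paths = paths))
}

.config_hash <- function(config) {
  ord <- order(names(config))
  txt <- paste(names(config)[ord], vapply(config[ord], paste, ""),
               sep = "=", collapse = ";")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(md5sum(f))
}
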