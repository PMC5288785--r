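# Coordinate conventions: every user-facing table and every file read or
# written by this package uses BED-style 0-based half-open intervals
# ([start, end), a 1-bp feature has end = start + 1). GTF input (1-based,
# closed) is converted on read. Conversion to the 1-based closed IRanges
# representation happens only inside the overlap helpers.

#' Construct a gene-model table
#'
#' A gene-model table holds one row per gene: locus coordinates (0-based
#' half-open), strand, the derived TSS/TTS, and the transcript length used
#' as the FPKM denominator. The TSS is `start` on the plus strand and `end`
#' on the minus strand (so the +/-2 kb promoter window is
#' `[tss - flank, tss + flank)` on both strands); the TTS is the opposite
#' locus end.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`), `transcript_length`.
#' @return A `data.table` of class `gene_models` with added `tss` and `tts`
#'   columns, ordered by chrom, start, gene_id.
#' @export
gene_models <- function(df) {
  gm <- as.data.table(df)
  req <- c("gene_id", "chrom", "start", "end", "strand", "transcript_length")
  miss <- setdiff(req, names(gm))
  if (length(miss))
    stop("gene_models: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(gm$gene_id))
    stop("gene_models: duplicated gene_id(s): ",
         paste(unique(gm$gene_id[duplicated(gm$gene_id)]), collapse = ", "))
  if (!all(gm$strand %chin% c("+", "-")))
    stop("gene_models: strand must be '+' or '-' for every gene")
  bad <- gm$start < 0 | gm$start >= gm$end
  if (any(bad))
    stop("gene_models: invalid interval (need 0 <= start < end) for: ",
         paste(gm$gene_id[bad], collapse = ", "))
  bad <- gm$transcript_length < 1 | gm$transcript_length > gm$end - gm$start
  if (any(bad))
    stop("gene_models: transcript_length out of [1, locus width] for: ",
         paste(gm$gene_id[bad], collapse = ", "))
  gm[, `:=`(tss = ifelse(strand == "+", start, end),
            tts = ifelse(strand == "+", end, start))]
  setorder(gm, chrom, start, gene_id)
  setattr(gm, "class", c("gene_models", class(data.table())))
  gm[]
}

#' Read gene annotation from GTF or BED
#'
#' Parses a GTF (Ensembl dialect; gene/transcript/exon features) or a
#' BED6/BED12 file into a [gene_models] table. One representative transcript
#' is chosen per gene: the longest one (ties broken by transcript id), and
#' its summed exon length becomes `transcript_length`. GTF coordinates
#' (1-based closed) are converted to 0-based half-open; BED is taken as-is.
#' For BED6 the transcript length is the interval width.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (sniff by content), `"gtf"`, `"bed12"` or `"bed6"`.
#' @return A `gene_models` table.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed12", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("annotation file is empty: ", path)
  if (format == "auto") {
    nf <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
    format <- if (nf == 9 && grepl("gene_id", lines[1], fixed = TRUE)) "gtf"
              else if (nf >= 12) "bed12" else if (nf >= 6) "bed6"
              else stop("cannot determine annotation format of ", path)
  }
  if (format == "gtf") .parse_gtf(lines, lineno) else .parse_bed_genes(lines, lineno, format)
}

.parse_gtf <- function(lines, lineno) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9))
    stop("malformed GTF line ", lineno[which(nf != 9)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf != 9)[1]])
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 4]))
  end <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(start) | is.na(end) | start < 1 | end < start)
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1]], ": invalid coordinates")
  gid <- .gtf_attr(m[, 9], "gene_id")
  tid <- .gtf_attr(m[, 9], "transcript_id")
  feat <- m[, 3]
  ex <- which(feat == "exon")
  if (any(is.na(gid[ex])))
    stop("malformed GTF line ", lineno[ex[which(is.na(gid[ex]))[1]]],
         ": exon without gene_id attribute")
  gene_ids_seen <- unique(gid[!is.na(gid)])
  exons <- data.table(gene_id = gid[ex],
                      transcript_id = tid[ex],
                      chrom = m[ex, 1],
                      start = start[ex] - 1,  # to 0-based half-open
                      end = end[ex],
                      strand = m[ex, 7])
  no_exon <- setdiff(gene_ids_seen, unique(exons$gene_id))
  if (length(no_exon))
    stop("gene with zero exons: ", paste(no_exon, collapse = ", "))
  if (!length(ex)) stop("GTF contains no exon features")
  tl <- exons[, .(len = sum(end - start),
                  chrom = chrom[1], strand = strand[1],
                  lo = min(start), hi = max(end)),
              by = .(gene_id, transcript_id)]
  setorder(tl, gene_id, -len, transcript_id)
  rep <- tl[, .SD[1], by = gene_id]
  gene_models(rep[, .(gene_id, chrom, start = lo, end = hi, strand,
                      transcript_length = len)])
}

.gtf_attr <- function(attrs, key) {
  pat <- paste0(key, " \"([^\"]+)\"")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

.parse_bed_genes <- function(lines, lineno, format) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "bed12") 12L else 6L
  nf <- lengths(fields)
  if (any(nf < need))
    stop("malformed BED line ", lineno[which(nf < need)[1]],
         ": expected >= ", need, " fields")
  m <- do.call(rbind, lapply(fields, function(x) x[seq_len(need)]))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], ": invalid coordinates")
  tlen <- if (format == "bed12") {
    vapply(m[, 11], function(s) {
      sum(as.numeric(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]]))
    }, 0)
  } else end - start
  dt <- data.table(gene_id = m[, 4], chrom = m[, 1], start = start, end = end,
                   strand = m[, 6], transcript_length = tlen)
  # duplicated gene ids: keep the longest transcript (tie: first occurrence)
  setorder(dt, gene_id, -transcript_length)
  dt <- dt[, .SD[1], by = gene_id]
  gene_models(dt)
}

#' Mark-specific counting window for each gene
#'
#' H3K4me3 reads are counted in a promoter window from `flank` bp upstream to
#' `flank` bp downstream of the TSS; H3K27me3 reads from `flank` bp upstream
#' of the TSS to the transcription termination site (i.e. the gene body plus
#' the upstream flank). Windows are clipped at position 0 and, when a
#' chromosome size map is supplied, at the chromosome end.
#'
#' @param genes A [gene_models] table.
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @param flank Upstream/downstream extension in bp (default 2000).
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#' @return `data.table` with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open window per gene, same order as `genes`).
#' @export
mark_regions <- function(genes, mark = c("H3K4me3", "H3K27me3"), flank = 2000,
                         chrom_sizes = NULL) {
  mark <- match.arg(mark)
  stopifnot(flank >= 0)
  g <- as.data.table(genes)
  if (mark == "H3K4me3") {
    rs <- g$tss - flank
    re <- g$tss + flank
  } else {
    rs <- ifelse(g$strand == "+", g$tss - flank, g$tts)
    re <- ifelse(g$strand == "+", g$tts, g$tss + flank)
  }
  rs <- pmax(rs, 0)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[g$chrom]
    if (anyNA(sz))
      stop("mark_regions: chromosomes absent from size map: ",
           paste(unique(g$chrom[is.na(sz)]), collapse = ", "))
    re <- pmin(re, sz)
  }
  empty <- rs >= re
  if (any(empty))
    stop("mark_regions: clipping emptied the window for gene(s): ",
         paste(g$gene_id[empty], collapse = ", "))
  data.table(gene_id = g$gene_id, chrom = g$chrom, start = rs, end = re,
             strand = g$strand)
}

#' Aligned-read library
#'
#' Wraps a table of mapped read intervals together with a library id and the
#' retained (uniquely-mapped) read count used for RPM normalization.
#'
#' @param reads data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand` and logical `unique_flag`.
#' @param library_id Library label.
#' @return Object of class `read_set`: list with `library_id`, `reads`
#'   (data.table) and `total_mapped`.
#' @export
read_set <- function(reads, library_id = "library") {
  r <- as.data.table(reads)
  if (!nrow(r)) {
    r <- data.table(chrom = character(), start = numeric(), end = numeric(),
                    strand = character(), unique_flag = logical())
  } else {
    if (is.null(r$strand)) r[, strand := "."]
    if (is.null(r$unique_flag)) r[, unique_flag := TRUE]
    bad <- r$start < 0 | r$start >= r$end
    if (any(bad))
      stop("read_set: invalid read interval at row ", which(bad)[1])
  }
  structure(list(library_id = library_id, reads = r,
                 total_mapped = nrow(r)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set '", x$library_id, "': ", x$total_mapped,
      " mapped reads on ", length(unique(x$reads$chrom)),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read aligned reads from BED
#'
#' Reads a BED3/BED6 file of aligned read intervals. The optional score
#' column (5th field) carries the uniqueness indicator of the dialect used
#' here: `score > 0` marks a uniquely mapped read, `score == 0` a multi-hit
#' read. Files without a score column are taken as all-unique. With
#' `unique_only = TRUE` (the default, matching the unique-read filter applied
#' before all downstream counting) multi-hit reads are dropped and
#' `total_mapped` is the retained count.
#'
#' @param path BED file path.
#' @param unique_only Drop non-unique reads (default `TRUE`).
#' @param library_id Library label (default: file base name).
#' @return A [read_set].
#' @export
read_alignments_bed <- function(path, unique_only = TRUE, library_id = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  library_id <- library_id %||% sub("\\.bed$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(read_set(data.table(chrom = character(), start = numeric(),
                               end = numeric()), library_id))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lineno[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]],
         ": need numeric 0 <= start < end")
  uniq <- if (all(nf >= 5)) {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
    ifelse(is.na(sc), TRUE, sc > 0)
  } else rep(TRUE, length(chrom))
  strand <- if (all(nf >= 6)) vapply(fields, `[`, "", 6L) else rep(".", length(chrom))
  dt <- data.table(chrom = chrom, start = start, end = end, strand = strand,
                   unique_flag = uniq)
  if (unique_only) dt <- dt[unique_flag == TRUE]
  read_set(dt, library_id)
}

#' Write a read set (or region table) to BED6
#'
#' Coordinates are written 0-based half-open. For a [read_set] the score
#' column encodes uniqueness (1 = unique, 0 = multi-hit), so reading the file
#' back with [read_alignments_bed] round-trips intervals and `total_mapped`.
#'
#' @param x A [read_set] or a data.frame with `chrom`, `start`, `end` and
#'   optionally `gene_id`/`name` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "read_set")) {
    r <- x$reads
    nm <- if (nrow(r)) paste0(x$library_id, "_", seq_len(nrow(r))) else character()
    out <- data.table(chrom = r$chrom, start = as.integer(r$start),
                      end = as.integer(r$end), name = nm,
                      score = as.integer(r$unique_flag),
                      strand = if (nrow(r)) r$strand else character())
  } else {
    r <- as.data.table(x)
    out <- data.table(chrom = r$chrom, start = as.integer(r$start),
                      end = as.integer(r$end),
                      name = r$gene_id %||% r$name %||% paste0("region_", seq_len(nrow(r))),
                      score = 0L,
                      strand = r$strand %||% rep(".", nrow(r)))
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE,
         scipen = 50L)
  invisible(path)
}

# 0-based half-open table -> GRanges (1-based closed), with shared seqlevels
.to_granges <- function(chrom, start, end, seqlev) {
  GRanges(factor(chrom, levels = seqlev), IRanges(start + 1, end))
}

#' Count reads overlapping one region
#'
#' A read is counted when its interval overlaps the region by at least 1 bp
#' in half-open arithmetic, on the same chromosome; strand is ignored.
#'
#' @param reads A [read_set].
#' @param region One-row data.frame (or list) with `chrom`, `start`, `end`
#'   in 0-based half-open coordinates.
#' @return Integer count.
#' @export
count_overlaps <- function(reads, region) {
  region <- as.data.table(as.list(region)[c("chrom", "start", "end")])
  count_region_overlaps(reads, region)[1]
}

#' Count reads overlapping each of many regions
#'
#' Vectorized form of [count_overlaps]: one count per region row, computed
#' with an interval-tree overlap query.
#'
#' @param reads A [read_set].
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Integer vector, one count per region, in region order.
#' @export
count_region_overlaps <- function(reads, regions) {
  regions <- as.data.table(regions)
  if (!nrow(regions)) return(integer())
  r <- reads$reads
  if (!nrow(r)) return(integer(nrow(regions)))
  seqlev <- unique(c(regions$chrom, r$chrom))
  q <- .to_granges(regions$chrom, regions$start, regions$end, seqlev)
  s <- .to_granges(r$chrom, r$start, r$end, seqlev)
  as.integer(countOverlaps(q, s, ignore.strand = TRUE))
}

# midpoint (0-based position) of each read interval
.read_midpoints <- function(r) floor((r$start + r$end - 1) / 2)
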