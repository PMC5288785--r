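# Small fixtures built in code at test time.

toy_genes <- function() {
  gene_models(data.frame(
    gene_id = c("geneA", "geneB"),
    chrom = c("chr1", "chr1"),
    start = c(10000, 10000),
    end = c(15000, 15000),
    strand = c("+", "-"),
    transcript_length = c(5000, 5000)))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# BED6 read line helper (score = uniqueness)
bed_line <- function(chrom, start, end, name = "r", score = 1,
                     strand = ".") {
  paste(chrom, start, end, name, score, strand, sep = "\t")
}

# a read_set directly from vectors (chr1 by default)
mk_reads <- function(start, end, chrom = "chr1", id = "lib") {
  read_set(data.frame(chrom = chrom, start = start, end = end), id)
}
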