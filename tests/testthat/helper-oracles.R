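# Independent oracles, deliberately naive: these never call the package's
# overlap/statistics code paths.

# all-pairs nested-loop overlap counter on 0-based half-open intervals
oracle_count_overlaps <- function(reads_dt, regions_dt) {
  out <- integer(nrow(regions_dt))
  for (i in seq_len(nrow(regions_dt))) {
    n <- 0L
    for (j in seq_len(nrow(reads_dt))) {
      if (reads_dt$chrom[j] == regions_dt$chrom[i] &&
          reads_dt$start[j] < regions_dt$end[i] &&
          reads_dt$end[j] > regions_dt$start[i]) n <- n + 1L
    }
    out[i] <- n
  }
  out
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# random read table on one or more chromosomes
random_reads <- function(n, chroms = "chr1", chrom_len = 1e6,
                         read_len = 50) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_len - read_len))
  data.table::data.table(chrom = chrom, start = start,
                         end = start + read_len, strand = ".",
                         unique_flag = TRUE)
}
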