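# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Exact direct-sum Gaussian KDE at each grid point.
direct_kde <- function(x, grid, h) {
  vapply(grid, function(g) mean(stats::dnorm(g - x, sd = h)), numeric(1))
}

# Two-tailed Fisher exact p by full enumeration over all tables with the
# observed margins: sum of hypergeometric point probabilities <= that of
# the observed table (with a 1e-7 relative guard against float ties).
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Per-base boolean coverage of 0-based half-open intervals on [0, len).
per_base_cover <- function(intervals, len) {
  covered <- logical(len)
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) covered[(s + 1):e] <- TRUE
  }
  covered
}

# Write a hand-crafted VCF with GT-only sample columns.
# records: data.frame chrom, pos, ref, alt, plus one column per strain.
write_test_vcf <- function(records, strains, chrom_lengths, path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
  if (nrow(records) > 0) {
    gt_cols <- do.call(paste, c(lapply(strains, function(s) records[[s]]),
                                sep = "\t"))
    body <- paste(records$chrom, format(records$pos, scientific = FALSE,
                                        trim = TRUE),
                  ".", records$ref, records$alt, ".", "PASS", ".", "GT",
                  gt_cols, sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  path
}

# Small standard simulation used by several files.
toy_sim <- function(seed = 42, chrom_lengths = c(chr1 = 2e7),
                    ...) {
  simulate_mosaic(mosaic_params(chrom_lengths, seed = seed, ...))
}
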