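# Shared fixtures and independent brute-force oracles. Oracles deliberately
# work on enumerated base sets / all-pairs scans, never through the package's
# interval or matching code paths.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

one_region <- function(chrom = "chr6", start = 0L, len = 1000L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), stringsAsFactors = FALSE)
}

# brute force: union of covered base indices per chromosome
oracle_union_bases <- function(df) {
  out <- 0L
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    covered <- unique(unlist(mapply(function(s, e) seq(s, e - 1L),
                                    d$start, d$end, SIMPLIFY = FALSE)))
    out <- out + length(covered)
  }
  out
}

# brute force SNP-cluster scan: every window of `window` consecutive bases
oracle_snp_cluster <- function(pos, window = 20L, min_count = 3L) {
  flag <- logical(length(pos))
  if (!length(pos)) return(flag)
  for (s in (min(pos) - window):max(pos)) {
    inw <- which(pos >= s & pos <= s + window - 1L)
    if (length(inw) >= min_count) flag[inw] <- TRUE
  }
  flag
}

# brute force indel matcher on enumerated base sets; greedy left-to-right
# over calls, max-overlap unmatched truth, ties to leftmost truth interval
oracle_indel_match <- function(call_iv, truth_iv, min_overlap = 1L) {
  taken <- logical(nrow(truth_iv))
  tp <- 0L
  ord <- order(call_iv$chrom, call_iv$start)
  for (i in ord) {
    cb <- seq(call_iv$start[i], call_iv$end[i])
    best <- NA_integer_; best_ov <- -1L
    for (j in seq_len(nrow(truth_iv))) {
      if (taken[j] || truth_iv$chrom[j] != call_iv$chrom[i]) next
      ov <- length(intersect(cb, seq(truth_iv$start[j], truth_iv$end[j])))
      if (ov >= min_overlap &&
          (ov > best_ov ||
           (ov == best_ov && !is.na(best) &&
            truth_iv$start[j] < truth_iv$start[best]))) {
        best <- j; best_ov <- ov
      }
    }
    if (!is.na(best)) { taken[best] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = nrow(call_iv) - tp, fn = nrow(truth_iv) - tp)
}

# a small mutated world + simulated reads used by several test files
make_world <- function(level = 0.01, coverage = 10, n_regions = 2L,
                       region_length = 2000L, chroms = c(chr6 = 20000L,
                                                         chr7 = 12000L),
                       seed = 11L, error_rate = 0) {
  ref <- synthetic_reference(chroms, n_regions = n_regions,
                             region_length = region_length, seed = seed)
  sim <- simulate_mutations(ref$reference, ref$regions, level = level,
                            seed = seed + 1L)
  reads <- simulate_pairs(sim, sim_config(coverage = coverage,
                                          error_rate = error_rate,
                                          seed = seed + 2L))
  list(ref = ref, sim = sim, reads = reads)
}

# independent SAM text splitter (kept separate from package internals)
read_sam_lines_for_test <- function(path) {
  lines <- readLines(path)
  list(header = lines[startsWith(lines, "@")],
       records = lines[!startsWith(lines, "@")])
}

# hand-written minimal call VCF
write_calls_vcf <- function(path, rows,
                            header_contig = "##contig=<ID=chr6,length=1000000>") {
  hdr <- c("##fileformat=VCFv4.2", header_contig,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, qual = 50, gt = "0/1") {
  sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT\t%s", chrom, pos, ref, alt,
          format(qual), gt)
}

# truth-variant data.frame builder for matcher tests
tv <- function(chrom, pos, ref, alt, vtype, genotype = "het",
               qual = 100) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             qual = qual, genotype = genotype, vtype = vtype,
             stringsAsFactors = FALSE)
}
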