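## Paired-end read simulation with truth-origin tracking.
##
## Reads are drawn from the two mutated haplotypes of each region; every
## mate's true origin (leftmost reference coordinate of its first aligned
## base) is recorded in an origin table and additionally encoded in the read
## name as sim|chrom|start1|start2|strand|serial, so evaluators can work
## from the FASTQ/SAM alone.

#' Read-simulation configuration
#'
#' @param read_len read length in bases (100, matching 100-base paired-end
#'   sequencing).
#' @param coverage target mean per-base coverage (fold).
#' @param frag_mean,frag_sd fragment-length normal model, truncated at
#'   [2*read_len, haplotype length].
#' @param error_rate per-base substitution sequencing-error probability.
#' @param seed RNG seed.
#' @return list of class "sim_config".
#' @export
sim_config <- function(read_len = 100L, coverage = 100, frag_mean = 300,
                       frag_sd = 50, error_rate = 0.001, seed = 1L) {
  stopifnot(read_len >= 1, coverage >= 0, error_rate >= 0, error_rate < 1)
  if (frag_mean < 2 * read_len)
    stop("frag_mean must be at least 2 * read_len", call. = FALSE)
  structure(list(read_len = as.integer(read_len), coverage = coverage,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## constant Phred quality character implied by the error rate
qual_char <- function(error_rate) {
  q <- as.integer(round(-10 * log10(max(error_rate, 1e-4))))
  rawToChar(as.raw(min(q, 60L) + 33L))
}

## inject substitution errors at `rate` into a character vector of reads
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0L)
  for (i in idx) {
    b <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pp <- sample.int(length(b), n_err[i])
    b[pp] <- vapply(b[pp],
                    function(x) sample(setdiff(BASES, x), 1L), "")
    seqs[i] <- paste(b, collapse = "")
  }
  seqs
}

## reference coordinate of the first non-inserted haplotype base at/after h
origin_of <- function(hap, h) {
  while (h <= length(hap$inserted) && hap$inserted[h]) h <- h + 1L
  if (h > length(hap$coord_map)) h <- length(hap$coord_map)
  hap$coord_map[h]
}

#' Simulate paired-end reads from mutated haplotypes
#'
#' Per region, `ceiling(coverage * L / (2 * read_len))` fragments are drawn
#' (haplotype chosen uniformly, fragment length normal and truncated, strand
#' uniform); each fragment yields a forward and a reverse-complement mate.
#' Regions shorter than `2 * read_len` are skipped with a warning; regions
#' shorter than the mean fragment fall back to region-length fragments.
#'
#' @param sim a "mutation_sim" from [simulate_mutations()].
#' @param config a [sim_config()].
#' @return object of class "read_sim": `pairs` data.frame (read_name, seq1,
#'   qual1, seq2, qual2), `origins` data.frame with one row per mate
#'   (read_name, chrom, truth_start, strand, mate), plus the config and the
#'   chromosome lengths of the reference.
#' @export
simulate_pairs <- function(sim, config = sim_config()) {
  stopifnot(inherits(sim, "mutation_sim"))
  set.seed(config$seed)
  rl <- config$read_len
  qc <- qual_char(config$error_rate)
  serial <- 0L
  pair_chunks <- list(); origin_chunks <- list()

  for (hset in sim$haplotypes) {
    rg <- hset$region
    L <- rg$end - rg$start
    if (L < 2L * rl) {
      warning(sprintf("region %s:%d-%d shorter than 2*read_len; skipped",
                      rg$chrom, rg$start, rg$end), call. = FALSE)
      next
    }
    n_pairs <- as.integer(ceiling(config$coverage * L / (2 * rl)))
    if (n_pairs == 0L) next

    hap_idx <- sample.int(2L, n_pairs, replace = TRUE)
    frag <- as.integer(round(stats::rnorm(n_pairs, config$frag_mean,
                                          config$frag_sd)))
    fwd <- stats::runif(n_pairs) < 0.5

    left <- character(n_pairs); right_fwd <- character(n_pairs)
    o_left <- integer(n_pairs); o_right <- integer(n_pairs)
    for (j in seq_len(n_pairs)) {
      hap <- if (hap_idx[j] == 1L) hset$hap1 else hset$hap2
      hl <- nchar(hap$sequence)
      f <- min(max(frag[j], 2L * rl), hl)
      s <- sample.int(hl - f + 1L, 1L)            # fragment start on haplotype
      left[j]  <- substr(hap$sequence, s, s + rl - 1L)
      right_fwd[j] <- substr(hap$sequence, s + f - rl, s + f - 1L)
      o_left[j]  <- origin_of(hap, s)
      o_right[j] <- origin_of(hap, s + f - rl)
    }
    right <- revcomp(right_fwd)
    seq1 <- ifelse(fwd, left, right)
    seq2 <- ifelse(fwd, right, left)
    ts1 <- ifelse(fwd, o_left, o_right)
    ts2 <- ifelse(fwd, o_right, o_left)
    st1 <- ifelse(fwd, "+", "-")
    st2 <- ifelse(fwd, "-", "+")
    seq1 <- inject_errors(seq1, config$error_rate)
    seq2 <- inject_errors(seq2, config$error_rate)
    names <- sprintf("sim|%s|%d|%d|%s|%07d", rg$chrom, ts1, ts2, st1,
                     serial + seq_len(n_pairs))
    serial <- serial + n_pairs
    qual <- strrep(qc, rl)
    pair_chunks[[length(pair_chunks) + 1L]] <-
      data.frame(read_name = names, seq1 = seq1, qual1 = qual,
                 seq2 = seq2, qual2 = qual, stringsAsFactors = FALSE)
    origin_chunks[[length(origin_chunks) + 1L]] <-
      data.frame(read_name = rep(names, 2L),
                 chrom = rg$chrom,
                 truth_start = c(ts1, ts2),
                 strand = c(st1, st2),
                 mate = rep(1:2, each = n_pairs),
                 stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_chunks)
  origins <- do.call(rbind, origin_chunks)
  if (is.null(pairs)) {
    pairs <- data.frame(read_name = character(), seq1 = character(),
                        qual1 = character(), seq2 = character(),
                        qual2 = character(), stringsAsFactors = FALSE)
    origins <- data.frame(read_name = character(), chrom = character(),
                          truth_start = integer(), strand = character(),
                          mate = integer(), stringsAsFactors = FALSE)
  }
  origins <- origins[order(origins$read_name, origins$mate), , drop = FALSE]
  rownames(pairs) <- rownames(origins) <- NULL
  structure(list(pairs = pairs, origins = origins, config = config,
                 chrom_lengths = sim$chrom_lengths),
            class = "read_sim")
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf("Simulated reads: %d pairs (%d reads), read length %d\n",
              nrow(x$pairs), 2L * nrow(x$pairs), x$config$read_len))
  invisible(x)
}

#' Subsample read pairs to a lower coverage
#'
#' Each pair is kept independently with probability `target_cov / full_cov`;
#' both mates are kept or dropped together. Used to derive the
#' 80/60/40/20/10/5x subsets from a 100x simulation.
#'
#' @param reads a "read_sim" object.
#' @param target_cov target coverage (fold); may be a vector (e.g.
#'   `c(80, 60, 40, 20, 10, 5)`), in which case a named list of subsets is
#'   returned from one call, each drawn independently.
#' @param full_cov coverage the reads were simulated at; defaults to the
#'   config value.
#' @param seed RNG seed.
#' @return a "read_sim" with the surviving pairs and origins (or a named
#'   list of them when `target_cov` is a vector).
#' @export
subsample_pairs <- function(reads, target_cov, full_cov = NULL, seed = 1L) {
  stopifnot(inherits(reads, "read_sim"))
  if (is.null(full_cov)) full_cov <- reads$config$coverage
  if (length(target_cov) > 1L) {
    out <- lapply(seq_along(target_cov), function(i)
      subsample_pairs(reads, target_cov[i], full_cov, seed = seed + i - 1L))
    names(out) <- paste0(target_cov, "x")
    return(out)
  }
  if (target_cov <= 0 || target_cov > full_cov)
    stop("need 0 < target_cov <= full_cov", call. = FALSE)
  set.seed(seed)
  keep <- stats::runif(nrow(reads$pairs)) < target_cov / full_cov
  kept_names <- reads$pairs$read_name[keep]
  out <- reads
  out$pairs <- reads$pairs[keep, , drop = FALSE]
  out$origins <- reads$origins[reads$origins$read_name %in% kept_names, ,
                               drop = FALSE]
  rownames(out$pairs) <- rownames(out$origins) <- NULL
  out$config$coverage <- target_cov
  out
}

#' Trim reads to a fixed length and drop short pairs
#'
#' Mirrors the preprocessing applied to real exome FASTQs before mapping:
#' pairs with one or both mates shorter than `min_len` are filtered out, and
#' surviving reads keep only their first `min_len` bases (sequence and
#' quality alike).
#'
#' @param pairs data.frame with seq1/qual1/seq2/qual2 (e.g. the `pairs`
#'   element of a "read_sim", or from [read_fastq_pair()]).
#' @param min_len minimum/target length in bases.
#' @return list: `pairs` (trimmed data.frame), `n_input`, `n_dropped`,
#'   `n_kept`.
#' @export
trim_and_filter <- function(pairs, min_len = 100L) {
  stopifnot(is.data.frame(pairs))
  if (any(nchar(pairs$seq1) != nchar(pairs$qual1)) ||
      any(nchar(pairs$seq2) != nchar(pairs$qual2)))
    stop("sequence/quality length mismatch", call. = FALSE)
  ok <- nchar(pairs$seq1) >= min_len & nchar(pairs$seq2) >= min_len
  out <- pairs[ok, , drop = FALSE]
  out$seq1 <- substr(out$seq1, 1L, min_len)
  out$qual1 <- substr(out$qual1, 1L, min_len)
  out$seq2 <- substr(out$seq2, 1L, min_len)
  out$qual2 <- substr(out$qual2, 1L, min_len)
  rownames(out) <- NULL
  list(pairs = out, n_input = nrow(pairs),
       n_dropped = sum(!ok), n_kept = nrow(out))
}

#' Trim and filter a pair of FASTQ files
#'
#' File-level wrapper around [trim_and_filter()].
#'
#' @param in1,in2 input FASTQ paths (mates in matched order).
#' @param out1,out2 output FASTQ paths.
#' @param min_len minimum/target read length.
#' @return the count list from [trim_and_filter()], invisibly.
#' @export
trim_fastq_files <- function(in1, in2, out1, out2, min_len = 100L) {
  pairs <- read_fastq_pair(in1, in2)
  res <- trim_and_filter(pairs, min_len)
  write_fastq_pair(res$pairs, out1, out2)
  invisible(res)
}

#' Write paired FASTQ files
#'
#' @param pairs data.frame with read_name, seq1, qual1, seq2, qual2.
#' @param path1,path2 output paths for mate 1 and mate 2.
#' @return c(path1, path2), invisibly.
#' @export
write_fastq_pair <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, names, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(x) <- names
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  write_one(pairs$seq1, pairs$qual1, paste0(pairs$read_name, "/1"), path1)
  write_one(pairs$seq2, pairs$qual2, paste0(pairs$read_name, "/2"), path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files into a pair table
#'
#' @param path1,path2 FASTQ paths (mates in matched order).
#' @return data.frame with read_name, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pair <- function(path1, path2) {
  ## Biostrings warns about dropped metadata columns on perfectly plain FASTQ
  rd <- function(p) suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
  a <- rd(path1); b <- rd(path2)
  if (length(a) != length(b))
    stop("mate-count mismatch between FASTQ files", call. = FALSE)
  strip <- function(n) sub("/[12]$", "", sub("\\s.*$", "", n))
  na <- strip(names(a)); nb <- strip(names(b))
  if (!identical(na, nb))
    stop("FASTQ mates are not in matched order", call. = FALSE)
  data.frame(read_name = na,
             seq1 = as.character(a),
             qual1 = as.character(Biostrings::quality(a)),
             seq2 = as.character(b),
             qual2 = as.character(Biostrings::quality(b)),
             stringsAsFactors = FALSE)
}

#' Write the read-origin sidecar table
#'
#' @param reads a "read_sim" object or its `origins` data.frame.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_origins <- function(reads, path) {
  org <- if (inherits(reads, "read_sim")) reads$origins else reads
  utils::write.table(org, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-origin sidecar table
#'
#' @param path TSV written by [write_origins()].
#' @return origins data.frame.
#' @export
read_origins <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "character", "integer"))
}
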