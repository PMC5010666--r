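## SAM fixture generation: perfect truth alignments and controlled
## perturbations, so mapping/rescue evaluators can be exercised without any
## external mapper. SAM text is canonical; readers accept BAM too via
## Rsamtools.

FLAG_PAIRED <- 0x1; FLAG_UNMAPPED <- 0x4; FLAG_REVERSE <- 0x10
FLAG_MREVERSE <- 0x20; FLAG_MATE1 <- 0x40; FLAG_MATE2 <- 0x80
FLAG_SECONDARY <- 0x100; FLAG_SUPPLEMENTARY <- 0x800

sam_header <- function(chrom_lengths, sort_order = "unsorted") {
  c(sprintf("@HD\tVN:1.6\tSO:%s", sort_order),
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths)))
}

#' Emit a perfect truth SAM for simulated reads
#'
#' One primary record per mate, POS equal to the mate's true origin, CIGAR
#' `<read_len>M`, reverse-strand mates stored reference-forward as SAM
#' requires. Evaluating this file gives mapping rate and accuracy exactly 1.
#'
#' @param reads a "read_sim" object.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
emit_truth_alignments <- function(reads, path) {
  stopifnot(inherits(reads, "read_sim"))
  p <- reads$pairs
  org <- reads$origins
  o1 <- org[org$mate == 1L, ]; o2 <- org[org$mate == 2L, ]
  o1 <- o1[match(p$read_name, o1$read_name), ]
  o2 <- o2[match(p$read_name, o2$read_name), ]

  rec <- function(name, mateflag, strand, other_strand, pos, mpos,
                  seq, qual) {
    flag <- FLAG_PAIRED + mateflag +
      ifelse(strand == "-", FLAG_REVERSE, 0L) +
      ifelse(other_strand == "-", FLAG_MREVERSE, 0L)
    ## store reverse-strand reads in reference orientation
    fseq <- ifelse(strand == "-", revcomp(seq), seq)
    fqual <- ifelse(strand == "-", reverse_string(qual), qual)
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t%s",
            name, as.integer(flag), o1$chrom, pos, nchar(seq), mpos,
            fseq, fqual)
  }
  lines <- c(sam_header(reads$chrom_lengths),
             rec(p$read_name, FLAG_MATE1, o1$strand, o2$strand,
                 o1$truth_start, o2$truth_start, p$seq1, p$qual1),
             rec(p$read_name, FLAG_MATE2, o2$strand, o1$strand,
                 o2$truth_start, o1$truth_start, p$seq2, p$qual2))
  writeLines(lines, path)
  invisible(path)
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), "")
}

## --- text-level SAM record access (for fixture perturbation / merging) ----

read_sam_lines <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  list(header = lines[is_hdr], records = lines[!is_hdr])
}

sam_field <- function(records, i) {
  vapply(strsplit(records, "\t", fixed = TRUE), `[[`, "", i)
}

set_sam_fields <- function(record, values) {
  f <- strsplit(record, "\t", fixed = TRUE)[[1]]
  for (k in names(values)) f[as.integer(k)] <- values[[k]]
  paste(f, collapse = "\t")
}

#' Perturb a truth SAM with known per-read outcomes
#'
#' Moves a controlled fraction of records away from their true location so
#' evaluator behaviour can be checked against intended labels: position
#' shifts of `k` bases, soft-clipping of `s` leading bases (with POS moved
#' forward by `s`, so clip-adjustment recovers the true start), unmapping,
#' and relocation to a different chromosome. Assignment priority when rates
#' overlap: unmap > wrong_chrom > shift > softclip.
#'
#' @param sam_in input SAM (typically from [emit_truth_alignments()]).
#' @param sam_out output SAM path.
#' @param unmap,wrong_chrom,shift,softclip per-read perturbation rates in
#'   [0, 1]; their sum must be <= 1.
#' @param shift_k shift size(s) in bases; sampled uniformly per shifted read
#'   when a vector.
#' @param softclip_s leading soft-clip size(s) in bases (< read length).
#' @param seed RNG seed.
#' @return invisibly, a data.frame of intended labels per record:
#'   read_name, mate, label (one of d0/d1_2/d3_10/d11_20/d_gt20/other_chrom/
#'   unmapped; soft-clipped reads are labelled d0 because clip adjustment
#'   restores their start).
#' @export
perturb_alignments <- function(sam_in, sam_out, unmap = 0, wrong_chrom = 0,
                               shift = 0, softclip = 0, shift_k = 3L,
                               softclip_s = 5L, seed = 1L) {
  stopifnot(unmap >= 0, wrong_chrom >= 0, shift >= 0, softclip >= 0,
            unmap + wrong_chrom + shift + softclip <= 1)
  set.seed(seed)
  x <- read_sam_lines(sam_in)
  n <- length(x$records)
  qname <- sam_field(x$records, 1L)
  flag <- as.integer(sam_field(x$records, 2L))
  rname <- sam_field(x$records, 3L)
  pos <- as.integer(sam_field(x$records, 4L))
  cigar <- sam_field(x$records, 6L)
  read_len <- nchar(sam_field(x$records, 10L))
  if (any(softclip_s >= read_len))
    stop("softclip_s must be smaller than the read length", call. = FALSE)

  ## disjoint assignment by priority
  u <- stats::runif(n)
  cls <- rep("none", n)
  cls[u < unmap] <- "unmap"
  cls[u >= unmap & u < unmap + wrong_chrom] <- "wrong_chrom"
  cls[u >= unmap + wrong_chrom & u < unmap + wrong_chrom + shift] <- "shift"
  cls[u >= unmap + wrong_chrom + shift &
      u < unmap + wrong_chrom + shift + softclip] <- "softclip"

  sq <- sub("^@SQ\tSN:([^\t]+).*$", "\\1", grep("^@SQ", x$header, value = TRUE))
  header <- x$header
  decoy <- "chrUn_divbench_decoy"
  if (any(cls == "wrong_chrom")) {
    others <- setdiff(sq, unique(rname))
    if (!length(others)) {
      header <- c(header, sprintf("@SQ\tSN:%s\tLN:%d", decoy, 1000000L))
      others <- decoy
    }
    wrong_target <- sample(others, sum(cls == "wrong_chrom"), replace = TRUE)
  }

  k_draw <- if (length(shift_k) > 1L)
    sample(as.integer(shift_k), n, replace = TRUE) else rep(as.integer(shift_k), n)
  s_draw <- if (length(softclip_s) > 1L)
    sample(as.integer(softclip_s), n, replace = TRUE) else rep(as.integer(softclip_s), n)

  records <- x$records
  label <- rep("d0", n)
  wi <- 0L
  for (i in seq_len(n)) {
    if (cls[i] == "none") next
    if (cls[i] == "unmap") {
      records[i] <- set_sam_fields(records[i], list(
        "2" = as.character(bitwOr(flag[i], FLAG_UNMAPPED)),
        "3" = "*", "4" = "0", "5" = "0", "6" = "*", "7" = "*", "8" = "0"))
      label[i] <- "unmapped"
    } else if (cls[i] == "wrong_chrom") {
      wi <- wi + 1L
      records[i] <- set_sam_fields(records[i], list("3" = wrong_target[wi]))
      label[i] <- "other_chrom"
    } else if (cls[i] == "shift") {
      records[i] <- set_sam_fields(records[i], list(
        "4" = as.character(pos[i] + k_draw[i])))
      label[i] <- distance_bin(abs(k_draw[i]))
    } else {
      s <- s_draw[i]
      records[i] <- set_sam_fields(records[i], list(
        "4" = as.character(pos[i] + s),
        "6" = sprintf("%dS%dM", s, read_len[i] - s)))
      label[i] <- "d0"    # clip adjustment restores the start
    }
  }
  writeLines(c(header, records), sam_out)
  invisible(data.frame(read_name = qname,
                       mate = ifelse(bitwAnd(flag, FLAG_MATE2) > 0L, 2L, 1L),
                       label = label, stringsAsFactors = FALSE))
}
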