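## Two-step mapping scaffolding: a fast first-pass mapper leaves some pairs
## unmapped in divergent regions; those pairs are extracted back to FASTQ
## for re-mapping with a divergence-tolerant mapper, and the rescued
## alignments are merged back in place of the originals. The mappers
## themselves are external; this module only moves the reads.

#' Extract pairs with unmapped read(s) from an alignment
#'
#' A template is extracted iff either primary mate carries the unmapped
#' flag; both mates are emitted so a paired re-mapper can be run on them.
#' Reverse-strand records are reverse-complemented back to their original
#' sequencing orientation.
#'
#' @param sam SAM/BAM path or a data.frame from [read_alignments()].
#' @param out1,out2 optional FASTQ paths to write the extracted mates to.
#' @return list of class "pair_extraction": `pairs` (read_name, seq1, qual1,
#'   seq2, qual2), `report` with total_pairs, extracted_pairs, emitted_reads.
#' @export
extract_unmapped_pairs <- function(sam, out1 = NULL, out2 = NULL) {
  aln <- if (is.data.frame(sam)) sam else read_alignments(sam)
  m1 <- aln[aln$mate == 1L, , drop = FALSE]
  m2 <- aln[aln$mate == 2L, , drop = FALSE]
  only <- c(setdiff(m1$read_name, m2$read_name),
            setdiff(m2$read_name, m1$read_name))
  if (length(only))
    stop("template with a single mate present: ", only[1L], call. = FALSE)
  m2 <- m2[match(m1$read_name, m2$read_name), , drop = FALSE]

  take <- m1$unmapped | m2$unmapped
  orig <- function(m) {
    rev <- bitwAnd(m$flag, FLAG_REVERSE) > 0L
    list(seq = ifelse(rev, revcomp(m$seq), m$seq),
         qual = ifelse(rev, reverse_string(m$qual), m$qual))
  }
  s1 <- orig(m1[take, , drop = FALSE]); s2 <- orig(m2[take, , drop = FALSE])
  pairs <- data.frame(read_name = m1$read_name[take],
                      seq1 = s1$seq, qual1 = s1$qual,
                      seq2 = s2$seq, qual2 = s2$qual,
                      stringsAsFactors = FALSE)
  if (!is.null(out1) && !is.null(out2)) write_fastq_pair(pairs, out1, out2)
  structure(list(pairs = pairs,
                 report = list(total_pairs = nrow(m1),
                               extracted_pairs = sum(take),
                               emitted_reads = 2L * sum(take))),
            class = "pair_extraction")
}

#' @export
print.pair_extraction <- function(x, ...) {
  r <- x$report
  cat(sprintf("Extracted %d of %d pairs (%d reads) with unmapped mate(s)\n",
              r$extracted_pairs, r$total_pairs, r$emitted_reads))
  invisible(x)
}

#' Merge rescued alignments back into the primary alignment
#'
#' For every template present in the rescue file, the primary file's records
#' are replaced by the rescue records; all other primary records pass
#' through verbatim. Rescue records for templates that were not extracted
#' (i.e. fully mapped in the primary file) are an error. Output is
#' coordinate-sorted SAM text.
#'
#' @param primary_sam first-pass SAM path.
#' @param rescue_sam re-mapped SAM path for the extracted pairs.
#' @param out_path merged SAM output path.
#' @return `out_path`, invisibly.
#' @export
merge_alignments <- function(primary_sam, rescue_sam, out_path) {
  p <- read_sam_lines(primary_sam)
  r <- read_sam_lines(rescue_sam)
  pq <- sam_field(p$records, 1L)
  rq <- unique(sam_field(r$records, 1L))

  pflag <- as.integer(sam_field(p$records, 2L))
  unmapped_tmpl <- unique(pq[bitwAnd(pflag, FLAG_UNMAPPED) > 0L])
  bad <- setdiff(rq, unmapped_tmpl)
  if (length(bad))
    stop("rescue record for non-extracted template: ", bad[1L],
         call. = FALSE)

  keep <- !(pq %in% rq)
  records <- c(p$records[keep], r$records)
  rname <- sam_field(records, 3L)
  pos <- suppressWarnings(as.integer(sam_field(records, 4L)))
  sq <- sub("^@SQ\tSN:([^\t]+).*$", "\\1",
            grep("^@SQ", p$header, value = TRUE))
  chrom_rank <- match(rname, sq)          # "*" (unmapped) sorts last
  ord <- order(is.na(chrom_rank), chrom_rank, pos)
  header <- sub("SO:[^\t]+", "SO:coordinate", p$header)
  writeLines(c(header, records[ord]), out_path)
  invisible(out_path)
}
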