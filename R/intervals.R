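## Genomic interval arithmetic shared by all modules.
##
## Internally every interval is 0-based half-open [start, end), carried in a
## plain data.frame with columns chrom/start/end (a "region set" once merged).
## BED files use the same convention natively; SAM/VCF coordinates are 1-based
## and are converted at the I/O boundary only.

#' The 4-Mb HLA window on chromosome 6
#'
#' The human leukocyte antigen (HLA) locus, chr6:29,500,000-33,500,000
#' (1-based, both endpoints inclusive), the most divergent region of the
#' human genome and the stratification boundary used throughout the package.
#'
#' @return A one-row region data.frame (0-based half-open coordinates).
#' @export
hla_region <- function() {
  data.frame(chrom = "chr6", start = 29500000L - 1L, end = 33500000L,
             stringsAsFactors = FALSE)
}

## validate a chrom/start/end data.frame; `what` names the offender in errors
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x)) stop(what, "s must be a data.frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(what, "s need columns chrom, start, end", call. = FALSE)
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop("empty chromosome name in ", what, " set", call. = FALSE)
  bad <- which(x$end <= x$start | x$start < 0)
  if (length(bad)) {
    b <- bad[1L]
    stop(sprintf("invalid %s %s:%d-%d (need 0 <= start < end)",
                 what, x$chrom[b], x$start[b], x$end[b]), call. = FALSE)
  }
  invisible(x)
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge genomic intervals into a sorted, non-overlapping region set
#'
#' Overlapping and touching intervals are collapsed so the result covers
#' exactly the union of input bases, sorted by (chrom, start). This is how
#' target-region BEDs are canonicalised before simulation (the original
#' benchmark compiled non-overlapping exonic regions the same way).
#'
#' @param raw data.frame with columns chrom, start, end (0-based half-open).
#' @return data.frame of disjoint sorted intervals.
#' @examples
#' merge_intervals(data.frame(chrom = "chr6", start = c(10, 15, 40),
#'                            end = c(20, 30, 50)))
#' @export
merge_intervals <- function(raw) {
  validate_intervals(raw)
  if (nrow(raw) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(intervals_to_granges(raw))  # merges adjacent too
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- granges_to_intervals(gr)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count bases shared by two intervals
#'
#' @param a,b single intervals: list or one-row data.frame with chrom, start,
#'   end (0-based half-open).
#' @return Integer number of overlapping bases (0 if different chromosome or
#'   disjoint; half-open adjacency counts as 0).
#' @export
overlap_bases <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  max(0L, as.integer(ov))
}

#' Stratify a position as HLA or non-HLA
#'
#' A 1-based position is "HLA" iff it lies on chr6 within the closed window
#' 29,500,000-33,500,000; everything else (including other chromosomes) is
#' "non-HLA".
#'
#' @param chrom chromosome name(s).
#' @param pos 1-based position(s); recycled against `chrom`.
#' @return character vector of "HLA"/"non-HLA".
#' @export
stratify_hla <- function(chrom, pos) {
  stopifnot(all(pos >= 1))
  hla <- hla_region()
  ifelse(chrom == hla$chrom & pos >= hla$start + 1L & pos <= hla$end,
         "HLA", "non-HLA")
}

#' Read a BED file of target regions
#'
#' Minimum three columns; chromosome names pass through verbatim. Returns
#' 0-based half-open intervals matching the BED standard.
#'
#' @param path BED file.
#' @return data.frame with chrom, start, end (plus name when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- granges_to_intervals(gr)
  nm <- gr$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- nm
  validate_intervals(out, "BED interval")
  out
}

#' Write intervals to a BED file
#'
#' @param x data.frame with chrom, start, end (0-based half-open).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x, "BED interval")
  df <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
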