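## Scoring a mapper's SAM/BAM against read truth origins.
##
## Mapping rate = mapped reads / total simulated reads; mapping accuracy =
## reads whose soft-clip-adjusted start equals the true origin / total
## simulated reads. Mates are treated as independent single-end reads, and
## reads on the target chromosome are binned by the distance between the
## adjusted and true starts (0, 1-2, 3-10, 11-20, >20 bp), with separate
## classes for other-chromosome and unmapped reads.

MAPPING_CLASSES <- c("d0", "d1_2", "d3_10", "d11_20", "d_gt20",
                     "other_chrom", "unmapped")

distance_bin <- function(d) {
  ifelse(d == 0, "d0",
  ifelse(d <= 2, "d1_2",
  ifelse(d <= 10, "d3_10",
  ifelse(d <= 20, "d11_20", "d_gt20"))))
}

#' Read primary alignment records from SAM or BAM
#'
#' SAM text is converted through Rsamtools; secondary (0x100) and
#' supplementary (0x800) records are dropped so each simulated read is
#' counted once.
#'
#' @param path SAM or BAM file.
#' @param what extra fields to retrieve (seq/qual are included for rescue
#'   extraction).
#' @return data.frame with read_name, mate, flag, chrom (NA when unmapped),
#'   pos, cigar, mapq, seq, qual.
#' @export
read_alignments <- function(path,
                            what = c("qname", "flag", "rname", "pos",
                                     "cigar", "mapq", "seq", "qual")) {
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(bam,
         param = Rsamtools::ScanBamParam(what = what))[[1]]
  df <- data.frame(read_name = b$qname,
                   flag = b$flag,
                   chrom = as.character(b$rname),
                   pos = b$pos,
                   cigar = b$cigar,
                   mapq = b$mapq,
                   seq = as.character(b$seq),
                   qual = as.character(b$qual),
                   stringsAsFactors = FALSE)
  keep <- bitwAnd(df$flag, FLAG_SECONDARY + FLAG_SUPPLEMENTARY) == 0L
  df <- df[keep, , drop = FALSE]
  df$mate <- ifelse(bitwAnd(df$flag, FLAG_MATE2) > 0L, 2L, 1L)
  df$unmapped <- bitwAnd(df$flag, FLAG_UNMAPPED) > 0L
  rownames(df) <- NULL
  df
}

#' Soft-clip-adjusted alignment start
#'
#' The reported POS points at the first aligned base; leading soft-clipped
#' (or hard-clipped) bases are added back by subtracting their count, which
#' recovers the coordinate the full read would start at. Trailing clips do
#' not move the start.
#'
#' @param pos 1-based reported position(s).
#' @param cigar CIGAR string(s).
#' @return integer vector of adjusted 1-based starts.
#' @examples
#' adjusted_start(1005, "5S95M")  # 1000
#' @export
adjusted_start <- function(pos, cigar) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad))
    stop("unparseable CIGAR: ", cigar[bad][1L], call. = FALSE)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  lead <- vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    ty <- sub("^[0-9]+", "", o)
    tot <- 0L
    for (i in seq_along(ty)) {          # only clips before the first aligned op
      if (ty[i] %in% c("S", "H")) tot <- tot + n[i] else break
    }
    tot
  }, 1L)
  as.integer(pos - lead)
}

#' Classify one read against its truth origin
#'
#' @param rec one-row data.frame (or list) with flag/unmapped, chrom, pos,
#'   cigar.
#' @param origin one-row origin (chrom, truth_start).
#' @return one of the labels d0, d1_2, d3_10, d11_20, d_gt20, other_chrom,
#'   unmapped.
#' @export
classify_read <- function(rec, origin) {
  if (is.null(origin) || (is.data.frame(origin) && nrow(origin) == 0L))
    stop("missing origin for read ", rec$read_name, call. = FALSE)
  unmapped <- if (!is.null(rec$unmapped)) rec$unmapped
              else bitwAnd(rec$flag, FLAG_UNMAPPED) > 0L
  if (unmapped) return("unmapped")
  if (rec$chrom != origin$chrom) return("other_chrom")
  d <- abs(adjusted_start(rec$pos, rec$cigar) - origin$truth_start)
  distance_bin(d)
}

#' Score a SAM/BAM against the truth origins
#'
#' Every primary record is classified against its recorded origin; origins
#' with no record in the file count as unmapped (a read the mapper dropped
#' is still a simulated read). Both rate and accuracy use the total number
#' of simulated reads as denominator.
#'
#' @param sam path to SAM/BAM, or a data.frame from [read_alignments()].
#' @param origins origins data.frame (or a "read_sim" object).
#' @param target_chrom optional label for reporting ("Not on `chrom`"
#'   reads); classification itself always compares against each read's own
#'   origin chromosome.
#' @return object of class "mapping_report": per-class counts, `total`,
#'   `mapping_rate`, `accuracy`.
#' @export
summarize_mapping <- function(sam, origins, target_chrom = NULL) {
  aln <- if (is.data.frame(sam)) sam else read_alignments(sam)
  if (inherits(origins, "read_sim")) origins <- origins$origins
  key_a <- paste(aln$read_name, aln$mate)
  if (anyDuplicated(key_a)) {
    dup <- key_a[duplicated(key_a)][1L]
    stop("duplicate primary records for read ", dup, call. = FALSE)
  }
  key_o <- paste(origins$read_name, origins$mate)
  hit <- match(key_a, key_o)
  if (anyNA(hit))
    stop("alignment with no origin: ", key_a[which(is.na(hit))[1L]],
         call. = FALSE)

  label <- character(nrow(aln))
  label[aln$unmapped] <- "unmapped"
  m <- !aln$unmapped
  oc <- m & aln$chrom != origins$chrom[hit]
  label[oc] <- "other_chrom"
  ok <- m & !oc
  if (any(ok)) {
    d <- abs(adjusted_start(aln$pos[ok], aln$cigar[ok]) -
             origins$truth_start[hit[ok]])
    label[ok] <- distance_bin(d)
  }
  total <- nrow(origins)
  counts <- table(factor(label, levels = MAPPING_CLASSES))
  counts <- stats::setNames(as.integer(counts), MAPPING_CLASSES)
  ## simulated reads absent from the SAM are unmapped by definition
  counts["unmapped"] <- counts["unmapped"] + (total - nrow(aln))
  mapped <- total - counts["unmapped"]
  structure(list(counts = counts, total = total,
                 mapping_rate = unname(mapped) / total,
                 accuracy = unname(counts["d0"]) / total,
                 target_chrom = target_chrom),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("Mapping report", if (!is.null(x$target_chrom))
    sprintf(" (target %s)", x$target_chrom), "\n", sep = "")
  cat(sprintf("  total reads : %d\n", x$total))
  cat(sprintf("  mapping rate: %.4f\n", x$mapping_rate))
  cat(sprintf("  accuracy    : %.4f\n", x$accuracy))
  lab <- c(d0 = "distance 0", d1_2 = "distance 1-2", d3_10 = "distance 3-10",
           d11_20 = "distance 11-20", d_gt20 = "distance >20",
           other_chrom = "other chromosome", unmapped = "unmapped")
  for (k in MAPPING_CLASSES)
    cat(sprintf("  %-16s %d\n", lab[[k]], x$counts[[k]]))
  invisible(x)
}

#' Mapping report as a one-row data.frame
#'
#' @param report a "mapping_report".
#' @return data.frame with counts and rates.
#' @export
mapping_report_row <- function(report) {
  cbind(data.frame(total = report$total,
                   mapping_rate = report$mapping_rate,
                   accuracy = report$accuracy),
        as.data.frame(as.list(report$counts)))
}
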