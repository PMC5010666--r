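## Sequence-context annotation of variant calls: SnpCluster (>= 3 SNPs
## within 20 consecutive bases), LCR (low-complexity region) and SD
## (segmental duplication, >= 95 % identity over >= 1 kb) membership from
## BED tracks, plus HLA/non-HLA stratification.

#' Flag clustered SNPs
#'
#' A SNP is flagged iff it belongs to some set of at least `min_count` SNPs
#' all contained in `window` consecutive bases (positions p_i..p_j with
#' p_j - p_i <= window - 1); every member of a qualifying window is flagged.
#'
#' @param pos sorted 1-based SNP positions on one chromosome.
#' @param window window width in bases.
#' @param min_count minimum SNPs in a window.
#' @return logical vector parallel to `pos`.
#' @examples
#' flag_snp_clusters(c(100, 110, 119))  # all TRUE (span 19 < 20)
#' flag_snp_clusters(c(100, 110, 121))  # all FALSE
#' @export
flag_snp_clusters <- function(pos, window = 20L, min_count = 3L) {
  n <- length(pos)
  if (n == 0L) return(logical(0))
  if (is.unsorted(pos)) stop("positions must be sorted", call. = FALSE)
  flag <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && pos[j + 1L] - pos[i] <= window - 1L) j <- j + 1L
    if (j - i + 1L >= min_count) flag[i:j] <- TRUE
  }
  flag
}

#' Flag variants located in LCR / SD tracks
#'
#' A variant is flagged iff its reference footprint (deleted span for
#' deletions, anchor base otherwise) overlaps any interval of the track by
#' at least one base. SD intervals shorter than 1 kb trigger a warning (the
#' track definition requires >= 1 kb) but still count for membership.
#'
#' @param variants data.frame with chrom, pos, ref, vtype.
#' @param lcr,sd region data.frames (0-based half-open) or BED paths; NULL
#'   leaves the respective flag all-FALSE.
#' @return data.frame with logical columns `lcr` and `sd`.
#' @export
flag_regions <- function(variants, lcr = NULL, sd = NULL) {
  load_track <- function(x, check_sd = FALSE) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) x <- read_bed(x)
    x <- merge_intervals(x)
    if (check_sd && nrow(x) && any(x$end - x$start < 1000L))
      warning("SD track contains intervals shorter than 1 kb", call. = FALSE)
    x
  }
  lcr <- load_track(lcr)
  sd <- load_track(sd, check_sd = TRUE)

  fp_end <- ifelse(variants$vtype == "DEL" & nchar(variants$ref) > 1L,
                   variants$pos + nchar(variants$ref) - 1L,
                   variants$pos)
  fp_start <- ifelse(variants$vtype == "DEL" & nchar(variants$ref) > 1L,
                     variants$pos + 1L, variants$pos)
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(fp_start, fp_end))
  hits <- function(track) {
    if (is.null(track) || nrow(track) == 0L)
      return(rep(FALSE, nrow(variants)))
    GenomicRanges::countOverlaps(vgr, intervals_to_granges(track)) > 0L
  }
  data.frame(lcr = hits(lcr), sd = hits(sd))
}

#' Annotate variant calls by sequence context
#'
#' Adds SnpCluster, LCR, SD flags and the HLA/non-HLA region label to a
#' call table.
#'
#' @param variants call or truth data.frame (chrom, pos, ref, alt, vtype).
#' @param lcr,sd optional BED paths or region data.frames.
#' @param window,min_count SnpCluster parameters (20 bp, 3 SNPs).
#' @return `variants` with added columns snp_cluster, lcr, sd, region_label.
#' @export
annotate_variants <- function(variants, lcr = NULL, sd = NULL,
                              window = 20L, min_count = 3L) {
  n <- nrow(variants)
  snp_cluster <- logical(n)
  is_snp <- variants$vtype == "SNP"
  for (ch in unique(variants$chrom[is_snp])) {
    idx <- which(is_snp & variants$chrom == ch)
    idx <- idx[order(variants$pos[idx])]
    snp_cluster[idx] <- flag_snp_clusters(variants$pos[idx], window, min_count)
  }
  fl <- flag_regions(variants, lcr, sd)
  variants$snp_cluster <- snp_cluster
  variants$lcr <- fl$lcr
  variants$sd <- fl$sd
  variants$region_label <- stratify_hla(variants$chrom, variants$pos)
  variants
}

#' Write annotated variants as a VCF with INFO flags
#'
#' Emits SNPCLUSTER, LCR and SD as INFO flags on a minimal VCF so annotated
#' call sets can feed downstream tools.
#'
#' @param variants annotated data.frame from [annotate_variants()].
#' @param path output VCF.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(variants, path) {
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divbench-annotate",
           "##INFO=<ID=SNPCLUSTER,Number=0,Type=Flag,Description=\"Three or more SNPs within 20 bp\">",
           "##INFO=<ID=LCR,Number=0,Type=Flag,Description=\"Low complexity region\">",
           "##INFO=<ID=SD,Number=0,Type=Flag,Description=\"Segmental duplication\">",
           "##INFO=<ID=REGION,Number=1,Type=String,Description=\"HLA stratification\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  info <- vapply(seq_len(nrow(variants)), function(i) {
    f <- c(if (variants$snp_cluster[i]) "SNPCLUSTER",
           if (variants$lcr[i]) "LCR",
           if (variants$sd[i]) "SD",
           paste0("REGION=", sub("-", "", variants$region_label[i])))
    paste(f, collapse = ";")
  }, "")
  qual <- if ("qual" %in% names(variants))
    ifelse(is.na(variants$qual), ".", format(variants$qual)) else "."
  body <- if (nrow(variants))
    sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", variants$chrom, variants$pos,
            variants$ref, variants$alt, qual, info) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
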