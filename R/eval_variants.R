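## Comparing a caller's VCF to the simulation truth (or any reference set):
## quality filtering at Q >= 20, allele-exact SNP matching, overlap-based
## INDEL matching, sensitivity / precision / overall genotype concordance,
## and known/novel classification against a catalog VCF.

#' Load and filter variant calls from a VCF
#'
#' Reads a VCF (plain or bgzipped) through VariantAnnotation, splits
#' multi-allelic records into per-alternate calls sharing the record QUAL,
#' normalizes INDEL alleles (shared leading base kept, shared trailing bases
#' trimmed), and drops records below the quality threshold. The first
#' sample's GT, when present, is reduced per alternate allele: one copy of
#' the alt is "het", two copies "hom_alt"; alleles absent from the genotype
#' are dropped as non-calls.
#'
#' @param path VCF file.
#' @param min_qual minimum QUAL kept ("at least 20" is the benchmark rule);
#'   records with missing QUAL pass.
#' @param sample sample column used for genotypes (index or name); NULL
#'   takes the first when available.
#' @return data.frame of calls: chrom, pos, ref, alt, qual, genotype
#'   ("het"/"hom_alt"/NA), vtype ("SNP"/"INS"/"DEL"/"OTHER"), sorted by
#'   (chrom, pos).
#' @export
load_and_filter_calls <- function(path, min_qual = 20, sample = NULL) {
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  n <- length(rr)
  if (n == 0L) return(empty_calls())
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(v))
  alts <- VariantAnnotation::alt(v)              # DNAStringSetList
  qual <- VariantAnnotation::qual(v)
  gt <- NULL
  if ("GT" %in% names(VariantAnnotation::geno(v))) {
    g <- VariantAnnotation::geno(v)$GT
    j <- if (is.null(sample)) 1L else sample
    if (ncol(g) >= 1L) gt <- as.character(g[, j])
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- as.character(alts[[i]])
    a <- a[!(a %in% c("", ".", "*"))]
    if (!length(a)) next
    alleles <- if (is.null(gt) || is.na(gt[i])) NULL
               else strsplit(gt[i], "[/|]")[[1]]
    geno <- rep(NA_character_, length(a))
    keep <- rep(TRUE, length(a))
    if (!is.null(alleles) && !all(alleles == ".")) {
      cnt <- vapply(seq_along(a),
                    function(k) sum(alleles == as.character(k)), 1L)
      geno[cnt == 1L] <- "het"
      geno[cnt >= 2L] <- "hom_alt"
      keep <- cnt > 0L                 # 0/0 w.r.t. this alt: not a call
    }
    if (!any(keep)) next
    out[[i]] <- data.frame(chrom = chrom[i], pos = pos[i], ref = ref[i],
                           alt = a[keep], qual = qual[i],
                           genotype = geno[keep], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                            list(empty_calls()[, 1:6])))
  if (nrow(calls) == 0L) return(empty_calls())
  calls <- calls[is.na(calls$qual) | calls$qual >= min_qual, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty_calls())
  norm <- normalize_alleles(calls$pos, calls$ref, calls$alt)
  calls$pos <- norm$pos; calls$ref <- norm$ref; calls$alt <- norm$alt
  calls$vtype <- variant_type(calls$ref, calls$alt)
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), genotype = character(),
             vtype = character(), stringsAsFactors = FALSE)
}

variant_type <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNP",
  ifelse(lr == 1L & la > 1L, "INS",
  ifelse(la == 1L & lr > 1L, "DEL", "OTHER")))
}

## trim shared trailing bases (keeping at least one base each), then strip
## redundant shared leading bases beyond the single VCF anchor
normalize_alleles <- function(pos, ref, alt) {
  for (i in seq_along(ref)) {
    r <- ref[i]; a <- alt[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L) &&
           substr(r, 2L, 2L) == substr(a, 2L, 2L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

new_eval_result <- function(tp, fp, fn, pairs) {
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, precision = prec,
                 genotype_concordance = genotype_concordance(pairs),
                 pairs = pairs),
            class = "variant_eval")
}

#' @export
print.variant_eval <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("sensitivity %.4f  precision %.4f  genotype concordance %s\n",
              x$sensitivity, x$precision,
              ifelse(is.na(x$genotype_concordance), "NA",
                     sprintf("%.4f", x$genotype_concordance))))
  invisible(x)
}

#' Match called SNPs against truth SNPs
#'
#' A call is a true positive iff some truth SNP shares chromosome, position
#' and alternate allele; each truth record is matched at most once.
#' Unmatched calls are false positives; unmatched truth false negatives.
#'
#' @param calls,truth call/truth data.frames (as from
#'   [load_and_filter_calls()] or a "mutation_sim"'s `variants`); only rows
#'   with vtype "SNP" are considered.
#' @param by_position match on position only, ignoring the alternate allele
#'   (for sensitivity analyses).
#' @return object of class "variant_eval" with tp/fp/fn, sensitivity,
#'   precision, genotype_concordance, and the matched-pair table.
#' @export
match_snps <- function(calls, truth, by_position = FALSE) {
  c_s <- calls[calls$vtype == "SNP", , drop = FALSE]
  t_s <- truth[truth$vtype == "SNP", , drop = FALSE]
  keyfun <- if (by_position) function(d) paste(d$chrom, d$pos)
            else function(d) paste(d$chrom, d$pos, d$alt)
  hit <- match(keyfun(c_s), keyfun(t_s))
  hit[duplicated(hit, incomparables = NA)] <- NA   # each truth matched once
  tp_idx <- which(!is.na(hit))
  pairs <- data.frame(
    chrom = c_s$chrom[tp_idx], pos = c_s$pos[tp_idx],
    call_alt = c_s$alt[tp_idx], truth_alt = t_s$alt[hit[tp_idx]],
    call_genotype = c_s$genotype[tp_idx],
    truth_genotype = t_s$genotype[hit[tp_idx]],
    stringsAsFactors = FALSE)
  new_eval_result(tp = length(tp_idx),
                  fp = nrow(c_s) - length(tp_idx),
                  fn = nrow(t_s) - length(tp_idx),
                  pairs = pairs)
}

## reference-interval projection of an INDEL: deleted span for DEL, 1-base
## anchor for INS (1-based closed coordinates)
indel_interval <- function(d) {
  is_del <- d$vtype == "DEL"
  data.frame(chrom = d$chrom,
             start = ifelse(is_del, d$pos + 1L, d$pos),
             end = ifelse(is_del, d$pos + nchar(d$ref) - 1L, d$pos),
             stringsAsFactors = FALSE)
}

#' Match called INDELs against truth INDELs by interval overlap
#'
#' Each INDEL is projected to a reference interval (deletions to their
#' deleted span, insertions to the anchoring base) and calls are assigned
#' greedily left-to-right to the unmatched truth interval of maximal overlap
#' (ties to the leftmost), counting a true positive when the overlap is at
#' least `min_overlap` bases - the intersect-style matching used for
#' permuted vs called INDELs.
#'
#' @param calls,truth data.frames; rows with vtype "INS"/"DEL" are used.
#' @param min_overlap minimum overlapping bases for a match.
#' @return a "variant_eval" object.
#' @export
match_indels <- function(calls, truth, min_overlap = 1L) {
  c_i <- calls[calls$vtype %in% c("INS", "DEL"), , drop = FALSE]
  t_i <- truth[truth$vtype %in% c("INS", "DEL"), , drop = FALSE]
  ci <- indel_interval(c_i); ti <- indel_interval(t_i)
  ord <- order(ci$chrom, ci$start)
  c_i <- c_i[ord, , drop = FALSE]; ci <- ci[ord, , drop = FALSE]

  matched_truth <- rep(NA_integer_, nrow(c_i))
  taken <- logical(nrow(t_i))
  for (i in seq_len(nrow(c_i))) {
    same <- which(!taken & ti$chrom == ci$chrom[i])
    if (!length(same)) next
    ov <- pmin(ti$end[same], ci$end[i]) - pmax(ti$start[same], ci$start[i]) + 1L
    ok <- ov >= min_overlap
    if (!any(ok)) next
    best <- same[ok][order(-ov[ok], ti$start[same][ok])][1L]
    matched_truth[i] <- best
    taken[best] <- TRUE
  }
  tp_idx <- which(!is.na(matched_truth))
  pairs <- data.frame(
    chrom = c_i$chrom[tp_idx], pos = c_i$pos[tp_idx],
    call_alt = c_i$alt[tp_idx], truth_alt = t_i$alt[matched_truth[tp_idx]],
    call_genotype = c_i$genotype[tp_idx],
    truth_genotype = t_i$genotype[matched_truth[tp_idx]],
    stringsAsFactors = FALSE)
  new_eval_result(tp = length(tp_idx),
                  fp = nrow(c_i) - length(tp_idx),
                  fn = nrow(t_i) - length(tp_idx),
                  pairs = pairs)
}

#' Overall genotype concordance of matched pairs
#'
#' Fraction of true-positive matches whose unordered diploid genotype equals
#' the truth genotype. Undefined (NA) when there are no matched pairs or no
#' genotypes - never reported as 0 in that case.
#'
#' @param pairs matched-pair data.frame with call_genotype/truth_genotype
#'   columns (as produced by [match_snps()]/[match_indels()]).
#' @return fraction in [0, 1], or NA.
#' @export
genotype_concordance <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(NA_real_)
  cg <- pairs$call_genotype; tg <- pairs$truth_genotype
  use <- !is.na(cg) & !is.na(tg)
  if (!any(use)) return(NA_real_)
  mean(cg[use] == tg[use])
}

#' Evaluate a call set against the truth, SNPs and INDELs separately
#'
#' @param calls filtered calls (data.frame or VCF path, filtered at
#'   `min_qual`).
#' @param truth truth variants (data.frame, "mutation_sim", or VCF path).
#' @param min_qual quality threshold applied when `calls` is a path.
#' @param min_overlap INDEL overlap threshold.
#' @param stratify optional region (one-row data.frame, e.g.
#'   [hla_region()]): results are additionally reported inside/outside it.
#' @return list of class "variant_eval_set" with elements `snp` and `indel`
#'   (each a "variant_eval"), and `strata` when `stratify` is given.
#' @export
evaluate_calls <- function(calls, truth, min_qual = 20, min_overlap = 1L,
                           stratify = NULL) {
  if (is.character(calls)) calls <- load_and_filter_calls(calls, min_qual)
  if (inherits(truth, "mutation_sim")) truth <- truth$variants
  if (is.character(truth)) truth <- load_and_filter_calls(truth, min_qual = 0)
  res <- list(snp = match_snps(calls, truth),
              indel = match_indels(calls, truth, min_overlap))
  if (!is.null(stratify)) {
    inside <- function(d) {
      d[d$chrom == stratify$chrom & d$pos >= stratify$start + 1L &
          d$pos <= stratify$end, , drop = FALSE]
    }
    outside <- function(d) {
      d[!(d$chrom == stratify$chrom & d$pos >= stratify$start + 1L &
            d$pos <= stratify$end), , drop = FALSE]
    }
    res$strata <- list(
      inside = list(snp = match_snps(inside(calls), inside(truth)),
                    indel = match_indels(inside(calls), inside(truth),
                                         min_overlap)),
      outside = list(snp = match_snps(outside(calls), outside(truth)),
                     indel = match_indels(outside(calls), outside(truth),
                                          min_overlap)))
  }
  class(res) <- "variant_eval_set"
  res
}

#' @export
print.variant_eval_set <- function(x, ...) {
  cat("SNPs:\n"); print(x$snp)
  cat("INDELs:\n"); print(x$indel)
  invisible(x)
}

#' Classify calls as known or novel against a catalog
#'
#' A call is "known" iff the catalog holds a record with the same
#' chromosome, position and alternate allele (the dbSNP-style membership
#' rule); otherwise "novel".
#'
#' @param calls call data.frame.
#' @param catalog catalog VCF path or data.frame of catalog variants.
#' @return `calls` with an added `known` factor ("known"/"novel").
#' @export
classify_known <- function(calls, catalog) {
  if (is.character(catalog))
    catalog <- load_and_filter_calls(catalog, min_qual = 0)
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  calls$known <- factor(ifelse(key(calls) %in% key(catalog),
                               "known", "novel"),
                        levels = c("known", "novel"))
  calls
}
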