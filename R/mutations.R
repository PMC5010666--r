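## Divergence-controlled mutagenesis of target regions.
##
## The divergence level is the number of permuted events (SNPs + INDELs)
## divided by the total bases of the simulated regions. Events are placed
## uniformly with non-overlapping reference footprints; the truth is a
## data.frame of VCF-style variants (chrom, pos, ref, alt, vtype, genotype)
## with 1-based positions and, for INDELs, the anchoring base preceding the
## event.

BASES <- c("A", "C", "G", "T")

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Default divergence-level grid
#'
#' Seven divergence levels spanning 0.05 %--15 % plus the zero-divergence
#' control, the grid over which mapper/caller performance is benchmarked.
#'
#' @return numeric vector of event-per-base fractions.
#' @export
divergence_levels <- function() {
  c(0, 0.0005, 0.001, 0.005, 0.01, 0.05, 0.10, 0.15)
}

#' Divergence specification
#'
#' Bundles the knobs of the mutagenesis model: how many events per base,
#' the SNP:INDEL split, INDEL length cap, and zygosity.
#'
#' @param level events per base, in [0, max_level].
#' @param snp_fraction fraction of events that are SNPs (rest split evenly
#'   between insertions and deletions).
#' @param indel_max_len maximum INDEL length; lengths follow a geometric
#'   distribution (p = 0.5) truncated to 1..indel_max_len.
#' @param het_fraction probability an event is heterozygous (haplotype 2
#'   keeps the reference allele at het sites); set 0 for a haploid-style
#'   simulation.
#' @param seed RNG seed used by [simulate_mutations()].
#' @param max_level upper bound accepted for `level`.
#' @return list of class "divergence_spec".
#' @export
divergence_spec <- function(level, snp_fraction = 0.9, indel_max_len = 10L,
                            het_fraction = 0.5, seed = 1L,
                            max_level = 0.15) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level < 0)
    stop("divergence level must be a single non-negative number", call. = FALSE)
  if (level > max_level)
    stop(sprintf("divergence level %g exceeds max_level %g", level, max_level),
         call. = FALSE)
  stopifnot(snp_fraction >= 0, snp_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1, indel_max_len >= 1)
  structure(list(level = level, snp_fraction = snp_fraction,
                 indel_max_len = as.integer(indel_max_len),
                 het_fraction = het_fraction, seed = as.integer(seed),
                 max_level = max_level),
            class = "divergence_spec")
}

#' Number of variant events implied by a divergence level
#'
#' `round(region_length * level)`, rounding half away from zero, per the
#' definition of divergence as events over total bases.
#'
#' @param region_length total bases.
#' @param level events per base.
#' @return integer event count.
#' @examples
#' plan_variant_count(10000, 0.01)  # 100
#' @export
plan_variant_count <- function(region_length, level) {
  stopifnot(region_length > 0)
  if (level < 0) stop("divergence level must be >= 0", call. = FALSE)
  as.integer(round_half_away(region_length * level))
}

## geometric(p = 0.5) truncated to 1..max_len
rindel_len <- function(n, max_len) {
  w <- 0.5^(seq_len(max_len))
  sample.int(max_len, n, replace = TRUE, prob = w / sum(w))
}

#' Permute SNPs and INDELs into one region
#'
#' Places exactly `count` events at uniformly drawn positions with
#' non-overlapping reference footprints (collisions are redrawn up to 1,000
#' times before the request is declared infeasible). SNP alternates are
#' uniform over the three non-reference bases; insertions and deletions are
#' equiprobable within the INDEL budget. Uses the session RNG: seed before
#' calling for reproducibility.
#'
#' @param region_seq reference sequence of the region (character).
#' @param region one-row data.frame chrom/start/end (0-based half-open).
#' @param count number of events to place.
#' @param spec a [divergence_spec()].
#' @return data.frame of truth variants sorted by position, columns chrom,
#'   pos (1-based), ref, alt, vtype ("SNP"/"INS"/"DEL"), genotype
#'   ("het"/"hom_alt").
#' @export
permute_variants <- function(region_seq, region, count, spec) {
  L <- nchar(region_seq)
  stopifnot(L == region$end - region$start)
  if (count > L)
    stop("cannot place ", count, " events in ", L, " bases", call. = FALSE)
  if (count == 0L) return(empty_variants())

  bases <- strsplit(region_seq, "", fixed = TRUE)[[1]]
  occupied <- logical(L)
  n_indel_types <- 2L

  is_snp <- stats::runif(count) < spec$snp_fraction
  is_ins <- !is_snp & (stats::runif(count) < 0.5)
  lens <- ifelse(is_snp, 1L, rindel_len(count, spec$indel_max_len))
  genos <- ifelse(stats::runif(count) < spec$het_fraction, "het", "hom_alt")

  pos <- integer(count); ref <- character(count); alt <- character(count)
  vtype <- character(count)
  for (i in seq_len(count)) {
    placed <- FALSE
    for (attempt in seq_len(1000L)) {
      p <- sample.int(L, 1L)
      ## reference footprint: SNP/INS anchor base only; DEL anchor + deleted run
      fp_end <- if (!is_snp[i] && !is_ins[i]) p + lens[i] else p
      if (fp_end > L) next
      if (any(occupied[p:fp_end])) next
      if (!(bases[p] %in% BASES)) next
      if (!is_snp[i] && !is_ins[i] &&
          !all(bases[(p + 1L):fp_end] %in% BASES)) next
      occupied[p:fp_end] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place event ", i, " of ", count,
           " after 1000 attempts; region too saturated", call. = FALSE)
    pos[i] <- p
    if (is_snp[i]) {
      vtype[i] <- "SNP"
      ref[i] <- bases[p]
      alt[i] <- sample(setdiff(BASES, bases[p]), 1L)
    } else if (is_ins[i]) {
      vtype[i] <- "INS"
      ref[i] <- bases[p]
      alt[i] <- paste0(bases[p],
                       paste(sample(BASES, lens[i], replace = TRUE),
                             collapse = ""))
    } else {
      vtype[i] <- "DEL"
      ref[i] <- paste(bases[p:(p + lens[i])], collapse = "")
      alt[i] <- bases[p]
    }
  }
  out <- data.frame(chrom = region$chrom, pos = region$start + pos,
                    ref = ref, alt = alt, vtype = vtype, genotype = genos,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vtype = character(), genotype = character(),
             stringsAsFactors = FALSE)
}

#' Realize truth variants as a mutated haplotype
#'
#' Applies the variants carried by one haplotype to the region sequence and
#' returns the edited sequence together with a haplotype-to-reference
#' coordinate map, so downstream read simulation can express every read
#' origin in reference coordinates. Haplotype 1 carries every variant;
#' haplotype 2 carries only homozygous-alternate variants (het sites stay
#' reference).
#'
#' @param region_seq reference sequence of the region.
#' @param variants truth variants from [permute_variants()] (sorted,
#'   non-overlapping).
#' @param region one-row region data.frame.
#' @param haplotype_index 1 or 2.
#' @return list of class "mutated_haplotype": `sequence`, `coord_map`
#'   (1-based reference position of each haplotype base; inserted bases map
#'   to their anchor), `inserted` (logical mask of inserted bases).
#' @export
apply_variants <- function(region_seq, variants, region, haplotype_index = 1L) {
  stopifnot(haplotype_index %in% c(1L, 2L))
  L <- nchar(region_seq)
  apply_these <- if (haplotype_index == 1L) variants
                 else variants[variants$genotype == "hom_alt", , drop = FALSE]
  apply_these <- apply_these[order(apply_these$pos), , drop = FALSE]

  rel <- apply_these$pos - region$start            # 1-based region-relative
  fp_end <- rel + nchar(apply_these$ref) - 1L
  if (nrow(apply_these)) {
    if (any(rel < 1L) || any(fp_end > L))
      stop("variant outside region", call. = FALSE)
    if (any(rel[-1L] <= fp_end[-length(fp_end)]))
      stop("overlapping variant footprints", call. = FALSE)
  }

  seq_chunks <- character(0); map_chunks <- list(); ins_chunks <- list()
  ptr <- 1L
  for (i in seq_len(nrow(apply_these))) {
    p <- rel[i]
    if (p > ptr) {                                  # untouched stretch
      seq_chunks <- c(seq_chunks, substr(region_seq, ptr, p - 1L))
      map_chunks[[length(map_chunks) + 1L]] <- ptr:(p - 1L)
      ins_chunks[[length(ins_chunks) + 1L]] <- rep(FALSE, p - ptr)
    }
    v <- apply_these[i, ]
    if (v$vtype == "SNP") {
      seq_chunks <- c(seq_chunks, v$alt)
      map_chunks[[length(map_chunks) + 1L]] <- p
      ins_chunks[[length(ins_chunks) + 1L]] <- FALSE
      ptr <- p + 1L
    } else if (v$vtype == "INS") {
      seq_chunks <- c(seq_chunks, v$alt)            # anchor + inserted bases
      k <- nchar(v$alt) - 1L
      map_chunks[[length(map_chunks) + 1L]] <- rep(p, k + 1L)
      ins_chunks[[length(ins_chunks) + 1L]] <- c(FALSE, rep(TRUE, k))
      ptr <- p + 1L
    } else {                                        # DEL: keep anchor only
      seq_chunks <- c(seq_chunks, v$alt)
      map_chunks[[length(map_chunks) + 1L]] <- p
      ins_chunks[[length(ins_chunks) + 1L]] <- FALSE
      ptr <- p + nchar(v$ref)
    }
  }
  if (ptr <= L) {
    seq_chunks <- c(seq_chunks, substr(region_seq, ptr, L))
    map_chunks[[length(map_chunks) + 1L]] <- ptr:L
    ins_chunks[[length(ins_chunks) + 1L]] <- rep(FALSE, L - ptr + 1L)
  }
  coord_map <- as.integer(region$start + unlist(map_chunks))
  structure(list(sequence = paste(seq_chunks, collapse = ""),
                 coord_map = coord_map,
                 inserted = unlist(ins_chunks),
                 chrom = region$chrom),
            class = "mutated_haplotype")
}

#' Write a truth VCF
#'
#' Emits a minimal valid VCF 4.2 with a single sample carrying the simulated
#' genotype (GT 0/1 for het, 1/1 for hom_alt). QUAL is fixed at 100 so the
#' truth passes any downstream quality filter.
#'
#' @param variants truth-variant data.frame, sorted by (chrom, pos).
#' @param path output file.
#' @param contigs optional named integer vector of chromosome lengths for
#'   ##contig headers.
#' @param sample sample name.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(variants, path, contigs = NULL,
                            sample = "TRUTH") {
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants))) && nrow(variants) > 0L)
    stop("variants must be sorted by (chrom, pos)", call. = FALSE)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=divbench",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##INFO=<ID=VT,Number=1,Type=String,Description=\"Variant type\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample), collapse = "\t"))
  gt <- ifelse(variants$genotype == "het", "0/1", "1/1")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tVT=%s\tGT\t%s",
            variants$chrom, variants$pos, variants$ref, variants$alt,
            variants$vtype, gt)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate mutations over a set of target regions
#'
#' The top-level mutagenesis entry point: loads the reference and regions,
#' draws exactly `plan_variant_count(total_bases, level)` events (the global
#' budget is apportioned to regions by largest remainder so the requested
#' divergence is met exactly), and realizes both haplotypes of every region.
#'
#' @param reference FASTA path or a named [Biostrings::DNAStringSet].
#' @param regions BED path or a chrom/start/end data.frame; merged first.
#' @param level divergence level (events per base), or a
#'   [divergence_spec()] via `spec`.
#' @param spec optional [divergence_spec()]; overrides `level` and friends.
#' @param snp_fraction,indel_max_len,het_fraction,seed passed to
#'   [divergence_spec()] when `spec` is NULL.
#' @return object of class "mutation_sim": list with `variants` (truth
#'   data.frame), `regions`, `haplotypes` (per region, `hap1`/`hap2`
#'   mutated_haplotype objects), `spec`, `chrom_lengths`, and `per_region`
#'   achieved-divergence table.
#' @export
simulate_mutations <- function(reference, regions, level = 0.01, spec = NULL,
                               snp_fraction = 0.9, indel_max_len = 10L,
                               het_fraction = 0.5, seed = 1L) {
  if (is.null(spec))
    spec <- divergence_spec(level, snp_fraction, indel_max_len,
                            het_fraction, seed)
  ref <- load_reference(reference)
  if (is.character(regions) && length(regions) == 1L)
    regions <- read_bed(regions)
  regions <- merge_intervals(regions)
  missing_chrom <- setdiff(regions$chrom, names(ref))
  if (length(missing_chrom))
    stop("regions reference chromosomes absent from FASTA: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)

  set.seed(spec$seed)
  lens <- regions$end - regions$start
  total <- sum(lens)
  budget <- plan_variant_count(total, spec$level)
  counts <- apportion_counts(lens, budget)

  all_var <- vector("list", nrow(regions))
  haps <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    rseq <- substr(ref[[rg$chrom]], rg$start + 1L, rg$end)
    v <- permute_variants(rseq, rg, counts[i], spec)
    all_var[[i]] <- v
    haps[[i]] <- list(hap1 = apply_variants(rseq, v, rg, 1L),
                      hap2 = apply_variants(rseq, v, rg, 2L),
                      region = rg, ref_seq = rseq)
  }
  variants <- do.call(rbind, c(all_var, list(empty_variants())))
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  per_region <- data.frame(regions,
                           length = lens, events = counts,
                           divergence = counts / lens,
                           stringsAsFactors = FALSE)
  structure(list(variants = variants, regions = regions, haplotypes = haps,
                 spec = spec, chrom_lengths = vapply(ref, nchar, 1L),
                 per_region = per_region),
            class = "mutation_sim")
}

## largest-remainder apportionment of `budget` events over region lengths
apportion_counts <- function(lens, budget) {
  if (budget == 0L) return(integer(length(lens)))
  q <- lens / sum(lens) * budget
  base <- floor(q)
  rem <- budget - sum(base)
  if (rem > 0L) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference))) {
    ss <- Biostrings::readDNAStringSet(reference)
    names(ss) <- sub("\\s.*$", "", names(ss))   # drop FASTA descriptions
    reference <- ss
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference))) return(reference)
  stop("reference must be a FASTA path or named DNAStringSet", call. = FALSE)
}

#' @export
print.mutation_sim <- function(x, ...) {
  cat("Mutation simulation\n")
  cat(sprintf("  regions: %d (%s bases)\n", nrow(x$regions),
              format(sum(x$per_region$length), big.mark = ",")))
  cat(sprintf("  divergence level: %g  events: %d (%d SNP, %d INS, %d DEL)\n",
              x$spec$level, nrow(x$variants),
              sum(x$variants$vtype == "SNP"),
              sum(x$variants$vtype == "INS"),
              sum(x$variants$vtype == "DEL")))
  invisible(x)
}

#' Write the per-region achieved-divergence sidecar
#'
#' @param sim a "mutation_sim" object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_divergence_table <- function(sim, path) {
  utils::write.table(sim$per_region, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
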