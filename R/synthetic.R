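## Synthetic reference fixtures: random chromosomes plus non-overlapping
## target regions, so the whole pipeline (and its tests) runs without any
## external dataset.

#' Build a synthetic reference genome with target regions
#'
#' Draws uniform-random chromosome sequence and lays out non-overlapping
#' target regions separated by padding, mimicking a capture design of
#' exonic regions on a divergent chromosome.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_regions regions per chromosome.
#' @param region_length length of each region in bases.
#' @param pad minimum gap between regions and from the chromosome ends.
#' @param seed RNG seed.
#' @return list: `reference` (named character vector of sequences),
#'   `regions` (chrom/start/end data.frame, 0-based half-open).
#' @export
synthetic_reference <- function(chrom_lengths = c(chr6 = 60000L),
                                n_regions = 5L, region_length = 2000L,
                                pad = 500L, seed = 1L) {
  set.seed(seed)
  need <- n_regions * region_length + (n_regions + 1L) * pad
  if (any(chrom_lengths < need))
    stop("chromosomes too short for the requested region layout",
         call. = FALSE)
  reference <- vapply(chrom_lengths, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), "")
  regions <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    slot <- (L - pad) %/% n_regions
    start <- pad + (seq_len(n_regions) - 1L) * slot
    data.frame(chrom = ch, start = as.integer(start),
               end = as.integer(start + region_length),
               stringsAsFactors = FALSE)
  }))
  list(reference = reference, regions = merge_intervals(regions))
}

#' Write a synthetic reference to FASTA + BED files
#'
#' @param dir output directory (created if needed).
#' @param ... passed to [synthetic_reference()].
#' @return list with `fasta`, `bed` paths and the generated `reference` and
#'   `regions`.
#' @export
write_synthetic_reference <- function(dir, ...) {
  ref <- synthetic_reference(...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "reference.fa")
  bed <- file.path(dir, "regions.bed")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$reference), fasta)
  write_bed(ref$regions, bed)
  c(ref, list(fasta = fasta, bed = bed))
}
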