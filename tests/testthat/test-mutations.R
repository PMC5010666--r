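test_that("plan_variant_count applies the events-per-base definition", {
  expect_equal(plan_variant_count(10000, 0.01), 100L)
  expect_equal(plan_variant_count(123456, 0), 0L)
  expect_equal(plan_variant_count(2000, 0.0005), 1L)
  expect_equal(plan_variant_count(1000, 0.15), 150L)
  expect_equal(plan_variant_count(1000, 0.0005), 1L)  # 0.5 rounds away from 0
  expect_error(plan_variant_count(1000, -0.1), "level")
})

test_that("permute_variants places the requested events with disjoint footprints", {
  rg <- one_region(len = 1000L)
  set.seed(1)
  seq1k <- random_seq(1000L)
  expect_equal(nrow(permute_variants(seq1k, rg, 0L, divergence_spec(0.15))),
               0L)
  set.seed(7)
  v <- permute_variants(seq1k, rg, 150L, divergence_spec(0.15))
  expect_equal(nrow(v), 150L)
  # brute-force footprint scan: no base covered twice, all inside the region
  covered <- integer(0)
  for (i in seq_len(nrow(v))) {
    fp <- seq(v$pos[i], v$pos[i] + nchar(v$ref[i]) - 1L)
    expect_true(all(fp >= rg$start + 1L & fp <= rg$end))
    covered <- c(covered, fp)
  }
  expect_equal(anyDuplicated(covered), 0L)
  # allele shape invariants
  expect_true(all(v$ref != v$alt))
  snp <- v$vtype == "SNP"
  expect_true(all(nchar(v$ref[snp]) == 1L & nchar(v$alt[snp]) == 1L))
  expect_true(all(nchar(v$ref[v$vtype == "DEL"]) > 1L &
                  nchar(v$alt[v$vtype == "DEL"]) == 1L))
  expect_true(all(nchar(v$alt[v$vtype == "INS"]) > 1L &
                  nchar(v$ref[v$vtype == "INS"]) == 1L))
})

test_that("permutation is deterministic under a fixed seed", {
  rg <- one_region(len = 100L)
  set.seed(3); s <- random_seq(100L)
  spec <- divergence_spec(0.05, snp_fraction = 1.0)
  set.seed(99); a <- permute_variants(s, rg, 5L, spec)
  set.seed(99); b <- permute_variants(s, rg, 5L, spec)
  expect_identical(a, b)
  expect_true(all(a$vtype == "SNP"))
})

test_that("SNP fraction converges to the specification over many events", {
  ref <- synthetic_reference(c(chr6 = 80000L), n_regions = 1L,
                             region_length = 70000L, seed = 5)
  sim <- simulate_mutations(ref$reference, ref$regions, level = 0.15,
                            snp_fraction = 0.9, seed = 12)
  n <- nrow(sim$variants)
  expect_gte(n, 10000L)
  p_hat <- mean(sim$variants$vtype == "SNP")
  tol <- 4 * sqrt(0.9 * 0.1 / n)   # ~4 sigma binomial band
  expect_lt(abs(p_hat - 0.9), tol)
  # het fraction sanity under the same budget
  expect_lt(abs(mean(sim$variants$genotype == "het") - 0.5),
            4 * sqrt(0.25 / n))
})

test_that("apply_variants edits sequence and coordinate map consistently", {
  rg <- one_region(len = 50L)
  set.seed(2); s <- random_seq(50L)
  # no variants: identity
  h <- apply_variants(s, tv("chr6", 1, "A", "G", "SNP")[0, ], rg, 1L)
  expect_equal(h$sequence, s)
  expect_equal(h$coord_map, 1:50)
  # one 3-bp deletion: anchor at pos 10, ref spans 10..13
  del <- tv("chr6", 10, substr(s, 10, 13), substr(s, 10, 10), "DEL",
            genotype = "hom_alt")
  hd <- apply_variants(s, del, rg, 1L)
  expect_equal(nchar(hd$sequence), 47L)
  expect_equal(setdiff(1:50, hd$coord_map), 11:13)
  # independent edit-script replay: every base must match the reference
  # outside the deletion
  expect_equal(hd$sequence, paste0(substr(s, 1, 10), substr(s, 14, 50)))
  # SNPs only: same length, Hamming distance == number of SNPs
  snps <- tv(rep("chr6", 3), c(5, 20, 35),
             sapply(c(5, 20, 35), function(p) substr(s, p, p)),
             c("N1", "N2", "N3"), rep("SNP", 3), genotype = "hom_alt")
  for (i in 1:3) {
    base <- snps$ref[i]
    snps$alt[i] <- setdiff(c("A", "C", "G", "T"), base)[1]
  }
  hs <- apply_variants(s, snps, rg, 1L)
  expect_equal(nchar(hs$sequence), 50L)
  ham <- sum(strsplit(hs$sequence, "")[[1]] != strsplit(s, "")[[1]])
  expect_equal(ham, 3L)
  # haplotype 2 keeps the reference allele at het sites
  snps$genotype <- "het"
  h2 <- apply_variants(s, snps, rg, 2L)
  expect_equal(h2$sequence, s)
  # overlapping footprints rejected
  bad <- rbind(del, tv("chr6", 11, substr(s, 11, 11), "A", "SNP"))
  bad <- bad[order(bad$pos), ]
  expect_error(apply_variants(s, bad, rg, 1L), "overlap")
})

test_that("coord_map points every unedited haplotype base at its reference base", {
  w <- make_world(level = 0.05, coverage = 0)
  for (hset in w$sim$haplotypes) {
    hap <- hset$hap1
    rs <- strsplit(hset$ref_seq, "")[[1]]
    hb <- strsplit(hap$sequence, "")[[1]]
    rel <- hap$coord_map - hset$region$start
    # positions outside any variant footprint
    fp <- unlist(mapply(function(p, r) seq(p, p + nchar(r) - 1L),
                        w$sim$variants$pos, w$sim$variants$ref,
                        SIMPLIFY = FALSE))
    outside <- !(hap$coord_map %in% fp) & !hap$inserted
    expect_true(all(hb[outside] == rs[rel[outside]]))
    expect_false(is.unsorted(hap$coord_map))
  }
})

test_that("truth VCF writing round-trips through a standard VCF reader", {
  w <- make_world(level = 0.02, coverage = 0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_truth_vcf(w$sim$variants, path, contigs = w$sim$chrom_lengths)
  back <- load_and_filter_calls(path, min_qual = 0)
  expect_equal(back[, c("chrom", "pos", "ref", "alt", "vtype", "genotype")],
               w$sim$variants[, c("chrom", "pos", "ref", "alt", "vtype",
                                  "genotype")],
               ignore_attr = TRUE)
  # genotype encoding
  lines <- readLines(path)
  het_line <- grep("GT\t0/1", lines, value = TRUE)[1]
  expect_false(is.na(het_line))
  # a deletion record spans pos..pos+|ref|-1
  dels <- w$sim$variants[w$sim$variants$vtype == "DEL", ]
  if (nrow(dels)) {
    v <- VariantAnnotation::readVcf(path, genome = "x")
    rr <- SummarizedExperiment::rowRanges(v)
    i <- which(GenomicRanges::start(rr) == dels$pos[1] &
               as.character(GenomicRanges::seqnames(rr)) == dels$chrom[1])
    expect_equal(GenomicRanges::end(rr)[i[1]],
                 dels$pos[1] + nchar(dels$ref[1]) - 1L)
  }
  expect_error(write_truth_vcf(w$sim$variants[rev(seq_len(
    nrow(w$sim$variants))), ], path), "sorted")
})

test_that("control divergence yields no variants and reference haplotypes", {
  w <- make_world(level = 0, coverage = 0)
  expect_equal(nrow(w$sim$variants), 0L)
  for (hset in w$sim$haplotypes) {
    expect_equal(hset$hap1$sequence, hset$ref_seq)
    expect_equal(hset$hap2$sequence, hset$ref_seq)
    expect_equal(hset$hap1$coord_map,
                 (hset$region$start + 1L):hset$region$end)
  }
  path <- withr::local_tempfile(fileext = ".vcf")
  write_truth_vcf(w$sim$variants, path)
  expect_equal(nrow(load_and_filter_calls(path, min_qual = 0)), 0L)
})

test_that("the global event budget is met exactly across multiple regions", {
  ref <- synthetic_reference(c(chr6 = 30000L), n_regions = 4L,
                             region_length = 1700L, seed = 9)
  total <- sum(ref$regions$end - ref$regions$start)
  for (lv in c(0.0005, 0.001, 0.01, 0.1)) {
    sim <- simulate_mutations(ref$reference, ref$regions, level = lv,
                              seed = 21)
    expect_equal(nrow(sim$variants), plan_variant_count(total, lv))
  }
})
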