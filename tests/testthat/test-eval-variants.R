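test_that("quality filtering keeps Q >= 20 and splits multi-allelic records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(path, c(
    vcf_row("chr6", 100, "A", "G", qual = 19.9),
    vcf_row("chr6", 200, "A", "T", qual = 20.0),
    vcf_row("chr6", 300, "C", "G,T", qual = 45, gt = "1/2"),
    vcf_row("chr6", 400, "G", "A", qual = 99, gt = "1/1")))
  calls <- load_and_filter_calls(path, min_qual = 20)
  expect_equal(nrow(calls), 4L)               # 19.9 dropped, multiallelic split
  expect_false(any(calls$pos == 100))
  expect_equal(sort(calls$alt[calls$pos == 300]), c("G", "T"))
  expect_equal(calls$genotype[calls$pos == 300], c("het", "het"))
  expect_equal(calls$genotype[calls$pos == 400], "hom_alt")
  # empty body
  empty <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(empty, character(0))
  expect_equal(nrow(load_and_filter_calls(empty)), 0L)
})

test_that("INDEL alleles are normalized before matching", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(path, c(
    vcf_row("chr6", 100, "ACGT", "AT", qual = 50),    # del of CG, trailing T shared
    vcf_row("chr6", 200, "TTC", "TTCAC", qual = 50))) # ins with extra context
  calls <- load_and_filter_calls(path)
  d <- calls[calls$vtype == "DEL", ]
  expect_equal(d$ref, "ACG"); expect_equal(d$alt, "A")
  expect_equal(d$pos, 100L)
  i <- calls[calls$vtype == "INS", ]
  expect_equal(i$ref, "T"); expect_equal(i$alt, "TCA")
  expect_equal(i$pos, 201L)
})

test_that("SNP matching is allele-exact with hand-countable confusion", {
  truth <- tv(rep("chr6", 10), seq(100, 1000, by = 100),
              rep("A", 10), rep("G", 10), rep("SNP", 10))
  # 8 of the truth + 2 calls absent from truth
  calls <- rbind(truth[1:8, ], tv(rep("chr6", 2), c(5000, 6000),
                                  c("C", "C"), c("T", "T"), rep("SNP", 2)))
  res <- match_snps(calls, truth)
  expect_equal(res$tp, 8L); expect_equal(res$fp, 2L); expect_equal(res$fn, 2L)
  expect_equal(res$sensitivity, 0.8)
  expect_equal(res$precision, 0.8)
  # identity
  self <- match_snps(truth, truth)
  expect_equal(self$tp, 10L); expect_equal(self$fp, 0L)
  expect_equal(self$fn, 0L)
  expect_equal(self$sensitivity, 1.0); expect_equal(self$precision, 1.0)
  expect_equal(self$genotype_concordance, 1.0)
  # same position, different alt: one FP and one FN
  other <- truth[1, ]; other$alt <- "T"
  res2 <- match_snps(other, truth[1, ])
  expect_equal(res2$tp, 0L); expect_equal(res2$fp, 1L); expect_equal(res2$fn, 1L)
  # position-only mode recovers it
  expect_equal(match_snps(other, truth[1, ], by_position = TRUE)$tp, 1L)
})

test_that("INDEL overlap matching follows the interval rule", {
  # identical deletion
  t1 <- tv("chr6", 99, "TACGTA", "T", "DEL")     # deleted span 100..104
  expect_equal(match_indels(t1, t1)$tp, 1L)
  # truth DEL spanning 100-104, call DEL spanning 103-107: overlap 2 >= 1
  call <- tv("chr6", 102, "GTACG", "G", "DEL")   # deleted span 103..107
  res <- match_indels(call, t1)
  expect_equal(res$tp, 1L); expect_equal(res$fp, 0L); expect_equal(res$fn, 0L)
  # far-away insertions: FP + FN
  resi <- match_indels(tv("chr6", 200, "A", "AGG", "INS"),
                       tv("chr6", 250, "C", "CTT", "INS"))
  expect_equal(resi$tp, 0L); expect_equal(resi$fp, 1L); expect_equal(resi$fn, 1L)
  # raising min_overlap demotes the partial-overlap match
  expect_equal(match_indels(call, t1, min_overlap = 3L)$tp, 0L)
})

test_that("overlap matcher agrees with the brute-force all-pairs oracle", {
  set.seed(77)
  for (rep in 1:60) {
    nt <- sample(1:30, 1); nc <- sample(1:30, 1)
    truth <- tv(rep("chr6", nt), sample(1:2000, nt),
                strrep("A", sample(2:10, nt, replace = TRUE)),
                rep("A", nt), rep("DEL", nt))
    calls <- tv(rep("chr6", nc), sample(1:2000, nc),
                strrep("A", sample(2:10, nc, replace = TRUE)),
                rep("A", nc), rep("DEL", nc))
    ins_t <- sample(nt, max(1, nt %/% 3))
    truth$vtype[ins_t] <- "INS"; truth$ref[ins_t] <- "A"
    truth$alt[ins_t] <- "AGT"
    got <- match_indels(calls, truth)
    iv <- function(d) {
      is_del <- d$vtype == "DEL"
      data.frame(chrom = d$chrom,
                 start = ifelse(is_del, d$pos + 1L, d$pos),
                 end = ifelse(is_del, d$pos + nchar(d$ref) - 1L, d$pos))
    }
    want <- oracle_indel_match(iv(calls), iv(truth))
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
  }
})

test_that("genotype concordance is the matched-pair agreement fraction", {
  pairs <- data.frame(call_genotype = c("het", "het", "hom_alt", "het"),
                      truth_genotype = c("het", "het", "hom_alt", "hom_alt"))
  expect_equal(genotype_concordance(pairs), 0.75)
  expect_true(is.na(genotype_concordance(pairs[0, ])))
  disc <- data.frame(call_genotype = "het", truth_genotype = "hom_alt")
  expect_equal(genotype_concordance(disc), 0)
})

test_that("counts are conserved and filtering is monotone", {
  w <- make_world(level = 0.03, coverage = 0)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_truth_vcf(w$sim$variants, path, contigs = w$sim$chrom_lengths)
  calls <- load_and_filter_calls(path, min_qual = 0)
  res <- evaluate_calls(calls, w$sim$variants)
  n_snp_calls <- sum(calls$vtype == "SNP")
  n_snp_truth <- sum(w$sim$variants$vtype == "SNP")
  expect_equal(res$snp$tp + res$snp$fp, n_snp_calls)
  expect_equal(res$snp$tp + res$snp$fn, n_snp_truth)
  n_ind_calls <- sum(calls$vtype %in% c("INS", "DEL"))
  expect_equal(res$indel$tp + res$indel$fp, n_ind_calls)
  # self-comparison identity
  expect_equal(res$snp$sensitivity, 1.0)
  expect_equal(res$indel$sensitivity, 1.0)
  expect_equal(res$snp$genotype_concordance, 1.0)
  # raising min_qual can only shrink tp and fp (truth written at Q100)
  filtered <- load_and_filter_calls(path, min_qual = 101)
  res2 <- match_snps(filtered, w$sim$variants)
  expect_lte(res2$tp, res$snp$tp)
  expect_lte(res2$fp, res$snp$fp)
})

test_that("known/novel classification is alt-aware and exhaustive", {
  catalog <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(catalog, c(vcf_row("chr6", 100, "A", "G"),
                             vcf_row("chr6", 200, "C", "T")))
  calls <- tv(rep("chr6", 3), c(100, 200, 300), c("A", "C", "G"),
              c("G", "A", "T"), rep("SNP", 3))
  out <- classify_known(calls, catalog)
  expect_equal(as.character(out$known), c("known", "novel", "novel"))
  # empty catalog: everything novel
  empty <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(empty, character(0))
  out2 <- classify_known(calls, empty)
  expect_true(all(out2$known == "novel"))
})

test_that("HLA stratification splits evaluation results", {
  truth <- rbind(tv("chr6", 29600000, "A", "G", "SNP"),
                 tv("chr6", 1000, "C", "T", "SNP"))
  res <- evaluate_calls(truth, truth, stratify = hla_region())
  expect_equal(res$strata$inside$snp$tp, 1L)
  expect_equal(res$strata$outside$snp$tp, 1L)
})
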