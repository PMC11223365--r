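test_that("read_abo_sites returns one record per sample per locus", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, list(
    c261delG = c("0/0:30,0:30:99", "0/1:15,14:29:80", "1/1:0,25:25:90"),
    c802GA   = c("0/0:40,0:40:99", "0/0:33,1:34:95", "0/1:10,12:22:70")),
    sample_ids = c("A", "B", "C"))
  g <- read_abo_sites(vcf)
  expect_equal(nrow(g), 6L)
  expect_setequal(g$locus_id, c("c261delG", "c802GA"))
  expect_equal(g$dosage[g$sample_id == "B" & g$locus_id == "c261delG"], 1L)
  expect_equal(g$ad_alt[g$sample_id == "C" & g$locus_id == "c802GA"], 12L)
})

test_that("a VCF missing one configured site is a hard error naming the locus", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_fixture_vcf(vcf, list(c261delG = c("0/0:30,0:30:99")), sample_ids = "A")
  expect_error(read_abo_sites(vcf), "c802GA")
})

test_that("missing genotypes and unconfigured ALT alleles become missing calls", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=9>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT","A","B","C"),
          collapse = "\t"),
    # multiallelic record: configured ALT T is index 1, G is an extra allele
    paste(c("9","133255801",".","C","T,G",".","PASS",".","GT:AD:DP:GQ",
            "0/1:10,12,0:22:70", "0/2:10,0,9:19:50", "./.:.:.:."), collapse = "\t"),
    paste(c("9","133257521",".","TC","T",".","PASS",".","GT:AD:DP:GQ",
            "0/0:30,0:30:99", "0/0:28,0:28:99", "0/0:25,0:25:99"), collapse = "\t")),
    vcf)
  g <- suppressWarnings(read_abo_sites(vcf))
  g802 <- g[g$locus_id == "c802GA", ]
  expect_equal(g802$dosage[g802$sample_id == "A"], 1L)
  expect_true(is.na(g802$gt[g802$sample_id == "B"]))   # carries ALT G
  expect_true(is.na(g802$gt[g802$sample_id == "C"]))   # ./.
  qc <- apply_qc(g)
  expect_false(any(qc$qc_pass[qc$locus_id == "c802GA" &
                              qc$sample_id %in% c("B", "C")]))
})

test_that("QC thresholds behave at the published boundaries", {
  g <- data.frame(sample_id = c("a", "b", "c", "d"),
                  locus_id = "c802GA",
                  gt = c("0/0", "0/1", "0/0", "0/1"),
                  dosage = c(0L, 1L, 0L, 1L),
                  dp = c(9L, 30L, 8L, 30L),
                  gq = c(20L, 60L, 99L, 60L),
                  ad_ref = c(9L, 2L, 8L, 3L),
                  ad_alt = c(0L, 28L, 0L, 27L),
                  qc_pass = NA)
  qc <- apply_qc(g)
  expect_true(qc$qc_pass[1])    # hom at DP 9 / GQ 20 is exactly valid
  expect_false(qc$qc_pass[2])   # het with one allele at 2 reads fails AD >= 3
  expect_false(qc$qc_pass[3])   # DP 8 below threshold
  expect_true(qc$qc_pass[4])    # het with both alleles >= 3 reads passes
})

test_that("missing FORMAT subfields fail QC rather than defaulting", {
  g <- data.frame(sample_id = "a", locus_id = "c802GA", gt = "0/1",
                  dosage = 1L, dp = 40L, gq = NA_integer_,
                  ad_ref = 20L, ad_alt = 20L, qc_pass = NA)
  expect_false(apply_qc(g)$qc_pass)
})

test_that("QC is monotone in its thresholds and idempotent", {
  set.seed(42)
  n <- 300
  g <- data.frame(sample_id = as.character(seq_len(n)), locus_id = "c261delG",
                  gt = sample(c("0/0", "0/1", "1/1", NA), n, TRUE),
                  dp = rpois(n, 12), gq = sample(0:99, n, TRUE),
                  qc_pass = NA)
  g$dosage <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[g$gt]
  g$ad_alt <- rbinom(n, g$dp, ifelse(is.na(g$dosage), 0, g$dosage) / 2)
  g$ad_ref <- g$dp - g$ad_alt
  base <- apply_qc(g, qc_thresholds(9, 20, 3))
  for (t in list(qc_thresholds(12, 20, 3), qc_thresholds(9, 40, 3),
                 qc_thresholds(9, 20, 6), qc_thresholds(15, 50, 8))) {
    stricter <- apply_qc(g, t)
    expect_false(any(stricter$qc_pass & !base$qc_pass))
  }
  expect_identical(apply_qc(base), base)
})

test_that("simulated VCFs round-trip the generator's truth at high depth", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  cfg <- sim_config(n_samples = 100, mean_depth = 500, seed = 11)
  sim <- gen_genotypes(cfg, vcf)
  pairs <- genotypes_wide(apply_qc(read_abo_sites(vcf)))
  expect_equal(pairs$g261, sim$truth$g261)
  expect_equal(pairs$g802, sim$truth$g802)
})

test_that("QC failures become rare as depth grows", {
  fail_frac <- function(depth, seed) {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    cfg <- sim_config(n_samples = 1000, mean_depth = depth, seed = seed)
    gen_genotypes(cfg, vcf)
    qc <- apply_qc(read_abo_sites(vcf))
    mean(!qc$qc_pass)
  }
  f60 <- fail_frac(60, 5)
  f6 <- fail_frac(6, 5)
  expect_lt(f60, 0.01)
  expect_gt(f6, f60)
})
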