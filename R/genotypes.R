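#' Read the two ABO typing sites from a VCF
#'
#' Extracts per-sample GT, DP, GQ and AD at the two configured loci. Records
#' are located by chromosome, position, REF and ALT; in multiallelic records
#' only the configured REF/ALT pair is interpreted and genotypes carrying any
#' other ALT are set to missing. Missing FORMAT subfields (e.g. `GQ=.`) are
#' kept as `NA` and later fail QC rather than being defaulted.
#'
#' @param vcf_path Path to a VCF (v4.x, plain or bgzipped) with FORMAT fields
#'   GT, DP, GQ and AD.
#' @param loci A list of two [locus_spec()] objects covering `c261delG` and
#'   `c802GA`, e.g. [abo_default_loci()].
#' @return A data.frame with one row per sample per locus: `sample_id`,
#'   `locus_id`, `gt` (normalised to `"0/0"`, `"0/1"`, `"1/1"` or `NA`),
#'   `dosage` (ALT allele count 0/1/2 or `NA`), `dp`, `gq`, `ad_ref`,
#'   `ad_alt`, `qc_pass` (`NA` until [apply_qc()] is run).
#' @seealso [apply_qc()], [gen_genotypes()]
#' @export
read_abo_sites <- function(vcf_path, loci = abo_default_loci()) {
  loci <- check_locus_pair(loci)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path, call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  out <- lapply(loci, function(spec) {
    hit <- which(fix[, "CHROM"] == spec$chrom &
                 as.integer(fix[, "POS"]) == spec$pos &
                 fix[, "REF"] == spec$ref_allele)
    # the configured ALT must be among the record's ALT alleles
    alt_idx <- NA_integer_
    for (h in hit) {
      alts <- strsplit(fix[h, "ALT"], ",", fixed = TRUE)[[1]]
      i <- match(spec$alt_allele, alts)
      if (!is.na(i)) { hit <- h; alt_idx <- i; break }
    }
    if (is.na(alt_idx))
      stop("locus ", spec$locus_id, " not found in ", vcf_path, call. = FALSE)
    extract_locus(vcf, hit, alt_idx, spec$locus_id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Pull one record's FORMAT fields into the flat per-sample layout.
extract_locus <- function(vcf, row, alt_idx, locus_id) {
  gt_m <- vcfR::extract.gt(vcf, element = "GT")[row, , drop = TRUE]
  dp_m <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[row, ]))
  gq_m <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "GQ")[row, ]))
  ad_m <- vcfR::extract.gt(vcf, element = "AD")[row, , drop = TRUE]

  samples <- colnames(vcf@gt)[-1]
  ad_split <- strsplit(ifelse(is.na(ad_m), ".", ad_m), ",", fixed = TRUE)
  ad_ref <- suppressWarnings(vapply(ad_split, function(x) as.integer(x[1]), integer(1)))
  ad_alt <- suppressWarnings(vapply(ad_split, function(x)
    if (length(x) > alt_idx) as.integer(x[alt_idx + 1L]) else NA_integer_, integer(1)))

  dosage <- rep(NA_integer_, length(samples))
  gt <- rep(NA_character_, length(samples))
  alleles <- strsplit(ifelse(is.na(gt_m), ".", gt_m), "[/|]")
  for (i in seq_along(alleles)) {
    a <- suppressWarnings(as.integer(alleles[[i]]))
    if (length(a) != 2L || anyNA(a)) next
    if (!all(a %in% c(0L, alt_idx))) next   # some other ALT allele: missing
    dosage[i] <- sum(a == alt_idx)
    gt[i] <- c("0/0", "0/1", "1/1")[dosage[i] + 1L]
  }
  n_bad <- sum(!is.na(gt_m) & gt_m != "." & is.na(gt))
  if (n_bad > 0)
    warning(sprintf("%s: %d genotype(s) uninterpretable or carrying an unconfigured ALT; set to missing",
                    locus_id, n_bad), call. = FALSE)

  data.frame(sample_id = samples, locus_id = locus_id, gt = gt,
             dosage = dosage, dp = dp_m, gq = gq_m,
             ad_ref = ad_ref, ad_alt = ad_alt, qc_pass = NA,
             stringsAsFactors = FALSE)
}

#' Apply depth/quality QC to genotype calls
#'
#' A call passes when DP >= `min_depth`, GQ >= `min_gq`, and — if the call is
#' heterozygous — both allele depths are >= `min_het_allele_depth`. Missing
#' genotypes or missing numeric fields fail. QC never alters genotype
#' content; it only sets `qc_pass`, so the operation is idempotent and
#' monotone in the thresholds.
#'
#' @param genotypes Data.frame from [read_abo_sites()] (or any frame with
#'   columns `gt`, `dosage`, `dp`, `gq`, `ad_ref`, `ad_alt`).
#' @param thresholds A [qc_thresholds()] object.
#' @return The input with `qc_pass` set to `TRUE`/`FALSE` for every row.
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  het <- !is.na(genotypes$dosage) & genotypes$dosage == 1L
  ok_num <- function(x, min) !is.na(x) & x >= min
  pass <- !is.na(genotypes$gt) &
    ok_num(genotypes$dp, thresholds$min_depth) &
    ok_num(genotypes$gq, thresholds$min_gq)
  pass[het] <- pass[het] &
    ok_num(genotypes$ad_ref[het], thresholds$min_het_allele_depth) &
    ok_num(genotypes$ad_alt[het], thresholds$min_het_allele_depth)
  genotypes$qc_pass <- pass
  genotypes
}

#' Reshape long per-locus genotypes to one row per sample
#'
#' Keeps the ALT dosage at each locus for samples passing QC at that locus;
#' a locus that failed QC (or was missing) becomes `NA`. Samples with `NA`
#' at either locus are excluded from haplotype-frequency estimation and get
#' a missing blood-type call downstream.
#'
#' @param genotypes QC'd data.frame from [apply_qc()].
#' @return Data.frame with columns `sample_id`, `g261`, `g802` (dosages or NA).
#' @export
genotypes_wide <- function(genotypes) {
  if (!all(c("qc_pass") %in% names(genotypes)) || anyNA(genotypes$qc_pass))
    stop("run apply_qc() before reshaping", call. = FALSE)
  d <- genotypes$dosage
  d[!genotypes$qc_pass] <- NA_integer_
  samples <- unique(genotypes$sample_id)
  pick <- function(locus) {
    m <- genotypes$locus_id == locus
    d[m][match(samples, genotypes$sample_id[m])]
  }
  data.frame(sample_id = samples, g261 = pick("c261delG"), g802 = pick("c802GA"),
             stringsAsFactors = FALSE)
}
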