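#' Classify a two-locus haplotype as an O or non-O allele
#'
#' The c.261 deletion frameshifts the transferase and marks the deletional O
#' allele regardless of the c.802 state (the frameshift dominates); c.802G>A
#' on an intact c.261 background marks the nondeletional O allele; a
#' haplotype carrying neither variant is a non-O (A/B) allele.
#'
#' @param hap Haplotype code(s): `"rr"`, `"ra"`, `"ar"`, `"aa"` at
#'   (c261, c802), `r` = REF, `a` = ALT. Vectorised.
#' @return Character vector over `{"O_deletional", "O_nondeletional",
#'   "non_O"}`.
#' @export
classify_haplotype <- function(hap) {
  stopifnot(all(hap %in% ABO_HAPLOTYPES))
  out <- rep("non_O", length(hap))
  out[hap %in% c("ar", "aa")] <- "O_deletional"
  out[hap == "ra"] <- "O_nondeletional"
  out
}

is_o_allele <- function(cls) cls %in% c("O_deletional", "O_nondeletional")

#' Call O vs non-O blood type from a diplotype posterior
#'
#' Blood type O requires two O alleles; a single non-O allele makes the type
#' non-O. Each configuration in the posterior is classified, the reported
#' type is that of the maximum-probability configuration, and the posterior
#' is the summed probability of all configurations sharing that type (1 for
#' unambiguous diplotypes).
#'
#' @param diplotype Data.frame of configurations from [phase_individual()].
#' @return List with `blood_type` (`"O"`/`"non_O"`), `allele_classes`
#'   (classes of the MAP configuration), `posterior`.
#' @export
call_blood_type <- function(diplotype) {
  stopifnot(nrow(diplotype) >= 1)
  c1 <- classify_haplotype(diplotype$hap1)
  c2 <- classify_haplotype(diplotype$hap2)
  type <- ifelse(is_o_allele(c1) & is_o_allele(c2), "O", "non_O")
  map <- which.max(diplotype$prob)
  list(blood_type = type[map],
       allele_classes = c(c1[map], c2[map]),
       posterior = sum(diplotype$prob[type == type[map]]))
}

#' Call blood types for a cohort
#'
#' Runs [phase_individual()] and [call_blood_type()] over every sample.
#' Samples missing (or QC-failed) at either locus get `blood_type =
#' "missing"`: the source cohort excluded samples that failed ABO locus
#' sequencing rather than defaulting them to non-O, and this pipeline does
#' the same.
#'
#' @param pairs Data.frame from [genotypes_wide()].
#' @param freqs Haplotype frequencies from [em_haplotype_frequencies()].
#' @param min_posterior Calls with posterior below this are set to
#'   `"missing"`. Default 0 (hard calls).
#' @return Data.frame: `sample_id`, `blood_type` (`O`/`non_O`/`missing`),
#'   `allele_class_1`, `allele_class_2`, `posterior`.
#' @export
call_blood_types <- function(pairs, freqs, min_posterior = 0) {
  res <- data.frame(sample_id = pairs$sample_id,
                    blood_type = "missing",
                    allele_class_1 = NA_character_,
                    allele_class_2 = NA_character_,
                    posterior = NA_real_,
                    stringsAsFactors = FALSE)
  ok <- which(!is.na(pairs$g261) & !is.na(pairs$g802))
  for (i in ok) {
    d <- phase_individual(pairs$g261[i], pairs$g802[i], freqs)
    call <- call_blood_type(d)
    if (call$posterior >= min_posterior) {
      res$blood_type[i] <- call$blood_type
      res$allele_class_1[i] <- call$allele_classes[1]
      res$allele_class_2[i] <- call$allele_classes[2]
      res$posterior[i] <- call$posterior
    }
  }
  res
}

#' End-to-end blood typing from a VCF
#'
#' Convenience wrapper: read the two sites, apply QC, estimate haplotype
#' frequencies by EM, and call every sample.
#'
#' @inheritParams read_abo_sites
#' @inheritParams apply_qc
#' @inheritParams call_blood_types
#' @return List with `calls` (see [call_blood_types()]), `freqs`, and
#'   `genotypes` (the QC'd long table).
#' @export
blood_type_pipeline <- function(vcf_path, loci = abo_default_loci(),
                                thresholds = qc_thresholds(),
                                min_posterior = 0) {
  g <- apply_qc(read_abo_sites(vcf_path, loci), thresholds)
  pairs <- genotypes_wide(g)
  freqs <- em_haplotype_frequencies(pairs)
  list(calls = call_blood_types(pairs, freqs, min_posterior),
       freqs = freqs, genotypes = g)
}
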