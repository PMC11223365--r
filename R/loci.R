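#' Describe one of the two ABO typing loci
#'
#' A locus specification pins down how a typing site appears in the input VCF:
#' chromosome, 1-based position, and the exact REF/ALT pair. Records are
#' matched by all four fields; indels are matched against the left-aligned
#' representation given here, never re-normalised.
#'
#' @param locus_id Either `"c261delG"` (rs8176719, the single-base deletion
#'   marking the deletional O allele) or `"c802GA"` (the missense variant
#'   marking the nondeletional O allele).
#' @param chrom Chromosome name as it appears in the VCF.
#' @param pos 1-based position.
#' @param ref_allele,alt_allele REF and ALT strings. For `c261delG` the ALT is
#'   a single-base deletion relative to REF.
#' @return A `locus_spec` list.
#' @examples
#' abo_default_loci()
#' @export
locus_spec <- function(locus_id, chrom, pos, ref_allele, alt_allele) {
  locus_id <- match.arg(locus_id, c("c261delG", "c802GA"))
  stopifnot(is.character(chrom), length(chrom) == 1L,
            is.numeric(pos), length(pos) == 1L, pos >= 1,
            is.character(ref_allele), nzchar(ref_allele),
            is.character(alt_allele), nzchar(alt_allele))
  structure(list(locus_id = locus_id, chrom = chrom, pos = as.integer(pos),
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "locus_spec")
}

#' Default ABO locus pair
#'
#' GRCh38 coordinates on chromosome 9q34.2 for the deletion c.261G>del
#' (rs8176719, REF "TC" / ALT "T" in left-aligned form) and the missense
#' c.802G>A (genomic C>T; ABO is on the minus strand). These are defaults for
#' the simulator and for convenience; real inputs should pass a pair matching
#' their own VCF representation.
#'
#' @return List of two `locus_spec` objects named `c261delG` and `c802GA`.
#' @export
abo_default_loci <- function() {
  list(
    c261delG = locus_spec("c261delG", chrom = "9", pos = 133257521L,
                          ref_allele = "TC", alt_allele = "T"),
    c802GA   = locus_spec("c802GA",   chrom = "9", pos = 133255801L,
                          ref_allele = "C", alt_allele = "T")
  )
}

check_locus_pair <- function(loci) {
  stopifnot(is.list(loci), length(loci) == 2L)
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  if (anyDuplicated(ids))
    stop("the two locus specs must have distinct locus_ids", call. = FALSE)
  if (!setequal(ids, c("c261delG", "c802GA")))
    stop("loci must cover exactly c261delG and c802GA", call. = FALSE)
  loci[match(c("c261delG", "c802GA"), ids)]
}

#' Genotype-level quality-control thresholds
#'
#' Defaults follow the study's calling criteria: a genotype is valid when read
#' depth DP >= 9 and genotype quality GQ >= 20; heterozygous calls additionally
#' require an allele depth AD >= 3, applied here to both observed alleles
#' (the conservative reading).
#'
#' @param min_depth Minimum DP (reads). Default 9.
#' @param min_gq Minimum GQ (phred). Default 20.
#' @param min_het_allele_depth Minimum per-allele AD for heterozygotes
#'   (reads). Default 3.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_depth = 9L, min_gq = 20L,
                          min_het_allele_depth = 3L) {
  stopifnot(min_depth >= 0, min_gq >= 0, min_het_allele_depth >= 0)
  structure(list(min_depth = as.integer(min_depth),
                 min_gq = as.integer(min_gq),
                 min_het_allele_depth = as.integer(min_het_allele_depth)),
            class = "qc_thresholds")
}
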