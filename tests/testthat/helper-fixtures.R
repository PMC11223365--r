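# Hand-built VCF fixtures and small simulation helpers shared across tests.

# Write a two-site (or fewer) VCF with explicit FORMAT cells.
# `cells` is a list: locus_id -> character vector "GT:AD:DP:GQ" per sample.
write_fixture_vcf <- function(path, cells, sample_ids,
                              loci = abo_default_loci()) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=9>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
  ord <- names(cells)[order(vapply(loci[names(cells)], `[[`, 0L, "pos"))]
  body <- vapply(ord, function(id) {
    l <- loci[[id]]
    paste(c(l$chrom, l$pos, ".", l$ref_allele, l$alt_allele, ".", "PASS", ".",
            "GT:AD:DP:GQ", cells[[id]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Genotype pairs drawn directly from haplotype frequencies (no read noise).
hwe_pairs <- function(n, freqs, seed) {
  set.seed(seed)
  a261 <- c(0, 0, 1, 1); a802 <- c(0, 1, 0, 1)
  h1 <- sample.int(4, n, replace = TRUE, prob = freqs)
  h2 <- sample.int(4, n, replace = TRUE, prob = freqs)
  data.frame(sample_id = sprintf("S%d", seq_len(n)),
             g261 = a261[h1] + a261[h2], g802 = a802[h1] + a802[h2],
             hap1 = abostroke:::ABO_HAPLOTYPES[h1],
             hap2 = abostroke:::ABO_HAPLOTYPES[h2],
             stringsAsFactors = FALSE)
}

# Brute-force Benjamini-Hochberg step-up, written independently of p.adjust.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# Two-sided rank-sum p by literal enumeration of all group assignments.
ranksum_enumerate <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (N + 1) / 2
  w <- sum(r[seq_len(n1)])
  sums <- combn(N, n1, function(idx) sum(r[idx]))
  mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
}
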