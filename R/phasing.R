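#' @useDynLib abostroke, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Haplotypes at (c261, c802), r = REF, a = ALT, in the fixed order used
# throughout: rr = non-O background, ra = nondeletional O, ar and aa carry
# the c.261 deletion (deletional O).
ABO_HAPLOTYPES <- c("rr", "ra", "ar", "aa")

# 3x3 genotype-class counts (ALT dosage at c261 in rows 0..2, c802 in cols)
genotype_counts <- function(pairs) {
  ok <- !is.na(pairs$g261) & !is.na(pairs$g802)
  table(factor(pairs$g261[ok], levels = 0:2),
        factor(pairs$g802[ok], levels = 0:2))
}

# P(genotype class | haplotype frequencies) for the 9 two-locus classes
genotype_class_probs <- function(f) {
  p <- matrix(0, 3, 3)
  p[1, 1] <- f[1]^2;        p[1, 2] <- 2 * f[1] * f[2]; p[1, 3] <- f[2]^2
  p[2, 1] <- 2 * f[1] * f[3]
  p[2, 2] <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
  p[2, 3] <- 2 * f[2] * f[4]
  p[3, 1] <- f[3]^2;        p[3, 2] <- 2 * f[3] * f[4]; p[3, 3] <- f[4]^2
  p
}

multinomial_loglik <- function(f, n) {
  p <- genotype_class_probs(f)
  use <- n > 0
  sum(n[use] * log(p[use]))
}

#' Two-locus haplotype frequencies by expectation-maximisation
#'
#' Maximum-likelihood estimation of the four haplotype frequencies at
#' (c.261G>del, c.802G>A) from unphased diploid genotypes under
#' Hardy-Weinberg equilibrium. With two biallelic sites the only phase
#' ambiguity is the double heterozygote, and this EM is the exact ML
#' solution; it replaces population-scale HMM phasing, whose machinery the
#' two-site problem does not need. The algorithm is deterministic: no
#' randomness, fixed iteration order, and the log-likelihood is
#' non-decreasing across iterations.
#'
#' @param pairs Data.frame from [genotypes_wide()]; rows with `NA` at either
#'   locus are excluded.
#' @param tol Convergence tolerance on the maximum absolute frequency change
#'   per iteration. Default 1e-8.
#' @param max_iter Iteration cap. Default 1000.
#' @param init Optional starting frequencies (length 4, order
#'   `rr, ra, ar, aa`). Default: product of observed allele frequencies
#'   (linkage-equilibrium start). Note the symmetric stationary point: a
#'   cohort of only double heterozygotes is unidentifiable and a uniform
#'   start stays uniform.
#' @return Named numeric of length 4 summing to 1, with attributes
#'   `loglik` (per-iteration trace), `iterations`, `converged`, and
#'   `n_samples` (samples used).
#' @seealso [phase_individual()], [grid_search_haplotype_frequencies()]
#' @export
em_haplotype_frequencies <- function(pairs, tol = 1e-8, max_iter = 1000L,
                                     init = NULL) {
  n <- genotype_counts(pairs)
  n_samp <- sum(n)
  if (n_samp == 0) stop("no samples with both loci QC-passed", call. = FALSE)

  if (is.null(init)) {
    p261 <- sum(n * matrix(0:2, 3, 3)) / (2 * n_samp)        # ALT freq c261
    p802 <- sum(n * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n_samp)
    f <- c((1 - p261) * (1 - p802), (1 - p261) * p802,
           p261 * (1 - p802), p261 * p802)
  } else {
    stopifnot(length(init) == 4, all(init > 0))
    f <- init / sum(init)
  }
  names(f) <- ABO_HAPLOTYPES

  # haplotype counts contributed by the 8 phase-unambiguous classes
  e_fixed <- c(2 * n[1, 1] + n[1, 2] + n[2, 1],
               n[1, 2] + 2 * n[1, 3] + n[2, 3],
               n[2, 1] + 2 * n[3, 1] + n[3, 2],
               n[3, 2] + 2 * n[3, 3] + n[2, 3])
  n_dh <- n[2, 2]

  ll <- multinomial_loglik(f, n)
  if (!is.finite(ll) && any(n > 0 & genotype_class_probs(f) == 0)) {
    # an LE start can put zero mass on an observed class; nudge off the face
    f <- 0.999 * f + 0.001 / 4
    ll <- multinomial_loglik(f, n)
  }
  if (is.na(ll)) stop("non-finite likelihood at initialisation", call. = FALSE)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cis <- f[1] * f[4]
    trans <- f[2] * f[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    e <- e_fixed + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- e / (2 * n_samp)
    ll <- multinomial_loglik(f_new, n)
    if (is.na(ll)) stop("non-finite likelihood during EM", call. = FALSE)
    trace <- c(trace, ll)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(f) <- ABO_HAPLOTYPES
  structure(f, loglik = trace, iterations = iter, converged = converged,
            n_samples = n_samp)
}

#' Brute-force grid maximisation of the haplotype likelihood
#'
#' Exhaustively evaluates the two-locus multinomial log-likelihood on a
#' regular grid over the frequency simplex (all quadruples of multiples of
#' `1/steps` summing to 1) and returns the maximising frequencies. Serves as
#' an independent reference for [em_haplotype_frequencies()]; the search is
#' compiled because the default grid has ~1.7e8 points.
#'
#' @param pairs Data.frame from [genotypes_wide()].
#' @param steps Grid resolution; step size is `1/steps`. Default 1000
#'   (step 0.001).
#' @return Named numeric of length 4 with attribute `loglik`.
#' @export
grid_search_haplotype_frequencies <- function(pairs, steps = 1000L) {
  n <- genotype_counts(pairs)
  if (sum(n) == 0) stop("no samples with both loci QC-passed", call. = FALSE)
  e_fixed <- c(2 * n[1, 1] + n[1, 2] + n[2, 1],
               n[1, 2] + 2 * n[1, 3] + n[2, 3],
               n[2, 1] + 2 * n[3, 1] + n[3, 2],
               n[3, 2] + 2 * n[3, 3] + n[2, 3])
  res <- grid_search_hapfreq_cpp(as.numeric(e_fixed), as.numeric(n[2, 2]),
                                 as.integer(steps))
  f <- res$f
  names(f) <- ABO_HAPLOTYPES
  structure(f, loglik = res$loglik)
}

#' Diplotype posterior for one individual
#'
#' Enumerates the haplotype-pair configurations consistent with a two-locus
#' genotype and weights them by population haplotype frequencies. Only the
#' double heterozygote is ambiguous: P(cis) is proportional to
#' `2 f(rr) f(aa)` and P(trans) to `2 f(ra) f(ar)`, normalised. Every other
#' genotype has a single configuration with probability 1.
#'
#' @param g261,g802 ALT dosages (0/1/2) at c.261G>del and c.802G>A; both
#'   must be non-missing (QC-passed).
#' @param freqs Haplotype frequencies from [em_haplotype_frequencies()].
#' @return Data.frame of configurations: `hap1`, `hap2` (codes `rr`, `ra`,
#'   `ar`, `aa`), `prob`; probabilities sum to 1, ordered most probable
#'   first.
#' @export
phase_individual <- function(g261, g802, freqs) {
  stopifnot(length(g261) == 1, length(g802) == 1)
  if (is.na(g261) || is.na(g802))
    stop("both loci must be QC-passed and non-missing", call. = FALSE)
  hap <- function(a1, a2) ABO_HAPLOTYPES[2 * a1 + a2 + 1L]
  if (g261 == 1 && g802 == 1) {
    cis <- 2 * freqs["rr"] * freqs["aa"]
    trans <- 2 * freqs["ra"] * freqs["ar"]
    tot <- cis + trans
    if (tot == 0) {
      warning("degenerate frequencies for a double heterozygote; using 0.5/0.5",
              call. = FALSE)
      p <- c(0.5, 0.5)
    } else p <- c(cis, trans) / tot
    out <- data.frame(hap1 = c("rr", "ra"), hap2 = c("aa", "ar"),
                      prob = as.numeric(p), stringsAsFactors = FALSE)
    return(out[order(-out$prob), , drop = FALSE])
  }
  # unambiguous: split each locus dosage into an ordered allele pair
  a261 <- c(g261 %/% 2, (g261 + 1) %/% 2)   # 0->(0,0), 1->(0,1), 2->(1,1)
  a802 <- c(g802 %/% 2, (g802 + 1) %/% 2)
  data.frame(hap1 = hap(a261[1], a802[1]), hap2 = hap(a261[2], a802[2]),
             prob = 1, stringsAsFactors = FALSE)
}
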