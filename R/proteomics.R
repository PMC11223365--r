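#' Per-protein differential expression between blood types
#'
#' Two-sample t-test per protein on log2 intensities with a volcano-style
#' classification: a protein is `up` when `p < alpha` and `log2fc >
#' fc_threshold`, `down` when `p < alpha` and `log2fc < -fc_threshold`,
#' otherwise `not_significant`. `log2fc` is mean(log2 O) minus
#' mean(log2 non-O). Zeros and missing intensities are imputed with half
#' the per-protein minimum positive value before the log transform.
#' Proteins constant within both groups have no defined test and are
#' returned as `not_significant` with `flagged = TRUE`.
#'
#' The default `fc_threshold = 1.2` reads the cutoff literally on the log2
#' scale (|log2FC| > 1.2, i.e. fold change > 2.3); set `fc_scale =
#' "linear"` to threshold the fold change itself (|log2FC| > log2(1.2)).
#'
#' @param intensities Numeric matrix, proteins x samples, non-negative.
#' @param group Character per sample column: `"O"` or `"non_O"`; each group
#'   needs >= 2 samples.
#' @param alpha Significance level. Default 0.05.
#' @param fc_threshold Fold-change cutoff. Default 1.2.
#' @param fc_scale `"log2"` (threshold applies to log2FC) or `"linear"`
#'   (applies to the fold change).
#' @param welch Use the unequal-variance (Welch) t-test. Default TRUE;
#'   FALSE gives Student's pooled-variance test.
#' @return Data.frame: `protein_id`, `log2fc`, `p_value`, `volcano_class`,
#'   `flagged`.
#' @export
differential_expression <- function(intensities, group, alpha = 0.05,
                                    fc_threshold = 1.2,
                                    fc_scale = c("log2", "linear"),
                                    welch = TRUE) {
  fc_scale <- match.arg(fc_scale)
  m <- as.matrix(intensities)
  stopifnot(ncol(m) == length(group), all(group %in% c("O", "non_O")))
  if (min(table(factor(group, levels = c("O", "non_O")))) < 2)
    stop("each group needs >= 2 samples", call. = FALSE)
  if (any(m < 0, na.rm = TRUE)) stop("intensities must be non-negative", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(m)))
  if (anyDuplicated(ids)) stop("duplicate protein ids", call. = FALSE)

  lm2 <- t(apply(m, 1, impute_half_min_log2))
  iso <- group == "O"
  thr <- if (fc_scale == "log2") fc_threshold else log2(fc_threshold)

  res <- vapply(seq_len(nrow(lm2)), function(i) {
    a <- lm2[i, iso]; b <- lm2[i, !iso]
    fc <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(c(fc, NA_real_, 1))
    p <- tryCatch(stats::t.test(a, b, var.equal = !welch)$p.value,
                  error = function(e) NA_real_)
    c(fc, p, 0)
  }, numeric(3))

  log2fc <- res[1, ]; p <- res[2, ]; flagged <- res[3, ] == 1 | is.na(p)
  cls <- rep("not_significant", length(p))
  sig <- !is.na(p) & p < alpha
  cls[sig & log2fc > thr] <- "up"
  cls[sig & log2fc < -thr] <- "down"
  data.frame(protein_id = ids, log2fc = log2fc, p_value = p,
             volcano_class = cls, flagged = flagged,
             stringsAsFactors = FALSE)
}

# half-minimum imputation of zeros/NAs, then log2
impute_half_min_log2 <- function(v) {
  pos <- v[!is.na(v) & v > 0]
  if (length(pos) == 0) return(rep(0, length(v)))   # all-zero protein
  v[is.na(v) | v == 0] <- min(pos) / 2
  log2(v)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each annotation term for enrichment of a query protein set against
#' a background (all detected proteins), with the upper-tail hypergeometric
#' p-value and Benjamini-Hochberg q-values across tested terms. Term sets
#' are intersected with the background first; terms smaller than
#' `min_term_size` after intersection are skipped.
#'
#' @param query Character vector, the significant set (must be a subset of
#'   `background`).
#' @param background Character vector of all detected proteins.
#' @param terms Named list of character vectors (e.g. from [read_gmt()]).
#' @param min_term_size Minimum in-background term size. Default 3.
#' @param q_cutoff Significance threshold on q. Default 0.05.
#' @return Data.frame sorted by p: `term_id`, `term_size` (in background),
#'   `overlap`, `p_value`, `q_value`, `significant`.
#' @export
overrepresentation <- function(query, background, terms, min_term_size = 3,
                               q_cutoff = 0.05) {
  query <- unique(query); background <- unique(background)
  if (length(query) == 0 || length(background) == 0)
    stop("query and background must be non-empty", call. = FALSE)
  if (!all(query %in% background))
    stop("query must be a subset of the background", call. = FALSE)
  tsets <- lapply(terms, intersect, y = background)
  keep <- vapply(tsets, length, integer(1)) >= min_term_size
  tsets <- tsets[keep]
  if (length(tsets) == 0) stop("no term passes min_term_size", call. = FALSE)

  Nb <- length(background); k <- length(query)
  term_size <- vapply(tsets, length, integer(1))
  overlap <- vapply(tsets, function(s) sum(query %in% s), integer(1))
  # P(X >= overlap), X ~ Hypergeometric(term in bg, bg \ term, draws = |query|)
  p <- stats::phyper(overlap - 1, term_size, Nb - term_size, k,
                     lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = names(tsets), term_size = term_size,
                    overlap = overlap, p_value = p, q_value = q,
                    significant = q < q_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term_id), , drop = FALSE]
}

#' Read a GMT term-set file
#'
#' @param path GMT file (term, description, tab-separated members).
#' @return Named list of character member vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write a GMT term-set file
#'
#' @param terms Named list of character member vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of term descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
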