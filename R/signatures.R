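#' Build a CD34+ gene signature from reference samples
#'
#' Ranks genes by their mean expression over the CD34+ reference samples,
#' after per-gene centering against the cohort mean (so that the ranking
#' reflects reference-specific regulation rather than probe-level baseline),
#' and extracts the top and bottom `top_frac` as the up- and down-regulated
#' signature gene sets. Ties are broken deterministically by gene identifier
#' order.
#'
#' @param expr Numeric matrix, genes x samples, with gene identifiers as row
#'   names; log-scale intensities.
#' @param reference_samples Column names (or indices) of the CD34+ reference
#'   samples.
#' @param top_frac Fraction of genes per set (default 0.05); each set has
#'   `max(1, floor(top_frac * n_genes))` genes.
#' @param centering `"cohort-mean"` (default) subtracts each gene's mean over
#'   all cohort samples before ranking; `"none"` ranks raw reference means.
#' @return Object of class `"cd34_signature"`: list with `up_genes`,
#'   `down_genes`, `reference_label`, `centering` and `n_reference_genes`.
#' @examples
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' sig <- build_signature(m, reference_samples = c("s1", "s2"))
#' sig
#' @export
build_signature <- function(expr, reference_samples, top_frac = 0.05,
                            centering = c("cohort-mean", "none")) {
  centering <- match.arg(centering)
  expr <- .check_expr_matrix(expr)
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene identifiers in expression matrix", call. = FALSE)
  ref <- expr[, reference_samples, drop = FALSE]
  if (ncol(ref) < 1L) stop("need at least one reference sample", call. = FALSE)
  n_genes <- nrow(expr)
  n_top <- max(1L, floor(top_frac * n_genes))
  if (n_genes < 2L * n_top)
    stop(sprintf("too few genes (%d) for two disjoint sets of %d",
                 n_genes, n_top), call. = FALSE)
  centered <- switch(centering,
                     "cohort-mean" = rowMeans(ref, na.rm = TRUE) -
                       rowMeans(expr, na.rm = TRUE),
                     "none" = rowMeans(ref, na.rm = TRUE))
  # decreasing value, ties broken by gene id order
  ord <- order(-centered, rownames(expr))
  up <- rownames(expr)[ord[seq_len(n_top)]]
  down <- rev(rownames(expr)[ord[seq.int(n_genes - n_top + 1L, n_genes)]])
  structure(list(up_genes = up, down_genes = down,
                 reference_label = paste(colnames(ref), collapse = ","),
                 centering = centering, n_reference_genes = n_genes),
            class = "cd34_signature")
}

#' @export
print.cd34_signature <- function(x, ...) {
  cat(sprintf("CD34+ signature: %d up / %d down genes (top %.3g%% of %d; centering: %s)\n",
              length(x$up_genes), length(x$down_genes),
              100 * length(x$up_genes) / x$n_reference_genes,
              x$n_reference_genes, x$centering))
  invisible(x)
}

#' CD34+ similarity score of one sample
#'
#' Two-sided Wilcoxon rank-sum test between the sample's expression values
#' over the signature's up-regulated and down-regulated gene sets, reported
#' as a signed log10 p-value: positive when the up-set values exceed the
#' down-set values (sample resembles the CD34+ reference), negative
#' otherwise. The exact rank-sum distribution is used when both sets have at
#' most 25 genes (and no ties); the normal approximation with continuity
#' correction otherwise. Values must be on the same (centered) scale that
#' was used to build the signature; [score_cohort()] handles that.
#'
#' @param values Named numeric vector of expression values (gene id ->
#'   value).
#' @param signature A [build_signature()] object.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present among `values` (default 0.8).
#' @return Object of class `"cd34_score"`: list with `score` (signed log10
#'   p), `p_value`, `direction` (+1/-1/0) and coverage per set.
#' @export
similarity_score <- function(values, signature, min_coverage = 0.8) {
  stopifnot(inherits(signature, "cd34_signature"))
  if (is.null(names(values))) stop("'values' must be named by gene id",
                                   call. = FALSE)
  up <- values[intersect(signature$up_genes, names(values))]
  down <- values[intersect(signature$down_genes, names(values))]
  up <- up[is.finite(up)]; down <- down[is.finite(down)]
  if (length(up) == 0L || length(down) == 0L)
    stop("sample covers no genes of the up and/or down signature set",
         call. = FALSE)
  cov_up <- length(up) / length(signature$up_genes)
  cov_down <- length(down) / length(signature$down_genes)
  if (min(cov_up, cov_down) < min_coverage)
    stop(sprintf("signature coverage %.2f below the %.2f threshold",
                 min(cov_up, cov_down), min_coverage), call. = FALSE)
  exact <- length(up) <= 25L && length(down) <= 25L
  p <- suppressWarnings(
    stats::wilcox.test(up, down, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  p <- max(p, .Machine$double.xmin)  # keep the signed log10 finite
  d <- sign(stats::median(up) - stats::median(down))
  structure(list(score = d * -log10(p), p_value = p, direction = d,
                 coverage_up = cov_up, coverage_down = cov_down),
            class = "cd34_score")
}

#' @export
print.cd34_score <- function(x, ...) {
  cat(sprintf("CD34+ similarity score %.4g (two-sided rank-sum p = %.3g, direction %+d)\n",
              x$score, x$p_value, x$direction))
  invisible(x)
}

#' CD34+ similarity scores for a whole cohort
#'
#' Applies the per-gene cohort-mean centering used at signature construction
#' and scores every sample with [similarity_score()]. Samples that cannot be
#' scored (e.g. missing all signature genes) are flagged rather than
#' aborting the cohort.
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param signature A [build_signature()] object.
#' @param min_coverage Passed to [similarity_score()].
#' @return A data.frame with columns `sample_id`, `score`, `p_value`,
#'   `direction`, `flagged` (TRUE when scoring failed; score is `NA`) and
#'   `note`.
#' @export
score_cohort <- function(expr, signature, min_coverage = 0.8) {
  stopifnot(inherits(signature, "cd34_signature"))
  expr <- .check_expr_matrix(expr)
  centered <- if (signature$centering == "cohort-mean")
    expr - rowMeans(expr, na.rm = TRUE) else expr
  res <- lapply(colnames(centered), function(s) {
    out <- tryCatch(similarity_score(centered[, s], signature, min_coverage),
                    error = function(e) e)
    if (inherits(out, "error"))
      data.frame(sample_id = s, score = NA_real_, p_value = NA_real_,
                 direction = NA_integer_, flagged = TRUE,
                 note = conditionMessage(out))
    else
      data.frame(sample_id = s, score = out$score, p_value = out$p_value,
                 direction = out$direction, flagged = FALSE, note = "")
  })
  do.call(rbind, res)
}

.check_expr_matrix <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression input must be a numeric genes x samples matrix",
         call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expression matrix needs gene identifiers as row names",
         call. = FALSE)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("sample", seq_len(ncol(expr)))
  expr
}
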