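#' Read a gene-expression matrix
#'
#' Reads a tab-separated genes x samples table (first column: gene
#' identifiers, header row: sample identifiers). GEO series-matrix files
#' are accepted read-only: metadata lines starting with `!` are skipped and
#' the table between `!series_matrix_table_begin` / `_end` is used.
#' Genes with any missing value are dropped (complete-cases rule), and when
#' a gene list is supplied the matrix is restricted to its intersection
#' with the list.
#'
#' @param path Path to the TSV or series-matrix file.
#' @param gene_list Optional character vector of gene identifiers (e.g. the
#'   low-information-ratio subset) or a path to a one-id-per-line file.
#' @return Numeric matrix, genes x samples, with the number of dropped
#'   incomplete genes in attribute `"n_incomplete_dropped"`.
#' @export
read_expression <- function(path, gene_list = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (any(startsWith(lines, "!"))) {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("malformed series-matrix file: table markers not found",
           call. = FALSE)
    lines <- lines[(beg + 1L):(end - 1L)]
  }
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("malformed header: need gene id column plus samples",
                           call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in expression file", call. = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) storage.mode(m) <- "double"
  rownames(m) <- ids
  complete <- stats::complete.cases(m)
  dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (!is.null(gene_list)) {
    if (length(gene_list) == 1L && file.exists(gene_list))
      gene_list <- read_gene_list(gene_list)
    keep <- intersect(rownames(m), gene_list)
    if (length(keep) == 0L)
      stop("gene list has empty intersection with the expression matrix",
           call. = FALSE)
    m <- m[keep, , drop = FALSE]
  }
  attr(m, "n_incomplete_dropped") <- dropped
  m
}

#' Read a gene list (one identifier per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write an expression matrix as TSV
#' @param expr Genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-separated table with columns `sample_id`, `stage` (CP, AP, APcyto or
#' BC), optional `blast_count` and optional logical `is_cd34_reference`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "stage") %in% names(tab)))
    stop("annotation needs 'sample_id' and 'stage' columns", call. = FALSE)
  if (is.null(tab$blast_count)) tab$blast_count <- NA_real_
  if (is.null(tab$is_cd34_reference)) tab$is_cd34_reference <- FALSE
  tab
}

#' Apply the cohort data-preparation rules
#'
#' Validates the stage vocabulary and applies the blast-count rules:
#' chronic-phase samples with a missing blast count are assigned blast
#' count 1; blast-crisis samples with a missing blast count are excluded;
#' other stages keep the missing value and are flagged.
#'
#' @param annotations Annotation data.frame (see [read_annotation()]).
#' @return Cleaned data.frame with a logical `blast_missing` column; the
#'   ids of excluded BC samples are in attribute `"excluded"`.
#' @export
prepare_cohort <- function(annotations) {
  stages <- c("CP", "AP", "APcyto", "BC")
  bad <- setdiff(unique(annotations$stage), stages)
  if (length(bad) > 0L)
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(annotations$blast_count < 0 | annotations$blast_count > 100,
          na.rm = TRUE))
    stop("blast counts must lie in [0, 100]", call. = FALSE)
  miss <- is.na(annotations$blast_count)
  annotations$blast_missing <- miss
  excl <- annotations$sample_id[miss & annotations$stage == "BC"]
  if (length(excl) > 0L)
    message(sprintf("excluding %d BC sample(s) with missing blast count: %s",
                    length(excl), paste(excl, collapse = ", ")))
  annotations$blast_count[miss & annotations$stage == "CP"] <- 1
  out <- annotations[!(annotations$sample_id %in% excl), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}

#' Run the full staging pipeline
#'
#' End-to-end orchestration: simulate the compartment model, derive the
#' simulated entropy curve and its minimum, build the CD34+ signature from
#' the flagged reference samples, score and entropy-profile every sample,
#' pin the chronic-phase patients onto disease time, split T1/T2 at the
#' entropy minimum, and compute the downstream cohort statistics. All
#' randomness derives from `seed`. When `out_dir` is given, every table is
#' written as TSV together with a JSON manifest (seed, parameters, package
#' version).
#'
#' @param expr Genes x samples expression matrix (log scale), or a path
#'   readable by [read_expression()].
#' @param annotation Annotation data.frame or path ([read_annotation()]).
#' @param params A [model_params()] object.
#' @param gene_list Optional gene universe restriction.
#' @param seed Master seed; SGEM and permutation seeds derive from it.
#' @param n_sgem_seeds SGEM replicates for the entropy-minimum estimate.
#' @param smoothing_window Entropy argmin smoothing (odd; default 11).
#' @param n_bins,log_base Entropy estimator settings.
#' @param cohort_binning `"global"` (default) computes every sample's
#'   entropy over the pooled cohort value range so entropies are directly
#'   comparable across samples; `"per-sample"` uses each sample's own range.
#' @param match Pinning mode, see [pin_patients()].
#' @param n_perm Permutations for the stage-grid control.
#' @param out_dir Optional output directory.
#' @return Object of class `"cml_pipeline"`: list with `scores`,
#'   `entropies`, `curve`, `boundary` (days), `mapping`, `vshape`, `grid`,
#'   `null`, `de_t1_t2` and `manifest`.
#' @export
run_pipeline <- function(expr, annotation, params = model_params(),
                         gene_list = NULL, seed = 1L, n_sgem_seeds = 10L,
                         smoothing_window = 11L, n_bins = 64L,
                         log_base = exp(1),
                         cohort_binning = c("global", "per-sample"),
                         match = "two-step",
                         n_perm = 1000L, out_dir = NULL) {
  if (is.character(expr)) expr <- read_expression(expr, gene_list)
  else if (!is.null(gene_list)) {
    keep <- intersect(rownames(expr), gene_list)
    if (length(keep) == 0L)
      stop("gene list has empty intersection with the expression matrix",
           call. = FALSE)
    expr <- expr[keep, , drop = FALSE]
  }
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  ann <- prepare_cohort(annotation)
  expr <- expr[, intersect(colnames(expr), ann$sample_id), drop = FALSE]
  ann <- ann[match(colnames(expr), ann$sample_id), , drop = FALSE]

  # model side
  traj <- simulate_trajectories(params)
  emin <- entropy_minimum_time(traj, n_seeds = n_sgem_seeds, seed = seed,
                               n_genes = nrow(expr),
                               smoothing_window = smoothing_window,
                               n_bins = n_bins, log_base = log_base)
  boundary <- emin$t_min
  curve <- emin$curve

  # patient side
  sig <- build_signature(expr, ann$sample_id[ann$is_cd34_reference])
  scores <- score_cohort(expr, sig)
  cohort_binning <- match.arg(cohort_binning)
  ent_range <- if (cohort_binning == "global") range(expr) else NULL
  entropies <- apply(expr, 2L, sample_entropy, n_bins = n_bins,
                     log_base = log_base, range = ent_range)
  patients <- !ann$is_cd34_reference
  sc <- stats::setNames(scores$score, scores$sample_id)[patients]
  en <- entropies[patients]
  st <- ann$stage[patients]

  cp <- st == "CP" & !is.na(sc)
  vs <- vshape_test(en[cp], sc[cp])
  mapping <- pin_patients(sc[cp], en[cp], curve, match = match)
  mapping <- classify_T1_T2(mapping, boundary)

  grid <- stage_fraction_grid(sc[!is.na(sc)], en[!is.na(sc)],
                              st[!is.na(sc)])
  nullc <- randomization_control(grid, st[!is.na(sc)], n_perm = n_perm,
                                 seed = seed + 1000L)
  t1 <- mapping$sample_id[mapping$phase_label == "T1"]
  t2 <- mapping$sample_id[mapping$phase_label == "T2"]
  de <- if (length(t1) >= 2L && length(t2) >= 2L)
    differential_expression(expr, t1, t2) else NULL

  manifest <- list(seed = seed, n_sgem_seeds = n_sgem_seeds,
                   n_bins = n_bins, smoothing_window = smoothing_window,
                   match = match, n_perm = n_perm,
                   cohort_binning = cohort_binning,
                   n_genes = nrow(expr), n_samples = ncol(expr),
                   boundary_days = boundary,
                   params = unclass(params),
                   package_version =
                     as.character(utils::packageVersion("cmlstage")))

  res <- structure(list(scores = scores, entropies = entropies,
                        curve = curve, boundary = boundary,
                        mapping = mapping, vshape = vs, grid = grid,
                        null = nullc, de_t1_t2 = de, signature = sig,
                        annotation = ann, manifest = manifest),
                   class = "cml_pipeline")
  if (!is.null(out_dir)) .write_pipeline(res, out_dir)
  res
}

#' @export
print.cml_pipeline <- function(x, ...) {
  cat("CML staging pipeline\n")
  cat(sprintf("  %d genes x %d samples; entropy-minimum boundary at %g d\n",
              x$manifest$n_genes, x$manifest$n_samples, x$boundary))
  cat(sprintf("  CP patients pinned: %d (T1 %d / T2 %d)\n",
              nrow(x$mapping), sum(x$mapping$phase_label == "T1"),
              sum(x$mapping$phase_label == "T2")))
  cat(sprintf("  V-shape quadratic p = %.4g\n", x$vshape$p_value))
  if (!is.null(x$de_t1_t2))
    cat(sprintf("  T1 vs T2: %d DE genes (%.2f%%) at FDR < %g\n",
                attr(x$de_t1_t2, "n_significant"),
                attr(x$de_t1_t2, "fraction_significant"),
                attr(x$de_t1_t2, "alpha")))
  invisible(x)
}

.write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(res$scores, "scores.tsv")
  w(data.frame(sample_id = names(res$entropies),
               entropy = unname(res$entropies)), "entropies.tsv")
  w(data.frame(time = res$curve$times, s_t = res$curve$entropy,
               mixing_entropy = res$curve$mixing_entropy,
               cd34_ratio = res$curve$cd34_ratio), "simulated_curve.tsv")
  w(as.data.frame(res$mapping), "mapping.tsv")
  if (!is.null(res$de_t1_t2)) w(as.data.frame(res$de_t1_t2), "de_t1_t2.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
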