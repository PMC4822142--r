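#' Configuration of a synthetic CML cohort
#'
#' Describes a synthetic cohort shaped like the clinical microarray cohorts
#' this pipeline targets: 42 chronic-phase (CP), 9 accelerated-phase (AP),
#' 8 cytogenetically accelerated (APcyto) and 28 blast-crisis (BC) samples
#' over 6,384 genes, with stage-dependent CD34-signature shifts, a
#' stage-dependent entropy structure and planted missing blast counts. CP
#' samples carry a known ground-truth disease time uniform over the model
#' window.
#'
#' @param n_per_stage Named integer vector of sample counts for CP, AP,
#'   APcyto and BC.
#' @param n_genes Number of genes.
#' @param n_signature_genes Number of planted CD34-associated genes, split
#'   into an up- and a down-regulated half (default: 10 percent of
#'   `n_genes`, matching the two 5-percent tails a signature extracts).
#' @param signature_effect_size Mean shift of signature genes in CD34+
#'   populations, in units of the baseline SD (default 1, i.e. a 2-SD gap
#'   between CD34+ and CD34- populations; large enough to rank reliably,
#'   small enough that the rank-sum score statistic does not saturate).
#' @param noise_sd Per-measurement Gaussian noise SD in baseline-SD units
#'   (default 0.5; log-scale intensities).
#' @param cp_time_range_days Range of CP ground-truth times (days).
#' @param n_reference Number of CD34+ reference samples appended to the
#'   cohort (default 3).
#' @param missing_blast_fraction Fraction of CP and BC samples with the
#'   blast count removed (default 0.1).
#' @param rng_seed Seed for cohort generation.
#' @return Object of class `"synthetic_cohort_config"`.
#' @export
synthetic_cohort_config <- function(n_per_stage = c(CP = 42L, AP = 9L,
                                                    APcyto = 8L, BC = 28L),
                                    n_genes = 6384L,
                                    n_signature_genes = 2L * floor(0.05 * n_genes),
                                    signature_effect_size = 1,
                                    noise_sd = 0.5,
                                    cp_time_range_days = c(0, 2200),
                                    n_reference = 3L,
                                    missing_blast_fraction = 0.1,
                                    rng_seed = 1L) {
  stopifnot(all(n_per_stage >= 0), n_genes >= 2,
            n_signature_genes >= 1, n_signature_genes < n_genes,
            signature_effect_size >= 0, noise_sd >= 0,
            length(cp_time_range_days) == 2L,
            cp_time_range_days[1L] >= 0,
            diff(cp_time_range_days) > 0,
            missing_blast_fraction >= 0, missing_blast_fraction <= 1)
  needed <- c("CP", "AP", "APcyto", "BC")
  if (!all(needed %in% names(n_per_stage)))
    stop("'n_per_stage' must name CP, AP, APcyto and BC", call. = FALSE)
  structure(list(n_per_stage = n_per_stage[needed], n_genes = as.integer(n_genes),
                 n_signature_genes = as.integer(n_signature_genes),
                 signature_effect_size = signature_effect_size,
                 noise_sd = noise_sd,
                 cp_time_range_days = cp_time_range_days,
                 n_reference = as.integer(n_reference),
                 missing_blast_fraction = missing_blast_fraction,
                 rng_seed = rng_seed),
            class = "synthetic_cohort_config")
}

#' Base expression profiles of the model cell populations
#'
#' Builds the per-population ground-truth expression matrix that gives the
#' random-matrix idea biological structure: i.i.d. uniform baseline values
#' (matching the SGEM entry distribution, whose non-Gaussian shape carries
#' the entropy signal), with planted CD34-associated genes. The first half
#' of `signature_genes` is shifted up by `effect` baseline SDs in CD34+
#' populations and down elsewhere; the second half is shifted the opposite
#' way, mirroring the up- and down-regulated tails a CD34+ reference
#' signature extracts. CD34 status per population follows the model
#' parameters (healthy compartments up to `cd34_cutoff`, leukemic up to
#' `cml_cd34_cutoff`).
#'
#' @param n_genes Number of genes.
#' @param signature_genes Integer indices (or names) of the planted genes;
#'   split into an up-regulated first half and a down-regulated second half.
#' @param effect Shift in baseline-SD units.
#' @param params A [model_params()] object (sets population count and CD34
#'   status).
#' @param seed Seed.
#' @return Matrix `2 K x n_genes` with attributes `cd34_positive` (logical
#'   per row), `signature_up` and `signature_down` (gene ids); row/column
#'   names as in the SGEM.
#' @export
generate_compartment_profiles <- function(n_genes, signature_genes, effect,
                                          params = model_params(),
                                          seed = 1L) {
  K <- params$n_compartments
  gene_ids <- paste0("g", seq_len(n_genes))
  if (is.character(signature_genes))
    signature_genes <- match(signature_genes, gene_ids)
  if (anyNA(signature_genes) || any(signature_genes < 1) ||
      any(signature_genes > n_genes))
    stop("signature genes must be a subset of the gene list", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  base <- matrix(stats::runif(2L * K * n_genes), nrow = 2L * K,
                 dimnames = list(c(paste0("healthy.", 1:K),
                                   paste0("cml.", 1:K)), gene_ids))
  sd_u <- sqrt(1 / 12)  # SD of the uniform baseline
  cd34 <- c(seq_len(K) <= params$cd34_cutoff,
            seq_len(K) <= params$cml_cd34_cutoff)
  n_up <- ceiling(length(signature_genes) / 2)
  up <- signature_genes[seq_len(n_up)]
  down <- signature_genes[-seq_len(n_up)]
  delta <- effect * sd_u
  base[cd34, up] <- base[cd34, up] + delta
  base[!cd34, up] <- base[!cd34, up] - delta
  if (length(down) > 0L) {
    base[cd34, down] <- base[cd34, down] - delta
    base[!cd34, down] <- base[!cd34, down] + delta
  }
  attr(base, "cd34_positive") <- cd34
  attr(base, "signature_up") <- gene_ids[up]
  attr(base, "signature_down") <- gene_ids[down]
  base
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort of mixed-population expression samples from the
#' compartment model: each CP sample at true time `t` is the
#' population-weighted mixture of the base profiles at `t` plus Gaussian
#' measurement noise. Advanced stages (AP, APcyto, BC) are not covered by
#' the chronic-phase model; they are represented as synthetic
#' leukemic-template-dominated mixtures with progressively larger CD34+
#' mass and extra dispersion, so that CD34+ similarity rises and entropy is
#' elevated along CP to BC. CD34+ reference samples (pure CD34+ mixtures)
#' are appended and flagged for signature construction. Blast counts are
#' drawn stage-dependently with planted missingness.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @param traj A [simulate_trajectories()] result covering the CP time
#'   range.
#' @param base_profiles A [generate_compartment_profiles()] matrix.
#' @param boundary_days T1/T2 boundary used for the ground-truth labels
#'   (default 1476; pass the boundary the analysis will use, e.g. the
#'   simulated-entropy minimum, for consistent truth labels).
#' @return List with `expression` (genes x samples), `annotation`
#'   (data.frame: `sample_id`, `stage`, `blast_count`,
#'   `is_cd34_reference`) and `truth` (data.frame: `sample_id`, `stage`,
#'   `true_time_days`, `true_label`).
#' @export
generate_cohort <- function(cfg, traj, base_profiles,
                            boundary_days = 1476) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"),
            inherits(traj, "cml_trajectories"))
  if (max(cfg$cp_time_range_days) > max(traj$times))
    stop("trajectory does not cover the CP time range", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$rng_seed)

  K <- dim(traj$counts)[3L]
  W <- .population_weights(traj)
  G <- ncol(base_profiles)
  cd34 <- attr(base_profiles, "cd34_positive")
  sd_u <- sqrt(1 / 12)

  # leukemic CD34+ template: the clone's late-time compartment profile
  w_end <- W[nrow(W), ]
  cml_rows <- grepl("^cml\\.", colnames(W))
  w_cml <- w_end * (cml_rows & cd34)
  if (sum(w_cml) == 0) w_cml[cml_rows][1L] <- 1
  w_cml <- w_cml / sum(w_cml)

  # stage templates: leukemic-template mass and extra noise dispersion
  stage_mix <- c(AP = 0.5, APcyto = 0.4, BC = 0.9)
  stage_disp <- c(AP = 1.25, APcyto = 1.5, BC = 1.5)

  n <- cfg$n_per_stage
  stages <- rep(names(n), n)
  ids <- sprintf("%s_%02d", stages, unlist(lapply(n, seq_len)))
  t_true <- rep(NA_real_, length(ids))
  weights <- matrix(0, length(ids), ncol(W))
  noise_mult <- rep(1, length(ids))
  is_cp <- stages == "CP"
  cp_times <- stats::runif(sum(is_cp), cfg$cp_time_range_days[1L],
                           cfg$cp_time_range_days[2L])
  cp_idx <- vapply(cp_times, function(t) which.min(abs(traj$times - t)),
                   integer(1))
  t_true[is_cp] <- traj$times[cp_idx]
  weights[is_cp, ] <- W[cp_idx, , drop = FALSE]
  for (s in c("AP", "APcyto", "BC")) {
    sel <- stages == s
    if (!any(sel)) next
    weights[sel, ] <- matrix(stage_mix[[s]] * w_cml +
                               (1 - stage_mix[[s]]) * w_end,
                             sum(sel), ncol(W), byrow = TRUE)
    noise_mult[sel] <- stage_disp[[s]]
  }

  # CD34+ reference samples: balanced pool over all CD34+ populations of
  # both lineages (emulating CD34+ enrichment of patient material, which
  # equalises the sorted populations rather than preserving steady-state
  # proportions)
  if (cfg$n_reference > 0L) {
    w_ref <- as.numeric(cd34)
    w_ref <- w_ref / sum(w_ref)
    ref_ids <- sprintf("CD34REF_%02d", seq_len(cfg$n_reference))
    ids <- c(ids, ref_ids)
    stages <- c(stages, rep("CP", cfg$n_reference))
    t_true <- c(t_true, rep(NA_real_, cfg$n_reference))
    weights <- rbind(weights, matrix(w_ref, cfg$n_reference, ncol(W),
                                     byrow = TRUE))
    noise_mult <- c(noise_mult, rep(1, cfg$n_reference))
  }

  expr <- weights %*% base_profiles
  expr <- expr + matrix(stats::rnorm(length(expr)), nrow(expr), G) *
    (cfg$noise_sd * sd_u * noise_mult)
  expr <- t(expr)
  dimnames(expr) <- list(colnames(base_profiles), ids)

  is_ref <- grepl("^CD34REF_", ids)
  blast <- numeric(length(ids))
  blast[stages == "CP"] <- round(stats::runif(sum(stages == "CP"), 0, 9), 1)
  blast[stages == "AP"] <- round(stats::runif(sum(stages == "AP"), 15, 29), 1)
  blast[stages == "APcyto"] <- round(stats::runif(sum(stages == "APcyto"),
                                                  0, 9), 1)
  blast[stages == "BC"] <- round(stats::runif(sum(stages == "BC"), 30, 95), 1)
  for (s in c("CP", "BC")) {
    sel <- which(stages == s & !is_ref)
    n_miss <- floor(cfg$missing_blast_fraction * length(sel))
    if (n_miss > 0L)
      blast[sample(sel, n_miss)] <- NA_real_
  }
  blast[is_ref] <- NA_real_

  annotation <- data.frame(sample_id = ids, stage = stages,
                           blast_count = blast,
                           is_cd34_reference = is_ref, row.names = NULL)
  truth <- data.frame(sample_id = ids, stage = stages,
                      true_time_days = t_true,
                      true_label = ifelse(is.na(t_true), NA_character_,
                                          ifelse(t_true < boundary_days,
                                                 "T1", "T2")),
                      row.names = NULL)
  list(expression = expr, annotation = annotation, truth = truth)
}
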