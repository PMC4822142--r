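#' Parameters of the multi-compartment hematopoiesis model
#'
#' Builds and validates the parameter set of the deterministic compartment
#' model of hematopoiesis carrying a CML clone. Defaults reproduce the
#' hierarchy described in the compartment-model literature this model family
#' derives from: 32 compartments, compartment-1 replication about once per
#' year, replication rates increasing by a factor 1.26 per compartment, a
#' healthy differentiation probability of 0.85 (which implies the familiar
#' ~1.93 steady-state size ratio between adjacent compartments) and a reduced
#' differentiation probability of 0.72 for leukemic cells. None of these rate
#' constants is specific to this package; they are the standard literature
#' values and every one of them can be overridden.
#'
#' CD34 phenotype: healthy cells lose CD34 once they pass `cd34_cutoff`
#' (default compartment 23, where committed precursors start to dominate).
#' Leukemic cells, owing to the differentiation block, retain the immature
#' CD34+ phenotype through `cml_cd34_cutoff`, which defaults to the last
#' compartment (the whole clone is treated as a CD34+ blast pool). Setting
#' `cml_cd34_cutoff = cd34_cutoff` recovers a strictly compartment-indexed,
#' lineage-blind CD34 assignment.
#'
#' @param n_compartments Number of maturation compartments (>= 2).
#' @param replication_rate_base Replication rate of compartment 1, per day.
#' @param replication_rate_ratio Multiplicative increase of the replication
#'   rate per compartment (dimensionless).
#' @param epsilon_healthy Differentiation probability per division for healthy
#'   cells, in (0, 1).
#' @param epsilon_cml Differentiation probability per division for leukemic
#'   cells, in (0, 1). Values below `epsilon_healthy` amplify the clone.
#' @param steady_state_ratio Ratio of healthy steady-state sizes between
#'   adjacent compartments. `NULL` (default) uses the value implied by the
#'   dynamics, `2 e / ((2 e - 1) r)`, so that the healthy lineage is exactly
#'   stationary.
#' @param stem_cells_healthy Healthy compartment-1 cell count.
#' @param cml_init_cells Leukemic cells seeded in compartment 1 at time 0.
#' @param cd34_cutoff Last compartment whose healthy cells are CD34+.
#' @param cml_cd34_cutoff Last compartment whose leukemic cells are CD34+
#'   (default `n_compartments`).
#' @param t_max_days Simulation horizon in days.
#' @param dt_days Output grid step in days.
#'
#' @return An object of class `"cml_model_params"`.
#' @examples
#' p <- model_params()
#' p
#' @export
model_params <- function(n_compartments = 32L,
                         replication_rate_base = 1 / 365,
                         replication_rate_ratio = 1.26,
                         epsilon_healthy = 0.85,
                         epsilon_cml = 0.72,
                         steady_state_ratio = NULL,
                         stem_cells_healthy = 400,
                         cml_init_cells = 1,
                         cd34_cutoff = 23L,
                         cml_cd34_cutoff = n_compartments,
                         t_max_days = 2200,
                         dt_days = 1) {
  n_compartments <- as.integer(n_compartments)
  if (is.na(n_compartments) || n_compartments < 2L)
    stop("'n_compartments' must be an integer >= 2", call. = FALSE)
  for (nm in c("replication_rate_base", "replication_rate_ratio",
               "stem_cells_healthy", "t_max_days", "dt_days")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm), call. = FALSE)
  }
  for (nm in c("epsilon_healthy", "epsilon_cml")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("'%s' must lie strictly between 0 and 1", nm),
           call. = FALSE)
  }
  if (cml_init_cells < 0)
    stop("'cml_init_cells' must be >= 0", call. = FALSE)
  cd34_cutoff <- as.integer(cd34_cutoff)
  if (cd34_cutoff < 1L || cd34_cutoff >= n_compartments)
    stop("'cd34_cutoff' must satisfy 1 <= cutoff < n_compartments",
         call. = FALSE)
  cml_cd34_cutoff <- as.integer(cml_cd34_cutoff)
  if (cml_cd34_cutoff < 1L || cml_cd34_cutoff > n_compartments)
    stop("'cml_cd34_cutoff' must satisfy 1 <= cutoff <= n_compartments",
         call. = FALSE)
  if (is.null(steady_state_ratio)) {
    steady_state_ratio <- 2 * epsilon_healthy /
      ((2 * epsilon_healthy - 1) * replication_rate_ratio)
  } else if (!is.numeric(steady_state_ratio) || steady_state_ratio <= 0) {
    stop("'steady_state_ratio' must be positive", call. = FALSE)
  }

  structure(list(
    n_compartments = n_compartments,
    replication_rate_base = replication_rate_base,
    replication_rate_ratio = replication_rate_ratio,
    epsilon_healthy = epsilon_healthy,
    epsilon_cml = epsilon_cml,
    steady_state_ratio = steady_state_ratio,
    stem_cells_healthy = stem_cells_healthy,
    cml_init_cells = cml_init_cells,
    cd34_cutoff = cd34_cutoff,
    cml_cd34_cutoff = cml_cd34_cutoff,
    t_max_days = t_max_days,
    dt_days = dt_days
  ), class = "cml_model_params")
}

#' @export
print.cml_model_params <- function(x, ...) {
  cat("Multi-compartment hematopoiesis model parameters\n")
  cat(sprintf("  compartments: %d (CD34+ through %d healthy / %d leukemic)\n",
              x$n_compartments, x$cd34_cutoff, x$cml_cd34_cutoff))
  cat(sprintf("  replication:  r_k = %.5g * %.3g^(k-1) per day\n",
              x$replication_rate_base, x$replication_rate_ratio))
  cat(sprintf("  differentiation probability: healthy %.3g, CML %.3g\n",
              x$epsilon_healthy, x$epsilon_cml))
  cat(sprintf("  healthy steady-state ratio:  %.4g (stem compartment %g cells)\n",
              x$steady_state_ratio, x$stem_cells_healthy))
  cat(sprintf("  CML seed: %g cell(s); horizon %g d, step %g d\n",
              x$cml_init_cells, x$t_max_days, x$dt_days))
  invisible(x)
}

# replication rates per compartment
.replication_rates <- function(params) {
  params$replication_rate_base *
    params$replication_rate_ratio ^ (seq_len(params$n_compartments) - 1L)
}

# healthy steady-state compartment sizes (exact fixed point of the update
# when steady_state_ratio is the implied value)
.healthy_steady_state <- function(params) {
  params$stem_cells_healthy *
    params$steady_state_ratio ^ (seq_len(params$n_compartments) - 1L)
}
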