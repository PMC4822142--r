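#' Min-max normalization to the unit interval
#'
#' Affine rescaling \eqn{(v - \min)/(\max - \min)} with the transform
#' recorded for inverse mapping.
#'
#' @param values Numeric vector with at least two distinct finite values.
#' @return List with `values` (normalized), `min` and `range`.
#' @examples
#' normalize_unit_interval(c(2, 4, 6))$values  # 0, 0.5, 1
#' @export
normalize_unit_interval <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("need at least 2 distinct finite values to normalize",
         call. = FALSE)
  lo <- min(v); rg <- diff(range(v))
  list(values = (values - lo) / rg, min = lo, range = rg)
}

#' Pin chronic-phase patients onto disease-evolutionary time
#'
#' Maps each chronic-phase (CP) patient to a model time point by matching
#' the patient's normalized CD34+ similarity score against the normalized
#' model CD34 ratio, then refining by entropy. Both axes are independently
#' min-max normalized to \[0, 1\] (over the CP cohort and over the full
#' simulated window, respectively). Before matching, the observed and
#' simulated entropy profiles are aligned ("pinning") by shifting the
#' patients' CD34 coordinates: the default `"profile"` alignment chooses the
#' shift minimizing the summed squared distance between each patient's
#' normalized entropy and the normalized simulated entropy at the matched
#' time (least-squares registration of the two entropy profiles, which
#' aligns their minima); the `"vertex"` alternative shifts the fitted
#' quadratic V vertex of observed entropy onto the simulated argmin.
#'
#' Matching modes:
#' \describe{
#'   \item{`"two-step"`}{(default) step 1: candidate time minimizing
#'     `|score - cd34_ratio(t)|` on the normalized axes; step 2: within a
#'     CD34 neighbourhood of the candidate (half-width `neighbourhood` on
#'     the normalized CD34 axis) the final time minimizes
#'     `|observed entropy - simulated entropy(t)|` (both normalized).}
#'   \item{`"joint"`}{single 2-D Euclidean nearest neighbour over
#'     (CD34, entropy).}
#' }
#'
#' @param cp_scores Numeric vector of CP patients' CD34+ similarity scores,
#'   named by sample id (or a [score_cohort()] data.frame, from which
#'   unflagged rows are taken).
#' @param cp_entropies Numeric vector of the same patients' observed
#'   expression entropies (same order/names).
#' @param curve An [simulated_entropy_curve()] result covering the window.
#' @param match `"two-step"` or `"joint"`.
#' @param neighbourhood CD34 half-width of the entropy refinement window on
#'   the normalized axis (default 0.05).
#' @param align `"profile"` (default) aligns by least-squares registration
#'   of the entropy profiles; `"vertex"` shifts the observed-entropy V
#'   vertex (quadratic fit) onto the simulated argmin, falling back to the
#'   unshifted joint nearest-neighbour match with a warning flag when the V
#'   is unfittable or its vertex lies outside the observed score range;
#'   `"none"` disables the alignment shift. Alignment applies to the
#'   two-step mode.
#' @param shift_grid Candidate shifts scanned by the `"profile"` alignment
#'   (normalized CD34 units).
#' @return Object of class `"cml_pinning"`: a data.frame with one row per
#'   patient (`sample_id`, `normalized_cd34`, `matched_time_days`,
#'   `matched_model_entropy`, `observed_entropy`, `fallback`), with the
#'   alignment shift, matching settings and curve stored as attributes.
#' @export
pin_patients <- function(cp_scores, cp_entropies, curve,
                         match = c("two-step", "joint"),
                         neighbourhood = 0.05,
                         align = c("profile", "vertex", "none"),
                         shift_grid = seq(-0.5, 0.5, by = 0.005)) {
  match <- match.arg(match)
  align <- match.arg(align)
  if (is.data.frame(cp_scores)) {
    keep <- !cp_scores$flagged
    sc <- stats::setNames(cp_scores$score[keep], cp_scores$sample_id[keep])
  } else sc <- cp_scores
  if (is.null(names(sc)))
    names(sc) <- paste0("patient", seq_along(sc))
  if (length(cp_entropies) != length(sc))
    stop("scores and entropies must cover the same patients", call. = FALSE)

  x <- normalize_unit_interval(sc)$values          # patient CD34 axis
  rn <- normalize_unit_interval(curve$cd34_ratio)$values
  sn <- normalize_unit_interval(curve$entropy)$values
  he <- normalize_unit_interval(cp_entropies)$values

  fallback <- FALSE
  shift <- 0
  if (match == "two-step" && align == "profile") {
    obj <- vapply(shift_grid, function(d) {
      xi <- pmin(1, pmax(0, x + d))
      sum((he - sn[.nearest_idx(xi, rn)])^2)
    }, numeric(1))
    shift <- shift_grid[which.min(obj)]
  } else if (match == "two-step" && align == "vertex") {
    vfit <- tryCatch(vshape_test(cp_entropies, x), error = function(e) NULL)
    t_star <- curve$times[which.min(curve$entropy)]
    # the vertex must lie inside the observed (normalized) score range;
    # an extrapolated vertex makes the alignment shift meaningless
    if (!is.null(vfit) && is.finite(vfit$vertex) &&
        vfit$vertex >= 0 && vfit$vertex <= 1) {
      shift <- rn[which.min(abs(curve$times - t_star))] - vfit$vertex
    } else {
      fallback <- TRUE
    }
  }
  xs <- pmin(1, pmax(0, x + shift))

  pin_one <- function(xi, hi) {
    if (match == "joint" || fallback) {
      return(which.min((xi - rn)^2 + (hi - sn)^2))
    }
    cand <- which.min(abs(xi - rn))
    nb <- which(abs(rn - rn[cand]) <= neighbourhood)
    nb[which.min(abs(hi - sn[nb]))]
  }
  idx <- mapply(pin_one, xs, he)

  out <- data.frame(sample_id = names(sc),
                    normalized_cd34 = unname(x),
                    matched_time_days = curve$times[idx],
                    matched_model_entropy = curve$entropy[idx],
                    observed_entropy = unname(cp_entropies),
                    fallback = fallback,
                    row.names = NULL)
  class(out) <- c("cml_pinning", "data.frame")
  attr(out, "shift") <- shift
  attr(out, "match") <- match
  attr(out, "neighbourhood") <- neighbourhood
  attr(out, "align") <- align
  attr(out, "curve") <- curve
  if (fallback)
    warning("observed-entropy V not fittable; joint nearest-neighbour match used",
            call. = FALSE)
  out
}

#' @export
print.cml_pinning <- function(x, ...) {
  cat(sprintf("Pinned %d CP patients onto 0..%g d (match: %s, CD34 shift %+.3f)\n",
              nrow(x), max(attr(x, "curve")$times), attr(x, "match"),
              attr(x, "shift")))
  if ("phase_label" %in% names(x))
    cat(sprintf("  T1: %d, T2: %d\n", sum(x$phase_label == "T1"),
                sum(x$phase_label == "T2")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
summary.cml_pinning <- function(object, ...) {
  cat(sprintf("Matched times: median %g d, range %g..%g d\n",
              stats::median(object$matched_time_days),
              min(object$matched_time_days), max(object$matched_time_days)))
  cat(sprintf("Spearman rho(normalized CD34, matched time) = %.3f\n",
              stats::cor(object$normalized_cd34, object$matched_time_days,
                         method = "spearman")))
  invisible(object)
}

#' @export
plot.cml_pinning <- function(x, ...) {
  curve <- attr(x, "curve")
  sn <- normalize_unit_interval(curve$entropy)$values
  hn <- normalize_unit_interval(x$observed_entropy)$values
  plot(curve$times, sn, type = "l", lwd = 2, col = "grey50",
       xlab = "disease time (days)", ylab = "normalized entropy",
       main = "Observed vs simulated entropy after pinning", ...)
  cols <- if ("phase_label" %in% names(x))
    ifelse(x$phase_label == "T1", "darkgreen", "darkorange") else "darkgreen"
  graphics::points(x$matched_time_days, hn, pch = 8, col = cols)
  invisible(x)
}

#' Split chronic phase into early (T1) and late (T2)
#'
#' Labels each pinned patient T1 when the matched disease time lies strictly
#' before the boundary and T2 otherwise (a patient exactly on the boundary
#' is labelled T2).
#'
#' @param mapping A [pin_patients()] result.
#' @param boundary_time Boundary in days, typically the simulated-entropy
#'   minimum time.
#' @return The mapping with an added `phase_label` factor column.
#' @export
classify_T1_T2 <- function(mapping, boundary_time) {
  stopifnot(inherits(mapping, "cml_pinning"))
  curve <- attr(mapping, "curve")
  if (boundary_time < min(curve$times) || boundary_time > max(curve$times))
    stop("'boundary_time' outside the simulated window", call. = FALSE)
  mapping$phase_label <- factor(
    ifelse(mapping$matched_time_days < boundary_time, "T1", "T2"),
    levels = c("T1", "T2"))
  attr(mapping, "boundary_time") <- boundary_time
  mapping
}


# index of the nearest grid value for each query; grid need not be sorted
.nearest_idx <- function(q, grid) {
  if (!is.unsorted(grid)) {
    j <- findInterval(q, grid, all.inside = TRUE)
    jj <- pmin(length(grid), j + 1L)
    ifelse(abs(q - grid[j]) <= abs(q - grid[jj]), j, jj)
  } else {
    vapply(q, function(v) which.min(abs(v - grid)), integer(1))
  }
}
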