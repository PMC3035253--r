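#' Classification error ratio of a distance threshold
#'
#' For a calibration set of genome pairs with both an in-silico distance
#' (\code{ggd}) and a wet-lab DDH percentage, the error ratio of a
#' threshold \eqn{T} is (false positives + false negatives) / N, where a
#' false positive is a pair with distance at most \eqn{T} but DDH below the
#' cutoff, and a false negative a pair with distance above \eqn{T} but DDH
#' at least the cutoff. The boundary is inclusive: distance exactly equal
#' to \eqn{T} predicts same-species.
#'
#' @param records data.frame with numeric columns \code{ggd} and \code{ddh}
#'   (as from \code{\link{read_calibration_table}}).
#' @param T distance threshold.
#' @param ddh_cutoff DDH percentage defining the species boundary
#'   (default 70).
#' @return the error ratio, a fraction in [0, 1].
#' @examples
#' rec <- data.frame(ggd = c(0.01, 0.02, 0.05, 0.08),
#'                   ddh = c(95, 85, 60, 40))
#' error_ratio(rec, T = 0.03)   # 0
#' error_ratio(rec, T = 0.01)   # 0.25: the (0.02, 85) pair is missed
#' @export
error_ratio <- function(records, T, ddh_cutoff = 70) {
  stopifnot(is.finite(T))
  if (nrow(records) == 0L) stop("empty calibration record set")
  fp <- sum(records$ggd <= T & records$ddh < ddh_cutoff)
  fn <- sum(records$ggd > T & records$ddh >= ddh_cutoff)
  (fp + fn) / nrow(records)
}

#' Fit the error-ratio-optimal species-delineation threshold
#'
#' Estimates the genome-to-genome distance threshold that best mimics the
#' DDH species boundary (conventionally 70\% re-association): the error
#' ratio is evaluated on a regular grid of 1001 thresholds spanning the
#' observed distance range inclusive (step width 1/1000 of the range), and
#' the smallest threshold attaining the minimum error ratio is returned.
#' The fitted threshold can then replace wet-lab DDH in real genome
#' comparisons via \code{\link{predict.ggd_threshold}}.
#'
#' @param records data.frame with numeric columns \code{ggd} and \code{ddh};
#'   a \code{pair_id} column is carried through if present.
#' @param ddh_cutoff DDH percentage defining the species boundary; default
#'   70, adjustable for taxa where other cutoffs are accepted practice.
#' @param grid_steps number of grid intervals (default 1000, i.e. 1001
#'   evaluated thresholds).
#' @return An object of class \code{"ggd_threshold"}: a list with
#'   \code{optimal_T}, \code{min_error_ratio}, \code{grid_step},
#'   \code{errors_by_T} (data.frame of every evaluated threshold and its
#'   error ratio), \code{ddh_cutoff}, \code{records} and \code{n}.
#' @examples
#' rec <- data.frame(ggd = c(0.01, 0.02, 0.05, 0.08),
#'                   ddh = c(95, 85, 60, 40))
#' fit <- ggd_threshold(rec)
#' coef(fit)
#' predict(fit, newdistance = c(0.03, 0.5))
#' @export
ggd_threshold <- function(records, ddh_cutoff = 70, grid_steps = 1000L) {
  stopifnot(is.data.frame(records),
            all(c("ggd", "ddh") %in% names(records)),
            grid_steps >= 1L)
  if (nrow(records) < 2L)
    stop("need at least 2 calibration records")
  if (any(!is.finite(records$ggd)) || any(records$ggd < 0))
    stop("ggd values must be finite and non-negative")
  if (any(records$ddh < 0 | records$ddh > 100))
    stop("ddh values must lie in [0, 100]")
  rng <- range(records$ggd)
  if (diff(rng) == 0)
    stop("all ggd values identical; threshold range is degenerate")
  grid <- seq(rng[1L], rng[2L], length.out = grid_steps + 1L)
  errs <- vapply(grid, function(T) error_ratio(records, T, ddh_cutoff),
                 numeric(1L))
  best <- which.min(errs)  # smallest T attaining the minimum
  structure(
    list(optimal_T = grid[best],
         min_error_ratio = errs[best],
         grid_step = diff(rng) / grid_steps,
         errors_by_T = data.frame(T = grid, error_ratio = errs),
         ddh_cutoff = ddh_cutoff,
         records = records,
         n = nrow(records),
         call = match.call()),
    class = "ggd_threshold")
}

#' @export
print.ggd_threshold <- function(x, digits = 6, ...) {
  cat("GGD species-delineation threshold (DDH cutoff ", x$ddh_cutoff,
      "%)\n", sep = "")
  cat("  n pairs:          ", x$n, "\n", sep = "")
  cat("  optimal T:        ", format(x$optimal_T, digits = digits), "\n", sep = "")
  cat("  min error ratio:  ", format(x$min_error_ratio, digits = digits),
      "\n", sep = "")
  invisible(x)
}

#' @method summary ggd_threshold
#' @export
summary.ggd_threshold <- function(object, ...) {
  same <- object$records$ddh >= object$ddh_cutoff
  pred_same <- object$records$ggd <= object$optimal_T
  out <- list(
    fit = object,
    n = object$n,
    n_same_species = sum(same),
    n_diff_species = sum(!same),
    false_positives = sum(pred_same & !same),
    false_negatives = sum(!pred_same & same),
    prevalence_bound = min(mean(same), 1 - mean(same)))
  class(out) <- "summary.ggd_threshold"
  out
}

#' @export
print.summary.ggd_threshold <- function(x, ...) {
  print(x$fit)
  cat("  pairs with DDH >= cutoff: ", x$n_same_species,
      "; below: ", x$n_diff_species, "\n", sep = "")
  cat("  false positives: ", x$false_positives,
      "; false negatives: ", x$false_negatives, "\n", sep = "")
  cat("  trivial one-class error bound: ",
      format(x$prevalence_bound), "\n", sep = "")
  invisible(x)
}

#' @method coef ggd_threshold
#' @export
coef.ggd_threshold <- function(object, ...) {
  c(optimal_T = object$optimal_T,
    min_error_ratio = object$min_error_ratio)
}

#' Predict species identity from genome-to-genome distances
#'
#' Applies the fitted (or a user-supplied) threshold: a distance at most as
#' large as the threshold predicts DDH at or above the cutoff, i.e. the two
#' genomes belong to the same species.
#'
#' @param object a \code{"ggd_threshold"} fit.
#' @param newdistance numeric vector of genome-to-genome distances.
#' @param ... unused.
#' @return factor with levels \code{same_species}, \code{different_species}.
#' @method predict ggd_threshold
#' @export
predict.ggd_threshold <- function(object, newdistance, ...) {
  predict_species_identity(newdistance, object$optimal_T)
}

#' Species call from a distance and a threshold
#' @param distance numeric vector of distances.
#' @param T threshold (e.g. 0.044, the published reference threshold for
#'   BLASTN-based distances without filtering).
#' @return factor with levels \code{same_species}, \code{different_species};
#'   \code{distance <= T} (boundary inclusive) maps to \code{same_species}.
#' @export
predict_species_identity <- function(distance, T = 0.044) {
  factor(ifelse(distance <= T, "same_species", "different_species"),
         levels = c("same_species", "different_species"))
}

#' Plot the error-ratio profile of a threshold fit
#' @param x a \code{"ggd_threshold"}.
#' @param ... passed to \code{plot.default}.
#' @return \code{x}, invisibly.
#' @method plot ggd_threshold
#' @export
plot.ggd_threshold <- function(x, ...) {
  graphics::plot(x$errors_by_T$T, x$errors_by_T$error_ratio, type = "s",
                 xlab = "distance threshold T", ylab = "error ratio", ...)
  graphics::abline(v = x$optimal_T, lty = 2)
  graphics::points(x$optimal_T, x$min_error_ratio, pch = 19)
  invisible(x)
}

#' Exhaustive threshold scan (compatibility wrapper)
#'
#' Functional interface returning the same fit as
#' \code{\link{ggd_threshold}}.
#' @inheritParams ggd_threshold
#' @return a \code{"ggd_threshold"} object.
#' @export
optimal_threshold <- function(records, ddh_cutoff = 70, grid_steps = 1000L) {
  ggd_threshold(records, ddh_cutoff = ddh_cutoff, grid_steps = grid_steps)
}
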