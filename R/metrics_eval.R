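#' Evaluation metrics
#'
#' Regression quality is reported as MSE, concordance index (CI), the
#' modified determination coefficient rm-squared, and Pearson / Spearman
#' correlations; docking-pose ranking as the Top1 success rate (fraction of
#' complexes whose best-scored pose lies within 2.0 Angstrom of the native
#' pose).
#'
#' @name metrics_eval
NULL

#' Mean squared error
#' @param y,yhat Equal-length numeric vectors.
#' @return `mean((y - yhat)^2)`.
#' @export
mse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    ap_abort("mse needs equal-length non-empty vectors", "affipose_invalid_input")
  }
  mean((y - yhat)^2)
}

#' Concordance index
#'
#' Over all pairs with `y_i > y_j`: credit 1 when `yhat_i > yhat_j`, 0.5 on a
#' prediction tie, 0 otherwise; the denominator counts only strictly-ordered
#' label pairs.
#'
#' @param y,yhat Numeric vectors, length >= 2.
#' @return CI in \[0, 1\].
#' @export
concordance_index <- function(y, yhat) {
  n <- length(y)
  if (n < 2 || length(yhat) != n) {
    ap_abort("concordance index needs n >= 2", "affipose_invalid_input")
  }
  dy <- outer(y, y, `-`)
  comp <- dy > 0
  Z <- sum(comp)
  if (Z == 0) {
    ap_abort("all labels tied; concordance index undefined",
             "affipose_undefined_metric")
  }
  dyh <- outer(yhat, yhat, `-`)
  credit <- (dyh > 0) + 0.5 * (dyh == 0)
  sum(credit[comp]) / Z
}

#' Modified determination coefficient rm-squared
#'
#' `rm2 = R2 * (1 - sqrt(R2 - R02))` with `R2` the squared Pearson
#' correlation of (y, yhat) and `R02` the determination coefficient of the
#' least-squares fit `yhat = k * y` through the origin. A negative radicand
#' (degenerate fits) is clipped to zero, giving `rm2 = R2`, and flagged via
#' the `"clipped"` attribute.
#'
#' @param y,yhat Numeric vectors, length >= 3, both with nonzero variance.
#' @return rm-squared (attribute `clipped` marks the degenerate case).
#' @export
rm_squared <- function(y, yhat) {
  if (length(y) < 3 || length(yhat) != length(y)) {
    ap_abort("rm_squared needs n >= 3", "affipose_invalid_input")
  }
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    ap_abort("zero variance; rm_squared undefined", "affipose_undefined_metric")
  }
  r2 <- stats::cor(y, yhat)^2
  k <- sum(y * yhat) / sum(y^2)
  r02 <- 1 - sum((yhat - k * y)^2) / sum((yhat - mean(yhat))^2)
  rad <- r2 - r02
  clipped <- rad < 0
  if (clipped) rad <- 0
  out <- r2 * (1 - sqrt(rad))
  attr(out, "clipped") <- clipped
  out
}

#' Pearson correlation coefficient
#' @param y,yhat Numeric vectors with nonzero variance.
#' @export
pearson <- function(y, yhat) {
  if (length(y) < 2) ap_abort("pearson needs n >= 2", "affipose_invalid_input")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    ap_abort("zero variance; correlation undefined", "affipose_undefined_metric")
  }
  stats::cor(y, yhat, method = "pearson")
}

#' Spearman correlation coefficient (average-rank tie handling)
#' @param y,yhat Numeric vectors.
#' @export
spearman <- function(y, yhat) {
  if (length(y) < 2) ap_abort("spearman needs n >= 2", "affipose_invalid_input")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    ap_abort("zero variance; correlation undefined", "affipose_undefined_metric")
  }
  stats::cor(y, yhat, method = "spearman")
}

NEAR_NATIVE_RMSD <- 2.0  # Angstrom (0.2 nm)

#' Top1 docking success rate
#'
#' Per complex, the pose with the lowest predicted RMSD score is selected
#' (ties broken by lowest pose index); the complex is a success iff that
#' pose's true RMSD is at most 2.0 Angstrom (inclusive).
#'
#' @param pose_sets Named list; each element a data.frame/list with
#'   `predicted_score` and `true_rmsd` vectors (one entry per pose).
#' @return List with `rate`, and `per_complex` data.frame (complex id, picked
#'   pose index, its true RMSD, success flag).
#' @export
top1_success_rate <- function(pose_sets) {
  if (length(pose_sets) == 0) {
    ap_abort("no pose sets supplied", "affipose_invalid_input")
  }
  ids <- names(pose_sets) %||% as.character(seq_along(pose_sets))
  rows <- lapply(seq_along(pose_sets), function(k) {
    ps <- pose_sets[[k]]
    if (length(ps$predicted_score) == 0) {
      ap_abort(sprintf("complex '%s' has an empty pose set", ids[k]),
               "affipose_invalid_input")
    }
    best <- which.min(ps$predicted_score)  # first minimum = lowest index
    data.frame(complex_id = ids[k],
               top1_pose = best,
               true_rmsd = ps$true_rmsd[best],
               success = ps$true_rmsd[best] <= NEAR_NATIVE_RMSD,
               stringsAsFactors = FALSE)
  })
  per_complex <- do.call(rbind, rows)
  list(rate = mean(per_complex$success), per_complex = per_complex)
}

#' Bundle every applicable metric for an evaluation run
#'
#' Metrics whose inputs are absent (e.g. no pose labels) are omitted from the
#' report rather than reported as zero.
#'
#' @param y,yhat Affinity labels / predictions (optional).
#' @param pose_sets Pose sets for [top1_success_rate()] (optional).
#' @return A `metric_report` list with an `n` field.
#' @export
evaluate_metrics <- function(y = NULL, yhat = NULL, pose_sets = NULL) {
  rep <- list()
  if (!is.null(y) && !is.null(yhat)) {
    keep <- !is.na(y) & !is.na(yhat)
    y <- y[keep]; yhat <- yhat[keep]
    rep$n <- length(y)
    if (length(y) >= 1) rep$mse <- mse(y, yhat)
    if (length(y) >= 2 && stats::sd(y) > 0) {
      rep$ci <- concordance_index(y, yhat)
      if (stats::sd(yhat) > 0) {
        rep$pcc <- pearson(y, yhat)
        rep$scc <- spearman(y, yhat)
        if (length(y) >= 3) rep$rm2 <- as.numeric(rm_squared(y, yhat))
      }
    }
  }
  if (!is.null(pose_sets)) {
    t1 <- top1_success_rate(pose_sets)
    rep$top1_success_rate <- t1$rate
    attr(rep, "per_complex") <- t1$per_complex
  }
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, format(x[[nm]], digits = 4)))
  }
  invisible(x)
}

#' Write a metric report as JSON (plus per-complex TSV when available)
#'
#' @param report A `metric_report`.
#' @param json_path Output JSON file.
#' @param tsv_path Optional per-complex TSV (complex id, top1 pose, true
#'   RMSD, success flag).
#' @export
write_metric_report <- function(report, json_path, tsv_path = NULL) {
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE, digits = NA)
  pc <- attr(report, "per_complex")
  if (!is.null(tsv_path) && !is.null(pc)) {
    utils::write.table(pc, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
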