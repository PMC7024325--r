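#' Fit a precision-calibrated consensus model
#'
#' `pcc()` is the package's central fitting function.  Given a boolean
#' compound-by-model match matrix for a labelled calibration set, it
#' estimates every pharmacophore model's activity probability as its
#' precision (actives retrieved / total retrieved) and returns a fitted
#' consensus object that can score and rank new compound libraries with
#' [predict.pcc()].
#'
#' Each model may exclude its own training compounds from calibration via
#' `exclusions`, so different models can legally have different
#' calibration universes.  Per-class match rates (sensitivity on actives,
#' false-positive rate on inactives) are also recorded; they drive
#' [simulate.pcc()].
#'
#' @param matches Logical match matrix (compounds x models, dimnames
#'   required) on the calibration set.
#' @param labels Named `"active"`/`"inactive"` vector (or data.frame with
#'   `compound_id`, `label`) covering every matrix row.
#' @param exclusions Optional per-model calibration exclusions; see
#'   [compute_precision_table()].
#' @param scheme Default consensus scheme for `predict()`: `"max"`,
#'   `"mean"` or `"cha"`.
#' @param denominator Default Mean-scheme denominator; see [score_mean()].
#' @return An object of class `"pcc"` with components `precision_table`,
#'   `model_ids`, `n_active`, `n_inactive`, `sensitivity`, `fpr`,
#'   `scheme`, `denominator`, `call`.
#' @seealso [predict.pcc()], [coef.pcc()], [simulate.pcc()],
#'   [evaluate_ranking()]
#' @examples
#' design <- synthetic_design(n_active = 200, n_inactive = 600,
#'                            sensitivity = c(0.8, 0.4),
#'                            fpr = c(0.02, 0.3))
#' bench <- generate_match_benchmark(design, seed = 7)
#' fit <- pcc(bench$calibration$matches, bench$calibration$labels)
#' coef(fit)
#' ranked <- predict(fit, bench$test$matches)
#' head(ranked)
#' @export
pcc <- function(matches, labels, exclusions = NULL,
                scheme = c("max", "mean", "cha"),
                denominator = c("total", "matched")) {
  scheme <- match.arg(scheme)
  denominator <- match.arg(denominator)
  matches <- .ps_check_matrix(matches)
  labels <- as_label_vector(labels)
  table <- compute_precision_table(matches, labels, exclusions)
  labels <- labels[rownames(matches)]
  active <- labels == "active"
  n_a <- sum(active)
  n_i <- sum(!active)
  sens <- if (n_a) colMeans(matches[active, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, ncol(matches)), colnames(matches))
  fpr <- if (n_i) colMeans(matches[!active, , drop = FALSE]) else
    stats::setNames(rep(NA_real_, ncol(matches)), colnames(matches))
  structure(
    list(precision_table = table, model_ids = colnames(matches),
         n_active = n_a, n_inactive = n_i,
         sensitivity = sens, fpr = fpr,
         scheme = scheme, denominator = denominator,
         call = match.call()),
    class = "pcc"
  )
}

#' @export
print.pcc <- function(x, ...) {
  cat("Precision-calibrated consensus of pharmacophore models\n\n")
  cat("Call:  ", deparse(x$call), "\n\n")
  cat(sprintf("Models: %d   Calibration set: %d active / %d inactive\n",
              length(x$model_ids), x$n_active, x$n_inactive))
  p <- x$precision_table$precision
  cat(sprintf("Precision: defined for %d model(s); range %s\n",
              sum(!is.na(p)),
              if (any(!is.na(p)))
                paste(format(range(p, na.rm = TRUE), digits = 3), collapse = " - ")
              else "-"))
  cat(sprintf("Default scheme: %s\n", x$scheme))
  invisible(x)
}

#' Model-wise activity probabilities of a fitted consensus
#'
#' @param object A [pcc()] fit.
#' @param ... Unused.
#' @return Named numeric vector of calibration precisions (`NA` where a
#'   model retrieved no calibration compound).
#' @export
coef.pcc <- function(object, ...) {
  stats::setNames(object$precision_table$precision, object$model_ids)
}

#' @export
summary.pcc <- function(object, ...) {
  tab <- object$precision_table
  tab$sensitivity <- unname(object$sensitivity[tab$model_id])
  tab$fpr <- unname(object$fpr[tab$model_id])
  structure(list(table = tab, n_active = object$n_active,
                 n_inactive = object$n_inactive, scheme = object$scheme,
                 call = object$call),
            class = "summary.pcc")
}

#' @export
print.summary.pcc <- function(x, digits = 3, ...) {
  cat("Precision-calibrated consensus -- calibration summary\n\n")
  cat(sprintf("Calibration set: %d active / %d inactive compounds\n\n",
              x$n_active, x$n_inactive))
  tab <- x$table
  tab$precision <- round(tab$precision, digits)
  tab$sensitivity <- round(tab$sensitivity, digits)
  tab$fpr <- round(tab$fpr, digits)
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("\nDefault scheme: %s\n", x$scheme))
  invisible(x)
}

#' Score a new library with a fitted consensus
#'
#' Applies the fitted per-model probabilities to a new match matrix and
#' returns the library ranked by consensus score (see [rank_library()]).
#' Columns of `newdata` must be a subset of the fitted model set; scoring
#' uses the calibration precisions, never the new labels.
#'
#' @param object A [pcc()] fit.
#' @param newdata Logical match matrix for the library to score.
#' @param scheme,denominator Override the fit's defaults.
#' @param type `"library"` (default) returns the ranked
#'   `scored_library`; `"score"` returns a named score vector in
#'   `newdata` row order.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.pcc <- function(object, newdata, scheme = object$scheme,
                        denominator = object$denominator,
                        type = c("library", "score"), ...) {
  type <- match.arg(type)
  newdata <- .ps_check_matrix(newdata)
  unknown <- setdiff(colnames(newdata), object$model_ids)
  if (length(unknown))
    stop_validation(sprintf("newdata has model(s) absent from the fit: %s",
                            paste(unknown, collapse = ", ")))
  ranked <- rank_library(newdata, object$precision_table, scheme = scheme,
                         denominator = denominator)
  if (type == "library") return(ranked)
  stats::setNames(ranked$score[match(rownames(newdata), ranked$compound_id)],
                  rownames(newdata))
}

#' Simulate labelled match matrices from a fitted consensus
#'
#' Draws Bernoulli match matrices using the fitted per-class match rates
#' (sensitivity for actives, false-positive rate for inactives), i.e.
#' parametric-bootstrap replicates of the calibration experiment.
#'
#' @param object A [pcc()] fit.
#' @param nsim Number of replicate matrices.
#' @param seed Optional integer seed.
#' @param n_active,n_inactive Class sizes; default the calibration sizes.
#' @param ... Unused.
#' @return A list of length `nsim`; each element has `matches` (logical
#'   matrix) and `labels` (named vector).
#' @export
simulate.pcc <- function(object, nsim = 1, seed = NULL,
                         n_active = object$n_active,
                         n_inactive = object$n_inactive, ...) {
  if (any(is.na(object$sensitivity)) || any(is.na(object$fpr)))
    stop_degenerate("cannot simulate: calibration set lacked one class entirely")
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE, {
    .ps_draw_labelled_matrix(n_active, n_inactive, object$sensitivity,
                             object$fpr, object$model_ids)
  })
}

#' Plot a fitted consensus
#'
#' Bar plot of per-model calibration precisions, sorted decreasingly;
#' undefined precisions are shown as zero-height bars marked `NA`.
#'
#' @param x A [pcc()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @method plot pcc
#' @export
plot.pcc <- function(x, ...) {
  p <- coef(x)
  ord <- order(-replace(p, is.na(p), -Inf))
  shown <- replace(p, is.na(p), 0)[ord]
  bp <- graphics::barplot(shown, ylim = c(0, 1), las = 2,
                          ylab = "calibration precision  P(Y|x)",
                          main = "Per-model activity probability", ...)
  nai <- which(is.na(p[ord]))
  if (length(nai)) graphics::text(bp[nai], 0.02, "NA", srt = 90, adj = 0)
  invisible(x)
}
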