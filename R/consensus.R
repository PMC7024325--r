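# Consensus scoring: combine per-model activity probabilities (their
# calibration precisions) into one per-compound probability.  Undefined
# precisions (models that retrieved nothing on calibration) contribute 0
# in every scheme -- no evidence of precision is treated as no evidence of
# activity.  Compounds matching no model score 0 in every scheme.

.ps_precision_lookup <- function(table) {
  if (!inherits(table, "precision_table"))
    stop_argument("'table' must be a precision_table")
  p <- table$precision
  p[is.na(p)] <- 0
  stats::setNames(p, table$model_id)
}

.ps_matched_precisions <- function(matched_ids, lookup) {
  unknown <- setdiff(matched_ids, names(lookup))
  if (length(unknown))
    stop_validation(sprintf("model id(s) not in precision table: %s",
                            paste(unknown, collapse = ", ")))
  lookup[matched_ids]
}

#' Consensus activity probability: Max scheme
#'
#' The compound's activity probability is the largest precision among the
#' models it matches.  With every precision forced to 1 this reduces to
#' the OR-consensus selection rule (any positive score = any match).  An
#' empty match profile scores 0.
#'
#' @param matched_ids Character vector of matched model ids (possibly
#'   empty).
#' @param table A [compute_precision_table()] result covering all matched
#'   ids.
#' @return Score in \[0,1\].
#' @export
score_max <- function(matched_ids, table) {
  lookup <- .ps_precision_lookup(table)
  p <- .ps_matched_precisions(matched_ids, lookup)
  if (!length(p)) 0 else max(p)
}

#' Consensus activity probability: Mean scheme
#'
#' The sum of the matched models' precisions divided by `model_set_size`
#' (the total number of models in the set; the default denominator) or by
#' the number of matched models (`denominator = "matched"`).  With every
#' precision forced to 1 and the total denominator, the score equals the
#' matched fraction, i.e. the common-hits approach.  An empty profile
#' scores 0.
#'
#' @inheritParams score_max
#' @param model_set_size Total number of models in the set; must be at
#'   least the number of matched ids.
#' @param denominator `"total"` (default) or `"matched"`.
#' @return Score in \[0,1\].
#' @export
score_mean <- function(matched_ids, table, model_set_size,
                       denominator = c("total", "matched")) {
  denominator <- match.arg(denominator)
  if (!is_count(model_set_size, min = 1L))
    stop_argument("'model_set_size' must be a positive integer")
  if (model_set_size < length(matched_ids))
    stop_argument("'model_set_size' smaller than the number of matched models")
  lookup <- .ps_precision_lookup(table)
  p <- .ps_matched_precisions(matched_ids, lookup)
  if (!length(p)) return(0)
  if (denominator == "total") sum(p) / model_set_size else mean(p)
}

#' Consensus score: common-hits approach (CHA)
#'
#' The fraction of models the compound matches; all models weigh equally,
#' no calibration involved.
#'
#' @inheritParams score_mean
#' @return Score in \[0,1\].
#' @export
score_cha <- function(matched_ids, model_set_size) {
  if (!is_count(model_set_size, min = 1L))
    stop_argument("'model_set_size' must be a positive integer")
  if (model_set_size < length(matched_ids))
    stop_argument("'model_set_size' smaller than the number of matched models")
  length(matched_ids) / model_set_size
}

#' Pooled consensus scores (comparison only)
#'
#' Geometric mean, harmonic mean and product pooling of matched
#' precisions.  These poolings are dominated by the weakest matched model
#' -- a single near-zero precision drags the score to zero -- which is the
#' opposite of the robustness to poor models that consensus screening
#' needs.  They are provided only for side-by-side comparison and are
#' never used by [rank_library()] or [predict.pcc()].
#'
#' @inheritParams score_max
#' @param method One of `"geometric"`, `"harmonic"`, `"product"`.
#' @return Score in \[0,1\]; 0 for an empty profile.
#' @export
score_pooled <- function(matched_ids, table,
                         method = c("geometric", "harmonic", "product")) {
  method <- match.arg(method)
  lookup <- .ps_precision_lookup(table)
  p <- .ps_matched_precisions(matched_ids, lookup)
  if (!length(p)) return(0)
  switch(method,
         geometric = exp(mean(log(pmax(p, .Machine$double.xmin)))) *
           (if (any(p == 0)) 0 else 1),
         harmonic = if (any(p == 0)) 0 else length(p) / sum(1 / p),
         product = prod(p))
}

#' OR-consensus hit selection
#'
#' The set of compounds matching at least one retained model.  This is a
#' selection, not a ranking: the returned ids carry no order information
#' (they are reported in matrix row order purely for reproducibility).
#' With no retained model the hit set is empty.
#'
#' @param matches Logical match matrix with dimnames.
#' @param retained_model_ids Character vector of model ids (columns) to
#'   consider.
#' @return Character vector of hit compound ids.
#' @export
select_or_consensus <- function(matches, retained_model_ids) {
  matches <- .ps_check_matrix(matches)
  unknown <- setdiff(retained_model_ids, colnames(matches))
  if (length(unknown))
    stop_validation(sprintf("unknown model id(s): %s",
                            paste(unknown, collapse = ", ")))
  if (!length(retained_model_ids)) return(character(0))
  hit <- rowSums(matches[, retained_model_ids, drop = FALSE]) > 0
  rownames(matches)[hit]
}

#' Score and rank a screened library
#'
#' Scores every compound of a match matrix under one consensus scheme and
#' returns the library in descending-score order.  Ties are broken by
#' input (matrix row) order -- a stable, deterministic rule -- so repeated
#' runs give identical rankings.
#'
#' @param matches Logical match matrix with dimnames.
#' @param table Precision table covering all matrix columns (not needed
#'   for `scheme = "cha"`).
#' @param scheme `"max"`, `"mean"` or `"cha"`.
#' @param denominator Mean-scheme denominator, see [score_mean()].
#' @return A data.frame of class `"scored_library"` with columns
#'   `compound_id`, `scheme`, `score`, `rank`, `n_models_matched`,
#'   `matched_model_ids` (semicolon-joined), ordered by rank.
#' @export
rank_library <- function(matches, table = NULL,
                         scheme = c("max", "mean", "cha"),
                         denominator = c("total", "matched")) {
  scheme <- match.arg(scheme)
  denominator <- match.arg(denominator)
  matches <- .ps_check_matrix(matches)
  mids <- colnames(matches)
  s <- ncol(matches)
  if (scheme != "cha") {
    if (is.null(table)) stop_argument("'table' is required for this scheme")
    lookup <- .ps_precision_lookup(table)
    unknown <- setdiff(mids, names(lookup))
    if (length(unknown))
      stop_validation(sprintf("model id(s) not in precision table: %s",
                              paste(unknown, collapse = ", ")))
    pvec <- lookup[mids]
  }
  score <- numeric(nrow(matches))
  nmatch <- rowSums(matches)
  for (i in seq_len(nrow(matches))) {
    hit <- matches[i, ]
    score[i] <- switch(scheme,
      max = if (any(hit)) max(pvec[hit]) else 0,
      mean = if (any(hit)) {
        if (denominator == "total") sum(pvec[hit]) / s else mean(pvec[hit])
      } else 0,
      cha = sum(hit) / s)
  }
  ord <- order(-score)  # stable: ties keep input order
  out <- data.frame(
    compound_id = rownames(matches)[ord],
    scheme = scheme,
    score = score[ord],
    rank = seq_along(ord),
    n_models_matched = as.integer(nmatch[ord]),
    matched_model_ids = vapply(ord, function(i)
      paste(mids[matches[i, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("scored_library", "data.frame")
  out
}

#' @export
print.scored_library <- function(x, n = 10L, ...) {
  cat(sprintf("Scored library: %d compounds, scheme '%s'\n", nrow(x),
              x$scheme[1] %||% "?"))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' @rdname rank_library
#' @param ranked A `scored_library`.
#' @param path Output CSV path.
#' @export
write_scored_library <- function(ranked, path) {
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
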