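#' Assign activity classes from log-affinity values
#'
#' Compounds are attributed to the active class when their affinity, on
#' the negative log-molar scale, reaches the threshold (boundary
#' included), and to the inactive class otherwise.  The conventional
#' threshold of 6 log units (1 uM) is the default but is a study choice,
#' not a constant.
#'
#' @param affinity_log Numeric vector of -log10 molar affinities.
#' @param threshold Activity threshold in log units; default 6.
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
assign_activity_class <- function(affinity_log, threshold = 6.0) {
  if (!is.numeric(affinity_log) || any(!is.finite(affinity_log)))
    stop_argument("'affinity_log' must be finite numeric")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop_argument("'threshold' must be a single finite number")
  ifelse(affinity_log >= threshold, "active", "inactive")
}

#' Remove structures with conflicting activity labels
#'
#' Duplicated structures (same structure key, e.g. a canonical SMILES
#' supplied by the caller) that occur with both the active and the
#' inactive label are removed entirely; duplicates within one class are
#' collapsed to a single record.  A removal log reports every dropped
#' record with its reason.
#'
#' @param records A data.frame with columns `compound_id`, `label`
#'   (`"active"`/`"inactive"`) and `structure_key`.
#' @return A list with elements `records` (the filtered data.frame) and
#'   `removed` (data.frame `compound_id`, `structure_key`, `reason`).
#' @export
remove_conflicting_duplicates <- function(records) {
  need <- c("compound_id", "label", "structure_key")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_validation("records must have columns compound_id, label, structure_key")
  if (any(is.na(records$structure_key) | !nzchar(records$structure_key)))
    stop_validation("every record needs a non-empty structure_key")
  bad <- setdiff(unique(records$label), c("active", "inactive"))
  if (length(bad)) stop_validation("labels must be 'active' or 'inactive'")
  if (nrow(records) == 0L) {
    return(list(records = records,
                removed = data.frame(compound_id = character(0),
                                     structure_key = character(0),
                                     reason = character(0))))
  }
  n_lab <- tapply(records$label, records$structure_key,
                  function(x) length(unique(x)))
  conflicted <- names(n_lab)[n_lab > 1]
  is_conflict <- records$structure_key %in% conflicted
  keep_first <- !duplicated(records$structure_key) & !is_conflict
  reason <- ifelse(is_conflict, "conflicting labels", "within-class duplicate")
  removed <- data.frame(compound_id = records$compound_id[!keep_first],
                        structure_key = records$structure_key[!keep_first],
                        reason = reason[!keep_first],
                        stringsAsFactors = FALSE)
  out <- records[keep_first, , drop = FALSE]
  rownames(out) <- NULL
  rownames(removed) <- NULL
  list(records = out, removed = removed)
}

#' Per-model precision on a labelled calibration set
#'
#' For each model, counts the labelled compounds it retrieves and the
#' actives among them, and estimates the model's activity probability as
#' precision = actives retrieved / total retrieved.  A model retrieving
#' nothing has undefined precision, recorded as `NA`; downstream
#' consensus treats such models as contributing probability zero (no
#' evidence of precision), and precision filters drop them.
#'
#' Each model may have its own calibration universe: compounds in a
#' model's exclusion set (typically its training compounds) are ignored
#' for that model only.
#'
#' @param matches Logical match matrix (compounds x models) with
#'   dimnames.
#' @param labels Named character vector (or data.frame with
#'   `compound_id`, `label`) labelling every matrix row as
#'   `"active"`/`"inactive"`.
#' @param exclusions Optional; either a named list mapping model_id to a
#'   character vector of compound ids, or a data.frame with columns
#'   `model_id`, `compound_id`.
#' @return A data.frame of class `"precision_table"` with columns
#'   `model_id`, `n_retrieved`, `n_active_retrieved`, `precision`.
#' @export
compute_precision_table <- function(matches, labels, exclusions = NULL) {
  matches <- .ps_check_matrix(matches)
  labels <- as_label_vector(labels)
  missing <- setdiff(rownames(matches), names(labels))
  if (length(missing))
    stop_validation(sprintf("unlabelled compounds in match matrix: %s",
                            paste(utils::head(missing, 5), collapse = ", ")))
  labels <- labels[rownames(matches)]
  exclusions <- .ps_check_exclusions(exclusions, rownames(matches),
                                     colnames(matches))
  active <- labels == "active"
  mids <- colnames(matches)
  n_ret <- integer(length(mids))
  n_act <- integer(length(mids))
  for (j in seq_along(mids)) {
    use <- rep(TRUE, nrow(matches))
    excl <- exclusions[[mids[j]]]
    if (!is.null(excl)) use[rownames(matches) %in% excl] <- FALSE
    hit <- matches[use, j]
    n_ret[j] <- sum(hit)
    n_act[j] <- sum(hit & active[use])
  }
  out <- data.frame(model_id = mids, n_retrieved = n_ret,
                    n_active_retrieved = n_act,
                    precision = ifelse(n_ret > 0, n_act / n_ret, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("precision_table", "data.frame")
  out
}

.ps_check_matrix <- function(matches) {
  if (!is.matrix(matches) || is.null(rownames(matches)) || is.null(colnames(matches)))
    stop_validation("'matches' must be a matrix with compound/model dimnames")
  storage.mode(matches) <- "logical"
  if (anyDuplicated(rownames(matches)) || anyDuplicated(colnames(matches)))
    stop_validation("duplicate ids in match matrix dimnames")
  matches
}

.ps_check_exclusions <- function(exclusions, compound_ids, model_ids) {
  if (is.null(exclusions)) return(list())
  if (is.data.frame(exclusions)) {
    if (!all(c("model_id", "compound_id") %in% names(exclusions)))
      stop_validation("exclusions data.frame needs model_id and compound_id columns")
    exclusions <- split(as.character(exclusions$compound_id),
                        as.character(exclusions$model_id))
  }
  bad_m <- setdiff(names(exclusions), model_ids)
  if (length(bad_m))
    stop_validation(sprintf("exclusions reference unknown model(s): %s",
                            paste(bad_m, collapse = ", ")))
  bad_c <- setdiff(unique(unlist(exclusions)), compound_ids)
  if (length(bad_c))
    stop_validation(sprintf("exclusions reference unknown compound(s): %s",
                            paste(utils::head(bad_c, 5), collapse = ", ")))
  exclusions
}

#' Filter a model set by precision and complexity
#'
#' Retains models whose calibration precision is strictly greater than
#' `min_precision` ("larger than": a model at exactly the threshold is
#' dropped) and whose number of features with distinct coordinates is at
#' least `min_distinct_features`.  Models with undefined precision are
#' dropped whenever a precision threshold is active.  An empty result is
#' legal: with no model retained, downstream selection is empty and
#' enrichment drops to zero.
#'
#' @param table A [compute_precision_table()] result.
#' @param models Optional named list of [pharmacophore()] models; required
#'   when `min_distinct_features` is given.
#' @param min_precision Precision threshold in \[0,1\], or `NULL` to skip.
#' @param min_distinct_features Minimum number of features with distinct
#'   coordinates (>= 1), or `NULL` to skip.
#' @return Character vector of retained model ids, in table order.
#' @export
filter_models <- function(table, models = NULL, min_precision = NULL,
                          min_distinct_features = NULL) {
  if (!inherits(table, "precision_table"))
    stop_argument("'table' must be a precision_table")
  keep <- rep(TRUE, nrow(table))
  if (!is.null(min_precision)) {
    if (!is_prob(min_precision) || length(min_precision) != 1L)
      stop_argument("'min_precision' must be a single value in [0,1]")
    keep <- keep & !is.na(table$precision) & table$precision > min_precision
  }
  if (!is.null(min_distinct_features)) {
    if (!is_count(min_distinct_features, min = 1L))
      stop_argument("'min_distinct_features' must be an integer >= 1")
    if (is.null(models))
      stop_argument("'models' is required to filter on distinct feature count")
    mids <- vapply(models, function(m) m$model_id, character(1))
    missing <- setdiff(table$model_id, mids)
    if (length(missing))
      stop_validation(sprintf("models missing for ids: %s",
                              paste(missing, collapse = ", ")))
    counts <- vapply(models, count_distinct_features, integer(1))[
      match(table$model_id, mids)]
    keep <- keep & counts >= min_distinct_features
  }
  table$model_id[keep]
}

#' Read / write helpers for calibration files
#'
#' `read_labels()` reads a CSV with a `compound_id` column and either a
#' `label` column (`active`/`inactive`) or an `affinity_log` column, in
#' which case classes are assigned at `threshold` via
#' [assign_activity_class()].  `read_exclusions()` reads a two-column CSV
#' `model_id`, `compound_id`.  `write_precision_table()` writes the
#' four-column precision table, with an empty cell for undefined
#' precision.
#'
#' @param path File path.
#' @param threshold Activity threshold used when labels are derived from
#'   `affinity_log`.
#' @return `read_labels()`: named character vector of labels;
#'   `read_exclusions()`: named list of compound-id vectors.
#' @export
read_labels <- function(path, threshold = 6.0) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"compound_id" %in% names(df))
    stop_validation("labels file needs a 'compound_id' column")
  if ("label" %in% names(df)) {
    lab <- df$label
  } else if ("affinity_log" %in% names(df)) {
    lab <- assign_activity_class(df$affinity_log, threshold)
  } else {
    stop_validation("labels file needs a 'label' or 'affinity_log' column")
  }
  as_label_vector(stats::setNames(lab, df$compound_id))
}

#' @rdname read_labels
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("model_id", "compound_id") %in% names(df)))
    stop_validation("exclusions file needs model_id and compound_id columns")
  split(as.character(df$compound_id), as.character(df$model_id))
}

#' @rdname read_labels
#' @param table A precision table.
#' @export
write_precision_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_labels
#' @export
read_precision_table <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("model_id", "n_retrieved", "n_active_retrieved", "precision")
  if (!all(need %in% names(df)))
    stop_validation("precision table file lacks required columns")
  df$precision <- as.numeric(df$precision)
  class(df) <- c("precision_table", "data.frame")
  df
}

#' @export
print.precision_table <- function(x, ...) {
  cat(sprintf("Precision table: %d model(s), %d with defined precision\n",
              nrow(x), sum(!is.na(x$precision))))
  print.data.frame(x, ...)
  invisible(x)
}
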