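#' Construct a pharmacophore model
#'
#' A pharmacophore model is an ordered set of typed feature points in 3D
#' space, identified by a unique `model_id`.
#'
#' @param model_id Unique identifier string.
#' @param features A data.frame with columns `type` (one of
#'   [feature_types()]), `x`, `y`, `z` (coordinates in Angstrom); at least
#'   one row.
#' @param meta Optional free-form provenance list.
#' @return An object of class `"pharmacophore"`.
#' @export
pharmacophore <- function(model_id, features, meta = list()) {
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id))
    stop_validation("'model_id' must be a non-empty string")
  features <- validate_feature_set(features)
  if (nrow(features) == 0L)
    stop_validation("a pharmacophore model needs at least one feature")
  structure(list(model_id = model_id, features = features, meta = meta),
            class = "pharmacophore")
}

validate_feature_set <- function(features) {
  if (!is.data.frame(features) || !all(c("type", "x", "y", "z") %in% names(features)))
    stop_validation("features must be a data.frame with columns type, x, y, z")
  features$type <- as.character(features$type)
  bad <- setdiff(unique(features$type), feature_types())
  if (length(bad))
    stop_validation(sprintf("unknown feature type(s): %s",
                            paste(bad, collapse = ", ")))
  coords <- as.matrix(features[, c("x", "y", "z")])
  storage.mode(coords) <- "double"
  if (nrow(coords) && any(!is.finite(coords)))
    stop_validation("feature coordinates must be finite")
  data.frame(type = features$type, x = coords[, 1], y = coords[, 2],
             z = coords[, 3], stringsAsFactors = FALSE)
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat(sprintf("Pharmacophore model '%s' (%d features, %d with distinct coordinates)\n",
              x$model_id, nrow(x$features), count_distinct_features(x)))
  tab <- table(x$features$type)
  cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Construct a compound's conformer set
#'
#' All conformers of a compound -- across enumerated stereoisomers --
#' are pooled into a single set: a compound matches a model if any one of
#' its conformers does.  A compound with no conformers matches nothing.
#'
#' @param compound_id Unique identifier string.
#' @param conformers A list of feature data.frames (columns `type`, `x`,
#'   `y`, `z`), one per conformer; may be empty.
#' @return An object of class `"conformer_set"`.
#' @export
conformer_set <- function(compound_id, conformers = list()) {
  if (!is.character(compound_id) || length(compound_id) != 1L)
    stop_validation("'compound_id' must be a string")
  conformers <- lapply(conformers, validate_feature_set)
  structure(list(compound_id = compound_id, conformers = conformers),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<compound '%s': %d conformer(s)>\n", x$compound_id,
              length(x$conformers)))
  invisible(x)
}

#' Count features with distinct coordinates
#'
#' Model complexity is measured as the number of features remaining after
#' collapsing features whose positions coincide.  Coincidence is
#' transitive: positions closer than `tol` are merged into one group
#' (single linkage), and each group counts once regardless of feature
#' type.
#'
#' @param model A [pharmacophore()] model.
#' @param tol Coincidence tolerance in Angstrom; positions closer than
#'   this are considered identical.  The default 0.01 A separates genuine
#'   co-location from numerical noise.
#' @return Integer count, at most the raw number of features.
#' @export
count_distinct_features <- function(model, tol = 0.01) {
  coords <- as.matrix(model$features[, c("x", "y", "z")])
  n <- nrow(coords)
  if (n <= 1L) return(n)
  d <- as.matrix(stats::dist(coords))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (d[i, j] < tol) parent[find(j)] <- find(i)
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# ---------------------------------------------------------------------------
# JSON model interchange:
#   {"model_id": "...", "features": [{"type": "HBA", "x": 1, "y": 2, "z": 3}],
#    "meta": {...}}
# A file may hold one such object or a list of them.

#' Read pharmacophore models from JSON
#'
#' @param path Path to a JSON file holding a single model object or a list
#'   of them (fields `model_id`, `features` with `type`/`x`/`y`/`z`, and
#'   optional `meta`).
#' @return A named list of [pharmacophore()] models.
#' @export
read_pharmacophores <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$model_id)) raw <- list(raw)
  models <- lapply(raw, function(obj) {
    if (is.null(obj$model_id) || is.null(obj$features))
      stop_validation("each model object needs 'model_id' and 'features'")
    feats <- do.call(rbind, lapply(obj$features, function(f) {
      data.frame(type = as.character(f$type), x = as.numeric(f$x),
                 y = as.numeric(f$y), z = as.numeric(f$z))
    }))
    pharmacophore(as.character(obj$model_id), feats, meta = obj$meta %||% list())
  })
  ids <- vapply(models, function(m) m$model_id, character(1))
  if (anyDuplicated(ids))
    stop_validation("duplicate model_id in model file")
  stats::setNames(models, ids)
}

#' Write pharmacophore models to JSON
#'
#' @param models A single model or list of [pharmacophore()] models.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophores <- function(models, path) {
  if (inherits(models, "pharmacophore")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(model_id = m$model_id,
         features = lapply(seq_len(nrow(m$features)), function(i) {
           list(type = m$features$type[i], x = m$features$x[i],
                y = m$features$y[i], z = m$features$z[i])
         }),
         meta = m$meta)
  })
  if (length(payload) == 1L) payload <- payload[[1]]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
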