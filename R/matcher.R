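#' Match a compound against a pharmacophore model
#'
#' A compound matches a model if at least one of its conformers admits an
#' injective assignment of model features to conformer features such that
#' (a) every assigned pair has the same feature type and (b) every pair of
#' assigned model features reproduces the model's inter-feature distance
#' to within `tolerance`.  This pairwise-distance correspondence needs no
#' explicit superposition and is invariant under rigid rotation and
#' translation of the conformer.  Matching is monotone in `tolerance`: a
#' match at tolerance t is a match at any larger tolerance.
#'
#' @param compound A [conformer_set()].
#' @param model A [pharmacophore()] model.
#' @param tolerance Maximum allowed absolute deviation of any pairwise
#'   distance, in Angstrom; must be positive.  Default 1.0 A.
#' @return `TRUE` or `FALSE`.
#' @export
match_model <- function(compound, model, tolerance = 1.0) {
  if (!inherits(compound, "conformer_set"))
    stop_argument("'compound' must be a conformer_set")
  if (!inherits(model, "pharmacophore"))
    stop_argument("'model' must be a pharmacophore")
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      !is.finite(tolerance) || tolerance <= 0)
    stop_argument("'tolerance' must be a positive number")
  for (conf in compound$conformers) {
    if (.ps_match_conformer(model$features, conf, tolerance)) return(TRUE)
  }
  FALSE
}

# Backtracking search over injective, type-compatible assignments with
# pairwise-distance pruning.  Model features are visited scarcest-first
# (fewest type-compatible candidates) to cut the branching factor; the
# result does not depend on the visit order.
.ps_match_conformer <- function(mfeat, cfeat, tol) {
  m <- nrow(mfeat)
  nc <- nrow(cfeat)
  if (nc < m) return(FALSE)
  cand <- lapply(mfeat$type, function(tp) which(cfeat$type == tp))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(FALSE)
  ord <- order(vapply(cand, length, integer(1)))
  dm <- as.matrix(stats::dist(mfeat[, c("x", "y", "z")]))
  dc <- as.matrix(stats::dist(cfeat[, c("x", "y", "z")]))

  assign_to <- integer(m)   # model index -> conformer index (0 = unset)
  used <- logical(nc)
  rec <- function(k) {
    if (k > m) return(TRUE)
    i <- ord[k]
    placed <- ord[seq_len(k - 1L)]
    for (j in cand[[i]]) {
      if (used[j]) next
      ok <- TRUE
      for (p in placed) {
        if (abs(dm[i, p] - dc[j, assign_to[p]]) > tol) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_to[i] <<- j
      used[j] <<- TRUE
      if (rec(k + 1L)) return(TRUE)
      used[j] <<- FALSE
      assign_to[i] <<- 0L
    }
    FALSE
  }
  rec(1L)
}

#' Build a compound-by-model boolean match matrix
#'
#' @param library A list of [conformer_set()] objects with unique
#'   compound ids.
#' @param models A list of [pharmacophore()] models with unique model ids.
#' @param tolerance Pairwise-distance tolerance passed to [match_model()].
#' @return A logical matrix with one row per compound (in input order)
#'   and one column per model (in input order), dimnames set to the ids.
#' @export
build_match_matrix <- function(library, models, tolerance = 1.0) {
  cids <- vapply(library, function(x) x$compound_id, character(1))
  mids <- vapply(models, function(x) x$model_id, character(1))
  if (anyDuplicated(cids))
    stop_validation("duplicate compound_id in library")
  if (anyDuplicated(mids))
    stop_validation("duplicate model_id in model set")
  out <- matrix(FALSE, nrow = length(cids), ncol = length(mids),
                dimnames = list(cids, mids))
  for (i in seq_along(library)) for (j in seq_along(models)) {
    out[i, j] <- match_model(library[[i]], models[[j]], tolerance)
  }
  out
}

#' Read / write a match matrix
#'
#' Exchange format: CSV (or TSV, by file extension), first column
#' `compound_id`, remaining columns named by model id, cells 0/1.
#'
#' @param path File path; `.tsv`/`.tab` extensions select tab separation.
#' @return For the reader, a logical matrix with compound ids as rownames.
#' @export
read_match_matrix <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("file not found: ", path))
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "compound_id")
    stop_validation("match matrix file must start with a 'compound_id' column")
  if (anyDuplicated(df$compound_id))
    stop_validation("duplicate compound_id in match matrix file")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- df$compound_id
  m
}

#' @rdname read_match_matrix
#' @param matches Logical match matrix with dimnames.
#' @export
write_match_matrix <- function(matches, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  df <- data.frame(compound_id = rownames(matches),
                   matches * 1L, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
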