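# Synthetic benchmarks with known ground truth.  Two generators: (1)
# Bernoulli match matrices whose per-model precisions are analytically
# known from the design, standing in for a labelled calibration/test
# corpus; (2) geometric toy fixtures -- typed 3D point sets -- with a
# recorded intended match matrix, for exercising the 3D matcher.

#' Specify a Bernoulli match-matrix design
#'
#' Each model matches actives independently with probability
#' `sensitivity[i]` and inactives with probability `fpr[i]`.  The
#' analytic expected precision of model i is then
#' s_i n_A / (s_i n_A + b_i n_I).  Matches are drawn independently
#' across models by default -- a simplification relative to real
#' pharmacophores, which share features; `latent_sd > 0` induces
#' correlation by shifting each compound's match logits by a shared
#' normal "matchability" term.
#'
#' @param n_active,n_inactive Class sizes (positive integers).
#' @param sensitivity,fpr Per-model match probabilities in \[0,1\], equal
#'   length.
#' @param latent_sd Standard deviation of the shared per-compound logit
#'   shift; 0 (default) gives independent matches.
#' @return An object of class `"synthetic_design"`.
#' @export
synthetic_design <- function(n_active, n_inactive, sensitivity, fpr,
                             latent_sd = 0) {
  if (!is_count(n_active, 1L) || !is_count(n_inactive, 1L))
    stop_argument("'n_active' and 'n_inactive' must be positive integers")
  if (length(sensitivity) != length(fpr) || !length(sensitivity))
    stop_argument("'sensitivity' and 'fpr' must have equal positive length")
  if (!is_prob(sensitivity) || !is_prob(fpr))
    stop_argument("match probabilities must lie in [0,1]")
  if (!is.numeric(latent_sd) || latent_sd < 0)
    stop_argument("'latent_sd' must be non-negative")
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive),
                 sensitivity = as.numeric(sensitivity),
                 fpr = as.numeric(fpr), latent_sd = latent_sd),
            class = "synthetic_design")
}

#' Analytic expected precision of a design
#'
#' @param design A [synthetic_design()].
#' @return Numeric vector, one expected precision per model (`NA` where
#'   the expected retrieval is zero).
#' @export
analytic_precision <- function(design) {
  num <- design$sensitivity * design$n_active
  den <- num + design$fpr * design$n_inactive
  ifelse(den > 0, num / den, NA_real_)
}

.ps_draw_labelled_matrix <- function(n_active, n_inactive, sens, fpr,
                                     model_ids, latent_sd = 0,
                                     id_prefix = c("A", "D")) {
  n <- n_active + n_inactive
  cids <- c(sprintf("%s%05d", id_prefix[1], seq_len(n_active)),
            sprintf("%s%05d", id_prefix[2], seq_len(n_inactive)))
  p <- rbind(matrix(sens, n_active, length(sens), byrow = TRUE),
             matrix(fpr, n_inactive, length(fpr), byrow = TRUE))
  if (latent_sd > 0) {
    z <- stats::rnorm(n, 0, latent_sd)
    p <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + z)
  }
  m <- matrix(stats::runif(n * length(sens)) < p, n, length(sens),
              dimnames = list(cids, model_ids))
  labels <- stats::setNames(rep(c("active", "inactive"),
                                c(n_active, n_inactive)), cids)
  list(matches = m, labels = labels)
}

#' Generate a synthetic calibration/test benchmark
#'
#' Draws two independent labelled match matrices (a calibration set and a
#' test set) from the same design, reproducibly for a fixed seed.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed; the same seed always yields the same pair of
#'   matrices.
#' @return A list with `calibration` and `test` (each `matches` +
#'   `labels`), plus `design` and `seed`.
#' @export
generate_match_benchmark <- function(design, seed = 1L) {
  if (!inherits(design, "synthetic_design"))
    stop_argument("'design' must be a synthetic_design")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_argument("'seed' must be a single integer")
  set.seed(as.integer(seed))
  mids <- sprintf("M%02d", seq_along(design$sensitivity))
  cal <- .ps_draw_labelled_matrix(design$n_active, design$n_inactive,
                                  design$sensitivity, design$fpr, mids,
                                  design$latent_sd, c("CA", "CI"))
  test <- .ps_draw_labelled_matrix(design$n_active, design$n_inactive,
                                   design$sensitivity, design$fpr, mids,
                                   design$latent_sd, c("TA", "TI"))
  list(calibration = cal, test = test, design = design,
       seed = as.integer(seed))
}

#' Write a synthetic benchmark to disk
#'
#' Emits the same CSV/JSON formats the rest of the package consumes:
#' match matrices and label files for the calibration and test splits,
#' and a manifest JSON recording the design parameters and seed.
#'
#' @param bench A [generate_match_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_match_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    calibration_matches = file.path(dir, "calibration_matches.csv"),
    calibration_labels = file.path(dir, "calibration_labels.csv"),
    test_matches = file.path(dir, "test_matches.csv"),
    test_labels = file.path(dir, "test_labels.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_match_matrix(bench$calibration$matches, paths["calibration_matches"])
  write_match_matrix(bench$test$matches, paths["test_matches"])
  for (split in c("calibration", "test")) {
    lab <- bench[[split]]$labels
    utils::write.csv(data.frame(compound_id = names(lab), label = unname(lab)),
                     paths[paste0(split, "_labels")], row.names = FALSE)
  }
  jsonlite::write_json(
    list(design = unclass(bench$design), seed = bench$seed,
         analytic_precision = analytic_precision(bench$design)),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# ---------------------------------------------------------------------------
# Geometric fixtures for the 3D matcher.

.ps_random_point_set <- function(k, dmin = 2, dmax = 10) {
  # rejection-sample k points with all pairwise distances in [dmin, dmax]
  repeat {
    pts <- matrix(stats::runif(3 * k, 0, dmax * 0.7), k, 3)
    if (k == 1L) return(pts)
    d <- stats::dist(pts)
    if (all(d >= dmin & d <= dmax)) return(pts)
  }
}

#' Generate geometric toy fixtures for the 3D matcher
#'
#' Builds `n_models` pharmacophore models as random typed point sets
#' (pairwise distances 2-10 Angstrom, each model with a distinct set of
#' feature types so cross-model matches are impossible by type), plus:
#'
#' * "active" compounds that embed one model's geometry under a random
#'   rigid motion, each point displaced by less than `tolerance / 2`
#'   (so every pairwise distance deviates by less than `tolerance`, and
#'   the intended match is guaranteed), with optional distractor
#'   features;
#' * "decoy" compounds derived from a model by stretching one
#'   inter-feature distance by more than `2 * tolerance`, which makes the
#'   (type-forced) assignment infeasible.
#'
#' The intended match matrix is returned as ground truth.
#'
#' @param n_models,n_actives,n_decoys Positive counts; `n_models` at most
#'   15 (the number of distinct 4-type subsets).
#' @param seed Integer seed.
#' @param tolerance Matching tolerance the fixtures are built for.
#' @param n_features Features per model (3-6); default 4.
#' @param noise Per-point displacement bound for actives, in Angstrom;
#'   default `tolerance / 2` (exclusive bound, sampled strictly inside).
#' @param n_distractors Extra far-away features added to each active.
#' @return A list with `models` (named list of [pharmacophore()]),
#'   `compounds` (named list of [conformer_set()]), `truth` (logical
#'   intended match matrix), `tolerance`, `seed`.
#' @export
generate_geometric_fixtures <- function(n_models, n_actives, n_decoys,
                                        seed = 1L, tolerance = 1.0,
                                        n_features = 4L,
                                        noise = tolerance / 2,
                                        n_distractors = 1L) {
  if (!is_count(n_models, 1L) || !is_count(n_actives, 0L) ||
      !is_count(n_decoys, 0L))
    stop_argument("counts must be non-negative integers (n_models >= 1)")
  if (!is_count(n_features, 3L) || n_features > 6L)
    stop_argument("'n_features' must be between 3 and 6")
  type_sets <- utils::combn(feature_types(), n_features, simplify = FALSE)
  if (n_models > length(type_sets))
    stop_argument(sprintf("at most %d models of %d distinct types",
                          length(type_sets), n_features))
  set.seed(as.integer(seed))
  type_sets <- type_sets[sample.int(length(type_sets), n_models)]

  models <- lapply(seq_len(n_models), function(i) {
    pts <- .ps_random_point_set(n_features)
    pharmacophore(sprintf("M%02d", i),
                  data.frame(type = type_sets[[i]], x = pts[, 1],
                             y = pts[, 2], z = pts[, 3]))
  })
  names(models) <- vapply(models, `[[`, character(1), "model_id")

  rigid <- function(pts) {
    q <- matrix(stats::rnorm(9), 3, 3)
    qr_d <- qr(q)
    rot <- qr.Q(qr_d)
    if (det(rot) < 0) rot[, 1] <- -rot[, 1]
    sweep(pts %*% rot, 2, stats::runif(3, -20, 20), `+`)
  }
  jitter_in_ball <- function(pts, r) {
    if (r <= 0) return(pts)
    for (i in seq_len(nrow(pts))) {
      repeat {
        v <- stats::runif(3, -r, r)
        if (sqrt(sum(v^2)) < r) break
      }
      pts[i, ] <- pts[i, ] + v * 0.999
    }
    pts
  }

  compounds <- list()
  truth_rows <- list()
  for (i in seq_len(n_actives)) {
    m <- ((i - 1L) %% n_models) + 1L
    base <- as.matrix(models[[m]]$features[, c("x", "y", "z")])
    pts <- jitter_in_ball(rigid(base), noise)
    types <- models[[m]]$features$type
    if (n_distractors > 0) {
      # distractors reuse the model's own types, far outside its span
      extra_t <- sample(types, n_distractors, replace = TRUE)
      extra_p <- matrix(stats::runif(3 * n_distractors, 40, 60),
                        n_distractors, 3)
      types <- c(types, extra_t)
      pts <- rbind(pts, extra_p)
    }
    id <- sprintf("ACT%04d", i)
    compounds[[id]] <- conformer_set(id, list(
      data.frame(type = types, x = pts[, 1], y = pts[, 2], z = pts[, 3])))
    row <- rep(FALSE, n_models)
    row[m] <- TRUE
    truth_rows[[id]] <- row
  }
  for (i in seq_len(n_decoys)) {
    m <- ((i - 1L) %% n_models) + 1L
    base <- as.matrix(models[[m]]$features[, c("x", "y", "z")])
    # stretch the first pairwise distance by > 2 * tolerance
    dir <- base[2, ] - base[1, ]
    dir <- dir / sqrt(sum(dir^2))
    base[2, ] <- base[2, ] + dir * (2.5 * tolerance)
    pts <- rigid(base)
    id <- sprintf("DEC%04d", i)
    compounds[[id]] <- conformer_set(id, list(
      data.frame(type = models[[m]]$features$type, x = pts[, 1],
                 y = pts[, 2], z = pts[, 3])))
    truth_rows[[id]] <- rep(FALSE, n_models)
  }
  truth <- do.call(rbind, truth_rows)
  dimnames(truth) <- list(names(truth_rows), names(models))
  list(models = models, compounds = compounds, truth = truth,
       tolerance = tolerance, seed = as.integer(seed))
}
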