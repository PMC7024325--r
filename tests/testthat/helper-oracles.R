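# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: the matcher oracle enumerates every injective
# type-compatible assignment and checks complete assignments only; the
# metric oracles count prefixes / pairs / weights directly.

# Exhaustive matcher: TRUE iff any injective, type-compatible assignment
# of model features to conformer features satisfies all pairwise distance
# constraints.  No pruning on distances; leaves are checked in full.
oracle_match_conformer <- function(mfeat, cfeat, tol) {
  m <- nrow(mfeat)
  nc <- nrow(cfeat)
  if (nc < m) return(FALSE)
  dm <- as.matrix(dist(mfeat[, c("x", "y", "z")]))
  dc <- as.matrix(dist(cfeat[, c("x", "y", "z")]))
  cand <- lapply(mfeat$type, function(tp) which(cfeat$type == tp))
  found <- FALSE
  assign <- integer(m)
  recurse <- function(i) {
    if (found) return()
    if (i > m) {
      for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m)) {
        if (abs(dm[a, b] - dc[assign[a], assign[b]]) > tol) return()
      }
      found <<- TRUE
      return()
    }
    for (j in cand[[i]]) {
      if (j %in% assign[seq_len(i - 1L)]) next
      assign[i] <<- j
      recurse(i + 1L)
      if (found) return()
    }
  }
  if (m == 1L) return(length(cand[[1]]) > 0L)
  recurse(1L)
  found
}

oracle_match <- function(compound, model, tol) {
  for (conf in compound$conformers) {
    if (oracle_match_conformer(model$features, conf, tol)) return(TRUE)
  }
  FALSE
}

# Prefix-count EF / precision / recall on an already-ranked label vector.
oracle_ef <- function(labels_ranked, fraction, n_active_total, n_total) {
  n_sel <- length(labels_ranked)
  if (n_sel == 0) return(0)
  n_f <- min(n_sel, max(1, ceiling(fraction * n_sel - 1e-9)))
  a_f <- sum(labels_ranked[1:n_f] == "active")
  (a_f / n_f) / (n_active_total / n_total)
}

oracle_precision_recall <- function(labels_ranked, fraction, n_active_total) {
  n_sel <- length(labels_ranked)
  n_f <- min(n_sel, max(1, ceiling(fraction * n_sel - 1e-9)))
  a_f <- sum(labels_ranked[1:n_f] == "active")
  c(precision = a_f / n_f, recall = a_f / n_active_total)
}

# Pairwise Mann-Whitney AUC, ties counted one half.
oracle_auc <- function(scores, labels) {
  sa <- scores[labels == "active"]
  si <- scores[labels == "inactive"]
  tot <- 0
  for (x in sa) for (y in si) {
    tot <- tot + (if (x > y) 1 else if (x == y) 0.5 else 0)
  }
  tot / (length(sa) * length(si))
}

# BEDROC by direct weighted sums, normalised between the worst and best
# possible placements: (RIE - RIE_min) / (RIE_max - RIE_min), with RIE
# computed from explicit exponential sums (no closed forms).
oracle_bedroc <- function(scores, labels, alpha) {
  N <- length(scores)
  n <- sum(labels == "active")
  r <- rank(-scores, ties.method = "average")[labels == "active"]
  mean_w <- sum(exp(-alpha * (1:N) / N)) / N
  rie <- function(rr) (sum(exp(-alpha * rr / N)) / n) / mean_w
  (rie(r) - rie((N - n + 1):N)) / (rie(1:n) - rie((N - n + 1):N))
}

# Random feature-set generator for matcher stress tests.
random_feature_set <- function(n, types = feature_types(), spread = 8) {
  data.frame(type = sample(types, n, replace = TRUE),
             x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread))
}

random_rigid_transform <- function(pts) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(as.matrix(pts) %*% q, 2, runif(3, -50, 50), `+`)
}

apply_rigid <- function(feats) {
  out <- feats
  out[, c("x", "y", "z")] <- random_rigid_transform(feats[, c("x", "y", "z")])
  out
}

# Random labelled match matrix (for calibration / consensus properties).
random_match_instance <- function(n_compounds, n_models, p_match = 0.4,
                                  p_active = 0.4) {
  m <- matrix(runif(n_compounds * n_models) < p_match, n_compounds, n_models,
              dimnames = list(sprintf("c%03d", seq_len(n_compounds)),
                              sprintf("m%02d", seq_len(n_models))))
  labels <- setNames(ifelse(runif(n_compounds) < p_active, "active",
                            "inactive"), rownames(m))
  list(matches = m, labels = labels)
}

# Precision table built directly (bypassing compute_precision_table), for
# consensus tests that need prescribed precisions.
make_precision_table <- function(precisions) {
  out <- data.frame(model_id = names(precisions),
                    n_retrieved = ifelse(is.na(precisions), 0L, 100L),
                    n_active_retrieved = ifelse(is.na(precisions), 0L,
                                                as.integer(round(100 * precisions))),
                    precision = unname(precisions),
                    stringsAsFactors = FALSE)
  class(out) <- c("precision_table", "data.frame")
  out
}
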