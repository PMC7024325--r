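# Virtual-screening evaluation metrics, under the following universe
# conventions: enrichment factor, precision and recall are computed over
# the compounds selected by at least one model (ranked by consensus
# score), while ROC AUC and BEDROC consider the full test set, with
# unselected compounds tied at score zero.  The enrichment baseline rate
# is always the full test set's active rate, so EF at 100% of the
# selected compounds is a non-trivial baseline ("EF_100%").

.ps_slice_size <- function(fraction, n) {
  # top-slice size: ceil(f * n), never empty, never beyond the list
  min(n, max(1L, as.integer(ceiling(fraction * n - 1e-9))))
}

.ps_check_fraction <- function(fraction, allow_one = TRUE) {
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1 || (!allow_one && fraction == 1))
    stop_argument(if (allow_one) "'fraction' must be in (0, 1]"
                  else "'fraction' must be in (0, 1)")
  fraction
}

# Actives among the top n_f entries.  With ties = "expected", scores must
# be supplied; a tie group cut by the slice boundary contributes its
# expected active count under random permutation of the group, k * g_a/g.
.ps_top_actives <- function(labels, n_f, ties = "stable", scores = NULL) {
  if (ties == "stable" || is.null(scores)) {
    return(sum(labels[seq_len(n_f)] == "active"))
  }
  a <- 0
  i <- 1L
  n <- length(labels)
  while (i <= n_f) {
    grp <- which(scores == scores[i] & seq_len(n) >= i)
    g <- length(grp)
    g_a <- sum(labels[grp] == "active")
    take <- min(g, n_f - i + 1L)
    a <- a + take * g_a / g
    i <- i + g
  }
  a
}

#' Enrichment factor at a fixed retrieved fraction
#'
#' EF(f) = (a_f / n_f) / (A_total / N_total), where n_f = ceil(f * N_sel)
#' is the size of the top slice of the ranked *selected* compounds, a_f
#' the actives in it, and A_total / N_total the active rate of the full
#' test set.  `fraction = 1` gives the EF_100% baseline: the enrichment
#' of the whole selected set.  An empty selected set has EF 0 by
#' convention (no model, no enrichment).
#'
#' @param labels_ranked Labels (`"active"`/`"inactive"`) of the selected
#'   compounds, in descending rank order.
#' @param fraction Retrieved fraction, in (0, 1].
#' @param n_active_total Number of actives in the full test set (> 0).
#' @param n_total Size of the full test set.
#' @param ties `"stable"` (slice exactly at the deterministic ranking) or
#'   `"expected"` (average analytically over permutations of the tie
#'   group cut by the slice boundary; requires `scores`).
#' @param scores Scores aligned with `labels_ranked`, only used for
#'   `ties = "expected"`.
#' @return Non-negative enrichment factor.
#' @export
enrichment_factor <- function(labels_ranked, fraction, n_active_total, n_total,
                              ties = c("stable", "expected"), scores = NULL) {
  ties <- match.arg(ties)
  .ps_check_fraction(fraction)
  if (!is_count(n_active_total, 0L) || !is_count(n_total, 1L))
    stop_argument("'n_active_total' and 'n_total' must be counts")
  if (n_active_total == 0L)
    stop_argument("enrichment is undefined with zero actives in the test set")
  n_sel <- length(labels_ranked)
  if (n_sel == 0L) return(0)
  if (sum(labels_ranked == "active") > n_active_total)
    stop_validation("more actives in the ranked list than in the full set")
  n_f <- .ps_slice_size(fraction, n_sel)
  a_f <- .ps_top_actives(labels_ranked, n_f, ties, scores)
  (a_f / n_f) / (n_active_total / n_total)
}

#' Precision and recall at a fixed retrieved fraction
#'
#' Over the top `fraction` of the ranked selected compounds: precision is
#' the active fraction of the slice, recall the slice's actives over all
#' actives of the full test set.
#'
#' @inheritParams enrichment_factor
#' @return Named numeric vector `c(precision = , recall = )`; both 0 for
#'   an empty selected set.
#' @export
precision_recall_at <- function(labels_ranked, fraction, n_active_total,
                                ties = c("stable", "expected"), scores = NULL) {
  ties <- match.arg(ties)
  .ps_check_fraction(fraction)
  if (!is_count(n_active_total, 0L) || n_active_total == 0L)
    stop_argument("'n_active_total' must be a positive count")
  n_sel <- length(labels_ranked)
  if (n_sel == 0L) return(c(precision = 0, recall = 0))
  n_f <- .ps_slice_size(fraction, n_sel)
  a_f <- .ps_top_actives(labels_ranked, n_f, ties, scores)
  c(precision = a_f / n_f, recall = a_f / n_active_total)
}

#' BEDROC decay parameter for a retrieved fraction
#'
#' Chooses the exponential decay alpha such that the top `fraction` of a
#' ranked list carries a fixed share (80% by default) of the total
#' exponential weight: (1 - exp(-alpha f)) = share * (1 - exp(-alpha)).
#' For small fractions this reduces to the familiar alpha = ln(5)/f
#' (e.g. about 160.9 at 1%, 32.2 at 5%, 16.1 at 10%); as the fraction
#' grows towards 1 the prescribed alpha falls to 0, where BEDROC is no
#' longer defined -- hence the domain error at `fraction = 1`.
#'
#' @param fraction Top fraction of interest, strictly between 0 and 1
#'   (and below `weight_share`, beyond which the exponential weighting
#'   degenerates).
#' @param weight_share Weight share assigned to the top fraction;
#'   default 0.8.
#' @return Positive alpha, strictly decreasing in `fraction`.
#' @export
alpha_from_fraction <- function(fraction, weight_share = 0.8) {
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0)
    stop_argument("'fraction' must be in (0, 1)")
  if (fraction >= 1)
    ps_stop(paste0("BEDROC cannot be evaluated for selection of 100% of ",
                   "compounds: the prescribed alpha is zero"),
            c("ps_domain_error", "ps_argument_error", "ps_validation_error"))
  if (fraction >= weight_share)
    ps_stop(sprintf(paste0("no positive alpha assigns a weight share of %.2f ",
                           "to the top %.2f fraction; alpha degenerates to 0"),
                    weight_share, fraction),
            c("ps_domain_error", "ps_argument_error", "ps_validation_error"))
  g <- function(a) (1 - exp(-a * fraction)) - weight_share * (1 - exp(-a))
  upper <- 2 * log(1 / (1 - weight_share)) / fraction + 10
  stats::uniroot(g, lower = 1e-9, upper = upper, tol = 1e-12)$root
}

.ps_check_binary <- function(labels) {
  bad <- setdiff(unique(labels), c("active", "inactive"))
  if (length(bad)) stop_validation("labels must be 'active'/'inactive'")
  n_a <- sum(labels == "active")
  if (n_a == 0L || n_a == length(labels))
    stop_degenerate("metric undefined: need at least one active and one inactive")
  n_a
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Exponentially early-weighted ranking metric on the full test set,
#' normalised to \[0,1\].  With active ranks r_i (1 = best) among N
#' compounds, n actives, Ra = n/N:
#' \deqn{RIE = \frac{\frac{1}{n}\sum_i e^{-\alpha r_i/N}}{\frac{1}{N}\,
#'   \frac{1-e^{-\alpha}}{e^{\alpha/N}-1}}, \qquad
#'   BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2)-\cosh(\alpha/2-\alpha R_a)} +
#'   \frac{1}{1-e^{\alpha(1-R_a)}}}
#' Tied scores (typically the unselected compounds at score 0) receive
#' tie-group-average ranks, which keeps the value independent of input
#' order.  As alpha tends to 0 BEDROC tends to the ROC AUC.
#'
#' @param scores Numeric scores for every test compound (higher =
#'   earlier).
#' @param labels `"active"`/`"inactive"` labels aligned with `scores`.
#' @param alpha Positive decay parameter, e.g. from
#'   [alpha_from_fraction()].
#' @return BEDROC value in \[0,1\].
#' @export
bedroc <- function(scores, labels, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop_argument("'alpha' must be a positive number")
  if (length(scores) != length(labels))
    stop_validation("'scores' and 'labels' lengths differ")
  n <- .ps_check_binary(labels)
  N <- length(scores)
  ra <- n / N
  r <- rank(-scores, ties.method = "average")[labels == "active"]
  s <- sum(exp(-alpha * r / N))
  rie <- (s / n) / ((1 / N) * (-expm1(-alpha)) / expm1(alpha / N))
  # cosh(a/2) - cosh(a/2 - a*ra) rewritten with sinh for small-alpha
  # stability (exact identity)
  denom <- 2 * sinh(alpha * ra / 2) * sinh(alpha * (1 - ra) / 2)
  rie * ra * sinh(alpha / 2) / denom - 1 / expm1(alpha * (1 - ra))
}

#' ROC AUC with the Mann-Whitney tie convention
#'
#' Probability that a uniformly chosen active outranks a uniformly chosen
#' inactive, ties counted one half.  Computed over the full test set;
#' unselected compounds all tie at score zero.
#'
#' @inheritParams bedroc
#' @return AUC in \[0,1\]; 0.5 when every score is equal.
#' @export
auc_roc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_validation("'scores' and 'labels' lengths differ")
  n <- .ps_check_binary(labels)
  m <- length(scores) - n
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "active"]) - n * (n + 1) / 2) / (n * m)
}

#' Evaluate a consensus ranking with the full screening battery
#'
#' Ranks the library under one consensus scheme and computes enrichment
#' factors, precision and recall at the requested fractions (over the
#' selected universe), the EF_100% baseline, and BEDROC (with
#' fraction-derived alpha) and ROC AUC over the full universe with
#' unselected compounds at score zero.
#'
#' @param matches Logical match matrix of the test library.
#' @param table Precision table from calibration (not used by
#'   `scheme = "cha"`).
#' @param scheme `"max"`, `"mean"` or `"cha"`.
#' @param labels Labels for every matrix row.
#' @param fractions Retrieved fractions; default
#'   `c(0.0025, 0.005, 0.01, 0.02, 0.05, 0.10)` (0.25% to 10%).
#' @param denominator Mean-scheme denominator.
#' @param ties Tie handling at slice boundaries, see
#'   [enrichment_factor()].
#' @return An object of class `"screening_report"`: a list with `ef_at`,
#'   `ef_100`, `bedroc_at`, `auc_roc`, `precision_at`, `recall_at`
#'   (named by fraction), plus `scheme`, `fractions`, `n_selected`,
#'   `n_total`, `n_active_total`.
#' @export
evaluate_ranking <- function(matches, table = NULL,
                             scheme = c("max", "mean", "cha"), labels,
                             fractions = c(0.0025, 0.005, 0.01, 0.02, 0.05, 0.10),
                             denominator = c("total", "matched"),
                             ties = c("stable", "expected")) {
  scheme <- match.arg(scheme)
  denominator <- match.arg(denominator)
  ties <- match.arg(ties)
  matches <- .ps_check_matrix(matches)
  labels <- as_label_vector(labels)
  missing <- setdiff(rownames(matches), names(labels))
  if (length(missing))
    stop_validation("every test compound needs a label")
  if (any(fractions <= 0 | fractions > 1))
    stop_argument("fractions must lie in (0, 1]")
  ranked <- rank_library(matches, table, scheme = scheme,
                         denominator = denominator)
  lab_ranked <- unname(labels[ranked$compound_id])
  sel <- ranked$n_models_matched > 0
  sel_labels <- lab_ranked[sel]
  sel_scores <- ranked$score[sel]
  n_total <- nrow(matches)
  n_active_total <- sum(labels[rownames(matches)] == "active")
  if (n_active_total == 0L)
    stop_argument("test set contains no actives")

  fr_names <- format_fraction(fractions)
  ef <- pr <- rc <- stats::setNames(numeric(length(fractions)), fr_names)
  for (k in seq_along(fractions)) {
    ef[k] <- enrichment_factor(sel_labels, fractions[k], n_active_total,
                               n_total, ties = ties, scores = sel_scores)
    prk <- precision_recall_at(sel_labels, fractions[k], n_active_total,
                               ties = ties, scores = sel_scores)
    pr[k] <- prk["precision"]
    rc[k] <- prk["recall"]
  }
  ef100 <- enrichment_factor(sel_labels, 1.0, n_active_total, n_total,
                             ties = ties, scores = sel_scores)
  bed_fr <- fractions[fractions < 1]
  bed <- stats::setNames(vapply(bed_fr, function(f)
    bedroc(ranked$score, lab_ranked, alpha_from_fraction(f)), numeric(1)),
    format_fraction(bed_fr))
  structure(
    list(ef_at = ef, ef_100 = ef100, bedroc_at = bed,
         auc_roc = auc_roc(ranked$score, lab_ranked),
         precision_at = pr, recall_at = rc,
         scheme = scheme, fractions = fractions,
         n_selected = sum(sel), n_total = n_total,
         n_active_total = n_active_total),
    class = "screening_report"
  )
}

format_fraction <- function(f) {
  vapply(f, function(x) paste0(format(100 * x, trim = TRUE), "%"), character(1))
}

#' @export
print.screening_report <- function(x, digits = 3, ...) {
  cat(sprintf("Screening report -- scheme '%s'\n", x$scheme))
  cat(sprintf("Test set: %d compounds (%d active), %d selected by >=1 model\n\n",
              x$n_total, x$n_active_total, x$n_selected))
  tab <- data.frame(fraction = names(x$ef_at),
                    EF = round(x$ef_at, digits),
                    precision = round(x$precision_at, digits),
                    recall = round(x$recall_at, digits),
                    BEDROC = round(x$bedroc_at[names(x$ef_at)], digits))
  print.data.frame(tab, row.names = FALSE)
  cat(sprintf("\nEF_100%%: %s   AUC ROC: %s\n",
              format(round(x$ef_100, digits)),
              format(round(x$auc_roc, digits))))
  invisible(x)
}

#' Plot enrichment-factor and BEDROC curves
#'
#' Draws EF (solid) against the retrieved fraction on a log axis, with
#' the EF_100% baseline as a horizontal line; optionally a second panel
#' with BEDROC values.
#'
#' @param x A `screening_report`.
#' @param what `"ef"` or `"bedroc"`.
#' @param ... Passed to [graphics::plot()].
#' @method plot screening_report
#' @export
plot.screening_report <- function(x, what = c("ef", "bedroc"), ...) {
  what <- match.arg(what)
  f <- 100 * x$fractions
  if (what == "ef") {
    plot(f, x$ef_at, type = "b", log = "x", xlab = "% of compounds retrieved",
         ylab = "enrichment factor", main = paste("EF --", x$scheme), ...)
    graphics::abline(h = x$ef_100, lty = 2)
    graphics::legend("topright", lty = c(1, 2), legend = c(x$scheme, "EF 100%"),
                     bty = "n")
  } else {
    fb <- 100 * x$fractions[x$fractions < 1]
    plot(fb, x$bedroc_at, type = "b", log = "x",
         xlab = "% of compounds retrieved", ylab = "BEDROC",
         ylim = c(0, 1), main = paste("BEDROC --", x$scheme), ...)
  }
  invisible(x)
}

#' Write a screening report
#'
#' CSV layout: one row per (metric, fraction) with columns `metric`,
#' `fraction`, `scheme`, `value`; scalar metrics (EF_100%, AUC) carry an
#' empty fraction.  The JSON form mirrors the report structure.
#'
#' @param report A `screening_report`.
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    payload <- unclass(report)
    for (fld in c("ef_at", "bedroc_at", "precision_at", "recall_at")) {
      payload[[fld]] <- as.list(payload[[fld]])   # keep fraction names
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  rows <- rbind(
    data.frame(metric = "EF", fraction = names(report$ef_at),
               value = unname(report$ef_at)),
    data.frame(metric = "precision", fraction = names(report$precision_at),
               value = unname(report$precision_at)),
    data.frame(metric = "recall", fraction = names(report$recall_at),
               value = unname(report$recall_at)),
    data.frame(metric = "BEDROC", fraction = names(report$bedroc_at),
               value = unname(report$bedroc_at)),
    data.frame(metric = "EF", fraction = "100%", value = report$ef_100),
    data.frame(metric = "AUC_ROC", fraction = "", value = report$auc_roc)
  )
  rows$scheme <- report$scheme
  utils::write.csv(rows[, c("metric", "fraction", "scheme", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
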