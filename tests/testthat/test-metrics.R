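test_that("enrichment factor follows its defining ratio", {
  # 10 selected (5 active) from a 20-compound / 5-active test set;
  # the top 20% slice (2 compounds) is all active
  lab <- c("active", "active", "inactive", "active", "inactive",
           "active", "inactive", "active", "inactive", "inactive")
  expect_equal(enrichment_factor(lab, 0.2, 5, 20), (2 / 2) / (5 / 20))
  expect_equal(enrichment_factor(lab, 1.0, 5, 20), (5 / 10) / (5 / 20))

  # a list at the base rate at every prefix has EF 1 everywhere
  base <- rep(c("active", "inactive"), 10)
  for (f in c(0.1, 0.2, 0.5, 1)) {
    expect_equal(enrichment_factor(base, f, 10, 20), 1)
  }

  expect_identical(enrichment_factor(character(0), 0.1, 5, 20), 0)
  expect_error(enrichment_factor(lab, 0.1, 0, 20), class = "ps_argument_error")
  expect_error(enrichment_factor(lab, 1.2, 5, 20), class = "ps_argument_error")
  expect_error(enrichment_factor(lab, 0.1, 2, 20), class = "ps_validation_error")
})

test_that("precision and recall at a fraction count the top slice", {
  lab <- c("active", "active", "inactive", "active")
  pr <- precision_recall_at(lab, 0.5, n_active_total = 6)
  expect_equal(pr[["precision"]], 1)
  expect_equal(pr[["recall"]], 2 / 6)
  pr_all <- precision_recall_at(lab, 1.0, n_active_total = 6)
  expect_equal(pr_all[["recall"]], 3 / 6)
  expect_equal(precision_recall_at(character(0), 0.5, 6),
               c(precision = 0, recall = 0))
})

test_that("alpha from fraction is the exact weight-share solution", {
  # the exponential-weight construction forces monotone decrease
  a <- vapply(c(0.01, 0.05, 0.10), alpha_from_fraction, numeric(1))
  expect_true(all(diff(a) < 0))
  # regression values: ln(5)/f in the small-fraction regime
  expect_equal(alpha_from_fraction(0.05), 32.188758, tolerance = 1e-6)
  expect_equal(alpha_from_fraction(0.01), 160.943791, tolerance = 1e-6)
  # the defining share property holds at the root
  for (f in c(0.02, 0.1, 0.3)) {
    al <- alpha_from_fraction(f)
    expect_equal((1 - exp(-al * f)) / (1 - exp(-al)), 0.8, tolerance = 1e-8)
  }
  expect_error(alpha_from_fraction(1.0), class = "ps_domain_error")
  expect_error(alpha_from_fraction(0), class = "ps_argument_error")
  expect_error(alpha_from_fraction(0.95), class = "ps_domain_error")
})

test_that("BEDROC attains its closed-form extremes and known reference values", {
  lab <- rep(c("active", "inactive"), c(5, 95))
  best <- bedroc(100:1, lab, alpha = 20)
  worst <- bedroc(1:100, lab, alpha = 20)
  expect_gt(best, 0.999)
  expect_lt(worst, 1e-6)
  expect_gte(worst, 0 - 1e-12)

  # reference value computed with an independent implementation of the
  # same exponential-weight definition (8 compounds, actives at ranks
  # 1, 2 and 4, alpha = 20)
  lab8 <- ifelse(1:8 %in% c(1, 2, 4), "active", "inactive")
  expect_equal(bedroc(8:1, lab8, 20), 0.994319658946641, tolerance = 1e-12)

  # ties get group-average ranks: input order cannot matter
  sc <- c(3, 1, 1, 1, 0)
  lb <- c("inactive", "active", "inactive", "active", "inactive")
  perm <- c(1, 4, 3, 2, 5)
  expect_equal(bedroc(sc, lb, 10), bedroc(sc[perm], lb[perm], 10))

  expect_error(bedroc(1:4, rep("active", 4), 20),
               class = "ps_degenerate_error")
  expect_error(bedroc(1:4, c("active", rep("inactive", 3)), 0),
               class = "ps_argument_error")
})

test_that("ROC AUC is the Mann-Whitney statistic with half-ties", {
  expect_equal(auc_roc(10:1, rep(c("active", "inactive"), c(3, 7))), 1)
  expect_equal(auc_roc(rep(0, 10), rep(c("active", "inactive"), 5)), 0.5)
  # 6-compound worked case: one discordant pair, one tied pair
  sc <- c(6, 5, 4, 4, 2, 1)
  lb <- c("active", "inactive", "active", "inactive", "active", "inactive")
  # pairs: the 6 beats all 3; the active 4 beats 1, ties 1; the 2 beats 1
  # -> (3 + 1.5 + 1) / 9
  expect_equal(auc_roc(sc, lb), 5.5 / 9)
  expect_equal(auc_roc(sc, lb), oracle_auc(sc, lb))
})

test_that("rank metrics are invariant under positive monotone score transforms", {
  set.seed(12)
  for (i in 1:20) {
    n <- 40
    sc <- round(runif(n), 2)   # rounding creates ties
    lb <- ifelse(runif(n) < 0.3, "active", "inactive")
    if (length(unique(lb)) < 2) next
    tr <- function(x) exp(3 * x) + 1   # strictly increasing
    expect_equal(auc_roc(tr(sc), lb), auc_roc(sc, lb))
    expect_equal(bedroc(tr(sc), lb, 16.1), bedroc(sc, lb, 16.1))
    ord <- order(-sc)
    expect_equal(enrichment_factor(lb[ord], 0.1, sum(lb == "active"), n),
                 enrichment_factor(lb[order(-tr(sc))], 0.1,
                                   sum(lb == "active"), n))
  }
})

test_that("EF never exceeds the maximum possible enrichment", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    lb <- ifelse(runif(n) < runif(1, 0.1, 0.6), "active", "inactive")
    n_a <- sum(lb == "active")
    if (n_a == 0) next
    f <- runif(1, 0.02, 1)
    expect_lte(enrichment_factor(lb, f, n_a, n), n / n_a + 1e-12)
  }
})

test_that("evaluate_ranking composes the battery under the stated conventions", {
  set.seed(14)
  inst <- random_match_instance(200, 3, p_match = 0.25)
  tab <- compute_precision_table(inst$matches, inst$labels)
  rep_max <- evaluate_ranking(inst$matches, tab, scheme = "max",
                              labels = inst$labels)
  expect_s3_class(rep_max, "screening_report")
  expect_identical(names(rep_max$ef_at),
                   c("0.25%", "0.5%", "1%", "2%", "5%", "10%"))
  expect_true(all(rep_max$bedroc_at >= 0 & rep_max$bedroc_at <= 1))
  expect_gte(rep_max$auc_roc, 0)

  # EF_100% is the enrichment of the whole selected set
  sel <- rowSums(inst$matches) > 0
  a_sel <- sum(inst$labels[sel] == "active")
  expect_equal(rep_max$ef_100,
               (a_sel / sum(sel)) / (sum(inst$labels == "active") / 200))

  # all-ones precisions make Mean(total) identical to CHA, report-wide
  ones <- make_precision_table(setNames(rep(1, 3), colnames(inst$matches)))
  rep_mean1 <- evaluate_ranking(inst$matches, ones, scheme = "mean",
                                labels = inst$labels)
  rep_cha <- evaluate_ranking(inst$matches, NULL, scheme = "cha",
                              labels = inst$labels)
  for (fld in c("ef_at", "ef_100", "bedroc_at", "auc_roc", "precision_at",
                "recall_at")) {
    expect_equal(rep_mean1[[fld]], rep_cha[[fld]])
  }

  # empty hit set: EF drops to 0, AUC sits at the all-tie value
  none <- matrix(FALSE, 20, 2,
                 dimnames = list(sprintf("c%02d", 1:20), c("a", "b")))
  lab_none <- setNames(rep(c("active", "inactive"), 10), rownames(none))
  tab_none <- make_precision_table(c(a = NA, b = NA))
  rep0 <- evaluate_ranking(none, tab_none, scheme = "max", labels = lab_none)
  expect_true(all(rep0$ef_at == 0))
  expect_identical(rep0$ef_100, 0)
  expect_equal(rep0$auc_roc, 0.5)
  expect_identical(rep0$n_selected, 0L)
})

test_that("screening reports print, plot and serialise", {
  set.seed(15)
  inst <- random_match_instance(100, 2, p_match = 0.3)
  tab <- compute_precision_table(inst$matches, inst$labels)
  rep <- evaluate_ranking(inst$matches, tab, scheme = "max",
                          labels = inst$labels)
  expect_output(print(rep), "Screening report")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(rep))
  expect_silent(plot(rep, what = "bedroc"))

  pj <- tempfile(fileext = ".json")
  pc <- tempfile(fileext = ".csv")
  write_screening_report(rep, pj)
  write_screening_report(rep, pc)
  back <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_equal(back$auc_roc, rep$auc_roc, tolerance = 1e-12)
  csv <- read.csv(pc)
  expect_identical(names(csv), c("metric", "fraction", "scheme", "value"))
  expect_equal(csv$value[csv$metric == "EF" & csv$fraction == "100%"],
               rep$ef_100, tolerance = 1e-12)
})
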