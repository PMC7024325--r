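test_that("activity classes are assigned with the boundary in the active class", {
  expect_identical(assign_activity_class(6.0), "active")
  expect_identical(assign_activity_class(5.999), "inactive")
  expect_identical(assign_activity_class(9.3), "active")
  expect_identical(assign_activity_class(c(5, 6, 7)),
                   c("inactive", "active", "active"))
  expect_identical(assign_activity_class(6.9, threshold = 7), "inactive")
  expect_error(assign_activity_class(NaN), class = "ps_argument_error")
  expect_error(assign_activity_class(Inf), class = "ps_argument_error")
})

test_that("conflicting duplicates are removed, within-class ones collapsed", {
  recs <- data.frame(
    compound_id = c("a1", "a2", "b1"),
    label = c("active", "inactive", "active"),
    structure_key = c("S1", "S1", "S2"))
  out <- remove_conflicting_duplicates(recs)
  expect_identical(out$records$compound_id, "b1")
  expect_identical(sort(out$removed$compound_id), c("a1", "a2"))
  expect_true(all(out$removed$reason == "conflicting labels"))

  recs2 <- data.frame(compound_id = c("a1", "a2"), label = "active",
                      structure_key = "S1")
  out2 <- remove_conflicting_duplicates(recs2)
  expect_identical(out2$records$compound_id, "a1")
  expect_identical(out2$removed$reason, "within-class duplicate")

  empty <- recs[0, ]
  out3 <- remove_conflicting_duplicates(empty)
  expect_identical(nrow(out3$records), 0L)
  expect_identical(nrow(out3$removed), 0L)

  recs$structure_key[1] <- ""
  expect_error(remove_conflicting_duplicates(recs),
               class = "ps_validation_error")
})

test_that("precision equals the retrieved-active fraction, with NA at zero retrieval", {
  m <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE,
                FALSE, FALSE, FALSE, FALSE, FALSE), 5, 2,
              dimnames = list(paste0("c", 1:5), c("good", "empty")))
  labels <- setNames(c("active", "active", "active", "inactive", "active"),
                     paste0("c", 1:5))
  tab <- compute_precision_table(m, labels)
  expect_identical(tab$n_retrieved, c(4L, 0L))
  expect_identical(tab$n_active_retrieved, c(3L, 0L))
  expect_equal(tab$precision, c(0.75, NA_real_))

  # unlabelled rows are a validation error
  expect_error(compute_precision_table(m, labels[-1]),
               class = "ps_validation_error")
})

test_that("per-model exclusions restrict each model's calibration universe", {
  set.seed(10)
  inst <- random_match_instance(40, 3)
  excl <- list(m01 = rownames(inst$matches)[1:10])
  tab_all <- compute_precision_table(inst$matches, inst$labels)
  tab_ex <- compute_precision_table(inst$matches, inst$labels, excl)
  keep <- rownames(inst$matches)[-(1:10)]
  expect_identical(tab_ex$n_retrieved[1], sum(inst$matches[keep, 1]))
  expect_identical(tab_ex$n_active_retrieved[1],
                   sum(inst$matches[keep, 1] & inst$labels[keep] == "active"))
  # other models are untouched
  expect_identical(tab_ex$n_retrieved[-1], tab_all$n_retrieved[-1])

  expect_error(compute_precision_table(inst$matches, inst$labels,
                                       list(zzz = "c001")),
               class = "ps_validation_error")
  expect_error(compute_precision_table(inst$matches, inst$labels,
                                       list(m01 = "ghost")),
               class = "ps_validation_error")
})

test_that("precision is invariant to row permutation and monotone in added rows", {
  set.seed(77)
  for (i in 1:20) {
    inst <- random_match_instance(sample(5:30, 1), sample(1:4, 1))
    tab <- compute_precision_table(inst$matches, inst$labels)
    perm <- sample(nrow(inst$matches))
    tab_p <- compute_precision_table(inst$matches[perm, , drop = FALSE],
                                     inst$labels)
    expect_equal(tab_p, tab)

    # appending a retrieved inactive never increases precision; a
    # retrieved active never decreases it
    add <- function(lab) {
      m2 <- rbind(inst$matches,
                  matrix(TRUE, 1, ncol(inst$matches),
                         dimnames = list("zz", colnames(inst$matches))))
      compute_precision_table(m2, c(inst$labels, zz = lab))$precision
    }
    base <- ifelse(is.na(tab$precision), 0, tab$precision)
    expect_true(all(add("inactive") <= base + 1e-12))
    p_act <- add("active")
    expect_true(all(p_act >= ifelse(tab$n_retrieved == 0, 0, tab$precision) - 1e-12))
  }
})

test_that("estimated precision approaches the analytic value on Bernoulli data", {
  design <- synthetic_design(n_active = 500, n_inactive = 1500,
                             sensitivity = 0.6, fpr = 0.05)
  expect_equal(analytic_precision(design), 0.8)
  bench <- generate_match_benchmark(design, seed = 2024)
  tab <- compute_precision_table(bench$calibration$matches,
                                 bench$calibration$labels)
  # 99% binomial band around the analytic value, at the observed retrieval
  n_ret <- tab$n_retrieved
  band <- qbinom(c(0.005, 0.995), n_ret, 0.8) / n_ret
  expect_gte(tab$precision, band[1])
  expect_lte(tab$precision, band[2])
})

test_that("model filtering is strict on precision and counts distinct features", {
  tab <- make_precision_table(c(a = 0.5, b = 0.51, c = 0.9, d = NA))
  expect_identical(filter_models(tab, min_precision = 0.5), c("b", "c"))
  expect_identical(filter_models(tab, min_precision = 0.9), character(0))
  # no thresholds: everything (even undefined) is retained, input order
  expect_identical(filter_models(tab), c("a", "b", "c", "d"))

  pts <- matrix(rnorm(12), 4, 3) * 5
  mk <- function(id, p) pharmacophore(id, data.frame(type = "HBA", x = p[, 1],
                                                     y = p[, 2], z = p[, 3]))
  models <- list(a = mk("a", pts[1:3, ]),            # 3 distinct
                 b = mk("b", pts),                   # 4 distinct
                 c = mk("c", rbind(pts, pts[4, ])),  # 5 raw, 4 distinct
                 d = mk("d", pts))
  got <- filter_models(tab, models, min_distinct_features = 4)
  expect_identical(got, c("b", "c", "d"))
  both <- filter_models(tab, models, min_precision = 0.5,
                        min_distinct_features = 4)
  expect_identical(both, c("b", "c"))

  expect_error(filter_models(tab, min_precision = 1.5),
               class = "ps_argument_error")
  expect_error(filter_models(tab, min_distinct_features = 4),
               class = "ps_argument_error")  # models missing
})

test_that("calibration file formats round-trip, including undefined precision", {
  tab <- make_precision_table(c(m1 = 0.25, m2 = NA))
  p <- tempfile(fileext = ".csv")
  write_precision_table(tab, p)
  got <- read_precision_table(p)
  expect_equal(got$precision, c(0.25, NA_real_))
  # undefined precision is an empty cell, not the string NA
  expect_false(any(grepl("NA", readLines(p))))

  labp <- tempfile(fileext = ".csv")
  write.csv(data.frame(compound_id = c("x", "y"), affinity_log = c(6.0, 4.2)),
            labp, row.names = FALSE)
  expect_identical(read_labels(labp), c(x = "active", y = "inactive"))
  expect_identical(read_labels(labp, threshold = 7),
                   c(x = "inactive", y = "inactive"))

  exp_ <- tempfile(fileext = ".csv")
  write.csv(data.frame(model_id = c("m1", "m1", "m2"),
                       compound_id = c("x", "y", "x")), exp_, row.names = FALSE)
  expect_identical(read_exclusions(exp_), list(m1 = c("x", "y"), m2 = "x"))
})
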