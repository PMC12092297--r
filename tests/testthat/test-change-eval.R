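test_that("strict sign rule classifies worsening, improvement, and exclusions", {
  sched_days <- c(7, 180)
  scores <- data.frame(participant_id = rep(c("A", "B", "C", "D"), each = 2),
                       timepoint_day = rep(sched_days, 4), domain = "d",
                       score = c(0, 0.5,   0.2, 0,   1, 1,   0, NA))
  panel <- data.frame(participant_id = rep(c("A", "B", "C", "D"), each = 2),
                      timepoint_day = rep(sched_days, 4), domain = "d",
                      feature = "f",
                      symptom_score = 0,
                      marker_value = c(0, 1,  1, 0,  0, 2,  0, 1))
  rec <- compute_changes(scores, panel)
  expect_equal(rec$true_class[rec$participant_id == "A"], "worsening")
  expect_equal(rec$true_class[rec$participant_id == "B"], "improvement")
  expect_equal(rec$true_class[rec$participant_id == "C"], "excluded")  # delta 0
  expect_equal(rec$true_class[rec$participant_id == "D"], "excluded")  # missing endpoint
  expect_equal(rec$predicted_class[rec$participant_id == "A"], "worsening")
  expect_error(compute_changes(scores, panel, endpoints = c(7, 99)),
               "scheduled")
})

test_that("confusion metrics reproduce direct counts and their identities", {
  cm <- confusion(records_fixture(40, 20, 10, 30))
  expect_equal(cm$sensitivity, 0.8)
  expect_equal(cm$specificity, 0.6)
  expect_equal(cm$ppv, 2 / 3, tolerance = 1e-12)
  expect_equal(cm$npv, 0.75)
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, cm$n_scored)
  # ppv identity through prevalence
  pi <- cm$prevalence
  expect_equal(cm$ppv, cm$sensitivity * pi /
                 (cm$sensitivity * pi + (1 - cm$specificity) * (1 - pi)),
               tolerance = 1e-12)
  # record order is irrelevant
  rec <- records_fixture(7, 3, 2, 8)
  expect_equal(confusion(rec[rev(seq_len(nrow(rec))), ]), confusion(rec))
  # perfect prediction
  perf <- confusion(records_fixture(5, 0, 0, 5))
  expect_equal(c(perf$sensitivity, perf$specificity, perf$ppv, perf$npv),
               rep(1, 4))
  # zero denominators give missing metrics, not zero
  no_pos <- confusion(records_fixture(0, 0, 0, 5))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$ppv))
})

test_that("uninformative prediction has ppv near prevalence", {
  set.seed(5)
  n <- 20000
  truth <- ifelse(runif(n) < 0.3, "worsening", "improvement")
  pred <- ifelse(runif(n) < 0.5, "worsening", "improvement")
  rec <- data.frame(participant_id = as.character(1:n), domain = "d",
                    feature = "f", delta_marker = 1, delta_symptom = 1,
                    true_class = truth, predicted_class = pred)
  cm <- confusion(rec)
  expect_lt(abs(cm$ppv - cm$prevalence), 0.02)
})

marker_row <- function(est, status = "validated",
                       type = "longitudinal") {
  data.frame(feature = "f", domain = "d", association_type = type,
             est_identification = est, p_identification = 1e-5,
             est_validation = est, p_validation = 1e-5,
             p_adj_identification = 1e-4, p_adj_validation = 1e-4,
             status = status)
}

test_that("negatively associated markers are inverted, swapping sensitivity and specificity", {
  rec <- records_fixture(40, 20, 10, 30)
  pos <- evaluate_markers(marker_row(0.4), rec)
  neg <- evaluate_markers(marker_row(-0.4), rec)
  expect_equal(pos$sensitivity, 0.8)
  # inverting predictions: sens' = 1 - sens, spec' = 1 - spec
  expect_equal(neg$sensitivity, 1 - pos$sensitivity)
  expect_equal(neg$specificity, 1 - pos$specificity)
  # candidates and cross-sectional rows are not evaluated
  expect_equal(nrow(evaluate_markers(marker_row(0.4, status = "candidate"), rec)), 0L)
  expect_equal(nrow(evaluate_markers(marker_row(0.4, type = "cross_sectional"), rec)), 0L)
  expect_equal(nrow(evaluate_markers(marker_row(0.4)[0, ], rec)), 0L)
})

test_that("a marker tracking within-person change predicts worsening above prevalence", {
  set.seed(6)
  n <- 600
  ds <- rnorm(n, mean = -0.3)            # improvement-leaning cohort
  dm <- 0.6 * ds + 0.8 * rnorm(n)        # marker change, rho ~ 0.6
  rec <- data.frame(participant_id = as.character(1:n), domain = "d",
                    feature = "f", delta_marker = dm, delta_symptom = ds,
                    true_class = langmarker:::change_class(ds),
                    predicted_class = langmarker:::change_class(dm))
  out <- evaluate_markers(marker_row(0.6), rec)
  expect_gt(out$ppv, out$pct_worsening / 100)
})
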