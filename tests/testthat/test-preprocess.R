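fm_fixture <- function() {
  data.frame(participant_id = rep(c("A", "B"), each = 5),
             date = rep(as.Date("2020-01-01") + 0:4, 2),
             word_count = c(50, 20000, 10000, 10001, 30, 40, 50, 60, 70, 80),
             f_sparse = c(rep(0, 9), 1),
             f_dense = 1:10 + 0.5,
             f_mid = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 2))
}

test_that("zero-percentage filter is strict at the 90% boundary and ignores missing cells", {
  fm <- fm_fixture()                       # f_sparse: 90% zeros -> kept
  res <- filter_zero_features(fm)
  expect_equal(res$dropped, character(0))
  fm$f_sparse[10] <- 0                     # 100% zeros -> dropped
  res <- filter_zero_features(fm)
  expect_equal(res$dropped, "f_sparse")
  expect_false("f_sparse" %in% names(res$matrix))
  # 19 of 20 zeros among non-missing cells (95%) -> dropped
  fm2 <- data.frame(participant_id = "A", date = as.Date("2020-01-01") + 1:25,
                    word_count = 1,
                    f = c(rep(0, 19), 1, rep(NA, 5)))
  expect_equal(filter_zero_features(fm2)$dropped, "f")
  # exactly 90/100 zeros -> kept (rule is strictly greater than)
  fm3 <- data.frame(participant_id = "A", date = as.Date("2020-01-01") + 1:100,
                    word_count = 1, f = c(rep(0, 90), 1:10))
  expect_equal(filter_zero_features(fm3)$dropped, character(0))
})

test_that("word-count mask is strict at 10,000 and leaves percent features alone", {
  fm <- fm_fixture()
  res <- cap_word_count(fm)
  expect_equal(res$n_cells_masked, 2L)          # 20000 and 10001
  expect_true(is.na(res$matrix$word_count[2]))
  expect_false(is.na(res$matrix$word_count[3])) # exactly 10,000 kept
  expect_true(is.na(res$matrix$word_count[4]))
  expect_equal(res$matrix$f_dense, fm$f_dense)  # percents untouched
})

test_that("OS switchers are removed; unknown participants kept with warning", {
  fm <- fm_fixture()
  log_ok <- data.frame(participant_id = c("A", "A", "B", "B"),
                       date = as.Date("2020-01-01") + c(0, 90, 0, 90),
                       os = c("android", "android", "android", "ios"))
  res <- drop_os_switchers(fm, log_ok)
  expect_equal(res$removed, "B")
  expect_false("B" %in% res$matrix$participant_id)
  # a switch after the window does not count
  log_late <- data.frame(participant_id = c("A", "B", "B"),
                         date = as.Date("2020-01-01") + c(0, 0, 200),
                         os = c("android", "android", "ios"))
  expect_equal(drop_os_switchers(fm, log_late)$removed, character(0))
  expect_warning(res2 <- drop_os_switchers(fm, log_ok[1:2, ]), "absent")
  expect_equal(res2$removed, character(0))
  expect_warning(res3 <- drop_os_switchers(fm, log_ok[0, ]), "empty")
  expect_equal(res3$removed, character(0))
})

test_that("zero filter and OS drop commute when their domains are disjoint", {
  # the all-zero feature is zero for every participant, so the participant
  # removal cannot change the zero-filter decision
  fm <- fm_fixture(); fm$f_sparse[] <- 0; fm$f_mid[1:8] <- 1
  dl <- data.frame(participant_id = c("A", "B", "B"),
                   date = as.Date("2020-01-01") + c(0, 0, 30),
                   os = c("android", "android", "ios"))
  a <- drop_os_switchers(filter_zero_features(fm)$matrix, dl)$matrix
  b <- filter_zero_features(drop_os_switchers(fm, dl)$matrix)$matrix
  expect_equal(a, b)
})

test_that("redundancy pruning keeps the feature with the stronger score association", {
  set.seed(2)
  n <- 300
  ids <- sprintf("P%03d", 1:n)
  sc <- rnorm(n)
  x <- sc + rnorm(n)                     # shared signal tied to the score
  fm <- data.frame(participant_id = ids, date = as.Date("2020-01-05"),
                   word_count = 1,
                   fa = x + 0.05 * rnorm(n),
                   fb = x + 0.40 * rnorm(n),  # same component, weaker link
                   fz = rnorm(n))
  sched <- data.frame(participant_id = ids, timepoint_day = 5, date = fm$date)
  scores <- data.frame(participant_id = ids, timepoint_day = 5,
                       domain = "d", score = sc)
  stopifnot(cor(fm$fa, fm$fb, method = "spearman") > 0.85)
  res <- prune_redundant(fm, scores, sched)
  expect_equal(res$report$dropped, "fb")
  expect_equal(res$report$retained, "fa")
  expect_true(all(c("fa", "fz") %in% names(res$matrix)))
})

test_that("pruning collapses a fully connected triple to one survivor and respects the strict threshold", {
  set.seed(3)
  n <- 400
  x <- rnorm(n)
  fm <- data.frame(participant_id = sprintf("P%03d", 1:n),
                   date = as.Date("2020-01-01"), word_count = 1,
                   a = x + 0.1 * rnorm(n), b = x + 0.1 * rnorm(n),
                   c = x + 0.1 * rnorm(n))
  sched <- data.frame(participant_id = fm$participant_id, timepoint_day = 0,
                      date = fm$date)
  scores <- data.frame(participant_id = fm$participant_id, timepoint_day = 0,
                       domain = "d", score = rnorm(n))
  res <- prune_redundant(fm, scores, sched)
  expect_equal(nrow(res$report), 2L)               # 3-feature component -> 1 kept
  expect_equal(length(unique(res$report$retained)), 1L)
  # a correlation of exactly the threshold is NOT an edge
  r <- 0.99
  cm <- matrix(c(1, r, r, 1), 2)
  expect_true(all(langmarker:::graph_components(cm > 0.99)[[1]] == 1))
  # survivor count equals component count: nothing is ever fully dropped
  expect_equal(length(setdiff(c("a", "b", "c"), res$report$dropped)), 1L)
  # explicit priority overrides the strength rule
  res2 <- prune_redundant(fm, scores, sched, priority = "c")
  expect_equal(unique(res2$report$retained), "c")
})

test_that("alignment averages day-prior and day-of values, tolerating one missing day", {
  sched <- data.frame(participant_id = "A", timepoint_day = c(7, 14, 21),
                      date = as.Date("2020-01-01") + c(7, 14, 21))
  fm <- data.frame(participant_id = "A",
                   date = as.Date("2020-01-01") + c(6, 7, 13, 21),
                   word_count = 1,
                   f = c(2, 4, 5, 9))
  scores <- data.frame(participant_id = "A", timepoint_day = c(7, 14, 21),
                       domain = "d", score = c(1, 2, 3))
  panel <- align_observations(fm, scores, sched)
  m <- panel$marker_value[match(c(7, 14, 21), panel$timepoint_day)]
  expect_equal(m, c(3, 5, 9))   # mean(2,4); day-of missing -> day-prior; day-of only
  # both days absent -> marker missing (row kept: symptom present)
  fm2 <- fm[fm$date != as.Date("2020-01-08"), ]
  sched2 <- rbind(sched, data.frame(participant_id = "A", timepoint_day = 28,
                                    date = as.Date("2020-01-29")))
  scores2 <- rbind(scores, data.frame(participant_id = "A", timepoint_day = 28,
                                      domain = "d", score = 4))
  p2 <- align_observations(fm2, scores2, sched2)
  expect_true(is.na(p2$marker_value[p2$timepoint_day == 28]))
  # duplicated survey rows are a data error
  expect_error(align_observations(fm, rbind(scores, scores[1, ]), sched),
               "duplicate")
  # row count bound: at most (#survey rows) x (#features)
  expect_lte(nrow(panel), nrow(scores) * 1)
})

test_that("missingness diagnostic flags severity-dependent completion", {
  set.seed(4)
  n <- 300
  ids <- sprintf("P%03d", 1:n)
  sev <- rnorm(n)
  scores <- data.frame(participant_id = rep(ids, 2),
                       timepoint_day = rep(c(7, 30), each = n),
                       domain = "dom1", score = rep(sev, 2) + rnorm(2 * n, sd = .2))
  indep <- data.frame(participant_id = rep(ids, 2),
                      activity = rep(c("survey", "words"), each = n),
                      completion_rate = runif(2 * n))
  d1 <- missingness_diagnostic(scores, indep)
  expect_true(d1$mar_plausible)
  expect_true(all(abs(d1$correlations$r) < 0.1))
  dep <- indep
  dep$completion_rate[dep$activity == "survey"] <-
    plogis(-sev) * 0.8 + runif(n) * 0.2
  d2 <- missingness_diagnostic(scores, dep)
  expect_false(d2$mar_plausible)
  # constant completion rate -> missing correlation, not zero
  const <- indep; const$completion_rate <- 0.5
  d3 <- missingness_diagnostic(scores, const)
  expect_true(all(is.na(d3$correlations$r)))
  expect_error(missingness_diagnostic(scores[scores$participant_id == ids[1], ],
                                      indep), "single participant")
})
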