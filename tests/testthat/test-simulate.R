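small_config <- function(...) {
  args <- list(n_participants = 15,
               item_loadings = rep(list(c(0.8, 0.7, 0.6)), 2),
               planted_pairs = list(list(feature = 1, domain = 1,
                                         rho_b = 0.4, rho_w = 0.2)),
               seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("identical seeds reproduce the cohort byte for byte", {
  a <- simulate_cohort(small_config())
  b <- simulate_cohort(small_config())
  expect_identical(a$word_bags, b$word_bags)
  expect_identical(a$survey_items, b$survey_items)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(a$word_bags, c$word_bags))
  p1 <- simulate_blmm_panel(20, 4, seed = 7)
  p2 <- simulate_blmm_panel(20, 4, seed = 7)
  expect_identical(p1, p2)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_participants = 0), "positive")
  expect_error(sim_config(timepoints = c(7, 7, 14)), "strictly increasing")
  expect_error(small_config(planted_pairs = list(
    list(feature = 1, domain = 1, rho_b = 1.4, rho_w = 0))), "\\[-1, 1\\]")
  expect_error(small_config(planted_pairs = list(
    list(feature = 1, domain = 1, rho_b = .2, rho_w = .1),
    list(feature = 1, domain = 2, rho_b = .2, rho_w = .1))),
    "more than one")
  expect_error(small_config(planted_pairs = list(
    list(feature = 99, domain = 1, rho_b = .2, rho_w = .1))), "does not exist")
})

test_that("word bags have positive integer counts and unique keys", {
  wb <- simulate_cohort(small_config())$word_bags
  expect_true(all(wb$count > 0))
  expect_true(all(wb$count == as.integer(wb$count)))
  expect_equal(anyDuplicated(wb[c("participant_id", "date", "word")]), 0L)
  expect_true(all(wb$word == tolower(wb$word)))
})

test_that("sample correlations converge to the planted values", {
  pan <- simulate_blmm_panel(2000, 30, rho_b = 0.3, rho_w = 0.15, seed = 10)
  pm_s <- tapply(pan$symptom, pan$participant_id, mean)
  pm_f <- tapply(pan$feature, pan$participant_id, mean)
  # participant means: corr -> (rho_b + rho_w/T) / (1 + 1/T), ~ rho_b at T=30
  expect_lt(abs(cor(pm_s, pm_f) - 0.3), 0.03)
  cs <- pan$symptom - ave(pan$symptom, pan$participant_id)
  cf <- pan$feature - ave(pan$feature, pan$participant_id)
  expect_lt(abs(cor(cs, cf) - 0.15), 0.03)
})

test_that("perfect within-subject correlation makes centred deviations identical", {
  pan <- simulate_blmm_panel(50, 6, rho_b = 0.2, rho_w = 1, seed = 11)
  cs <- pan$symptom - ave(pan$symptom, pan$participant_id)
  cf <- pan$feature - ave(pan$feature, pan$participant_id)
  expect_equal(cs, cf, tolerance = 1e-10)
})

test_that("survey item covariance matches the one-factor structure", {
  cf <- sim_config(n_participants = 400,
                   item_loadings = rep(list(c(0.8, 0.7, 0.6)), 2),
                   latent_trend = rep(0, 10),
                   missing_rate_survey = 0, missing_rate_words = 1,
                   extra_days = 0, words_per_day_mean = 1, seed = 12)
  coh <- simulate_cohort(cf)
  it <- coh$survey_items
  d1 <- it[grepl("^d01", it$item_id), ]
  X <- sapply(split(d1$value, d1$item_id), identity)
  lam <- c(0.8, 0.7, 0.6)
  expected <- tcrossprod(lam) + diag(1 - lam^2)
  expect_lt(max(abs(cov(X) - expected)), 0.06)
})

test_that("fixtures round-trip through files unchanged", {
  coh <- simulate_cohort(small_config())
  dir <- tempfile("fixture")
  paths <- write_fixture(coh, dir)
  expect_true(all(file.exists(paths)))
  wb <- read_word_bags(paths[["word_bags"]])
  expect_equal(wb, coh$word_bags, ignore_attr = TRUE)
  si <- read_survey_items(paths[["survey_items"]])
  expect_equal(si, coh$survey_items, ignore_attr = TRUE)
  expect_equal(length(unique(wb$participant_id)),
               length(unique(coh$word_bags$participant_id)))
  # empty table still writes a header-only csv that reads back empty
  empty <- coh; empty$word_bags <- coh$word_bags[0, ]
  p2 <- write_fixture(empty, file.path(dir, "e"))
  expect_equal(nrow(read_word_bags(p2[["word_bags"]])), 0L)
  # the ground-truth sidecar is clearly named and separate
  expect_match(paths[["truth"]], "truth")
})

test_that("MAR mode links survey completion to severity", {
  base <- sim_config(n_participants = 250, missing_mode = "MAR",
                     mar_strength = 2, missing_rate_survey = 0.3,
                     item_loadings = rep(list(c(0.8, 0.7, 0.6)), 2),
                     missing_rate_words = 1, words_per_day_mean = 1,
                     extra_days = 0, seed = 13)
  coh <- simulate_cohort(base)
  sev <- tapply(coh$truth$severity$eta, coh$truth$severity$participant_id, mean)
  compl <- coh$completion[coh$completion$activity == "flash_survey", ]
  r <- cor(sev[compl$participant_id], compl$completion_rate)
  expect_lt(r, -0.2)  # higher severity, more dropout
})
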