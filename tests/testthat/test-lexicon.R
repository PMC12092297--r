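test_that("category scoring matches hand counts, wildcards are prefix-anchored", {
  self <- category_lexicon("self", c("i", "me", "my"))
  expect_equal(score_category(c(i = 2, happy = 1, dog = 1), self), 50.0)
  expect_equal(score_category(c(happy = 1, dog = 1),
                              category_lexicon("art", c("a", "an", "the"))), 0.0)
  # "silk" must not match "ill*": matching anchors at the word start
  ill <- category_lexicon("ill", c("ill*", "sick"))
  expect_equal(score_category(c(illness = 3, sick = 1, silk = 1), ill), 80.0)
  # a word matching both a literal and a pattern is counted once
  both <- category_lexicon("b", c("sick", "sic*"))
  expect_equal(score_category(c(sick = 1, well = 1), both), 50.0)
  expect_true(is.na(score_category(c(), self)))
})

test_that("weighted scoring is linear in relative frequency and weights", {
  lex <- weighted_lexicon("w", c(happy = 2.0, sad = -1.0), intercept = 0.1)
  bag <- c(happy = 1, dog = 1)
  expect_equal(score_weighted(bag, lex), 1.1)
  expect_equal(score_weighted(c(dog = 3), lex), 0.1)          # no overlap
  expect_equal(score_weighted(bag * 10, lex), 1.1)            # scale-free
  # linearity in the weights
  l1 <- weighted_lexicon("a", c(happy = 1), intercept = 0)
  l2 <- weighted_lexicon("b", c(sad = 1), intercept = 0)
  l12 <- weighted_lexicon("c", c(happy = 3, sad = 2), intercept = 0)
  b <- c(happy = 2, sad = 1, dog = 1)
  expect_equal(score_weighted(b, l12),
               3 * score_weighted(b, l1) + 2 * score_weighted(b, l2))
})

test_that("disjoint category lexicons covering the bag sum to 100", {
  bag <- c(i = 2, sad = 1, dog = 3, run = 4)
  lx <- list(category_lexicon("a", c("i", "sad")),
             category_lexicon("b", c("dog")),
             category_lexicon("c", c("run")))
  expect_equal(sum(vapply(lx, function(l) score_category(bag, l), 0)), 100)
})

test_that("feature matrix has one row per active day, stable under permutation", {
  bags <- tiny_bags()
  cats <- list(category_lexicon("self", c("i", "me", "my")),
               category_lexicon("neg", c("sad", "sick")))
  wl <- list(weighted_lexicon("wt", c(i = 1, sad = 2)))
  fm <- build_feature_matrix(bags, cats, wl)
  expect_equal(dim(fm), c(4L, 6L))  # 2 keys + word_count + 3 features
  expect_equal(names(fm), c("participant_id", "date", "word_count",
                            "self", "neg", "wt"))
  # permuting input rows leaves the matrix unchanged
  fm2 <- build_feature_matrix(bags[sample(nrow(bags)), ], cats, wl)
  expect_equal(fm2, fm)
  # splitting a count across duplicate rows leaves scores unchanged
  split_bags <- rbind(bags, bags[1, ])
  split_bags$count[1] <- 1L; split_bags$count[nrow(split_bags)] <- 1L
  expect_equal(build_feature_matrix(split_bags, cats, wl), fm)
  # a day absent from the input has no row (missing, not zero)
  expect_false(any(fm$participant_id == "A" & fm$date == as.Date("2020-01-12")))
  expect_error(build_feature_matrix(bags, list(category_lexicon("wt", "x")), wl),
               "duplicate")
})

test_that("normalization z-scores with n-1 sd, is idempotent, keeps NAs", {
  fm <- data.frame(participant_id = c("A", "A", "B"),
                   date = as.Date("2020-01-01") + 0:2,
                   word_count = c(10, 20, 30),
                   f1 = c(1, 2, 3), f2 = c(5, NA, 7))
  nz <- normalize_features(fm)
  expect_equal(nz$f1, c(-1, 0, 1))
  expect_true(is.na(nz$f2[2]))
  expect_equal(attr(nz, "normalization")$f1, c(mean = 2, sd = 1))
  # refitting on already-standardized values changes nothing
  nz2 <- normalize_features(nz)
  expect_equal(nz2$f1, nz$f1, tolerance = 1e-12)
  # raw word_count is untouched; a z-scored copy appears
  expect_equal(nz$word_count, c(10, 20, 30))
  expect_equal(nz$word_count_z, c(-1, 0, 1))
  fm$f1 <- c(2, 2, 2)
  expect_error(normalize_features(fm), "f1")
})

test_that("lexicon files round-trip with lower-casing and intercept", {
  cats <- read_category_lexicons(system.file("extdata", "toy_categories.csv",
                                             package = "langmarker"))
  expect_true(all(c("pronoun_i", "negemo", "health") %in% names(cats)))
  expect_equal(score_category(c(i = 1, me = 1, dog = 2), cats$pronoun_i), 50)
  wt <- read_weighted_lexicon(system.file("extdata", "toy_distress.csv",
                                          package = "langmarker"))
  expect_equal(score_weighted(c(sad = 1, the = 1), wt), 1.0)  # 0 + 2.0/2
})
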