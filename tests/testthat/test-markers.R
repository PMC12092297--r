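test_that("participant split is an equal, seed-deterministic partition", {
  s1 <- split_participants(letters[1:10], seed = 1)
  expect_equal(sort(table(as.vector(s1))), sort(c(identification = 5L,
                                                  validation = 5L)),
               ignore_attr = TRUE)
  expect_identical(as.vector(s1), as.vector(split_participants(letters[1:10], 1)))
  s2 <- split_participants(letters[1:11], seed = 3)
  expect_equal(sort(as.vector(table(as.vector(s2)))), c(5L, 6L))
  # different seeds give different partitions (with overwhelming probability)
  alt <- vapply(2:6, function(sd)
    identical(as.vector(split_participants(letters[1:10], sd)),
              as.vector(s1)), TRUE)
  expect_false(all(alt))
  expect_error(split_participants("a", 1), "2 participants")
})

test_that("BH adjustment matches the step-up definition exactly", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.02, 0.04)),
               c(0.004, 0.02, 8 / 300, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)                   # m = 1
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))   # symmetry
  set.seed(11)
  for (k in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_identical(bh_adjust(p), bh_bruteforce(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Bonferroni adjustment multiplies by the family size and caps at 1", {
  expect_equal(bonferroni_adjust(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni_adjust(c(0.6, 0.7)), c(1, 1))
  expect_equal(bonferroni_adjust(0.4), 0.4)
  expect_equal(bonferroni_adjust(c(0.01, 0.2), m = 5), c(0.05, 1))
})

fits_fixture <- function(p1_b, p1_w, p2_b = p1_b, p2_w = p1_w) {
  n <- length(p1_b)
  f <- function(pb, pw) data.frame(
    feature = sprintf("f%02d", seq_len(n)), domain = "d1",
    rho_b = 0.3, p_rho_b = pb, rho_w = 0.2, p_rho_w = pw,
    converged = TRUE)
  list(f(p1_b, p1_w), f(p2_b, p2_w))
}

test_that("two-stage selection behaves at the degenerate alphas and is order-invariant", {
  fx <- fits_fixture(p1_b = c(1e-8, 0.5, 0.9), p1_w = c(1e-7, 0.6, 0.8))
  none <- run_selection(fx[[1]], fx[[2]], alpha = 0)
  expect_equal(sum(none$status != "rejected"), 0L)
  tiny <- run_selection(fx[[1]], fx[[2]], alpha = 0.05)
  expect_equal(tiny$status[tiny$feature == "f01"], c("validated", "validated"))
  # with alpha = 1 every converged pair is at least a candidate
  all_cand <- run_selection(fx[[1]], fx[[2]], alpha = 1)
  expect_true(all(all_cand$status != "rejected"))
  # permuting the input pair order leaves the validated set unchanged
  perm <- sample(nrow(fx[[1]]))
  mk1 <- run_selection(fx[[1]], fx[[2]])
  mk2 <- run_selection(fx[[1]][perm, ], fx[[2]][perm, ])
  expect_equal(mk2, mk1)
  # mismatched pair coverage is an error
  expect_error(run_selection(fx[[1]][-1, ], fx[[2]]), "identical")
})

test_that("lowering alpha never adds markers", {
  set.seed(21)
  pb <- c(runif(20, 0, 1e-4), runif(20))
  pw <- c(runif(20, 0, 1e-4), runif(20))
  fx <- fits_fixture(pb, pw, runif(40, 0, 0.02), runif(40, 0, 0.02))
  sel <- lapply(c(0.01, 0.05, 0.2), function(a)
    with(run_selection(fx[[1]], fx[[2]], alpha = a),
         paste(feature, association_type)[status == "validated"]))
  expect_true(all(sel[[1]] %in% sel[[2]]))
  expect_true(all(sel[[2]] %in% sel[[3]]))
})

test_that("adjusted p-values never fall below raw ones and validated implies candidate", {
  set.seed(22)
  fx <- fits_fixture(runif(30), runif(30), runif(30), runif(30))
  mk <- run_selection(fx[[1]], fx[[2]])
  expect_true(all(mk$p_adj_identification >= mk$p_identification))
  ok <- !is.na(mk$p_adj_validation)
  expect_true(all(mk$p_adj_validation[ok] >= mk$p_validation[ok]))
  expect_true(all(is.na(mk$p_adj_validation[mk$status == "rejected"])))
})

test_that("non-converged pairs are excluded and counted", {
  fx <- fits_fixture(c(1e-9, 1e-9), c(1e-9, 1e-9))
  fx[[1]]$converged[2] <- FALSE
  mk <- run_selection(fx[[1]], fx[[2]])
  expect_equal(attr(mk, "n_excluded"), 1L)
  expect_false("f02" %in% mk$feature)
})

test_that("split-half selection validates planted pairs in a small replicate", {
  r <- selection_replicate(n_participants = 120, n_timepoints = 5,
                           n_features = 8, n_domains = 3,
                           planted = list(list(feature = 2, domain = 3,
                                               rho_b = 0.7, rho_w = 0.5)),
                           seed = 31)
  expect_equal(r$n_true_validated, 1L)
  expect_equal(r$n_false_validated, 0L)
})
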