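test_that("cross-validation replicates are deterministic under a fixed seed", {
  d <- quick_dataset()
  r1 <- within_cycle_cv(d, "C1", "grain_yield", reps = 4, seed = 5)
  r2 <- within_cycle_cv(d, "C1", "grain_yield", reps = 4, seed = 5)
  expect_identical(r1$replicates, r2$replicates)
  r3 <- within_cycle_cv(d, "C1", "grain_yield", reps = 4, seed = 6)
  expect_false(identical(r1$replicates, r3$replicates))
  a1 <- across_cycle_cv(d, "grain_yield", 30, reps = 3, seed = 5)
  a2 <- across_cycle_cv(d, "grain_yield", 30, reps = 3, seed = 5)
  expect_identical(a1$replicates, a2$replicates)
})

test_that("between-cycle bias reuses the within-cycle folds bit-exactly", {
  d <- quick_dataset()
  w <- within_cycle_cv(d, "C1", "grain_yield", reps = 4, seed = 7)
  b <- between_cycle_bias(d, "C1", "grain_yield", reps = 4, seed = 7,
                          targets = c("C2", "C3"))
  expect_identical(b$within$replicates, w$replicates)
  expect_equal(b$r_within, w$mean)
  ## bias arithmetic is consistent with its inputs
  ok <- !b$bias$undefined
  expect_equal(b$bias$bias_pct[ok],
               (b$r_within - b$bias$r_between[ok]) / b$bias$r_between[ok] * 100)
  expect_true(all(is.na(b$bias$bias_pct[b$bias$undefined])))
})

test_that("excluding nothing reproduces the plain across-cycle scheme", {
  d <- quick_dataset()
  a <- across_cycle_cv(d, "grain_yield", 30, reps = 3, seed = 9)
  o <- outlier_corrected_cv(d, "grain_yield", character(0), 30, reps = 3,
                            seed = 9)
  expect_identical(a$replicates, o$replicates)
})

test_that("across-cycle scheme validates its sampling design", {
  d <- quick_dataset()
  expect_error(across_cycle_cv(d, "grain_yield", 0, reps = 2, seed = 1),
               "positive")
  odd <- across_cycle_cv(d, "grain_yield", 31, reps = 2, seed = 1)
  expect_equal(odd$train_size, 31)
  expect_error(across_cycle_cv(d, "grain_yield", 3000, reps = 2, seed = 1),
               "exceeds the size of cycle")
  one <- d
  one$blues <- one$blues[one$blues$cycle == "C1", ]
  expect_error(across_cycle_cv(one, "grain_yield", 10, reps = 2, seed = 1),
               ">= 2")
})

test_that("accuracies stay in [-1, 1] and r_MT accompanies synthetic data", {
  d <- quick_dataset()
  res <- within_cycle_cv(d, "C2", "protein_content", reps = 4, seed = 3)
  expect_true(all(abs(res$replicates) <= 1))
  expect_length(res$r_mt, 4)
  expect_true(all(abs(res$r_mt) <= 1))
})

test_that("the pairwise cycle matrix is deterministic with within-cycle diagonal", {
  d <- quick_dataset()
  M1 <- pairwise_cycle_matrix(d, "grain_yield", diag_reps = 3, seed = 4)
  M2 <- pairwise_cycle_matrix(d, "grain_yield", diag_reps = 3, seed = 4)
  expect_identical(M1, M2)
  expect_equal(dim(M1), c(4, 4))  # 3 cycles + validation cohort
  expect_equal(M1["C1", "C1"],
               within_cycle_cv(d, "C1", "grain_yield", reps = 3, seed = 4)$mean)
  expect_true(all(abs(M1[is.finite(M1)]) <= 1))
})

test_that("outlier identification follows the SD rule and the negative rule", {
  mk <- function(rows) {
    M <- matrix(rep(rows, each = 5), 5, 5, byrow = FALSE,
                dimnames = list(paste0("U", 1:5), paste0("U", 1:5)))
    for (i in 1:5) M[i, ] <- rows[i]
    diag(M) <- NA
    M
  }
  even <- mk(rep(0.4, 5))
  expect_length(identify_outliers(even), 0)
  skew <- mk(c(0.4, 0.42, 0.38, 0.41, 0.05))
  expect_equal(as.character(identify_outliers(skew)), "U5")
  neg <- mk(c(0.3, 0.32, 0.28, 0.33, -0.05))
  expect_true("U5" %in% identify_outliers(neg, rule_threshold_sd = 10,
                                          flag_negative = TRUE))
  expect_length(identify_outliers(neg, rule_threshold_sd = 10,
                                  flag_negative = FALSE), 0)
  expect_error(identify_outliers(even[1:2, 1:2]), ">= 3")
})

test_that("selection proportions hit their closed-form extremes", {
  set.seed(2)
  blue <- setNames(rnorm(60), sprintf("L%02d", 1:60))
  expect_equal(selection_proportion(blue, blue, 0.1), 1)
  expect_equal(selection_proportion(blue, blue, 0.3, "worst"), 1)
  expect_equal(selection_proportion(-blue, blue, 0.1), 0)
  p <- selection_proportion(sample(blue), blue, 0.2)
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("independent validation rejects overlap and reports proportions", {
  d <- quick_dataset()
  res <- independent_validation(d, c("C1", "C2", "C3"), "V", "grain_yield",
                                corrections = list(no_C2 = "C2"))
  expect_equal(nrow(res$accuracy), 2)
  expect_true(all(abs(res$accuracy$r_gs) <= 1))
  expect_true(all(res$proportions$proportion >= 0 &
                    res$proportions$proportion <= 1))
  expect_equal(nrow(res$proportions), 2 * 3 * 2) # 2 sets x 3 q x 2 directions
  bad <- d
  bad$blues$cycle[bad$blues$cycle == "V"] <- "C1"
  expect_error(independent_validation(bad, "C1", "C1", "grain_yield"),
               "overlap|disjoint|usable")
})

test_that("relatedness-accuracy curves cover the requested k grid", {
  d <- quick_dataset()
  w <- capture_warnings(
    rc <- relatedness_accuracy_correlation(d, "grain_yield",
                                           k_range = c(1, 10, 5000)))
  expect_true(any(grepl("truncated", w)))
  expect_true(all(c("cycle", "k", "correlation") %in% names(rc)))
  expect_true(all(abs(na.omit(rc$correlation)) <= 1))
  expect_true(all(rc$k <= nrow(d$blues)))
})

test_that("folds partition the sampling frame: no line in train and test", {
  ## reconstruct the fold assignment of a replicate through the substream
  d <- quick_dataset()
  lines <- d$blues$line[d$blues$cycle == "C1" &
                          !is.na(d$blues$grain_yield)]
  f <- gscycles:::substream_seed(5, "folds", "C1", 1)
  fold <- gscycles:::local_seed(f, sample(rep(1:5, length.out = length(lines))))
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), length(lines))
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("relatedness to the training set tracks line reliability at intermediate k", {
  d <- quick_dataset()
  rc <- suppressWarnings(
    relatedness_accuracy_correlation(d, "grain_yield", k_range = c(10, 20)))
  expect_gt(mean(rc$correlation[rc$k == 10]), 0.3)
})
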