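test_that("heritability formulas follow their closed forms and clamp", {
  expect_equal(piepho_moehring_h2(0, 1), 0)
  expect_equal(piepho_moehring_h2(3, 0), 1)
  expect_equal(piepho_moehring_h2(2, 2), 2 / 3, tolerance = 1e-12)
  expect_error(piepho_moehring_h2(0, 0), "undefined")
  expect_equal(across_trial_h2(0, 1, 3), 0)
  expect_equal(across_trial_h2(37.00, 54.48, 8), 0.8446, tolerance = 1e-4)
  expect_equal(across_trial_h2(0.18, 0.07, 2), 0.8372, tolerance = 1e-4)
  expect_error(across_trial_h2(1, 1, 0), "count")
  expect_error(across_trial_h2(0, 0, 2), "undefined")
})

test_that("heritability is scale invariant and non-decreasing in trials", {
  for (c_ in c(0.1, 1, 7, 1000)) {
    expect_equal(piepho_moehring_h2(2 * c_, 5 * c_), piepho_moehring_h2(2, 5),
                 tolerance = 1e-12)
    expect_equal(across_trial_h2(2 * c_, 5 * c_, 4), across_trial_h2(2, 5, 4),
                 tolerance = 1e-12)
  }
  h <- vapply(1:10, function(t) across_trial_h2(2, 5, t), 0)
  expect_true(all(diff(h) > 0))
})

fake_trial <- function(id, h2, cycle = "C1") {
  structure(list(trial_id = id, cycle = cycle, trait = "grain_yield",
                 blues = c(a = 1), se = c(a = 1), check_lines = character(0),
                 sigma2_G = 1, MVD = 1, h2 = h2, model_tag = "baseline",
                 converged = TRUE), class = "trial_result")
}

test_that("trial selection applies a strict heritability threshold", {
  trs <- list(fake_trial("T1", 0.30), fake_trial("T2", 0.31))
  kept <- select_trials(trs, 0.3)
  expect_equal(vapply(kept, `[[`, "", "trial_id"), "T2")
  all_pass <- list(fake_trial("T1", 0.5), fake_trial("T2", 0.6))
  expect_equal(length(select_trials(all_pass, 0.3)), 2)
  six <- lapply(1:6, function(i) fake_trial(paste0("T", i), i / 10))
  expect_equal(length(select_trials(six, 0.3)), 3)
  expect_error(select_trials(list(fake_trial("T1", 0.1))), "no usable trials")
})

test_that("a near-noise-free trial returns the plot values as BLUEs with h2 -> 1", {
  cfg <- program_config(n_cycles = 1, lines_per_cycle = 12, n_founders = 6,
                        n_markers = 60, n_qtl = 15, trials_per_cycle = 1,
                        gxe_variance_ratio = 0,
                        spatial_sd = c(grain_yield = 0, protein_content = 0),
                        resid_sd = c(grain_yield = 1e-3, protein_content = 1e-4),
                        missing_rate = 0, seed = 19)
  pop <- simulate_genotypes(cfg)
  plots <- simulate_phenotypes(pop)
  one <- plots[plots$trial == "C1_T1", ]
  res <- fit_trial_model(one, trait = "grain_yield", models = "baseline")
  test_plots <- one[one$trait == "grain_yield" & !one$is_check, ]
  expect_equal(unname(res$blues[test_plots$line]), test_plots$value,
               tolerance = 1e-6)
  expect_lt(res$MVD, 1e-4)
  expect_gt(res$h2, 0.999)
})

test_that("balanced replicated-trial BLUEs equal line means (OLS oracle)", {
  set.seed(12)
  lines <- sprintf("L%02d", 1:10)
  plots <- expand.grid(line = lines, rep = 1:3, stringsAsFactors = FALSE)
  plots$cycle <- "C1"; plots$trial <- "T1"; plots$is_check <- FALSE
  plots$row <- plots$rep; plots$col <- match(plots$line, lines)
  plots$trait <- "grain_yield"
  eff <- rnorm(10, 80, 3)
  plots$value <- eff[match(plots$line, lines)] + rnorm(nrow(plots), 0, 1)
  res <- fit_trial_model(plots, trait = "grain_yield", models = "baseline")
  oracle <- tapply(plots$value, plots$line, mean)
  expect_equal(res$blues[names(oracle)], oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a strong row effect makes the row model win the AIC comparison", {
  wins <- replicate(20, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    lines <- sprintf("L%02d", 1:20)
    entries <- c(lines, rep(sprintf("CHK%d", 1:2), each = 4))
    n <- length(entries)
    rowpos <- rep(1:4, length.out = n)
    plots <- data.frame(cycle = "C1", trial = "T1", line = entries,
                        is_check = grepl("CHK", entries),
                        row = rowpos, col = seq_len(n),
                        trait = "grain_yield",
                        value = rnorm(28, 80, 2)[match(entries, unique(entries))] +
                          rnorm(4, 0, 4)[rowpos] + rnorm(n, 0, 1))
    fit_trial_model(plots, trait = "grain_yield",
                    models = c("baseline", "row"))$model_tag
  })
  expect_gt(mean(wins == "row"), 0.5)
})

test_that("stage 2 recovers variance components and their heritability", {
  ## direct stage-2 level simulation: known sigma2_G = 5, sigma2_GT = 20, 4 trials
  h2s <- replicate(20, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    L <- 40
    g <- rnorm(L, 0, sqrt(5)); tj <- rnorm(4, 0, 3)
    trs <- lapply(1:4, function(j) {
      blue <- 80 + g + tj[j] + rnorm(L, 0, sqrt(20)) + rnorm(L, 0, 0.5)
      structure(list(trial_id = paste0("T", j), cycle = "C1",
                     trait = "grain_yield",
                     blues = setNames(blue, sprintf("L%02d", 1:L)),
                     se = setNames(rep(0.5, L), sprintf("L%02d", 1:L)),
                     check_lines = character(0), sigma2_G = NA, MVD = NA,
                     h2 = 0.9, model_tag = "baseline", converged = TRUE),
                class = "trial_result")
    })
    fit_stage2(trs, trait = "grain_yield")$h2
  })
  expect_lt(abs(mean(h2s) - 5 / (5 + 20 / 4)), 0.1)
})

test_that("two identical trials give a vanishing interaction variance", {
  set.seed(5)
  L <- 25
  blue <- setNames(rnorm(L, 80, 2), sprintf("L%02d", 1:L))
  mk <- function(id) structure(
    list(trial_id = id, cycle = "C1", trait = "grain_yield", blues = blue,
         se = setNames(rep(0.4, L), names(blue)), check_lines = character(0),
         sigma2_G = NA, MVD = NA, h2 = 0.9, model_tag = "baseline",
         converged = TRUE), class = "trial_result")
  cb <- fit_stage2(list(mk("T1"), mk("T2")), trait = "grain_yield")
  expect_lt(cb$sigma2_GT, 0.05)
  expect_gt(cb$h2, 0.95)
  expect_error(fit_stage2(list(mk("T1")), trait = "grain_yield"), ">= 2 trials")
})

test_that("with equal weights and balanced data stage-2 BLUEs are line means", {
  set.seed(8)
  L <- 15
  lines <- sprintf("L%02d", 1:L)
  vals <- matrix(rnorm(L * 3, 80, 3), L, 3)
  trs <- lapply(1:3, function(j) structure(
    list(trial_id = paste0("T", j), cycle = "C1", trait = "grain_yield",
         blues = setNames(vals[, j], lines),
         se = setNames(rep(1, L), lines), check_lines = character(0),
         sigma2_G = NA, MVD = NA, h2 = 0.9, model_tag = "baseline",
         converged = TRUE), class = "trial_result"))
  cb <- fit_stage2(trs, trait = "grain_yield")
  expect_equal(unname(cb$blues[lines]), unname(rowMeans(vals)),
               tolerance = 1e-6)
})

test_that("check lines are excluded from stage 2", {
  set.seed(3)
  L <- 12
  lines <- c(sprintf("L%02d", 1:L), "CHK1")
  mk <- function(id) structure(
    list(trial_id = id, cycle = "C1", trait = "grain_yield",
         blues = setNames(rnorm(L + 1, 80, 2), lines),
         se = setNames(rep(0.5, L + 1), lines), check_lines = "CHK1",
         sigma2_G = NA, MVD = NA, h2 = 0.9, model_tag = "baseline",
         converged = TRUE), class = "trial_result")
  cb <- fit_stage2(list(mk("T1"), mk("T2")), trait = "grain_yield")
  expect_false("CHK1" %in% names(cb$blues))
  expect_equal(cb$n_lines, L)
})

test_that("stage-1 errors are informative", {
  plots <- data.frame(cycle = "C1", trial = "T1",
                      line = sprintf("L%02d", 1:10), is_check = FALSE,
                      row = 1:10, col = 1, trait = "grain_yield",
                      value = rnorm(10, 80, 2))
  expect_error(fit_trial_model(plots, trait = "grain_yield"),
               "no replication")
  expect_error(fit_trial_model(plots, trait = "bogus"), "unknown trait")
})
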