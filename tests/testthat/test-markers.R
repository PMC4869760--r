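## hand-set 10-line x 6-marker QC fixture: per-marker missingness and minor
## allele frequency patterns chosen to hit each rule
qc_fixture <- function() {
  m <- matrix(1, 10, 6, dimnames = list(sprintf("L%02d", 1:10),
                                        sprintf("M%d", 1:6)))
  m[, 1] <- c(-1, 1, -1, 1, -1, 1, -1, 1, -1, 1)   # clean, MAF 0.5
  m[, 2] <- 1                                      # monomorphic
  m[1:2, 3] <- NA; m[3:10, 3] <- c(-1, 1, -1, 1, -1, 1, -1, 1) # 20% missing
  m[1, 4] <- NA; m[2:10, 4] <- c(1, -1, 1, 1, 1, 1, 1, 1, 1)   # 10% miss, MAF 1/9
  m[, 5] <- c(rep(1, 9), -1)                        # MAF 0.05 -> below 0.05? = 0.05
  m[, 6] <- c(rep(1, 8), -1, -1)                    # MAF 0.2, clean
  m
}

test_that("marker QC matches a brute-force evaluation of the three rules", {
  m <- marker_matrix(qc_fixture())
  f <- filter_markers(m, min_call_rate = 0.90, min_maf = 0.05,
                      max_missing = 0.10)
  ## independent brute force, marker by marker
  keep_oracle <- logical(6)
  for (k in 1:6) {
    col <- qc_fixture()[, k]
    cr <- mean(!is.na(col))
    p <- mean((col[!is.na(col)] + 1) / 2)
    keep_oracle[k] <- cr >= 0.90 && min(p, 1 - p) >= 0.05 &&
      mean(is.na(col)) <= 0.10
  }
  expect_identical(colnames(f), colnames(m)[keep_oracle])
  ## spot checks: clean marker kept, monomorphic and high-missing removed
  expect_true("M1" %in% colnames(f))
  expect_false("M2" %in% colnames(f))
  expect_false("M3" %in% colnames(f))
  counts <- attr(f, "qc_counts")
  expect_equal(unname(counts["retained"] + counts["removed"]), 6)
})

test_that("QC errors when every marker is removed", {
  m <- marker_matrix(matrix(1, 5, 3, dimnames = list(paste0("L", 1:5),
                                                     paste0("M", 1:3))))
  expect_error(filter_markers(m), "empty marker set")
})

test_that("imputation returns complete data without touching observed calls", {
  pop <- simulate_genotypes(program_config(
    n_cycles = 2, lines_per_cycle = c(30, 30), n_founders = 10,
    n_markers = 150, n_qtl = 30, trials_per_cycle = c(2, 2), target_h2 = 0.5,
    missing_rate = 0.05, seed = 17))
  m <- filter_markers(pop$geno)
  obs <- !is.na(unclass(m))
  imp <- impute_missing(m)
  expect_false(anyNA(unclass(imp)))
  expect_equal(unclass(imp)[obs], unclass(m)[obs])
  expect_true(all(unclass(imp) >= -1 & unclass(imp) <= 1))
  ## a matrix without missing entries comes back unchanged
  expect_equal(unclass(impute_missing(imp)), unclass(imp), ignore_attr = TRUE)
})

test_that("imputation exploits a duplicated line profile", {
  set.seed(4)
  base <- matrix(sample(c(-1, 1), 8 * 300, TRUE), 8, 300,
                 dimnames = list(sprintf("L%02d", 1:8), sprintf("M%03d", 1:300)))
  base[2, ] <- base[1, ]               # line 2 duplicates line 1
  truth <- base[2, 40]
  base[2, 40] <- NA
  imp <- impute_missing(marker_matrix(base))
  expect_lt(abs(unclass(imp)[2, 40] - truth), 0.1)
})

test_that("MVN-EM beats column-mean imputation on missing-at-random data", {
  pop <- simulate_genotypes(program_config(
    n_cycles = 2, lines_per_cycle = c(35, 35), n_founders = 8,
    n_markers = 160, n_qtl = 30, trials_per_cycle = c(2, 2), target_h2 = 0.5,
    missing_rate = 0, seed = 23))
  X <- unclass(pop$geno_true)
  set.seed(99)
  mask <- matrix(runif(length(X)) < 0.05, nrow(X))
  Xm <- X; Xm[mask] <- NA
  imp <- impute_missing(marker_matrix(Xm))
  mse_em <- mean((unclass(imp)[mask] - X[mask])^2)
  colmean <- matrix(rep(colMeans(Xm, na.rm = TRUE), each = nrow(X)), nrow(X))
  mse_cm <- mean((colmean[mask] - X[mask])^2)
  expect_lt(mse_em, mse_cm)
})

test_that("kinship matches a brute-force centred cross-product on a 3x4 fixture", {
  Z <- matrix(c(1, -1, 1, 1,
                -1, 1, 1, -1,
                1, 1, -1, 1), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("M", 1:4)))
  K <- compute_kinship(marker_matrix(Z))
  ## independent brute force with explicit loops
  p <- numeric(4); W <- Z * 0
  for (k in 1:4) {
    p[k] <- mean((Z[, k] + 1) / 2)
    W[, k] <- Z[, k] - mean(Z[, k])
  }
  denom <- 2 * sum(p * (1 - p))
  Ko <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) Ko[i, j] <- sum(W[i, ] * W[j, ]) / denom
  expect_equal(unclass(K), Ko, ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(unclass(K)))), 1e-8)
})

test_that("duplicated fully homozygous lines have identical kinship rows", {
  set.seed(6)
  Z <- matrix(sample(c(-1, 1), 6 * 40, TRUE), 6, 40,
              dimnames = list(paste0("L", 1:6), paste0("M", 1:40)))
  Z[2, ] <- Z[1, ]
  Z[3, ] <- -Z[1, ]   # guarantees every marker stays polymorphic
  K <- unclass(compute_kinship(marker_matrix(Z)))
  expect_equal(K[1, ], K[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_equal(K[1, 2], K[2, 2], tolerance = 1e-12)
})

test_that("kinship is invariant to marker order and equivariant to line order", {
  set.seed(7)
  Z <- matrix(sample(c(-1, 0, 1), 8 * 50, TRUE, prob = c(.48, .04, .48)), 8, 50,
              dimnames = list(paste0("L", 1:8), paste0("M", 1:50)))
  K <- unclass(compute_kinship(marker_matrix(Z)))
  pm <- sample(50); pl <- sample(8)
  K2 <- unclass(compute_kinship(marker_matrix(Z[, pm])))
  expect_equal(K2, K, tolerance = 1e-12, ignore_attr = TRUE)
  K3 <- unclass(compute_kinship(marker_matrix(Z[pl, ])))
  expect_equal(K3, K[pl, pl], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("kinship refuses monomorphic or missing input", {
  Z <- matrix(c(1, 1, 1, -1, 1, -1), 3, 2,
              dimnames = list(paste0("L", 1:3), c("mono", "ok")))
  expect_error(compute_kinship(marker_matrix(Z)), "monomorphic")
  Z2 <- Z; Z2[1, 2] <- NA
  expect_error(compute_kinship(marker_matrix(Z2)), "impute")
})

test_that("QC -> imputation -> kinship is idempotent on clean data", {
  pop <- simulate_genotypes(program_config(
    n_cycles = 1, lines_per_cycle = 20, n_founders = 8, n_markers = 100,
    n_qtl = 20, trials_per_cycle = 2, target_h2 = 0.5, missing_rate = 0,
    seed = 31))
  m1 <- impute_missing(filter_markers(pop$geno))
  m2 <- impute_missing(filter_markers(m1))
  expect_equal(unclass(m1), unclass(m2), ignore_attr = TRUE)
  expect_equal(unclass(compute_kinship(m1)), unclass(compute_kinship(m2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("genotypes survive a VCF round-trip, multiallelic rows are skipped", {
  Z <- matrix(c(-1, 0, 1, NA, 1, -1, 0, 1, -1, 1, 1, -1), 4, 3,
              dimnames = list(paste0("L", 1:4), paste0("M", 1:3)))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(marker_matrix(Z), vcf)
  back <- read_genotypes_vcf(vcf)
  expect_equal(unclass(back)[rownames(Z), colnames(Z)], unclass(Z))
  ## append a multiallelic record: it must be skipped with a warning
  lines <- readLines(vcf)
  lines <- c(lines, "1\t99\tMx\tA\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0")
  writeLines(lines, vcf)
  expect_warning(back2 <- read_genotypes_vcf(vcf), "multiallelic")
  expect_false("Mx" %in% colnames(back2))
})

test_that("the kinship matrix survives a CSV round-trip", {
  set.seed(9)
  Z <- matrix(sample(c(-1, 1), 6 * 30, TRUE), 6, 30,
              dimnames = list(paste0("L", 1:6), paste0("M", 1:30)))
  Z[2, ] <- -Z[1, ]
  K <- compute_kinship(marker_matrix(Z))
  f <- withr::local_tempfile(fileext = ".csv")
  write_kinship_csv(K, f)
  back <- read_kinship_csv(f)
  expect_equal(unclass(back), unclass(K), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(K))
})
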