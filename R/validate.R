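## validate: cross-validation schemes and diagnostics for genomic selection
## across breeding cycles. Accuracy r_GS is the Pearson correlation between
## GEBVs and (withheld) line BLUEs; on simulated data the correlation with
## true breeding values r_MT is reported alongside. All schemes draw their
## randomness from indexed substreams of one master seed, so the
## between-cycle scheme can reuse the within-cycle folds bit-exactly.

#' Bundle genotypes, line BLUEs and (optionally) true breeding values
#'
#' @param geno A complete (imputed) [marker_matrix()] covering all lines.
#' @param blues Data frame with columns `line`, `cycle` and one numeric
#'   column per trait (stage-2 adjusted means).
#' @param tbv Optional data frame `line` + per-trait true breeding values.
#' @param K Optional precomputed `kinship_matrix` (computed on demand
#'   otherwise).
#' @return A list of class `gs_data`.
#' @export
gs_data <- function(geno, blues, tbv = NULL, K = NULL) {
  stopifnot(is.data.frame(blues), all(c("line", "cycle") %in% names(blues)))
  if (anyNA(unclass(geno))) stop("genotypes contain missing calls: impute first")
  missing_geno <- setdiff(blues$line, rownames(geno))
  if (length(missing_geno))
    stop("lines without genotypes: ", paste(head(missing_geno, 5), collapse = ", "))
  if (anyDuplicated(blues[, c("line", "cycle")]))
    stop("duplicated line/cycle rows in blues")
  structure(list(geno = geno, blues = blues, tbv = tbv, K = K),
            class = "gs_data")
}

#' @export
print.gs_data <- function(x, ...) {
  cat("gs_data:", nrow(x$blues), "line records in",
      length(unique(x$blues$cycle)), "cycles;",
      ncol(x$geno), "markers; traits:",
      paste(setdiff(names(x$blues), c("line", "cycle")), collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a `gs_data` object from a simulated population and its analysis
#'
#' Runs marker QC and imputation on the population's genotypes and collects
#' the stage-2 BLUEs of every trait and cycle into the wide layout used by
#' the cross-validation schemes.
#'
#' @param pop A `true_population`.
#' @param analysis A `pheno_analysis` from [analyze_phenotypes()].
#' @return A [gs_data()] object (with `tbv` attached).
#' @export
gs_data_from_analysis <- function(pop, analysis) {
  geno <- impute_missing(filter_markers(pop$geno))
  lines <- unique(unlist(lapply(analysis, function(a)
    lapply(a$cycles, function(cb) names(cb$blues)))))
  out <- data.frame(line = lines,
                    cycle = unname(pop$cycle[lines]),
                    stringsAsFactors = FALSE)
  for (tr in names(analysis)) {
    v <- rep(NA_real_, length(lines))
    for (cb in analysis[[tr]]$cycles) {
      idx <- match(names(cb$blues), lines)
      v[idx[!is.na(idx)]] <- cb$blues[!is.na(idx)]
    }
    out[[tr]] <- v
  }
  gs_data(geno, out, tbv = pop$tbv)
}

cv_lines <- function(data, cycle, trait) {
  b <- data$blues
  keep <- b$cycle == cycle & !is.na(b[[trait]])
  b$line[keep]
}

safe_cor <- function(a, b) {
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

blue_of <- function(data, lines, trait) {
  b <- data$blues
  setNames(b[[trait]], b$line)[lines]
}

tbv_of <- function(data, lines, trait) {
  if (is.null(data$tbv) || !trait %in% names(data$tbv)) return(NULL)
  setNames(data$tbv[[trait]], data$tbv$line)[lines]
}

new_cv_result <- function(scheme, trait, train_size, r_gs, r_mt = NULL, ...) {
  structure(list(scheme = scheme, trait = trait, train_size = train_size,
                 replicates = r_gs, r_mt = r_mt,
                 mean = mean(r_gs, na.rm = TRUE),
                 sd = sd(r_gs, na.rm = TRUE), ...),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s CV (%s): mean r_GS = %.3f (sd %.3f, %d replicates, n_train ~ %d)\n",
              x$scheme, x$trait, x$mean, x$sd, length(x$replicates),
              round(x$train_size)))
  invisible(x)
}

## shared engine for within-cycle folds, optionally predicting other cycles
## with the same per-fold training populations
cycle_cv_engine <- function(data, cycle, trait, n_folds, reps, seed,
                            targets = character(0),
                            pooling = c("per_fold", "pooled")) {
  pooling <- match.arg(pooling)
  lines <- cv_lines(data, cycle, trait)
  n <- length(lines)
  if (n < n_folds) stop("cycle ", cycle, " has fewer lines than folds")
  if (floor(n / n_folds) < 3)
    stop("folds would have < 3 lines: correlation undefined")
  blue <- blue_of(data, lines, trait)
  tbv <- tbv_of(data, lines, trait)
  Z <- unclass(data$geno)[lines, , drop = FALSE]
  tgt <- lapply(targets, function(tc) {
    tl <- cv_lines(data, tc, trait)
    list(lines = tl, blue = blue_of(data, tl, trait),
         Z = unclass(data$geno)[tl, , drop = FALSE])
  })
  names(tgt) <- targets
  r_gs <- numeric(reps); r_mt <- if (!is.null(tbv)) numeric(reps) else NULL
  r_tgt <- matrix(NA_real_, reps, length(targets),
                  dimnames = list(NULL, targets))
  for (r in seq_len(reps)) {
    fold <- local_seed(substream_seed(seed, "folds", cycle, r),
                       sample(rep(seq_len(n_folds), length.out = n)))
    fr <- numeric(n_folds); fmt <- numeric(n_folds)
    ftgt <- matrix(NA_real_, n_folds, length(targets))
    pool_g <- NULL; pool_b <- NULL; pool_t <- NULL
    for (f in seq_len(n_folds)) {
      tr_i <- fold != f; te_i <- !tr_i
      fit <- suppressWarnings(fit_rrblup(blue[tr_i], Z[tr_i, , drop = FALSE]))
      gebv <- drop(Z[te_i, , drop = FALSE] %*% fit$u)
      fr[f] <- safe_cor(gebv, blue[te_i])
      if (!is.null(tbv)) fmt[f] <- safe_cor(gebv, tbv[te_i])
      pool_g <- c(pool_g, gebv); pool_b <- c(pool_b, blue[te_i])
      if (!is.null(tbv)) pool_t <- c(pool_t, tbv[te_i])
      for (j in seq_along(tgt)) {
        gt <- drop(tgt[[j]]$Z %*% fit$u)
        ftgt[f, j] <- safe_cor(gt, tgt[[j]]$blue)
      }
    }
    if (pooling == "per_fold") {
      r_gs[r] <- mean(fr, na.rm = TRUE)
      if (!is.null(tbv)) r_mt[r] <- mean(fmt, na.rm = TRUE)
    } else {
      r_gs[r] <- safe_cor(pool_g, pool_b)
      if (!is.null(tbv)) r_mt[r] <- safe_cor(pool_g, pool_t)
    }
    if (length(targets)) r_tgt[r, ] <- colMeans(ftgt, na.rm = TRUE)
  }
  list(r_gs = r_gs, r_mt = r_mt, r_tgt = r_tgt,
       train_size = n - n / n_folds, n = n)
}

#' Within-cycle fivefold cross-validation
#'
#' Lines of one cycle are split into `n_folds` near-equal random folds; the
#' model is trained on the others (80% of lines for five folds) and the
#' left-out fold predicted. The replicate accuracy is the per-fold Pearson
#' correlation averaged over folds (set `pooling = "pooled"` to correlate
#' the pooled predictions instead).
#'
#' @param data A [gs_data()] object.
#' @param cycle Cycle label.
#' @param trait Trait name.
#' @param n_folds,reps Folds per replicate and number of replicates.
#' @param seed Master seed.
#' @param pooling Replicate summary, see above.
#' @return A `cv_result`; `r_mt` holds the accuracy against true breeding
#'   values when `data$tbv` is available.
#' @export
within_cycle_cv <- function(data, cycle, trait, n_folds = 5, reps = 100,
                            seed = 1, pooling = c("per_fold", "pooled")) {
  eng <- cycle_cv_engine(data, cycle, trait, n_folds, reps, seed,
                         pooling = match.arg(pooling))
  new_cv_result("within_cycle", trait, eng$train_size, eng$r_gs, eng$r_mt,
                cycle = cycle, n_folds = n_folds, seed = seed)
}

#' Between-cycle prediction and bias of within-cycle cross-validation
#'
#' Reuses the exact within-cycle training folds of `train_cycle` (same master
#' seed, bit-identical partitions) to predict every other cycle in full, and
#' quantifies the bias of the within-cycle estimate as
#' `(r_within - r_between) / r_between * 100` per target cycle (positive bias
#' means within-cycle cross-validation overestimates). Targets with
#' `r_between <= 0` are flagged and their bias reported as `NA`.
#'
#' @inheritParams within_cycle_cv
#' @param train_cycle Cycle providing the training folds.
#' @param targets Cycles to predict (default: all others).
#' @return A list with `within` (the `cv_result`), `r_within`, and `bias`
#'   (data frame: target cycle, `r_between`, `bias_pct`, `undefined`).
#' @export
between_cycle_bias <- function(data, train_cycle, trait, targets = NULL,
                               n_folds = 5, reps = 100, seed = 1) {
  cycles <- unique(data$blues$cycle)
  targets <- targets %||% setdiff(cycles, train_cycle)
  if (!length(targets)) stop("need >= 2 cycles")
  eng <- cycle_cv_engine(data, train_cycle, trait, n_folds, reps, seed,
                         targets = targets)
  r_within <- mean(eng$r_gs, na.rm = TRUE)
  r_between <- colMeans(eng$r_tgt, na.rm = TRUE)
  undefined <- r_between <= 0
  bias <- ifelse(undefined, NA_real_,
                 (r_within - r_between) / r_between * 100)
  list(within = new_cv_result("within_cycle", trait, eng$train_size,
                              eng$r_gs, eng$r_mt, cycle = train_cycle),
       r_within = r_within,
       bias = data.frame(target_cycle = targets,
                         r_between = unname(r_between),
                         bias_pct = unname(bias),
                         undefined = unname(undefined),
                         row.names = NULL))
}

#' Across-cycle cross-validation with cycles as folds
#'
#' Each cycle in turn is held out; an equal number of lines is sampled from
#' every remaining cycle so that the training population totals
#' `train_size_total`, a fixed cycle (year) effect is included when requested,
#' and all lines of the held-out cycle are predicted. The replicate value is
#' the mean accuracy over held-out cycles. `exclude` removes cycles from the
#' training role (their sampling quota is re-divided over the remaining
#' cycles, keeping the training size constant); by default excluded cycles
#' are not used as validation folds either (`predict_excluded = TRUE` keeps
#' them as folds).
#'
#' @inheritParams within_cycle_cv
#' @param train_size_total Total training population size; divided equally
#'   over the training cycles (a remainder is spread one line per cycle).
#' @param with_year_effect Include fixed cycle-indicator effects.
#' @param exclude Cycles dropped from the training role.
#' @param predict_excluded Keep excluded cycles as validation folds.
#' @return A `cv_result` (scheme `"across_cycle"` or `"outlier_corrected"`),
#'   with a `per_cycle` matrix (replicates x held-out cycle) attached.
#' @export
across_cycle_cv <- function(data, trait, train_size_total, reps = 100,
                            seed = 1, with_year_effect = TRUE,
                            exclude = NULL, predict_excluded = FALSE) {
  if (train_size_total <= 0) stop("train_size_total must be positive")
  cycles <- unique(data$blues$cycle)
  cycles <- cycles[vapply(cycles, function(cc) length(cv_lines(data, cc, trait)) > 0, TRUE)]
  if (length(setdiff(cycles, exclude)) < 2) stop("need >= 2 training cycles")
  folds_out <- if (predict_excluded) cycles else setdiff(cycles, exclude)
  per_cycle <- matrix(NA_real_, reps, length(folds_out),
                      dimnames = list(NULL, folds_out))
  per_cycle_mt <- per_cycle
  has_tbv <- !is.null(data$tbv) && trait %in% names(data$tbv)
  train_sets <- lapply(folds_out, function(h) setdiff(setdiff(cycles, h), exclude))
  names(train_sets) <- folds_out
  quotas_for <- function(tc) {
    ## equal quotas; any remainder is spread one line per cycle in order
    q <- rep(train_size_total %/% length(tc), length(tc))
    rem <- train_size_total - sum(q)
    if (rem > 0) q[seq_len(rem)] <- q[seq_len(rem)] + 1
    names(q) <- tc
    q
  }
  for (h in folds_out) {
    q <- quotas_for(train_sets[[h]])
    for (cc in names(q)) {
      if (length(cv_lines(data, cc, trait)) < q[[cc]])
        stop("quota ", q[[cc]], " exceeds the size of cycle ", cc)
    }
  }
  for (r in seq_len(reps)) {
    for (h in folds_out) {
      tc <- train_sets[[h]]
      q <- quotas_for(tc)
      tr_lines <- unlist(lapply(tc, function(cc) {
        ls <- cv_lines(data, cc, trait)
        local_seed(substream_seed(seed, "acv", r, h, cc),
                   sample(ls, q[[cc]]))
      }))
      te_lines <- cv_lines(data, h, trait)
      y <- blue_of(data, tr_lines, trait)
      Z <- unclass(data$geno)[tr_lines, , drop = FALSE]
      cyc_f <- factor(data$blues$cycle[match(tr_lines, data$blues$line)])
      X <- if (with_year_effect && nlevels(cyc_f) > 1)
        model.matrix(~cyc_f) else NULL
      fit <- suppressWarnings(fit_rrblup(y, Z, X = X))
      gebv <- drop(unclass(data$geno)[te_lines, , drop = FALSE] %*% fit$u)
      per_cycle[r, h] <- safe_cor(gebv, blue_of(data, te_lines, trait))
      if (has_tbv)
        per_cycle_mt[r, h] <- safe_cor(gebv, tbv_of(data, te_lines, trait))
    }
  }
  res <- new_cv_result(if (length(exclude)) "outlier_corrected" else "across_cycle",
                       trait, train_size_total,
                       rowMeans(per_cycle, na.rm = TRUE),
                       if (has_tbv) rowMeans(per_cycle_mt, na.rm = TRUE),
                       seed = seed, exclude = exclude)
  res$per_cycle <- per_cycle
  res
}

#' Across-cycle cross-validation with outlier cycles removed
#'
#' Thin wrapper over [across_cycle_cv()] that drops `excluded_units` from the
#' training role while keeping the training population size constant.
#'
#' @inheritParams across_cycle_cv
#' @param excluded_units Cycles to exclude.
#' @export
outlier_corrected_cv <- function(data, trait, excluded_units,
                                 train_size_total, reps = 100, seed = 1,
                                 with_year_effect = TRUE,
                                 predict_excluded = FALSE) {
  across_cycle_cv(data, trait, train_size_total, reps = reps, seed = seed,
                  with_year_effect = with_year_effect,
                  exclude = excluded_units,
                  predict_excluded = predict_excluded)
}

#' Pairwise prediction-accuracy matrix between breeding cycles
#'
#' Off-diagonal entry (a, b): train on all lines of cycle a, predict all
#' lines of cycle b. The diagonal holds the mean within-cycle
#' cross-validation accuracy. The matrix is not symmetric in general; row a
#' summarises how well cycle a serves as a training population.
#'
#' @inheritParams within_cycle_cv
#' @param diag_reps Replicates for the within-cycle diagonal.
#' @return A cycles x cycles numeric matrix.
#' @export
pairwise_cycle_matrix <- function(data, trait, n_folds = 5, diag_reps = 20,
                                  seed = 1) {
  cycles <- unique(data$blues$cycle)
  cycles <- cycles[vapply(cycles, function(cc)
    length(cv_lines(data, cc, trait)) >= 3, TRUE)]
  if (length(cycles) < 2) stop("need >= 2 cycles")
  M <- matrix(NA_real_, length(cycles), length(cycles),
              dimnames = list(train = cycles, test = cycles))
  fits <- lapply(cycles, function(a) {
    ls <- cv_lines(data, a, trait)
    suppressWarnings(fit_rrblup(blue_of(data, ls, trait),
                                unclass(data$geno)[ls, , drop = FALSE]))
  })
  names(fits) <- cycles
  for (a in cycles) {
    for (b in cycles) {
      if (a == b) next
      tl <- cv_lines(data, b, trait)
      gebv <- drop(unclass(data$geno)[tl, , drop = FALSE] %*% fits[[a]]$u)
      M[a, b] <- safe_cor(gebv, blue_of(data, tl, trait))
    }
    M[a, a] <- tryCatch(
      within_cycle_cv(data, a, trait, n_folds = n_folds, reps = diag_reps,
                      seed = seed)$mean,
      error = function(e) NA_real_)
  }
  M
}

#' Pairwise prediction-accuracy matrix between trials of one cycle
#'
#' Trains on the stage-1 BLUEs of one trial and predicts the genotyped lines
#' of every other trial, approximating the genetic correlation among trials.
#' The diagonal is `NA`.
#'
#' @param stage1 List of `trial_result` objects (one cycle, one trait).
#' @param geno Complete [marker_matrix()].
#' @return A trials x trials matrix.
#' @export
pairwise_trial_matrix <- function(stage1, geno) {
  ids <- vapply(stage1, `[[`, "", "trial_id")
  if (length(ids) < 2) stop("need >= 2 trials")
  sets <- lapply(stage1, function(tr) {
    keep <- setdiff(names(tr$blues), tr$check_lines)
    keep <- intersect(keep, rownames(geno))
    list(lines = keep, blue = tr$blues[keep])
  })
  names(sets) <- ids
  M <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(train = ids, test = ids))
  for (a in ids) {
    fit <- suppressWarnings(fit_rrblup(sets[[a]]$blue,
                      unclass(geno)[sets[[a]]$lines, , drop = FALSE]))
    for (b in setdiff(ids, a)) {
      gebv <- drop(unclass(geno)[sets[[b]]$lines, , drop = FALSE] %*% fit$u)
      M[a, b] <- safe_cor(gebv, sets[[b]]$blue)
    }
  }
  M
}

#' Identify outlier cycles or trials from a pairwise accuracy matrix
#'
#' A unit is flagged when its mean off-diagonal accuracy in the training role
#' (row mean) falls below the overall mean by more than `rule_threshold_sd`
#' standard deviations of the row means. With `flag_negative = TRUE` (the
#' trial-level rule) units whose mean training accuracy is negative are
#' flagged as well.
#'
#' @param mat Matrix from [pairwise_cycle_matrix()] or
#'   [pairwise_trial_matrix()].
#' @param rule_threshold_sd Threshold in SD units.
#' @param flag_negative Additionally flag negative row means.
#' @return Character vector of flagged unit labels; the row-mean table is
#'   attached as attribute `summary`.
#' @export
identify_outliers <- function(mat, rule_threshold_sd = 1.0,
                              flag_negative = FALSE) {
  if (nrow(mat) < 3) stop("need >= 3 units to identify outliers")
  off <- mat
  diag(off) <- NA
  rm_ <- rowMeans(off, na.rm = TRUE)
  mu <- mean(rm_); s <- sd(rm_)
  flagged <- rm_ < mu - rule_threshold_sd * s
  if (flag_negative) flagged <- flagged | rm_ < 0
  out <- names(rm_)[flagged]
  attr(out, "summary") <- data.frame(unit = names(rm_), train_mean = unname(rm_),
                                     flagged = unname(flagged), row.names = NULL)
  out
}

#' Proportion of correctly selected lines
#'
#' Fraction of the truly best (or worst) `q` of lines by BLUE that are also
#' in the best (worst) `q` by GEBV; ties are broken by line id.
#'
#' @param gebv,blue Named, aligned numeric vectors.
#' @param q Selected fraction in (0, 1).
#' @param direction `"best"` (largest values) or `"worst"`.
#' @return A proportion in `[0, 1]`.
#' @export
selection_proportion <- function(gebv, blue, q, direction = c("best", "worst")) {
  direction <- match.arg(direction)
  stopifnot(length(gebv) == length(blue), q > 0, q < 1)
  n_sel <- max(1L, round(q * length(blue)))
  sgn <- if (direction == "best") -1 else 1
  ids <- names(blue) %||% as.character(seq_along(blue))
  top_g <- ids[order(sgn * gebv, ids)][seq_len(n_sel)]
  top_b <- ids[order(sgn * blue, ids)][seq_len(n_sel)]
  length(intersect(top_g, top_b)) / n_sel
}

#' Independent validation with selection proportions
#'
#' Fits the model on the full training cycles and on each corrected training
#' set, predicts the independent validation cycle, and reports the accuracy
#' together with the proportion of correctly selected best/worst lines over a
#' grid of selection fractions.
#'
#' @inheritParams within_cycle_cv
#' @param train_cycles Cycles forming the training population.
#' @param validation_cycle The independent cycle (disjoint line set).
#' @param corrections Named list of cycle subsets to drop from training
#'   (e.g. `list(drop_C3 = "C3")`).
#' @param q Selection fractions.
#' @param with_year_effect Include fixed cycle effects in training.
#' @return A list with `accuracy` (data frame: training set, `r_gs`, optional
#'   `r_mt`, `n_train`) and `proportions` (data frame over training set, `q`,
#'   direction).
#' @export
independent_validation <- function(data, train_cycles, validation_cycle,
                                   trait, corrections = list(),
                                   q = c(0.1, 0.2, 0.3),
                                   with_year_effect = TRUE) {
  val_lines <- cv_lines(data, validation_cycle, trait)
  if (!length(val_lines)) stop("validation cycle has no usable lines")
  sets <- c(list(full = train_cycles),
            lapply(corrections, function(ex) setdiff(train_cycles, ex)))
  blue_v <- blue_of(data, val_lines, trait)
  tbv_v <- tbv_of(data, val_lines, trait)
  acc <- list(); props <- list()
  for (nm in names(sets)) {
    tl <- unlist(lapply(sets[[nm]], cv_lines, data = data, trait = trait))
    if (length(intersect(tl, val_lines)))
      stop("training and validation line sets overlap")
    y <- blue_of(data, tl, trait)
    cyc_f <- factor(data$blues$cycle[match(tl, data$blues$line)])
    X <- if (with_year_effect && nlevels(cyc_f) > 1) model.matrix(~cyc_f) else NULL
    fit <- suppressWarnings(fit_rrblup(y, unclass(data$geno)[tl, , drop = FALSE], X = X))
    gebv <- drop(unclass(data$geno)[val_lines, , drop = FALSE] %*% fit$u)
    names(gebv) <- val_lines
    acc[[nm]] <- data.frame(training = nm, n_train = length(tl),
                            r_gs = safe_cor(gebv, blue_v),
                            r_mt = if (!is.null(tbv_v)) safe_cor(gebv, tbv_v)
                                   else NA_real_)
    for (qq in q) for (dir in c("best", "worst")) {
      props[[length(props) + 1]] <- data.frame(
        training = nm, q = qq, direction = dir,
        proportion = selection_proportion(gebv, blue_v, qq, dir))
    }
  }
  list(accuracy = do.call(rbind, acc), proportions = do.call(rbind, props))
}

#' Correlation between relatedness to the training set and line accuracy
#'
#' Leave-one-cycle-out: for every line of the held-out cycle, the mean
#' kinship to its `k` most related training lines is computed and correlated
#' (per `k`) with the G-BLUP reliability `r_PEV` of that line.
#'
#' @inheritParams within_cycle_cv
#' @param k_range Numbers of most-related lines to average over.
#' @param with_year_effect Include fixed cycle effects in the training fit.
#' @return Data frame with `cycle`, `k`, `correlation`.
#' @export
relatedness_accuracy_correlation <- function(data, trait,
                                             k_range = c(1, 2, 5, 10, 20,
                                                         50, 70, 100, 200, 500),
                                             with_year_effect = TRUE) {
  K <- data$K %||% compute_kinship(data$geno)
  cycles <- unique(data$blues$cycle)
  out <- list()
  for (v in cycles) {
    val <- cv_lines(data, v, trait)
    tl <- unlist(lapply(setdiff(cycles, v), cv_lines, data = data, trait = trait))
    if (length(val) < 3 || length(tl) < 3) next
    ks <- unique(pmin(k_range, length(tl)))
    if (any(k_range > length(tl)))
      warning("k truncated to training size ", length(tl))
    y <- blue_of(data, tl, trait)
    cyc_f <- factor(data$blues$cycle[match(tl, data$blues$line)])
    X <- if (with_year_effect && nlevels(cyc_f) > 1) model.matrix(~cyc_f) else NULL
    fit <- suppressWarnings(fit_gblup(y, unclass(K)[tl, tl], X = X))
    pr <- predict_gblup(fit, K, val)
    Kvt <- unclass(K)[val, tl, drop = FALSE]
    ord <- t(apply(Kvt, 1, sort, decreasing = TRUE))
    for (k in ks) {
      rel <- rowMeans(ord[, seq_len(k), drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        cycle = v, k = k, correlation = safe_cor(rel, pr$r_pev[val]))
    }
  }
  do.call(rbind, out)
}
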