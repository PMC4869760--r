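## pheno: two-stage analysis of multi-environment trial data.
## Stage 1 fits each trial separately with line as fixed effect, comparing a
## baseline model against row and/or column random-effect models by AIC
## (REML), and summarises each trial by line BLUEs, their standard errors and
## a Piepho-Moehring heritability. Stage 2 combines the per-trial BLUEs of
## one breeding cycle in a weighted mixed model with fixed trial effects,
## random line and line-by-trial effects, weights 1/se^2 and the residual
## variance fixed to a trait-specific constant.

#' Piepho-Moehring heritability from a single trial
#'
#' `h2 = sigma2_G / (sigma2_G + MVD/2)` where MVD is the mean variance of a
#' difference between two line BLUEs; the result is clamped to `[0, 1]`.
#'
#' @param sigma2_G Genetic variance (from a random-line fit).
#' @param MVD Mean variance of a difference of BLUEs.
#' @return Heritability in `[0, 1]`.
#' @export
piepho_moehring_h2 <- function(sigma2_G, MVD) {
  if (sigma2_G < 0 || MVD < 0) stop("variance inputs must be >= 0")
  if (sigma2_G == 0 && MVD == 0) stop("h2 undefined: both inputs are zero")
  min(1, max(0, sigma2_G / (sigma2_G + MVD / 2)))
}

#' Across-trial (entry-mean) heritability
#'
#' `h2 = sigma2_G / (sigma2_G + sigma2_GT / t)`, dividing the line-by-trial
#' interaction variance by the number of trials; clamped to `[0, 1]`.
#'
#' @param sigma2_G Genetic variance.
#' @param sigma2_GT Line-by-trial interaction variance.
#' @param t Number of trials (>= 1).
#' @return Heritability in `[0, 1]`.
#' @export
across_trial_h2 <- function(sigma2_G, sigma2_GT, t) {
  if (length(t) != 1 || t < 1) stop("t must be a count >= 1")
  if (sigma2_G < 0 || sigma2_GT < 0) stop("variance inputs must be >= 0")
  if (sigma2_G == 0 && sigma2_GT == 0) stop("h2 undefined: both inputs are zero")
  min(1, max(0, sigma2_G / (sigma2_G + sigma2_GT / t)))
}

mvd_from_vcov <- function(V) {
  L <- nrow(V)
  if (L < 2) return(NA_real_)
  d <- diag(V)
  (2 * (L - 1) * sum(d) - 2 * (sum(V) - sum(d))) / (L * (L - 1))
}

stage1_candidates <- function() c("baseline", "row", "col", "rowcol")

fit_one_candidate <- function(tag, dat) {
  rows_ok <- nlevels(dat$rowf) >= 2
  cols_ok <- nlevels(dat$colf) >= 2
  form <- switch(tag,
    baseline = NULL,
    row    = if (rows_ok) value ~ 0 + line + (1 | rowf),
    col    = if (cols_ok) value ~ 0 + line + (1 | colf),
    rowcol = if (rows_ok && cols_ok) value ~ 0 + line + (1 | rowf) + (1 | colf))
  if (tag != "baseline" && is.null(form)) return(NULL)
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch({
      if (tag == "baseline")
        nlme::gls(value ~ 0 + line, data = dat, method = "REML")
      else
        lme4::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
    }, error = function(e) NULL),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") },
    message = function(m) invokeRestart("muffleMessage"))
  if (is.null(fit)) return(NULL)
  list(tag = tag, fit = fit, aic = AIC(fit), warned = warned)
}

#' Fit a single trial (stage 1)
#'
#' Fits the candidate models (baseline, plus random row and/or column
#' effects) by REML with line as a fixed effect, picks the smallest AIC,
#' and returns line BLUEs with standard errors. The genetic variance is taken
#' from a companion fit with line random (same spatial terms), and the
#' heritability is the Piepho-Moehring form `sigma2_G/(sigma2_G + MVD/2)`.
#' Checks and test lines are both included in the fit.
#'
#' @param plots Plot-table rows of a single trial (long format, as produced
#'   by [simulate_phenotypes()]).
#' @param trait Trait to analyse (required when several are present).
#' @param models Candidate model tags among `"baseline"`, `"row"`, `"col"`,
#'   `"rowcol"`; restricting the set (e.g. to `"baseline"`) skips spatial
#'   candidates.
#' @return A list of class `trial_result`: `trial_id`, `cycle`, `trait`,
#'   `blues`, `se` (named vectors over all lines incl. checks),
#'   `check_lines`, `sigma2_G`, `MVD`, `h2`, `model_tag`, `converged`.
#' @export
fit_trial_model <- function(plots, trait = NULL, models = stage1_candidates()) {
  models <- match.arg(models, stage1_candidates(), several.ok = TRUE)
  if ("trait" %in% names(plots)) {
    avail <- unique(plots$trait)
    if (is.null(trait)) {
      if (length(avail) > 1) stop("several traits present; specify 'trait'")
      trait <- avail
    }
    if (!trait %in% avail) stop("unknown trait: ", trait)
    plots <- plots[plots$trait == trait, , drop = FALSE]
  }
  if (length(unique(plots$trial)) != 1) stop("expected plots from a single trial")
  dat <- data.frame(line = factor(plots$line),
                    rowf = factor(plots$row), colf = factor(plots$col),
                    value = plots$value)
  if (nlevels(dat$line) < 2) stop("need >= 2 lines")
  if (!anyDuplicated(plots$line))
    stop("no replication in trial ", plots$trial[1],
         ": error variance not estimable")
  cands <- Filter(Negate(is.null), lapply(models, fit_one_candidate, dat = dat))
  if (!length(cands)) stop("no stage-1 candidate model could be fitted")
  best <- cands[[which.min(vapply(cands, `[[`, 0, "aic"))]]
  if (inherits(best$fit, "gls")) {
    b <- coef(best$fit); V <- as.matrix(vcov(best$fit))
  } else {
    b <- lme4::fixef(best$fit); V <- as.matrix(vcov(best$fit))
  }
  names(b) <- sub("^line", "", names(b))
  blues <- b
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- names(b)
  MVD <- mvd_from_vcov(V)

  ## companion random-line fit for sigma2_G (same spatial terms as winner)
  rand_tail <- switch(best$tag, baseline = "", row = " + (1|rowf)",
                      col = " + (1|colf)", rowcol = " + (1|rowf) + (1|colf)")
  comp_form <- stats::as.formula(paste0("value ~ 1 + (1|line)", rand_tail))
  comp_warn <- FALSE
  comp <- withCallingHandlers(
    tryCatch(lme4::lmer(comp_form, data = dat, REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE)),
             error = function(e) NULL),
    warning = function(w) { comp_warn <<- TRUE; invokeRestart("muffleWarning") },
    message = function(m) invokeRestart("muffleMessage"))
  sigma2_G <- if (is.null(comp)) NA_real_ else {
    vc <- as.data.frame(lme4::VarCorr(comp))
    vc$vcov[vc$grp == "line"][1]
  }
  h2 <- if (is.na(sigma2_G) || (sigma2_G == 0 && MVD == 0)) NA_real_
        else piepho_moehring_h2(sigma2_G, MVD)
  is_chk <- tapply(plots$is_check, plots$line, any)
  structure(list(trial_id = as.character(plots$trial[1]),
                 cycle = as.character(plots$cycle[1] %||% NA),
                 trait = trait %||% NA_character_,
                 blues = blues, se = se,
                 check_lines = names(is_chk)[is_chk],
                 sigma2_G = sigma2_G, MVD = MVD, h2 = h2,
                 model_tag = best$tag,
                 converged = !(best$warned || comp_warn || is.null(comp))),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("trial %s (%s): %d lines, model '%s', h2 = %.2f\n",
              x$trial_id, x$trait, length(x$blues), x$model_tag, x$h2))
  invisible(x)
}

#' Retain trials exceeding a heritability threshold
#'
#' Keeps trials with `h2 > min_h2` (strict inequality), preserving order;
#' dropped trial ids are attached as attribute `dropped`.
#'
#' @param results List of `trial_result` objects.
#' @param min_h2 Heritability threshold.
#' @return The retained sublist; errors if nothing survives.
#' @export
select_trials <- function(results, min_h2 = 0.3) {
  h2 <- vapply(results, function(r) r$h2 %||% NA_real_, 0)
  keep <- !is.na(h2) & h2 > min_h2
  if (!any(keep)) stop("no usable trials: all heritabilities <= ", min_h2)
  out <- results[keep]
  attr(out, "dropped") <- vapply(results[!keep], `[[`, "", "trial_id")
  out
}

stage2_resid_var <- function(trait) {
  if (is.null(trait) || is.na(trait)) return(1)
  if (grepl("protein", trait)) 0.1 else 1
}

#' Weighted across-trial analysis of one breeding cycle (stage 2)
#'
#' Fits `y_ij = mu + g_i + t_j + gt_ij + e` to the stage-1 BLUEs of one
#' cycle, with fixed trial effects, random line and line-by-trial effects,
#' per-observation known variances `resid_var * se_ij^2` (the inverse-squared
#' standard errors act as weights and the residual variance is fixed to the
#' trait-specific constant: 1 for grain yield, 0.1 for the protein traits).
#' Variance components come from a REML fit with line random
#' (\code{metafor::rma.mv}); line BLUEs are then obtained by refitting with
#' line fixed (generalised least squares with the known diagonal variances).
#' Check lines (no genomic data) are excluded.
#'
#' @param trials List of `trial_result` objects for one cycle (>= 2 after
#'   [select_trials()]).
#' @param trait Trait label (defaults to the trials' trait).
#' @param resid_var Fixed residual variance constant; default chosen by trait.
#' @param blue_method `"fixed"` (default) refits with line fixed for the
#'   BLUEs; `"random"` back-solves the line BLUPs from the variance-component
#'   fit instead.
#' @return A list of class `cycle_blues`: `cycle`, `trait`, `blues`, `se`,
#'   `sigma2_G`, `sigma2_GT`, `n_trials`, `h2`, `n_lines`.
#' @export
fit_stage2 <- function(trials, trait = NULL, resid_var = NULL,
                       blue_method = c("fixed", "random")) {
  blue_method <- match.arg(blue_method)
  if (length(trials) < 2)
    stop("need >= 2 trials: line-by-trial variance not estimable from one")
  trait <- trait %||% trials[[1]]$trait
  resid_var <- resid_var %||% stage2_resid_var(trait)
  dat <- do.call(rbind, lapply(trials, function(tr) {
    keep <- setdiff(names(tr$blues), tr$check_lines)
    data.frame(line = keep, trial = tr$trial_id,
               blue = unname(tr$blues[keep]), se = unname(tr$se[keep]),
               stringsAsFactors = FALSE)
  }))
  dat$se <- pmax(dat$se, 1e-6)
  dat$obs <- seq_len(nrow(dat))
  fit <- metafor::rma.mv(yi = blue, V = resid_var * se^2, mods = ~ trial,
                         random = list(~ 1 | line, ~ 1 | obs),
                         data = dat, sparse = TRUE, method = "REML")
  sigma2_G <- max(0, fit$sigma2[1])
  sigma2_GT <- max(0, fit$sigma2[2])
  t <- length(unique(dat$trial))

  ## known total diagonal variance for each observation given the estimates
  vtot <- sigma2_GT + resid_var * dat$se^2
  Xl <- model.matrix(~ 0 + line, data = transform(dat, line = factor(line)))
  Xt <- model.matrix(~ trial, data = transform(dat, trial = factor(trial)))[, -1, drop = FALSE]
  lines <- levels(factor(dat$line))
  if (blue_method == "fixed") {
    X <- cbind(Xl, Xt)
    XtWX <- crossprod(X / sqrt(vtot))
    Vb <- solve(XtWX)
    bhat <- drop(Vb %*% crossprod(X / vtot, dat$blue))
    L <- length(lines); Tn <- ncol(Xt)
    ## adjusted mean = line coefficient + average trial effect (ref = 0)
    Cmat <- cbind(diag(L), matrix(1 / (Tn + 1), L, Tn))
    blues <- drop(Cmat %*% bhat)
    se2 <- rowSums((Cmat %*% Vb) * Cmat)
    blues <- setNames(blues, lines)
    se <- setNames(sqrt(pmax(se2, 0)), lines)
  } else {
    ## BLUP back-solve: line random at the estimated sigma2_G, trial fixed
    X <- cbind(`(Intercept)` = 1, Xt)
    Vfull <- sigma2_G * tcrossprod(Xl) + diag(vtot)
    Vi <- solve(Vfull)
    bhat <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% dat$blue))
    resid <- dat$blue - drop(X %*% bhat)
    g <- sigma2_G * drop(crossprod(Xl, Vi %*% resid))
    mu <- bhat[1] + mean(c(0, bhat[-1]))
    blues <- setNames(mu + g, lines)
    se <- setNames(rep(NA_real_, length(lines)), lines)
  }
  structure(list(cycle = trials[[1]]$cycle, trait = trait,
                 blues = blues, se = se,
                 sigma2_G = sigma2_G, sigma2_GT = sigma2_GT,
                 n_trials = t, h2 = across_trial_h2(max(sigma2_G, 1e-12),
                                                    sigma2_GT, t),
                 n_lines = length(lines)),
            class = "cycle_blues")
}

#' @export
print.cycle_blues <- function(x, ...) {
  cat(sprintf("cycle %s (%s): %d lines, %d trials, s2G=%.3f s2GT=%.3f h2=%.2f\n",
              x$cycle, x$trait, x$n_lines, x$n_trials,
              x$sigma2_G, x$sigma2_GT, x$h2))
  invisible(x)
}

#' Run the full two-stage analysis for all cycles and traits
#'
#' Convenience wrapper: stage 1 per trial, trial selection at `min_h2`, and
#' stage 2 per cycle, for each requested trait.
#'
#' @param plots A plot table (long format).
#' @param traits Traits to analyse.
#' @param min_h2 Stage-1 heritability threshold (`NULL` to keep all trials).
#' @param models Stage-1 candidate set, see [fit_trial_model()].
#' @return A list of class `pheno_analysis`: per trait, a list with elements
#'   `stage1` (trial results), `cycles` (named list of `cycle_blues`) and
#'   `dropped` (trial ids removed by the threshold).
#' @export
analyze_phenotypes <- function(plots, traits = unique(plots$trait),
                               min_h2 = 0.3, models = stage1_candidates()) {
  out <- list()
  for (tr in traits) {
    sub <- plots[plots$trait == tr, , drop = FALSE]
    if (!nrow(sub)) stop("unknown trait: ", tr)
    stage1 <- lapply(split(sub, sub$trial), fit_trial_model,
                     trait = tr, models = models)
    stage1 <- stage1[order(names(stage1))]
    cycles <- list(); dropped <- character(0)
    for (cyc in unique(sub$cycle)) {
      trs <- Filter(function(r) r$cycle == cyc, stage1)
      if (!is.null(min_h2)) {
        trs <- select_trials(trs, min_h2)
        dropped <- c(dropped, attr(trs, "dropped"))
      }
      cycles[[cyc]] <- fit_stage2(trs, trait = tr)
    }
    out[[tr]] <- list(stage1 = stage1, cycles = cycles, dropped = dropped)
  }
  structure(out, class = "pheno_analysis")
}

#' Variance-component summary table
#'
#' One row per trait x cycle with the number of retained trials, variance
#' components, heritability and line count (the across-cycle analogue of a
#' multi-environment trial report).
#'
#' @param analysis A `pheno_analysis` from [analyze_phenotypes()].
#' @return A data frame.
#' @export
variance_report <- function(analysis) {
  rows <- list()
  for (tr in names(analysis)) {
    for (cyc in names(analysis[[tr]]$cycles)) {
      cb <- analysis[[tr]]$cycles[[cyc]]
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, cycle = cyc, trials = cb$n_trials,
        sigma2_G = cb$sigma2_G, sigma2_GT = cb$sigma2_GT,
        h2 = cb$h2, n_lines = cb$n_lines)
    }
  }
  do.call(rbind, rows)
}
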