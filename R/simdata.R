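## simdata: multi-cycle breeding-program simulator with known true breeding
## values. Emulates a winter-wheat line-breeding program where every year a
## new cohort ("breeding cycle") of inbred lines enters multi-location
## testing: related families derived from crosses among the previous cycle's
## lines, unreplicated test plots alongside replicated checks, trial and year
## main effects, genotype-by-trial interaction, and optional outlier trials
## whose genetic signal is inverted.

#' Simulated trait names
#'
#' Two traits are simulated directly (grain yield in dt/ha, protein content
#' in %); protein yield (dt/ha) is derived per plot as
#' `grain_yield * protein_content / 100`.
#' @export
gs_traits <- function() c("grain_yield", "protein_content", "protein_yield")

traits_sim <- function() c("grain_yield", "protein_content")

#' Configuration for the breeding-program simulator
#'
#' Returns a validated configuration list. Defaults emulate the scale of a
#' commercial winter-wheat program observed over five cycles: 64--176 lines
#' per cycle, 2--8 trials per cycle, entry-mean heritabilities between about
#' 0.14 and 0.84, and a negative genetic correlation between grain yield and
#' protein content. Marker counts default to a desk-scale 1000 (the QC'd
#' real-data panels in this field are ~10K).
#'
#' @param n_cycles Number of breeding cycles.
#' @param lines_per_cycle Integer vector (length `n_cycles`) of cohort sizes.
#' @param n_founders Number of founder inbreds.
#' @param n_markers Number of biallelic markers.
#' @param n_qtl Number of QTL (a shared set for both simulated traits; the
#'   genetic correlation arises from correlated effect draws at these loci).
#' @param trait_means Named vector: `grain_yield` (dt/ha), `protein_content`
#'   (%). Cohort means on the natural scale.
#' @param genetic_var Named vector of additive genetic variances on the trait
#'   scale (dt^2/ha^2 resp. %^2).
#' @param target_h2 Across-trial entry-mean heritability targets; a single
#'   number, a per-trait named vector, or a 2 x `n_cycles` matrix with rows
#'   `grain_yield`, `protein_content`. A value of 0 removes the genetic
#'   signal for that trait/cycle.
#' @param trials_per_cycle Integer vector of trials per cycle.
#' @param gxe_variance_ratio If non-`NULL`, overrides the heritability
#'   calibration and sets the genotype-by-trial variance to
#'   `ratio * genetic_var` for every trait and cycle (0 switches G x T off).
#' @param cycle_genetic_frac Named per-trait fraction of cycle-specific,
#'   marker-encoded genetic variance (genotype-by-year interaction): each
#'   cycle draws fresh QTL effect deviations scaled to
#'   `frac * var(TBV within cycle)`. This component is learnable by a marker
#'   model within a cycle but does not transfer across cycles, which is what
#'   inflates within-cycle cross-validation accuracy. Default 0 (off).
#' @param year_effect_sd,trial_effect_sd Named per-trait standard deviations
#'   of cycle (year) and trial main effects.
#' @param spatial_sd Named per-trait standard deviation of random row and
#'   column effects within a trial (0 disables spatial trend).
#' @param resid_sd Named per-trait plot residual standard deviation.
#' @param outlier_trials List of entries `list(cycle =, trial =, traits =)`
#'   marking trials whose genetic effects are sign-flipped (defaults to all
#'   traits), producing a negative phenotypic correlation with sibling
#'   trials. See [outlier_cycle_spec()] to flag a whole cycle.
#' @param genetic_corr_gy_pc Genetic correlation between grain yield and
#'   protein content QTL effects (default -0.3, the typical negative
#'   yield--protein relation).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param n_selfing Selfing generations after the F1 (single-seed descent);
#'   the default 5 corresponds to F6-derived material and leaves residual
#'   heterozygosity around 1%.
#' @param dh If `TRUE`, lines are doubled haploids (fully homozygous).
#' @param n_checks,check_reps Number of replicated check varieties per trial
#'   and replicates of each.
#' @param validation_lines If positive, an additional independent validation
#'   cohort (cycle label `"V"`) of this many lines is generated from the last
#'   cycle's parents.
#' @param validation_trials Number of trials for the validation cohort.
#' @param seed Integer master seed; it fully determines all output.
#' @return A list of class `program_config`.
#' @export
program_config <- function(n_cycles = 5,
                           lines_per_cycle = c(94, 64, 165, 160, 176),
                           n_founders = 24,
                           n_markers = 1000,
                           n_qtl = 100,
                           trait_means = c(grain_yield = 80, protein_content = 14),
                           genetic_var = c(grain_yield = 5, protein_content = 0.3),
                           target_h2 = rbind(grain_yield    = c(0.32, 0.54, 0.53, 0.45, 0.84),
                                             protein_content = c(0.72, 0.84, 0.80, 0.69, 0.50)),
                           trials_per_cycle = c(5, 6, 4, 5, 8),
                           gxe_variance_ratio = NULL,
                           cycle_genetic_frac = c(grain_yield = 0,
                                                  protein_content = 0),
                           year_effect_sd = c(grain_yield = 5, protein_content = 0.5),
                           trial_effect_sd = c(grain_yield = 3, protein_content = 0.4),
                           spatial_sd = c(grain_yield = 1, protein_content = 0.1),
                           resid_sd = c(grain_yield = 2, protein_content = 0.45),
                           outlier_trials = list(),
                           genetic_corr_gy_pc = -0.3,
                           missing_rate = 0.02,
                           n_selfing = 5,
                           dh = FALSE,
                           n_checks = 3,
                           check_reps = 4,
                           validation_lines = 0,
                           validation_trials = 4,
                           seed = 1L) {
  cfg <- list(n_cycles = as.integer(n_cycles),
              lines_per_cycle = as.integer(lines_per_cycle),
              n_founders = as.integer(n_founders),
              n_markers = as.integer(n_markers),
              n_qtl = as.integer(n_qtl),
              trait_means = trait_means, genetic_var = genetic_var,
              target_h2 = target_h2, trials_per_cycle = as.integer(trials_per_cycle),
              gxe_variance_ratio = gxe_variance_ratio,
              cycle_genetic_frac = cycle_genetic_frac,
              year_effect_sd = year_effect_sd, trial_effect_sd = trial_effect_sd,
              spatial_sd = spatial_sd, resid_sd = resid_sd,
              outlier_trials = outlier_trials,
              genetic_corr_gy_pc = genetic_corr_gy_pc,
              missing_rate = missing_rate, n_selfing = as.integer(n_selfing),
              dh = isTRUE(dh), n_checks = as.integer(n_checks),
              check_reps = as.integer(check_reps),
              validation_lines = as.integer(validation_lines),
              validation_trials = as.integer(validation_trials),
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_cycles < 1) stop_config("n_cycles", "must be >= 1")
  if (length(cfg$lines_per_cycle) == 1L)
    cfg$lines_per_cycle <- rep(cfg$lines_per_cycle, cfg$n_cycles)
  if (length(cfg$lines_per_cycle) != cfg$n_cycles)
    stop_config("lines_per_cycle", "length must match n_cycles")
  if (any(cfg$lines_per_cycle < 2)) stop_config("lines_per_cycle", "cohorts need >= 2 lines")
  if (cfg$n_founders < 4) stop_config("n_founders", "must be >= 4")
  if (cfg$n_markers < 10) stop_config("n_markers", "must be >= 10")
  if (cfg$n_qtl < 1 || cfg$n_qtl > cfg$n_markers)
    stop_config("n_qtl", "must be in [1, n_markers]")
  if (length(cfg$trials_per_cycle) == 1L)
    cfg$trials_per_cycle <- rep(cfg$trials_per_cycle, cfg$n_cycles)
  if (length(cfg$trials_per_cycle) != cfg$n_cycles)
    stop_config("trials_per_cycle", "length must match n_cycles")
  if (any(cfg$trials_per_cycle < 1)) stop_config("trials_per_cycle", "must be positive")
  for (f in c("trait_means", "genetic_var", "year_effect_sd",
              "trial_effect_sd", "spatial_sd", "resid_sd")) {
    v <- cfg[[f]]
    if (!all(traits_sim() %in% names(v)))
      stop_config(f, "needs named entries grain_yield and protein_content")
    if (any(!is.finite(v)) || (f != "trait_means" && any(v < 0)))
      stop_config(f, "entries must be finite (and non-negative)")
  }
  h2 <- cfg$target_h2
  if (is.null(dim(h2))) {
    if (length(h2) == 1L) h2 <- setNames(rep(h2, 2), traits_sim())
    if (is.null(names(h2)) || !all(traits_sim() %in% names(h2)))
      stop_config("target_h2", "per-trait values must be named")
    h2 <- rbind(grain_yield = rep(h2[["grain_yield"]], cfg$n_cycles),
                protein_content = rep(h2[["protein_content"]], cfg$n_cycles))
  }
  if (ncol(h2) > cfg$n_cycles) h2 <- h2[, seq_len(cfg$n_cycles), drop = FALSE]
  if (ncol(h2) < cfg$n_cycles)   # recycle the last column for extra cycles
    h2 <- cbind(h2, h2[, rep(ncol(h2), cfg$n_cycles - ncol(h2)), drop = FALSE])
  assert_prob(as.numeric(h2), "target_h2")
  cfg$target_h2 <- h2[traits_sim(), , drop = FALSE]
  if (!is.null(cfg$gxe_variance_ratio) &&
      (!is.numeric(cfg$gxe_variance_ratio) || cfg$gxe_variance_ratio < 0))
    stop_config("gxe_variance_ratio", "must be >= 0")
  cgf <- cfg$cycle_genetic_frac %||% c(grain_yield = 0, protein_content = 0)
  if (length(cgf) == 1L && is.null(names(cgf)))
    cgf <- setNames(rep(cgf, 2), traits_sim())
  if (!all(traits_sim() %in% names(cgf)) || any(cgf < 0))
    stop_config("cycle_genetic_frac", "needs non-negative named entries")
  cfg$cycle_genetic_frac <- cgf
  if (abs(cfg$genetic_corr_gy_pc) > 1) stop_config("genetic_corr_gy_pc", "must be in [-1,1]")
  assert_prob(cfg$missing_rate, "missing_rate", open_upper = TRUE)
  if (cfg$n_selfing < 0) stop_config("n_selfing", "must be >= 0")
  structure(cfg, class = "program_config")
}

#' Mark all trials of a cycle as sign-flipped outliers
#'
#' @param cycle Cycle label (e.g. `"C3"`).
#' @param n_trials Number of trials in that cycle.
#' @param traits Traits whose genetic effects are flipped.
#' @return A list suitable for the `outlier_trials` config field.
#' @export
outlier_cycle_spec <- function(cycle, n_trials, traits = gs_traits()) {
  lapply(seq_len(n_trials), function(j) list(cycle = cycle, trial = j, traits = traits))
}

cycle_labels <- function(cfg) {
  lab <- paste0("C", seq_len(cfg$n_cycles))
  if (cfg$validation_lines > 0) lab <- c(lab, "V")
  lab
}

## simulate one biparental family: cross two inbred parents, then selfing
## (SSD, no linkage) or DH. Returns n x M matrix of {-1,0,1} codes.
make_family <- function(p1, p2, n, n_selfing, dh) {
  M <- length(p1)
  base <- matrix(rep(p1, each = n), nrow = n)
  het <- which(p1 != p2)
  if (length(het)) {
    if (dh) {
      draw <- matrix(sample(c(-1, 1), n * length(het), replace = TRUE),
                     nrow = n)
    } else {
      p_het <- 0.5^n_selfing
      u <- matrix(runif(n * length(het)), nrow = n)
      draw <- matrix(sample(c(-1, 1), n * length(het), replace = TRUE),
                     nrow = n)
      draw[u < p_het] <- 0
    }
    base[, het] <- draw
  }
  base
}

#' Simulate multi-cycle genotypes and true breeding values
#'
#' Founder inbreds are drawn at per-marker allele frequencies ~ Uniform(0.1,
#' 0.9); each subsequent cycle consists of biparental families whose parents
#' are drawn preferentially from the previous cycle, so that mean
#' between-cycle kinship is lower than mean within-cycle kinship. Lines are
#' taken to near-homozygosity by simulated single-seed descent (or DH). True
#' breeding values are computed from a shared QTL set with correlated effects
#' for the two component traits; the derived-trait TBV is the product of the
#' component TBVs on the natural scale.
#'
#' @param config A [program_config()].
#' @return A list of class `true_population` with elements `geno` (masked
#'   [marker_matrix()]), `geno_true` (complete codes), `cycle` (named cycle
#'   label per line), `family`, `tbv` (data frame of TBV deviations per trait,
#'   with attributes `trait_means` and `py_mean`), `qtl` (marker effects) and
#'   `config`.
#' @export
simulate_genotypes <- function(config) {
  cfg <- validate_config(config)
  local_seed(substream_seed(cfg$seed, "genotypes"), {
    M <- cfg$n_markers
    p <- runif(M, 0.1, 0.9)
    founders <- matrix(2 * rbinom(cfg$n_founders * M, 1, rep(p, each = cfg$n_founders)) - 1,
                       nrow = cfg$n_founders)
    labs <- cycle_labels(cfg)
    sizes <- cfg$lines_per_cycle
    if (cfg$validation_lines > 0) sizes <- c(sizes, cfg$validation_lines)
    geno <- NULL; cyc <- character(0); fam <- character(0)
    prev <- founders; all_prev <- founders
    for (ci in seq_along(labs)) {
      n <- sizes[ci]
      n_fam <- max(2L, as.integer(ceiling(n / 8)))
      fam_sizes <- diff(round(seq(0, n, length.out = n_fam + 1)))
      rows <- vector("list", n_fam)
      for (fi in seq_len(n_fam)) {
        if (fam_sizes[fi] == 0) { rows[[fi]] <- NULL; next }
        i1 <- sample(nrow(prev), 1)
        pool2 <- if (runif(1) < 0.9 || nrow(all_prev) == nrow(prev)) prev else all_prev
        repeat {
          i2 <- sample(nrow(pool2), 1)
          if (!(identical(nrow(pool2), nrow(prev)) && i2 == i1)) break
        }
        rows[[fi]] <- make_family(prev[i1, ], pool2[i2, ], fam_sizes[fi],
                                  cfg$n_selfing, cfg$dh)
        fam <- c(fam, rep(sprintf("%s_F%02d", labs[ci], fi), fam_sizes[fi]))
      }
      g <- do.call(rbind, rows)
      rownames(g) <- sprintf("%s_L%03d", labs[ci], seq_len(n))
      geno <- rbind(geno, g)
      cyc <- c(cyc, rep(labs[ci], n))
      prev <- g
      all_prev <- rbind(all_prev, g)
    }
    colnames(geno) <- sprintf("M%04d", seq_len(M))
    names(cyc) <- rownames(geno); names(fam) <- rownames(geno)

    ## QTL effects: shared loci, bivariate-normal effects with the requested
    ## genetic correlation between grain yield and protein content
    qtl_idx <- sort(sample(M, cfg$n_qtl))
    rho <- cfg$genetic_corr_gy_pc
    z1 <- rnorm(cfg$n_qtl); z2 <- rnorm(cfg$n_qtl)
    a_gy <- z1
    a_pc <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2
    raw_gy <- drop(geno[, qtl_idx, drop = FALSE] %*% a_gy)
    raw_pc <- drop(geno[, qtl_idx, drop = FALSE] %*% a_pc)
    sc <- function(raw, v) {
      s <- stats::sd(raw)
      if (s == 0 || v == 0) rep(0, length(raw)) else (raw - mean(raw)) * sqrt(v) / s
    }
    tbv_gy <- sc(raw_gy, cfg$genetic_var[["grain_yield"]])
    tbv_pc <- sc(raw_pc, cfg$genetic_var[["protein_content"]])
    py_abs <- (cfg$trait_means[["grain_yield"]] + tbv_gy) *
      (cfg$trait_means[["protein_content"]] + tbv_pc) / 100
    tbv <- data.frame(line = rownames(geno),
                      grain_yield = tbv_gy, protein_content = tbv_pc,
                      protein_yield = py_abs - mean(py_abs),
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(tbv, "trait_means") <- cfg$trait_means
    attr(tbv, "py_mean") <- mean(py_abs)

    geno_true <- geno
    if (cfg$missing_rate > 0) {
      mask <- runif(length(geno)) < cfg$missing_rate
      geno[mask] <- NA
    }
    structure(list(geno = marker_matrix(geno),
                   geno_true = marker_matrix(geno_true),
                   cycle = cyc, family = fam, tbv = tbv,
                   qtl = data.frame(marker = colnames(geno)[qtl_idx],
                                    eff_grain_yield = a_gy, eff_protein_content = a_pc),
                   config = cfg),
              class = "true_population")
  })
}

#' @export
print.true_population <- function(x, ...) {
  cat("Simulated breeding population:",
      nrow(x$geno), "lines x", ncol(x$geno), "markers,",
      length(unique(x$cycle)), "cycles\n")
  invisible(x)
}

gt_sd_for <- function(cfg, trait, cycle_idx, n_trials, gv) {
  if (!is.null(cfg$gxe_variance_ratio))
    return(sqrt(cfg$gxe_variance_ratio * cfg$genetic_var[[trait]]))
  h2 <- cfg$target_h2[trait, min(cycle_idx, ncol(cfg$target_h2))]
  if (h2 <= 0) return(sqrt(cfg$genetic_var[[trait]]))
  if (h2 >= 1) return(0)
  sqrt(gv * n_trials * (1 / h2 - 1))
}

#' Simulate plot-level phenotypes for a population
#'
#' Generates unreplicated test plots plus replicated checks for every trial,
#' with cycle (year) and trial main effects, genotype-by-trial deviations
#' calibrated so the two-stage across-trial heritability matches the
#' configured target in expectation, optional random row/column trends, and
#' plot residual noise. Protein yield is computed per plot as the product of
#' the grain-yield and protein-content plot values divided by 100. Trials
#' named in `config$outlier_trials` have their genetic effects (line TBV and
#' G-by-T deviation) sign-flipped for the listed traits.
#'
#' @param pop A `true_population` from [simulate_genotypes()].
#' @param config A [program_config()]; defaults to `pop$config`.
#' @return A data frame ("plot table") with columns `cycle`, `trial`, `line`,
#'   `is_check`, `row`, `col`, `trait`, `value`.
#' @export
simulate_phenotypes <- function(pop, config = pop$config) {
  cfg <- validate_config(config)
  stopifnot(inherits(pop, "true_population"))
  labs <- unique(pop$cycle)
  out <- vector("list", 0)
  local_seed(substream_seed(cfg$seed, "phenotypes"), {
    checks <- if (cfg$n_checks > 0) sprintf("CHK%02d", seq_len(cfg$n_checks)) else character(0)
    check_gv <- sapply(traits_sim(), function(tr)
      rnorm(cfg$n_checks, 0, sqrt(cfg$genetic_var[[tr]])))
    if (cfg$n_checks == 1) check_gv <- matrix(check_gv, nrow = 1,
                                              dimnames = list(NULL, traits_sim()))
    for (ci in seq_along(labs)) {
      lab <- labs[ci]
      lines <- names(pop$cycle)[pop$cycle == lab]
      n_tr <- if (lab == "V") cfg$validation_trials else cfg$trials_per_cycle[ci]
      year_eff <- sapply(traits_sim(), function(tr) rnorm(1, 0, cfg$year_effect_sd[[tr]]))
      tbv_c <- pop$tbv[match(lines, pop$tbv$line), , drop = FALSE]
      ## cycle-specific marker-encoded genetic deviations (genotype-by-year)
      Zq <- unclass(pop$geno_true)[lines, pop$qtl$marker, drop = FALSE]
      delta_c <- sapply(traits_sim(), function(tr) {
        frac <- cfg$cycle_genetic_frac[[tr]]
        if (frac <= 0) return(rep(0, length(lines)))
        raw <- drop(Zq %*% rnorm(nrow(pop$qtl)))
        sv <- stats::sd(raw)
        if (sv == 0) return(rep(0, length(lines)))
        (raw - mean(raw)) / sv * sqrt(frac * stats::var(tbv_c[[tr]]))
      })
      if (length(lines) == 1) delta_c <- matrix(delta_c, nrow = 1,
                                                dimnames = list(NULL, traits_sim()))
      for (j in seq_len(n_tr)) {
        trial_id <- sprintf("%s_T%d", lab, j)
        entries <- c(lines, rep(checks, each = cfg$check_reps))
        is_check <- c(rep(FALSE, length(lines)),
                      rep(TRUE, length(checks) * cfg$check_reps))
        ord <- sample(length(entries))
        entries <- entries[ord]; is_check <- is_check[ord]
        nc <- ceiling(sqrt(length(entries)))
        nr <- ceiling(length(entries) / nc)
        rowpos <- ((seq_along(entries) - 1) %/% nc) + 1
        colpos <- ((seq_along(entries) - 1) %% nc) + 1
        vals <- list()
        for (tr in traits_sim()) {
          flip <- any(vapply(cfg$outlier_trials, function(o)
            identical(as.character(o$cycle), lab) && o$trial == j &&
              tr %in% (o$traits %||% gs_traits()), TRUE))
          trial_eff <- rnorm(1, 0, cfg$trial_effect_sd[[tr]])
          g_on <- is.null(cfg$gxe_variance_ratio) &&
            cfg$target_h2[tr, min(ci, ncol(cfg$target_h2))] <= 0
          g_line <- if (g_on) rep(0, length(lines)) else
            tbv_c[[tr]] + delta_c[, tr]
          gt_sd <- gt_sd_for(cfg, tr, ci, n_tr, stats::var(g_line))
          gt <- rnorm(length(lines), 0, gt_sd)
          gen <- setNames(g_line + gt, lines)
          if (length(checks)) gen <- c(gen, setNames(check_gv[, tr], checks))
          if (flip) gen <- -gen
          re <- rnorm(nr, 0, cfg$spatial_sd[[tr]])
          ce <- rnorm(nc, 0, cfg$spatial_sd[[tr]])
          vals[[tr]] <- cfg$trait_means[[tr]] + year_eff[[tr]] + trial_eff +
            gen[entries] + re[rowpos] + ce[colpos] +
            rnorm(length(entries), 0, cfg$resid_sd[[tr]])
        }
        vals$protein_yield <- vals$grain_yield * vals$protein_content / 100
        for (tr in gs_traits()) {
          out[[length(out) + 1]] <- data.frame(
            cycle = lab, trial = trial_id, line = entries, is_check = is_check,
            row = rowpos, col = colpos, trait = tr,
            value = unname(vals[[tr]]), stringsAsFactors = FALSE)
        }
      }
    }
  })
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  plots
}

#' Write simulator outputs as plain-text files
#'
#' `write_genotypes_tsv()` writes a lines x markers matrix of codes
#' -1/0/1 with `NA` for missing calls; `write_phenotypes_csv()` the
#' long-format plot table; `write_truth_csv()` the line/trait/TBV table.
#'
#' @param geno A [marker_matrix()].
#' @param plots A plot table from [simulate_phenotypes()].
#' @param tbv The `tbv` element of a `true_population`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  df <- data.frame(line = rownames(geno), as.data.frame(unclass(geno)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_phenotypes_csv <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_truth_csv <- function(tbv, path) {
  long <- do.call(rbind, lapply(gs_traits(), function(tr)
    data.frame(line = tbv$line, trait = tr, tbv = tbv[[tr]])))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
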