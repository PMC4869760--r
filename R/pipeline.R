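## pipeline: configuration-driven orchestration of the full workflow
## (simulate -> QC -> impute -> stage 1 -> stage 2 -> cross-validation /
## outlier / derived-trait analyses), writing plain CSV artifacts plus a run
## manifest. A thin command-line wrapper lives in inst/exec/gscycles-run.R.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  config$stages <- config$stages %||%
    c("simulate", "qc", "impute", "stage1", "stage2", "cv")
  config$seed <- as.integer(config$seed %||% 1L)
  config$traits <- config$traits %||% gs_traits()
  config
}

config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 0
  for (cp in utf8ToInt(txt)) h <- (h * 131 + cp) %% 2147483629
  sprintf("%08x", h)
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the configuration-driven analysis pipeline
#'
#' Executes the requested stages over either a simulated population
#' (`simulate:` section with [program_config()] fields) or plain-text inputs
#' (`inputs: {genotypes:, phenotypes:}`), writing all artifacts as CSV/TSV
#' into `output_dir` together with a `manifest.json` (seed, package version,
#' config hash). Output is idempotent for a fixed seed. Configuration errors
#' (e.g. requesting across-cycle cross-validation with a single cycle) are
#' raised before any computation.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   list. Recognised sections: `seed`, `output_dir`, `stages` (subset of
#'   `simulate`, `qc`, `impute`, `stage1`, `stage2`, `cv`, `outliers`,
#'   `derived`), `simulate`, `inputs`, `qc`, `stage1`
#'   (`models`, `min_h2`), `traits`, `cv` (`schemes`, `train_size_total`,
#'   `reps`, `n_folds`), `derived` (`train_sizes`, `reps`).
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a named list of artifact file paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out <- output_dir %||% cfg$output_dir %||% stop("output_dir required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  art <- list()
  wants <- function(s) s %in% stages

  ## ---- early validation, before any compute
  n_cycles_known <- if (!is.null(cfg$simulate)) {
    cfg$simulate$n_cycles %||% length(cfg$simulate$lines_per_cycle %||% numeric(5))
  } else NA
  if (wants("cv") && !is.na(n_cycles_known)) {
    schemes <- cfg$cv$schemes %||% c("within", "across")
    if ("across" %in% schemes && n_cycles_known < 2)
      stop("stage 'cv' failed: across-cycle cross-validation needs >= 2 cycles",
           call. = FALSE)
  }

  pop <- NULL; plots <- NULL; geno <- NULL
  if (wants("simulate")) {
    stage_try("simulate", {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% cfg$seed
      for (f in c("lines_per_cycle", "trials_per_cycle"))
        if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
      for (f in c("trait_means", "genetic_var", "year_effect_sd",
                  "trial_effect_sd", "spatial_sd", "resid_sd"))
        if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
      pcfg <- do.call(program_config, sim_args)
      pop <- simulate_genotypes(pcfg)
      plots <- simulate_phenotypes(pop)
      geno <- pop$geno
      art$genotypes <- write_genotypes_tsv(pop$geno, file.path(out, "genotypes.tsv"))
      art$phenotypes <- write_phenotypes_csv(plots, file.path(out, "phenotypes.csv"))
      art$truth <- write_truth_csv(pop$tbv, file.path(out, "truth.csv"))
    })
  } else if (!is.null(cfg$inputs)) {
    stage_try("load", {
      geno <- read_genotypes_tsv(cfg$inputs$genotypes)
      plots <- read.csv(cfg$inputs$phenotypes, stringsAsFactors = FALSE)
    })
  } else stop("config needs a 'simulate' section or 'inputs' paths")

  if (wants("qc")) stage_try("qc", {
    qc <- cfg$qc %||% list()
    geno <- filter_markers(geno,
                            min_call_rate = qc$min_call_rate %||% 0.90,
                            min_maf = qc$min_maf %||% 0.05,
                            max_missing = qc$max_missing %||% 0.10)
    counts <- attr(geno, "qc_counts")
    write.csv(data.frame(rule = names(counts), markers = as.integer(counts)),
              art$qc_report <- file.path(out, "qc_report.csv"),
              row.names = FALSE)
  })
  if (wants("impute")) stage_try("impute", {
    geno <- impute_missing(geno)
  })

  analysis <- NULL
  if (wants("stage1") || wants("stage2")) stage_try("stage1", {
    s1 <- cfg$stage1 %||% list()
    mh <- s1$min_h2 %||% 0.3
    if (!is.null(mh) && mh < 0) mh <- NULL  # negative = keep all trials
    analysis <- analyze_phenotypes(plots, traits = cfg$traits,
                                    min_h2 = mh,
                                    models = unlist(s1$models) %||% stage1_candidates())
    rows <- do.call(rbind, lapply(names(analysis), function(tr)
      do.call(rbind, lapply(analysis[[tr]]$stage1, function(x)
        data.frame(trait = tr, cycle = x$cycle, trial = x$trial_id,
                   model = x$model_tag, sigma2_G = x$sigma2_G, MVD = x$MVD,
                   h2 = x$h2, converged = x$converged)))))
    write.csv(rows, art$stage1 <- file.path(out, "stage1_trials.csv"),
              row.names = FALSE)
  })
  data <- NULL
  if (wants("stage2")) stage_try("stage2", {
    vr <- variance_report(analysis)
    write.csv(vr, art$variance_components <-
                file.path(out, "variance_components.csv"), row.names = FALSE)
    rows <- do.call(rbind, lapply(names(analysis), function(tr)
      do.call(rbind, lapply(analysis[[tr]]$cycles, function(cb)
        data.frame(trait = tr, cycle = cb$cycle, line = names(cb$blues),
                   blue = unname(cb$blues), se = unname(cb$se))))))
    write.csv(rows, art$stage2 <- file.path(out, "stage2_blues.csv"),
              row.names = FALSE)
    if (!is.null(pop)) data <- gs_data_from_analysis(pop, analysis)
  })

  if (wants("cv")) stage_try("cv", {
    if (is.null(data)) stop("cv requires the stage2 results of a simulated run")
    cvc <- cfg$cv %||% list()
    schemes <- cvc$schemes %||% c("within", "across")
    reps <- cvc$reps %||% 10; nf <- cvc$n_folds %||% 5
    main_cycles <- setdiff(unique(data$blues$cycle), "V")
    if ("across" %in% schemes && length(main_cycles) < 2)
      stop("across-cycle cross-validation needs >= 2 cycles")
    rows <- list()
    for (tr in intersect(cfg$traits, names(data$blues))) {
      if ("within" %in% schemes) for (cc in main_cycles) {
        res <- within_cycle_cv(data, cc, tr, n_folds = nf, reps = reps,
                               seed = cfg$seed)
        rows[[length(rows) + 1]] <- data.frame(
          scheme = "within_cycle", trait = tr, unit = cc,
          train_size = res$train_size, replicate = seq_along(res$replicates),
          r_gs = res$replicates,
          r_mt = res$r_mt %||% NA_real_)
      }
      if ("across" %in% schemes) {
        tst <- cvc$train_size_total %||%
          ((length(main_cycles) - 1) * min(table(data$blues$cycle[data$blues$cycle %in% main_cycles])) %/% 2)
        tst <- (tst %/% (length(main_cycles) - 1)) * (length(main_cycles) - 1)
        sub <- data; sub$blues <- sub$blues[sub$blues$cycle %in% main_cycles, ]
        res <- across_cycle_cv(sub, tr, tst, reps = reps, seed = cfg$seed)
        rows[[length(rows) + 1]] <- data.frame(
          scheme = "across_cycle", trait = tr, unit = "all",
          train_size = tst, replicate = seq_along(res$replicates),
          r_gs = res$replicates, r_mt = res$r_mt %||% NA_real_)
      }
    }
    write.csv(do.call(rbind, rows), art$cv <- file.path(out, "cv_results.csv"),
              row.names = FALSE)
  })

  if (wants("outliers")) stage_try("outliers", {
    if (is.null(data)) stop("outlier analysis requires stage2 results")
    main_cycles <- setdiff(unique(data$blues$cycle), "V")
    sub <- data; sub$blues <- sub$blues[sub$blues$cycle %in% main_cycles, ]
    rows <- list()
    for (tr in intersect(cfg$traits, names(data$blues))) {
      M <- pairwise_cycle_matrix(sub, tr, diag_reps = cfg$cv$reps %||% 10,
                                 seed = cfg$seed)
      write.csv(data.frame(train = rownames(M), as.data.frame(M)),
                file.path(out, paste0("pairwise_", tr, ".csv")),
                row.names = FALSE)
      fl <- identify_outliers(M)
      s <- attr(fl, "summary"); s$trait <- tr
      rows[[length(rows) + 1]] <- s
    }
    write.csv(do.call(rbind, rows),
              art$outliers <- file.path(out, "outlier_report.csv"),
              row.names = FALSE)
  })

  if (wants("derived")) stage_try("derived", {
    if (is.null(data)) stop("derived-trait analysis requires stage2 results")
    dv <- cfg$derived %||% list()
    main_cycles <- setdiff(unique(data$blues$cycle), "V")
    sub <- data; sub$blues <- sub$blues[sub$blues$cycle %in% main_cycles, ]
    ts <- unlist(dv$train_sizes) %||%
      ((length(main_cycles) - 1) * 8)
    cmp <- compare_direct_vs_component(sub, ts, reps = dv$reps %||% 5,
                                       seed = cfg$seed)
    write.csv(cmp$table, art$derived <- file.path(out, "derived_comparison.csv"),
              row.names = FALSE)
  })

  manifest <- list(package = "gscycles",
                   version = as.character(utils::packageVersion("gscycles")),
                   seed = cfg$seed, stages = stages,
                   config_hash = config_hash(cfg),
                   artifacts = vapply(art, basename, ""))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  art$manifest <- file.path(out, "manifest.json")
  invisible(art)
}

#' Collect pipeline artifacts into report tables
#'
#' Reads whatever CSV artifacts are present in `dir` and returns them as a
#' named list of data frames (variance components, stage-1 trial summary,
#' cross-validation accuracies aggregated by scheme/trait, pairwise matrices,
#' outlier report, derived-trait comparison). Missing artifacts are listed in
#' the `missing` element; the report is still produced for the rest and a
#' plain-text summary is written to `report.txt`.
#'
#' @param dir Artifact directory from [run_pipeline()].
#' @return A named list of data frames, invisibly; element `missing` names
#'   absent artifacts.
#' @export
make_report <- function(dir) {
  want <- c(variance_components = "variance_components.csv",
            stage1 = "stage1_trials.csv",
            cv = "cv_results.csv",
            outliers = "outlier_report.csv",
            derived = "derived_comparison.csv")
  rep <- list(); missing <- character(0)
  for (nm in names(want)) {
    p <- file.path(dir, want[[nm]])
    if (file.exists(p)) rep[[nm]] <- read.csv(p, stringsAsFactors = FALSE)
    else missing <- c(missing, want[[nm]])
  }
  pw <- list.files(dir, "^pairwise_.*\\.csv$", full.names = TRUE)
  for (p in pw) rep[[sub("\\.csv$", "", basename(p))]] <-
    read.csv(p, stringsAsFactors = FALSE)
  if (!is.null(rep$cv)) {
    agg <- aggregate(r_gs ~ scheme + trait + unit + train_size, rep$cv, mean)
    names(agg)[names(agg) == "r_gs"] <- "mean_r_gs"
    rep$cv_summary <- agg
  }
  rep$missing <- missing
  txt <- c("gscycles pipeline report", "")
  if (length(rep) == 1 && length(missing) == length(want)) {
    txt <- c(txt, "no artifacts found")
  } else {
    for (nm in setdiff(names(rep), "missing")) {
      txt <- c(txt, paste0("## ", nm),
               utils::capture.output(print(utils::head(rep[[nm]], 20))), "")
    }
    if (length(missing)) txt <- c(txt, paste("missing:", paste(missing, collapse = ", ")))
  }
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(rep)
}
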