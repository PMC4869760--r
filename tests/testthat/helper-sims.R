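## shared simulation fixtures, built in code and cached per session so the
## heavier Monte-Carlo suites can reuse them

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## a five-cycle desk-scale program: high-heritability grain yield, low
## protein content, hence a low-heritability product trait
bias_config <- function(seed, outlier_cycle = NULL) {
  ot <- if (is.null(outlier_cycle)) list() else
    outlier_cycle_spec(outlier_cycle, 3)
  program_config(n_cycles = 5, lines_per_cycle = rep(40, 5), n_founders = 16,
                 n_markers = 250, n_qtl = 50,
                 target_h2 = rbind(grain_yield = rep(0.75, 5),
                                   protein_content = rep(0.30, 5)),
                 trials_per_cycle = rep(3, 5), missing_rate = 0.02,
                 spatial_sd = c(grain_yield = 0, protein_content = 0),
                 cycle_genetic_frac = c(grain_yield = 0.15,
                                        protein_content = 2),
                 outlier_trials = ot, seed = seed)
}

## full two-stage pipeline on a simulated program, baseline stage-1 models
## (no spatial trend simulated), returning a gs_data bundle
sim_dataset <- function(seed, outlier_cycle = NULL,
                        traits = gs_traits(), min_h2 = NULL) {
  key <- paste0("ds_", seed, "_", outlier_cycle %||% "none", "_",
                paste(substr(traits, 1, 2), collapse = ""))
  cached(key, {
    pop <- simulate_genotypes(bias_config(seed, outlier_cycle))
    plots <- simulate_phenotypes(pop)
    an <- analyze_phenotypes(plots, traits = traits, min_h2 = min_h2,
                             models = "baseline")
    gs_data_from_analysis(pop, an)
  })
}

## small three-cycle dataset for quick scheme-level tests
quick_dataset <- function(seed = 11) {
  cached(paste0("quick_", seed), {
    pop <- simulate_genotypes(program_config(
      n_cycles = 3, lines_per_cycle = rep(45, 3), n_founders = 12,
      n_markers = 200, n_qtl = 40, target_h2 = 0.6,
      trials_per_cycle = rep(3, 3), missing_rate = 0.02,
      spatial_sd = c(grain_yield = 0, protein_content = 0),
      validation_lines = 30, seed = seed))
    plots <- simulate_phenotypes(pop)
    an <- analyze_phenotypes(plots, traits = gs_traits(), min_h2 = 0.2,
                             models = "baseline")
    gs_data_from_analysis(pop, an)
  })
}

## direct marker-architecture draw (no trial structure): y = Zu + e at a
## given heritability, for the GS-model recovery checks
draw_marker_trait <- function(seed, N = 200, M = 300, h2 = 0.5) {
  local({
    set.seed(seed)
    Z <- matrix(sample(c(-1, 1), N * M, TRUE), N, M,
                dimnames = list(sprintf("L%03d", 1:N), sprintf("M%03d", 1:M)))
    u <- rnorm(M, 0, sqrt(2 / M))
    g <- drop(Z %*% u)
    e <- rnorm(N, 0, sqrt(var(g) * (1 - h2) / h2))
    list(Z = Z, g = g, e = e, y = 10 + g + e,
         h2_real = var(g) / (var(g) + var(e)))
  })
}
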