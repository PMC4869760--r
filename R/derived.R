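## derived: predicting a product trait (protein yield, dt/ha) from the GEBVs
## of its component traits (grain yield, dt/ha; protein content, %) instead
## of modelling it directly. GEBVs are genetic deviations, so the cohort
## means are added back before multiplying; the /100 converts the percent
## units.

#' Product-trait GEBV from component-trait GEBVs
#'
#' `(mean_gy + gebv_gy) * (mean_pc + gebv_pc) / 100` per line. With
#' `deviations_only = TRUE` the raw product of the centred GEBVs is returned
#' instead (a ranking that ignores the mean structure; kept for comparison).
#'
#' @param gebv_gy,gebv_pc Named, aligned GEBV vectors (genetic deviations).
#' @param mean_gy,mean_pc Cohort means on the natural scale (dt/ha, %).
#' @param deviations_only Multiply the centred deviations without the means.
#' @return Named numeric vector of derived-trait predictions (dt/ha).
#' @export
product_trait_gebv <- function(gebv_gy, mean_gy, gebv_pc, mean_pc,
                               deviations_only = FALSE) {
  if (length(gebv_gy) != length(gebv_pc))
    stop("component GEBV vectors are misaligned")
  if (!is.null(names(gebv_gy)) && !is.null(names(gebv_pc))) {
    if (!identical(names(gebv_gy), names(gebv_pc)))
      stop("component GEBV vectors are misaligned (line ids differ)")
  }
  if (deviations_only) return(gebv_gy * gebv_pc / 100)
  (mean_gy + gebv_gy) * (mean_pc + gebv_pc) / 100
}

#' Compare direct and component-product prediction of the derived trait
#'
#' Runs the across-cycle cross-validation twice on identical training
#' samples: once fitting the derived trait (protein yield) directly, once
#' fitting the two component traits and combining their GEBVs with
#' [product_trait_gebv()]. Both arms share folds and seeds, so accuracy
#' differences are attributable to the estimator alone.
#'
#' @inheritParams across_cycle_cv
#' @param train_sizes Training population sizes to evaluate.
#' @param derived_trait,component_traits Trait names (columns of
#'   `data$blues`).
#' @return A list with `table` (train_size, replicate, `direct_r`,
#'   `component_r`, `delta_pct`) and `summary` (per train_size means and
#'   relative change %).
#' @export
compare_direct_vs_component <- function(data, train_sizes, reps = 100,
                                        seed = 1, with_year_effect = TRUE,
                                        derived_trait = "protein_yield",
                                        component_traits = c("grain_yield",
                                                             "protein_content")) {
  traits <- c(derived_trait, component_traits)
  miss <- setdiff(traits, names(data$blues))
  if (length(miss)) stop("traits absent from data: ", paste(miss, collapse = ", "))
  cycles <- unique(data$blues$cycle)
  rows <- list()
  for (ts in train_sizes) {
    for (r in seq_len(reps)) {
      dir_acc <- c(); comp_acc <- c()
      for (h in cycles) {
        tc <- setdiff(cycles, h)
        q <- rep(ts %/% length(tc), length(tc))
        rem <- ts - sum(q)
        if (rem > 0) q[seq_len(rem)] <- q[seq_len(rem)] + 1
        tr_lines <- unlist(lapply(seq_along(tc), function(i) {
          cc <- tc[i]
          ls <- cv_lines(data, cc, derived_trait)
          if (length(ls) < q[i])
            stop("quota ", q[i], " exceeds the size of cycle ", cc)
          local_seed(substream_seed(seed, "acv", r, h, cc), sample(ls, q[i]))
        }))
        te_lines <- cv_lines(data, h, derived_trait)
        cyc_f <- factor(data$blues$cycle[match(tr_lines, data$blues$line)])
        X <- if (with_year_effect && nlevels(cyc_f) > 1) model.matrix(~cyc_f) else NULL
        Ztr <- unclass(data$geno)[tr_lines, , drop = FALSE]
        Zte <- unclass(data$geno)[te_lines, , drop = FALSE]
        blue_te <- blue_of(data, te_lines, derived_trait)
        ## direct arm
        fit_d <- suppressWarnings(fit_rrblup(blue_of(data, tr_lines, derived_trait), Ztr, X = X))
        dir_acc <- c(dir_acc, safe_cor(drop(Zte %*% fit_d$u), blue_te))
        ## component arm: same training lines, same folds
        fit_gy <- suppressWarnings(fit_rrblup(blue_of(data, tr_lines, component_traits[1]), Ztr, X = X))
        fit_pc <- suppressWarnings(fit_rrblup(blue_of(data, tr_lines, component_traits[2]), Ztr, X = X))
        m_gy <- mean(blue_of(data, tr_lines, component_traits[1]))
        m_pc <- mean(blue_of(data, tr_lines, component_traits[2]))
        comp <- product_trait_gebv(drop(Zte %*% fit_gy$u), m_gy,
                                   drop(Zte %*% fit_pc$u), m_pc)
        comp_acc <- c(comp_acc, safe_cor(comp, blue_te))
      }
      d <- mean(dir_acc, na.rm = TRUE); cm <- mean(comp_acc, na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        train_size = ts, replicate = r, direct_r = d, component_r = cm,
        delta_pct = if (abs(d) > 1e-12) (cm - d) / abs(d) * 100 else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$train_size), function(s) {
    d <- mean(s$direct_r, na.rm = TRUE); cm <- mean(s$component_r, na.rm = TRUE)
    data.frame(train_size = s$train_size[1], direct_r = d, component_r = cm,
               delta_pct = if (abs(d) > 1e-12) (cm - d) / abs(d) * 100 else NA_real_)
  }))
  rownames(summ) <- NULL
  list(table = tab, summary = summ)
}
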