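#!/usr/bin/env Rscript
# Fit the four growth-curve models (polynomial LMM with CAR(1), skew-t LMM,
# semi-parametric spline LMM, SITAR) to each sex stratum of the simulated
# cohort and tabulate fit quality: subject-level R^2, squared-error
# summaries, logLik and AIC. Also verifies the AIC-based knot and df
# selections around the shipped presets. Run 01_simulate_cohort.R first.

suppressPackageStartupMessages(library(bmigrowth))
dir.create("results", showWarnings = FALSE)

cohort <- read_cohort("results/data/visits.csv")
genotypes <- read_genotypes("results/data/genotypes.csv", obesity_snp_panel())
st <- stratify_by_sex(cohort, genotypes)

rows <- list()
for (sx in c("female", "male")) {
  co <- st[[sx]]$cohort
  message("fitting ", sx, " stratum (", length(unique(co$subject_id)),
          " subjects)")
  fits <- list(
    LMM = fit_lmm(co, preset_spec("lmm")),
    STLMM = fit_stlmm(co, max_iter = 150, se = FALSE),
    SPLMM = fit_lmm(co, preset_spec("splmm")),
    NLMM = fit_sitar(co, df = if (sx == "female") 3 else 4)
  )
  for (m in names(fits)) {
    r <- comparison_row(fits[[m]], m)
    r$sex <- sx
    rows[[paste(sx, m)]] <- r
  }
  # fitted population curves for plotting / reporting
  grid <- seq(1, 17, by = 0.25)
  curves <- data.frame(
    sex = sx, age = grid,
    splmm_bmi = predict(fits$SPLMM, grid, scale = "bmi"),
    lmm_bmi = predict(fits$LMM, grid, scale = "bmi"),
    nlmm_bmi = predict(fits$NLMM, grid, scale = "bmi"))
  file <- sprintf("results/population_curves_%s.csv", sx)
  write.csv(curves, file, row.names = FALSE)
  rebound <- grid[which.min(curves$splmm_bmi[grid < 12])]
  message(sprintf(paste("  %s fitted-curve minimum: %.2f years (the",
                        "allele-score slope effect pulls it earlier than",
                        "the genetics-free rebound)"), sx, rebound))
}

tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/model_comparison.csv", row.names = FALSE)
print(tab[, c("sex", "method", "response_scale", "r_squared",
            "sq_err_median", "aic")],
      digits = 4)

# knot-grid selection around the preset spline knots (female stratum)
grids <- list(c(2, 8, 12), c(1.5, 8, 12), c(2.5, 8, 12), c(2, 7.5, 12),
              c(2, 8.5, 12), c(2, 8, 11.5), c(2, 8, 12.5))
sel <- select_spline_model(st$female$cohort, grids)
message("AIC-selected female knots: ", paste(sel$best_knots, collapse = ", "))
write.csv(sel$table, "results/knot_selection_female.csv", row.names = FALSE)

# SITAR df choice per sex
for (sx in c("female", "male")) {
  ds <- choose_sitar_df(st[[sx]]$cohort, dfs = 3:6)
  message(sprintf("AIC-selected SITAR df (%s): %d", sx, ds$best_df))
  write.csv(ds$table, sprintf("results/sitar_df_%s.csv", sx),
            row.names = FALSE)
}
cat("wrote results/model_comparison.csv and selection tables\n")
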