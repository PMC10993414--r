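#!/usr/bin/env Rscript
# Step 4 — simulation studies validating the pipeline's guarantees, plus
# the two summary figures (when ggplot2 is available): the specificity
# scatter (SR_baseline vs SR_cytotoxicity with the threshold guides) and
# the per-sample BEQ contribution bars.

suppressPackageStartupMessages(library(mitotox))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[[1]]) else 1L
dir.create("results/validation", showWarnings = FALSE, recursive = TRUE)

cat("== EC10 recovery across six potency decades (100 chemicals) ==\n")
rec <- ec10_recovery_study(n_chems = 100, noise = noise_model(),
                           seed = seed)
cat(sprintf("median |log10(EC10_est/EC10_true)| = %.4f; %.0f%% active\n",
            median(abs(rec$log10_err), na.rm = TRUE),
            100 * mean(rec$active)))
write_full_precision(rec, "results/validation/ec10_recovery.csv")

cat("\n== Iceberg closure under concentration addition ==\n")
for (label in c("design noise", "noise-free")) {
  noise <- if (label == "design noise") noise_model() else noise_model(0, 0)
  cl <- mixture_closure_study(noise = noise, seed = seed + 1)
  cat(sprintf("%s: %.1f%% of the mixture effect explained\n", label,
              cl$pct_explained))
}
part <- mixture_closure_study(noise = noise_model(0, 0), seed = seed + 1,
                              withhold = "unc_a")
cat(sprintf(paste0("withholding one constituent (true BEQ share %.1f%%):",
                   " %.1f%% explained\n"),
            100 * part$withheld_beq_fraction, part$pct_explained))

cat("\n== Specificity-class recovery over 200 noisy screens ==\n")
cls <- classification_recovery_study(n_rep = 200, noise = noise_model(),
                                     seed = seed + 2)
cat(sprintf("baseline toxicant -> baseline_like: %.1f%%\n",
            100 * cls$baseline_rate))
cat(sprintf("complex-I profile -> specific MMP: %.1f%%\n",
            100 * cls$complexI_rate))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  spec <- read.csv("results/chemical_screen/sr_scatter.csv")
  p1 <- ggplot(spec, aes(sr_cyto, sr_baseline, colour = mie_class)) +
    geom_point(size = 3, na.rm = TRUE) +
    geom_hline(yintercept = 10, linetype = "dashed") +
    geom_vline(xintercept = 10, linetype = "dashed") +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "SR_cytotoxicity", y = "SR_baseline",
         title = "Specificity of MMP disruption",
         subtitle = "dashed: specificity threshold 10; diagonal: TR = 1")
  ggsave("results/validation/sr_scatter.pdf", p1, width = 6, height = 5)

  contrib <- read.csv("results/water_screen/contributions.csv")
  p2 <- ggplot(contrib, aes(sample_id, beq_i, fill = chem_id)) +
    geom_col() +
    labs(x = NULL, y = "BEQ (mol reference-equivalents / L water)",
         title = "Chemical contributions to the predicted mixture effect")
  ggsave("results/validation/beq_contributions.pdf", p2, width = 5,
         height = 4)
  cat("\nwrote results/validation/{sr_scatter,beq_contributions}.pdf\n")
}
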