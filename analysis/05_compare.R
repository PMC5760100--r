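#!/usr/bin/env Rscript
# Group statistics over the study tables written by 04_study.R: reads the
# deposited-style kinetics/contacts tables back through the table reader,
# recomputes the study-wide grand means, and runs the statistical protocol
# (Student's t wt vs mutant, Mann-Whitney U for contacts, one-way ANOVA
# across the wild-type groups). Writes results/comparisons.csv and
# results/grand_means.csv.

suppressPackageStartupMessages(library(punctatrack))

study_long <- read_s1_table("results/study")
gm <- s1_grand_means(study_long)
cat("Grand means over all photoreceptors:\n")
cat(sprintf("  displacement %.0f nm | trajectory %.1f um | max speed %.0f nm/s | area %.2f um^2\n",
            gm["displacement"], gm["trajectory"], gm["max_speed"], gm["size"]))
cat(sprintf("  contact proportion %.3f | contacting puncta per PR up to %.0f\n",
            gm["contact_proportion"],
            max(study_long$value[study_long$metric == "n_contacting"])))

wide <- utils::read.csv("results/study/kinetics.csv", check.names = FALSE)
contacts <- utils::read.csv("results/study/contacts.csv", check.names = FALSE)
summaries <- data.frame(
  animal_id = wide$Animal, cell_id = wide$PR, condition = wide$Condition,
  n_tracks = NA_integer_,
  displacement_nm = wide$Displacement, trajectory_um = wide$Trajectory,
  max_speed_nm_s = wide$`Maximum Speed`, area_um2 = wide$Size,
  directionality = NA_real_,
  contact_proportion = contacts$`Proportion contacting`,
  n_contacting = contacts$`Number contacting`)
# directionality lives in the per-track table; aggregate it per cell
m <- utils::read.csv("results/study/track_metrics.csv")
agg <- tapply(m$directionality, m$cell_id, mean, na.rm = TRUE)
summaries$directionality <- as.numeric(agg[summaries$cell_id])

cmp <- study_comparisons(summaries)
utils::write.csv(cmp, "results/comparisons.csv", row.names = FALSE)
utils::write.csv(
  data.frame(metric = names(gm), grand_mean = as.numeric(gm)),
  "results/grand_means.csv", row.names = FALSE)

cat("\nComparisons (", nrow(cmp), " tests):\n", sep = "")
sig <- cmp[cmp$stars != "ns", ]
if (nrow(sig)) {
  for (i in seq_len(nrow(sig))) {
    cat(sprintf("  %s %-18s %-34s p = %.3g\n", sig$stars[i], sig$metric[i],
                sig$comparison[i], sig$p[i]))
  }
} else {
  cat("  no comparison significant at 0.05\n")
}
cat("Wrote results/comparisons.csv and results/grand_means.csv\n")
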