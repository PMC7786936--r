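#!/usr/bin/env Rscript
# Assembles the outputs of 02/03 into the two headline tables:
#   results/table_accuracy.csv  - percent correct MTD, method x scenario
#   results/table_summary.csv   - classification percentages averaged over
#                                 clinical, theoretical, and all curves
# Run after 02_simulate_3p3.R and 03_simulate_crm.R.

library(crmcompare)

p3 <- read.csv("results/sim_3p3.csv")
cr <- read.csv("results/sim_crm.csv")
p3$skeleton <- NA_character_
all <- rbind(p3[names(cr)], cr)

grid <- accuracy_grid(all)
cat("Percent of 1000 simulated trials selecting the true MTD:\n\n")
print(grid, row.names = FALSE)
write.csv(grid, "results/table_accuracy.csv", row.names = FALSE)

clinical <- names(clinical_scenarios())
method_rows <- function(sub, label) {
  sub$method <- ifelse(sub$design == "3p3", "3+3", paste0("CRM ", sub$skeleton))
  out <- do.call(rbind, lapply(split(sub, sub$method), function(g) {
    a <- aggregate_across_scenarios(g)
    data.frame(curves = label, method = g$method[1],
               true_selected = round(a$pct_correct, 1),
               underestimated = round(a$pct_under, 1),
               overestimated = round(a$pct_over, 1),
               not_determined = round(a$pct_not_determined, 1))
  }))
  out[order(-out$true_selected), ]
}
summary_tab <- rbind(
  method_rows(all[all$scenario %in% clinical, ], "clinical"),
  method_rows(all[!all$scenario %in% clinical, ], "theoretical"),
  method_rows(all, "all"))
rownames(summary_tab) <- NULL

cat("\nClassification percentages averaged over curves:\n\n")
print(summary_tab, row.names = FALSE)
write.csv(summary_tab, "results/table_summary.csv", row.names = FALSE)

over_all <- summary_tab[summary_tab$curves == "all", ]
cat(sprintf("\nLeast overestimation: %s (%.1f%%); most: %s (%.1f%%).\n",
            over_all$method[which.min(over_all$overestimated)],
            min(over_all$overestimated),
            over_all$method[which.max(over_all$overestimated)],
            max(over_all$overestimated)))
cat("wrote results/table_accuracy.csv, results/table_summary.csv\n")
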