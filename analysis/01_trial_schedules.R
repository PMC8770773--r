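#!/usr/bin/env Rscript
# Build the trial schedules for every experimental phase, apply the
# analysis-inclusion rules, and record the per-condition trial accounting.
#
# Findings checked here: the conditioning phase (6 runs) leaves exactly 12
# analysable trials per condition after excluding reinforced CS+ trials and
# the run-edge CS- trials; the regulation phase (8 runs) leaves 16; a
# truncated 5-run regulation phase (one participant stopped early) leaves 10.

library(imagfear)

out <- "results/design"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

seed <- 20260925
phases <- list(
  classifier_training = 6, preconditioning = 3, conditioning = 6, regulation = 8
)

accounting <- NULL
for (phase in names(phases)) {
  sch <- apply_exclusions(build_phase_schedule(phase, phases[[phase]], seed))
  schedule_events(sch, file.path(out, paste0(phase, "_events.tsv")))
  cc <- count_analyzable(sch)
  accounting <- rbind(accounting, cbind(phase = phase, n_runs = phases[[phase]], cc))
  cat(sprintf("%-20s %d runs: %3d trials, %s included per condition\n",
              phase, phases[[phase]], nrow(sch$trials),
              paste(unique(cc$n_included), collapse = "/")))
}

# the early-stopping participant: 5 regulation runs -> 10 per condition
sch5 <- apply_exclusions(build_phase_schedule("regulation", 5, seed))
cc5 <- count_analyzable(sch5)
accounting <- rbind(accounting, cbind(phase = "regulation_truncated",
                                      n_runs = 5, cc5))
cat(sprintf("%-20s %d runs: %3d trials, %s included per condition\n",
            "regulation (5 runs)", 5, nrow(sch5$trials),
            paste(unique(cc5$n_included), collapse = "/")))

write.table(accounting, file.path(out, "trial_accounting.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "trial_accounting.tsv"), "\n")
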