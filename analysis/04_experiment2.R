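#!/usr/bin/env Rscript
# Full synthetic replication of visit two: regulation of fear conditioning
# by mental imagery.
#
# The 12 returning participants view one conditioned stimulus while
# imagining the opposite one on regulate trials. Visual-ROI classifiers are
# trained on the (day one) classifier-training phase and score regulate
# trials against the viewed stimulus; the amygdala analysis trains on
# day-one conditioning view trials and is gated on its view-trial positive
# control, in both the forward and the reverse direction.

library(imagfear)

cfg <- experiment_config(n_perm = 1000, n_boot = 2000, seed = 20260925)
t0 <- Sys.time()
bundle <- suppressWarnings(run_experiment2(cfg))
cat("experiment 2 finished in", format(Sys.time() - t0, digits = 3), "\n\n")

cat("visual-ROI decoding (view / regulate):\n")
print(bundle$decoding, row.names = FALSE, digits = 4)
cat("\nview - regulate accuracy differences:\n")
print(bundle$differences, row.names = FALSE, digits = 4)

for (dir in names(bundle$amygdala)) {
  g <- bundle$amygdala[[dir]]
  cat(sprintf("\namygdala %s (%s): positive control p = %.4f -> %s\n",
              dir, g$direction, g$gate_p,
              if (g$gate_passed) "proceed" else "dependent analysis not run"))
  print(g$accuracies, row.names = FALSE, digits = 4)
  if (!is.null(g$difference)) print(g$difference, row.names = FALSE, digits = 4)
}

cat("\nSCR 2x2 rm-ANOVA (two-tailed policy):\n")
print(bundle$scr$anova, row.names = FALSE, digits = 4)
cat("\nself-reported fear rm-ANOVA:\n")
print(bundle$ratings$anova, row.names = FALSE, digits = 4)

write_report(bundle, "results/experiment2")
cat("\nwrote results/experiment2\n")
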