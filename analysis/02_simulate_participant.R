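#!/usr/bin/env Rscript
# Simulate one synthetic participant end to end and export the raw artefacts:
# the classifier-training and conditioning ROI pattern matrices, the 1 kHz
# skin conductance trace with its event markers, and the scored trial peaks.
#
# This is the unit of data every downstream analysis consumes; the exported
# TSVs double as worked examples of the package's serialization formats.

library(imagfear)

out <- "results/participant_example"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925

ct <- apply_exclusions(build_phase_schedule("classifier_training", 6, seed))
cond <- apply_exclusions(build_phase_schedule("conditioning", 6, seed))

group_truth <- pattern_truth(500, view_gain = 1, imagery_gain = 0.5,
                             noise_sd = 8, seed = seed)
truth <- participant_pattern_truth(group_truth, "p01", seed)
train <- simulate_roi_dataset(ct, truth, derive_seed(seed, "train"),
                              roi_name = "V1", participant_id = "p01")
test <- simulate_roi_dataset(cond, truth, derive_seed(seed, "test"),
                             roi_name = "V1", participant_id = "p01")

clf <- train_classifier(train, select_features(train, 120))
acc <- cross_classify(clf, test)
cat("within-participant cross-classification (V1-sized ROI):\n")
print(acc, row.names = FALSE)
write.table(acc, file.path(out, "decoding_accuracy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# raw traces are bulky (1 kHz x ~240 s x 6 runs); keep the scored artefacts.
# write_scr_trace() exports the full two-column TSV serialization if needed.
trace <- simulate_scr(cond, scr_truth(), derive_seed(seed, "scr"))
peaks <- score_trial_peaks(scr_epochs(scr_preprocess(trace)))
means <- scr_condition_means(peaks)
cat("\nSCR condition means (uS):\n")
print(means, row.names = FALSE)
write.table(peaks[, c("run_index", "position_in_run", "instruction",
                      "viewed_stimulus", "imagined_stimulus", "reinforced",
                      "included", "peak", "zeroed")],
            file.path(out, "scr_trial_peaks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(means, file.path(out, "scr_condition_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote", out, "\n")
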