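#!/usr/bin/env Rscript
# Measure plaque echogenicity for every frame/observer pair produced by
# 01_simulate_images.R: denoise, normalize brightness against the annotated
# references, compute plaque gray statistics, aggregate to participant GSM,
# and summarize interobserver agreement on a reliability subsample.

suppressPackageStartupMessages(library(carotidgsm))

img_dir <- "results/images"
stopifnot(dir.exists(img_dir))
ann_files <- list.files(img_dir, pattern = "_obs[0-9]+\\.json$", full.names = TRUE)

rows <- lapply(ann_files, function(f) {
  ann <- read_annotation(f)
  frame <- read_frame(file.path(img_dir, paste0(ann$frame_id, ".png")),
                      frame_id = ann$frame_id)
  r <- measure_frame(frame, ann)
  r$participant_id <- sub("_f[0-9]+$", "", ann$frame_id)
  r
})
res <- do.call(rbind, rows)
write.csv(res, "results/echogenicity.csv", row.names = FALSE)

participants <- aggregate_participants(res, value = "gsm_median")
write.csv(participants, "results/participant_gsm.csv", row.names = FALSE)

truth <- read.csv(file.path(img_dir, "ground_truth.csv"))
cmp <- merge(participants, truth, by = "participant_id")
cat(sprintf("participants measured: %d; mean |GSM - truth| = %.2f units\n",
            nrow(cmp), mean(abs(cmp$gsm - cmp$true_gsm))))

# interobserver agreement on a reliability subsample
ids <- interobserver_subsample(unique(res$participant_id), fraction = 0.25, seed = 5)
sub <- res[res$participant_id %in% ids, ]
wide <- reshape(sub[, c("frame_id", "observer_id", "gsm_mean")],
                idvar = "frame_id", timevar = "observer_id", direction = "wide")
agr <- interobserver_agreement(wide$gsm_mean.obs1, wide$gsm_mean.obs2)
cat(sprintf("interobserver ICC(2,1) = %.3f, mean difference = %.2f, LoA = [%.2f, %.2f], %d outlier(s) flagged\n",
            agr$icc, agr$mean_diff, agr$loa[1], agr$loa[2], length(agr$outliers)))
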