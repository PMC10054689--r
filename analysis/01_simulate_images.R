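#!/usr/bin/env Rscript
# Simulate a batch of annotated ultrasound-like frames with known plaque
# echogenicity. Writes PNG frames plus JSON annotations (two observers per
# frame, the second with a slightly perturbed outline) and a ground-truth
# table under results/images/.

suppressPackageStartupMessages(library(carotidgsm))

out_dir <- "results/images"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
set.seed(20160208)

n_participants <- 20
truth <- list()
for (p in seq_len(n_participants)) {
  pid <- sprintf("P%03d", p)
  target <- runif(1, 35, 85)             # plaques across the echolucent-echogenic range
  spec <- image_spec(target_gsm = target, sigma = 6)
  gi <- generate_image(spec, seed = 1000 + p, frame_id = paste0(pid, "_f1"),
                       observer_id = "obs1")
  write_frame(gi$frame, file.path(out_dir, paste0(pid, "_f1.png")))
  write_annotation(gi$annotation, file.path(out_dir, paste0(pid, "_f1_obs1.json")))
  # second observer: same frame, outline jittered vertex-wise (~2 px) plus a
  # small systematic over/under-segmentation, as human re-readings show
  ann2 <- gi$annotation
  ann2$observer_id <- "obs2"
  scale2 <- runif(1, 0.93, 1.07)
  ctr <- colMeans(ann2$plaque)
  ann2$plaque <- sweep(sweep(ann2$plaque, 2, ctr) * scale2, 2, ctr, "+") +
    matrix(rnorm(length(ann2$plaque), 0, 2), ncol = 2)
  write_annotation(ann2, file.path(out_dir, paste0(pid, "_f1_obs2.json")))
  truth[[p]] <- data.frame(participant_id = pid,
                           frame_id = paste0(pid, "_f1"),
                           true_gsm = gi$ground_truth$gsm_mean,
                           n_plaque_pixels = gi$ground_truth$n_plaque_pixels)
}
truth <- do.call(rbind, truth)
write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
cat(sprintf("wrote %d frames (x2 observers) and ground truth to %s\n",
            n_participants, out_dir))
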