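# Small fixtures built in code.

# A 32x32 frame with distinct lumen/adventitia strips and simple rectangle
# annotations, for normalization tests where exact anchor values matter.
tiny_annotated_frame <- function(lumen_value = 40, adventitia_value = 160,
                                 body_value = 100) {
  px <- matrix(body_value, 32, 32)
  px[5:12, ] <- lumen_value
  px[20:27, ] <- adventitia_value
  ann <- annotation_set("tiny", "obs1",
                        plaque = cbind(x = c(2, 30, 30, 2), y = c(13, 13, 19, 19)),
                        lumen = cbind(x = c(2, 30, 30, 2), y = c(5, 5, 11, 11)),
                        adventitia = cbind(x = c(2, 30, 30, 2), y = c(20, 20, 26, 26)),
                        frame_dims = c(32, 32))
  list(frame = ultrasound_frame(px, "tiny"), annotation = ann)
}

random_polygon <- function(n_vertices, dims, seed) {
  set.seed(seed)
  cx <- dims[2] / 2; cy <- dims[1] / 2
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.15, 0.45) * min(dims)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Wide FFQ fixture in long format over the synthetic composition table.
synthetic_composition <- function() {
  utils::read.csv(system.file("extdata", "composition_synthetic.csv",
                              package = "carotidgsm"))
}
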