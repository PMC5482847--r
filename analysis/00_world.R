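# Shared world definition for the analysis scripts: a synthetic
# hyperscanning study at the design's sample size (15 dyads -> 30 cases,
# 5 topics + rest, 90-s epochs at 250 Hz) on an 8-channel montage.
#
# The world plants all three kinds of structure the analysis must
# separate:
#   * direct interbrain coupling: 4 alpha + 4 beta channel pairs locked
#     (kappa = 0.85) to trial-unique drivers independent of the speech;
#   * speech-mediated coupling: listener and speaker channels 1-2
#     entrained to the shared speech envelope in theta, with per-case
#     strength varying over [0.15, 1] x 0.8;
#   * everything else: null pairs (1/f noise + uncoupled oscillators).

suppressPackageStartupMessages(library(dyadsync))

world_coupling <- function() {
  data.frame(listener = 1:8, speaker = c(2:8, 1),
             band = rep(c("alpha", "beta"), each = 4), kappa = 0.85)
}

world_env_coupling <- function() {
  ec <- expand.grid(role = c("speak", "listen"), channel = 1:2, band = "theta",
                    stringsAsFactors = FALSE)
  ec$kappa <- 0.8
  ec
}

world_config <- function(seed = 1) {
  synth_config(n_dyads = 15, n_channels = 8, epoch_len = 90, n_topics = 5,
               coupling = world_coupling(), env_coupling = world_env_coupling(),
               case_scale_range = c(0.15, 1), seed = seed)
}

mediated_pairs <- function() expand.grid(l = 1:2, s = 1:2)

arg_seed <- function(default = 1L) {
  a <- commandArgs(trailingOnly = TRUE)
  i <- which(a == "--seed")
  if (length(i) == 1 && i < length(a)) as.integer(a[i + 1]) else default
}

results_dir <- function() {
  d <- "results"
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
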