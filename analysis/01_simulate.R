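#!/usr/bin/env Rscript
# Simulate the synthetic hyperscanning world and inspect one dyad.
#
# Writes: results/ground_truth.tsv      planted coupling and entrainment
#         results/world_config.json     full generator configuration
#         results/envelope_spectrum.tsv periodogram of one speech envelope

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_world.R"))

seed <- arg_seed()
cfg <- world_config(seed)
dir <- results_dir()

ses <- generate_dyad_session(cfg, 1)
cat(sprintf("dyad 1: %d epochs per participant (%s)\n",
            length(ses$epochs$A$epochs),
            paste(names(table(vapply(ses$epochs$A$epochs, `[[`, character(1), "role"))),
                  collapse = "/")))
cat(sprintf("%d speech envelopes (one per speaking turn)\n", length(ses$envelopes)))

truth <- rbind(
  data.frame(kind = "interbrain",
             listener = cfg$channels[world_coupling()$listener],
             speaker = cfg$channels[world_coupling()$speaker],
             role = NA, channel = NA,
             band = world_coupling()$band, kappa = world_coupling()$kappa),
  data.frame(kind = "envelope", listener = NA, speaker = NA,
             role = world_env_coupling()$role,
             channel = cfg$channels[world_env_coupling()$channel],
             band = world_env_coupling()$band, kappa = world_env_coupling()$kappa)
)
write.table(truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("ground truth: %d coupled pairs, %d entrained channel-roles\n",
            sum(truth$kind == "interbrain"), sum(truth$kind == "envelope")))

env <- ses$envelopes[[1]]$values
sp <- stats::spec.pgram(stats::ts(env - mean(env), frequency = cfg$rate),
                        taper = 0, spans = 21, plot = FALSE)
keep <- sp$freq <= 15
write.table(data.frame(freq_hz = sp$freq[keep], power = sp$spec[keep]),
            file.path(dir, "envelope_spectrum.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
pk <- sp$freq[keep][which.max(sp$spec[keep])]
cat(sprintf("envelope fluctuation peak: %.2f Hz (syllabic range)\n", pk))

cfg_json <- cfg
cfg_json$bands <- data.frame(name = names(cfg$bands),
                             lo = vapply(cfg$bands, `[[`, numeric(1), "lo"),
                             hi = vapply(cfg$bands, `[[`, numeric(1), "hi"))
jsonlite::write_json(cfg_json, file.path(dir, "world_config.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE)
cat("wrote ground_truth.tsv, envelope_spectrum.tsv, world_config.json\n")
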