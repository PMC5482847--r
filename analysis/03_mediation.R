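#!/usr/bin/env Rscript
# Inspect the mediation regression scan and the exclusion mask produced
# by 02_synchronization.R: which significant interbrain pairs are
# explained by both brains' coupling to the speech envelope, and which
# survive as speech-independent interbrain coupling.
#
# Reads:  results/pipeline/{mediation.tsv, exclusion_provenance.tsv,
#         exclusion_survivors.tsv}
# Writes: results/mediation_summary.tsv, results/exclusion_summary.tsv

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "00_world.R"))

dir <- results_dir()
pdir <- file.path(dir, "pipeline")
if (!file.exists(file.path(pdir, "mediation.tsv"))) {
  stop("run analysis/02_synchronization.R first")
}
med <- read.delim(file.path(pdir, "mediation.tsv"))
prov <- read.delim(file.path(pdir, "exclusion_provenance.tsv"))
surv <- read.delim(file.path(pdir, "exclusion_survivors.tsv"))

ms <- aggregate(significant ~ band + model, med, sum)
names(ms)[3] <- "n_significant"
ms$n_tests <- nrow(med) / nrow(unique(med[c("band", "model")]))
write.table(ms, file.path(dir, "mediation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mediation scan, significant fits per band and model:\n")
print(ms)

cfg <- world_config(arg_seed())
mp <- mediated_pairs()
med$pair <- paste(med$listener, med$speaker, med$band)
planted <- paste(cfg$channels[mp$l], cfg$channels[mp$s], "theta")
flagged <- tapply(med$significant[med$pair %in% planted],
                  med$pair[med$pair %in% planted], any)
cat(sprintf("\nplanted mediated pairs flagged by the scan: %d/%d\n",
            sum(flagged), length(planted)))

es <- as.data.frame(table(prov$band, prov$status))
names(es) <- c("band", "status", "n")
write.table(es[es$n > 0, ], file.path(dir, "exclusion_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nexclusion outcomes for significant interbrain pairs:\n")
print(table(prov$band, prov$status))
cat(sprintf("\nsurviving speech-independent pairs: %d (%s)\n", nrow(surv),
            paste(sprintf("%s: %d", names(table(surv$band)), table(surv$band)),
                  collapse = ", ")))
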