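#!/usr/bin/env Rscript
# Simulate a cohort of chamber-preference sessions with known ground truth.
#
# Two genotypes are generated: a wildtype whose test-chamber (warm) drift is
# elevated relative to neutral (it leaves the warm chamber faster), and a
# knockout-like genotype with a reduced test-chamber drift (longer warm
# visits, the phenotype reported for Trpm2-/- animals). The ground-truth
# visit tables and the rendered keypoint tracks go under results/01/.

library(thermodrift)

out <- "results/01"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- behavior_sim_config(n_animals_per_genotype = 10L, seed = 1L)
sessions <- gen_behavior_sessions(cfg)

readr::write_csv(sessions$visits, file.path(out, "ground_truth_visits.csv"))
readr::write_csv(sessions$animals, file.path(out, "animals.csv"))
# one example session as a pose-export style table
write_keypoint_csv(sessions$tracks[[1]],
                   file.path(out, "example_track.csv"))

cat(sprintf("Simulated %d sessions (%d visits in total); mean visit length %.1f s\n",
            length(sessions$tracks), nrow(sessions$visits),
            mean(sessions$visits$duration)))
cat(sprintf("Warm-chamber median visit: wildtype %.1f s, trpm2_ko %.1f s\n",
            median(with(sessions$visits,
                        duration[genotype == "wildtype" & chamber == "test" & !censored])),
            median(with(sessions$visits,
                        duration[genotype == "trpm2_ko" & chamber == "test" & !censored]))))
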