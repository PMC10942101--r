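#!/usr/bin/env Rscript
# Generate the synthetic study session and summarize what it contains:
# session structure, trial counts, spine geometry, and ground-truth labels.

source(file.path("analysis", "00_common.R"))

s <- get_session("effect")
meta <- s$metadata

cat(sprintf("Session: %.0f s, %d imaged frames at %.1f Hz in %d blocks\n",
            s$config$session_length, length(s$frames$times),
            s$config$frame_rate, length(unique(s$frames$block))))
cat(sprintf("Trials: %d cues, %d rewarded presses, %d total presses\n",
            nrow(s$behavior$trials),
            sum(!is.na(s$behavior$trials$reward_s)),
            length(s$behavior$press_onsets)))
cat(sprintf("Spines: %d on %d dendrites (%d eliminated, %d stable)\n",
            nrow(meta), length(unique(meta$dendrite_id)),
            sum(meta$label == "eliminated"), sum(meta$label == "stable")))
cat(sprintf("Ground-truth MRS fraction: %.2f\n", mean(meta$mrs_true)))

write.csv(meta, file.path(RESULTS, "01_spine_metadata.csv"),
          row.names = FALSE)

# demonstrate the on-disk session format on a miniature session
mini <- generate_session(sim_config(seed = STUDY_SEED, n_dendrites = 1L,
                                    spines_per_dendrite = 4L,
                                    session_length = 80, block_on = 60,
                                    block_off = 20, trial_period = 8))
write_session(mini, file.path(RESULTS, "01_mini_session"))
cat("Wrote spine metadata and a miniature CSV session bundle under results/\n")
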