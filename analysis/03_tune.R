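#!/usr/bin/env Rscript
# Between the two steps: AICc-based search over regularization multipliers
# and feature-class sets for each retained subset, on the non-holdout
# occurrence set.

source(file.path("analysis", "common.R"))
s <- analysis_setup()

tuned <- run_stage(run_tune(s$config, s$out))

if (length(tuned)) {
  for (sid in names(tuned)) {
    cat(sprintf("%s -> classes %s, multiplier %g (AICc %.1f)\n", sid,
                tuned[[sid]]$class_set, tuned[[sid]]$reg_multiplier,
                tuned[[sid]]$aicc))
  }
} else {
  cat("nothing to tune: no subset was retained\n")
}
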