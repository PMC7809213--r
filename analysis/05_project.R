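#!/usr/bin/env Rscript
# Future ensemble: every kept model is projected onto each (GCM, RCP, year)
# scenario stack and binarized at its stored current-climate threshold;
# binary maps are pooled into one consensus per (RCP, year) plus per-GCM
# centered deviation maps.

source(file.path("analysis", "common.R"))
s <- analysis_setup()

pr <- run_stage(run_project(s$config, s$out))

if (nrow(pr$tasks)) {
  cat(sprintf("projected %d ensemble tasks into %d scenario groups\n",
              nrow(pr$tasks), length(pr$consensus)))
  for (g in names(pr$consensus)) {
    frac <- mean(pr$consensus[[g]]$mean$values >= 0.5, na.rm = TRUE)
    cat(sprintf("  %s: %d maps pooled; %.1f%% of cells suitable for a majority of models\n",
                g, pr$consensus[[g]]$n_models, 100 * frac))
  }
} else {
  cat("nothing to project: no final models were kept\n")
}
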