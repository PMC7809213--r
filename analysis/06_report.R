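#!/usr/bin/env Rscript
# Agreement report: unanimity and high-agreement area fractions for the
# current-climate and every scenario consensus, globally and over the focal
# window, under cell-count and cosine-latitude weighting.

source(file.path("analysis", "common.R"))
s <- analysis_setup()

tab <- run_stage(run_report(s$config, s$out))

cat(sprintf("wrote %d agreement rows to %s\n", nrow(tab),
            file.path(s$out, "agreement.csv")))
if (nrow(tab)) {
  cur <- tab[tab$scenario == "current" & tab$weighting == "cos_latitude", ]
  for (i in seq_len(nrow(cur))) {
    cat(sprintf("current climate, %s scope: %.2f%% unanimously suitable, %.2f%% unanimously unsuitable, %.1f%% high agreement\n",
                cur$scope[i], 100 * cur$frac_unanimous_suitable[i],
                100 * cur$frac_unanimous_unsuitable[i],
                100 * cur$frac_high_agreement[i]))
  }
}
cat(paste(readLines(file.path(s$out, "summary.txt")), collapse = "\n"), "\n")
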