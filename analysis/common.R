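# Shared plumbing for the numbered analysis scripts: config loading, the
# run directory, and exit-code conventions (0 ok, 2 config error, 3 missing
# upstream stage, 4 data error).

suppressPackageStartupMessages(library(sdmensemble))

analysis_setup <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  cfg <- tryCatch(
    read_config(get_opt("--config", file.path("analysis", "config.yaml"))),
    config_error = function(e) { message("config error: ", conditionMessage(e)); quit(status = 2) })
  seed <- get_opt("--seed", NULL)
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  overrides <- args[which(args == "--override") + 1]
  if (length(overrides) && !anyNA(overrides)) {
    cfg <- tryCatch(config_override(cfg, overrides),
      config_error = function(e) { message("config error: ", conditionMessage(e)); quit(status = 2) })
  }
  out <- get_opt("--out", file.path("results", "run"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  list(config = cfg, out = out)
}

run_stage <- function(expr) {
  tryCatch(expr,
    config_error = function(e) { message("config error: ", conditionMessage(e)); quit(status = 2) },
    missing_dependency = function(e) { message(conditionMessage(e)); quit(status = 3) },
    error = function(e) { message("data error: ", conditionMessage(e)); quit(status = 4) })
}
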