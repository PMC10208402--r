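#!/usr/bin/env Rscript

# Thin command-line wrapper over the pipeline functions:
#   Rscript scripts/run_study.R --config study.yaml [--stage all]
# Stages: simulate, fit, roistats, resample, report, all.

suppressMessages({
  library(optparse)
  library(amura)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML study configuration (defaults used if omitted)"),
  make_option("--stage", type = "character", default = "all")
)))

cfg <- if (is.null(opts$config)) study_config() else
  read_study_config(opts$config)

stages <- list(simulate = cmd_simulate, fit = cmd_fit,
               roistats = cmd_roistats, resample = cmd_resample,
               report = cmd_report)
run <- if (opts$stage == "all") names(stages) else opts$stage
bad <- setdiff(run, names(stages))
if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
for (s in run) stages[[s]](cfg)
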