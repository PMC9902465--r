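#!/usr/bin/env Rscript

# Thin command-line wrapper over fcfusion::run_pipeline(): simulate or
# load a cohort, extract the configured measures, run the nested-CV
# evaluation, fusion and biomarker stages, and write all tables into the
# output directory.
#
# Usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed 1] [--out DIR]

suppressPackageStartupMessages({
  library(optparse)
  library(fcfusion)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML file of overrides to default_config()"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = "pipeline_out")
)))

cfg <- if (is.null(opts$config)) {
  default_config()
} else {
  do.call(default_config, yaml::read_yaml(opts$config))
}
if (!is.null(opts$seed)) cfg$seed <- opts$seed

res <- run_pipeline(cfg, out_dir = opts$out)
print(res$summary)
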