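#!/usr/bin/env Rscript
# Run a full linking-accuracy grid (all C_R x C_I cells, calibration
# thresholds, pass flags) from a YAML experiment config and write the report.
# At the reference scale (5x5 cells, 30 replications, J=100) this is an
# hours-long job; reduce `replications`, the grid, or the sampler length in
# the config for desk-scale runs.
#
# Usage: Rscript scripts/full_grid.R --config cfg.yaml --out report.csv
#        Rscript scripts/full_grid.R --scenario 1 --reps 30 --out report.csv

suppressMessages({
  library(optparse)
  library(facetlink)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML experiment config (see ?load_config)"),
  make_option("--scenario", type = "integer", default = 1L,
              help = "shift scenario 1-4 when no config file is given"),
  make_option("--reps", type = "integer", default = 30L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "grid_report.csv")
)))

cfg <- if (!is.null(opts$config)) {
  load_config(opts$config)
} else {
  experiment_config(J = 100, I = 10, R = 10,
                    new_spec = scenario_spec(opts$scenario),
                    C_R = 1:5, C_I = 1:5,
                    replications = opts$reps, seed = opts$seed)
}

print(cfg)
report <- run_grid(cfg, verbose = TRUE)
write_grid_report(report, opts$out)
format_grid(report)
message("wrote ", opts$out)
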