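#!/usr/bin/env Rscript
# Thin command-line wrapper over the chromarch R API.
#
#   chromarch simulate --outdir DIR [--seed N] [--config sim.yaml]
#   chromarch pipeline --outdir DIR [--seed N] [--config sim.yaml]
#
# A YAML config, if given, holds overrides for sim_config() fields.

suppressPackageStartupMessages({
  library(optparse)
  library(chromarch)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !args[1] %in% c("simulate", "pipeline")) {
  cat("usage: chromarch <simulate|pipeline> --outdir DIR [--seed N] [--config sim.yaml]\n")
  quit(status = 2)
}
cmd <- args[1]
opts <- parse_args(OptionParser(option_list = list(
  make_option("--outdir", type = "character"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--config", type = "character", default = NULL)
)), args = args[-1])
if (is.null(opts$outdir)) {
  cat("error: --outdir is required\n")
  quit(status = 2)
}

overrides <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
overrides$seed <- opts$seed
cfg <- tryCatch(do.call(sim_config, overrides), error = function(e) {
  cat("input error:", conditionMessage(e), "\n")
  quit(status = 2)
})

status <- tryCatch({
  if (cmd == "simulate") {
    truth <- make_genome(cfg)
    dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)
    write_genes(truth$genes, file.path(opts$outdir, "genes.tsv"))
    for (cond in c("control", "treatment")) {
      write_contacts(simulate_contacts(truth, cfg, cond),
                     file.path(opts$outdir, sprintf("contacts_%s.tsv", cond)))
      tk <- simulate_tracks(truth, cfg, cond)
      for (mark in names(tk$peaks)) {
        write_bed(tk$peaks[[mark]],
                  file.path(opts$outdir, sprintf("peaks_%s_%s.bed", mark, cond)))
        write_bedgraph(tk$tracks[[mark]],
                       file.path(opts$outdir, sprintf("track_%s_%s.bedgraph",
                                                      mark, cond)))
      }
      write_bedgraph(tk$tracks$methylation,
                     file.path(opts$outdir,
                               sprintf("track_methylation_%s.bedgraph", cond)))
    }
    write_expression(simulate_expression(truth, cfg),
                     file.path(opts$outdir, "expression.tsv"))
  } else {
    run_pipeline(cfg, opts$outdir)
  }
  0
}, error = function(e) {
  cat("stage failure:", conditionMessage(e), "\n")
  3
})
quit(status = status)
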