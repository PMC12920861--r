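#!/usr/bin/env Rscript
# Thin command-line wrapper over the vfpose package:
#   vfpose synth  --out DIR [--patients N] [--size PX] [--seed S] [--force]
#   vfpose run    --data DIR --out DIR [--methods a,b,c] [--k K] [--width W]
#                 [--input PX] [--epochs E] [--seed S]
#   vfpose tables
#   vfpose report

suppressMessages({
  library(optparse)
  library(vfpose)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args)) args[[1]] else ""
rest <- args[-1]

usage <- function() {
  cat("usage: vfpose <synth|run|tables|report> [options]\n")
  quit(status = 2)
}

if (cmd == "synth") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character"),
    make_option("--patients", type = "integer", default = 124L),
    make_option("--size", type = "integer", default = 640L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--force", action = "store_true", default = FALSE))),
    args = rest)
  if (is.null(o$out)) usage()
  cfg <- synth_config(n_patients = o$patients, width = o$size,
                      height = round(o$size * 0.75), seed = o$seed)
  ds <- generate_dataset(cfg, dir = o$out, force = o$force)
  cat(sprintf("wrote %d frames from %d patients to %s\n",
              length(ds$records), o$patients, o$out))
} else if (cmd == "run") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--data", type = "character"),
    make_option("--out", type = "character"),
    make_option("--methods", type = "character",
                default = "heatmap,direct,segmentation"),
    make_option("--k", type = "integer", default = 5L),
    make_option("--width", type = "double", default = 1.0),
    make_option("--input", type = "integer", default = 224L),
    make_option("--epochs", type = "integer", default = 200L),
    make_option("--patience", type = "integer", default = 10L),
    make_option("--seed", type = "integer", default = 1L))),
    args = rest)
  if (is.null(o$data) || is.null(o$out)) usage()
  records <- load_dataset(o$data, file.path(o$data, "annotations.json"))
  exp <- run_experiment(records,
                        methods = strsplit(o$methods, ",")[[1]],
                        k = o$k,
                        config = model_config("heatmap", o$input, o$width),
                        control = train_config(max_epochs = o$epochs,
                                               patience = o$patience,
                                               seed = o$seed),
                        seed = o$seed, out_dir = o$out, verbose = TRUE)
  print(exp)
  quit(status = if (length(exp$failures)) 1 else 0)
} else if (cmd == "tables" || cmd == "report") {
  v <- report_reference()
  quit(status = if (isTRUE(attr(v, "all_pass"))) 0 else 1)
} else usage()
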