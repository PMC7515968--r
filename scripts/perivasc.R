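#!/usr/bin/env Rscript
# Thin command-line front end over the perivasc package.
#
# Usage:
#   Rscript scripts/perivasc.R <subcommand> [options]
#
# Subcommands:
#   simulate     --config cfg.yaml --out DIR [--seed N]
#   classify     --stack DIR --out results.csv [--rule zscore] [--z 3]
#   metrics      --results results.csv --annotations ann.csv --out DIR
#   morphometry  --mask mask.tif --pixel-size UM
#   stats        --table animal_summaries.csv --value COLUMN
#   run          --config cfg.yaml --out DIR [--seed N] [--log-level info]
#   demo         --out DIR [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(perivasc)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) {
  cat("usage: perivasc.R <simulate|classify|metrics|morphometry|stats|run|demo> [options]\n")
  quit(status = 2)
}
cmd <- args[1]
rest <- args[-1]

opt_list <- list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "perivasc_out"),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--stack", type = "character", default = NULL),
  make_option("--annotations", type = "character", default = NULL),
  make_option("--results", type = "character", default = NULL),
  make_option("--mask", type = "character", default = NULL),
  make_option("--pixel-size", type = "double", default = NULL,
              dest = "pixel_size"),
  make_option("--table", type = "character", default = NULL),
  make_option("--value", type = "character",
              default = "mean_positive_fraction_pct"),
  make_option("--rule", type = "character", default = "zscore"),
  make_option("--z", type = "double", default = 3),
  make_option("--log-level", type = "character", default = "info",
              dest = "log_level"))
opt <- parse_args(OptionParser(option_list = opt_list), args = rest)

status <- tryCatch({
  switch(cmd,
    simulate = {
      cfg <- yaml::read_yaml(opt$config)
      if (!is.null(cfg$simulate)) cfg <- cfg$simulate
      sim <- do.call(sim_config, cfg)
      if (!is.null(opt$seed)) sim$seed <- opt$seed
      generate_dataset(sim, opt$out)
      message("dataset written to ", opt$out)
      0
    },
    classify = {
      ds <- read_dataset(opt$stack)
      rule <- classification_rule(mode = opt$rule, z_threshold = opt$z)
      out <- do.call(rbind, lapply(ds$frames, analyze_frame,
                                   vessels = ds$vessels, rule = rule))
      write.csv(out, opt$out, row.names = FALSE)
      message("classifications written to ", opt$out)
      0
    },
    metrics = {
      sides <- read.csv(opt$results)
      ann <- read.csv(opt$annotations)
      dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
      fs <- do.call(rbind, lapply(split(sides, sides$frame_t), function(s) {
        calls <- vessel_calls(s)
        frame_summary(calls)
      }))
      write.csv(time_course(fs), file.path(opt$out, "frame_summaries.csv"),
                row.names = FALSE)
      calls <- vessel_calls(sides[sides$frame_t == fs$t_min[which.max(fs$positive_fraction_pct)], ])
      calls$distance_to_source_um <-
        ann$distance_to_source_um[match(calls$vessel_id, ann$id)]
      write.csv(distance_strata(calls),
                file.path(opt$out, "distance_strata.csv"), row.names = FALSE)
      message("metrics written to ", opt$out)
      0
    },
    morphometry = {
      mask <- read_wall_mask(opt$mask, opt$pixel_size)
      comp <- wall_composition(mask)
      print(comp)
      bm <- bm_thickness(mask)
      cat(sprintf("abluminal basement-membrane thickness (max): %s um\n",
                  if (is.na(bm)) paste0("NA (", attr(bm, "reason"), ")")
                  else sprintf("%.3f", bm)))
      0
    },
    stats = {
      tab <- read.csv(opt$table)
      grs <- sort(unique(na.omit(tab$group)))
      if (length(grs) != 2) stop("need exactly two groups, found ",
                                 length(grs))
      v <- split(tab[[opt$value]], tab$group)
      print(two_group_test(v[[grs[1]]], v[[grs[2]]], labels = grs))
      0
    },
    run = {
      run_pipeline(opt$config, opt$out, seed = opt$seed,
                   log_level = opt$log_level)
      0
    },
    demo = {
      cfg <- system.file("extdata", "demo_config.yaml", package = "perivasc")
      run_pipeline(cfg, opt$out, seed = opt$seed)
      0
    },
    { cat("unknown subcommand: ", cmd, "\n"); 2 })
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1
})
quit(status = status)
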