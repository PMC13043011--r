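#!/usr/bin/env Rscript

## Thin command-line wrapper over the CheckinBiomarkers pipeline.
##
##   Rscript scripts/pipeline.R simulate  --n 8 --sessions 3 --seed 1 --out dir
##   Rscript scripts/pipeline.R extract   --bundles dir --out dir [--config cfg.yaml]
##   Rscript scripts/pipeline.R correlate --features f.csv --scores s.csv \
##                                        --alpha 0.05 [--bh] --out dir
##   Rscript scripts/pipeline.R riskscore --features f.csv --scores s.csv \
##                                        --correlations c.csv --measure fatigue --out dir
##   Rscript scripts/pipeline.R run       --n 8 --sessions 3 --seed 1 --out dir
##
## Exit codes: 0 ok, 2 usage/validation error, 1 runtime failure.

suppressPackageStartupMessages({
  library(optparse)
  library(CheckinBiomarkers)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args) || !args[1] %in%
      c("simulate", "extract", "correlate", "riskscore", "run")) {
  message("usage: pipeline.R <simulate|extract|correlate|riskscore|run> [options]")
  quit(status = 2)
}
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--n", type = "integer", default = 8L),
  make_option("--sessions", type = "integer", default = 3L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL),
  make_option("--bundles", type = "character", default = NULL),
  make_option("--features", type = "character", default = NULL),
  make_option("--scores", type = "character", default = NULL),
  make_option("--correlations", type = "character", default = NULL),
  make_option("--measure", type = "character", default = "fatigue"),
  make_option("--alpha", type = "double", default = 0.05),
  make_option("--bh", action = "store_true", default = FALSE),
  make_option("--out", type = "character", default = "pipeline_out")))
opt <- parse_args(parser, args = args[-1])

need <- function(x, flag) {
  if (is.null(x)) { message("missing required option ", flag); quit(status = 2) }
  x
}
cfg <- loadConfig(opt$config)

result <- tryCatch(switch(cmd,
  simulate = {
    cc <- cohortConfig(nParticipants = opt$n,
                       sessionsPerParticipant = opt$sessions,
                       seed = opt$seed)
    sim <- simulateCohort(cc, outDir = opt$out)
    message("wrote ", length(sim$sessions), " session bundles to ", opt$out)
  },
  extract = {
    se <- extractCohort(need(opt$bundles, "--bundles"), cfg)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    writeFeatureCSV(se, file.path(opt$out, "features.csv"),
                    file.path(opt$out, "scores.csv"))
    message("extracted ", ncol(se), " sessions -> ", opt$out)
  },
  correlate = {
    se <- readFeatureCSV(need(opt$features, "--features"),
                         need(opt$scores, "--scores"))
    res <- correlateAll(selectBaseline(se), alpha = opt$alpha, bh = opt$bh)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$results, file.path(opt$out, "correlations.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(res$table),
              file.path(opt$out, "significance_table.csv"))
    message(sum(res$results$significant), " significant feature-measure pairs")
  },
  riskscore = {
    se <- readFeatureCSV(need(opt$features, "--features"),
                         need(opt$scores, "--scores"))
    corr <- read.csv(need(opt$correlations, "--correlations"))
    risk <- compositeRisk(se, corr, opt$measure)
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    write.csv(risk, file.path(opt$out, paste0("risk_", opt$measure, ".csv")),
              row.names = FALSE)
    message("risk series for ", length(unique(risk$participant_id)),
            " participants")
  },
  run = {
    cc <- cohortConfig(nParticipants = opt$n,
                       sessionsPerParticipant = opt$sessions,
                       seed = opt$seed)
    runPipeline(opt$out, cohort = cc, bundleDir = opt$bundles, config = cfg,
                alpha = opt$alpha)
  }),
  error = function(e) { message("error: ", conditionMessage(e)); quit(status = 1) })
invisible(result)
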