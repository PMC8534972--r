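#!/usr/bin/env Rscript
# Thin command-line front end over the angioflow package.
#
#   Rscript scripts/angioflow.R simulate --shape loop --flow 600 --rate 6 \
#       --modality dsa --seed 42 --out phantom.afs
#   Rscript scripts/angioflow.R measure --input phantom.afs \
#       --roi1 180,191,74,85 --roi2 760,771,74,85 --algorithm cc --fit gv \
#       --threshold 0.12 --spacing 25 --out result.json
#   Rscript scripts/angioflow.R evaluate --config grid.cfg --out results.csv
#
# The evaluate config file is flat key = value, e.g.:
#   shapes = straight            modalities = DSA
#   rates = 3,6                  algorithms = cc,pp
#   fits = gamma_variate,none    n_reps = 20
#   seed = 1

suppressPackageStartupMessages(library(angioflow))

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: angioflow.R <simulate|measure|evaluate> [options]")
cmd <- args[1]
args <- args[-1]

getopt <- function(flag, default = NULL) {
  i <- match(paste0("--", flag), args)
  if (is.na(i)) return(default)
  args[i + 1L]
}

fit_alias <- c(gv = "gamma_variate", ln = "lagged_normal",
               poly = "polynomial", none = "none")
canon_fit <- function(x) {
  if (x %in% names(fit_alias)) fit_alias[[x]] else x
}

if (cmd == "simulate") {
  cfg <- phantom_config(
    tube_shape = getopt("shape", "straight"),
    true_flow_ml_min = as.numeric(getopt("flow", 600)),
    sampling_rate_per_s = as.numeric(getopt("rate", 6)),
    modality = toupper(getopt("modality", "dsa")),
    seed = as.integer(getopt("seed", 1)))
  out <- getopt("out", "phantom.afs")
  ph <- render_sequence(cfg)
  write_sequence(ph$sequence, out)
  truth_file <- sub("\\.[a-z]+$", "_truth.json", out)
  rois <- default_rois(ph$truth)
  jsonlite::write_json(
    list(true_flow_ml_min = ph$truth$true_flow_ml_min,
         arc_length_cm = ph$truth$arc_length_cm,
         mean_velocity_cm_s = ph$truth$mean_velocity_cm_s,
         true_transit_s = true_transit_s(ph$truth),
         roi_s_cm = ph$truth$roi_s_cm,
         rois = lapply(rois, unclass)),
    truth_file, auto_unbox = TRUE, digits = NA)
  cat("wrote", out, "and", truth_file, "\n")
} else if (cmd == "measure") {
  input <- getopt("input")
  if (is.null(input)) stop("measure needs --input")
  ov <- list()
  if (!is.null(getopt("dt"))) ov$frame_interval_s <- as.numeric(getopt("dt"))
  if (!is.null(getopt("pixel-cm")))
    ov$pixel_spacing_cm <- as.numeric(getopt("pixel-cm"))
  seq <- read_sequence(input, overrides = ov)
  parse_roi <- function(s, label) {
    v <- as.integer(strsplit(s, ",")[[1]])
    if (length(v) != 4) stop("ROI must be r0,r1,c0,c1")
    roi(v[1], v[2], v[3], v[4], label)
  }
  res <- measure_flow(
    seq,
    parse_roi(getopt("roi1"), "ROI1"),
    parse_roi(getopt("roi2"), "ROI2"),
    algorithm = tolower(getopt("algorithm", "cc")),
    fit_model = canon_fit(tolower(getopt("fit", "gv"))),
    config = list(threshold_frac = as.numeric(getopt("threshold", 0.12)),
                  spacing_px = as.numeric(getopt("spacing", 25)),
                  upsample = as.integer(getopt("upsample", 100))))
  print(res)
  out <- getopt("out")
  if (!is.null(out)) {
    write_flow_result(res, out)
    cat("wrote", out, "\n")
  }
} else if (cmd == "evaluate") {
  cfgf <- getopt("config")
  if (is.null(cfgf)) stop("evaluate needs --config")
  cfg <- read_config(cfgf)
  splitc <- function(x) trimws(strsplit(as.character(x), ",")[[1]])
  conditions <- expand.grid(shape = splitc(cfg$shapes %||% "straight"),
                            modality = toupper(splitc(cfg$modalities %||% "DSA")),
                            sampling_rate = as.numeric(splitc(cfg$rates %||% "6")),
                            stringsAsFactors = FALSE)
  methods <- expand.grid(algorithm = splitc(cfg$algorithms %||% "cc"),
                         fit_model = vapply(splitc(cfg$fits %||% "gamma_variate"),
                                            canon_fit, character(1)),
                         stringsAsFactors = FALSE)
  res <- run_benchmark(conditions, methods,
                       n_reps = as.integer(cfg$n_reps %||% 20),
                       seed = as.integer(cfg$seed %||% 1))
  out <- getopt("out", "benchmark.csv")
  write.csv(res, out, row.names = FALSE)
  summ <- summarize_benchmark(res)
  print(summ)
  jsonlite::write_json(summ, sub("\\.csv$", "_summary.json", out),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  cat("wrote", out, "\n")
} else {
  stop("unknown subcommand: ", cmd)
}
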