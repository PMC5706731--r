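#!/usr/bin/env Rscript
# Command-line front end for the olfactory-bulb gamma simulator.
#
#   obgamma list-scenarios
#   obgamma run --scenario control [--seeds 1:5] [--quick] [--out DIR]
#               [--set key=value ...]
#   obgamma sweep --param tau_decay_gaba --values 3,9,15,18,24,30
#               [--scenario control] [--seeds 1:5] [--out DIR]
#   obgamma analyze --recording DIR
#   obgamma surrogate [--freq 32.4] [--concentration 4] [--out DIR]

suppressPackageStartupMessages(library(obgamma))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  stop("usage: obgamma <list-scenarios|run|sweep|analyze|surrogate> [options]")
}
verb <- args[1]
args <- args[-1]

opt <- list(scenario = "control", seeds = NULL, quick = TRUE, out = NULL,
            param = NULL, values = NULL, recording = NULL,
            freq = 32.4, concentration = 4, set = list())
i <- 1
while (i <= length(args)) {
  a <- args[i]
  get_val <- function() { i <<- i + 1; args[i] }
  switch(a,
    "--scenario" = { opt$scenario <- get_val() },
    "--seeds" = { opt$seeds <- eval(parse(text = get_val())) },
    "--quick" = { opt$quick <- TRUE },
    "--full" = { opt$quick <- FALSE },
    "--out" = { opt$out <- get_val() },
    "--param" = { opt$param <- get_val() },
    "--values" = { opt$values <- as.numeric(strsplit(get_val(), ",")[[1]]) },
    "--recording" = { opt$recording <- get_val() },
    "--freq" = { opt$freq <- as.numeric(get_val()) },
    "--concentration" = { opt$concentration <- as.numeric(get_val()) },
    "--set" = {
      kv <- strsplit(get_val(), "=")[[1]]
      val <- suppressWarnings(as.numeric(kv[2]))
      opt$set[[kv[1]]] <- if (is.na(val)) kv[2] else val
    },
    stop("unknown option: ", a))
  i <- i + 1
}

if (verb == "list-scenarios") {
  reg <- scenario_registry()
  for (nm in names(reg)) cat(sprintf("%-18s %s\n", nm, reg[[nm]]$description))
} else if (verb == "run") {
  res <- run_scenario(opt$scenario, overrides = opt$set, seeds = opt$seeds,
                      quick = opt$quick, out_dir = opt$out)
  print(res)
} else if (verb == "sweep") {
  if (is.null(opt$param) || is.null(opt$values)) {
    stop("sweep needs --param and --values")
  }
  tab <- sweep_parameter(opt$param, opt$values, name = opt$scenario,
                         seeds = opt$seeds, quick = opt$quick)
  print(tab, row.names = FALSE)
  if (!is.null(opt$out)) {
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(opt$out, paste0("sweep_", opt$param, ".csv")),
                     row.names = FALSE)
  }
} else if (verb == "analyze") {
  if (is.null(opt$recording)) stop("analyze needs --recording DIR")
  rec <- read_recording(opt$recording)
  win <- c(0, max(rec$t_ms))
  print(analyze_recording(rec, window_ms = win), row.names = FALSE)
} else if (verb == "surrogate") {
  spec <- surrogate_spec(freq_hz = opt$freq,
                         concentration = opt$concentration)
  rec <- make_surrogate_recording(spec)
  print(analyze_recording(rec, window_ms = c(0, spec$duration_ms)),
        row.names = FALSE)
  if (!is.null(opt$out)) write_recording(rec, opt$out)
} else {
  stop("unknown verb: ", verb)
}
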