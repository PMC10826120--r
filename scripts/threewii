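#!/usr/bin/env Rscript

# Thin command-line wrapper over the threewii package.
#
#   Rscript scripts/threewii simulate --cases 500 --controls 500 --snps 50 \
#       [--triplet base,effect] [--seed 1] --out prefix
#   Rscript scripts/threewii assoc --bfile prefix [--alpha 0.01] --out file.tsv
#   Rscript scripts/threewii run --bfile prefix [--seed 1] [--skip-assoc] \
#       [--n-perm 1000] --out dir

suppressMessages(library(threewii))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: threewii <simulate|assoc|run> [options]")
cmd <- args[1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
has_flag <- function(flag) flag %in% args

if (cmd == "simulate") {
  triplets <- list()
  tr <- opt("--triplet")
  if (!is.null(tr)) {
    be <- as.numeric(strsplit(tr, ",")[[1]])
    triplets <- list(make_parity_penetrance(base = be[1], effect = be[2]))
  }
  spec <- simulation_spec(
    n_cases = as.integer(opt("--cases", "500")),
    n_controls = as.integer(opt("--controls", "500")),
    n_background_snps = as.integer(opt("--snps", "50")),
    planted_triplets = triplets,
    baseline_prevalence = as.numeric(opt("--prevalence", "0.1")),
    missing_rate = as.numeric(opt("--missing", "0")),
    seed = as.integer(opt("--seed", "1"))
  )
  co <- simulate_cohort(spec)
  prefix <- opt("--out", "cohort")
  write_plink(co, prefix)
  jsonlite::write_json(planted_truth(co), paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE)
  cat("wrote", paste0(prefix, ".bed/.bim/.fam"), "and truth sidecar\n")
} else if (cmd == "assoc") {
  co <- read_plink(opt("--bfile"))
  res <- allelic_assoc(co)
  alpha <- as.numeric(opt("--alpha", "0.01"))
  out <- opt("--out", "assoc.tsv")
  write_assoc_tsv(res, out)
  cat(length(filter_by_p(res, alpha)), "of", nrow(res),
      "SNPs pass p <", alpha, "; table written to", out, "\n")
} else if (cmd == "run") {
  seed <- as.integer(opt("--seed", "1"))
  r <- run_pipeline(
    opt("--bfile"),
    assoc_alpha = if (has_flag("--skip-assoc")) NULL
                  else as.numeric(opt("--alpha", "0.01")),
    rf = rf_config(seed = seed),
    triplets = pipeline_config(n_perm = as.integer(opt("--n-perm", "1000")),
                               seed = seed),
    out_dir = opt("--out", "threewii_out")
  )
  print(r)
} else {
  stop("unknown subcommand: ", cmd)
}
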