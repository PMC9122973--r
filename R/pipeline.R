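# Config-driven, reproducible runs tying the stages together:
# simulate -> count-repeats -> scan -> classify -> synteny -> southern.
# Single plain-text key-value (DCF) config; every random operation is
# seeded from the global seed plus a fixed per-stage offset; all outputs
# carry the config hash.

PIPELINE_STAGES <- c("simulate", "count_repeats", "scan", "classify",
                     "synteny", "southern")

KNOWN_CONFIG_KEYS <- c(
  "seed", "outdir", "stages",
  "array.vector_len", "array.flank_left_len", "array.flank_right_len",
  "array.unit_len", "array.n_units", "array.per_unit_snv_rate",
  "reads.n_reads", "reads.mean_len", "reads.sd_len", "reads.sub_rate",
  "reads.ins_rate", "reads.del_rate", "reads.min_len",
  "repeat.k", "repeat.window", "repeat.mode", "repeat.bootstrap",
  "scan.seed_len", "scan.min_len", "scan.min_identity",
  "scan.scaffold_identity", "scan.cds_model",
  "southern.enzyme", "southern.min_identity", "southern.min_span",
  "southern.gel_merge_tol", "southern.min_size")

STAGE_SEED_OFFSET <- c(simulate = 11L, count_repeats = 23L, scan = 37L,
                       classify = 41L, synteny = 53L, southern = 67L)

#' Read and validate a pipeline run configuration
#'
#' Plain-text key-value (DCF) format, e.g. `array.n_units: 12`.  Unknown
#' keys are rejected before any work is done.
#'
#' @param path config file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  raw <- read.dcf(path)
  kv <- stats::setNames(as.list(raw[1, ]), colnames(raw))
  unknown <- setdiff(names(kv), KNOWN_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  }
  num_keys <- setdiff(KNOWN_CONFIG_KEYS,
                      c("outdir", "stages", "repeat.mode",
                        "southern.enzyme", "scan.cds_model"))
  for (k in intersect(names(kv), num_keys)) kv[[k]] <- as.numeric(kv[[k]])
  if (!is.null(kv$stages)) {
    kv$stages <- strsplit(trimws(kv$stages), "\\s+")[[1]]
    bad <- setdiff(kv$stages, PIPELINE_STAGES)
    if (length(bad) > 0L) {
      stop("validation error: unknown stage(s): ", paste(bad, collapse = ", "))
    }
  } else {
    kv$stages <- PIPELINE_STAGES
  }
  kv$seed <- as.integer(kv$seed %||% 1L)
  kv$outdir <- kv$outdir %||% "afptools_run"
  kv$config_path <- path
  kv$config_hash <- unname(tools::md5sum(path))
  class(kv) <- "run_config"
  kv
}

cfg_get <- function(cfg, key, default) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

write_report_tsv <- function(df, path, cfg, stage, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# afptools stage=%s seed=%d config_sha=%s",
                     stage, seed, cfg$config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline described by a config
#'
#' Executes the requested stages in dependency order on the synthetic
#' fixture set; each stage is seeded from the global seed plus a fixed
#' offset, every output carries the config hash, and a log records
#' versions, seeds and parameters.  Any stage error aborts with the stage
#' name and cause.
#'
#' @param cfg a `run_config` or config file path.
#' @param outdir optional override of the config's output directory.
#' @return list of class `run_report`: per-stage outputs and file paths.
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  log_lines <- c(sprintf("afptools %s", as.character(utils::packageVersion("afptools"))),
                 sprintf("R %s", getRversion()),
                 sprintf("config %s sha %s", cfg$config_path, cfg$config_hash),
                 sprintf("seed %d", cfg$seed),
                 sprintf("stages %s", paste(cfg$stages, collapse = " ")))
  report <- list(config = cfg, outputs = list())
  stage_seed <- function(stage) cfg$seed + STAGE_SEED_OFFSET[[stage]]

  run_stage <- function(stage, fun) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", stage,
                                      conditionMessage(e))), logf)
      stop("pipeline aborted at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s ok (%.1fs, seed %d)",
                                       stage,
                                       as.numeric(Sys.time() - t0, units = "secs"),
                                       stage_seed(stage)))
    report$outputs[[stage]] <<- res
  }

  acfg <- array_config(
    vector_len = cfg_get(cfg, "array.vector_len", 7500),
    flank_left_len = cfg_get(cfg, "array.flank_left_len", 6000),
    flank_right_len = cfg_get(cfg, "array.flank_right_len", 6000),
    unit_len = cfg_get(cfg, "array.unit_len", 11200),
    n_units = cfg_get(cfg, "array.n_units", 12),
    per_unit_snv_rate = cfg_get(cfg, "array.per_unit_snv_rate", 5e-4),
    seed = stage_seed("simulate"))

  state <- new.env(parent = emptyenv())

  run_stage("simulate", function() {
    bac <- build_tandem_bac(acfg)
    rcfg <- read_sim_config(
      n_reads = cfg_get(cfg, "reads.n_reads", 1000),
      mean_len = cfg_get(cfg, "reads.mean_len", 8000),
      sd_len = cfg_get(cfg, "reads.sd_len", 4000),
      sub_rate = cfg_get(cfg, "reads.sub_rate", 0.08),
      ins_rate = cfg_get(cfg, "reads.ins_rate", 0.05),
      del_rate = cfg_get(cfg, "reads.del_rate", 0.02),
      min_len = cfg_get(cfg, "reads.min_len", 500),
      seed = stage_seed("simulate") + 1L)
    reads <- simulate_reads(bac, rcfg)
    prov <- build_provenance_pair(
      shared_scaffold_identity = cfg_get(cfg, "scan.scaffold_identity", 0.85),
      cds_model = cfg_get(cfg, "scan.cds_model", "replaced"),
      seed = stage_seed("simulate") + 2L)
    write_fasta(bac$record, file.path(outdir, "bac.fasta"))
    write_gff3(bac, file.path(outdir, "bac.gff3"))
    write_fastq(reads$reads, file.path(outdir, "reads.fastq"))
    state$bac <- bac; state$reads <- reads; state$prov <- prov
    list(bac = bac$record$id, n_reads = length(reads$reads),
         files = c("bac.fasta", "bac.gff3", "reads.fastq"))
  })

  run_stage("count_repeats", function() {
    if (is.null(state$bac)) stop("count_repeats needs the simulate stage")
    ref <- component_reference_from_truth(state$bac)
    counts <- classify_reads(state$reads, ref,
                             k = cfg_get(cfg, "repeat.k", 15),
                             window = cfg_get(cfg, "repeat.window", 500))
    est <- estimate_copy_number(
      counts, ref, mode = cfg_get(cfg, "repeat.mode", "bases"),
      B = cfg_get(cfg, "repeat.bootstrap", 1000),
      seed = stage_seed("count_repeats"))
    df <- data.frame(n_hat = est$n_hat, se = est$se,
                     ci_low = est$ci95[1], ci_high = est$ci95[2],
                     se_poisson = est$se_poisson, mode = est$mode,
                     n_reads = est$n_reads_used)
    write_report_tsv(df, file.path(outdir, "repeat_estimate.tsv"), cfg,
                     "count_repeats", stage_seed("count_repeats"))
    write_report_tsv(est$category_table,
                     file.path(outdir, "read_categories.tsv"), cfg,
                     "count_repeats", stage_seed("count_repeats"))
    est
  })

  run_stage("scan", function() {
    if (is.null(state$prov)) stop("scan needs the simulate stage")
    blocks <- local_blocks(state$prov$locus_a, state$prov$locus_b,
                           seed_len = cfg_get(cfg, "scan.seed_len", 12),
                           min_len = cfg_get(cfg, "scan.min_len", 100),
                           min_identity = cfg_get(cfg, "scan.min_identity", 0.70))
    ann <- annotate_blocks(blocks, state$prov$locus_a)
    write_report_tsv(as.data.frame(ann$blocks),
                     file.path(outdir, "blocks.tsv"), cfg, "scan",
                     stage_seed("scan"))
    write_report_tsv(ann$summary, file.path(outdir, "contrast.tsv"), cfg,
                     "scan", stage_seed("scan"))
    ann
  })

  run_stage("classify", function() {
    if (is.null(state$bac)) stop("classify needs the simulate stage")
    census <- census_locus(state$bac)
    write_report_tsv(census$calls, file.path(outdir, "census.tsv"), cfg,
                     "classify", stage_seed("classify"))
    census
  })

  run_stage("synteny", function() {
    orders <- demo_gene_orders()
    tab <- synteny_table(orders)
    write_synteny_tsv(tab, file.path(outdir, "synteny.tsv"))
    rows <- attr(tab, "rows")
    rel <- relocation_call(rows[[1]], rows[[2]])
    write_report_tsv(data.frame(a = rel$species_pair[1],
                                b = rel$species_pair[2],
                                verdict = rel$verdict),
                     file.path(outdir, "relocation.tsv"), cfg, "synteny",
                     stage_seed("synteny"))
    list(table = tab, relocation = rel)
  })

  run_stage("southern", function() {
    if (is.null(state$bac)) stop("southern needs the simulate stage")
    enz <- get_enzyme(cfg_get(cfg, "southern.enzyme", "DraI"))
    d <- digest(state$bac$record, enz)
    pf <- state$bac$features[state$bac$features$kind == "probe", ,
                             drop = FALSE]
    if (nrow(pf) == 0L) stop("locus has no probe feature")
    probe <- extract_feature_seq(state$bac, pf[1, , drop = FALSE])
    bands <- probe_bands(
      d, state$bac$record, probe,
      min_identity = cfg_get(cfg, "southern.min_identity", 0.80),
      min_span = cfg_get(cfg, "southern.min_span", 50),
      gel_merge_tol = cfg_get(cfg, "southern.gel_merge_tol", 0.05),
      min_size = cfg_get(cfg, "southern.min_size", 200))
    write_report_tsv(as.data.frame(bands), file.path(outdir, "bands.tsv"),
                     cfg, "southern", stage_seed("southern"))
    bands
  })

  writeLines(log_lines, logf)
  report$log <- logf
  class(report) <- "run_report"
  report
}

# Gig2 gene orders of selected flatfishes and relatives (focal family
# flanks as reported for these species)
demo_gene_orders <- function() {
  list(
    gene_order("starry_flounder", c("MTX2", "Gig2", "Gig2", "Gig2", "Gig2",
                                    "Gig2", "CADH5")),
    gene_order("pacific_halibut", c("HDAC5", "ZG57", "Gig2", "Gig2",
                                    "XYLT1")),
    gene_order("greenland_halibut", c("HDAC5", "ZG57", "Gig2", "Gig2",
                                      "Gig2", "XYLT1")),
    gene_order("spotted_halibut", c("HDAC5", "ZG57", "Gig2", "Gig2",
                                    "XYLT1")),
    gene_order("olive_flounder", c("HDAC5", "ZG57", "Gig2", "XYLT1")),
    gene_order("turbot", c("RAB40C", "ZG57", "Gig2", "Gig2", "Gig2",
                           "Gig2", "Gig2", "UNK93")),
    gene_order("barramundi", c("RAB40C", "ZG57", "Gig2", "Gig2", "Gig2",
                               "XYLT1")),
    gene_order("yellow_perch", c("RAB40C", "ZG57", "Gig2", "Gig2",
                                 "XYLT1")))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `count-repeats`, `scan`, `classify`,
#' `synteny`, `southern`, `run-all`.  Each maps to [run_pipeline()] with
#' the corresponding stage list; `--config FILE` supplies parameters,
#' `--seed` and `--out` override the config.
#'
#' @param args character vector (defaults to the command line).
#' @return exit status, invisibly.
#' @export
afp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: afptools <simulate|count-repeats|scan|classify|synteny|",
    "southern|run-all> [--config FILE] [--seed N] [--out DIR]", sep = "")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opts <- list(config = NULL, seed = NULL, out = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("bad argument: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  stage_map <- c("simulate" = "simulate", "count-repeats" = "count_repeats",
                 "scan" = "scan", "classify" = "classify",
                 "synteny" = "synteny", "southern" = "southern")
  if (!(sub %in% c(names(stage_map), "run-all"))) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(1L))
  }
  cfg <- if (!is.null(opts$config)) read_run_config(opts$config)
         else read_run_config(system.file("extdata", "demo_config.dcf",
                                          package = "afptools"))
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) cfg$outdir <- opts$out
  if (sub != "run-all") {
    want <- stage_map[[sub]]
    # honour stage dependencies: everything but simulate needs simulate
    cfg$stages <- unique(c(if (want != "simulate") "simulate", want))
  }
  run_pipeline(cfg)
  invisible(0L)
}
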