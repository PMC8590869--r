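# End-to-end pipeline: simulate -> label -> featurize -> sample -> train ->
# predict -> evaluate, with a YAML run configuration, a manifest recording
# seeds, hashes, row counts and timings, and artifact-level resumability.

#' Default run configuration
#'
#' Stage blocks mirror the pipeline stages; all times are hours since ICU
#' admission and all volumes are cc. Model defaults are 200 boosting rounds
#' at learning rate 0.1.
#'
#' @param seed global seed; stage seeds derive from it.
#' @param out_dir artifact directory.
#' @return nested config list (YAML-serializable).
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("hsi_run_")) {
  list(
    schema_version = 1L,
    seed = as.integer(seed),
    out_dir = out_dir,
    generator = list(n_stays = 500L, unstable_fraction = 0.18),
    sampler = list(lead = 1, test_fraction = 0.2),
    model = list(n_rounds = 200L, learning_rate = 0.1, max_bins = 256L),
    uncertainty = list(n_bootstrap = 20L, n_feature_draws = 20L, z = 1.96),
    evaluation = list(modes = hsi_modes(), leads = c(1L, 6L, 12L))
  )
}

#' @rdname default_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(base, cfg)
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @param config config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

validate_config <- function(config) {
  if (config$model$learning_rate <= 0) stop("learning_rate must be > 0")
  if (config$model$n_rounds < 1) stop("n_rounds must be >= 1")
  if (config$generator$unstable_fraction < 0 ||
      config$generator$unstable_fraction > 1) {
    stop("unstable_fraction must lie in [0, 1]")
  }
  if (config$sampler$lead <= 0) stop("lead must be > 0")
  invisible(config)
}

config_hash <- function(config) {
  content_hash(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                             digits = NA)))
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes all artifacts plus
#' \code{manifest.json} under \code{config$out_dir}. With
#' \code{resume = TRUE}, stages whose artifacts already exist are skipped, so
#' deleting a downstream artifact and re-running resumes without
#' re-simulating. Re-running with an identical config reproduces identical
#' artifacts.
#'
#' @param config from [default_config()] or [read_config()].
#' @param resume skip stages whose outputs already exist.
#' @return invisible manifest list.
#' @export
run_pipeline <- function(config = default_config(), resume = FALSE) {
  validate_config(config)
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  registry <- hsi_registry()
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  log_path <- file.path(dir, "run.log")
  logline <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, outputs, fun) {
    paths <- file.path(dir, outputs)
    if (resume && all(file.exists(paths))) {
      logline("stage ", name, ": artifacts present, skipped")
      manifest$stages[[name]] <<- list(skipped = TRUE)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2),
      artifacts = as.list(stats::setNames(
        vapply(paths, function(p) if (file.exists(p)) nrow_artifact(p) else NA_integer_,
               integer(1)), outputs)))
    logline("stage ", name, ": done")
    invisible(res)
  }

  stage("simulate", c("stays.csv", "observations.csv", "treatments.csv"),
        function() {
    cohort <- generate_cohort(generator_config(
      n_stays = config$generator$n_stays,
      unstable_fraction = config$generator$unstable_fraction,
      seed = config$seed))
    write_cohort(cohort, dir)
  })

  stage("label", "segments.csv", function() {
    cohort <- read_cohort(dir)
    segs <- label_cohort(cohort$treatments)
    data.table::fwrite(segs, file.path(dir, "segments.csv"))
  })

  stage("sample", c("samples.csv", "split.json"), function() {
    cohort <- read_cohort(dir)
    segs <- data.table::fread(file.path(dir, "segments.csv"),
                              colClasses = list(character = c("stay_id", "criteria")))
    # provisional stats from all stays just to test snapshot validity
    stats0 <- population_stats(cohort$observations, registry)
    smp <- draw_samples(cohort$stays, segs, cohort$observations, stats0,
                        lead = config$sampler$lead, seed = config$seed,
                        registry = registry)
    split <- split_patients(smp, config$sampler$test_fraction,
                            seed = config$seed)
    data.table::fwrite(smp, file.path(dir, "samples.csv"))
    jsonlite::write_json(split, file.path(dir, "split.json"))
  })

  stage("featurize", c("features.csv", "stats.json"), function() {
    cohort <- read_cohort(dir)
    smp <- data.table::fread(file.path(dir, "samples.csv"),
                             colClasses = list(character = "stay_id"))
    split <- data.table::as.data.table(
      jsonlite::read_json(file.path(dir, "split.json"), simplifyVector = TRUE))
    train_ids <- split$stay_id[split$split == "train"]
    stats <- population_stats(
      cohort$observations[cohort$observations$stay_id %in% train_ids, ],
      registry)
    write_stats(stats, file.path(dir, "stats.json"))
    fv <- build_features(cohort$observations, smp[, .(stay_id, time)], stats,
                         registry, mode = "all")
    data.table::fwrite(fv, file.path(dir, "features.csv"))
  })

  stage("train", "model.json", function() {
    fv <- data.table::fread(file.path(dir, "features.csv"),
                            colClasses = list(character = "stay_id"))
    smp <- data.table::fread(file.path(dir, "samples.csv"),
                             colClasses = list(character = "stay_id"))
    split <- data.table::as.data.table(
      jsonlite::read_json(file.path(dir, "split.json"), simplifyVector = TRUE))
    train_ids <- split$stay_id[split$split == "train"]
    tr <- which(smp$stay_id %in% train_ids & fv$valid)
    # last 20% of training stays (seeded, patient-disjoint) held for Platt
    set.seed(config$seed + 1L)
    cal_ids <- sample(unique(smp$stay_id[tr]),
                      max(2L, round(0.2 * length(unique(smp$stay_id[tr])))))
    boost <- tr[!smp$stay_id[tr] %in% cal_ids]
    cal <- tr[smp$stay_id[tr] %in% cal_ids]
    ens <- fit_hsi(fv[boost], smp$label[boost],
                   n_rounds = config$model$n_rounds,
                   learning_rate = config$model$learning_rate,
                   max_bins = config$model$max_bins, registry = registry)
    ens <- calibrate_hsi(ens, fv[cal], smp$label[cal])
    save_model(ens, file.path(dir, "model.json"))
  })

  stage("predict", "predictions.csv", function() {
    ens <- load_model(file.path(dir, "model.json"), registry)
    fv <- data.table::fread(file.path(dir, "features.csv"),
                            colClasses = list(character = "stay_id"))
    keep <- which(fv$valid)
    sc <- hsi_score(ens, fv[keep])
    out <- cbind(fv[keep, .(stay_id, time)], sc)
    data.table::fwrite(out, file.path(dir, "predictions.csv"))
  })

  stage("evaluate", "report.json", function() {
    ens <- load_model(file.path(dir, "model.json"), registry)
    cohort <- read_cohort(dir)
    smp <- data.table::fread(file.path(dir, "samples.csv"),
                             colClasses = list(character = "stay_id"))
    split <- data.table::as.data.table(
      jsonlite::read_json(file.path(dir, "split.json"), simplifyVector = TRUE))
    stats <- read_stats(file.path(dir, "stats.json"))
    test_ids <- split$stay_id[split$split == "test"]
    te <- smp[stay_id %in% test_ids]
    obs_te <- cohort$observations[cohort$observations$stay_id %in% test_ids, ]
    modes <- evaluate_modes(ens, obs_te, te, stats,
                            modes = config$evaluation$modes)
    fv <- build_features(obs_te, te[, .(stay_id, time)], stats, registry,
                         mode = "all")
    keep <- fv$valid
    sc <- hsi_score(ens, fv[keep])
    subgroups <- evaluate_subgroups(
      sc$raw_score, te$label[keep],
      as.data.frame(te[keep, .(unit_type, admission_source, ventilated)]))
    report <- list(modes = modes, subgroups = subgroups)
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

nrow_artifact <- function(path) {
  if (grepl("\\.csv$", path)) {
    nrow(data.table::fread(path))
  } else {
    NA_integer_
  }
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate}, \code{label}, \code{run}. \code{run}
#' executes the whole pipeline from a YAML config (or defaults).
#'
#' @param args character vector of CLI arguments (defaults to the process
#'   arguments, so \code{Rscript -e 'hsindex::hsi_cli()' run ...} works).
#' @return exit status, invisibly.
#' @export
hsi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: hsi <simulate|label|run> [options]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  parse <- function(opts) {
    optparse::parse_args(optparse::OptionParser(option_list = opts),
                         args = rest)
  }
  if (cmd == "simulate") {
    o <- parse(list(
      optparse::make_option("--n-stays", type = "integer", default = 500L,
                            dest = "n_stays"),
      optparse::make_option("--unstable-fraction", type = "double",
                            default = 0.18, dest = "unstable_fraction"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "hsi_out")))
    cohort <- generate_cohort(generator_config(
      n_stays = o$n_stays, unstable_fraction = o$unstable_fraction,
      seed = o$seed))
    write_cohort(cohort, o$out)
    message("wrote cohort (", nrow(cohort$stays), " stays) to ", o$out)
  } else if (cmd == "label") {
    o <- parse(list(
      optparse::make_option("--treatments", type = "character"),
      optparse::make_option("--out", type = "character",
                            default = "segments.csv")))
    trt <- data.table::fread(o$treatments,
                             colClasses = list(character = "stay_id"))
    segs <- label_cohort(trt)
    data.table::fwrite(segs, o$out)
    message("wrote ", nrow(segs), " segment(s) to ", o$out)
  } else if (cmd == "run") {
    o <- parse(list(
      optparse::make_option("--config", type = "character", default = NA),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "hsi_run")))
    cfg <- if (!is.na(o$config)) read_config(o$config) else default_config()
    cfg$seed <- o$seed
    cfg$out_dir <- o$out
    run_pipeline(cfg)
    message("pipeline artifacts in ", o$out)
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
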