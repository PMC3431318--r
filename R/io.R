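# Configuration, serialization and the pipeline entry point. All artifacts
# are plain text: CSV (header row, UTF-8) for tables, JSON for manifests and
# summaries, YAML or JSON for configs.

#' Load a run configuration
#'
#' Reads a YAML or JSON config and resolves it into the package's parameter
#' objects. Recognized blocks: `task` (one of "init-comp", "simulate-det",
#' "simulate-ens", "synth", "analyze"), `seed`, `out`, a `params` block
#' (keys `w_photo`, `light_hours`, `light_dark_propensity`, `brood_size`,
#' `female_fecundity`, `cross_fecundity`, `sample_size`, `n_runs`,
#' `max_generations`, `adult_census`) and a `design` block (keys of
#' [experiment_design] other than `params`/`seed`). Configs round-trip:
#' loading a dumped config reproduces the same resolved objects.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List of class `run_config` with elements `task`, `seed`, `out`,
#'   `params` ([model_params]), `design_spec` (raw list or NULL), `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  resolve_config(raw)
}

#' @rdname load_config
#' @param raw A config as a plain list (as read from file).
#' @export
resolve_config <- function(raw) {
  stopifnot(is.list(raw))
  tasks <- c("init-comp", "simulate-det", "simulate-ens", "synth", "analyze")
  task <- raw$task %||% "simulate-det"
  if (!task %in% tasks)
    stop("config error at 'task': must be one of ", paste(tasks, collapse = ", "))
  p <- raw$params %||% list()
  bad <- setdiff(names(p), c("w_photo", "light_hours", "light_dark_propensity",
                             "brood_size", "female_fecundity", "cross_fecundity",
                             "sample_size", "n_runs", "max_generations",
                             "adult_census"))
  if (length(bad)) stop("config error at 'params': unknown key(s) ",
                        paste(bad, collapse = ", "))
  mating <- mating_params(
    w_photo = p$w_photo %||% 1,
    light_hours = p$light_hours %||% 12,
    light_dark_propensity = p$light_dark_propensity %||% c(0.402, 0.598))
  params <- model_params(
    mating = mating,
    brood_size = p$brood_size %||% 30,
    female_fecundity = p$female_fecundity %||% c(0.388, 0.9, 1),
    cross_fecundity = if (!is.null(p$cross_fecundity))
      matrix(unlist(p$cross_fecundity), nrow = 2, byrow = TRUE),
    sample_size = p$sample_size %||% 300,
    n_runs = p$n_runs %||% 100,
    max_generations = p$max_generations %||% 1000,
    adult_census = p$adult_census %||% 100)
  structure(list(task = task, seed = raw$seed, out = raw$out,
                 params = params, design_spec = raw$design, raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cage dataset as CSV files
#'
#' Serializes the tables of a `cage_dataset` into a directory
#' (`offspring.csv`, `adults.csv`, `matings.csv`, `availability.csv`,
#' `truth.csv`) plus a `manifest.json` embedding the design's true
#' parameters and seed, so any dataset can be regenerated bit-for-bit.
#' Readers validate genotype labels and reject unknown ones.
#'
#' @param dataset A `cage_dataset`.
#' @param dir Output directory (created if missing).
#' @return `write_cage_dataset`: the directory, invisibly.
#'   `read_cage_dataset`: a `cage_dataset` (with `design` restored from the
#'   manifest when present).
#' @export
write_cage_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cage_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tbl in c("offspring", "adults", "matings", "availability", "truth"))
    utils::write.csv(dataset[[tbl]], file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE)
  d <- dataset$design
  manifest <- list(
    package = "saadyn",
    version = as.character(utils::packageVersion("saadyn")),
    seed = d$seed,
    n_lines = d$n_lines, n_generations = d$n_generations,
    founding = list(male = as.list(d$founding$male),
                    female = as.list(d$founding$female),
                    n_male = d$founding$n_male, n_female = d$founding$n_female),
    light_schedule = d$light_schedule,
    obs_per_generation = d$obs_per_generation,
    params = list(
      w_photo = d$params$mating$w_photo,
      light_hours = d$params$mating$light_hours,
      light_dark_propensity = d$params$mating$light_dark_propensity,
      cross_fecundity = unname(as.list(as.data.frame(t(d$params$cross_fecundity)))),
      sample_size = d$params$sample_size,
      n_runs = d$params$n_runs,
      max_generations = d$params$max_generations,
      adult_census = d$params$adult_census))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cage_dataset
#' @export
read_cage_dataset <- function(dir) {
  tables <- lapply(c(offspring = "offspring", adults = "adults",
                     matings = "matings", availability = "availability",
                     truth = "truth"), function(tbl) {
    path <- file.path(dir, paste0(tbl, ".csv"))
    if (!file.exists(path)) stop("missing table: ", path)
    utils::read.csv(path, stringsAsFactors = FALSE)
  })
  if (nrow(tables$matings) &&
      !all(tables$matings$winner %in% male_genotypes))
    stop("unknown genotype labels in matings.csv: ",
         paste(setdiff(tables$matings$winner, male_genotypes), collapse = ", "))
  if (!all(saa_genotypes %in% names(tables$adults)))
    stop("adults.csv must carry the five genotype columns: ",
         paste(saa_genotypes, collapse = ", "))
  design <- NULL
  man_path <- file.path(dir, "manifest.json")
  if (file.exists(man_path)) {
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    cf <- man$params$cross_fecundity
    cf <- if (is.list(cf)) do.call(rbind, cf) else as.matrix(cf)
    founding <- state_from_counts(stats::setNames(
      round(c(unlist(man$founding$male) * man$founding$n_male,
              unlist(man$founding$female) * man$founding$n_female)),
      saa_genotypes))
    design <- experiment_design(
      n_lines = man$n_lines, n_generations = man$n_generations,
      founding = founding, light_schedule = man$light_schedule,
      obs_per_generation = man$obs_per_generation,
      params = model_params(
        mating = mating_params(man$params$w_photo, man$params$light_hours,
                               man$params$light_dark_propensity),
        cross_fecundity = cf,
        sample_size = man$params$sample_size, n_runs = man$params$n_runs,
        max_generations = man$params$max_generations,
        adult_census = man$params$adult_census),
      seed = man$seed)
  }
  structure(c(tables, list(design = design)), class = "cage_dataset")
}

#' Write a trajectory or ensemble summary as CSV
#'
#' @param x A `saa_trajectory` or `saa_ensemble`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  df <- if (inherits(x, "saa_ensemble")) x$summary else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches on `config$task` and writes the stage's artifacts under
#' `config$out` (a directory), plus a `run_manifest.json` recording the
#' resolved config, seed and package version. Stages: `init-comp` (starting
#' composition for `design$q`), `simulate-det` (deterministic trajectory),
#' `simulate-ens` (stochastic ensemble), `synth` (synthetic cage dataset),
#' `analyze` (frequency trajectories and summaries of a dataset at
#' `design$data_dir`).
#'
#' @param config A `run_config` (see [load_config]) or a path to one.
#' @param quiet Suppress the per-stage log line (default FALSE; logs go to
#'   stderr).
#' @return The artifact, invisibly (composition, trajectory, ensemble,
#'   dataset, or analysis list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- config$design_spec %||% list()
  log_line <- function(...) if (!quiet) message("[saadyn] ", ...)
  needs_seed <- config$task %in% c("simulate-ens", "synth")
  if (needs_seed && is.null(config$seed))
    stop("config error at 'seed': task '", config$task, "' requires a seed")

  initial <- if (!is.null(d$preset)) founding_composition(d$preset)
    else if (!is.null(d$q)) hw_selection_composition(d$q, d$n_per_sex %||% 100)
    else founding_composition("P1")

  result <- switch(config$task,
    "init-comp" = {
      comp <- if (!is.null(d$preset)) founding_composition(d$preset)
        else hw_selection_composition(d$q %||% 0.3, d$n_per_sex %||% 100)
      jsonlite::write_json(
        list(counts = as.list(stats::setNames(as.integer(comp), names(comp))),
             percent = composition_percent(comp)),
        file.path(out_dir, "composition.json"), auto_unbox = TRUE, digits = NA)
      log_line("init-comp: ", paste(as.integer(comp), collapse = ", "),
               " (", composition_percent(comp), "% SAA)")
      comp
    },
    "simulate-det" = {
      traj <- run_deterministic(config$params, initial, d$n_generations %||% 100)
      write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
      log_line("simulate-det: ", nrow(traj), " generations, final freq ",
               format(traj$saa_x_freq[nrow(traj)], digits = 6))
      traj
    },
    "simulate-ens" = {
      ens <- run_ensemble(config$params, initial, d$n_generations %||% 100,
                          seed = config$seed)
      write_trajectory_csv(ens, file.path(out_dir, "ensemble.csv"))
      log_line("simulate-ens: ", nrow(ens$freqs), " runs x ",
               nrow(ens$summary), " generations")
      ens
    },
    "synth" = {
      design <- experiment_design(
        n_lines = d$n_lines %||% 4, n_generations = d$n_generations %||% 16,
        founding = d$preset %||% "P1",
        light_schedule = d$light_schedule %||% 12,
        obs_per_generation = d$obs_per_generation %||% 6,
        params = config$params, seed = config$seed)
      ds <- generate_experiment(design)
      write_cage_dataset(ds, out_dir)
      log_line("synth: ", nrow(ds$offspring), " scored-offspring rows -> ", out_dir)
      ds
    },
    "analyze" = {
      ds <- read_cage_dataset(d$data_dir %||% out_dir)
      traj <- frequency_trajectory(ds)
      utils::write.csv(traj, file.path(out_dir, "frequencies.csv"),
                       row.names = FALSE)
      per_line <- lapply(split(traj, traj$line), function(s)
        equilibrium_estimate(s, window = min(5, nrow(s))))
      jsonlite::write_json(per_line, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("analyze: ", length(per_line), " lines summarized")
      list(frequencies = traj, equilibria = per_line)
    })

  manifest <- list(task = config$task, seed = config$seed,
                   package = "saadyn",
                   version = as.character(utils::packageVersion("saadyn")),
                   config = config$raw)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
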