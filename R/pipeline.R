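# Declarative orchestration: one config (R list or YAML file) describing a
# sequence of named stages, one seed stream per stage derived from the
# global seed by a stable string hash (so adding a stage never shifts
# another stage's randomness), and a JSON manifest recording every artifact.

stage_types <- c("simulate", "load", "global_signal_regress", "bandpass",
                 "decimate", "fc", "contrast", "compare", "splits",
                 "minmaxp", "classify", "classify_splits")

#' Run a declarative analysis pipeline
#'
#' Executes the stages of a run configuration in order. The configuration is
#' a list (or the path of a YAML file parsing to one) with fields:
#' * `seed`: global integer seed;
#' * `out_dir`: output directory;
#' * `stages`: a list of stages, each with a unique `name`, a `stage` type
#'   (one of `r fcrepro:::stage_types`), and type-specific fields —
#'   `simulate` takes [sim_config()] arguments under `params` (plus optional
#'   `effect_seed`/`n_effect_pairs`/`delta_z` shortcuts), `load` takes a
#'   collection `path`, the temporal operations name an input `collection`,
#'   `compare` names collections `a` and `b`, `splits` / `classify_splits`
#'   name a `collection`, `minmaxp` a list of `collections`, and `classify`
#'   `train` and `test`.
#'
#' Stage randomness is seeded per stage as a stable hash of the global seed
#' and the stage name. Every declared output lands under `out_dir` and is
#' listed in `manifest.json` with its producing stage, parameters and seed;
#' rerunning the same configuration reproduces every number.
#'
#' @param config A list or a YAML file path.
#' @param out_dir Optional override of the configuration's output directory.
#' @return Invisibly, the manifest (also written as JSON), as a list with one
#'   entry per stage.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$stages))
  global_seed <- as.integer(config$seed %||% 1L)
  out_dir <- out_dir %||% config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- new.env(parent = emptyenv())
  manifest <- list(seed = global_seed, out_dir = out_dir, stages = list())
  names_seen <- character()
  for (st in config$stages) {
    if (is.null(st$name) || is.null(st$stage)) {
      abort("every stage needs `name` and `stage` fields.",
            class = "fcrepro_config_error")
    }
    if (st$name %in% names_seen) {
      abort(paste0("duplicate stage name: ", st$name),
            class = "fcrepro_config_error")
    }
    names_seen <- c(names_seen, st$name)
    seed <- derive_seed(global_seed, st$name)
    artifacts <- tryCatch(
      run_stage(st, seed, registry, out_dir),
      error = function(e) {
        abort(paste0("stage `", st$name, "` (", st$stage, ") failed: ",
                     conditionMessage(e)),
              class = "fcrepro_stage_error", parent = e)
      }
    )
    manifest$stages[[st$name]] <- list(
      stage = st$stage, seed = seed,
      params = st[setdiff(names(st), c("name", "stage"))],
      artifacts = artifacts
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

get_collection <- function(registry, name, stage_name) {
  if (!exists(name, envir = registry)) {
    abort(sprintf("stage `%s` references unknown collection `%s`.",
                  stage_name, name),
          class = "fcrepro_config_error")
  }
  get(name, envir = registry)
}

run_stage <- function(st, seed, registry, out_dir) {
  type <- match.arg(st$stage, stage_types)
  name <- st$name
  art <- character()
  emit <- function(file) {
    art <<- c(art, file)
    file.path(out_dir, file)
  }
  switch(type,
    simulate = {
      params <- st$params %||% list()
      params$seed <- params$seed %||% seed
      params$dataset_id <- params$dataset_id %||% name
      if (!is.null(st$n_effect_pairs)) {
        params$effect_pairs <- list(sample_effect_pairs(
          params$n_regions %||% 90, st$n_effect_pairs,
          st$delta_z %||% 0.35, seed = st$effect_seed %||% seed))
      }
      if (!is.null(params$effect_pairs)) {
        params$effect_pairs <- lapply(params$effect_pairs, function(ef) {
          list(pairs = as.integer(unlist(ef$pairs)),
               delta_z = as.numeric(ef$delta_z))
        })
      }
      sim <- simulate_cohort(do.call(sim_config, params))
      assign(name, sim$scans, envir = registry)
      dir <- emit(name)
      write_scan_collection(sim$scans, dir)
      write_ground_truth(sim, dir)
    },
    load = {
      assign(name, read_scan_collection(st$path), envir = registry)
    },
    global_signal_regress = {
      x <- get_collection(registry, st$collection, name)
      assign(name, global_signal_regress(x), envir = registry)
    },
    bandpass = {
      x <- get_collection(registry, st$collection, name)
      assign(name, ideal_bandpass(x, st$low_hz %||% 0.01, st$high_hz),
             envir = registry)
    },
    decimate = {
      x <- get_collection(registry, st$collection, name)
      assign(name, decimate_double_tr(x), envir = registry)
    },
    fc = {
      x <- get_collection(registry, st$collection, name)
      write_fc_table(fc_table(x), emit(paste0(name, ".tsv")))
    },
    contrast = {
      x <- get_collection(registry, st$collection, name)
      write_contrast(welch_contrast(x, sample_unit = st$sample_unit %||% "scan"),
                     emit(paste0(name, ".tsv")))
    },
    compare = {
      a <- get_collection(registry, st$a, name)
      b <- get_collection(registry, st$b, name)
      pr <- permutation_p(a, b, n_perm = st$n_perm %||% 1000, seed = seed,
                          perm_unit = st$perm_unit %||% "subject")
      jsonlite::write_json(glance(pr), emit(paste0(name, ".json")),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
      readr::write_tsv(tidy(pr), emit(paste0(name, "_scatter.tsv")),
                       progress = FALSE)
      readr::write_tsv(tibble(r_null = pr$null_sample),
                       emit(paste0(name, "_null.tsv")), progress = FALSE)
    },
    splits = {
      x <- get_collection(registry, st$collection, name)
      sb <- split_batch(x, mode = st$mode %||% "split_subjects",
                        n_splits = st$n_splits %||% 200,
                        n_perm = st$n_perm %||% 1000, seed = seed)
      jsonlite::write_json(glance(sb), emit(paste0(name, ".json")),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
      readr::write_tsv(tidy(sb), emit(paste0(name, "_splits.tsv")),
                       progress = FALSE)
    },
    minmaxp = {
      xs <- lapply(st$collections, get_collection,
                   registry = registry, stage_name = name)
      ct <- consistency_permutation_test(
        xs, direction = st$direction %||% "plus",
        n_perm = st$n_perm %||% 1000, seed = seed)
      jsonlite::write_json(glance(ct), emit(paste0(name, ".json")),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
      readr::write_tsv(tidy(ct), emit(paste0(name, "_table.tsv")),
                       progress = FALSE)
    },
    classify = {
      train <- get_collection(registry, st$train, name)
      test <- get_collection(registry, st$test, name)
      ev <- evaluate(train, test,
                     classifier = st$classifier %||% "linear_svm",
                     n_features = st$n_features %||% 100)
      jsonlite::write_json(ev, emit(paste0(name, ".json")),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
    },
    classify_splits = {
      x <- get_collection(registry, st$collection, name)
      sh <- split_half_batch(x, classifier = st$classifier %||% "linear_svm",
                             n_features = st$n_features %||% 100,
                             n_repeats = st$n_repeats %||% 500, seed = seed)
      jsonlite::write_json(glance(sh), emit(paste0(name, ".json")),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA)
      readr::write_tsv(tidy(sh), emit(paste0(name, "_repeats.tsv")),
                       progress = FALSE)
    }
  )
  art
}
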