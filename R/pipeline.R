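# Top-level configuration-driven pipeline: simulate -> reconstruct ->
# estimate -> evaluate, with one master seed feeding stage-keyed substreams
# and a manifest recording digests of everything written.

pipeline_known_keys <- list(
  top = c("seed", "out_dir", "stages", "simulate", "reconstruct",
          "estimate", "evaluate"),
  simulate = c("population", "n_females", "n_males", "total_offspring",
               "male_reuse_rate", "contamination_rate",
               "fecundity_dispersion", "n_loci", "maf_low", "maf_high",
               "error_rate", "missing_rate"),
  reconstruct = c("mating_system", "error_rate", "restarts", "moves_factor",
                  "cooling", "greedy_sweeps", "max_component_parents"),
  estimate = c("method"),
  evaluate = c("fractions", "replicates")
)

#' Validate a pipeline configuration
#'
#' Checks a configuration file (YAML) or list for unknown keys, range
#' errors, and intentional-but-suspicious crossings (an assumed
#' reconstruction error rate different from the simulated one is a
#' warning, not an error: crossing them is a legitimate design).
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @return the parsed configuration, invisibly, with any warnings attached
#'   as attribute `notes`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  notes <- character(0)
  unknown <- setdiff(names(config), pipeline_known_keys$top)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (sec in c("simulate", "reconstruct", "estimate", "evaluate")) {
    if (is.null(config[[sec]])) next
    unknown <- setdiff(names(config[[sec]]), pipeline_known_keys[[sec]])
    if (length(unknown)) {
      stop("unknown keys in '", sec, "': ", paste(unknown, collapse = ", "))
    }
  }
  sim <- config$simulate
  if (!is.null(sim)) {
    # full range validation happens in sim_config(); check the cheap
    # cross-field constraint here so errors name the config, not the call
    if (!is.null(sim$maf_low) && !is.null(sim$maf_high) &&
        sim$maf_low > sim$maf_high) {
      stop("config error: maf_low > maf_high")
    }
  }
  if (!is.null(sim$error_rate) && !is.null(config$reconstruct$error_rate) &&
      sim$error_rate != config$reconstruct$error_rate) {
    notes <- c(notes, sprintf(
      "assumed reconstruction error rate (%g) differs from simulated rate (%g)",
      config$reconstruct$error_rate, sim$error_rate))
  }
  for (w in notes) warning(w)
  invisible(structure(config, notes = notes))
}

#' Run the simulate/reconstruct/estimate pipeline from a configuration
#'
#' Executes the requested stages in order, deriving every stage's RNG seed
#' from the single top-level seed, writing all outputs under `out_dir`,
#' and returning a manifest listing the configuration snapshot, seeds,
#' per-stage timings, and an MD5 digest of every file written. Re-running
#' the same configuration and seed reproduces byte-identical outputs.
#'
#' @param config path to a YAML configuration or an equivalent list; see
#'   [validate_config()]. Recognised stages: `"simulate"` (pedigree,
#'   genotypes, truth), `"reconstruct"`, `"estimate"`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param seed master seed (overrides `config$seed`).
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`. On stage failure the manifest records
#'   the completed stages and the failing stage before the error is
#'   re-thrown.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) stop("no seed given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "reconstruct", "estimate")

  manifest <- list(
    package_version = as.character(packageVersion("sibnb")),
    seed = as.integer(seed),
    config = config[setdiff(names(config), "notes")],
    stages = list(), files = list(), failed_stage = NULL)
  paths <- list()
  finish <- function() {
    digests <- lapply(paths, function(p) unname(tools::md5sum(p)))
    manifest$files <<- digests
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  fit <- NULL
  genotypes <- NULL
  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      if (stage == "simulate") {
        sim <- config$simulate
        if (!is.null(sim$population)) {
          pop <- sim$population
          sim$population <- NULL
          cfg <- do.call(population_config,
                         c(list(population = pop), sim,
                           list(seed = derive_seed(seed, "simulate"))))
        } else {
          cfg <- do.call(sim_config,
                         c(sim, list(seed = derive_seed(seed, "simulate"))))
        }
        ped <- simulate_pedigree(cfg)
        genotypes <- simulate_genotypes(ped, cfg)
        paths$pedigree <- file.path(out_dir, "pedigree.csv")
        paths$roster <- file.path(out_dir, "roster.csv")
        paths$genotypes <- file.path(out_dir, "genotypes.csv")
        paths$truth <- file.path(out_dir, "truth.json")
        write_pedigree(ped, paths$pedigree, paths$roster)
        write_genotypes(genotypes, paths$genotypes)
        write_truth(ped, paths$truth)
      } else if (stage == "reconstruct") {
        if (is.null(genotypes)) {
          genotypes <- read_genotypes(file.path(out_dir, "genotypes.csv"))
        }
        rc <- do.call(recon_config,
                      c(config$reconstruct,
                        list(seed = derive_seed(seed, "reconstruct"))))
        fit <- reconstruct_sibships(genotypes, rc)
        paths$partition <- file.path(out_dir, "partition.BestCluster")
        write_best_cluster(fit$partition, paths$partition)
      } else if (stage == "estimate") {
        if (is.null(fit)) stop("estimate stage requires reconstruct")
        s <- summary(fit)
        est <- list(method = "both",
                    nb_sa = as.numeric(s$nb_sa),
                    nb_pwop = as.numeric(s$nb_pwop),
                    alpha = s$alpha,
                    q1 = s$q$q1, q2 = s$q$q2, q3 = s$q$q3, n = s$n)
        paths$estimates <- file.path(out_dir, "estimates.json")
        jsonlite::write_json(est, paths$estimates, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
      } else {
        stop("unknown stage: ", stage)
      }
      TRUE
    }, error = function(e) e)
    if (inherits(ok, "error")) {
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(ok)
      finish()
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(ok))
    }
    manifest$stages[[stage]] <- list(
      seed = derive_seed(seed, stage),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  finish()
  invisible(manifest)
}
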