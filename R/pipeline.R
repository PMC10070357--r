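#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' every stage parameter at its standard value. Supplied values override
#' defaults; unknown keys are rejected.
#'
#' @param ... named overrides, e.g. `scenarios = c("apo", "full_agonist")`,
#'   `seed = 7`, `n_target_bursts = 500`.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scenarios = c("apo", "antagonist", "partial_agonist", "full_agonist"),
    inputs = NULL,               # named photon-file paths instead of simulation
    n_target_bursts = 800,
    seed = 1,
    out_dir = NULL,
    corrections = NULL,          # NULL: use simulation truth
    burst_search = list(window_s = 500e-6, min_per_window = 5,
                        min_photons = 50, duration_range = c(0, 20e-3)),
    indicators = list(enabled = TRUE, n_groups = 20, min_bursts = 100,
                      repetitions = 200),
    ffcs = list(enabled = TRUE, n_bins = 32, bin_s = 2e-6, window_s = 10e-3),
    pda = list(enabled = TRUE, durations = c(0.5e-3, 1e-3, 2e-3),
               restarts = 3),
    sim = list()                 # sim_config() overrides
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && !is.null(names(over[[nm]]))) {
      bad2 <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad2) && nm != "sim")
        stop("unknown config key(s) in '", nm, "': ", paste(bad2, collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full apo-vs-ligand comparison workflow
#'
#' Orchestrates simulate (or read) -> burst search -> per-burst photometry ->
#' species selection -> dynamics indicators (FRET-2CDE re-coloring null,
#' BVA) -> species-filtered FCS -> dynamic PDA for every condition, and
#' assembles a report. All randomness flows from `config$seed`; the same
#' config yields identical numeric output. Intermediate tables are written
#' under `config$out_dir` when set.
#'
#' @param config list from [pipeline_config()] or path to a YAML file.
#' @return report list: per condition the burst table, E histogram summary,
#'   indicator tables, fFCS fit and PDA populations, plus a stage log.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  t_start <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    log[[length(log) + 1L]] <<- data.frame(
      stage = stage, message = msg,
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    invisible(NULL)
  }
  if (!is.null(config$inputs)) {
    missing <- config$inputs[!file.exists(unlist(config$inputs))]
    if (length(missing))
      stop("input file(s) not found: ", paste(unlist(missing), collapse = ", "))
  }
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- do.call(sim_config, config$sim)
  corrections <- if (is.null(config$corrections)) scfg$corrections
                 else do.call(correction_set, config$corrections)
  conditions <- if (!is.null(config$inputs)) names(config$inputs) else config$scenarios
  per_cond <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    if (!is.null(config$inputs)) {
      stream <- read_photons(config$inputs[[cond]])
      truth <- NULL
      note("input", "%s: read %d photons", cond, length(stream))
    } else {
      ref <- generate_reference_dataset(cond, config$n_target_bursts,
                                        seed = config$seed + ci,
                                        config = scfg,
                                        burst_opts = config$burst_search)
      stream <- ref$stream
      truth <- ref$truth
      note("simulate", "%s: %d photons, %d bursts targeted", cond,
           length(stream), config$n_target_bursts)
    }
    bursts <- do.call(find_bursts, c(list(stream), config$burst_search))
    bt <- analyze_bursts(stream, bursts, corrections)
    note("bursts", "%s: %d bursts, %d double-labeled", cond, nrow(bt),
         sum(bt$species == "double"))
    dbl <- bt[bt$species == "double", ]
    res <- list(condition = cond, truth = truth, stream = stream,
                bursts = bt, double = dbl,
                E_mean = mean(dbl$E, na.rm = TRUE),
                E_hist = if (nrow(dbl)) bin_histogram(dbl$E, seq(-0.1, 1.1, 0.02))
                         else NULL)
    if (isTRUE(config$indicators$enabled) && nrow(dbl) >= 50) {
      pd <- burst_photon_data(stream, dbl)
      res$fret_2cde_null <- fret_2cde_null_test(
        pd, dbl$E, n_groups = config$indicators$n_groups,
        min_bursts = config$indicators$min_bursts,
        repetitions = config$indicators$repetitions)
      res$bva <- bva(pd, n_groups = config$indicators$n_groups,
                     min_bursts = config$indicators$min_bursts,
                     corrections = corrections,
                     repetitions = config$indicators$repetitions)
      note("indicators", "%s: %d 2CDE groups, %d BVA groups", cond,
           nrow(res$fret_2cde_null), nrow(res$bva$groups))
    }
    if (!is.null(out_dir)) {
      data.table::fwrite(bt, file.path(out_dir, paste0(cond, "_bursts.tsv")),
                         sep = "\t")
    }
    per_cond[[cond]] <- res
  }
  ## fFCS: patterns from merged double-labeled bursts across all conditions
  report <- list(conditions = per_cond)
  if (isTRUE(config$ffcs$enabled)) {
    merged_ok <- all(vapply(per_cond, function(r) nrow(r$double) > 20, TRUE))
    if (merged_ok) {
      ffcs_res <- list()
      for (cond in conditions) {
        r <- per_cond[[cond]]
        pat <- build_species_patterns(r$stream, r$double,
                                      n_bins = config$ffcs$n_bins)
        j <- stacked_channel(r$stream, config$ffcs$n_bins)
        filt <- compute_filters(pat, tabulate(j[!is.na(j)], 4 * config$ffcs$n_bins))
        curve <- filtered_correlation(r$stream, filt, r$double,
                                      bin_s = config$ffcs$bin_s,
                                      window_s = config$ffcs$window_s,
                                      n_bins = config$ffcs$n_bins)
        agonist <- grepl("agonist", cond) && !grepl("antagonist", cond)
        fit <- tryCatch(
          fit_ffcs_model(stats::setNames(list(curve), cond), n_terms = 1),
          error = function(e) NULL)
        ffcs_res[[cond] ] <- list(curve = curve, fit = fit,
                                  tau2_s = if (!is.null(fit))
                                    fit$conditions[[1]]$tau[1] else NA)
        note("ffcs", "%s: tau2 = %.3g s", cond,
             if (!is.null(fit)) fit$conditions[[1]]$tau[1] else NA)
      }
      report$ffcs <- ffcs_res
    }
  }
  if (isTRUE(config$pda$enabled)) {
    pda_res <- list()
    for (cond in conditions) {
      r <- per_cond[[cond]]
      if (nrow(r$double) < 50) next
      pdat <- bin_bursts(r$stream, r$double, corrections,
                         durations = config$pda$durations)
      agonist <- grepl("agonist", cond) && !grepl("antagonist", cond)
      tau_ex <- if (agonist && !is.null(report$ffcs[[cond]]$tau2_s) &&
                    is.finite(report$ffcs[[cond]]$tau2_s))
        report$ffcs[[cond]]$tau2_s else 0.2
      fit <- fit_pda(pdat,
                     states_init = data.frame(R_mean = c(61.7, 49, 38.9),
                                              R_sigma = 6),
                     pair = c(2, 3), tau_ex_s = tau_ex,
                     restarts = config$pda$restarts, seed = config$seed)
      pda_res[[cond]] <- list(fit = fit, tau_ex_s = tau_ex,
                              populations = fit$conditions[[1]]$populations,
                              chi2_red = fit$conditions[[1]]$chi2_red)
      note("pda", "%s: populations %s", cond,
           paste(round(fit$conditions[[1]]$populations, 3), collapse = "/"))
    }
    report$pda <- pda_res
  }
  report$log <- do.call(rbind, log)
  if (!is.null(out_dir)) {
    summ <- list(
      seed = config$seed,
      E_mean = lapply(per_cond, `[[`, "E_mean"),
      pda_populations = lapply(report$pda, `[[`, "populations"),
      ffcs_tau2_s = lapply(report$ffcs, `[[`, "tau2_s"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    data.table::fwrite(report$log, file.path(out_dir, "pipeline_log.tsv"),
                       sep = "\t")
  }
  report
}

#' Summarise replica results as mean and standard deviation
#'
#' @param replicas list of named numeric vectors (one per technical
#'   replica) carrying the same statistics.
#' @return data.frame with `statistic`, `mean`, `sd` (`NA` for a single
#'   replica), `n`, and the per-replica values as attribute `"values"`.
#' @export
summarize_replicas <- function(replicas) {
  stopifnot(length(replicas) >= 1)
  keys <- names(replicas[[1]])
  for (r in replicas) {
    if (!identical(sort(names(r)), sort(keys)))
      stop("replica statistics differ: ",
           paste(union(setdiff(names(r), keys), setdiff(keys, names(r))),
                 collapse = ", "))
  }
  vals <- sapply(replicas, function(r) r[keys])
  vals <- matrix(vals, nrow = length(keys),
                 dimnames = list(keys, NULL))
  out <- data.frame(statistic = keys,
                    mean = rowMeans(vals),
                    sd = if (ncol(vals) >= 2) apply(vals, 1, stats::sd)
                         else NA_real_,
                    n = ncol(vals))
  attr(out, "values") <- vals
  out
}
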