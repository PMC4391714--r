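#' Pipeline configuration
#'
#' Bundles the settings of every stage of the end-to-end analysis:
#' synthetic-data generation (or input file paths), cohort construction,
#' the FDR levels of the co-occurrence screen, sex-ratio and lead/lag
#' settings, and the master seed.
#'
#' @param simulation a [sim_config()] describing the synthetic dataset, or
#'   `NULL` when `demographics_path`/`events_path` point at existing files.
#' @param demographics_path,events_path optional input files used instead
#'   of simulation.
#' @param cohort list: `definition`, `reference_year`, `max_age`,
#'   `age_group_width` (see [build_cohort()]).
#' @param alphas FDR levels swept in the screen; `alpha` is the primary
#'   level used for the reported comorbidity list.
#' @param alpha primary FDR level.
#' @param min_cell contingency-table cell rule threshold.
#' @param sr list: `p_zero`, `orientation`, `attributes` (`NULL` = the
#'   candidate diagnosis codes plus the configured ATC groups).
#' @param leadlag list: `z`, `n_surrogates`, `p_threshold`,
#'   `max_age_lag_dm1`, `codes` (`NULL` = comorbidity list of the primary
#'   screen).
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            demographics_path = NULL, events_path = NULL,
                            cohort = list(),
                            alphas = c(0.001, 0.01, 0.1),
                            alpha = 0.01,
                            min_cell = 10,
                            sr = list(),
                            leadlag = list(),
                            seed = 1L) {
  stopifnot(all(alphas > 0 & alphas < 1), alpha > 0, alpha < 1)
  cohort <- utils::modifyList(list(definition = "inpatient",
                                   reference_year = NULL, max_age = 95,
                                   age_group_width = 5), cohort)
  sr <- utils::modifyList(list(p_zero = 0.05,
                               orientation = "female_positive",
                               attributes = NULL), sr)
  leadlag <- utils::modifyList(list(z = 50, n_surrogates = 1000,
                                    p_threshold = 0.01, max_age_lag_dm1 = 30,
                                    codes = NULL), leadlag)
  structure(list(simulation = simulation,
                 demographics_path = demographics_path,
                 events_path = events_path,
                 cohort = cohort, alphas = sort(alphas), alpha = alpha,
                 min_cell = min_cell, sr = sr, leadlag = leadlag,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] /
#' [sim_config()] arguments; `simulation.rr_effects` and
#' `simulation.temporal_effects` are sequences of records and
#' `simulation.sex_effects` a code-to-ratio map.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    for (f in c("rr_effects", "temporal_effects")) {
      if (!is.null(s[[f]])) s[[f]] <- rbindlist(s[[f]])
    }
    if (!is.null(s$sex_effects)) s$sex_effects <- unlist(s$sex_effects)
    sim <- do.call(sim_config, s)
  }
  pipeline_config(
    simulation = sim,
    demographics_path = y$demographics_path, events_path = y$events_path,
    cohort = y$cohort %||% list(),
    alphas = unlist(y$alphas) %||% c(0.001, 0.01, 0.1),
    alpha = y$alpha %||% 0.01,
    min_cell = y$min_cell %||% 10,
    sr = y$sr %||% list(),
    leadlag = y$leadlag %||% list(),
    seed = y$seed %||% 1L
  )
}

#' Run the full comorbidity pipeline
#'
#' Chains simulate (or load) -> cohort -> co-occurrence screen (over the
#' configured FDR levels) -> sex ratios -> lead/lag analysis -> recall
#' validation, writing each stage's output as a plain delimited file under
#' `outdir` plus a JSON run manifest. Identical configuration and seed
#' produce byte-identical stage outputs; progress and per-stage timings go
#' to the message stream.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param verbose emit per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    say("stage %-10s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  say("pipeline seed %d, outdir %s", config$seed, outdir)

  truth <- NULL
  data <- stage("simulate", {
    if (!is.null(config$simulation)) {
      sim_cfg <- config$simulation
      sim_cfg$seed <- config$seed
      sim <- simulate_population(sim_cfg)
      truth <- sim$truth
      write_claims(sim$data, file.path(outdir, "demographics.csv"),
                   file.path(outdir, "events.csv"))
      fwrite(truth$rr, file.path(outdir, "planted_rr.csv"))
      fwrite(truth$sex_sign, file.path(outdir, "planted_sex_sign.csv"))
      fwrite(truth$lead_pairs, file.path(outdir, "planted_lead_pairs.csv"))
      sim$data
    } else {
      if (is.null(config$demographics_path) || is.null(config$events_path)) {
        stopf("pipeline stage simulate failed: no simulation block and no input files")
      }
      read_claims(config$demographics_path, config$events_path)
    }
  })

  cohort <- stage("cohort", {
    co <- build_cohort(data, definition = config$cohort$definition,
                       reference_year = config$cohort$reference_year,
                       max_age = config$cohort$max_age,
                       age_group_width = config$cohort$age_group_width)
    summ <- cohort_summary(co)
    fwrite(summ$counts, file.path(outdir, "cohort_counts.csv"))
    fwrite(summ$by_age, file.path(outdir, "cohort_by_age.csv"))
    co
  })

  codes <- candidate_codes(cohort)
  screens <- stage("cooccur", {
    out <- lapply(config$alphas, function(al) {
      run_cooccurrence(cohort, codes = codes, alpha = al,
                       min_cell = config$min_cell)
    })
    names(out) <- sprintf("alpha_%g", config$alphas)
    primary <- out[[sprintf("alpha_%g", config$alpha)]] %||%
      run_cooccurrence(cohort, codes = codes, alpha = config$alpha,
                       min_cell = config$min_cell)
    for (ty in c("DM1", "DM2")) {
      fwrite(primary$results[diabetes_type == ty,
                             .(code, age_group, rr, ci_low, ci_high,
                               p_value, significant)],
             file.path(outdir, sprintf("cooccurrence_%s.csv", tolower(ty))))
    }
    fwrite(data.table(alpha = config$alphas,
                      n_comorbidities = vapply(out, function(o)
                        length(o$comorbidities$union), integer(1)),
                      expected_false_positives = vapply(out, function(o)
                        expected_false_positives(
                          length(o$comorbidities$union), o$alpha), numeric(1))),
           file.path(outdir, "discoveries_by_alpha.csv"))
    c(out, list(primary = primary))
  })

  sr_tab <- stage("sexratio", {
    attrs <- config$sr$attributes %||% c(
      lapply(codes, attr_diag),
      lapply(names(config$simulation$atc_prevalence %||%
                     default_atc_universe()), attr_atc))
    tab <- run_sex_ratio(cohort, attrs, p_zero = config$sr$p_zero,
                         orientation = config$sr$orientation)
    fwrite(tab[, .(attribute, age_group, sr, p_value, zeroed)],
           file.path(outdir, "sex_ratios.csv"))
    tab
  })

  ll_tab <- stage("leadlag", {
    ll_codes <- config$leadlag$codes %||% screens$primary$comorbidities$union
    tab <- run_leadlag(cohort, codes = ll_codes,
                       z = config$leadlag$z,
                       n_surrogates = config$leadlag$n_surrogates,
                       seed = config$seed,
                       p_threshold = config$leadlag$p_threshold,
                       max_age_lag_dm1 = config$leadlag$max_age_lag_dm1)
    fwrite(tab[, .(d_i, x, sex, i_lead, p_lead, i_lag, p_lag,
                   excluded_reason)],
           file.path(outdir, "leadlag.csv"))
    tab
  })

  recalls <- stage("validate", {
    rec <- data.table(
      alpha = config$alphas,
      recall = vapply(sprintf("alpha_%g", config$alphas), function(nm)
        recall(screens[[nm]]$comorbidities$union), numeric(1)))
    fwrite(rec, file.path(outdir, "recall.csv"))
    rec
  })

  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_file)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    n_patients = nrow(cohort$patients),
    n_candidate_codes = length(codes),
    n_scheduled_tests = screens$primary$n_scheduled,
    comorbidities = lapply(screens[names(screens) != "primary"],
                           function(o) o$comorbidities$union),
    recall = as.list(stats::setNames(recalls$recall,
                                     sprintf("alpha_%g", recalls$alpha))),
    outputs = sort(list.files(outdir))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, screens = screens, sex_ratios = sr_tab,
                 leadlag = ll_tab, recalls = recalls, truth = truth,
                 manifest = manifest))
}

# config in plain-list form for the YAML snapshot / hash
serialize_config <- function(config) {
  x <- unclass(config)
  if (!is.null(x$simulation)) {
    s <- unclass(x$simulation)
    s$dm_prevalence <- as.list(as.data.frame(s$dm_prevalence))
    if (!is.null(s$rr_effects)) s$rr_effects <- as.list(as.data.frame(s$rr_effects))
    if (!is.null(s$temporal_effects)) {
      s$temporal_effects <- as.list(as.data.frame(s$temporal_effects))
    }
    x$simulation <- s
  }
  x$sr$attributes <- if (!is.null(x$sr$attributes)) {
    vapply(x$sr$attributes, function(a) a$name, character(1))
  }
  x
}
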