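## End-to-end orchestration: environment -> states -> cohorts -> survival
## -> models, from one configuration, with plain-file outputs and a run
## manifest for reproducibility.

default_pipeline_config <- function() {
  list(seed = 1,
       simulate = NULL, inputs = NULL,
       environment = list(max_gap = 1 / 12, rho = 1025, g = 9.81),
       states = list(k = 5, run_gap = FALSE, gap_k_max = 8, gap_B = 20,
                     gap_subsample = 1500, n_samples = 5),
       cohorts = list(min_gap = 1, max_pulse = 1.5, convention = "midpoint",
                      cov_quantile = 0.8),
       shifts = list(dominance_threshold = 0.4, persistence = 1),
       models = list(run = TRUE, k = 10))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.data.frame(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full cohort-demography pipeline
#'
#' Executes every analysis stage from one configuration: environmental
#' preprocessing (temperature gap filling, weekly wave-energy series),
#' algal-state clustering and timelines with persistent-shift detection,
#' cohort window detection and parameter extraction, pooled Kaplan-Meier
#' survivorship, factor analysis, the additive models of cohort size and
#' longevity, temporal trend tests, and the demographic-event summary
#' table. Inputs come either from a `simulate` block (a
#' [simulation_config()] argument list) or from an `inputs` block of CSV
#' paths (`census`, `plants`, `temperature`, `waves`, optional
#' `site_meta`). Any stage failure aborts with the stage name and cause.
#'
#' @param config a nested configuration list (see
#'   `kelpcohorts:::default_pipeline_config()` for the defaults), or a
#'   path to a YAML file holding one. Data may also be passed pre-loaded
#'   via `config$data` (a list like the return of [simulate_dataset()]).
#' @param out_dir optional output directory; when given, all result
#'   tables are written as CSV plus a JSON run manifest with the config
#'   hash and seed.
#' @return a list of all stage results (`data`, `env`, `states`,
#'   `timeline`, `shifts`, `windows`, `cohorts`, `survival`, `factors`,
#'   `screen`, `model_size`, `model_longevity`, `trends`, `summary`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)

  data <- run_stage("data", {
    if (!is.null(cfg$data)) cfg$data
    else if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      simulate_dataset(do.call(simulation_config, sim_args))
    } else if (!is.null(cfg$inputs)) {
      ins <- cfg$inputs
      for (need in c("census", "plants", "temperature", "waves"))
        if (is.null(ins[[need]]))
          stopf("input '%s' missing from config", need)
      list(census = load_census(ins$census),
           plants = load_plants(ins$plants,
                                dialect = ins$plants_dialect %||% "wide"),
           temperature = load_env_series(ins$temperature, "temperature"),
           waves = load_env_series(ins$waves, "wave"),
           site_meta = if (!is.null(ins$site_meta)) load_site_meta(ins$site_meta))
    } else stopf("config needs a 'simulate', 'inputs', or 'data' block")
  })

  env <- run_stage("environment", {
    if (is.null(data$temperature) || is.null(data$waves))
      stopf("temperature and wave series are required")
    list(temperature = interpolate_gaps(data$temperature,
                                        max_gap = cfg$environment$max_gap),
         waves_weekly = wave_energy_series(data$waves, rho = cfg$environment$rho,
                                           g = cfg$environment$g))
  })

  states <- run_stage("states", {
    guilds <- scale_features(pool_guilds(data$census))
    gap <- NULL
    if (isTRUE(cfg$states$run_gap)) {
      m <- guild_matrix(guilds)
      sub <- if (nrow(m) > cfg$states$gap_subsample)
        with_seed(child_seed(cfg$seed, 5),
                  m[sample.int(nrow(m), cfg$states$gap_subsample), ]) else m
      gap <- gap_statistic(sub, k_max = cfg$states$gap_k_max,
                           B = cfg$states$gap_B, seed = cfg$seed)
    }
    st <- cluster_states(guilds, k = cfg$states$k, seed = cfg$seed,
                         n_samples = cfg$states$n_samples)
    if (cfg$states$k == 5) st <- label_states(st)
    list(states = st, gap = gap, guilds = guilds)
  })
  timeline <- run_stage("states", state_timeline(states$states))
  shifts <- run_stage("states",
    detect_state_shifts(timeline, cfg$shifts$dominance_threshold,
                        cfg$shifts$persistence))

  windows <- run_stage("cohorts", {
    w <- detect_cohort_windows(data$plants, min_gap = cfg$cohorts$min_gap,
                               max_pulse = cfg$cohorts$max_pulse)
    w
  })
  plants <- run_stage("cohorts", assign_plants(windows, data$plants))
  cohorts <- run_stage("cohorts",
    cohort_parameters(windows, plants, data$census, env$temperature,
                      env$waves_weekly, site_meta = data$site_meta,
                      convention = cfg$cohorts$convention,
                      cov_quantile = cfg$cohorts$cov_quantile))

  surv <- run_stage("survival", {
    ls <- lifespan(plants, cfg$cohorts$convention)
    list(pooled = km_fit(ls$duration, ls$event),
         by_site = pooled_site_curves(plants, "site", cfg$cohorts$convention))
  })

  factors <- screen <- model_size <- model_longevity <- trends <- NULL
  if (isTRUE(cfg$models$run)) {
    dead <- cohorts[!cohorts$alive, ]
    factors <- run_stage("models", factor_model(dead))
    screen <- run_stage("models",
      screen_predictors(dead, "life_mn",
                        predictors = c("temp80", "wave80", "psu_density",
                                       "rsu_density", "Ad", "understory_1yr",
                                       "juveniles_1yr", "depth"),
                        seed = cfg$seed))
    model_size <- run_stage("models",
      fit_cohort_size_model(cohorts, k = cfg$models$k))
    model_longevity <- run_stage("models",
      fit_longevity_model(cohorts, k = cfg$models$k))
    trends <- run_stage("models", trend_tests(cohorts))
  }
  summary_tab <- run_stage("summary", demographic_summary(cohorts))

  result <- list(data = data, env = env, states = states$states,
                 gap = states$gap, timeline = timeline, shifts = shifts,
                 windows = windows, plants = plants, cohorts = cohorts,
                 survival = surv, factors = factors, screen = screen,
                 model_size = model_size, model_longevity = model_longevity,
                 trends = trends, summary = summary_tab, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

## Serialize the main result tables as CSV plus a JSON manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    name
  }
  files <- c(
    wcsv(result$timeline, "state_timeline.csv"),
    wcsv(result$shifts, "state_shifts.csv"),
    wcsv(as.data.frame(result$windows), "cohort_windows.csv"),
    wcsv(as.data.frame(result$cohorts), "cohort_parameters.csv"),
    wcsv(result$summary, "demographic_summary.csv"))
  curves <- do.call(rbind, lapply(names(result$survival$by_site), function(s) {
    cv <- result$survival$by_site[[s]]$curve
    cbind(site_id = s, cv)
  }))
  files <- c(files, wcsv(curves, "survival_curves.csv"))
  if (!is.null(result$factors)) {
    L <- result$factors$loadings
    files <- c(files, wcsv(data.frame(parameter = rownames(L), unclass(L)),
                           "factor_loadings.csv"))
  }
  for (nm in c("model_size", "model_longevity")) {
    m <- result[[nm]]
    if (is.null(m)) next
    tab <- rbind(
      data.frame(term = rownames(m$parametric), kind = "parametric",
                 estimate = m$parametric[, 1], se = m$parametric[, 2],
                 z = m$parametric[, 3], edf = NA, chisq = NA,
                 p = m$parametric[, 4]),
      data.frame(term = rownames(m$smooth_table), kind = "smooth",
                 estimate = NA, se = NA, z = NA, edf = m$smooth_table[, 1],
                 chisq = m$smooth_table[, 3], p = m$smooth_table[, 4]))
    files <- c(files, wcsv(tab, paste0(nm, ".csv")))
  }
  cfg_json <- jsonlite::toJSON(result$config, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(seed = result$config$seed,
                   config_hash = unname(tools::md5sum(tf)),
                   n_census = nrow(result$data$census),
                   n_plants = nrow(result$plants),
                   n_cohorts = nrow(result$cohorts),
                   files = files)
  unlink(tf)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
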