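#' Pipeline configuration
#'
#' Bundles every stage option of the end-to-end run: synthetic generation,
#' panel + fitting, multi-replicate simulation, dementia allocation,
#' reporting and health expectancy. Can be read from a YAML file whose keys
#' mirror the argument names (`synthetic:`, `run:`, `report_years:` ...).
#'
#' @param synthetic a [synthetic_config()].
#' @param run a [run_config()].
#' @param registry a `characteristic_registry`.
#' @param allocation an [allocation_table()].
#' @param report_years snapshot years summarised in the output tables.
#' @param healthexp_years two years compared in the Sullivan decomposition.
#' @param condition_set_name `"diseases_only"` or
#'   `"diseases_and_impairments"`.
#' @param seed master seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            run = run_config(),
                            registry = default_registry(),
                            allocation = default_allocation_table(),
                            report_years = c(2015L, 2025L, 2035L),
                            healthexp_years = c(2015L, 2035L),
                            condition_set_name = "diseases_only",
                            seed = 1L) {
  run$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, run = run, registry = registry,
                 allocation = allocation,
                 report_years = as.integer(report_years),
                 healthexp_years = as.integer(healthexp_years),
                 condition_set_name = condition_set_name,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `seed`, `n_individuals`, `horizon`, `n_replicates`,
#' `scale_factor`, `report_years`, `healthexp_years`, `condition_set`.
#' Unspecified keys take the package defaults.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- synthetic_config(
    n_individuals = y$n_individuals %||% 30000L,
    scale_factor = y$scale_factor %||% 100)
  run <- run_config(
    horizon = y$horizon %||% 2035L,
    n_replicates = y$n_replicates %||% 1L,
    scale_factor = y$scale_factor %||% 100,
    seed = y$seed %||% 1L)
  pipeline_config(synthetic = syn, run = run,
                  report_years = unlist(y$report_years %||% c(2015L, 2025L, 2035L)),
                  healthexp_years = unlist(y$healthexp_years %||% c(2015L, 2035L)),
                  condition_set_name = y$condition_set %||% "diseases_only",
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the JSON-serialised config: stamped into every output CSV
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    list(seed = config$seed, n = config$synthetic$n_individuals,
         horizon = config$run$horizon,
         n_replicates = config$run$n_replicates,
         report_years = config$report_years,
         healthexp_years = config$healthexp_years,
         condition_set = config$condition_set_name),
    tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# manifest: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full projection pipeline
#'
#' generate base population -> generate panel from the ground-truth bundle
#' -> fit transition models -> simulate `n_replicates` monthly runs ->
#' allocate dementia -> prevalence / multi-morbidity / percent-change
#' tables -> Sullivan health expectancy and decomposition. All stage seeds
#' derive from the single master seed; a manifest (JSON) makes the run
#' reproducible from the config alone. Artifacts are written under
#' `out_dir`, each CSV stamped with the manifest hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param fit if `FALSE`, simulate directly from the ground-truth bundle
#'   and skip the panel + fitting stages.
#' @return invisibly, a list with the in-memory artifacts (base, bundle,
#'   replicates, tables, health expectancy, decomposition, manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run"),
                         fit = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .msim_error(paste0("pipeline stage '", name, "' failed: ",
                         conditionMessage(e)), "morbsim_pipeline_error"))
  }
  schedule <- gompertz_schedule()
  base <- stage("generate",
    generate_base_population(config$synthetic, seed = seed))
  write_population(base, file.path(out_dir, "base_population.csv"),
                   comment = paste0("manifest: ", hash))
  truth <- default_truth_bundle(config$registry)
  bundle <- truth
  if (fit) {
    panel <- stage("panel",
      generate_panel(base, truth, seed = replicate_seed(seed, 101L)))
    bundle <- stage("fit", fit_transition_bundle(panel, config$registry))
    write_bundle(bundle, file.path(out_dir, "bundle.json"))
  }
  reps <- stage("simulate", run_replicates(base, bundle, schedule, config$run))
  reps <- stage("allocate", lapply(seq_along(reps), function(r)
    allocate_dementia(reps[[r]], config$allocation,
                      seed = replicate_seed(seed, 200L + r))))
  cs <- if (config$condition_set_name == "diseases_only") diseases_only()
        else diseases_and_impairments()
  keep_years <- as.character(config$report_years)
  main <- reps[[1]]
  main_snaps <- main$snapshots[intersect(keep_years, names(main$snapshots))]
  prev <- stage("report", prevalence_table(main_snaps,
    scale_factor = config$run$scale_factor))
  mm <- multimorbidity_table(main_snaps, cs,
    scale_factor = config$run$scale_factor)
  write_stamped_csv(prev, file.path(out_dir, "prevalence.csv"), hash)
  write_stamped_csv(mm, file.path(out_dir, "multimorbidity.csv"), hash)
  y0 <- keep_years[1]
  chg <- mm[mm$year == y0, c("age_group", "category")]
  for (yr in keep_years[-1]) {
    a <- mm$count[mm$year == y0]
    bcnt <- mm$count[mm$year == yr]
    ok <- a > 0
    chg[[paste0("pct_change_", y0, "_", yr)]] <-
      ifelse(ok, percent_change(pmax(a, 1), bcnt), NA)
  }
  write_stamped_csv(chg, file.path(out_dir, "percent_change.csv"), hash)

  # replicate range of 65+ multi-morbidity prevalence (sensitivity harness)
  range_tab <- NULL
  if (length(reps) > 1L) {
    vals <- sapply(reps, function(r) {
      snaps <- r$snapshots[intersect(keep_years, names(r$snapshots))]
      m <- multimorbidity_table(snaps, cs, config$run$scale_factor)
      m$prevalence[m$age_group == "65+" & m$category == "2+"]
    })
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
    range_tab <- data.frame(year = intersect(keep_years, names(main$snapshots)),
                            min = apply(vals, 1, min),
                            max = apply(vals, 1, max),
                            range = apply(vals, 1, max) - apply(vals, 1, min))
    write_stamped_csv(range_tab, file.path(out_dir, "replicate_range.csv"), hash)
  }

  # Sullivan health expectancy + decomposition between the two settings
  ya <- as.character(config$healthexp_years[1])
  yb <- as.character(config$healthexp_years[2])
  hx_rows <- list()
  decomp <- list()
  for (sx in c("male", "female")) {
    lt_a <- build_lifetable(schedule, config$healthexp_years[1], sx)
    lt_b <- build_lifetable(schedule, config$healthexp_years[2], sx)
    sf_a <- prevalence_surface(main$snapshots[[ya]], cs, sx)
    sf_b <- prevalence_surface(main$snapshots[[yb]], cs, sx)
    hx_a <- sullivan(lt_a, sf_a)
    hx_b <- sullivan(lt_b, sf_b)
    for (yr_hx in list(list(ya, hx_a), list(yb, hx_b)))
      hx_rows[[length(hx_rows) + 1L]] <- data.frame(
        year = yr_hx[[1]], sex = sx, total_le = yr_hx[[2]]$total_le,
        category = names(yr_hx[[2]]$years),
        years = unname(yr_hx[[2]]$years),
        share = unname(yr_hx[[2]]$shares))
    decomp[[sx]] <- decompose_change(lt_a, sf_a, lt_b, sf_b, "2+")
  }
  hx_tab <- do.call(rbind, hx_rows)
  write_stamped_csv(hx_tab, file.path(out_dir, "health_expectancy.csv"), hash)
  dec_tab <- do.call(rbind, lapply(names(decomp), function(sx)
    data.frame(sex = sx, category = decomp[[sx]]$category,
               delta = decomp[[sx]]$delta,
               mortality = decomp[[sx]]$mortality,
               prevalence = decomp[[sx]]$prevalence)))
  write_stamped_csv(dec_tab, file.path(out_dir, "decomposition.csv"), hash)

  manifest <- list(package = "morbsim",
                   version = as.character(utils::packageVersion("morbsim")),
                   hash = hash, seed = seed,
                   n_individuals = config$synthetic$n_individuals,
                   n_replicates = config$run$n_replicates,
                   horizon = config$run$horizon,
                   replicate_seeds = vapply(seq_len(config$run$n_replicates),
                     function(r) replicate_seed(seed, r), numeric(1)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(base = base, bundle = bundle, replicates = reps,
                 prevalence = prev, multimorbidity = mm,
                 percent_change = chg, replicate_range = range_tab,
                 health_expectancy = hx_tab, decomposition = decomp,
                 manifest = manifest, out_dir = out_dir))
}
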