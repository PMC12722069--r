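#' @title End-to-end pipeline
#' @description Orchestrates ingest, kinship canonicalization, fusion,
#'   descriptives, scale coding and both model families, writing tidy CSV
#'   outputs and a reproducibility manifest.
#' @name pipeline_cli
NULL

#' Run the full analysis pipeline
#'
#' Stages: read and validate the survey tables; fuse every household
#' network; write node/edge lists and GraphML exports; compute network
#' summaries, category means and weighted assortativity; code scales and
#' diet flags; fit the dyadic mixed models (specifications 1--3) and the
#' diet GEE models per scope and outcome. Warnings (unresolved nodes,
#' undefined assortativity networks, non-convergent fits) are collected in
#' the manifest and never abort the run.
#'
#' @param participants_path,alters_path,ratings_path,overrides_path input
#'   CSVs (overrides optional).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (stages are
#'   deterministic; the seed is for provenance of any future stochastic
#'   stage).
#' @param fit_models fit the regression stages (TRUE) or stop after metrics.
#' @param write_graphml also export one GraphML file per household.
#' @return invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(participants_path, alters_path, ratings_path,
                         overrides_path = NULL, out_dir, seed = 1L,
                         fit_models = TRUE, write_graphml = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  warnings_log <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- expr
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), ts,
                                                  units = "secs")), 3)
    out
  }
  surveys <- stage("ingest", read_household_surveys(
    participants_path, alters_path, ratings_path, overrides_path))
  networks <- stage("fuse", lapply(surveys, fuse_household))
  regs <- do.call(rbind, lapply(networks, function(nw) {
    r <- as.data.frame(nw$registry)
    r$household_id <- nw$household_id
    r
  }))
  n_unres <- sum(regs$term == "other" & regs$resolution == "unresolved")
  if (n_unres > 0)
    warnings_log <- c(warnings_log,
                      paste(n_unres, "node(s) left unresolved (relation 'other')"))
  utils::write.csv(regs[, c("household_id", "node_id", "term", "sex", "age",
                            "health", "effort", "surveyed", "reporter_count",
                            "resolution")],
                   file.path(out_dir, "nodes.csv"), row.names = FALSE)
  edges_all <- do.call(rbind, lapply(networks, function(nw) {
    e <- nw$edges
    if (nrow(e)) cbind(household_id = nw$household_id, e)
  }))
  utils::write.csv(edges_all, file.path(out_dir, "edges.csv"),
                   row.names = FALSE)
  if (write_graphml) {
    gml_dir <- file.path(out_dir, "graphml")
    dir.create(gml_dir, showWarnings = FALSE)
    for (nw in networks)
      write_network_graphml(nw, file.path(gml_dir,
                                          paste0(nw$household_id, ".graphml")))
  }
  metrics <- stage("metrics", {
    ns <- summarize_networks(networks)
    cm <- category_means(networks)
    ac <- assortativity_cohort(networks)
    list(network_summary = ns, category_means = cm, assortativity = ac)
  })
  n_drop <- sum(metrics$assortativity$n_undefined)
  if (n_drop > 0)
    warnings_log <- c(warnings_log, paste(n_drop,
      "network x attribute x weight cells with undefined assortativity dropped"))
  utils::write.csv(metrics$network_summary$per_network,
                   file.path(out_dir, "network_summary.csv"), row.names = FALSE)
  utils::write.csv(metrics$category_means,
                   file.path(out_dir, "category_means.csv"), row.names = FALSE)
  utils::write.csv(metrics$assortativity,
                   file.path(out_dir, "assortativity.csv"), row.names = FALSE)
  scales <- stage("scales", code_participants(surveys))
  utils::write.csv(scales$coded, file.path(out_dir, "coded_participants.csv"),
                   row.names = FALSE)
  summary_tab <- summarize_cohort(surveys)
  utils::write.csv(summary_tab, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  models <- NULL
  if (fit_models) {
    models <- stage("models", {
      records <- do.call(rbind, lapply(networks, build_directed_records))
      records <- attach_scale_flags(records, scales$coded)
      dyad <- list()
      for (spec in 1:3) {
        f <- tryCatch(fit_dyad_mixed(records, model_spec = spec),
                      error = function(e) e)
        if (inherits(f, "error")) {
          warnings_log <- c(warnings_log,
                             paste("dyad model", spec, "failed:",
                                   conditionMessage(f)))
          f <- NULL
        } else if (!f$converged) {
          warnings_log <- c(warnings_log,
                             paste("dyad model", spec, "convergence not clean"))
        }
        dyad[[spec]] <- f
      }
      participants <- do.call(rbind, lapply(surveys, `[[`, "participants"))
      averages <- cohort_network_averages(networks)
      utils::write.csv(averages, file.path(out_dir, "network_averages.csv"),
                       row.names = FALSE)
      diet <- list()
      for (sc in c("full", "family_excl_spouse", "friends")) {
        for (out in c("veg_meets", "fruit_meets", "fastfood_none",
                      "snacks_low")) {
          f <- tryCatch(fit_diet_gee(participants, scales$coded, averages,
                                     out, scope = sc),
                        error = function(e) e)
          if (inherits(f, "error")) {
            warnings_log <- c(warnings_log,
                               paste("diet model", out, "/", sc, "failed:",
                                     conditionMessage(f)))
            f <- NULL
          }
          diet[[paste(sc, out, sep = ".")]] <- f
        }
      }
      list(dyad = dyad, diet = diet,
           records = records, averages = averages)
    })
    dyad_tab <- do.call(rbind, lapply(seq_along(models$dyad), function(i) {
      f <- models$dyad[[i]]
      if (is.null(f)) return(NULL)
      cbind(model = paste0("dyad_", i), f$tidy, n = f$n_used,
            or_scale = FALSE)
    }))
    diet_tab <- do.call(rbind, lapply(names(models$diet), function(nm) {
      f <- models$diet[[nm]]
      if (is.null(f)) return(NULL)
      td <- f$tidy
      data.frame(model = nm, term = td$term, estimate = td$estimate,
                 se = td$se, ci_low = td$ci_low, ci_high = td$ci_high,
                 n = td$n, or_scale = TRUE)
    }))
    utils::write.csv(dyad_tab, file.path(out_dir, "dyad_models.csv"),
                     row.names = FALSE)
    utils::write.csv(diet_tab, file.path(out_dir, "diet_models.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = seed,
    inputs = list(
      participants = unname(tools::md5sum(participants_path)),
      alters = unname(tools::md5sum(alters_path)),
      ratings = unname(tools::md5sum(ratings_path)),
      overrides = if (!is.null(overrides_path) && file.exists(overrides_path))
        unname(tools::md5sum(overrides_path)) else NA),
    n_households = length(surveys),
    stage_seconds = timings,
    warnings = warnings_log,
    finished = format(t0, "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(list(surveys = surveys, networks = networks, metrics = metrics,
                 scales = scales, models = models, manifest = manifest))
}

#' Simulate a cohort and write its survey tables
#'
#' Convenience wrapper: [generate_cohort()] plus [write_cohort()] and a JSON
#' truth file.
#'
#' @param config generator configuration.
#' @param out_dir output directory.
#' @return invisibly, the cohort object.
#' @export
simulate_to_dir <- function(config = generator_config(), out_dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_dir)
  truth <- cohort$truth
  truth$config$templates <- lapply(truth$config$templates, as.list)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(cohort)
}
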