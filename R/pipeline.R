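#' Configuration for the full analysis pipeline
#'
#' Collects every tunable of the end-to-end analysis: where the maps come
#' from (a fixture directory, or the simulator), the identity-link
#' threshold, the QAP permutation count, seed and tail, Cox tie handling
#' and colony term, the possible-founder policy, and an optional output
#' directory. The resolved configuration is embedded in every results
#' bundle for provenance.
#'
#' @param input_dir Fixture directory (as written by [export_fixture()]),
#'   or `NULL` to simulate.
#' @param sim A [sim_config()] used when `input_dir` is `NULL`.
#' @param max_link_distance Identity-link threshold (m).
#' @param B QAP permutation count.
#' @param tail,ties,colony_term Passed to [qap_cox()].
#' @param policy Possible-founder policy for the budding models.
#' @param seed Master seed; each test derives its own substream.
#' @param out_dir Optional directory for results files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, sim = sim_config(),
                            max_link_distance = 2, B = 999,
                            tail = "two_sided", ties = "efron",
                            colony_term = "factor", policy = "exclude",
                            seed = 1L, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full dynamic nest-network analysis
#'
#' Executes the pipeline end to end: load or simulate colony time series;
#' per-map metrics; event extraction; the nest- and trail-survival QAP
#' test suite (resource flow, nest size, flow adjusted for size,
#' worker:forager ratio, tree distance, canopy; trail minimum endpoint
#' flow, traffic, weight, worker:forager ratio — each trail model also
#' carrying the endpoint-survival indicator); the budding
#' analysis-of-deviance suite (flow, change in flow, worker:forager ratio
#' and its change, size and its change, tree distance, canopy, season);
#' and model-based survival curves for the low / medium / high flow
#' profiles (normalised betweenness 0.1, 0.5, 0.9). A stage that fails is
#' recorded in the bundle's `failures` manifest and the rest of the
#' pipeline continues.
#'
#' With `out_dir` set, writes `report.txt` (one line per test:
#' statistic, n, B, seed, p), `results.json` (all results plus the
#' resolved config, seed and input hash), `curves.csv`,
#' `survival_records.csv`, `budding_data.csv` and one GraphML file per
#' map. Reruns with the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A results bundle (list): `config`, `provenance`, `colonies`,
#'   `metrics`, `events`, `nest_records`, `trail_records`,
#'   `budding_data`, `qap` (list of [qap_cox()] results), `qap_summary`,
#'   `aod` (tibble of analysis-of-deviance rows), `curves`,
#'   `report_lines`, `failures`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  failures <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  colonies <- try_stage("input", {
    if (is.null(config$input_dir)) {
      simulate_colonies(config$sim)$colonies
    } else {
      read_fixture(config$input_dir, config$max_link_distance)$colonies
    }
  })
  if (is.null(colonies)) {
    return(list(config = config, failures = failures))
  }

  metrics <- try_stage("metrics", {
    suppressWarnings(bind_rows(purrr::map(colonies, function(s) {
      bind_rows(purrr::map(s$maps, colony_metrics))
    })))
  })
  events <- try_stage("events",
                      bind_rows(purrr::map(colonies, extract_events)))

  nest_records <- try_stage("nest_records", {
    build_survival_records(colonies, metrics, "nest") |>
      mutate(log_size = log(.data$size),
             log_wf_ratio = log(.data$wf_ratio))
  })
  trail_records <- try_stage("trail_records", {
    build_survival_records(colonies, metrics, "trail") |>
      mutate(log_traffic = log(.data$traffic),
             log_wf_ratio = log(.data$wf_ratio))
  })
  budding_data <- try_stage("budding_data", {
    build_budding_data(colonies, metrics) |>
      mutate(log_size = log(.data$size),
             log_wf_ratio = log(.data$wf_ratio),
             d_size_z = as.numeric(scale(.data$d_size)))
  })

  nest_tests <- list(
    nest_flow = list(rec = "nest", cov = "betweenness"),
    nest_size = list(rec = "nest", cov = "log_size"),
    nest_flow_adj_size = list(rec = "nest",
                              cov = c("betweenness", "log_size")),
    nest_wf_ratio = list(rec = "nest", cov = "log_wf_ratio"),
    nest_tree_dist = list(rec = "nest", cov = "tree_dist"),
    nest_canopy = list(rec = "nest", cov = "canopy"),
    trail_min_flow = list(rec = "trail",
                          cov = c("min_betweenness", "endpoint_lost")),
    trail_traffic = list(rec = "trail",
                         cov = c("log_traffic", "endpoint_lost")),
    trail_weight = list(rec = "trail", cov = c("weight", "endpoint_lost")),
    trail_wf_ratio = list(rec = "trail",
                          cov = c("log_wf_ratio", "endpoint_lost"))
  )
  qap <- list()
  for (i in seq_along(nest_tests)) {
    tname <- names(nest_tests)[i]
    spec_i <- nest_tests[[i]]
    recs <- if (spec_i$rec == "nest") nest_records else trail_records
    qap[[tname]] <- try_stage(paste0("qap_", tname), {
      suppressMessages(qap_cox(
        recs, spec_i$cov, covariate = spec_i$cov[1],
        colony = config$colony_term, ties = config$ties, B = config$B,
        tail = config$tail, seed = config$seed + i))
    })
  }
  qap <- qap[!vapply(qap, is.null, TRUE)]
  qap_summary <- bind_rows(purrr::imap(qap, function(q, nm) {
    tidy(q) |> mutate(test = nm, seed = q$seed, .before = 1L)
  }))

  bud_effects <- c(
    bud_flow = "betweenness", bud_d_flow = "d_betweenness",
    bud_wf_ratio = "log_wf_ratio", bud_d_wf_ratio = "d_wf_ratio",
    bud_size = "log_size", bud_d_size = "d_size_z",
    bud_tree_dist = "tree_dist", bud_canopy = "canopy",
    bud_season = "season")
  aod <- purrr::imap(bud_effects, function(eff, nm) {
    try_stage(paste0("aod_", nm), {
      founder_aod(budding_data, eff, config$policy) |>
        mutate(test = nm, .before = 1L)
    })
  })
  aod <- bind_rows(aod[!vapply(aod, is.null, TRUE)])

  curves <- try_stage("curves", {
    fit <- suppressMessages(fit_extended_cox(
      nest_records, "betweenness", config$colony_term, config$ties))
    survival_curve(nest_records, fit, tibble(
      betweenness = c(0.1, 0.5, 0.9),
      label = c("low flow (0.1)", "medium flow (0.5)",
                "high flow (0.9)")))
  })

  report_lines <- c(
    "dynamic nest-network analysis report",
    sprintf("maps: %d  nests(rows): %s  trails(rows): %s  events: %s",
            sum(vapply(colonies, function(s) length(s$maps), 1L)),
            if (is.null(nest_records)) "NA" else nrow(nest_records),
            if (is.null(trail_records)) "NA" else nrow(trail_records),
            if (is.null(events)) "NA" else nrow(events)),
    sprintf("seed: %d  B: %d  tail: %s  ties: %s  policy: %s",
            config$seed, config$B, config$tail, config$ties,
            config$policy),
    "",
    "survival (QAP extended Cox):",
    purrr::imap_chr(qap, function(q, nm) {
      sprintf("  %-20s z = %8.4f  n = %4d  B = %5d  seed = %d  p = %.4g",
              nm, q$observed_stat, q$n, q$B_ok, q$seed, q$p_value)
    }),
    "",
    "budding (binomial GLMM analysis of deviance):",
    if (nrow(aod)) {
      sprintf("  %-20s chisq = %8.4f  df = %d  n = %4d  p = %.4g",
              aod$test, aod$chisq, aod$df, aod$n, aod$p)
    } else {
      "  (none)"
    },
    if (length(failures)) {
      c("", "FAILED STAGES:",
        paste0("  ", names(failures), ": ", unlist(failures)))
    } else {
      character(0)
    }
  )

  bundle <- list(
    config = config,
    provenance = list(seed = config$seed,
                      # the output location is not part of the analysis:
                      # reruns into different directories must hash alike
                      config_hash = rlang::hash(
                        unclass(config)[names(config) != "out_dir"]),
                      input_hash = rlang::hash(
                        purrr::map(colonies, function(s) {
                          purrr::map(s$maps, function(m) {
                            list(m$nodes, m$trails)
                          })
                        }))),
    colonies = colonies, metrics = metrics, events = events,
    nest_records = nest_records, trail_records = trail_records,
    budding_data = budding_data, qap = qap, qap_summary = qap_summary,
    aod = aod, curves = curves, report_lines = report_lines,
    failures = failures)

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' Write a pipeline results bundle to a text-file directory
#'
#' Writes `report.txt`, `results.json` (provenance, configuration, QAP
#' and analysis-of-deviance summaries, failure manifest), `curves.csv`,
#' `survival_records.csv`, `budding_data.csv` and one GraphML file per
#' colony map. Called automatically by [run_pipeline()] when the
#' configuration has an `out_dir`.
#'
#' @param bundle A results bundle from [run_pipeline()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$report_lines, file.path(dir, "report.txt"))
  jsonlite::write_json(list(
    provenance = bundle$provenance,
    config = unclass(bundle$config)[
      !names(bundle$config) %in% c("sim", "out_dir")],
    sim = unclass(bundle$config$sim),
    qap = bundle$qap_summary,
    aod = bundle$aod,
    failures = bundle$failures
  ), file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, force = TRUE)
  if (!is.null(bundle$curves)) {
    readr::write_csv(bundle$curves, file.path(dir, "curves.csv"),
                     progress = FALSE)
  }
  if (!is.null(bundle$nest_records)) {
    readr::write_csv(bundle$nest_records,
                     file.path(dir, "survival_records.csv"),
                     progress = FALSE)
  }
  if (!is.null(bundle$budding_data)) {
    readr::write_csv(bundle$budding_data,
                     file.path(dir, "budding_data.csv"), progress = FALSE)
  }
  gdir <- file.path(dir, "graphml")
  dir.create(gdir, showWarnings = FALSE)
  for (s in bundle$colonies) {
    for (m in s$maps) {
      write_colony_graphml(m, file.path(
        gdir, paste0(m$colony_id, "_", m$timepoint, ".graphml")))
    }
  }
  invisible(dir)
}
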