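# End-to-end orchestration with plain-TSV intermediates: each stage reads
# and writes ordinary tables, so any stage can be re-run and tested in
# isolation, and a fixed seed makes the whole run byte-reproducible.

#' Assemble a run configuration
#'
#' @param simulation A [simulation_config()].
#' @param map A [chromosome_map()].
#' @param min_depth,min_var Filtering thresholds (see [apply_depth_filter()],
#'   [apply_variance_filter()]).
#' @param segmentation A [segmentation_config()].
#' @param categorizer A [categorizer_config()].
#' @param pericentric_pad Pericentric window padding for division calls, bp.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = simulation_config(),
                       map = ndj_chr2_map(),
                       min_depth = 8, min_var = 0.01,
                       segmentation = segmentation_config(),
                       categorizer = categorizer_config(),
                       pericentric_pad = 1e6) {
  structure(list(simulation = simulation, map = map,
                 min_depth = min_depth, min_var = min_var,
                 segmentation = segmentation, categorizer = categorizer,
                 pericentric_pad = pericentric_pad),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `simulation` (fields of
#' [simulation_config()]), `map` (inline chromosome-map structure or path to
#' a map YAML), `min_depth`, `min_var`, `segmentation`, `categorizer`,
#' `pericentric_pad`. Missing keys take the package defaults.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the one in the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation
  if (!is.null(seed)) sim_args$seed <- seed
  sim <- do.call(simulation_config, if (is.null(sim_args)) list() else sim_args)
  map <- if (is.null(y$map)) {
    ndj_chr2_map()
  } else if (is.character(y$map)) {
    read_chromosome_map(y$map)
  } else {
    chromosome_map_from_list(y$map)
  }
  seg <- do.call(segmentation_config,
                 if (is.null(y$segmentation)) list() else y$segmentation)
  cat_ <- do.call(categorizer_config,
                  if (is.null(y$categorizer)) list() else y$categorizer)
  run_config(simulation = sim, map = map,
             min_depth = if (is.null(y$min_depth)) 8 else y$min_depth,
             min_var = if (is.null(y$min_var)) 0.01 else y$min_var,
             segmentation = seg, categorizer = cat_,
             pericentric_pad = if (is.null(y$pericentric_pad)) 1e6 else y$pericentric_pad)
}

#' Run the full pipeline: simulate, filter, call, classify, summarize
#'
#' Stages: (1) forward-simulate the cohort and write the counts and truth
#' tables; (2) apply the depth and population-variance filters and write the
#' filtered counts plus a filter report; (3) segment every sample's track
#' and write crossover calls; (4) classify division, monosomy-rescue status
#' and cause category per event; (5) compute cohort statistics
#' (crossover-class fractions with the MII adjustment, zero-crossover
#' chromosome fraction, arm association, category breakdown) and write a
#' machine-readable summary with a provenance block (seed, configuration,
#' package version). A failing stage aborts with the stage named.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the per-stage results (`sim`, `counts`,
#'   `events`, `calls`, `stats`, `summary`) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  map <- config$map

  sim <- stage("simulate", {
    s <- simulate_cohort(config$simulation, map)
    write_simulation(s, out_dir)
    s
  })

  counts <- stage("filter", {
    m <- counts_matrix(sim$counts)
    m <- apply_depth_filter(m, config$min_depth)
    if (length(unique(m$sample)) >= 2) {
      m <- apply_variance_filter(m, config$min_var)
    }
    write_tsv(m, file.path(out_dir, "counts_filtered.tsv"))
    rep_ <- filter_report(counts_matrix(sim$counts), m)
    jsonlite::write_json(rep_, file.path(out_dir, "filter_report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    m
  })

  cls <- stage("classify", {
    classify_events(counts, map, config$segmentation, config$categorizer,
                    config$pericentric_pad)
  })
  stage("write_calls", {
    write_tsv(cls$calls, file.path(out_dir, "calls.tsv"))
    write_tsv(cls$events, file.path(out_dir, "events.tsv"))
  })

  stats_ <- stage("stats", {
    ev <- cls$events
    if (nrow(ev) > 0) {
      arms <- arm_names(map)
      arm_counts <- do.call(rbind, lapply(arms, function(nm) {
        data.frame(class = ev$division, n_co = ev[[paste0("n_calls_", nm)]])
      }))
      arm_counts <- arm_counts[!is.na(arm_counts$class), ]
      list(
        co_class_fractions = if (nrow(arm_counts)) co_class_fractions(arm_counts) else NULL,
        zero_co_fraction_by_division = vapply(
          split(ev, ev$division),
          function(s) zero_co_chromosome_fraction(s), 0),
        arm_association = arm_association(data.frame(
          class = ev$division,
          left_co = ev[[paste0("n_calls_", arms[1])]],
          right_co = ev[[paste0("n_calls_", arms[length(arms)])]])),
        category_breakdown = category_breakdown(ev),
        division_table = as.list(table(ev$division))
      )
    } else {
      list(co_class_fractions = NULL, zero_co_fraction_by_division = NULL,
           arm_association = NULL, category_breakdown = NULL,
           division_table = NULL)
    }
  })

  summary_ <- stage("summarize", {
    s <- list(
      provenance = list(
        package = "ndjmap",
        version = as.character(packageVersion("ndjmap")),
        seed = config$simulation$seed,
        n_events = config$simulation$n_events,
        mode_mixture = as.list(config$simulation$mode_mixture),
        min_depth = config$min_depth, min_var = config$min_var,
        switch_penalty = config$segmentation$switch_penalty,
        min_segment_snps = config$segmentation$min_segment_snps
      ),
      events = cls$events,
      stats = stats_
    )
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    s
  })

  invisible(list(sim = sim, counts = counts, events = cls$events,
                 calls = cls$calls, stats = stats_, summary = summary_,
                 out_dir = out_dir))
}
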