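# Study orchestration: one call runs simulate -> aggregate -> describe ->
# dispro and writes every report table plus a machine-readable run manifest.
# Identical config + seed gives byte-identical outputs.

#' Serialize / deserialize a synthetic spec as JSON
#'
#' @param spec A [synthetic_spec()].
#' @param path JSON path.
#' @return `write_synthetic_spec` returns `path` invisibly;
#'   `read_synthetic_spec` returns a `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  payload <- list(
    mode = spec$mode, seed = spec$seed, other_pt_name = spec$other_pt_name,
    drugs = lapply(spec$drugs, function(d) {
      list(n_icsrs = d$n_icsrs,
           conditions = lapply(d$conditions, function(cc) {
             out <- list(outcomes = as.list(cc$outcomes))
             if (!is.null(cc$pt_weights)) out$pt_weights <- as.list(cc$pt_weights)
             out
           }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  drugs <- lapply(p$drugs, function(d) {
    list(n_icsrs = d$n_icsrs,
         conditions = lapply(d$conditions, function(cc) {
           list(outcomes = unlist(cc$outcomes),
                pt_weights = if (!is.null(cc$pt_weights)) unlist(cc$pt_weights))
         }))
  })
  synthetic_spec(drugs, mode = p$mode, seed = p$seed,
                 other_pt_name = p$other_pt_name %||% "Nausea")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a pipeline run configuration
#'
#' Exactly one input source must be given: a synthetic spec (object, JSON path
#' or the string `"bevpan_fixture"` for the built-in study fixture), a
#' line-listing CSV, or an aggregate-table CSV (the latter skips stages that
#' need row-level data).
#'
#' @param out_dir Output directory for report tables and the manifest.
#' @param synthetic_spec A [synthetic_spec()], path to its JSON form, or
#'   `"bevpan_fixture"`.
#' @param line_listing Path to a line-listing CSV.
#' @param aggregate_table Path to an aggregate-table CSV.
#' @param targets Target drug names for the disproportionality stage.
#' @param comparators Comparator drug names (order preserved in outputs).
#' @param conditions Condition sets to screen, as a list of character vectors;
#'   each set yields one panel per target.
#' @param min_reports,z Signal-rule and interval parameters.
#' @param seed Seed overriding the spec's (synthetic input only); `NULL` keeps
#'   the spec's own seed.
#' @param force Overwrite existing output tables.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       synthetic_spec = NULL, line_listing = NULL,
                       aggregate_table = NULL,
                       targets = character(), comparators = character(),
                       conditions = list("resistance", "ineffectiveness"),
                       min_reports = 5L, z = 1.96, seed = NULL,
                       force = FALSE) {
  sources <- c(synthetic = !is.null(synthetic_spec),
               line_listing = !is.null(line_listing),
               aggregates = !is.null(aggregate_table))
  if (sum(sources) != 1L) {
    stop("exactly one input source must be set (got ", sum(sources), ")",
         call. = FALSE)
  }
  if (!is.list(conditions)) conditions <- as.list(conditions)
  structure(list(out_dir = out_dir, synthetic_spec = synthetic_spec,
                 line_listing = line_listing,
                 aggregate_table = aggregate_table,
                 targets = targets, comparators = comparators,
                 conditions = conditions,
                 min_reports = as.integer(min_reports), z = z,
                 seed = seed, force = isTRUE(force)),
            class = "run_config")
}

#' Load a pipeline configuration from JSON
#'
#' JSON mirror of [run_config()]; fields use the same names, with the input
#' source under `input: {type, path}` (`type` one of `synthetic`,
#' `line_listing`, `aggregate_table`; for `synthetic`, `path` may be
#' `"bevpan_fixture"`).
#'
#' @param path JSON config path.
#' @param ... Overrides applied on top of the file values (argument name =
#'   [run_config()] argument).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$input$type)) stop("config is missing input.type", call. = FALSE)
  args <- list(
    out_dir = p$out_dir %||% ".",
    targets = p$targets %||% character(),
    comparators = p$comparators %||% character(),
    min_reports = p$min_reports %||% 5L,
    z = p$z %||% 1.96,
    seed = p$seed,
    force = p$force %||% FALSE
  )
  if (!is.null(p$conditions)) args$conditions <- as.list(p$conditions)
  args[[switch(p$input$type,
               synthetic = "synthetic_spec",
               line_listing = "line_listing",
               aggregate_table = "aggregate_table",
               stop("unknown input.type: ", p$input$type, call. = FALSE))]] <-
    p$input$path
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(run_config, args)
}

resolve_spec <- function(x) {
  if (inherits(x, "synthetic_spec")) return(x)
  if (identical(x, "bevpan_fixture")) return(bevpan_fixture())
  read_synthetic_spec(x)
}

pipeline_write <- function(x, path, force) {
  if (file.exists(path) && !force) {
    stop("output exists (use force = TRUE to overwrite): ", path,
         call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full study pipeline
#'
#' Loads or generates the input data, aggregates it, computes the descriptive
#' tables and the disproportionality panels, and writes everything under
#' `config$out_dir` together with `manifest.json` recording inputs, seed,
#' package version, row counts, the dictionary checksum, and the completed
#' stages. Identical config and seed give byte-identical outputs. If a stage
#' fails, the manifest is still written with the failed stage recorded.
#'
#' @param config A `run_config` (or path to its JSON form).
#' @param stages Subset of `c("simulate", "aggregate", "describe", "dispro")`;
#'   later stages read this run's earlier outputs, so each stage also composes
#'   on disk across separate calls.
#' @param dictionary Dictionary tibble.
#' @return Named list of output paths (the manifest under `$manifest`),
#'   invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "aggregate", "describe",
                                    "dispro"),
                         dictionary = meddra_dictionary()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if ("dispro" %in% stages && length(config$comparators) == 0L) {
    stop("dispro stage requested but comparator list is empty", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  manifest <- list(
    package = "rorsignal",
    version = as.character(utils::packageVersion("rorsignal")),
    dictionary_md5 = unname(tools::md5sum(
      system.file("extdata", "meddra_conditions.csv", package = "rorsignal")
    )),
    parameters = list(min_reports = config$min_reports, z = config$z,
                      conditions = config$conditions,
                      targets = config$targets,
                      comparators = config$comparators),
    stages = list()
  )
  out <- function(name) file.path(config$out_dir, name)
  failed <- NULL

  run_stage <- function(name, fun) {
    if (!is.null(failed)) return(invisible(NULL))
    res <- tryCatch({fun(); "ok"},
                    error = function(e) {
                      failed <<- list(stage = name, message = conditionMessage(e))
                      "failed"
                    })
    manifest$stages[[name]] <<- res
  }

  dataset <- NULL
  aggs <- NULL

  # -- input / simulate ------------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(config$synthetic_spec)) {
      spec <- resolve_spec(config$synthetic_spec)
      if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
      manifest$input <<- list(type = "synthetic", mode = spec$mode,
                              seed = spec$seed)
      if ("simulate" %in% stages) {
        dataset <<- generate_icsr(spec, dictionary)
        path <- out("line_listing.csv")
        if (file.exists(path) && !config$force) {
          stop("output exists (use force = TRUE to overwrite): ", path,
               call. = FALSE)
        }
        write_line_listing(dataset, path)
        paths$line_listing <<- path
      }
    } else if (!is.null(config$line_listing)) {
      manifest$input <<- list(type = "line_listing",
                              path = config$line_listing)
      dataset <<- read_line_listing(config$line_listing, dictionary)
    } else {
      manifest$input <<- list(type = "aggregate_table",
                              path = config$aggregate_table)
      aggs <<- read_aggregate_table(config$aggregate_table)
    }
  })

  # -- aggregate -------------------------------------------------------------
  run_stage("aggregate", function() {
    if (is.null(aggs)) {
      if (is.null(dataset)) {
        path <- out("line_listing.csv")
        if (!file.exists(path)) {
          stop("missing upstream line listing: ", path, call. = FALSE)
        }
        dataset <<- read_line_listing(path, dictionary)
      }
      aggs <<- aggregate_icsr(dataset, dictionary)
    }
    manifest$rows <<- list(
      adr_rows = if (!is.null(dataset)) nrow(dataset$records) else NA,
      drugs = length(unique(aggs$drug))
    )
    paths$aggregates <<- pipeline_write(aggs, out("aggregates.csv"),
                                        config$force)
  })

  # -- describe --------------------------------------------------------------
  if ("describe" %in% stages) run_stage("describe", function() {
    if (is.null(dataset)) {
      stop("describe stage needs row-level data ",
           "(synthetic or line-listing input)", call. = FALSE)
    }
    desc <- describe_dataset(dataset, dictionary)
    for (nm in names(desc)) {
      paths[[nm]] <<- pipeline_write(desc[[nm]], out(paste0(nm, ".csv")),
                                     config$force)
    }
  })

  # -- disproportionality ----------------------------------------------------
  if ("dispro" %in% stages) run_stage("dispro", function() {
    if (is.null(aggs)) {
      path <- out("aggregates.csv")
      if (!file.exists(path)) {
        stop("missing upstream aggregate table: ", path, call. = FALSE)
      }
      aggs <<- read_aggregate_table(path)
    }
    targets <- if (length(config$targets) > 0) config$targets else
      setdiff(unique(aggs$drug), config$comparators)
    panels <- dplyr::bind_rows(lapply(targets, function(tg) {
      dplyr::bind_rows(lapply(config$conditions, function(cond) {
        run_panel(aggs, tg, setdiff(config$comparators, tg), cond,
                  z = config$z, min_reports = config$min_reports)
      }))
    }))
    tmp <- out("signal_table.csv")
    if (file.exists(tmp) && !config$force) {
      stop("output exists (use force = TRUE to overwrite): ", tmp,
           call. = FALSE)
    }
    write_signal_table(panels, tmp)
    paths$signal_table <<- tmp
  })

  if (!is.null(failed)) manifest$failed <- failed
  manifest_path <- out("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path
  if (!is.null(failed)) {
    stop("pipeline stage '", failed$stage, "' failed: ", failed$message,
         call. = FALSE)
  }
  invisible(paths)
}
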