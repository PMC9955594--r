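# Reproducibility shell: scenario files, tabular report writers, round-trip
# readers. Interchange formats are tidy CSV (with "#" metadata comment
# lines) and JSON (metadata + records).

.report_table <- function(x) {
  if (inherits(x, "simulation_report")) {
    tidy(x)
  } else if (inherits(x, "d_walk_stats")) {
    x$absorption
  } else if (is.data.frame(x)) {
    as_tibble(x)
  } else {
    abort("don't know how to serialise this object; expected a data frame or report.")
  }
}

.report_meta <- function(x) {
  meta <- list(package = "castvote",
               version = as.character(utils::packageVersion("castvote")))
  if (inherits(x, "simulation_report")) {
    meta$seed <- x$seed
    meta$n_runs <- x$n_runs
    meta$abilities <- x$profile$ability
    meta$max_abs_d <- x$max_abs_d
    meta$cascade_rate <- x$cascade_rate
  } else if (inherits(x, "d_walk_stats")) {
    meta$seed <- x$seed
    meta$n_runs <- x$n_runs
    meta$max_abs_d <- x$max_abs_d
    meta$prop_absorbed <- x$prop_absorbed
  } else if (inherits(x, "seq_result")) {
    meta$partition <- attr(x, "partition")
    meta$abilities <- x$ability
  }
  meta
}

#' Write a result to CSV or JSON
#'
#' CSV output carries the run metadata (seed, profile, package version) as
#' leading `#` comment lines above a tidy table; JSON output nests the same
#' metadata beside the records. Floats are written at 12 significant
#' digits; column order is fixed by the result type.
#'
#' @param x A result object: a [simulate_chain()] report, a
#'   [d_walk_statistics()] summary, a [run_sequence()] result, or any tidy
#'   data frame (grids, curves).
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_report(exact_curve(generate_profile("equal", n = 3, p = 0.7)), tmp)
#' @export
write_report <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  tab <- .report_table(x)
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.double), ~ signif(.x, 12)))
  meta <- .report_meta(x)
  if (format == "csv") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (key in names(meta)) {
      writeLines(sprintf("# %s: %s", key,
                         jsonlite::toJSON(meta[[key]], auto_unbox = TRUE)), con)
    }
    utils::write.table(tab, con, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(metadata = meta, records = tab), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read back a written report
#'
#' Inverse of [write_report()]: JSON reports round-trip to a list with
#' `metadata` and a `records` tibble; CSV reports return the tibble with
#' the parsed metadata attached as attribute `"metadata"`.
#'
#' @param path File written by [write_report()].
#' @param format `"csv"` or `"json"`; defaults to the file extension.
#' @return A list (`json`) or tibble (`csv`).
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    out <- jsonlite::fromJSON(path)
    out$records <- as_tibble(out$records)
    out
  } else {
    lines <- readLines(path)
    meta_lines <- grep("^# ", lines, value = TRUE)
    meta <- lapply(meta_lines, function(l) {
      kv <- sub("^# ([^:]+): ", "", l)
      jsonlite::fromJSON(kv)
    })
    names(meta) <- sub("^# ([^:]+):.*$", "\\1", meta_lines)
    tab <- as_tibble(utils::read.csv(text = lines[!grepl("^# ", lines)]))
    attr(tab, "metadata") <- meta
    tab
  }
}

.resolve_profile <- function(x) {
  if (is.numeric(x)) {
    ability_profile(x)
  } else if (is.list(x) && !is.null(x$abilities)) {
    ability_profile(unlist(x$abilities))
  } else if (is.list(x) && !is.null(x$kind)) {
    do.call(generate_profile, x)
  } else {
    abort("profile must be abilities (numeric / `abilities:` list) or a `kind:` spec.")
  }
}

#' Read a scenario file
#'
#' Scenarios are YAML files describing one run or sweep: a `command` (one
#' of `run`, `simulate`, `exact`, `sweep`, `three-person`, `expert`,
#' `effective-n`), a profile (inline `abilities`, or a `kind:` block passed
#' to [generate_profile()]), and command parameters (`runs`, `seed`, `tol`,
#' grids, `primaries`, ...).
#'
#' @param path Path to a YAML scenario file.
#' @return A list of class `scenario_spec`.
#' @export
read_scenario <- function(path) {
  spec <- .fix_yaml_keys(yaml::read_yaml(path))
  if (is.null(spec$command)) abort("scenario file must name a `command`.")
  structure(spec, class = "scenario_spec")
}

# YAML 1.1 reads a bare `n:` key as boolean FALSE (and `y:` as TRUE);
# restore the intended key names recursively.
.fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    nm[nm == "TRUE"] <- "y"
    names(x) <- nm
  }
  lapply(x, .fix_yaml_keys)
}

#' Execute a scenario
#'
#' Dispatches a [read_scenario()] spec (or an equivalent list) to the
#' corresponding package function and returns its result. Used by the
#' command-line wrapper; callable directly for scripted sweeps.
#'
#' @param spec A `scenario_spec` or plain list with at least `command`.
#' @return The result object of the dispatched computation.
#' @export
run_scenario <- function(spec) {
  cmd <- spec$command
  tol <- spec$tol %||% 1e-9
  prof <- if (!is.null(spec$profile)) .resolve_profile(spec$profile)
  switch(cmd,
    run = {
      primaries <- unlist(spec$primaries)
      if (is.null(primaries)) {
        if (!is.null(spec$seed)) set.seed(spec$seed)
        z <- rbinom(nrow(prof), 1L, prof$ability) == 1L
        # draw in the truth frame, then relabel so the first answer is "s"
        primaries <- ifelse(z == z[1], "s", "t")
      }
      run_sequence(prof, primaries, tol = tol)
    },
    simulate = simulate_chain(prof, n_runs = spec$runs %||% 10000L,
                              seed = spec$seed, tol = tol),
    exact = exact_curve(prof, tol = tol),
    sweep = {
      p_grid <- spec$p_grid %||% seq(0.55, 0.95, by = 0.05)
      n <- spec$n %||% 13L
      purrr::map_dfr(p_grid, function(p) {
        tibble(p = p, order = seq_len(n),
               performance = mean_performance_equal(p, seq_len(n)))
      })
    },
    `three-person` = three_person_grid(p3 = spec$p3 %||% 0.7,
                                       step = spec$grid %||% 0.01),
    expert = {
      n_max <- spec$n_max %||% 13L
      tibble(
        order = seq_len(n_max),
        performance = expert_performance(spec$p, spec$q, seq_len(n_max),
                                         aware = isTRUE(spec$aware))
      )
    },
    `effective-n` = effective_voters_curve(spec$p_grid %||% seq(0.51, 0.99, by = 0.01)),
    abort(sprintf("unknown command '%s'.", cmd))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
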