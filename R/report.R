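#' Read and validate a QA configuration file
#'
#' YAML configuration shared by the command-line workflows. Recognized
#' blocks: `geometry` (`sad_cm`, `sid_cm`, `pixel_pitch_mm`,
#' `central_pixel_uv`, `panel_extent_cm`), `analysis` (`excluded_angles`,
#' `gamma` criteria fields, `isocentre_tolerance_mm`), `chamber` (`n_dw`,
#' `k_bmq`, `c_b`, `voltage_ratio`), `output_dir`, `seed`. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A list with class `qa_config`; `$geometry` is a
#'   [machine_geometry()].
#' @export
read_qa_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(cfg, c("geometry", "analysis", "chamber", "output_dir", "seed"),
             "config")
  g <- cfg$geometry %||% list()
  check_keys(g, c("sad_cm", "sid_cm", "pixel_pitch_mm", "central_pixel_uv",
                  "panel_extent_cm"), "geometry block")
  geom <- machine_geometry(
    sad_cm = g$sad_cm %||% 143.5,
    sid_cm = g$sid_cm %||% 215.25,
    pixel_pitch_mm = g$pixel_pitch_mm %||% 0.25,
    panel_extent_cm = as.numeric(unlist(g$panel_extent_cm %||% c(22, 9.5))),
    central_pixel = if (!is.null(g$central_pixel_uv)) {
      as.numeric(unlist(g$central_pixel_uv))
    }
  )
  a <- cfg$analysis %||% list()
  check_keys(a, c("excluded_angles", "gamma", "isocentre_tolerance_mm"),
             "analysis block")
  if (!is.null(a$gamma)) {
    check_keys(a$gamma, c("dose_diff_pct", "dta_mm", "normalization",
                          "suppression_pct", "interpolation_step"),
               "gamma block")
  }
  ch <- cfg$chamber %||% list()
  check_keys(ch, c("n_dw", "k_bmq", "c_b", "k_bq", "voltage_ratio"),
             "chamber block")
  structure(list(geometry = geom, analysis = a, chamber = ch,
                 output_dir = cfg$output_dir %||% ".",
                 seed = as.integer(cfg$seed %||% 1L)),
            class = "qa_config")
}

#' Structured QA report
#'
#' A serializable record of one QA analysis: the test name, a digest of the
#' inputs, the parameters, the numeric results and the verdict against the
#' configured tolerance. Round-trips losslessly through JSON.
#'
#' @param test Test name, e.g. `"mv_isocentre"`.
#' @param inputs Character vector describing/digesting the inputs.
#' @param parameters Named list of analysis parameters.
#' @param results Named list of numeric results.
#' @param passed Logical verdict, or NA when no tolerance applies.
#' @param tolerance Named list describing the tolerance used.
#' @return An object of class `qa_report`.
#' @export
qa_report <- function(test, inputs = character(), parameters = list(),
                      results = list(), passed = NA, tolerance = list()) {
  structure(
    list(test = test,
         inputs = as.character(inputs),
         parameters = parameters,
         results = results,
         passed = passed,
         tolerance = tolerance,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         software = paste0("mrlqa ", as.character(utils::packageVersion("mrlqa")))),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %s [%s]\n", x$test,
              if (isTRUE(x$passed)) "PASS" else if (isFALSE(x$passed)) "FAIL"
              else "no tolerance"))
  for (nm in names(x$results)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(format(x$results[[nm]], digits = 6), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a QA report as JSON
#' @param report A [qa_report()].
#' @param path JSON file path.
#' @return `write_qa_report()` returns `path` invisibly; `read_qa_report()`
#'   a [qa_report()].
#' @export
write_qa_report <- function(report, path) {
  stopifnot(inherits(report, "qa_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qa_report
#' @export
read_qa_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$inputs <- as.character(x$inputs)
  structure(x, class = "qa_report")
}
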