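#' Read a digestion or glucose time series from CSV
#'
#' Expects a header with a `time_min` column plus either `C_percent`
#' (returns a [digestion_curve()]) or `glucose_mg` (returns a
#' [glucose_series()]; supply `TS`/`GF`). Comma and tab dialects are
#' auto-detected; the decimal separator is always the point. Malformed
#' rows are rejected with line-numbered messages rather than coerced.
#'
#' @param path Path to the CSV/TSV file.
#' @param TS,GF Total starch and free glucose (mg), used only for glucose
#'   series.
#' @return A [digestion_curve()] or [glucose_series()], depending on the
#'   columns present.
#' @export
read_timeseries <- function(path, TS = 200, GF = 0) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  header <- trimws(strsplit(lines[1L], sep, fixed = TRUE)[[1L]])
  if (!"time_min" %in% header) {
    stop("missing `time_min` column in ", path, call. = FALSE)
  }
  value_col <- intersect(c("C_percent", "glucose_mg"), header)
  if (length(value_col) == 0L) {
    stop("need a `C_percent` or `glucose_mg` column in ", path,
         call. = FALSE)
  }
  value_col <- value_col[1L]
  it <- match("time_min", header)
  iv <- match(value_col, header)
  n <- length(lines) - 1L
  times <- numeric(n)
  values <- numeric(n)
  for (i in seq_len(n)) {
    cells <- trimws(strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]])
    if (length(cells) < max(it, iv)) {
      stop(sprintf("line %d: too few columns", i + 1L), call. = FALSE)
    }
    tv <- suppressWarnings(as.numeric(cells[c(it, iv)]))
    if (any(is.na(tv))) {
      stop(sprintf("line %d: non-numeric cell", i + 1L), call. = FALSE)
    }
    times[i] <- tv[1L]
    values[i] <- tv[2L]
  }
  dup <- which(duplicated(times))
  if (length(dup)) {
    stop(sprintf("line %d: duplicate time %g min", dup[1L] + 1L,
                 times[dup[1L]]), call. = FALSE)
  }
  ord <- order(times)
  times <- times[ord]
  values <- values[ord]
  if (value_col == "C_percent") {
    digestion_curve(times, values)
  } else {
    glucose_series(times, values, TS = TS, GF = GF)
  }
}

#' Read a two-column x/y text file (SAXS, FTIR, XRD)
#'
#' Reads whitespace- or comma-separated two-column numeric data, skipping
#' `#` comment lines, and returns the kind-appropriate container with
#' range checks: SAXS data outside the usual 0.010--0.25 1/Angstrom window
#' warn (not error); FTIR/XRD spectra are checked to cover their analysis
#' windows by the downstream metrics, not here.
#'
#' @param path Path to the text file.
#' @param kind One of `"saxs"`, `"ftir"`, `"xrd"`.
#' @return A [scattering_curve()] (`kind = "saxs"`) or [spectrum_xy()].
#' @export
read_xy <- function(path, kind = c("saxs", "ftir", "xrd")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  xy <- matrix(NA_real_, length(lines), 2L)
  for (i in seq_along(lines)) {
    cells <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1L]]
    if (length(cells) < 2L) {
      stop(sprintf("line %d: need two columns", i), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(cells[1:2]))
    if (any(is.na(v))) {
      stop(sprintf("line %d: non-numeric cell", i), call. = FALSE)
    }
    xy[i, ] <- v
  }
  if (kind == "saxs") {
    if (min(xy[, 1L]) < 0.010 || max(xy[, 1L]) > 0.25) {
      warning("q outside the usual 0.010-0.25 1/Angstrom window",
              call. = FALSE)
    }
    scattering_curve(xy[, 1L], xy[, 2L])
  } else {
    spectrum_xy(xy[, 1L], xy[, 2L])
  }
}

#' Write an analysis report as JSON (plus summary text)
#'
#' Serializes a result bundle to JSON at full precision together with a
#' provenance manifest (seed, package version, timestamp), and writes a
#' short human-readable summary next to it. Re-reading the JSON reproduces
#' every numeric value exactly.
#'
#' @param results Named list of results; `los_result`, `fraction_result`,
#'   `lamellar_result`, `fractal_result` and `texture_result` objects are
#'   flattened to plain named lists, other values are passed through.
#' @param path Output path for the JSON document; a `.txt` summary with
#'   the same stem is written alongside.
#' @param seed Seed recorded in the manifest (default NA).
#' @return Invisibly, the list that was serialized.
#' @export
write_report <- function(results, path, seed = NA) {
  stopifnot(is.list(results), length(results) > 0L)
  flatten <- function(x) {
    if (inherits(x, "los_result")) {
      list(
        classical = unclass(x$classical),
        phases = lapply(x$phases, unclass),
        breakpoints = x$breakpoints,
        dropped_points = x$dropped_points,
        AUC = x$AUC, HI = x$HI, EGI = x$EGI,
        auc_source = x$auc_source, t0 = x$t0, tf = x$tf
      )
    } else if (is.object(x)) {
      unclass(x)
    } else {
      x
    }
  }
  doc <- list(
    manifest = list(
      package = "starchkinetics",
      version = as.character(utils::packageVersion("starchkinetics")),
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    results = lapply(results, flatten)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  summary_path <- sub("\\.json$", ".txt", path)
  if (identical(summary_path, path)) summary_path <- paste0(path, ".txt")
  lines <- c(
    sprintf("starchkinetics report (seed %s)", seed),
    vapply(names(doc$results), function(nm) {
      x <- doc$results[[nm]]
      vals <- unlist(x)
      num <- suppressWarnings(as.numeric(vals))
      shown <- ifelse(is.na(num), as.character(vals), sprintf("%.2f", num))
      paste0(nm, ": ", paste(names(vals), shown, sep = "=",
                             collapse = ", "))
    }, character(1L))
  )
  writeLines(lines, summary_path)
  invisible(doc)
}
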