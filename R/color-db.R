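#' Per-channel summary statistics of a stream of Lab readings
#'
#' Characterizes a surface (or reference green) by the mean, median, sample
#' standard deviation (n-1 denominator), minimum and maximum of each Lab
#' channel. The standard deviations are the "noise" terms that drive the
#' statistical existence rule and the minimum-coverage model.
#'
#' @param readings A data frame or matrix with columns `L`, `a`, `b`
#'   (extra columns such as `t_s`, `x_cm` are ignored), or a list of
#'   [lab()] colors.
#' @return An object of class `"lab_stats"`: a list with `lab_color`
#'   elements `mean`, `median`, `min`, `max`, a named numeric `sigma`
#'   (per-channel sample sd) and the reading count `n`.
#' @examples
#' r <- data.frame(L = c(11.2, 11.4), a = c(4.7, 4.9), b = c(20.0, 20.2))
#' lab_summary(r)
#' @export
lab_summary <- function(readings) {
  m <- readings_matrix(readings)
  if (nrow(m) < 2L)
    stop("need at least 2 readings to estimate a standard deviation, got ",
         nrow(m), call. = FALSE)
  lab_stats(
    mean   = lab(mean(m[, "L"]), mean(m[, "a"]), mean(m[, "b"])),
    median = lab(stats::median(m[, "L"]), stats::median(m[, "a"]),
                 stats::median(m[, "b"])),
    sigma  = c(L = stats::sd(m[, "L"]), a = stats::sd(m[, "a"]),
               b = stats::sd(m[, "b"])),
    min    = lab(min(m[, "L"]), min(m[, "a"]), min(m[, "b"])),
    max    = lab(max(m[, "L"]), max(m[, "a"]), max(m[, "b"])),
    n      = nrow(m))
}

readings_matrix <- function(readings) {
  if (is.list(readings) && !is.data.frame(readings) &&
      all(vapply(readings, inherits, logical(1), "lab_color"))) {
    m <- do.call(rbind, lapply(readings, unclass))
  } else {
    readings <- as.data.frame(readings)
    miss <- setdiff(c("L", "a", "b"), names(readings))
    if (length(miss))
      stop("readings lack column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- as.matrix(readings[, c("L", "a", "b")])
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("L", "a", "b")
  if (any(!is.finite(m)))
    stop("readings contain non-finite Lab values", call. = FALSE)
  m
}

#' Low-level constructor for Lab summary statistics
#'
#' Assembles a `"lab_stats"` object from already-known summaries, e.g. when
#' transcribing a published characterization table rather than summarizing
#' raw readings. Any channel where `min <= mean <= max` fails is recorded in
#' the `suspect` field (transcription errors in printed tables do occur) --
#' flagged, never silently corrected.
#'
#' @param mean,min,max `lab_color` values (`min`/`max` optional).
#' @param median Optional `lab_color`.
#' @param sigma Optional named non-negative numeric `(L, a, b)`; when
#'   absent, [sigma_of()] falls back to the quarter-range convention.
#' @param n Optional reading count.
#' @param suspect Character vector of channel annotations carried through
#'   from a transcription source.
#' @return A `"lab_stats"` object.
#' @export
lab_stats <- function(mean, sigma = NULL, median = NULL, min = NULL,
                      max = NULL, n = NULL, suspect = character()) {
  mean <- as_lab(mean)
  if (!is.null(median)) median <- as_lab(median)
  if (!is.null(min)) min <- as_lab(min)
  if (!is.null(max)) max <- as_lab(max)
  if (!is.null(sigma)) {
    sigma <- sigma[c("L", "a", "b")]
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop("sigma components must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(min) && !is.null(max)) {
    for (ch in c("L", "a", "b")) {
      if (min[[ch]] > mean[[ch]] || mean[[ch]] > max[[ch]]) {
        flag <- sprintf("channel %s: min/mean/max ordering violated (%g, %g, %g)",
                        ch, min[[ch]], mean[[ch]], max[[ch]])
        if (!any(grepl(paste0("channel ", ch), suspect)))
          suspect <- c(suspect, flag)
      }
    }
  }
  structure(list(mean = mean, median = median, sigma = sigma,
                 min = min, max = max, n = n, suspect = suspect),
            class = "lab_stats")
}

#' @export
print.lab_stats <- function(x, ...) {
  cat("<lab_stats>", if (!is.null(x$n)) sprintf("n=%d", x$n), "\n")
  cat(sprintf("  mean : L=%.2f a=%.2f b=%.2f\n",
              x$mean[["L"]], x$mean[["a"]], x$mean[["b"]]))
  s <- sigma_of(x)
  cat(sprintf("  sigma: L=%.3f a=%.3f b=%.3f%s\n", s[["L"]], s[["a"]], s[["b"]],
              if (is.null(x$sigma)) " (quarter-range convention)" else ""))
  if (length(x$suspect))
    cat("  suspect:", paste(x$suspect, collapse = "; "), "\n")
  invisible(x)
}

#' Per-channel noise level of a characterized surface
#'
#' Returns the stored per-channel standard deviation when the
#' characterization carries one. When it does not (published reference-green
#' tables often print only mean/min/max), the quarter-range convention
#' `sigma = |max - min| / 4` is used per channel -- for small samples the
#' range spans roughly four standard deviations. This fallback is a stated
#' convention of the package, not ground truth, and can be overridden by
#' supplying `sigma` in [lab_stats()].
#'
#' @param stats A `"lab_stats"` object.
#' @return Named non-negative numeric `(L, a, b)`.
#' @export
sigma_of <- function(stats) {
  stopifnot(inherits(stats, "lab_stats"))
  if (!is.null(stats$sigma)) return(stats$sigma)
  if (is.null(stats$min) || is.null(stats$max))
    stop("lab_stats carries neither sigma nor min/max; noise level unknown",
         call. = FALSE)
  # |max - min|: transcribed tables may print the two rows swapped
  abs(unclass(stats$max) - unclass(stats$min)) / 4
}

#' Background surface class
#'
#' A named background surface -- `anthropogenic` (pavement, asphalt, gravel,
#' ...) or `natural` (bare soil, grassland) -- together with its Lab
#' characterization. Detection always happens *against* a surface class.
#'
#' @param name Surface label.
#' @param category `"anthropogenic"` or `"natural"`.
#' @param stats A `"lab_stats"` characterization.
#' @param table4_label Optional alternative label used in coverage-table
#'   output.
#' @return An object of class `"surface_class"`.
#' @export
surface_class <- function(name, category, stats, table4_label = NULL) {
  category <- match.arg(category, c("anthropogenic", "natural"))
  stopifnot(is.character(name), length(name) == 1L,
            inherits(stats, "lab_stats"))
  structure(list(name = name, category = category, stats = stats,
                 table4_label = table4_label),
            class = "surface_class")
}

#' Reference green tone
#'
#' A named reference green (a plant color card or a calibrated crop/weed
#' color) with its Lab characterization.
#'
#' @param name Green label.
#' @param stats A `"lab_stats"` characterization.
#' @return An object of class `"green_tone"`.
#' @export
green_tone <- function(name, stats) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(stats, "lab_stats"))
  structure(list(name = name, stats = stats), class = "green_tone")
}

#' Calibrate a background from a plant-free reading stream
#'
#' Field deployment starts by recording the bare background on a spot known
#' to be free of weeds; the resulting characterization is what every
#' detector compares readings against. This wraps [lab_summary()] into a
#' [surface_class()] and records provenance (reading count, timestamp).
#'
#' @inheritParams lab_summary
#' @inheritParams surface_class
#' @return A `"surface_class"` whose stats carry `n` and a `calibrated_at`
#'   attribute.
#' @examples
#' set.seed(1)
#' r <- data.frame(L = rnorm(200, 11.32, 0.13), a = rnorm(200, 4.81, 0.70),
#'                 b = rnorm(200, 20.10, 0.47))
#' calibrate_background(r, "plot 3 soil", "natural")
#' @export
calibrate_background <- function(readings, name, category) {
  s <- lab_summary(readings)
  attr(s, "calibrated_at") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  surface_class(name, category, s)
}

lab_to_list <- function(x) list(L = x[["L"]], a = x[["a"]], b = x[["b"]])
lab_from_list <- function(x, what) {
  if (is.null(x)) return(NULL)
  miss <- setdiff(c("L", "a", "b"), names(x))
  if (length(miss))
    stop("database field '", what, "' lacks component(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lab(x$L, x$a, x$b)
}

stats_to_list <- function(s) {
  out <- list(mean = lab_to_list(s$mean))
  if (!is.null(s$median)) out$median <- lab_to_list(s$median)
  if (!is.null(s$sigma))  out$sigma  <- as.list(s$sigma[c("L", "a", "b")])
  if (!is.null(s$min))    out$min    <- lab_to_list(s$min)
  if (!is.null(s$max))    out$max    <- lab_to_list(s$max)
  if (!is.null(s$n))      out$n      <- s$n
  if (length(s$suspect))  out$suspect <- as.list(s$suspect)
  out
}

stats_from_list <- function(x, what) {
  if (is.null(x$mean))
    stop("database entry '", what, "' lacks required field 'mean'",
         call. = FALSE)
  sigma <- NULL
  if (!is.null(x$sigma)) {
    miss <- setdiff(c("L", "a", "b"), names(x$sigma))
    if (length(miss))
      stop("database entry '", what, "' sigma lacks component(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    sigma <- c(L = as.numeric(x$sigma$L), a = as.numeric(x$sigma$a),
               b = as.numeric(x$sigma$b))
  }
  lab_stats(mean   = lab_from_list(x$mean, paste0(what, "$mean")),
            sigma  = sigma,
            median = lab_from_list(x$median, paste0(what, "$median")),
            min    = lab_from_list(x$min, paste0(what, "$min")),
            max    = lab_from_list(x$max, paste0(what, "$max")),
            n      = if (!is.null(x[["n"]])) as.integer(x[["n"]]),
            suspect = as.character(unlist(x[["suspect"]])))
}

#' Read and write color databases
#'
#' A color database bundles characterized background surfaces and reference
#' green tones as JSON:
#' `{"surfaces": [{"name", "category", "mean": {"L","a","b"}, "sigma": ...,
#' "min": ..., "max": ..., "n"}], "greens": [...]}`.
#' `save_color_db()` followed by `load_color_db()` is the identity on
#' values. Schema violations are rejected with the offending field named.
#'
#' @param path Path of the JSON database file.
#' @param db A `"color_db"` object (see [color_db()]).
#' @return `load_color_db()` returns a `"color_db"`; `save_color_db()`
#'   returns `path` invisibly.
#' @seealso [lab_db()] for the packaged reference database.
#' @export
load_color_db <- function(path) {
  if (!file.exists(path))
    stop("color database not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  surfaces <- lapply(raw$surfaces, function(s) {
    if (is.null(s$name)) stop("surface entry lacks 'name'", call. = FALSE)
    if (is.null(s$category))
      stop("surface '", s$name, "' lacks 'category'", call. = FALSE)
    surface_class(s$name, s$category, stats_from_list(s, s$name),
                  table4_label = s$table4_label)
  })
  greens <- lapply(raw$greens, function(g) {
    if (is.null(g$name)) stop("green entry lacks 'name'", call. = FALSE)
    green_tone(g$name, stats_from_list(g, g$name))
  })
  color_db(surfaces, greens)
}

#' @rdname load_color_db
#' @export
save_color_db <- function(db, path) {
  stopifnot(inherits(db, "color_db"))
  out <- list(
    surfaces = lapply(db$surfaces, function(s) {
      c(list(name = s$name, category = s$category),
        stats_to_list(s$stats),
        if (!is.null(s$table4_label)) list(table4_label = s$table4_label))
    }),
    greens = lapply(db$greens, function(g) {
      c(list(name = g$name), stats_to_list(g$stats))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble a color database
#'
#' @param surfaces List of [surface_class()] objects.
#' @param greens List of [green_tone()] objects.
#' @return An object of class `"color_db"` with surfaces and greens
#'   retrievable by name.
#' @export
color_db <- function(surfaces = list(), greens = list()) {
  stopifnot(all(vapply(surfaces, inherits, logical(1), "surface_class")),
            all(vapply(greens, inherits, logical(1), "green_tone")))
  names(surfaces) <- vapply(surfaces, `[[`, character(1), "name")
  names(greens)   <- vapply(greens, `[[`, character(1), "name")
  structure(list(surfaces = surfaces, greens = greens), class = "color_db")
}

#' @export
print.color_db <- function(x, ...) {
  cat(sprintf("<color_db> %d surfaces, %d greens\n",
              length(x$surfaces), length(x$greens)))
  for (s in x$surfaces)
    cat(sprintf("  %-22s (%s)\n", s$name, s$category))
  for (g in x$greens) cat(sprintf("  %-22s (green tone)\n", g$name))
  invisible(x)
}

#' Packaged reference color database
#'
#' The database shipped with the package: ten characterized background
#' surfaces (seven anthropogenic: grey paving stones, asphalt, gravel,
#' stone steps, fine chippings, red paving stones, sandy path; three
#' natural: arable land, grassland, grassland with dew) and four reference
#' green tones from bright to dark green. Backgrounds carry measured
#' per-channel mean and standard deviation; greens carry median, mean,
#' minimum and maximum (their standard deviation is estimated by the
#' quarter-range convention, see [sigma_of()]). Cells whose transcribed
#' min/max ordering is inconsistent are flagged in `suspect`.
#'
#' @return A `"color_db"` object.
#' @examples
#' db <- lab_db()
#' db$surfaces[["Arable land"]]$stats
#' @export
lab_db <- function() {
  path <- system.file("extdata", "reference_colors.json",
                      package = "labweed", mustWork = TRUE)
  load_color_db(path)
}

#' Lookup helpers for database entries
#'
#' @param db A `"color_db"`.
#' @param name Entry name.
#' @return The matching `"surface_class"` or `"green_tone"`; error when
#'   absent.
#' @export
db_surface <- function(db, name) {
  stopifnot(inherits(db, "color_db"))
  s <- db$surfaces[[name]]
  if (is.null(s))
    stop("no surface named '", name, "' in database (have: ",
         paste(names(db$surfaces), collapse = ", "), ")", call. = FALSE)
  s
}

#' @rdname db_surface
#' @export
db_green <- function(db, name) {
  stopifnot(inherits(db, "color_db"))
  g <- db$greens[[name]]
  if (is.null(g))
    stop("no green tone named '", name, "' in database (have: ",
         paste(names(db$greens), collapse = ", "), ")", call. = FALSE)
  g
}

#' Read a raw Lab reading stream from CSV
#'
#' Reading streams use columns `t_s` (seconds), `x_cm` (position along the
#' track), `L`, `a`, `b`; the header is mandatory, decimal point, comma
#' separator. Extra columns are preserved.
#'
#' @param path CSV file path.
#' @return A data frame with at least the five canonical columns.
#' @export
read_readings_csv <- function(path) {
  if (!file.exists(path))
    stop("readings file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  miss <- setdiff(c("t_s", "x_cm", "L", "a", "b"), names(df))
  if (length(miss))
    stop("readings CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("readings CSV is empty: ", path, call. = FALSE)
  bad <- which(!stats::complete.cases(df[, c("L", "a", "b")]) |
                 !apply(is.finite(as.matrix(df[, c("L", "a", "b")])), 1, all))
  if (length(bad))
    stop("malformed Lab values in ", path, " at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  df
}
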