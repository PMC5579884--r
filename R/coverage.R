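#' Minimum required relative coverage of the measuring spot
#'
#' Predicts, for one background x green x channel combination, the
#' smallest fraction of the measuring spot a plant must cover to be
#' detectable by the statistical existence rule. Under area-weighted linear
#' color mixing, a plant covering fraction `f` displaces the channel mean
#' by `f * |ch_Obj - ch_BG|`; the statistical rule fires once that
#' displacement reaches `sigma_BG + sigma_Obj`, so
#' \deqn{A_{ch} = 100 \cdot \frac{\sigma_{ch,BG} + \sigma_{ch,Obj}}
#'                              {|ch_{Obj} - ch_{BG}|}}
#' in percent of the spot area. The denominator is the absolute difference
#' of the channel means: only this form is dimensionally consistent with
#' the existence rule, and it reproduces the published coverage values for
#' the bright-green/luminance cells.
#'
#' The virtual channel `d` uses the means of `|a - b|` on both sides and a
#' conservative noise propagation `sigma_d = sigma_a + sigma_b` (an upper
#' bound on the sd of `a - b` for any correlation).
#'
#' @param bg Background characterization (`lab_stats` or `surface_class`).
#' @param obj Object characterization (`lab_stats` or `green_tone`);
#'   sigma via [sigma_of()] (quarter-range fallback).
#' @param channel One of `"L"`, `"a"`, `"b"`, `"d"`.
#' @return A list of class `"coverage_cell"` with `background`, `green`,
#'   `channel` and `A` -- the required coverage in percent, unrounded.
#'   `A` is `Inf` (with a warning) when the channel means coincide:
#'   the channel then carries no signal at any coverage. `A` may exceed
#'   100, meaning undetectable even at full coverage.
#' @examples
#' db <- lab_db()
#' cell <- required_coverage(db_surface(db, "Arable land"),
#'                           db_green(db, "Green 1"), "L")
#' round(cell$A, 1) # 0.5 percent of the spot
#' @export
required_coverage <- function(bg, obj, channel = c("L", "a", "b", "d")) {
  channel <- match.arg(channel)
  bg_name <- if (inherits(bg, "surface_class")) bg$name else NA_character_
  obj_name <- if (inherits(obj, "green_tone")) obj$name else NA_character_
  bg <- bg_stats(bg); obj <- bg_stats(obj)
  s_bg <- sigma_of(bg); s_obj <- sigma_of(obj)
  if (channel == "d") {
    mean_diff <- abs(virtual_d(obj$mean) - virtual_d(bg$mean))
    noise <- (s_bg[["a"]] + s_bg[["b"]]) + (s_obj[["a"]] + s_obj[["b"]])
  } else {
    mean_diff <- abs(obj$mean[[channel]] - bg$mean[[channel]])
    noise <- s_bg[[channel]] + s_obj[[channel]]
  }
  if (mean_diff == 0) {
    warning("channel ", channel, " means coincide; required coverage is ",
            "infinite (channel carries no signal)", call. = FALSE)
    A <- Inf
  } else {
    A <- 100 * noise / mean_diff
  }
  structure(list(background = bg_name, green = obj_name,
                 channel = channel, A = A),
            class = "coverage_cell")
}

#' Full coverage table over a color database
#'
#' Computes [required_coverage()] for every background x green x channel
#' combination, in the deterministic order backgrounds (database order) x
#' greens x channels.
#'
#' @param db A `"color_db"`, or `backgrounds`/`greens` lists given
#'   separately.
#' @param backgrounds,greens Optional explicit lists of [surface_class()] /
#'   [green_tone()] entries (default: all of `db`).
#' @param channels Channels to tabulate, default `c("L","a","b","d")`.
#' @return A long-format data frame with columns `background`, `green`,
#'   `channel`, `A` (unrounded percent). For the packaged database this is
#'   a 10 x 4 x 4 = 160-row grid.
#' @seealso [format_coverage_table()] for the wide layout with one-decimal
#'   rounding.
#' @export
coverage_table <- function(db = NULL, backgrounds = NULL, greens = NULL,
                           channels = c("L", "a", "b", "d")) {
  if (!is.null(db)) {
    stopifnot(inherits(db, "color_db"))
    if (is.null(backgrounds)) backgrounds <- db$surfaces
    if (is.null(greens)) greens <- db$greens
  }
  if (!length(backgrounds) || !length(greens))
    stop("coverage_table needs at least one background and one green",
         call. = FALSE)
  channels <- match.arg(channels, c("L", "a", "b", "d"), several.ok = TRUE)
  rows <- list()
  for (bg in backgrounds) for (g in greens) for (ch in channels) {
    cell <- required_coverage(bg, g, ch)
    rows[[length(rows) + 1L]] <- data.frame(
      background = bg$name, green = g$name, channel = ch, A = cell$A)
  }
  do.call(rbind, rows)
}

#' Wide coverage-table layout
#'
#' Reshapes the long [coverage_table()] grid to the conventional printed
#' layout: one row per background, column blocks `<green>.<channel>`,
#' values rounded to one decimal. Background rows use the `table4_label`
#' alias when the database provides one.
#'
#' @param tab Long data frame from [coverage_table()].
#' @param db Optional `"color_db"` supplying row-label aliases.
#' @param digits Rounding for display, default one decimal.
#' @return A wide data frame, first column `background`.
#' @export
format_coverage_table <- function(tab, db = NULL, digits = 1) {
  stopifnot(all(c("background", "green", "channel", "A") %in% names(tab)))
  bgs <- unique(tab$background)
  greens <- unique(tab$green)
  channels <- unique(tab$channel)
  out <- data.frame(background = bgs, stringsAsFactors = FALSE)
  if (!is.null(db)) {
    out$background <- vapply(bgs, function(nm) {
      s <- db$surfaces[[nm]]
      if (!is.null(s) && !is.null(s$table4_label)) s$table4_label else nm
    }, character(1))
  }
  for (g in greens) for (ch in channels) {
    col <- vapply(bgs, function(bgn) {
      tab$A[tab$background == bgn & tab$green == g & tab$channel == ch][1L]
    }, numeric(1))
    out[[paste(g, ch, sep = ".")]] <- round(col, digits)
  }
  out
}

#' Measuring-spot geometry
#'
#' @param diameter Spot diameter in cm (5 cm gives the usual ~20 cm^2
#'   spot; 10 cm gives ~80 cm^2).
#' @return A list of class `"spot_geometry"` with `diameter` (cm) and
#'   `area` (cm^2).
#' @export
spot_geometry <- function(diameter) {
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0)
    stop("spot diameter must be a single positive number", call. = FALSE)
  structure(list(diameter = diameter, area = pi * (diameter / 2)^2),
            class = "spot_geometry")
}

#' Smallest detectable plant area for a spot size
#'
#' Converts a required relative coverage (percent of the spot) into the
#' absolute plant area it corresponds to for a given lens: a coverage
#' requirement of 3% on a 5 cm spot (~20 cm^2) means plants of about
#' 0.6 cm^2 and larger are detectable; on a 10 cm spot (~80 cm^2), about
#' 2.4 cm^2.
#'
#' @param A_percent Required coverage in percent (>= 0).
#' @param spot A [spot_geometry()], or a diameter in cm.
#' @param digits Rounding of the reported area, default one decimal.
#' @return Plant area in cm^2.
#' @examples
#' min_plant_area(3.0, 5)  # 0.6 cm^2
#' min_plant_area(3.0, 10) # 2.4 cm^2
#' @export
min_plant_area <- function(A_percent, spot, digits = 1) {
  if (!is.numeric(A_percent) || any(!is.finite(A_percent)) ||
      any(A_percent < 0))
    stop("A_percent must be non-negative", call. = FALSE)
  if (!inherits(spot, "spot_geometry")) spot <- spot_geometry(spot)
  round(A_percent / 100 * spot$area, digits)
}
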