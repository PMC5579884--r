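#' CIE-Lab color triple
#'
#' Constructs a single CIE-Lab color value. `L` is the luminance channel
#' (0 = black, 100 = white); `a` is the green--red coloration axis
#' (negative = green, positive = red) and `b` the blue--yellow axis
#' (negative = blue, positive = yellow), both nominally in \[-128, 127\].
#'
#' Values outside the nominal ranges are accepted with a warning rather than
#' rejected: field sensors drift out of calibration and a recognition
#' pipeline should keep running on slightly out-of-gamut readings.
#' Non-finite values are always rejected.
#'
#' @param L Luminance, nominally in \[0, 100\].
#' @param a Green--red coloration, nominally in \[-128, 127\].
#' @param b Blue--yellow coloration, nominally in \[-128, 127\].
#' @return A named numeric vector of class `"lab_color"` with components
#'   `L`, `a`, `b`.
#' @examples
#' lab(11.32, 4.81, 20.10)   # mean reflection of bare arable land
#' lab(44.80, -15.24, 44.39) # a bright leaf green
#' @export
lab <- function(L, a, b) {
  vals <- c(L = as.numeric(L)[1L], a = as.numeric(a)[1L], b = as.numeric(b)[1L])
  if (length(L) != 1L || length(a) != 1L || length(b) != 1L)
    stop("lab() takes scalar L, a, b values", call. = FALSE)
  if (!all(is.finite(vals)))
    stop("Lab components must be finite numbers, got (",
         paste(format(vals), collapse = ", "), ")", call. = FALSE)
  if (vals[["L"]] < 0 || vals[["L"]] > 100)
    warning("L = ", format(vals[["L"]]),
            " is outside the nominal luminance range [0, 100]", call. = FALSE)
  if (any(vals[c("a", "b")] < -128) || any(vals[c("a", "b")] > 127))
    warning("a/b coloration outside the nominal range [-128, 127]",
            call. = FALSE)
  structure(vals, class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("<Lab> L=%.2f a=%.2f b=%.2f\n", x[["L"]], x[["a"]], x[["b"]]))
  invisible(x)
}

as_lab <- function(x) {
  if (inherits(x, "lab_color")) return(x)
  if (is.numeric(x) && length(x) == 3L) {
    if (!is.null(names(x)) && all(c("L", "a", "b") %in% names(x)))
      return(lab(x[["L"]], x[["a"]], x[["b"]]))
    return(lab(x[1L], x[2L], x[3L]))
  }
  stop("expected a lab_color or a numeric length-3 (L, a, b) vector",
       call. = FALSE)
}

#' Color difference Delta-E between two Lab colors
#'
#' The Euclidean distance in CIE-Lab space,
#' \deqn{\Delta E = \sqrt{(L_1-L_2)^2 + (a_1-a_2)^2 + (b_1-b_2)^2},}
#' the standard measure of perceived color difference. Detection of a plant
#' on a background reduces to asking whether the Delta-E between a reading
#' and the calibrated background color exceeds a threshold.
#'
#' @param c1,c2 `lab_color` values (or numeric `(L, a, b)` triples).
#' @return Non-negative scalar distance.
#' @seealso [delta_channels()] for per-channel differences,
#'   [delta_e_category()] for the perceptual interpretation.
#' @examples
#' field  <- lab(11.32, 4.81, 20.10)
#' green1 <- lab(44.80, -15.24, 44.39)
#' delta_e(field, green1) # ~46: a completely different color
#' @export
delta_e <- function(c1, c2) {
  c1 <- as_lab(c1); c2 <- as_lab(c2)
  sqrt(sum((unclass(c1) - unclass(c2))^2))
}

#' Per-channel color differences between two Lab colors
#'
#' Splits the color difference into its channel contributions: absolute
#' differences `dL`, `da`, `db`, the overall `dE` (identical to
#' [delta_e()]), and the virtual d-channel value `|a - b|` of each input
#' (`d_bg` for `c1`, `d_reading` for `c2`). Analyzing channels individually
#' tells a detector *why* two colors differ -- a luminance change, a shift
#' toward green, or both -- which is what the multistage classifier exploits.
#'
#' @inheritParams delta_e
#' @return A named numeric vector of class `"delta_vector"` with components
#'   `dE`, `dL`, `da`, `db`, `d_bg`, `d_reading`, all non-negative and
#'   satisfying `dE^2 == dL^2 + da^2 + db^2`.
#' @examples
#' delta_channels(lab(10, 0, 0), lab(7, 0, 0)) # pure luminance difference
#' @export
delta_channels <- function(c1, c2) {
  c1 <- as_lab(c1); c2 <- as_lab(c2)
  d <- abs(unclass(c1) - unclass(c2))
  structure(
    c(dE = sqrt(sum(d^2)), dL = d[["L"]], da = d[["a"]], db = d[["b"]],
      d_bg = virtual_d(c1), d_reading = virtual_d(c2)),
    class = "delta_vector")
}

#' Virtual d-channel of a Lab color
#'
#' The auxiliary discrimination feature `d = |a - b|`, the absolute gap
#' between the two coloration axes. Green vegetation has strongly negative
#' `a` and often positive `b`, so its d value is large, whereas many mineral
#' backgrounds have `a` and `b` of the same sign and modest gap.
#'
#' @param c A `lab_color` (or numeric `(L, a, b)` triple).
#' @return Non-negative scalar `|a - b|`.
#' @examples
#' virtual_d(lab(11.32, 4.81, 20.10))   # 15.29
#' virtual_d(lab(44.80, -15.24, 44.39)) # 59.63
#' @export
virtual_d <- function(c) {
  c <- as_lab(c)
  abs(c[["a"]] - c[["b"]])
}

# Perceptual interpretation bands for Delta-E. Printed interval endpoints
# overlap ("0.0...0.5", "0.5...1.0"); resolved as half-open [lower, upper),
# last band unbounded, so the mapping is total and deterministic.
.delta_e_breaks <- c(0, 0.5, 1, 2, 4, 5, Inf)
.delta_e_labels <- c(
  "no to almost no difference",
  "difference may be noticeable to the trained eye",
  "weak perceptible color difference",
  "perceived color difference",
  "substantial difference in color, which is rarely tolerated",
  "high difference defined as a different color")

#' Perceptual category of a Delta-E value
#'
#' Maps a color difference to one of six conventional evaluation categories,
#' from "no to almost no difference" (below 0.5) to "high difference defined
#' as a different color" (above 5). Intervals are half-open
#' `[lower, upper)`; the last category is unbounded above.
#'
#' @param dE Non-negative color difference(s); vectorized.
#' @return Character vector of category labels.
#' @examples
#' delta_e_category(c(0.3, 1.5, 6))
#' @export
delta_e_category <- function(dE) {
  dE <- as.numeric(dE)
  if (any(!is.finite(dE) & !is.infinite(dE)))
    stop("dE must be numeric", call. = FALSE)
  if (any(dE < 0))
    stop("dE must be non-negative, got ", min(dE), call. = FALSE)
  idx <- findInterval(dE, .delta_e_breaks, left.open = FALSE)
  .delta_e_labels[pmin(idx, length(.delta_e_labels))]
}
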