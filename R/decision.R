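#' Detection thresholds
#'
#' Bundles the thresholds used by the color-similarity detectors: `t_dE`
#' for the overall color difference and `t_dL`, `t_da`, `t_db` for the
#' per-channel detectors. Any subset may be set; `combine` controls whether
#' the channel detector fires when *any* set channel exceeds its threshold
#' (the default, most sensitive) or only when *all* do.
#'
#' @param t_dE,t_dL,t_da,t_db Non-negative thresholds, `NULL` = unset.
#' @param combine `"any"` or `"all"`.
#' @return An object of class `"thresholds"`.
#' @seealso [threshold_preset()] for field-proven scenario presets.
#' @export
thresholds <- function(t_dE = NULL, t_dL = NULL, t_da = NULL, t_db = NULL,
                       combine = c("any", "all")) {
  combine <- match.arg(combine)
  for (nm in c("t_dE", "t_dL", "t_da", "t_db")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L ||
                        !is.finite(v) || v < 0))
      stop(nm, " must be a single non-negative number", call. = FALSE)
  }
  structure(list(t_dE = t_dE, t_dL = t_dL, t_da = t_da, t_db = t_db,
                 combine = combine),
            class = "thresholds")
}

# Scenario presets for the Delta-E detector, as established in field trials:
# 5 for green objects on paved ground, 12 for artificial plants in a young
# wheat stand, 7 for broadleaf dock on grassland.
.presets <- list(
  "paved"          = 5,
  "wheat"          = 12,
  "grassland-dock" = 7)

#' Named threshold presets
#'
#' Returns a [thresholds()] object carrying the Delta-E threshold that
#' proved workable for a given field scenario: `"paved"` (green objects on
#' paved ground, threshold 5), `"wheat"` (young wheat stand, threshold 12,
#' higher because the crop itself is green), and `"grassland-dock"`
#' (broadleaf dock on grassland, threshold 7 -- a green-on-green task
#' driven mostly by luminance).
#'
#' @param name One of `"paved"`, `"wheat"`, `"grassland-dock"`.
#' @return A `"thresholds"` object with `t_dE` set.
#' @export
threshold_preset <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "' (available: ",
         paste(names(.presets), collapse = ", "), ")", call. = FALSE)
  thresholds(t_dE = .presets[[name]])
}

new_detection <- function(triggered, deltas, rule) {
  structure(list(detect = length(triggered) > 0L,
                 triggered = triggered, deltas = deltas, rule = rule),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection:%s> %s%s\n", x$rule,
              if (x$detect) "DETECT" else "no detection",
              if (x$detect) paste0(" [", paste(x$triggered, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Delta-E threshold detector
#'
#' The simplest detector: a plant (or any object) exists under the spot if
#' the color distance between the reading and the calibrated background
#' mean strictly exceeds the threshold `t$t_dE`. Readings exactly at the
#' threshold do not fire.
#'
#' @param reading A `lab_color` reading.
#' @param background A `"lab_stats"` background characterization (or a
#'   `"surface_class"`).
#' @param t A [thresholds()] object with `t_dE` set.
#' @return A `"detection"` with fields `detect`, `triggered` (subset of
#'   `E, L, a, b, d`), `deltas` (a `delta_vector`) and `rule`.
#' @export
detect_delta_e <- function(reading, background, t) {
  background <- bg_stats(background)
  stopifnot(inherits(t, "thresholds"))
  if (is.null(t$t_dE))
    stop("detect_delta_e requires t_dE to be set", call. = FALSE)
  d <- delta_channels(background$mean, as_lab(reading))
  new_detection(if (d[["dE"]] > t$t_dE) "E" else character(), d, "delta_e")
}

#' Per-channel threshold detector
#'
#' Compares each channel difference `|reading - background mean|` against
#' its own threshold (strictly greater). Channels without a threshold are
#' ignored. With `combine = "any"` one firing channel suffices; with
#' `"all"` every thresholded channel must fire. The triggered set always
#' records exactly the channels that exceeded their threshold.
#'
#' @inheritParams detect_delta_e
#' @param t A [thresholds()] with at least one of `t_dL`, `t_da`, `t_db`.
#' @return A `"detection"`.
#' @export
detect_channels <- function(reading, background, t) {
  background <- bg_stats(background)
  stopifnot(inherits(t, "thresholds"))
  chans <- c(L = "t_dL", a = "t_da", b = "t_db")
  set <- chans[!vapply(t[chans], is.null, logical(1))]
  if (!length(set))
    stop("detect_channels requires at least one of t_dL, t_da, t_db",
         call. = FALSE)
  d <- delta_channels(background$mean, as_lab(reading))
  fired <- vapply(names(set), function(ch) {
    d[[paste0("d", ch)]] > t[[set[[ch]]]]
  }, logical(1))
  ok <- if (t$combine == "any") any(fired) else all(fired)
  new_detection(if (ok) names(set)[fired] else character(), d, "channels")
}

#' Statistical existence rule
#'
#' A plant exists if, in at least one channel, the reading departs from the
#' background mean by at least the combined noise of background and object:
#' \deqn{|ch_{MA} - ch_{BG}| \ge \sigma_{ch,BG} + \sigma_{ch,Obj}}
#' for some channel `ch` in `{L, a, b}`. The rule needs no tuned threshold;
#' it derives its sensitivity from the calibrated noise levels, and the
#' triggered channels carry information usable for classification. The
#' comparison is `>=`, so a reading exactly at the noise boundary counts as
#' a detection.
#'
#' @inheritParams detect_delta_e
#' @param object A `"lab_stats"` (or `"green_tone"`) characterization of
#'   the expected object; its noise enters the rule. Greens without a
#'   stored sigma use the quarter-range convention (see [sigma_of()]).
#' @return A `"detection"`.
#' @export
detect_statistical <- function(reading, background, object) {
  background <- bg_stats(background)
  object <- bg_stats(object)
  reading <- as_lab(reading)
  s_bg <- sigma_of(background)
  s_obj <- sigma_of(object)
  d <- delta_channels(background$mean, reading)
  fired <- vapply(c("L", "a", "b"), function(ch) {
    d[[paste0("d", ch)]] >= s_bg[[ch]] + s_obj[[ch]]
  }, logical(1))
  new_detection(names(fired)[fired], d, "statistical")
}

bg_stats <- function(x) {
  if (inherits(x, "surface_class") || inherits(x, "green_tone")) return(x$stats)
  if (inherits(x, "lab_stats")) return(x)
  stop("expected a lab_stats, surface_class or green_tone", call. = FALSE)
}

#' Classify the green tone of a detected reading
#'
#' Second stage of the multistage crop/weed differentiation: once a reading
#' is flagged as suspicious, its *direction* of departure from the
#' background identifies the plant color independently of plant size.
#' Under area-weighted linear color mixing, a spot covered by a fraction
#' `f` of a green `g` reads
#' `background + f * (green_g - background)`, so the difference vector
#' `v = reading - background mean` is colinear with
#' `u_g = green_g mean - background mean` whatever `f > 0` is. The
#' classifier therefore returns the candidate green maximizing the cosine
#' similarity between `v` and `u_g`; the comparison of channels *relative
#' to each other* removes the influence of object size.
#'
#' @inheritParams detect_delta_e
#' @param greens A list of [green_tone()] candidates (or a `"color_db"`,
#'   whose greens are used).
#' @param use_d If `TRUE`, the virtual d-channel difference participates as
#'   a fourth vector component. Off by default: `d` is a function of `a`
#'   and `b` and adds no independent information in this similarity.
#' @return A list with `green` (winning candidate name), `score` (cosine
#'   similarity in \[-1, 1\]) and `scores` (all candidates). A reading equal
#'   to the background mean has no direction and is rejected; exact ties
#'   between candidates (within 1e-12) raise an error naming them.
#' @examples
#' db <- lab_db()
#' bg <- db_surface(db, "Grassland")$stats
#' g3 <- db_green(db, "Green 3")$stats
#' reading <- mixed_color(bg, g3, f = 0.1, noise = FALSE)
#' classify_green(reading, bg, db)$green # "Green 3" at any coverage
#' @export
classify_green <- function(reading, background, greens, use_d = FALSE) {
  background <- bg_stats(background)
  reading <- as_lab(reading)
  if (inherits(greens, "color_db")) greens <- greens$greens
  if (!length(greens))
    stop("need at least one candidate green tone", call. = FALSE)
  stopifnot(all(vapply(greens, inherits, logical(1), "green_tone")))

  feat <- function(col) {
    v <- unclass(as_lab(col))
    if (use_d) c(v, d = virtual_d(col)) else v
  }
  v <- feat(reading) - feat(background$mean)
  nv <- sqrt(sum(v^2))
  if (nv == 0)
    stop("reading equals the background mean; no direction to classify",
         call. = FALSE)
  scores <- vapply(greens, function(g) {
    u <- feat(g$stats$mean) - feat(background$mean)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(NA_real_) # green indistinguishable from background
    sum(v * u) / (nv * nu)
  }, numeric(1))
  names(scores) <- vapply(greens, `[[`, character(1), "name")
  best <- which.max(scores)
  tied <- which(scores >= scores[best] - 1e-12)
  if (length(tied) > 1L)
    stop("ambiguous green classification; tied candidates: ",
         paste(names(scores)[tied], collapse = ", "), call. = FALSE)
  list(green = names(scores)[best], score = unname(scores[best]),
       scores = scores)
}

#' Spray command from a detection
#'
#' Translates a detection into a valve command for the chosen operating
#' mode. In *positive* recognition, any detected plant is sprayed (weed
#' destruction on bare or paved ground). In *negative* recognition the
#' detector is tuned to the crop and spraying is suppressed where the crop
#' is detected -- everything else (inter-row ground and weeds) is sprayed.
#'
#' @param d A `"detection"`.
#' @param mode `"positive"` or `"negative"`.
#' @return A list of class `"spray_command"` with fields `spray` and
#'   `mode`.
#' @export
spray_decision <- function(d, mode = c("positive", "negative")) {
  stopifnot(inherits(d, "detection"))
  mode <- match.arg(mode)
  structure(list(spray = if (mode == "positive") d$detect else !d$detect,
                 mode = mode),
            class = "spray_command")
}

#' Run a detector over a transect or reading stream
#'
#' Applies one of the detectors reading-by-reading and returns a decision
#' table ready for [evaluate_detection()] or CSV export.
#'
#' @param readings A data frame with columns `L`, `a`, `b` (and optionally
#'   `t_s`, `x_cm`), e.g. a [make_transect()] result or a
#'   [read_readings_csv()] stream.
#' @param background Background characterization (`lab_stats` or
#'   `surface_class`).
#' @param detector `"delta_e"`, `"channels"` or `"statistical"`.
#' @param t [thresholds()] for the threshold detectors.
#' @param object Object characterization for the statistical rule.
#' @param mode Spray mode passed to [spray_decision()].
#' @return A data frame with one row per reading: `t_s`, `x_cm`, `dE`,
#'   `dL`, `da`, `db`, `detect`, `triggered` (channels joined with `+`),
#'   `spray`.
#' @export
decide_stream <- function(readings, background,
                          detector = c("delta_e", "channels", "statistical"),
                          t = NULL, object = NULL,
                          mode = c("positive", "negative")) {
  detector <- match.arg(detector)
  mode <- match.arg(mode)
  m <- readings_matrix(readings)
  n <- nrow(m)
  out <- data.frame(
    t_s = if ("t_s" %in% names(readings)) readings$t_s else NA_real_,
    x_cm = if ("x_cm" %in% names(readings)) readings$x_cm else NA_real_,
    dE = numeric(n), dL = numeric(n), da = numeric(n), db = numeric(n),
    detect = logical(n), triggered = character(n), spray = logical(n))
  for (i in seq_len(n)) {
    r <- lab(m[i, "L"], m[i, "a"], m[i, "b"])
    dec <- switch(detector,
      delta_e = detect_delta_e(r, background, t),
      channels = detect_channels(r, background, t),
      statistical = {
        if (is.null(object))
          stop("the statistical detector needs an object characterization",
               call. = FALSE)
        detect_statistical(r, background, object)
      })
    out$dE[i] <- dec$deltas[["dE"]]; out$dL[i] <- dec$deltas[["dL"]]
    out$da[i] <- dec$deltas[["da"]]; out$db[i] <- dec$deltas[["db"]]
    out$detect[i] <- dec$detect
    out$triggered[i] <- paste(dec$triggered, collapse = "+")
    out$spray[i] <- spray_decision(dec, mode)$spray
  }
  out
}
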