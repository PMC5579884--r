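#' Intersection area of two discs
#'
#' Exact circle--circle intersection (lens) area, used to compute how much
#' of the measuring spot a disc-shaped plant covers at each sensor
#' position. Degenerate configurations are handled analytically: disjoint
#' discs give 0, containment gives the full area of the smaller disc.
#'
#' @param c1,c2 Disc centers as `(x, y)` numeric pairs, cm.
#' @param r1,r2 Disc radii, cm (> 0).
#' @return Intersection area in cm^2, in `[0, pi * min(r1, r2)^2]`.
#' @export
disc_overlap_area <- function(c1, r1, c2, r2) {
  if (!is.numeric(r1) || !is.numeric(r2) || r1 <= 0 || r2 <= 0)
    stop("disc radii must be positive", call. = FALSE)
  d <- sqrt(sum((as.numeric(c1) - as.numeric(c2))^2))
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  # lens formula; clamp acos arguments against fp round-off
  a1 <- r1^2 * acos(max(-1, min(1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(max(-1, min(1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  k <- (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)
  area <- a1 + a2 - 0.5 * sqrt(max(0, k))
  min(max(area, 0), pi * min(r1, r2)^2)
}

#' Area-weighted mixed color of a partially covered spot
#'
#' The simulator's central model: a measuring spot covered by a fraction
#' `f` of an object over a background reads the area-weighted blend
#' `(1 - f) * bg_mean + f * green_mean` per channel. Optional Gaussian
#' channel noise with sd interpolating linearly between the two surfaces'
#' noise levels, `sigma = (1 - f) * sigma_bg + f * sigma_green`, is added
#' on top. This linear mixing is exactly the assumption under which the
#' statistical existence rule and the minimum-coverage model are
#' consistent with each other.
#'
#' Noise draws consume the current R random stream; seed it (or call from
#' [make_transect()], which seeds per scene) for reproducibility.
#'
#' @param bg,green `lab_stats` (or `surface_class`/`green_tone`)
#'   characterizations.
#' @param f Coverage fraction in `[0, 1]`.
#' @param noise Add Gaussian channel noise? Default `TRUE`.
#' @return A `lab_color` reading.
#' @export
mixed_color <- function(bg, green, f, noise = TRUE) {
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("coverage fraction f must be in [0, 1], got ", f, call. = FALSE)
  bg <- bg_stats(bg); green <- bg_stats(green)
  mu <- (1 - f) * unclass(bg$mean) + f * unclass(green$mean)
  if (noise) {
    s <- (1 - f) * sigma_of(bg) + f * sigma_of(green)
    mu <- mu + stats::rnorm(3L, 0, s)
  }
  suppressWarnings(lab(mu[["L"]], mu[["a"]], mu[["b"]]))
}

#' Scene specification for the transect simulator
#'
#' Describes one synthetic sensor run: a homogeneous background strewn
#' with disc-shaped objects, swept by a circular measuring spot travelling
#' along the track axis (`y = 0`) at constant speed with a fixed sampling
#' frequency. Defaults emulate the usual carrier setup: a 150 cm track at
#' 0.1 m/s sampled at 10 Hz, i.e. one reading per cm, with a 5 cm spot.
#'
#' @param background A [surface_class()] (or `lab_stats`).
#' @param objects A data frame with columns `center_x`, `center_y` (cm),
#'   `radius` (cm, > 0) and `green` (a list-column of [green_tone()]
#'   objects or a character vector resolved against `db`). May have zero
#'   rows.
#' @param spot_diameter Spot diameter, cm.
#' @param speed Forward speed, m/s.
#' @param frequency Sampling frequency, Hz.
#' @param track_length Track length, cm.
#' @param seed Integer seed for the per-scene noise stream.
#' @param noise Add Gaussian channel noise? Default `TRUE`.
#' @param db Optional `"color_db"` used to resolve green names.
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(background, objects = NULL, spot_diameter = 5,
                       speed = 0.1, frequency = 10, track_length = 150,
                       seed = 1L, noise = TRUE, db = NULL) {
  if (inherits(background, "lab_stats"))
    background <- surface_class("background", "natural", background)
  stopifnot(inherits(background, "surface_class"))
  for (nm in c("spot_diameter", "speed", "frequency", "track_length")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(nm, " must be a single positive number", call. = FALSE)
  }
  if (is.null(objects))
    objects <- data.frame(center_x = numeric(), center_y = numeric(),
                          radius = numeric())
  objects <- as.data.frame(objects)
  if (nrow(objects)) {
    miss <- setdiff(c("center_x", "center_y", "radius", "green"),
                    names(objects))
    if (length(miss))
      stop("objects lack column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (any(!is.finite(objects$radius)) || any(objects$radius <= 0))
      stop("object radii must be positive", call. = FALSE)
    if (is.character(objects$green)) {
      if (is.null(db))
        stop("green names in objects need a db to resolve against",
             call. = FALSE)
      objects$green <- I(lapply(objects$green, function(nm) db_green(db, nm)))
    }
    ok <- vapply(objects$green, inherits, logical(1), "green_tone")
    if (!all(ok))
      stop("objects$green must hold green_tone entries", call. = FALSE)
  }
  structure(list(background = background, objects = objects,
                 spot_diameter = spot_diameter, speed = speed,
                 frequency = frequency, track_length = track_length,
                 seed = as.integer(seed), noise = isTRUE(noise)),
            class = "scene_spec")
}

#' Simulate a sensor transect
#'
#' Sweeps the measuring spot along the track and produces one reading per
#' sampling instant: readings start at `x = 0` and advance by
#' `speed * 100 / frequency` cm (1 cm for the default 0.1 m/s at 10 Hz;
#' a 150 cm track yields 150 readings). Per reading, the ground-truth
#' coverage is the summed spot overlap of all objects divided by the spot
#' area (capped at 1; summation is the documented approximation for
#' overlapping objects), the reading color is the area-weighted
#' [mixed_color()] of the background with the *dominant* (largest-overlap)
#' object's green, and the dominant green's name is recorded. The noise
#' stream is seeded from the scene, so an identical `scene_spec` always
#' reproduces the identical transect.
#'
#' @param spec A [scene_spec()].
#' @return A data frame of class `"transect"` with columns `t_s`, `x_cm`,
#'   `L`, `a`, `b`, `truth_coverage`, `truth_green` (NA over bare
#'   background). The per-object overlap matrix (readings x objects, cm^2)
#'   is attached as attribute `"object_overlap"`, the spec as `"spec"`.
#' @export
make_transect <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  step <- spec$speed * 100 / spec$frequency # cm between readings
  n <- max(1L, floor(spec$track_length / step))
  x <- (seq_len(n) - 1L) * step
  t_s <- x / (spec$speed * 100)
  spot_r <- spec$spot_diameter / 2
  spot_area <- pi * spot_r^2
  n_obj <- nrow(spec$objects)
  overlap <- matrix(0, nrow = n, ncol = n_obj)
  if (n_obj) for (j in seq_len(n_obj)) {
    oc <- c(spec$objects$center_x[j], spec$objects$center_y[j])
    overlap[, j] <- vapply(x, function(xi)
      disc_overlap_area(c(xi, 0), spot_r, oc, spec$objects$radius[j]),
      numeric(1))
  }
  f <- pmin(1, rowSums(overlap) / spot_area)
  dominant <- if (n_obj) max.col(overlap, ties.method = "first") else
    integer(n)
  truth_green <- rep(NA_character_, n)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  m <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "a", "b")))
  bg <- spec$background$stats
  for (i in seq_len(n)) {
    if (n_obj && f[i] > 0) {
      g <- spec$objects$green[[dominant[i]]]
      truth_green[i] <- g$name
      col <- mixed_color(bg, g$stats, f[i], noise = spec$noise)
    } else {
      col <- mixed_color(bg, bg, 0, noise = spec$noise)
    }
    m[i, ] <- unclass(col)
  }
  out <- data.frame(t_s = t_s, x_cm = x, L = m[, "L"], a = m[, "a"],
                    b = m[, "b"], truth_coverage = f,
                    truth_green = truth_green)
  attr(out, "object_overlap") <- overlap
  attr(out, "spec") <- spec
  class(out) <- c("transect", "data.frame")
  out
}

#' Score a decision stream against transect ground truth
#'
#' Confusion counts per reading -- truth is `truth_coverage >
#' coverage_cutoff` -- and a per-object verdict: an object counts as
#' detected when at least one reading whose spot overlaps it fires.
#'
#' @param decisions Logical detection vector, or a [decide_stream()] data
#'   frame (its `detect` column is used).
#' @param transect A [make_transect()] result.
#' @param coverage_cutoff Coverage fraction above which a reading is truly
#'   "on object". Default 0: any overlap counts.
#' @return A list with `tp`, `fp`, `fn`, `tn`, `recall`, `precision`
#'   (reading-level), `object_detected` (logical per object) and
#'   `n_objects_detected`.
#' @export
evaluate_detection <- function(decisions, transect, coverage_cutoff = 0) {
  if (is.data.frame(decisions)) decisions <- decisions$detect
  decisions <- as.logical(decisions)
  stopifnot(inherits(transect, "transect"))
  if (length(decisions) != nrow(transect))
    stop("decision stream length (", length(decisions),
         ") does not match transect length (", nrow(transect), ")",
         call. = FALSE)
  truth <- transect$truth_coverage > coverage_cutoff
  tp <- sum(decisions & truth); fp <- sum(decisions & !truth)
  fn <- sum(!decisions & truth); tn <- sum(!decisions & !truth)
  overlap <- attr(transect, "object_overlap")
  object_detected <- if (!is.null(overlap) && ncol(overlap))
    vapply(seq_len(ncol(overlap)), function(j)
      any(decisions & overlap[, j] > 0), logical(1)) else logical()
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       object_detected = object_detected,
       n_objects_detected = sum(object_detected))
}

#' Transect CSV round trip
#'
#' Writes/reads a transect as CSV (`t_s, x_cm, L, a, b, truth_coverage,
#' truth_green`) with six-decimal numeric formatting; reading back a
#' written file reproduces the values at that precision.
#'
#' @param transect A transect data frame.
#' @param path CSV path.
#' @return `write_transect_csv()` returns `path` invisibly;
#'   `read_transect_csv()` returns a data frame.
#' @export
write_transect_csv <- function(transect, path) {
  df <- as.data.frame(transect)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transect_csv
#' @export
read_transect_csv <- function(path) {
  if (!file.exists(path))
    stop("transect file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE)
  miss <- setdiff(c("t_s", "x_cm", "L", "a", "b", "truth_coverage"),
                  names(df))
  if (length(miss))
    stop("transect CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read and write scene specifications as JSON
#'
#' The JSON form mirrors [scene_spec()]: `background` is a surface name
#' resolved against a color database, `objects` an array of
#' `{center_x, center_y, radius, green}` with green-tone names.
#'
#' @param path JSON file path.
#' @param db A `"color_db"` to resolve names (default: packaged database).
#' @param spec A `"scene_spec"` to write.
#' @return `read_scene_json()` returns a `"scene_spec"`.
#' @export
read_scene_json <- function(path, db = lab_db()) {
  if (!file.exists(path))
    stop("scene file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$background))
    stop("scene JSON lacks 'background'", call. = FALSE)
  objects <- NULL
  if (length(raw$objects)) {
    objects <- do.call(rbind, lapply(raw$objects, function(o) {
      miss <- setdiff(c("center_x", "center_y", "radius", "green"), names(o))
      if (length(miss))
        stop("scene object lacks field(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
      data.frame(center_x = o$center_x, center_y = o$center_y,
                 radius = o$radius, green = o$green)
    }))
  }
  args <- list(background = db_surface(db, raw$background),
               objects = objects, db = db)
  for (nm in c("spot_diameter", "speed", "frequency", "track_length",
               "seed", "noise"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(scene_spec, args)
}

#' @rdname read_scene_json
#' @export
write_scene_json <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  objects <- lapply(seq_len(nrow(spec$objects)), function(i)
    list(center_x = spec$objects$center_x[i],
         center_y = spec$objects$center_y[i],
         radius = spec$objects$radius[i],
         green = spec$objects$green[[i]]$name))
  jsonlite::write_json(
    list(background = spec$background$name, objects = objects,
         spot_diameter = spec$spot_diameter, speed = spec$speed,
         frequency = spec$frequency, track_length = spec$track_length,
         seed = spec$seed, noise = spec$noise),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
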