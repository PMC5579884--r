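# Shared fixtures and independent oracles for the test suite.

ref_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- lab_db()
    db
  }
})

# Random in-gamut Lab triples for property tests.
rand_lab <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  replicate(n, lab(runif(1, 0, 100), runif(1, -128, 127),
                   runif(1, -128, 127)),
            simplify = FALSE)
}

# Monte-Carlo rejection-sampling oracle for the disc-intersection area:
# sample uniformly in the smaller disc, count points inside the other.
# Independent of the closed-form lens formula under test.
mc_overlap <- function(c1, r1, c2, r2, n = 1e6) {
  if (r2 < r1) { tmp <- c1; c1 <- c2; c2 <- tmp; tmp <- r1; r1 <- r2; r2 <- tmp }
  theta <- runif(n, 0, 2 * pi)
  rad <- r1 * sqrt(runif(n))
  x <- c1[1] + rad * cos(theta)
  y <- c1[2] + rad * sin(theta)
  inside <- (x - c2[1])^2 + (y - c2[2])^2 <= r2^2
  mean(inside) * pi * r1^2
}

# Paved-ground scene with four small disc objects, one per reference green:
# the synthetic analog of a solid-background detection run.
paved_scene <- function(seed, noise = TRUE, db = ref_db()) {
  objects <- data.frame(
    center_x = c(30, 60, 90, 120), center_y = 0, radius = 1,
    green = I(lapply(paste("Green", 1:4), function(nm) db_green(db, nm))))
  scene_spec(db_surface(db, "Grey paving stones"), objects,
             spot_diameter = 5, speed = 0.1, frequency = 10,
             track_length = 150, seed = seed, noise = noise)
}

# Gaussian reading stream around a surface's characterization.
simulate_readings <- function(stats, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sigma_of(stats)
  data.frame(t_s = seq_len(n) / 10, x_cm = seq_len(n),
             L = rnorm(n, stats$mean[["L"]], s[["L"]]),
             a = rnorm(n, stats$mean[["a"]], s[["a"]]),
             b = rnorm(n, stats$mean[["b"]], s[["b"]]))
}
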