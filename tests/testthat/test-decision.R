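test_that("delta_e detector fires strictly above the threshold", {
  db <- ref_db()
  field <- db_surface(db, "Arable land")
  t5 <- thresholds(t_dE = 5)

  d0 <- detect_delta_e(field$stats$mean, field, t5)
  expect_false(d0$detect)
  expect_length(d0$triggered, 0L)

  g1 <- db_green(db, "Green 1")$stats$mean
  d1 <- detect_delta_e(g1, field, t5) # distance ~46 >> 5
  expect_true(d1$detect)
  expect_equal(d1$triggered, "E")
  expect_equal(d1$rule, "delta_e")

  # a reading exactly at the threshold does not fire
  at <- lab(field$stats$mean[["L"]] + 5, field$stats$mean[["a"]],
            field$stats$mean[["b"]])
  expect_false(detect_delta_e(at, field, t5)$detect)
  expect_error(detect_delta_e(g1, field, thresholds(t_dL = 5)), "t_dE")
})

test_that("delta_e detector agrees with a direct recomputation", {
  db <- ref_db()
  bg <- db_surface(db, "Sandy path")$stats
  set.seed(303)
  for (r in rand_lab(50)) {
    for (thr in c(1, 5, 12)) {
      got <- detect_delta_e(r, bg, thresholds(t_dE = thr))$detect
      want <- sqrt((r[["L"]] - bg$mean[["L"]])^2 +
                   (r[["a"]] - bg$mean[["a"]])^2 +
                   (r[["b"]] - bg$mean[["b"]])^2) > thr
      expect_identical(got, want)
    }
  }
})

test_that("channel detector compares per channel and combines", {
  db <- ref_db()
  paved <- db_surface(db, "Grey paving stones")
  t <- thresholds(t_dL = 5, t_da = 2, t_db = 2)

  expect_false(detect_channels(paved$stats$mean, paved, t)$detect)

  g1 <- db_green(db, "Green 1")$stats$mean
  d <- detect_channels(g1, paved, t)
  expect_true(d$detect)
  expect_true(all(c("L", "a", "b") %in% d$triggered))

  # strict inequality: a difference of exactly 2 on channel a does not fire
  m <- paved$stats$mean
  r <- lab(m[["L"]], m[["a"]] + 2, m[["b"]])
  expect_false(detect_channels(r, paved, thresholds(t_da = 2))$detect)
  expect_true(detect_channels(r, paved, thresholds(t_da = 1.999))$detect)

  # combine = "all" requires every thresholded channel
  r2 <- lab(m[["L"]] + 10, m[["a"]], m[["b"]])
  expect_true(detect_channels(r2, paved, thresholds(t_dL = 5, t_da = 2))$detect)
  expect_false(detect_channels(
    r2, paved, thresholds(t_dL = 5, t_da = 2, combine = "all"))$detect)
  expect_error(detect_channels(r2, paved, thresholds(t_dE = 5)),
               "at least one")
})

test_that("statistical rule uses the combined noise as its boundary", {
  db <- ref_db()
  field <- db_surface(db, "Arable land")
  g1 <- db_green(db, "Green 1")

  expect_false(detect_statistical(field$stats$mean, field, g1)$detect)

  # a pure green reading trips all three channels on bare soil
  d <- detect_statistical(g1$stats$mean, field, g1)
  expect_true(d$detect)
  expect_setequal(d$triggered, c("L", "a", "b"))

  # boundary is inclusive: displacement == sigma_BG + sigma_Obj detects
  s <- sigma_of(field$stats)[["L"]] + sigma_of(g1$stats)[["L"]]
  m <- field$stats$mean
  at <- lab(m[["L"]] + s, m[["a"]], m[["b"]])
  da <- detect_statistical(at, field, g1)
  expect_true(da$detect)
  expect_true("L" %in% da$triggered)

  # zero noise on both sides: any departure at all is a detection
  quiet <- lab_stats(mean = lab(10, 0, 10), sigma = c(L = 0, a = 0, b = 0))
  expect_true(detect_statistical(lab(10, 0, 10.001), quiet, quiet)$detect)
  expect_error(detect_statistical(m, field, lab_stats(mean = m)),
               "noise level")
})

test_that("raising a threshold never creates a detection", {
  db <- ref_db()
  bg <- db_surface(db, "Gravel")$stats
  set.seed(77)
  readings <- rand_lab(30)
  for (r in readings) {
    lo <- runif(1, 0, 10); hi <- lo + runif(1, 0, 10)
    expect_true(detect_delta_e(r, bg, thresholds(t_dE = hi))$detect <=
                  detect_delta_e(r, bg, thresholds(t_dE = lo))$detect)
    expect_true(
      detect_channels(r, bg, thresholds(t_dL = hi, t_da = hi, t_db = hi))$detect <=
        detect_channels(r, bg, thresholds(t_dL = lo, t_da = lo, t_db = lo))$detect)
  }
})

test_that("classify_green identifies the tone independent of plant size", {
  db <- ref_db()
  grass <- db_surface(db, "Grassland")$stats
  g3 <- db_green(db, "Green 3")$stats
  for (f in c(0.02, 0.10)) {
    r <- mixed_color(grass, g3, f, noise = FALSE)
    cl <- classify_green(r, grass, db)
    expect_equal(cl$green, "Green 3")
    expect_equal(cl$score, 1, tolerance = 1e-9)
  }
  # scale invariance of the direction: scaling v leaves scores unchanged
  v <- unclass(mixed_color(grass, g3, 0.1, noise = FALSE)) -
    unclass(grass$mean)
  for (k in c(0.5, 3)) {
    r <- lab(grass$mean[["L"]] + k * v[["L"]], grass$mean[["a"]] + k * v[["a"]],
             grass$mean[["b"]] + k * v[["b"]])
    expect_equal(classify_green(r, grass, db)$scores,
                 classify_green(mixed_color(grass, g3, 0.1, noise = FALSE),
                                grass, db)$scores,
                 tolerance = 1e-9)
  }
  expect_error(classify_green(grass$mean, grass, db), "no direction")
  expect_error(classify_green(lab(1, 1, 1), grass, list()), "at least one")
})

test_that("classify_green recovers greens from noisy grassland mixtures", {
  # Module baseline, established by this simulation: at 25% coverage on
  # grassland (the noisiest vegetated background), the dark greens are
  # recovered almost always; the two bright greens depart from grassland
  # in similar directions and are confused with each other in a minority
  # of draws.
  db <- ref_db()
  grass <- db_surface(db, "Grassland")$stats
  set.seed(4242)
  rate <- vapply(names(db$greens), function(gn) {
    g <- db_green(db, gn)$stats
    hits <- vapply(seq_len(200), function(i) {
      r <- mixed_color(grass, g, 0.25, noise = TRUE)
      identical(tryCatch(classify_green(r, grass, db)$green,
                         error = function(e) NA_character_), gn)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(rate[["Green 3"]], 0.95)
  expect_gte(rate[["Green 4"]], 0.95)
  expect_gte(rate[["Green 1"]], 0.70)
  expect_gte(rate[["Green 2"]], 0.70)
  expect_gte(mean(rate), 0.85) # far above the 25% chance level
})

test_that("spray commands follow the recognition mode", {
  db <- ref_db()
  field <- db_surface(db, "Arable land")
  hit <- detect_delta_e(db_green(db, "Green 1")$stats$mean, field,
                        thresholds(t_dE = 5))
  miss <- detect_delta_e(field$stats$mean, field, thresholds(t_dE = 5))
  expect_true(spray_decision(hit, "positive")$spray)
  expect_false(spray_decision(hit, "negative")$spray)
  expect_false(spray_decision(miss, "positive")$spray)
  expect_true(spray_decision(miss, "negative")$spray)
  expect_error(spray_decision(hit, "sometimes"), "arg")
})

test_that("threshold presets carry the field-trial values", {
  expect_equal(threshold_preset("paved")$t_dE, 5)
  expect_equal(threshold_preset("wheat")$t_dE, 12)
  expect_equal(threshold_preset("grassland-dock")$t_dE, 7)
  expect_error(threshold_preset("orchard"), "unknown preset")
})
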