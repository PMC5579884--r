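test_that("lab_summary computes per-channel sample statistics", {
  ten <- data.frame(L = rep(5, 10), a = rep(5, 10), b = rep(5, 10))
  s <- lab_summary(ten)
  expect_equal(unclass(s$mean), c(L = 5, a = 5, b = 5))
  expect_equal(unname(s$sigma), c(0, 0, 0))
  expect_equal(s$n, 10L)

  two <- data.frame(L = c(0, 2), a = c(0, 0), b = c(0, 0))
  s2 <- lab_summary(two)
  expect_equal(unclass(s2$mean), c(L = 1, a = 0, b = 0))
  expect_equal(s2$sigma[["L"]], sqrt(2)) # sample sd, n-1 denominator
  expect_equal(s2$min[["L"]], 0)
  expect_equal(s2$max[["L"]], 2)

  expect_error(lab_summary(data.frame(L = 1, a = 1, b = 1)), "at least 2")
  expect_error(lab_summary(data.frame(L = c(1, NA), a = 0, b = 0)),
               "non-finite")
})

test_that("lab_summary recovers known generator parameters", {
  set.seed(2024)
  n <- 10000
  r <- data.frame(L = rnorm(n, 11.32, 0.13), a = rnorm(n, 4.81, 0.70),
                  b = rnorm(n, 20.10, 0.47))
  s <- lab_summary(r)
  expect_equal(unclass(s$mean), c(L = 11.32, a = 4.81, b = 20.10),
               tolerance = 0.01)
  expect_lt(abs(s$sigma[["L"]] / 0.13 - 1), 0.05)
  expect_lt(abs(s$sigma[["a"]] / 0.70 - 1), 0.05)
  expect_lt(abs(s$sigma[["b"]] / 0.47 - 1), 0.05)
})

test_that("lab_summary is permutation-invariant", {
  set.seed(5)
  r <- data.frame(L = runif(50, 0, 100), a = runif(50, -50, 50),
                  b = runif(50, -50, 50))
  s1 <- lab_summary(r)
  s2 <- lab_summary(r[sample(nrow(r)), ])
  expect_equal(unclass(s1$mean), unclass(s2$mean))
  expect_equal(s1$sigma, s2$sigma)
  expect_equal(unclass(s1$min), unclass(s2$min))
  expect_equal(unclass(s1$max), unclass(s2$max))
})

test_that("calibrate_background wraps the summary with provenance", {
  const <- data.frame(L = rep(12, 8), a = rep(3, 8), b = rep(18, 8))
  sc <- calibrate_background(const, "lab bench", "anthropogenic")
  expect_s3_class(sc, "surface_class")
  expect_equal(unname(sc$stats$sigma), c(0, 0, 0))
  expect_equal(sc$stats$n, 8L)
  expect_false(is.null(attr(sc$stats, "calibrated_at")))
  expect_error(calibrate_background(const[1, ], "x", "natural"), "at least 2")
  expect_error(calibrate_background(const, "x", "urban"), "arg")

  # parameter recovery from a simulated arable-land stream
  stream <- simulate_readings(ref_db()$surfaces[["Arable land"]]$stats,
                              5000, seed = 99)
  sc2 <- calibrate_background(stream, "plot", "natural")
  expect_equal(unclass(sc2$stats$mean), c(L = 11.32, a = 4.81, b = 20.10),
               tolerance = 0.05)
  expect_lt(abs(sc2$stats$sigma[["L"]] / 0.13 - 1), 0.1)
})

test_that("packaged database transcribes the reference tables", {
  db <- ref_db()
  cats <- vapply(db$surfaces, `[[`, character(1), "category")
  expect_equal(sum(cats == "anthropogenic"), 7L)
  expect_equal(sum(cats == "natural"), 3L)
  expect_length(db$greens, 4L)

  field <- db_surface(db, "Arable land")
  expect_equal(field$stats$mean[["L"]], 11.32)
  expect_equal(field$stats$sigma[["L"]], 0.13)
  expect_equal(db_surface(db, "Grey paving stones")$stats$mean[["a"]], 2.80)
  g4 <- db_green(db, "Green 4")
  expect_equal(unclass(g4$stats$mean), c(L = 29.15, a = -61.51, b = -4.22))

  # dew-covered grassland has the noisiest luminance of all surfaces
  sig_L <- vapply(db$surfaces, function(s) s$stats$sigma[["L"]], numeric(1))
  expect_true(all(sig_L <= 2.23))
  # every green is greener (smaller a) than every background
  a_green <- vapply(db$greens, function(g) g$stats$mean[["a"]], numeric(1))
  a_bg <- vapply(db$surfaces, function(s) s$stats$mean[["a"]], numeric(1))
  expect_lt(max(a_green), min(a_bg))
  expect_equal(max(a_green), -15.24)
  expect_equal(min(a_bg), -6.32)

  # transcription inconsistencies are flagged, never corrected
  expect_true(any(grepl("channel a", db_green(db, "Green 2")$stats$suspect)))
  expect_equal(db_green(db, "Green 2")$stats$min[["a"]], -16.83)
  expect_equal(db_green(db, "Green 2")$stats$max[["a"]], -25.60)
})

test_that("green sigma falls back to the quarter-range convention", {
  g1 <- db_green(ref_db(), "Green 1")
  expect_null(g1$stats$sigma)
  s <- sigma_of(g1$stats)
  expect_equal(s[["L"]], (44.84 - 44.71) / 4)
  expect_equal(s[["a"]], abs(-15.73 - -14.85) / 4) # reversed min/max cell
  # explicit sigma wins over the convention
  st <- lab_stats(mean = lab(10, 0, 0), sigma = c(L = 1, a = 2, b = 3),
                  min = lab(0, -9, -9), max = lab(20, 9, 9))
  expect_equal(unname(sigma_of(st)), c(1, 2, 3))
  # neither sigma nor range: noise level genuinely unknown
  expect_error(sigma_of(lab_stats(mean = lab(1, 1, 1))), "noise level")
})

test_that("databases round-trip through JSON losslessly", {
  db <- ref_db()
  path <- withr::local_tempfile(fileext = ".json")
  save_color_db(db, path)
  back <- load_color_db(path)
  expect_equal(names(back$surfaces), names(db$surfaces))
  expect_equal(names(back$greens), names(db$greens))
  for (nm in names(db$surfaces)) {
    expect_equal(unclass(back$surfaces[[nm]]$stats$mean),
                 unclass(db$surfaces[[nm]]$stats$mean))
    expect_equal(back$surfaces[[nm]]$stats$sigma,
                 db$surfaces[[nm]]$stats$sigma)
    expect_equal(back$surfaces[[nm]]$category, db$surfaces[[nm]]$category)
  }
  for (nm in names(db$greens))
    expect_equal(unclass(back$greens[[nm]]$stats$max),
                 unclass(db$greens[[nm]]$stats$max))

  # schema violations name the offending field
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"surfaces": [{"name": "x", "category": "natural",
               "mean": {"L": 1, "a": 2}}], "greens": []}', bad)
  expect_error(load_color_db(bad), "mean.*lacks.*b")
})

test_that("reading streams are validated on import", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,x_cm,L,a,b", "0.1,1,11.3,4.8,20.1", "0.2,2,11.4,4.7,20.0"),
             path)
  df <- read_readings_csv(path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$L, c(11.3, 11.4))

  writeLines(c("t_s,x_cm,L,a", "0.1,1,11.3,4.8"), path)
  expect_error(read_readings_csv(path), "lacks column.*b")
  writeLines(c("t_s,x_cm,L,a,b", "0.1,1,11.3,oops,20.1"), path)
  expect_error(read_readings_csv(path), "row")
  writeLines("t_s,x_cm,L,a,b", path)
  expect_error(read_readings_csv(path), "empty")
})
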