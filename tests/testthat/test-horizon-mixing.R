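test_that("closed-form remaining thickness matches the reported design values", {
  # 20 * (1 - 0.1/20)^n for the treatment-level year counts
  expect_equal(round(remaining_thickness(20, 0.1, 20, 100), 2), 12.12)
  expect_equal(round(remaining_thickness(20, 0.1, 20, 200), 2), 7.34)
  expect_equal(round(remaining_thickness(20, 0.1, 20, 400), 2), 2.69)
  expect_equal(remaining_thickness(20, 0.1, 20, 0), 20)
})

test_that("remaining thickness is strictly decreasing in years and vanishes in the limit", {
  vals <- remaining_thickness(20, 0.1, 20, 0:500)
  expect_true(all(diff(vals) < 0))
  expect_lt(remaining_thickness(20, 0.1, 20, 10000), 1e-10)
})

test_that("invalid mixing parameters are rejected", {
  expect_error(remaining_thickness(20, 0.1, 20, -1), "non-negative")
  expect_error(remaining_thickness(20, 25, 20, 10), "0 < d < m")
  expect_error(remaining_thickness(-1, 0.1, 20, 10), "> 0")
})

test_that("years_for_erosion inverts treatment depths and rejects non-annual depths", {
  expect_identical(years_for_erosion(10, 0.1), 100L)
  expect_identical(years_for_erosion(0, 0.1), 0L)
  expect_identical(years_for_erosion(40, 0.1), 400L)
  expect_error(years_for_erosion(10.05, 0.1), "integer multiple")
})

test_that("simulator reproduces the reported horizon split at each treatment", {
  p <- default_profile()
  s100 <- simulate_mixing(p, 100)
  expect_equal(round(unname(s100["h0 (0-20 cm)"]), 2), 12.12)
  expect_equal(round(unname(s100["20-30 cm"]), 2), 7.88)
  s0 <- simulate_mixing(p, 0)
  expect_equal(as.numeric(unclass(s0)), 20, tolerance = 1e-12)
  expect_named(s0, "h0 (0-20 cm)")
  s200 <- simulate_mixing(p, 200)
  expect_equal(round(as.numeric(unclass(s200)), 2), c(7.34, 4.78, 7.88))
})

test_that("closed form and year-by-year simulator agree over arbitrary profiles", {
  set.seed(42)
  for (d in c(0.05, 0.1, 0.2)) {
    # random 5-10 cm layering above a parent base
    th <- runif(6, 5, 10)
    tops <- cumsum(c(0, th))
    layers <- data.frame(
      label = c(sprintf("L%d", seq_along(th)), "parent"),
      top_depth = tops, thickness = c(th, 10),
      material = c("cultivated", rep("subsoil", length(th) - 1), "parent"))
    prof <- soil_profile(layers, plow_depth = 20, annual_erosion = d)
    for (n in c(0, 1, 7, 50, 137, 500)) {
      sim <- simulate_mixing(prof, n)
      cf <- horizon_composition(prof, n = n)
      expect_equal(sum(sim), 20, tolerance = 1e-9)
      expect_equal(sum(cf), 20, tolerance = 1e-9)
      common <- union(names(sim), names(cf))
      get <- function(x) {
        v <- stats::setNames(numeric(length(common)), common)
        v[names(x)] <- unclass(x)
        v
      }
      expect_equal(get(sim), get(cf), tolerance = 1e-9)
    }
  }
})

test_that("plow zone exhaustion without parent material errors with the year", {
  layers <- data.frame(label = c("h0", "sub"), top_depth = c(0, 20),
                       thickness = c(20, 5),
                       material = c("cultivated", "subsoil"))
  prof <- soil_profile(layers, plow_depth = 20, annual_erosion = 0.1)
  expect_error(simulate_mixing(prof, 100), "year 51")
  expect_error(horizon_composition(prof, n = 100), "year 51")
  # exactly at the declared bottom is still fine
  expect_silent(simulate_mixing(prof, 50))
})

test_that("profiles round-trip through YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "plow_depth: 20", "annual_erosion: 0.1", "layers:",
    "  - {label: h0, top_depth: 0, thickness: 20, material: cultivated}",
    "  - {label: sub1, top_depth: 20, thickness: 10, material: subsoil}",
    "  - {label: base, top_depth: 30, thickness: 10, material: parent}"),
    path)
  prof <- read_profile(path)
  expect_s3_class(prof, "soil_profile")
  expect_equal(nrow(prof$layers), 3)
  expect_equal(round(unname(horizon_composition(prof, D = 10)["h0"]), 2),
               12.12)
})

test_that("malformed profiles are rejected", {
  bad <- data.frame(label = c("a", "b"), top_depth = c(0, 25),
                    thickness = c(20, 10),
                    material = c("cultivated", "subsoil"))
  expect_error(soil_profile(bad), "contiguous")
  expect_error(soil_profile(
    data.frame(label = "a", top_depth = 0, thickness = 20,
               material = "cultivated"),
    plow_depth = 20, annual_erosion = 25), "0 < d < plow depth")
})

test_that("the packaged profile config matches the built-in default", {
  cfg <- system.file("extdata", "default_profile.yaml", package = "erodyn")
  prof <- read_profile(cfg)
  expect_equal(prof$layers, default_profile()$layers)
  expect_equal(prof$annual_erosion, 0.1)
})
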