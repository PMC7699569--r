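test_that("panel construction, CSV round trip and balance checks", {
  df <- tiny_panel_df(2, 3)
  ds <- panel_dataset(df)
  expect_s3_class(ds, "panel_dataset")
  expect_equal(length(panel_countries(ds)) * length(panel_years(ds)) *
                 length(variable_names(ds)), 12)

  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(ds, path)
  back <- read_panel_csv(path)
  expect_identical(as.data.frame(back), as.data.frame(ds))

  # removing one row unbalances the panel
  broken <- df[-4, ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_panel_csv(p2), "unbalanced|missing year")

  # duplicate (country, year) and non-numeric cells are named
  dup <- rbind(df, df[1, ])
  expect_error(panel_dataset(dup), "duplicate")
  bad <- df
  bad$a <- as.character(bad$a)
  bad$a[2] <- "oops"
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p3, row.names = FALSE)
  expect_error(read_panel_csv(p3), "non-numeric.*'a'")

  # empty variable list still round-trips with a country,year header
  ds0 <- panel_dataset(df[, c("country", "year")])
  p4 <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(ds0, p4)
  expect_identical(readLines(p4)[1], "country,year")
  expect_identical(as.data.frame(read_panel_csv(p4)), as.data.frame(ds0))
})

test_that("a 14x23x7 panel writes 322 data rows", {
  spec <- default_panel_spec(seed = 2)
  ds <- gen_panel(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(ds, path)
  expect_equal(length(readLines(path)) - 1L, 322L)
  expect_equal(nrow(ds) * length(variable_names(ds)), 2254L)
})

test_that("log transform acts only on selected variables and rejects non-positive cells", {
  df <- tiny_panel_df(2, 3, vars = c("u", "v"))
  df$u[1] <- 1.0
  df$v[1] <- 22.0
  ds <- panel_dataset(df)
  lg <- log_transform(ds, "v")
  expect_equal(lg$u, ds$u)
  expect_equal(lg$v, log(ds$v))
  expect_equal(lg$v[lg$country == df$country[1] & lg$year == df$year[1]],
               3.0910425, tolerance = 1e-6)
  # the transform composes: applying twice to exp(e)-valued data gives 1
  df2 <- tiny_panel_df(1, 2, vars = "w")
  df2$w <- exp(exp(1))
  twice <- log_transform(log_transform(panel_dataset(df2), "w"), "w")
  expect_equal(twice$w, rep(1, 2))
  # non-positive values are a named hard error
  df$u[3] <- -2
  expect_error(log_transform(panel_dataset(df), "u"),
               "non-positive.*variable u")
})

test_that("design extraction is canonical and permutation-invariant", {
  spec <- default_panel_spec(seed = 5)
  ds <- gen_panel(spec)
  D <- to_design(ds, "LEAB", setdiff(variable_names(ds), "LEAB"))
  expect_equal(length(D$y), 322)
  expect_equal(dim(D$X), c(322, 6))

  # permuting CSV row order leaves the design unchanged
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(ds, path)
  lines <- readLines(path)
  set.seed(11)
  writeLines(c(lines[1], sample(lines[-1])), path)
  D2 <- to_design(read_panel_csv(path), "LEAB",
                  setdiff(variable_names(ds), "LEAB"))
  expect_identical(D2$y, D$y)
  expect_identical(D2$X, D$X)

  # empty predictor set keeps the response intact
  D0 <- to_design(ds, "LEAB", character(0))
  expect_equal(ncol(D0$X), 0)
  expect_identical(D0$y, D$y)

  expect_error(to_design(ds, "LEAB", c("GNI", "LEAB")), "may not appear")
  expect_error(to_design(ds, "nope"), "unknown variable")
})

test_that("descriptive statistics follow the sample conventions", {
  df <- data.frame(country = "A", year = 2000:2002,
                   cst = 5, abc = c(1, 2, 3), rng = c(75.3, 83.5, 80))
  s <- descriptive_stats(panel_dataset(df))
  cst <- s[s$variable == "cst", ]
  expect_equal(cst$mean, 5)
  expect_equal(cst$sd, 0)
  expect_equal(cst$range, 0)
  abc <- s[s$variable == "abc", ]
  expect_equal(abc$mean, 2)
  expect_equal(abc$sd, 1)        # sample (n - 1) denominator
  expect_equal(abc$variance, 1)
  expect_equal(abc$coef_var, 50)
  expect_equal(s[s$variable == "rng", ]$range, 8.2)
  # range = max - min for every variable
  expect_equal(s$range, s$max - s$min)
})
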