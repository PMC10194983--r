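test_that("series construction validates counts and derives rate and t", {
  s <- toy_series()
  expect_s3_class(s, "mortality_series")
  expect_equal(s$rate, s$deaths / s$births)
  expect_equal(s$t, s$year - 1930L)

  expect_error(mortality_series(c(1950, 1950), c(10, 10), c(1, 1)), "duplicate")
  expect_error(mortality_series(1950:1951, c(100, 100), c(101, 5)), "1950")
  expect_error(mortality_series(1950, 0, 0), "births")
})

test_that("read/write round-trips exactly and preserves year gaps", {
  path <- withr::local_tempfile(fileext = ".csv")
  s <- mortality_series(c(1942, 1943, 1946, 1947), c(900, 950, 1000, 1010),
                        c(50, 52, 41, 39))
  write_series(s, path)
  s2 <- read_series(path)
  expect_series_equal(s, s2)
  expect_equal(s2$t, c(12, 13, 16, 17)) # gap preserved, t per row

  # remapped column names
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(Year = 1950:1952, LiveBirths = c(10, 20, 30) * 100,
                   InfantDeaths = c(9, 12, 15)), path2)
  s3 <- read_series(path2, dialect = c(year = "Year", births = "LiveBirths",
                                       deaths = "InfantDeaths"))
  expect_equal(nrow(s3), 3)
  expect_equal(s3$deaths, c(9, 12, 15))
})

test_that("rows with missing counts are dropped with a warning, bad text errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,births,deaths", "1943,900,50", "1944,,", "1946,1000,41"),
             path)
  expect_warning(s <- read_series(path), "1944")
  expect_equal(s$year, c(1943L, 1946L))

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,births,deaths", "1950,abc,3"), path2)
  expect_error(read_series(path2), "unparseable")
})

test_that("pooling sums counts on the common years", {
  a <- toy_series()
  doubled <- suppressMessages(pool_series(list(a, a)))
  expect_equal(doubled$births, 2 * a$births)
  expect_equal(doubled$deaths, 2 * a$deaths)
  expect_equal(doubled$rate, a$rate)

  b <- mortality_series(1950:1951, c(1000, 1100), c(10, 12))
  c2 <- mortality_series(1950:1951, c(2000, 2100), c(30, 31))
  p <- suppressMessages(pool_series(list(b, c2)))
  expect_equal(p$rate[1], 40 / 3000)

  # associative and commutative on identical year ranges
  d <- mortality_series(1950:1951, c(500, 600), c(4, 5))
  p1 <- suppressMessages(pool_series(list(b, c2, d)))
  p2 <- suppressMessages(pool_series(list(pool_series(list(d, b)), c2)))
  expect_series_equal(p1, p2)

  expect_error(pool_series(list()), "empty")
  e <- mortality_series(1980:1981, c(10, 10), c(1, 1))
  expect_error(suppressMessages(pool_series(list(b, e))), "common years")
})

test_that("pooled deaths conserve the member totals", {
  members <- lapply(1:5, function(i) {
    mortality_series(1950:1960, rep(1e5 * i, 11), rep(100 * i, 11))
  })
  pooled <- suppressMessages(pool_series(members))
  expect_equal(sum(pooled$deaths),
               sum(vapply(members, function(m) sum(m$deaths), numeric(1))))
})

test_that("excluding years drops rows, commutes with pooling, no-ops cleanly", {
  s <- mortality_series(1931:2018, rep(1000, 88), rep(10, 88))
  expect_series_equal(exclude_years(s, integer(0)), s)
  expect_equal(nrow(suppressMessages(exclude_years(s, c(1940, 1945)))), 86)
  expect_series_equal(exclude_years(s, 1800), s) # absent year: no-op

  a <- mortality_series(1950:1952, c(1000, 1100, 1200), c(10, 11, 12))
  b <- mortality_series(1950:1952, c(2000, 2100, 2200), c(20, 21, 22))
  left <- suppressMessages(exclude_years(pool_series(list(a, b)), 1951))
  right <- suppressMessages(pool_series(list(exclude_years(a, 1951),
                                             exclude_years(b, 1951))))
  expect_series_equal(left, right)
})
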