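#' Build a validated annual mortality series
#'
#' A mortality series is a tibble with one row per calendar year holding the
#' number of live births and the number of deaths (infant deaths or, with
#' `deaths_role = "stillbirths"`, stillbirths against a live-birth
#' denominator). Two columns are always derived, never supplied: `rate`, the
#' proportion `deaths / births` (the per-1000 convention is presentation
#' only), and `t`, the model time index `year - origin` with the origin fixed
#' at 1930 so that published trend coefficients stay interpretable.
#'
#' @param year Integer calendar years, strictly increasing. Gaps are allowed
#'   (missing years are simply absent; they are never imputed).
#' @param births Positive integer live births per year.
#' @param deaths Non-negative integer deaths per year; must not exceed births.
#' @param deaths_role Label for what the deaths column counts,
#'   `"infant_deaths"` (default) or `"stillbirths"`.
#' @param origin Calendar year subtracted from `year` to form the time index
#'   `t`. Default 1930.
#'
#' @return A tibble of class `mortality_series` with columns `year`, `births`,
#'   `deaths`, `rate`, `t`.
#' @export
#' @examples
#' mortality_series(1950:1952, births = c(1000, 1100, 1200), deaths = c(30, 31, 28))
mortality_series <- function(year, births, deaths,
                             deaths_role = c("infant_deaths", "stillbirths"),
                             origin = 1930) {
  deaths_role <- match.arg(deaths_role)
  year <- as.integer(year)
  stopifnot(length(year) == length(births), length(year) == length(deaths))
  if (anyDuplicated(year)) {
    stop("duplicate years: ", paste(unique(year[duplicated(year)]), collapse = ", "))
  }
  if (is.unsorted(year, strictly = TRUE)) {
    ord <- order(year)
    year <- year[ord]; births <- births[ord]; deaths <- deaths[ord]
  }
  if (any(!is.finite(births)) || any(!is.finite(deaths))) {
    stop("births and deaths must be finite numbers")
  }
  if (any(births < 1)) stop("births must be >= 1 for every year")
  if (any(deaths < 0)) stop("deaths must be non-negative")
  bad <- deaths > births
  if (any(bad)) {
    stop("deaths exceed births in year(s): ", paste(year[bad], collapse = ", "))
  }
  out <- tibble::tibble(
    year = year,
    births = as.numeric(births),
    deaths = as.numeric(deaths),
    rate = as.numeric(deaths) / as.numeric(births),
    t = year - as.integer(origin)
  )
  structure(out,
    class = c("mortality_series", class(tibble::tibble())),
    deaths_role = deaths_role,
    origin = as.integer(origin)
  )
}

as_mortality_series <- function(df, ...) {
  mortality_series(df$year, df$births, df$deaths, ...)
}

#' Read an annual vital-statistics series from delimited text
#'
#' Expects a header row and columns for year, live births and deaths. Column
#' names can be remapped through `dialect` to accommodate external exports.
#' Rows with missing counts are dropped with a warning (year gaps, such as the
#' German 1944-45 gap, are preserved as absent years); non-numeric entries in
#' a count column are an error.
#'
#' @param path Path to a delimited text file (comma-separated by default).
#' @param dialect Named character vector mapping the canonical names to the
#'   file's column names, e.g. `c(year = "Year", births = "LiveBirths",
#'   deaths = "InfantDeaths")`.
#' @param delim Field delimiter, default `","`.
#' @inheritParams mortality_series
#' @return A `mortality_series` tibble.
#' @export
read_series <- function(path,
                        dialect = c(year = "year", births = "births", deaths = "deaths"),
                        delim = ",",
                        deaths_role = c("infant_deaths", "stillbirths"),
                        origin = 1930) {
  deaths_role <- match.arg(deaths_role)
  stopifnot(all(c("year", "births", "deaths") %in% names(dialect)))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_cols <- setdiff(unname(dialect[c("year", "births", "deaths")]), names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  df <- tibble::tibble(
    year = raw[[dialect[["year"]]]],
    births = raw[[dialect[["births"]]]],
    deaths = raw[[dialect[["deaths"]]]]
  )
  parse_num <- function(x, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & x != "" & is.na(out)
    if (any(bad)) {
      stop("unparseable ", what, " value(s): ", paste(utils::head(x[bad], 5), collapse = ", "))
    }
    out
  }
  df <- dplyr::mutate(df,
    year = parse_num(.data$year, "year"),
    births = parse_num(.data$births, "births"),
    deaths = parse_num(.data$deaths, "deaths")
  )
  incomplete <- !stats::complete.cases(df)
  if (any(incomplete)) {
    warning("dropping ", sum(incomplete), " row(s) with missing counts (years: ",
            paste(df$year[incomplete], collapse = ", "), ")")
    df <- df[!incomplete, ]
  }
  mortality_series(df$year, df$births, df$deaths,
                   deaths_role = deaths_role, origin = origin)
}

#' Write a mortality series as tidy CSV
#'
#' Writes the canonical three columns `year,births,deaths`; derived columns
#' are recomputed on read.
#'
#' @param series A `mortality_series`.
#' @param path Output file path.
#' @return `series`, invisibly.
#' @export
write_series <- function(series, path) {
  readr::write_csv(dplyr::select(tibble::as_tibble(series),
                                 "year", "births", "deaths"), path)
  invisible(series)
}

#' Pool several mortality series year by year
#'
#' Births and deaths are summed over members on the intersection of their
#' year ranges, so the pooled rate is the ratio of pooled counts (not a mean
#' of member rates).
#'
#' @param members A list of `mortality_series` objects.
#' @inheritParams mortality_series
#' @return A pooled `mortality_series` on the common years.
#' @export
pool_series <- function(members, deaths_role = c("infant_deaths", "stillbirths"),
                        origin = 1930) {
  deaths_role <- match.arg(deaths_role)
  if (!length(members)) stop("empty member list")
  common <- Reduce(intersect, lapply(members, function(m) m$year))
  if (!length(common)) stop("no common years across members")
  n_dropped <- sum(vapply(members, function(m) sum(!m$year %in% common), 0L))
  if (n_dropped > 0) {
    message("pooling on ", length(common), " common years; ",
            n_dropped, " member-year(s) outside the intersection dropped")
  }
  pooled <- purrr::map(members, function(m) {
    dplyr::filter(tibble::as_tibble(m), .data$year %in% common)
  }) |>
    purrr::list_rbind() |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(births = sum(.data$births), deaths = sum(.data$deaths),
                     .groups = "drop")
  mortality_series(pooled$year, pooled$births, pooled$deaths,
                   deaths_role = deaths_role, origin = origin)
}

#' Drop listed calendar years from a series
#'
#' Used to omit outlier years (for example war-time spikes) from a
#' regression. Excluding a year that is not present is a no-op.
#'
#' @param series A `mortality_series`.
#' @param years Calendar years to drop.
#' @return The series without the listed years; the input is not modified.
#' @export
exclude_years <- function(series, years) {
  years <- as.integer(years)
  hit <- series$year %in% years
  if (any(hit)) {
    message("excluding ", sum(hit), " year(s): ",
            paste(series$year[hit], collapse = ", "))
  }
  out <- dplyr::filter(tibble::as_tibble(series), !.data$year %in% years)
  mortality_series(out$year, out$births, out$deaths,
                   deaths_role = attr(series, "deaths_role") %||% "infant_deaths",
                   origin = attr(series, "origin") %||% 1930)
}
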