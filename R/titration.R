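#' Construct a titration series
#'
#' A titration series holds the ordered scans (or bare peak intensities) of
#' one fluorescence titration: a fixed protein concentration and temperature,
#' a zero-quencher control, and increasing quencher concentrations.
#'
#' @param data A data frame. Spectral form: columns `quencher_M`,
#'   `wavelength_nm`, `intensity` (long format, one block per concentration).
#'   Peak-only form: columns `quencher_M`, `intensity` (one row per
#'   concentration).
#' @param mode Scan mode; see [spectrum()].
#' @param temperature_K Temperature in kelvin shared by every point.
#' @param protein_conc_M Protein concentration in molar.
#' @param excitation_nm Excitation wavelength in nm (optional).
#'
#' @return A tibble of class `"titration_series"` carrying the metadata as
#'   attributes, including `peak_only`.
#'
#' @details Invariants enforced: quencher concentrations are non-negative
#'   with exactly one zero-concentration control (F0); within each
#'   concentration the wavelength grid is strictly increasing; intensities
#'   are finite.
#' @export
titration_series <- function(data, mode = "emission", temperature_K = 298,
                             protein_conc_M = 4e-6, excitation_nm = NA_real_) {
  df <- as_tibble(data)
  mode <- match.arg(mode, SPECTRUM_MODES)
  if (!"quencher_M" %in% names(df)) {
    abort("`data` must have a `quencher_M` column.")
  }
  peak_only <- !"wavelength_nm" %in% names(df)
  if (!"intensity" %in% names(df)) {
    abort("`data` must have an `intensity` column.")
  }
  df$quencher_M <- as.double(df$quencher_M)
  df$intensity <- as.double(df$intensity)
  if (any(!is.finite(df$quencher_M)) || any(df$quencher_M < 0)) {
    abort("quencher concentrations must be finite and >= 0.")
  }
  if (any(!is.finite(df$intensity))) {
    abort("all intensities must be finite.")
  }
  concs <- sort(unique(df$quencher_M))
  if (!any(concs == 0)) {
    abort("no F0 point: the series must contain a zero-quencher control.")
  }
  if (peak_only) {
    if (anyDuplicated(df$quencher_M)) {
      abort("peak-only series: one row per quencher concentration.")
    }
    df <- dplyr::arrange(df, .data$quencher_M)
  } else {
    df$wavelength_nm <- as.double(df$wavelength_nm)
    df <- dplyr::arrange(df, .data$quencher_M, .data$wavelength_nm)
    bad <- df |>
      dplyr::summarise(
        n = dplyr::n(),
        mono = all(diff(.data$wavelength_nm) > 0),
        .by = "quencher_M"
      ) |>
      dplyr::filter(.data$n < 3 | !.data$mono)
    if (nrow(bad) > 0) {
      abort("format error: each scan needs >= 3 strictly increasing wavelengths.")
    }
  }
  structure(df,
            mode = mode,
            temperature_K = as.double(temperature_K),
            protein_conc_M = as.double(protein_conc_M),
            excitation_nm = as.double(excitation_nm),
            peak_only = peak_only,
            class = c("titration_series", class(df)))
}

#' Quencher concentrations of a titration series
#' @param series A [titration_series()].
#' @return Sorted numeric vector of unique quencher concentrations in molar.
#' @export
series_concentrations <- function(series) {
  sort(unique(series$quencher_M))
}

#' Extract one scan of a titration series as a spectrum
#' @param series A spectral-form [titration_series()].
#' @param quencher_M The concentration (molar) of the scan to extract.
#' @return A [spectrum()].
#' @export
series_spectrum <- function(series, quencher_M) {
  if (isTRUE(attr(series, "peak_only"))) {
    abort("peak-only series holds no spectra.")
  }
  block <- series[series$quencher_M == quencher_M, , drop = FALSE]
  if (nrow(block) == 0) {
    abort(sprintf("no scan at quencher concentration %g M.", quencher_M))
  }
  spectrum(block$wavelength_nm, block$intensity,
           mode = attr(series, "mode"),
           temperature_K = attr(series, "temperature_K"),
           excitation_nm = attr(series, "excitation_nm"))
}

#' Peak features of every point in a titration series
#'
#' Applies [peak_intensity()] to each scan (or passes through the stored
#' intensity for peak-only series).
#'
#' @inheritParams series_spectrum
#' @inheritParams peak_intensity
#' @return Tibble with columns `quencher_M`, `lambda_max` (NA for peak-only
#'   series) and `f_max`.
#' @export
series_peaks <- function(series, window = NULL) {
  if (isTRUE(attr(series, "peak_only"))) {
    return(tibble(quencher_M = series$quencher_M,
                  lambda_max = NA_real_,
                  f_max = series$intensity))
  }
  purrr::map_dfr(series_concentrations(series), function(q) {
    pk <- tryCatch(
      peak_intensity(series_spectrum(series, q), window = window),
      error = function(e) {
        abort(sprintf("peak not detectable at quencher concentration %g M: %s",
                      q, conditionMessage(e)))
      }
    )
    dplyr::mutate(pk, quencher_M = q, .before = 1)
  })
}

# ---- delimited-text I/O -----------------------------------------------------

#' Write a titration series to a delimited text file
#'
#' The on-disk format is instrument-agnostic CSV: a `#`-prefixed key:value
#' metadata header (mode, temperature_K, protein_conc_M, excitation_nm,
#' peak_only) followed by a column header row and comma-separated data with
#' `.` decimals. Numbers are written with 17 significant digits so that
#' [read_titration_table()] reproduces the series bit-for-bit.
#'
#' @param series A [titration_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(series, path) {
  if (!inherits(series, "titration_series")) {
    abort("`series` must be a titration_series.")
  }
  if (nrow(series) == 0) abort("empty series: nothing to write.")
  meta <- c(
    "# specbind titration v1",
    sprintf("# mode: %s", attr(series, "mode")),
    sprintf("# temperature_K: %.17g", attr(series, "temperature_K")),
    sprintf("# protein_conc_M: %.17g", attr(series, "protein_conc_M")),
    sprintf("# excitation_nm: %.17g", attr(series, "excitation_nm")),
    sprintf("# peak_only: %s", isTRUE(attr(series, "peak_only")))
  )
  num <- function(v) sprintf("%.17g", v)
  if (isTRUE(attr(series, "peak_only"))) {
    header <- "quencher_M,intensity"
    rows <- paste(num(series$quencher_M), num(series$intensity), sep = ",")
  } else {
    header <- "quencher_M,wavelength_nm,intensity"
    rows <- paste(num(series$quencher_M), num(series$wavelength_nm),
                  num(series$intensity), sep = ",")
  }
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    abort(sprintf("cannot open '%s' for writing.", path))
  })
  on.exit(close(con))
  writeLines(c(meta, header, rows), con)
  invisible(path)
}

#' Read a titration series from a delimited text file
#'
#' Reads the format written by [write_titration_table()]. Instrument exports
#' using micromolar concentrations (`quencher_uM` column,
#' `protein_conc_uM` / `temperature_C` header keys) are accepted and
#' converted to molar / kelvin internally.
#'
#' @param path Input file path.
#' @return A [titration_series()].
#' @export
read_titration_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- .parse_header(meta_lines)
  # base read.csv: its strtod parsing is correctly rounded, so files written
  # at 17 significant digits round-trip bit-for-bit
  df <- as_tibble(utils::read.csv(text = lines[!startsWith(lines, "#")]))
  if ("quencher_uM" %in% names(df)) {
    df$quencher_M <- df$quencher_uM / 1e6
    df$quencher_uM <- NULL
  }
  if (!"quencher_M" %in% names(df)) {
    abort("format error: need a `quencher_M` (or `quencher_uM`) column.")
  }
  if (!any(df$quencher_M == 0)) {
    abort("no F0 point: file lacks the zero-quencher control row(s).")
  }
  temperature_K <- if (!is.null(meta$temperature_k)) {
    as.double(meta$temperature_k)
  } else if (!is.null(meta$temperature_c)) {
    as.double(meta$temperature_c) + 273.15
  } else 298
  protein_conc_M <- if (!is.null(meta$protein_conc_m)) {
    as.double(meta$protein_conc_m)
  } else if (!is.null(meta$protein_conc_um)) {
    as.double(meta$protein_conc_um) / 1e6
  } else NA_real_
  titration_series(
    df,
    mode = meta$mode %||% "emission",
    temperature_K = temperature_K,
    protein_conc_M = protein_conc_M,
    excitation_nm = .num_or_na(meta$excitation_nm)
  )
}

.num_or_na <- function(x) {
  if (is.null(x)) return(NA_real_)
  suppressWarnings(as.double(x))  # "NA" in a header parses to NA quietly
}

.parse_header <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  lines <- lines[grepl(":", lines)]
  keys <- tolower(trimws(sub(":.*$", "", lines)))
  vals <- trimws(sub("^[^:]*:", "", lines))
  setNames(as.list(vals), keys)
}
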