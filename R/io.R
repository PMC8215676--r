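# Delimited-text readers/writers for the pipeline's standard tables and a
# flat key=value serialisation for fitted surfaces.

#' Read replicate-level growth measurements
#'
#' Expects a delimited text file with a header and columns `intensity`
#' (umol/(m^2 s)), `day`, `replicate`, `dw_mg` (mg/seedling).  Fitting
#' aliases `t`, `I`, `dw` are added on read.
#'
#' @param path File path. @param sep Field separator (default tab;
#'   `","` for CSV).
#' @return Data frame of growth records.
#' @export
read_growth_data <- function(path, sep = "\t") {
  d <- read.delim(path, sep = sep, check.names = FALSE)
  need <- c("intensity", "day", "replicate", "dw_mg")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("growth table missing column(s): ", paste(miss, collapse = ", "))
  d$t <- d$day; d$I <- d$intensity; d$dw <- d$dw_mg
  d
}

#' @rdname read_growth_data
#' @param data Data frame with at least `intensity`, `day`, `replicate`,
#'   `dw_mg`.
#' @export
write_growth_data <- function(data, path, sep = "\t") {
  cols <- c("intensity", "day", "replicate", "dw_mg")
  if (!all(cols %in% names(data))) {
    data$intensity <- data$intensity %||% data$I
    data$day <- data$day %||% data$t
    data$dw_mg <- data$dw_mg %||% data$dw
    data$replicate <- data$replicate %||% seq_len(nrow(data))
  }
  write.table(data[cols], path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a photon-flux spectrum table
#'
#' Accepts either a per-wavelength table (columns `wavelength_nm`, `flux`)
#' or a per-band table (columns `band`, `flux`); both feed
#' [spectral_energy()].
#'
#' @param path File path. @param sep Field separator.
#' @return Data frame usable by [spectral_energy()].
#' @export
read_spectrum <- function(path, sep = "\t") {
  d <- read.delim(path, sep = sep, check.names = FALSE)
  if (!("flux" %in% names(d)) ||
      !any(c("wavelength_nm", "band") %in% names(d)))
    stop("spectrum table needs 'flux' plus 'wavelength_nm' or 'band'")
  d
}

#' Bundled illumination conditions of the measurement design
#'
#' Per-level band photon fluxes (umol/(m^2 s)), measured radiant energy
#' flux `E_I` (J/(m^2 s)) and the printed photon-to-energy ratio for the
#' ten white-LED intensity levels of the study design.
#'
#' @return Data frame with columns `intensity`, `uv`, `blue`, `green`,
#'   `red`, `far_red`, `E_I`, `ratio`.
#' @export
led_conditions <- function() {
  read.delim(system.file("extdata", "led_conditions.tsv", package = "ltbr"))
}

#' Read environment records
#'
#' Columns: `day`, `intensity`, `temp_C`, `rh_pct`.  An `abs_humidity`
#' column (g/m^3) is derived on read via [absolute_humidity()].
#'
#' @param path File path. @param sep Field separator.
#' @return Data frame of environment records.
#' @export
read_environment <- function(path, sep = "\t") {
  d <- read.delim(path, sep = sep, check.names = FALSE)
  need <- c("day", "intensity", "temp_C", "rh_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("environment table missing column(s): ",
         paste(miss, collapse = ", "))
  d$abs_humidity <- absolute_humidity(d$temp_C, d$rh_pct)
  d
}

#' Serialise / restore a piecewise surface as a flat key=value config
#'
#' One `key = value` pair per line: family names, named coefficients and
#' domain bounds.  Round-trips exactly at full double precision.
#'
#' @param surface An `ltbr_surface`. @param path Output file.
#' @return `write_surface_config()`: `path` invisibly;
#'   `read_surface_config()`: an `ltbr_surface`.
#' @export
write_surface_config <- function(surface, path) {
  stopifnot(inherits(surface, "ltbr_surface"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("region1.family = ", surface$region1$family),
    paste0("region1.", names(surface$region1$coef), " = ",
           fmt(surface$region1$coef)),
    paste0("region2.family = ", surface$region2$family),
    paste0("region2.", names(surface$region2$coef), " = ",
           fmt(surface$region2$coef)),
    paste0("domain.t_min = ", fmt(surface$t_range[1])),
    paste0("domain.t_max = ", fmt(surface$t_range[2])),
    paste0("domain.I_min = ", fmt(surface$I_range[1])),
    paste0("domain.I_max = ", fmt(surface$I_range[2])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_surface_config
#' @export
read_surface_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  grab <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, ".")) &
      !endsWith(keys, ".family")
    cf <- as.numeric(vals[sel])
    names(cf) <- sub(paste0("^", prefix, "\\."), "", keys[sel])
    fam <- vals[keys == paste0(prefix, ".family")]
    do.call(params_3d, c(list(fam), as.list(cf)))
  }
  ltbr_surface(
    grab("region1"), grab("region2"),
    t_range = as.numeric(c(vals[keys == "domain.t_min"],
                           vals[keys == "domain.t_max"])),
    I_range = as.numeric(c(vals[keys == "domain.I_min"],
                           vals[keys == "domain.I_max"])))
}
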