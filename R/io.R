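# Reading and writing the plain-text formats the package exchanges:
# diffusion-coefficient tables (CSV), binding-system configs (YAML), and
# dispersion traces (CSV with a commented metadata header).

.DTABLE_HEADER <- c("c1", "c2", "x1", "d11", "sd11", "d12", "sd12",
                    "d21", "sd21", "d22", "sd22")

#' Path to a packaged fixture file
#'
#' The package ships the published ternary diffusion-coefficient tables for
#' 5-fluorouracil with beta-cyclodextrin (`beta_cd_table2.csv`) and with
#' sodium dodecyl sulfate (`sds_table5.csv`), the species limiting
#' diffusivities (`species_table3.csv`, `species_table6.csv`), and ready
#' binding-system configs (`beta_cd_system.yml`, `sds_system.yml`).
#'
#' @param file Fixture file name; with no argument, lists available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' ternadiff_extdata()
#' ternadiff_extdata("beta_cd_table2.csv")
#' @export
ternadiff_extdata <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "ternadiff")))
  path <- system.file("extdata", file, package = "ternadiff")
  if (path == "") stop("no packaged fixture named '", file, "'")
  path
}

#' Read a ternary diffusion-coefficient table
#'
#' Reads a CSV with header
#' `c1,c2,x1,d11,sd11,d12,sd12,d21,sd21,d22,sd22` (concentrations in
#' mol dm^-3, coefficients in 1e-9 m^2 s^-1; `#` lines are comments).
#' Rows are validated: all cells numeric, concentrations non-negative with
#' `c1 + c2 > 0`, and the stored `x1` consistent with `c1/(c1+c2)` within
#' `x1_tol`; violations raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @param x1_tol Tolerance for the `x1` consistency check.
#' @return A `"dtable"` data.frame with the canonical columns (and `x1`
#'   recomputed from the concentrations).
#' @examples
#' read_dtable(ternadiff_extdata("beta_cd_table2.csv"))
#' @export
read_dtable <- function(path, x1_tol = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, comment.char = "#",
                                 strip.white = TRUE),
                 error = function(e)
                   stop("empty or unparseable diffusion table ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty diffusion table: ", path)
  miss <- setdiff(.DTABLE_HEADER, names(df))
  if (length(miss))
    stop("diffusion table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (cn in .DTABLE_HEADER) {
    if (!is.numeric(df[[cn]])) {
      conv <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(conv) & !is.na(df[[cn]]) & nzchar(trimws(df[[cn]])))
      if (length(bad))
        stop("non-numeric cell '", df[[cn]][bad[1L]], "' in column '", cn,
             "', row ", bad[1L], " of ", path)
      df[[cn]] <- conv
    }
  }
  .validate_dtable(df, check_x1 = TRUE, x1_tol = x1_tol)
}

#' Write a ternary diffusion-coefficient table
#'
#' Inverse of [read_dtable()]; numeric fields round-trip exactly (written
#' with full precision).
#'
#' @param dtable A diffusion table data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dtable <- function(dtable, path) {
  df <- .validate_dtable(as.data.frame(dtable), check_x1 = FALSE)
  cells <- vapply(df, function(col)
    vapply(col, function(v)
      if (is.na(v)) "" else format(v, digits = 17), character(1L)),
    character(nrow(df)))
  cells <- matrix(cells, nrow(df), length(df))
  lines <- c(paste(.DTABLE_HEADER, collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binding system from a YAML config
#'
#' The config is a flat key/value file with keys `d_free_drug`,
#' `d_free_carrier`, `d_complex`, optional `d_drug_infinite_dilution`,
#' `k_assoc`, and optional `cmc` (omitted or null for non-micellar
#' carriers).
#'
#' @param path YAML file path.
#' @return A [binding_system()].
#' @examples
#' read_binding_system(ternadiff_extdata("beta_cd_system.yml"))
#' @export
read_binding_system <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- c("d_free_drug", "d_free_carrier", "d_complex", "k_assoc")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("binding-system config ", path, " is missing keys: ",
         paste(miss, collapse = ", "))
  d0 <- if (!is.null(cfg$d_drug_infinite_dilution))
    cfg$d_drug_infinite_dilution else NA_real_
  binding_system(
    species_diffusivities(cfg$d_free_drug, cfg$d_free_carrier,
                          cfg$d_complex, d0),
    k_assoc = cfg$k_assoc,
    cmc = cfg$cmc)
}

#' Write a dispersion trace to CSV
#'
#' Two-column CSV `time_s,voltage` preceded by a `#`-prefixed header block
#' carrying the instrument geometry, the injection excess, the noise SD and
#' the seed, so [read_trace()] restores the full object.
#'
#' @param trace A `"dispersion_trace"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "dispersion_trace"))
  g <- trace$geometry
  hdr <- c(
    sprintf("# tube_length: %.17g", g$tube_length),
    sprintf("# tube_radius: %.17g", g$tube_radius),
    sprintf("# injection_volume: %.17g", g$injection_volume),
    sprintf("# sampling_interval: %.17g", g$sampling_interval),
    sprintf("# retention_time_nominal: %.17g", g$retention_time_nominal),
    sprintf("# injection_excess: %.17g %.17g",
            trace$injection_excess[1L], trace$injection_excess[2L]),
    sprintf("# noise_sd: %.17g", trace$noise_sd),
    sprintf("# seed: %s", if (is.null(trace$seed)) "NA" else trace$seed))
  body <- paste(format(trace$times, digits = 17),
                format(trace$voltages, digits = 17), sep = ",")
  writeLines(c(hdr, "time_s,voltage", body), path)
  invisible(path)
}

#' Read a dispersion trace written by [write_trace()]
#'
#' @param path Trace CSV path.
#' @return A `"dispersion_trace"`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- strsplit(trimws(sub("^[^:]*:\\s*", "", kv)), "\\s+")[[1L]]
    meta[[key]] <- suppressWarnings(as.numeric(val))
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  if (!all(c("time_s", "voltage") %in% names(df)))
    stop("trace file ", path, " lacks the time_s,voltage header")
  geom <- instrument_geometry(
    tube_length = meta$tube_length, tube_radius = meta$tube_radius,
    injection_volume = meta$injection_volume,
    sampling_interval = meta$sampling_interval,
    retention_time_nominal = meta$retention_time_nominal)
  seed <- meta$seed
  structure(list(times = df$time_s, voltages = df$voltage, geometry = geom,
                 injection_excess = meta$injection_excess,
                 noise_sd = meta$noise_sd,
                 seed = if (length(seed) && !is.na(seed)) seed else NULL),
            class = "dispersion_trace")
}
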