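## Readers and writers for the plain-text interchange formats: CSV tables
## with unit-suffixed headers, multi-page TIFF stacks with JSON sidecars.

#' Read a CSV table against a required schema
#'
#' @param path CSV file with a header row.
#' @param schema Character vector of required column names; unit suffixes
#'   (`_nM`, `_uM`, `_s`, `_ns`) are part of the contract.
#' @return Data frame with at least the schema columns, numerics coerced.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, comment.char = "#")
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop_domain("missing required column(s): ",
                paste(missing, collapse = ", "))
  for (nm in schema)
    if (grepl("_(nM|uM|s|ns|hz)$", nm) || nm %in% c("dF", "signal",
                                                    "counts", "irf",
                                                    "ratio", "intensity",
                                                    "response"))
      df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Read a dose-response curve from CSV
#'
#' Expected columns: `ligand_total_nM`, `dF`; optional `ligand_id`, `pH`.
#' @param path CSV file.
#' @return A [dose_response()].
#' @export
read_dose_response <- function(path) {
  df <- read_table(path, c("ligand_total_nM", "dF"))
  dose_response(df$ligand_total_nM, df$dF,
                ligand_id = if ("ligand_id" %in% names(df))
                  as.character(df$ligand_id[1]) else "cAMP",
                pH = if ("pH" %in% names(df)) df$pH[1] else NA)
}

#' Write a dose-response curve to CSV
#' @param curve A [dose_response()].
#' @param path Output path.
#' @export
write_dose_response <- function(curve, path) {
  df <- as.data.frame(curve)
  df$ligand_id <- attr(curve, "ligand_id")
  df$pH <- attr(curve, "pH")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a stopped-flow trace set (long CSV + JSON metadata)
#'
#' CSV columns: `trace_id`, `L_T_uM`, `time_s`, `signal`; the JSON
#' sidecar supplies `E_T_uM` and `sampling_rate_hz`.
#' @param csv_path Long-format CSV.
#' @param meta_path JSON metadata file.
#' @return A [sf_traceset()].
#' @export
read_traceset <- function(csv_path, meta_path) {
  df <- read_table(csv_path, c("trace_id", "L_T_uM", "time_s", "signal"))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$E_T_uM)) stop_domain("metadata must provide E_T_uM")
  traces <- lapply(split(df, df$trace_id), function(d)
    list(lt_uM = d$L_T_uM[1], times = d$time_s, signal = d$signal))
  sf_traceset(unname(traces), meta$E_T_uM,
              if (!is.null(meta$sampling_rate_hz)) meta$sampling_rate_hz
              else 200)
}

#' Write a stopped-flow trace set to long CSV + JSON metadata
#' @param ts A [sf_traceset()].
#' @param csv_path,meta_path Output paths.
#' @export
write_traceset <- function(ts, csv_path, meta_path) {
  rows <- do.call(rbind, lapply(seq_along(ts$traces), function(i) {
    tr <- ts$traces[[i]]
    data.frame(trace_id = i, L_T_uM = tr$lt_uM, time_s = tr$times,
               signal = tr$signal)
  }))
  write.csv(rows, csv_path, row.names = FALSE)
  jsonlite::write_json(list(E_T_uM = ts$et_uM,
                            sampling_rate_hz = ts$sampling_rate_hz),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a null-point experiment from CSV
#'
#' Format: a header record line `# R_basal=<x> analyte=<cAMP|pH>` followed
#' by a CSV with columns `concentration`, `ratio`.
#' @param path CSV file.
#' @return A [nullpoint_experiment()].
#' @export
read_nullpoint <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^#", first))
    stop_domain("missing header record line (# R_basal=... analyte=...)")
  rb <- as.numeric(sub(".*R_basal=([0-9.eE+-]+).*", "\\1", first))
  an <- sub(".*analyte=([A-Za-z]+).*", "\\1", first)
  df <- read_table(path, c("concentration", "ratio"))
  nullpoint_experiment(rb, as.numeric(df$concentration),
                       as.numeric(df$ratio), analyte = an)
}

#' Write a null-point experiment to CSV
#' @param exp A [nullpoint_experiment()].
#' @param path Output path.
#' @export
write_nullpoint <- function(exp, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# R_basal=%.15g analyte=%s", exp$r_basal, exp$analyte),
             con)
  write.csv(exp$titration, con, row.names = FALSE)
  invisible(path)
}

#' Read a TCSPC decay from CSV
#'
#' Columns: `time_ns`, `counts`, `irf`.
#' @param path CSV file.
#' @return A [tcspc_decay()].
#' @export
read_decay <- function(path) {
  df <- read_table(path, c("time_ns", "counts", "irf"))
  tcspc_decay(df$time_ns, df$counts, df$irf)
}

#' Write a TCSPC decay to CSV
#' @param decay A [tcspc_decay()].
#' @param path Output path.
#' @export
write_decay <- function(decay, path) {
  write.csv(data.frame(time_ns = decay$time_ns, counts = decay$counts,
                       irf = decay$irf), path, row.names = FALSE)
  invisible(path)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' @param stack 3D array `[rows, cols, pages]`.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param meta Named list of metadata; must include `pixel_size_um`.
#' @export
write_stack <- function(stack, path, meta) {
  if (is.null(meta$pixel_size_um)) stop_domain("meta must give pixel_size_um")
  mx <- max(stack, 1)
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) pmin(pmax(stack[, , k] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta$scale <- mx
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack with its JSON sidecar
#'
#' @param path TIFF path; metadata is read from `<path>.json`.
#' @return List with `stack` (3D array, original scale restored) and
#'   `meta`.
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_domain("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop_domain("sidecar must provide pixel_size_um")
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- simplify2array(pages)
  if (!is.null(meta$scale)) stack <- stack * meta$scale
  list(stack = stack, meta = meta)
}

#' Run an analysis stage from a configuration list
#'
#' Thin reproducible driver: dispatches on `config$stage`, reads the
#' declared inputs, runs the corresponding fitting function and writes a
#' JSON result plus a manifest (inputs, parameters, package version,
#' seed). Stages: `fit_binding`, `fit_kinetics`, `calibrate`, `fit_hill`.
#'
#' @param config Named list; see the stage functions for required fields
#'   (`input`, `out`, stage-specific parameters, optional `seed`).
#' @return The result object, invisibly; side effect: files under
#'   `config$out`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$stage)) stop_domain("config$stage is required")
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  result <- switch(
    config$stage,
    fit_binding = {
      curve <- read_dose_response(config$input)
      fit_binding(curve, et_uM = config$protein_uM)
    },
    fit_kinetics = {
      ts <- read_traceset(config$input, config$meta)
      global_fit_kinetics(ts)
    },
    calibrate = {
      exp <- read_nullpoint(config$input)
      nullpoint_calibrate(exp, range = config$range)
    },
    fit_hill = {
      df <- read_table(config$input, c("dose_uM", "response"))
      fit_hill(df$dose_uM, df$response, n_h_fixed = config$n_h_fixed)
    },
    stop_domain("unknown stage: ", config$stage)
  )
  jsonlite::write_json(
    list(estimate = result$estimate, se = result$se, rss = result$rss),
    file.path(config$out, "result.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(stage = config$stage, config = config[setdiff(names(config),
                                                       "stage")],
         package_version = as.character(utils::packageVersion("fretquant")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(config$out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(result)
}
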