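#' Write a labelled connectivity matrix as delimited text
#'
#' Tab-separated, ROI labels as header row and first column, full numeric
#' precision (round-trips within 1e-12), diagonal written as the \code{NaN}
#' sentinel.
#'
#' @param m \code{connectivity_matrix} or plain square matrix.
#' @param path output file.
#' @param labels ROI labels (default \code{ROI01..}).
#' @export
write_roi_matrix <- function(m, path, labels = NULL) {
  vals <- if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
  n <- nrow(vals)
  if (is.null(labels)) {
    labels <- rownames(vals)
    if (is.null(labels)) labels <- sprintf("ROI%02d", seq_len(n))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("roi", labels), collapse = "\t"), con)
  for (r in seq_len(n)) {
    row <- vapply(vals[r, ], function(v)
      if (is.na(v)) "NaN" else formatC(v, format = "g", digits = 17),
      character(1))
    writeLines(paste(c(labels[r], row), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a labelled matrix written by \code{\link{write_roi_matrix}}
#'
#' @param path input file.
#' @return numeric matrix with ROI dimnames; \code{NaN} sentinel preserved.
#' @export
read_roi_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("parse error at line 1: empty file")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "roi")
    stop("parse error at line 1: missing 'roi' header row")
  labels <- hdr[-1]
  n <- length(labels)
  if (length(lines) != n + 1)
    stop("parse error at line ", length(lines), ": expected ", n,
         " data rows, found ", length(lines) - 1)
  vals <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (r in seq_len(n)) {
    parts <- strsplit(lines[r + 1], "\t", fixed = TRUE)[[1]]
    if (length(parts) != n + 1)
      stop("parse error at line ", r + 1, ": expected ", n + 1, " fields")
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v) && any(parts[-1][is.na(v)] != "NaN"))
      stop("parse error at line ", r + 1, ": non-numeric value")
    vals[r, ] <- v
  }
  vals
}

#' Write a spectrum as two-column delimited text
#'
#' Columns \code{freq_hz} and \code{normalized_power}, tab-separated.
#'
#' @param spec \code{power_spectrum}.
#' @param path output file.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "power_spectrum"))
  df <- data.frame(freq_hz = formatC(spec$freqs, format = "g", digits = 17),
                   normalized_power = formatC(spec$power, format = "g",
                                              digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by \code{\link{write_spectrum}}
#'
#' @param path input file.
#' @param band band limits to attach (default from the grid).
#' @return \code{power_spectrum}.
#' @export
read_spectrum <- function(path, band = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("freq_hz", "normalized_power") %in% names(df)))
    stop("parse error at line 1: expected freq_hz / normalized_power header")
  if (is.null(band)) band <- range(df$freq_hz)
  structure(list(freqs = df$freq_hz, power = df$normalized_power,
                 band = as.numeric(band),
                 df = if (nrow(df) > 1) diff(df$freq_hz[1:2]) else NA_real_,
                 n_epochs = NA_integer_, n_rois = NA_integer_),
            class = "power_spectrum")
}

#' Write the consistency table as tidy delimited text
#'
#' @param table \code{consistency_table}.
#' @param path output file.
#' @export
write_consistency_table <- function(table, path) {
  tab <- as.data.frame(table)
  tab$value <- formatC(tab$value, format = "g", digits = 17)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a consistency table written by
#' \code{\link{write_consistency_table}}
#'
#' @param path input file.
#' @return \code{consistency_table}.
#' @export
read_consistency_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject", "kind", "key", "metric", "value")
  if (!all(need %in% names(df)))
    stop("parse error at line 1: expected columns ",
         paste(need, collapse = ", "))
  class(df) <- c("consistency_table", "data.frame")
  df
}

#' Write a simulated session to a directory
#'
#' One directory per subject/timepoint: \code{data.tsv} (channels x
#' samples), \code{geometry.tsv} (channel, kind, site coordinates, normal,
#' baseline) and \code{meta.json} (system, rate, head model, good-channel
#' mask).
#'
#' @param rec \code{sensor_recording}.
#' @param dir output directory (created if needed).
#' @export
write_sensor_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "sensor_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    cbind(channel = rec$array$channels$id,
          as.data.frame(formatC(rec$data, format = "g", digits = 17))),
    file.path(dir, "data.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(rec$array$channels, file.path(dir, "geometry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(system = rec$system, rate = rec$rate,
         head = list(center = rec$head$center, radius = rec$head$radius),
         good_channel_mask = rec$good_channel_mask),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session directory written by
#' \code{\link{write_sensor_recording}}
#'
#' Geometry is restored as channel metadata; the coil-level model is rebuilt
#' from the stored array kind.
#'
#' @param dir session directory.
#' @return \code{sensor_recording}.
#' @export
read_sensor_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  raw <- utils::read.table(file.path(dir, "data.tsv"), sep = "\t",
                           header = FALSE, stringsAsFactors = FALSE)
  data <- as.matrix(raw[, -1, drop = FALSE])
  dimnames(data) <- NULL
  array <- build_sensor_array(meta$system)
  head <- head_model(center = unlist(meta$head$center),
                     radius = meta$head$radius)
  structure(list(data = data, rate = meta$rate, array = array, head = head,
                 system = meta$system,
                 good_channel_mask = as.logical(meta$good_channel_mask)),
            class = "sensor_recording")
}

#' Write all artifacts of a pipeline run
#'
#' Spectra, connectivity matrices and the consistency table as delimited
#' text plus a JSON run report (per-session provenance, statistics, file
#' manifest with md5 checksums, package version). Re-running with the same
#' config and seed reproduces identical checksums.
#'
#' @param result \code{meg_consistency}.
#' @param outdir output directory.
#' @return path of the report JSON, invisibly.
#' @export
write_run_artifacts <- function(result, outdir) {
  stopifnot(inherits(result, "meg_consistency"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  tps <- result$config$cohort$timepoints
  for (i in seq_along(result$spectra)) {
    for (tp in tps) {
      f <- file.path(outdir, sprintf("spectrum_S%02d_%s.tsv", i, tp))
      write_spectrum(result$spectra[[i]][[tp]], f)
      files <- c(files, f)
      for (band in c("alpha", "beta")) {
        f <- file.path(outdir, sprintf("aec_%s_S%02d_%s.tsv", band, i, tp))
        write_roi_matrix(result$conn[[i]][[tp]][[band]], f)
        files <- c(files, f)
      }
    }
  }
  f <- file.path(outdir, "consistency_table.tsv")
  write_consistency_table(result$table, f)
  files <- c(files, f)
  stats_json <- lapply(result$stats, function(s)
    list(name = s$name, statistic = s$statistic, df = s$df, p = s$p,
         effect_size = s$effect_size, method = s$method, note = s$note))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report <- list(
    version = result$version,
    seed = result$config$seed,
    settings = list(
      bands = result$config$bands,
      bad_channel_z = result$config$bad_channel_z,
      artifact_mad = result$config$artifact_mad,
      cov_reg = result$config$cov_reg,
      decimate_stage = as.list(result$config$decimate_stage),
      duration_s = result$config$cohort$duration_s,
      n_subjects = result$config$cohort$n_subjects),
    sessions = result$provenance,
    statistics = stats_json,
    manifest = manifest)
  rp <- file.path(outdir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(rp)
}
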