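#' Pipeline run configuration
#'
#' Bundles the cohort specification, analysis bands, preprocessing
#' thresholds and the master seed. Every analysis default is overridable
#' here and the applied values are echoed in the run report.
#'
#' @param cohort \code{\link{cohort_spec}}.
#' @param bands named list: \code{alpha}, \code{beta} (connectivity),
#'   \code{spectral} (normalized-spectrum band), \code{beamformer}
#'   (covariance/reconstruction band), all in Hz.
#' @param bad_channel_z robust z threshold for channel flagging.
#' @param artifact_mad robust z threshold for epoch rejection.
#' @param cov_reg covariance diagonal-loading fraction.
#' @param decimate_stage named map timepoint -> \code{"none"},
#'   \code{"sensor"} or \code{"source"}: where the decimation to 312.5 Hz
#'   happens for that session (default: BL none, FU1 sensor, FU2 source).
#' @param centroids 90 x 3 source layout (default
#'   \code{\link{default_centroids}}).
#' @param outdir optional output directory for artifacts.
#' @param seed master seed; defaults to the cohort's.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(cohort = cohort_spec(),
                       bands = list(alpha = c(8, 13), beta = c(13, 30),
                                    spectral = c(0.5, 30),
                                    beamformer = c(0.5, 48)),
                       bad_channel_z = 4, artifact_mad = 6, cov_reg = 0.05,
                       decimate_stage = NULL,
                       centroids = default_centroids(),
                       outdir = NULL, seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_spec"))
  for (b in bands) {
    b <- band_limits(b)
    if (b[1] <= 0 || b[2] > 156.25)
      stop("config error: band outside (0, Nyquist] at 312.5 Hz")
  }
  if (is.null(decimate_stage)) {
    rates <- cohort$native_rate_per_timepoint[cohort$timepoints]
    decimate_stage <- ifelse(rates == 312.5, "none",
                             ifelse(rates == 625, "sensor", "source"))
    names(decimate_stage) <- cohort$timepoints
  }
  stopifnot(all(decimate_stage %in% c("none", "sensor", "source")),
            all(cohort$timepoints %in% names(decimate_stage)))
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3) stop("config error: centroids must be n x 3")
  structure(list(cohort = cohort, bands = bands,
                 bad_channel_z = bad_channel_z, artifact_mad = artifact_mad,
                 cov_reg = cov_reg, decimate_stage = decimate_stage,
                 centroids = centroids, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# one session: simulate -> project -> flag -> beamform (with the
# stage-appropriate decimation) -> epoch -> artifact-reject
.run_session <- function(config, fp, tp, arrays, head, orientations) {
  sp <- config$cohort
  rate <- sp$native_rate_per_timepoint[[tp]]
  array <- arrays[[sp$system_per_timepoint[[tp]]]]
  seed_sess <- derive_seed(config$seed, "session", fp$subject, tp)
  src <- simulate_source_activity(fp, rate, sp$duration_s, seed_sess)
  rec <- project_to_sensors(src, config$centroids, orientations, array, head,
                            noise_std = sp$noise,
                            seed = derive_seed(config$seed, "noise",
                                               fp$subject, tp))
  bad <- flag_bad_channels(rec, config$bad_channel_z)
  rec$good_channel_mask <- rec$good_channel_mask & !bad
  stage <- config$decimate_stage[[tp]]
  if (stage == "sensor" && rate > 312.5) {
    d <- decimate(rec$data, rate, 312.5)
    rec$data <- d$data; rec$rate <- d$rate
  }
  roi <- reconstruct_roi_series(rec, config$centroids, head,
                                band = config$bands$beamformer,
                                reg = config$cov_reg)
  rate_src <- attr(roi, "rate")
  if (stage == "source" && rate_src > 312.5) {
    d <- decimate(unclass(roi)[, , drop = FALSE], rate_src, 312.5)
    series <- d$data; rate_src <- d$rate
  } else series <- unclass(roi)[, , drop = FALSE]
  if (abs(rate_src - 312.5) > 1e-9)
    stop("session ", tp, ": source series not at 312.5 Hz")
  ep0 <- split_epochs(series, rate_src)
  ep <- reject_artifact_epochs(ep0, config$artifact_mad)
  list(epochs = ep, n_epochs_raw = dim(ep0$data)[1],
       flagged_channels = which(bad),
       dropped_epochs = setdiff(ep0$kept_epoch_ids, ep$kept_epoch_ids))
}

#' Run the full in-silico consistency pipeline
#'
#' Executes, for every subject and timepoint: source simulation from the
#' subject's fingerprint, forward projection onto that session's sensor
#' system, bad-channel flagging, scalar-beamformer reconstruction at the 90
#' centroids (decimating at the sensor or source stage as the session's
#' native rate requires), epoching and artifact rejection; then computes
#' area-normalized spectra, alpha/beta AEC-c connectivity matrices, the
#' within/between consistency table and the statistical layer
#' (repeated-measures ANOVAs across timepoints, within-vs-between unpaired
#' t-tests, post-hoc paired contrasts, peak frequencies). Deterministic
#' given the config seed.
#'
#' @param config \code{\link{run_config}} (or a \code{cohort_spec}, which is
#'   wrapped with default settings).
#' @param verbose print per-stage progress?
#' @return object of class \code{meg_consistency}: fields \code{table}
#'   (consistency table), \code{stats}, \code{spectra}, \code{conn},
#'   \code{peak_freq}, \code{provenance}, \code{config}.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (inherits(config, "cohort_spec")) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  sp <- config$cohort
  head <- head_model()
  kinds <- unique(sp$system_per_timepoint[sp$timepoints])
  arrays <- setNames(lapply(kinds, build_sensor_array), kinds)
  fps <- make_cohort(sp)
  # fixed per-subject dipole orientations, shared by that subject's sessions
  orientations <- lapply(seq_len(sp$n_subjects), function(i)
    with_seed(derive_seed(config$seed, "orient", i),
              random_tangential(config$centroids, head)))
  spectra <- list(); conn <- list(); prov <- list(); peaks <- NULL
  for (i in seq_len(sp$n_subjects)) {
    spectra[[i]] <- list(); conn[[i]] <- list()
    for (tp in sp$timepoints) {
      t0 <- proc.time()[3]
      ses <- tryCatch(
        .run_session(config, fps[[i]], tp, arrays, head, orientations[[i]]),
        error = function(e) stop("stage failure in session subject ", i,
                                 " / ", tp, ": ", conditionMessage(e)))
      spec <- average_normalized_spectrum(ses$epochs,
                                          band = config$bands$spectral)
      spectra[[i]][[tp]] <- spec
      conn[[i]][[tp]] <- list(
        alpha = aec_matrix(ses$epochs, config$bands$alpha),
        beta = aec_matrix(ses$epochs, config$bands$beta))
      peaks <- rbind(peaks, data.frame(
        subject = i, timepoint = tp,
        peak_hz = peak_frequency(spec), stringsAsFactors = FALSE))
      prov[[paste0("S", i, "_", tp)]] <- list(
        subject = i, timepoint = tp,
        seed = derive_seed(config$seed, "session", i, tp),
        n_epochs_raw = ses$n_epochs_raw,
        n_epochs_kept = dim(ses$epochs$data)[1],
        flagged_channels = ses$flagged_channels,
        dropped_epochs = ses$dropped_epochs,
        elapsed_s = round(proc.time()[3] - t0, 2))
      if (verbose)
        message(sprintf("subject %d %s: %d epochs (%.1f s)", i, tp,
                        dim(ses$epochs$data)[1],
                        proc.time()[3] - t0))
    }
  }
  table <- build_consistency_table(spectra, conn, sp$timepoints)
  stats <- .pipeline_stats(table, peaks, sp$timepoints)
  res <- structure(list(table = table, stats = stats, spectra = spectra,
                        conn = conn, peak_freq = peaks,
                        provenance = prov, config = config,
                        version = as.character(packageVersion("megconsist"))),
                   class = "meg_consistency")
  if (!is.null(config$outdir)) write_run_artifacts(res, config$outdir)
  res
}

# the statistical layer over the consistency table
.pipeline_stats <- function(table, peaks, timepoints) {
  out <- list()
  k <- length(timepoints)
  pairs <- apply(utils::combn(k, 2), 2, function(p)
    paste0(timepoints[p[1]], "-", timepoints[p[2]]))
  for (metric in unique(table$metric)) {
    wtab <- table[table$kind == "within" & table$metric == metric, ]
    btab <- table[table$kind == "between" & table$metric == metric, ]
    wmat <- sapply(pairs, function(p) wtab$value[wtab$key == p])
    bmat <- sapply(timepoints, function(tp) btab$value[btab$key == tp])
    out[[paste0(metric, "_within_anova")]] <-
      rm_anova(wmat, paste0("within over pairs (", metric, ")"))
    out[[paste0(metric, "_between_anova")]] <-
      rm_anova(bmat, paste0("between over timepoints (", metric, ")"))
    out[[paste0(metric, "_within_vs_between")]] <-
      compare_within_between(table, metric)
    for (pc in seq_len(ncol(utils::combn(k, 2)))) {
      ij <- utils::combn(k, 2)[, pc]
      out[[paste0(metric, "_between_paired_", timepoints[ij[1]], "_",
                  timepoints[ij[2]])]] <-
        paired_t(bmat[, ij[1]], bmat[, ij[2]],
                 paste0("between ", timepoints[ij[1]], " vs ",
                        timepoints[ij[2]], " (", metric, ")"))
    }
  }
  pm <- sapply(timepoints, function(tp)
    peaks$peak_hz[peaks$timepoint == tp])
  out$peak_freq_anova <- rm_anova(pm, "peak frequency over timepoints")
  out
}

#' @export
print.meg_consistency <- function(x, ...) {
  sp <- x$config$cohort
  cat(sprintf(
    "<meg_consistency: %d subjects x %d timepoints, %g s sessions, seed %d>\n",
    sp$n_subjects, length(sp$timepoints), sp$duration_s, x$config$seed))
  cat("Use summary() for consistency means and test statistics.\n")
  invisible(x)
}

#' @export
summary.meg_consistency <- function(object, ...) {
  tab <- object$table
  agg <- stats::aggregate(value ~ metric + kind + key, tab,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  cat("Consistency values, mean (SD):\n")
  for (metric in unique(tab$metric)) {
    cat(sprintf("  %s\n", metric))
    sub <- agg[agg$metric == metric, ]
    for (r in seq_len(nrow(sub)))
      cat(sprintf("    %-8s %-8s %.3f (%.3f)\n", sub$kind[r], sub$key[r],
                  sub$value[r, "mean"], sub$value[r, "sd"]))
  }
  cat("\nStatistics:\n")
  for (s in object$stats) print(s)
  invisible(object)
}

#' @export
plot.meg_consistency <- function(x, metric = "spearman_alpha", ...) {
  tab <- x$table[x$table$metric == metric, ]
  grp <- interaction(tab$kind, tab$key, drop = TRUE)
  graphics::boxplot(tab$value ~ grp, las = 2, xlab = "",
                    ylab = metric,
                    main = sprintf("Within vs between consistency (%s)",
                                   metric), ...)
  graphics::stripchart(tab$value ~ grp, vertical = TRUE, add = TRUE,
                       pch = 16, method = "jitter",
                       col = grDevices::adjustcolor("steelblue", 0.7))
  invisible(x)
}

#' Group-level ROI-wise within-subject consistency map
#'
#' Mean over subjects and the three within-subject timepoint pairs of the
#' per-ROI Spearman consistency of connectivity profiles.
#'
#' @param result \code{meg_consistency}.
#' @param band \code{"alpha"} or \code{"beta"}.
#' @return numeric vector of per-ROI mean consistency values.
#' @export
consistency_roi_map <- function(result, band = c("alpha", "beta")) {
  band <- match.arg(band)
  tps <- result$config$cohort$timepoints
  pairs <- utils::combn(length(tps), 2)
  maps <- NULL
  for (i in seq_along(result$conn)) {
    for (pc in seq_len(ncol(pairs))) {
      a <- result$conn[[i]][[tps[pairs[1, pc]]]][[band]]
      b <- result$conn[[i]][[tps[pairs[2, pc]]]][[band]]
      maps <- cbind(maps, roiwise_consistency_map(a, b))
    }
  }
  rowMeans(maps)
}
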