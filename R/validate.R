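# Stride-matched agreement statistics (error summaries, Pearson r,
# Bland-Altman bias and limits of agreement) and the IPM-vs-ZUPT
# comparison harness.

#' Match strides between two result tables by mid-stance time
#'
#' Greedy nearest-time matching of `ms_start_s` within a tolerance;
#' unmatched strides are excluded (mirroring the exclusion of invalid
#' reference strides in a motion-capture comparison).
#'
#' @param est,ref Stride tables (data.frames with `ms_start_s`).
#' @param tol_s Matching tolerance, seconds.
#' @return A list with `est` and `ref` (row-aligned matched tables) and
#'   `n_unmatched_est`, `n_unmatched_ref`.
#' @export
pair_strides <- function(est, ref, tol_s = 0.2) {
  if (nrow(est) == 0L || nrow(ref) == 0L) {
    warning("empty stride table; no pairs")
    return(list(est = est[0, ], ref = ref[0, ],
                n_unmatched_est = nrow(est), n_unmatched_ref = nrow(ref)))
  }
  d <- abs(outer(est$ms_start_s, ref$ms_start_s, "-"))
  pairs <- matrix(integer(0), ncol = 2)
  while (TRUE) {
    m <- which.min(d)
    if (length(m) == 0L || d[m] > tol_s || !is.finite(d[m])) break
    i <- (m - 1L) %% nrow(d) + 1L
    k <- (m - 1L) %/% nrow(d) + 1L
    pairs <- rbind(pairs, c(i, k))
    d[i, ] <- Inf; d[, k] <- Inf
    if (all(!is.finite(d))) break
  }
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  n_un_e <- nrow(est) - nrow(pairs)
  n_un_r <- nrow(ref) - nrow(pairs)
  if (n_un_e + n_un_r > 0)
    message(n_un_e, " estimated / ", n_un_r,
            " reference stride(s) unmatched (excluded)")
  list(est = est[pairs[, 1], , drop = FALSE],
       ref = ref[pairs[, 2], , drop = FALSE],
       n_unmatched_est = n_un_e, n_unmatched_ref = n_un_r)
}

#' Agreement statistics for one gait parameter
#'
#' Error is estimated minus reference per matched stride. Reports the mean
#' and SD of the error, of the absolute error, and of the relative
#' absolute error in percent (denominator: the reference value; pairs with
#' a zero reference are excluded from the relative metric), the Pearson
#' correlation, and the Bland-Altman bias with 1.96-SD limits of
#' agreement.
#'
#' @param pairs A [pair_strides()] result.
#' @param field Column name of the parameter, e.g. `"stride_length_m"`.
#' @return A list of class `agreement_stats`: `n`, `mean_error`,
#'   `sd_error`, `mean_abs_error`, `sd_abs_error`, `mean_rel_abs_error_pct`,
#'   `sd_rel_abs_error_pct`, `pearson_r` (`NA` with `r_defined = FALSE`
#'   when either series is constant), `ba_bias`, `ba_loa_low`,
#'   `ba_loa_high`.
#' @export
agreement <- function(pairs, field = "stride_length_m") {
  x <- pairs$est[[field]]
  y <- pairs$ref[[field]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2L) stop("need at least 2 matched strides")
  e <- x - y
  ae <- abs(e)
  nz <- y != 0
  if (any(!nz))
    message(sum(!nz), " pair(s) with zero reference excluded from the ",
            "relative error metric")
  rel <- 100 * ae[nz] / abs(y[nz])
  r_defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  r <- if (r_defined) stats::cor(x, y) else NA_real_
  bias <- mean(e)
  sde <- stats::sd(e)
  structure(list(n = n,
                 mean_error = bias, sd_error = sde,
                 mean_abs_error = mean(ae), sd_abs_error = stats::sd(ae),
                 mean_rel_abs_error_pct = mean(rel),
                 sd_rel_abs_error_pct = stats::sd(rel),
                 pearson_r = r, r_defined = r_defined,
                 ba_bias = bias,
                 ba_loa_low = bias - 1.96 * sde,
                 ba_loa_high = bias + 1.96 * sde),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats> n=%d E=%.4f (%.4f) |E|=%.4f (%.4f) |E|%%=%.2f (%.2f)\n",
    x$n, x$mean_error, x$sd_error, x$mean_abs_error, x$sd_abs_error,
    x$mean_rel_abs_error_pct, x$sd_rel_abs_error_pct))
  cat(sprintf("  r=%s  bias=%.4f  LOA=[%.4f, %.4f]\n",
              ifelse(x$r_defined, sprintf("%.3f", x$pearson_r), "undefined"),
              x$ba_bias, x$ba_loa_low, x$ba_loa_high))
  invisible(x)
}

#' Flatten agreement statistics to a one-row data.frame
#' @param stats An `agreement_stats` object.
#' @param label Optional label column.
#' @return One-row data.frame.
#' @export
agreement_as_row <- function(stats, label = NA_character_) {
  data.frame(label = label, n = stats$n,
             mean_error = stats$mean_error, sd_error = stats$sd_error,
             mean_abs_error = stats$mean_abs_error,
             sd_abs_error = stats$sd_abs_error,
             mean_rel_abs_error_pct = stats$mean_rel_abs_error_pct,
             sd_rel_abs_error_pct = stats$sd_rel_abs_error_pct,
             pearson_r = stats$pearson_r, ba_bias = stats$ba_bias,
             ba_loa_low = stats$ba_loa_low,
             ba_loa_high = stats$ba_loa_high)
}

#' Compare the pendulum update against the zero-velocity baseline
#'
#' Runs the full reconstruction twice on a synthetic trial (`method =
#' "ipm"` and `"zupt"`), matches each result against the simulator ground
#' truth, and returns agreement statistics per parameter and method.
#'
#' @param trial A [simulate_walk()] result.
#' @param r Sensor-to-malleolus distance; defaults to the trial's.
#' @param cfg Event-detection configuration.
#' @param fields Parameter columns to compare.
#' @param tol_s Stride-matching tolerance, seconds.
#' @return A list with `ipm` and `zupt` (named lists of `agreement_stats`
#'   per field), the reconstructions, and a `summary` data.frame.
#' @export
compare_methods <- function(trial, r = trial$config$r_m,
                            cfg = gait_event_config(),
                            fields = c("stride_length_m", "velocity_mps",
                                       "vertical_disp_m"),
                            tol_s = 0.25 * trial$config$stride_duration_s) {
  seg <- detect_gait_events(trial$rec, cfg = cfg)
  res <- list(ipm = reconstruct_gait(trial$rec, r, "ipm", seg = seg),
              zupt = reconstruct_gait(trial$rec, r, "zupt", seg = seg))
  out <- list(recon = res)
  rows <- list()
  for (m in names(res)) {
    pr <- pair_strides(res[[m]]$strides, trial$truth_params, tol_s = tol_s)
    st <- lapply(fields, function(f) agreement(pr, f))
    names(st) <- fields
    out[[m]] <- st
    for (f in fields)
      rows[[paste(m, f)]] <- agreement_as_row(st[[f]], paste(m, f))
  }
  out$summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}
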