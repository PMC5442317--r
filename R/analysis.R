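#' Interpolar fraction of a system state
#'
#' The bipolarity order parameter: the fraction of spindle MTs currently
#' engaged in at least one antiparallel crosslink with an MT nucleated from
#' the opposite pole. The default is the count-based definition; the
#' length-weighted alternative weights each engaged MT by its length.
#'
#' @param state a \code{spindle_state}.
#' @param method \code{"count"} (default) or \code{"length"}.
#' @return fraction in \code{[0, 1]}.
#' @export
interpolar_fraction <- function(state, method = c("count", "length")) {
  method <- match.arg(method)
  xl <- state$xl
  mt <- state$mt
  n_mt <- length(mt$spb)
  if (n_mt == 0) return(0)
  engaged <- rep(FALSE, n_mt)
  two <- which(xl$state == 2)
  for (i in two) {
    a <- xl$mt0[i]
    b <- xl$mt1[i]
    if (mt$spb[a] != mt$spb[b]) {
      engaged[a] <- TRUE
      engaged[b] <- TRUE
    }
  }
  if (method == "count") {
    sum(engaged) / n_mt
  } else {
    len <- mt$geom[, "length"]
    if (sum(len) == 0) return(0)
    sum(len[engaged]) / sum(len)
  }
}

#' Classify bipolar spindle assembly from an interpolar-fraction series
#'
#' A run is a successful bipolar spindle if its interpolar fraction rises
#' above the threshold (default 0.2) and stays above it until the end of the
#' run for at least \code{min_duration} (default 2 min), tolerating transient
#' dips below threshold of at most \code{max_dip} (default 12 s) each; the
#' tolerance applies to every dip inside the qualifying epoch and the epoch
#' clock is not reset by a tolerated dip. The formation start time is the
#' first threshold crossing of the qualifying epoch.
#'
#' @param if_series interpolar-fraction values at uniform spacing.
#' @param frame_interval spacing of the series, s.
#' @param threshold IF threshold.
#' @param min_duration minimum qualifying duration, s.
#' @param max_dip maximum tolerated sub-threshold dip, s.
#' @return list with logical \code{success} and \code{start_time} (s;
#'   \code{NA} on failure).
#' @examples
#' iff <- c(rep(0, 300), rep(0.5, 301)) # crossing at t = 300 s of 600
#' classify_success(iff, 1)
#' @export
classify_success <- function(if_series, frame_interval, threshold = 0.2,
                             min_duration = 120, max_dip = 12) {
  n <- length(if_series)
  total <- (n - 1) * frame_interval
  if (total < min_duration)
    stop("series too short to classify: covers ", total, " s < ",
         min_duration, " s", call. = FALSE)
  above <- if_series > threshold
  if (!any(above)) return(list(success = FALSE, start_time = NA_real_))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  # a below-run is a tolerated dip iff its duration <= max_dip
  dip_ok <- r$lengths * frame_interval <= max_dip
  k <- length(r$values)
  # walk candidate epochs from the earliest above-run: the epoch from an
  # above-run start qualifies iff every later below-run is a tolerated dip
  suffix_ok <- logical(k)
  ok <- TRUE
  for (j in k:1) {
    if (!r$values[j] && !dip_ok[j]) ok <- FALSE
    suffix_ok[j] <- ok
  }
  for (j in seq_len(k)) {
    if (!r$values[j] || !suffix_ok[j]) next
    t0 <- (starts[j] - 1) * frame_interval
    if (total - t0 >= min_duration)
      return(list(success = TRUE, start_time = t0))
  }
  list(success = FALSE, start_time = NA_real_)
}

#' Late-time SPB separation
#'
#' Mean SPB-SPB Euclidean distance over the final window of the run
#' (default: the last 30 s).
#'
#' @param trajectory a trajectory data frame with columns \code{time} and
#'   \code{separation} (as produced by \code{\link{run_simulation}}).
#' @param window averaging window, s.
#' @return mean separation, um.
#' @export
late_time_separation <- function(trajectory, window = 30) {
  t_end <- max(trajectory$time)
  sel <- trajectory$time >= t_end - window
  mean(trajectory$separation[sel])
}

#' Aggregate the outcomes of a parameter scan
#'
#' Per-sample success fractions and late-time separation statistics over
#' successful replicates, plus the scan-wide success percentage and marginal
#' summaries of success against each sampled parameter.
#'
#' @param scan the result of \code{\link{run_parameter_scan}}.
#' @param n_bins bins for the marginal summaries.
#' @return list with \code{per_sample} (data frame), \code{overall_success_pct}
#'   and \code{marginals} (one data frame per sampled parameter).
#' @export
aggregate_scan <- function(scan, n_bins = 5) {
  runs <- scan$runs
  samples <- scan$samples
  per <- do.call(rbind, lapply(split(runs, runs$sample_id), function(d) {
    succ <- d$success %in% TRUE
    sep <- d$late_separation[succ]
    data.frame(sample_id = d$sample_id[1],
               n_replicates = nrow(d),
               success_fraction = mean(succ),
               mean_separation = if (any(succ)) mean(sep) else NA_real_,
               sd_separation = if (sum(succ) > 1) stats::sd(sep) else NA_real_,
               mean_mt_length = mean(d$mean_mt_length))
  }))
  rownames(per) <- NULL
  vals <- do.call(rbind, lapply(samples, function(s) s$values))
  per <- cbind(per, as.data.frame(vals)[per$sample_id, , drop = FALSE])
  marg <- lapply(colnames(vals), function(nm) {
    x <- vals[per$sample_id, nm]
    if (length(unique(x)) <= 1) {
      return(data.frame(bin_mid = unique(x),
                        success_fraction = mean(per$success_fraction)))
    }
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    bin <- cut(x, br, include.lowest = TRUE)
    data.frame(bin_mid = (br[-1] + br[-length(br)]) / 2,
               success_fraction = as.numeric(
                 tapply(per$success_fraction, bin, mean)))
  })
  names(marg) <- colnames(vals)
  list(per_sample = per,
       overall_success_pct = 100 * mean(runs$success %in% TRUE),
       marginals = marg)
}
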