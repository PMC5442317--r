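#' Random-sampling parameter scan
#'
#' Draws \code{n_sets} parameter sets uniformly over the sampling ranges and
#' runs \code{replicates} independent simulations per set, recording for each
#' run the bipolarity outcome, formation start time, late-time SPB separation
#' and mean MT length. Per-run seeds are derived up-front from the master
#' seed, so results are independent of scheduling order, and finished samples
#' can be checkpointed to a JSON-lines file and skipped on resume.
#'
#' @param ranges a \code{\link{sampling_ranges}} object.
#' @param n_sets number of parameter sets.
#' @param replicates simulations per set.
#' @param stabilization_enabled if \code{FALSE}, all stabilization factors are
#'   pinned at 1 (the crosslinker-without-rescue-activity condition).
#' @param seed master seed.
#' @param base base parameters the samples override (use the \code{control}
#'   section to set the accuracy profile for the whole scan).
#' @param progress_file optional JSON-lines checkpoint path; with
#'   \code{resume = TRUE}, samples already present are not re-run.
#' @param resume logical.
#' @return list with \code{samples} (the \code{parameter_sample} list) and
#'   \code{runs} (data frame, one row per simulation).
#' @export
run_parameter_scan <- function(ranges, n_sets, replicates,
                               stabilization_enabled = TRUE, seed = 1,
                               base = reference_params(),
                               progress_file = NULL, resume = FALSE) {
  stopifnot(n_sets >= 1, replicates >= 1)
  samples <- sample_parameter_sets(ranges, n_sets, seed,
                                   stabilization_enabled, base)
  seeds <- matrix(derive_seeds(seed + 1L, n_sets * replicates),
                  nrow = n_sets)
  done <- list()
  if (resume && !is.null(progress_file) && file.exists(progress_file)) {
    lines <- readLines(progress_file)
    for (ln in lines) {
      rec <- jsonlite::fromJSON(ln)
      done[[as.character(rec$sample_id[1])]] <- rec
    }
  }
  rows <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    key <- as.character(i)
    if (!is.null(done[[key]])) {
      rec <- as.data.frame(done[[key]])
      for (col in c("sample_id", "replicate", "seed", "success",
                    "start_time", "late_separation", "mean_mt_length"))
        if (is.null(rec[[col]])) rec[[col]] <- NA
      rows[[i]] <- rec[, c("sample_id", "replicate", "seed", "success",
                           "start_time", "late_separation",
                           "mean_mt_length")]
      next
    }
    reps <- lapply(seq_len(replicates), function(j) {
      r <- run_simulation(samples[[i]]$params, seeds[i, j])
      data.frame(sample_id = i, replicate = j, seed = seeds[i, j],
                 success = r$summary$success,
                 start_time = r$summary$start_time,
                 late_separation = r$summary$late_separation,
                 mean_mt_length = r$summary$mean_mt_length)
    })
    rows[[i]] <- do.call(rbind, reps)
    if (!is.null(progress_file)) {
      cat(jsonlite::toJSON(rows[[i]], digits = NA), "\n",
          file = progress_file, append = TRUE)
    }
  }
  runs <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(runs) <- NULL
  list(samples = samples, runs = runs)
}

sweepable <- c(
  number = "crosslinkers",
  asymptotic_force = "wall_force",
  catastrophe_frequency = "dynamic_instability",
  rescue_frequency = "dynamic_instability",
  growth_speed = "dynamic_instability",
  shrinking_speed = "dynamic_instability",
  rescue_factor = "stabilization",
  shrink_factor = "stabilization",
  growth_factor = "stabilization",
  catastrophe_factor = "stabilization"
)

#' Single-parameter sweep
#'
#' Varies one parameter over a list of values (all other parameters held at
#' their reference values) with \code{replicates} simulations per value.
#'
#' @param parameter one of \code{number}, \code{asymptotic_force},
#'   \code{catastrophe_frequency}, \code{rescue_frequency},
#'   \code{growth_speed}, \code{shrinking_speed}, \code{rescue_factor},
#'   \code{shrink_factor}, \code{growth_factor}, \code{catastrophe_factor}.
#' @param values numeric values to sweep (e.g. 24 linearly spaced wall forces
#'   on \code{[0, 14.8]} pN).
#' @param replicates simulations per value.
#' @param seed master seed.
#' @param base base parameters.
#' @return list with \code{runs} (one row per simulation) and \code{summary}
#'   (per-value success fraction and mean late-time separation over
#'   successes).
#' @export
run_single_parameter_sweep <- function(parameter, values, replicates,
                                       seed = 1, base = reference_params()) {
  if (!parameter %in% names(sweepable))
    stop("usage error: unknown sweep parameter '", parameter, "'; one of: ",
         paste(names(sweepable), collapse = ", "), call. = FALSE)
  stopifnot(length(values) >= 1, replicates >= 1)
  section <- sweepable[[parameter]]
  seeds <- matrix(derive_seeds(seed, length(values) * replicates),
                  nrow = length(values))
  rows <- list()
  for (i in seq_along(values)) {
    p <- base
    p[[section]][[parameter]] <- values[i]
    validate_params(p)
    for (j in seq_len(replicates)) {
      r <- run_simulation(p, seeds[i, j])
      rows[[length(rows) + 1]] <-
        data.frame(value = values[i], replicate = j,
                   success = r$summary$success,
                   start_time = r$summary$start_time,
                   late_separation = r$summary$late_separation,
                   mean_mt_length = r$summary$mean_mt_length)
    }
  }
  runs <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(runs, runs$value), function(d) {
    succ <- d$success %in% TRUE
    data.frame(value = d$value[1],
               success_fraction = mean(succ),
               mean_separation = if (any(succ))
                 mean(d$late_separation[succ]) else NA_real_)
  }))
  rownames(smry) <- NULL
  smry <- smry[order(smry$value), ]
  list(parameter = parameter, runs = runs, summary = smry)
}
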