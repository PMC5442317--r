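#' Construct test and calibration fixtures
#'
#' Deterministic, simulation-free system states and engineered series used to
#' validate individual model components in isolation:
#' \describe{
#'   \item{frozen_antiparallel_pair}{two perfectly antiparallel MTs from
#'     opposite SPBs at a fixed perpendicular separation, plus free
#'     crosslinkers: the geometry for equilibrium-statistics oracles (the
#'     filaments are frozen; only crosslinker kinetics run on it).}
#'   \item{frozen_parallel_pair}{same geometry but parallel orientations:
#'     crosslinking must never occur.}
#'   \item{single_mt_ensemble}{recipe for an ensemble of independent dynamic
#'     MTs (consumed by \code{\link{simulate_mt_ensemble}}).}
#'   \item{engineered_if_series}{a synthetic interpolar-fraction time series
#'     with a plateau and optional sub-threshold dips, for classifier tests.}
#'   \item{randomized_force_closure}{a perturbed two-SPB state with random MT
#'     lengths/orientations and doubly bound crosslinkers on antiparallel
#'     pairs, for force/torque closure (Newton's third law) tests.}
#' }
#'
#' @param scenario one of the names above.
#' @param params a \code{spindle_params} object.
#' @param seed integer seed; every fixture is reproducible from
#'   \code{(scenario, seed)}.
#' @param ... scenario parameters: \code{separation}, \code{mt_length}
#'   (frozen pairs); \code{n_mt} (ensemble); \code{plateau}, \code{start},
#'   \code{total_time}, \code{frame_interval}, \code{dips} (a list of
#'   \code{c(at, length, value)}) for the engineered series; \code{n_xl_bound}
#'   for the closure state.
#' @return a \code{spindle_state}, a recipe list, or a series list, by
#'   scenario.
#' @export
make_fixture <- function(scenario, params = reference_params(), seed = 1,
                         ...) {
  args <- list(...)
  switch(scenario,
    frozen_antiparallel_pair = frozen_pair(params, seed, antiparallel = TRUE,
                                           args),
    frozen_parallel_pair = frozen_pair(params, seed, antiparallel = FALSE,
                                       args),
    single_mt_ensemble = {
      list(scenario = "single_mt_ensemble", params = params,
           n_mt = args$n_mt %||% 500, seed = seed)
    },
    engineered_if_series = engineered_if_series(args),
    randomized_force_closure = force_closure_state(params, seed, args),
    stop("usage error: unknown fixture scenario '", scenario, "'",
         call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_xl_geom <- function(n) {
  m <- matrix(0, n, 5)
  colnames(m) <- c("px", "py", "pz", "x0", "x1")
  m
}

mt_geom_matrix <- function(c_list, n_list, L) {
  m <- cbind(do.call(rbind, c_list), do.call(rbind, n_list), L)
  colnames(m) <- c("cx", "cy", "cz", "nx", "ny", "nz", "length")
  m
}

default_spbs <- function() {
  list(list(u = c(0, 0, 1), e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
       list(u = c(0, 0, -1), e1 = c(1, 0, 0), e2 = c(0, -1, 0)))
}

as_state <- function(time, spb, mt_geom, mt_state, mt_spb, mt_site, xl_geom,
                     xl_state, xl_mt0, xl_mt1) {
  structure(list(
    time = time, spb = spb,
    mt = list(geom = mt_geom, state = as.integer(mt_state),
              spb = as.integer(mt_spb), site = as.integer(mt_site)),
    xl = list(geom = xl_geom, state = as.integer(xl_state),
              mt0 = as.integer(xl_mt0), mt1 = as.integer(xl_mt1))),
    class = "spindle_state")
}

frozen_pair <- function(params, seed, antiparallel, args) {
  sep <- args$separation %||% params$crosslinkers$rest_length
  len <- args$mt_length %||% 2
  R <- params$geometry$envelope_diameter / 2
  if (len / 2 >= R)
    stop("fixture MT length does not fit in the envelope", call. = FALSE)
  n2 <- if (antiparallel) c(-1, 0, 0) else c(1, 0, 0)
  geom <- mt_geom_matrix(
    list(c(0, 0, -sep / 2), c(0, 0, sep / 2)),
    list(c(1, 0, 0), n2), c(len, len))
  n_xl <- params$crosslinkers$number
  pos <- with_local_seed(seed, {
    out <- matrix(0, n_xl, 3)
    i <- 1
    while (i <= n_xl) {
      cand <- stats::runif(3, -R, R)
      if (sum(cand^2) < R^2) {
        out[i, ] <- cand
        i <- i + 1
      }
    }
    out
  })
  xg <- empty_xl_geom(n_xl)
  xg[, 1:3] <- pos
  as_state(0, default_spbs(), geom, c(1, 1), c(1, 2), c(1, 1),
           xg, rep(0, n_xl), rep(0, n_xl), rep(0, n_xl))
}

engineered_if_series <- function(args) {
  total <- args$total_time %||% 600
  fi <- args$frame_interval %||% 1
  plateau <- args$plateau %||% 0.5
  start <- args$start %||% 300
  times <- seq(0, total, by = fi)
  iff <- ifelse(times >= start, plateau, 0)
  for (d in args$dips %||% list()) {
    at <- d[["at"]]
    len <- d[["length"]]
    val <- if (!is.na(d["value"])) d[["value"]] else 0.1
    iff[times >= at & times < at + len] <- val
  }
  list(time = times, if_series = iff, frame_interval = fi)
}

force_closure_state <- function(params, seed, args) {
  n_bound <- args$n_xl_bound %||% 10
  st <- initialize_spindle(params, seed)
  g <- params$geometry
  n_mt <- nrow(st$mt$geom)
  with_local_seed(seed + 1L, {
    # jitter lengths, positions and orientations so every spring is loaded
    geom <- st$mt$geom
    geom[, "length"] <- stats::runif(n_mt, 0.4, 1.2)
    for (i in seq_len(n_mt)) {
      n <- stats::rnorm(3)          # isotropic orientations so antiparallel
      n <- n / sqrt(sum(n^2))       # cross-pole pairs exist at any threshold
      geom[i, 4:6] <- n
      geom[i, 1:3] <- geom[i, 1:3] + stats::rnorm(3, 0, 0.05)
    }
    st$mt$geom <- geom
    # attach doubly bound crosslinkers to random antiparallel cross-pole pairs
    spb_of <- st$mt$spb
    placed <- 0
    tries <- 0
    while (placed < n_bound && tries < 10000) {
      tries <- tries + 1
      a <- sample.int(n_mt, 1)
      b <- sample.int(n_mt, 1)
      if (spb_of[a] == spb_of[b]) next
      if (sum(geom[a, 4:6] * geom[b, 4:6]) >=
          params$crosslinkers$antiparallel_threshold) next
      placed <- placed + 1
      i <- placed
      st$xl$state[i] <- 2L
      st$xl$mt0[i] <- a
      st$xl$mt1[i] <- b
      st$xl$geom[i, "x0"] <- stats::runif(1, 0, geom[a, "length"])
      st$xl$geom[i, "x1"] <- stats::runif(1, 0, geom[b, "length"])
    }
    if (placed < n_bound)
      stop("could not place the requested number of crosslinks", call. = FALSE)
  })
  st
}
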