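#' Threshold-training configuration
#'
#' Settings for the error-counting cost and its optimiser. A detection on a
#' turn trial within `tolerance_ms` of the reference onset costs nothing;
#' a premature or late detection (beyond the tolerance, in either
#' direction), a missed turn, or any detection on a straight trial each add
#' their weight to the cost. The default weights penalise all three error
#' types equally; applications that e.g. cannot afford false negatives can
#' raise that weight.
#'
#' @param tolerance_ms Detection tolerance in ms (default 500: the sum of a
#'   maximum acceptable actuation delay and the uncertainty of a manually
#'   annotated reference onset; deliberately configurable).
#' @param criterion Detection criterion, as in [threshold_pair()].
#' @param gyr_bounds,angle_bounds Search bounds (deg/s, deg) for the two
#'   thresholds; wide enough to contain all plausible optima.
#' @param error_weights Named numeric vector with entries `premature_late`,
#'   `false_negative`, `false_positive`, all `>= 0`.
#' @param optimizer_seed Integer seed making [optimize_thresholds()]
#'   deterministic.
#' @param search_start_ms Monitoring start passed to [detect_onset()].
#' @param baseline_window_s Baseline-zeroing window applied to each trial
#'   before detection.
#' @param pop_size,generations Population size and generation count of the
#'   differential-evolution optimiser.
#' @return An object of class `training_config`.
#' @export
training_config <- function(tolerance_ms = 500,
                            criterion = c("combined", "gyro_only", "angle_only"),
                            gyr_bounds = c(1, 300),
                            angle_bounds = c(1, 180),
                            error_weights = c(premature_late = 1,
                                              false_negative = 1,
                                              false_positive = 1),
                            optimizer_seed = 1L,
                            search_start_ms = 1000,
                            baseline_window_s = 1,
                            pop_size = 30L,
                            generations = 50L) {
  criterion <- match.arg(criterion)
  stopifnot(tolerance_ms > 0,
            length(gyr_bounds) == 2L, length(angle_bounds) == 2L,
            all(gyr_bounds > 0), all(angle_bounds > 0),
            gyr_bounds[1] < gyr_bounds[2], angle_bounds[1] < angle_bounds[2])
  w <- error_weights[c("premature_late", "false_negative", "false_positive")]
  if (anyNA(w) || any(w < 0))
    stop("error_weights must name premature_late, false_negative, false_positive, all >= 0")
  structure(list(tolerance_ms = as.numeric(tolerance_ms), criterion = criterion,
                 gyr_bounds = as.numeric(gyr_bounds),
                 angle_bounds = as.numeric(angle_bounds),
                 error_weights = w,
                 optimizer_seed = as.integer(optimizer_seed),
                 search_start_ms = as.numeric(search_start_ms),
                 baseline_window_s = as.numeric(baseline_window_s),
                 pop_size = as.integer(pop_size),
                 generations = as.integer(generations)),
            class = "training_config")
}

# Zero-referenced signals for one location of a trial.
zeroed_signals <- function(trial, location, config) {
  s <- trial$signals[[location]]
  if (is.null(s))
    stop(sprintf("trial %s carries no signals for location '%s'",
                 trial$trial_id, location))
  baseline_subtract(s, config$baseline_window_s)
}

#' Error-counting cost of a threshold pair on a trial database
#'
#' Runs [detect_onset()] on every trial and sums per-trial penalties: a turn
#' trial detected within `config$tolerance_ms` of its reference onset adds
#' 0; detected outside the tolerance adds the premature/late weight; an
#' undetected turn adds the false-negative weight; a straight trial with
#' any detection adds the false-positive weight. Minimising this count over
#' thresholds is how the detector is trained.
#'
#' @param thresholds A [threshold_pair].
#' @param database List of [trial_recording] objects (turn trials must
#'   carry `reference_onset_ms`).
#' @param location Sensor location to detect from.
#' @param config A [training_config].
#' @return The weighted error count (a single number; an integer count
#'   under unit weights). An empty database costs 0 (with a warning).
#' @export
detection_cost <- function(thresholds, database, location,
                           config = training_config()) {
  stopifnot(inherits(thresholds, "threshold_pair"),
            inherits(config, "training_config"))
  if (!length(database)) {
    warning("detection_cost called on an empty database; cost is 0")
    return(0)
  }
  w <- config$error_weights
  total <- 0
  for (trial in database) {
    sig <- zeroed_signals(trial, location, config)
    res <- detect_onset(sig, thresholds, config$search_start_ms)
    if (trial$path_label == "straight") {
      if (res$detected) total <- total + w[["false_positive"]]
    } else if (!res$detected) {
      total <- total + w[["false_negative"]]
    } else if (abs(res$onset_ms - trial$reference_onset_ms) > config$tolerance_ms) {
      total <- total + w[["premature_late"]]
    }
  }
  total
}

# ---- fast cost surface -------------------------------------------------
#
# The cost is piecewise constant in (gyr_thresh, angle_thresh): for one
# trial the first sample whose |signal| strictly exceeds a threshold is a
# step function of that threshold, recoverable from the running maximum of
# the rectified signal by binary search. Precomputing the two running
# maxima per trial makes one cost evaluation O(trials * log n), which the
# optimiser and the reference grid both rely on.

surface_terms <- function(database, location, config) {
  lapply(database, function(trial) {
    sig <- zeroed_signals(trial, location, config)
    n <- length(sig$angle)
    i0 <- as.integer(ceiling(config$search_start_ms / 1000 * sig$sample_rate - 1e-9)) + 1L
    if (i0 > n) stop("search_start_ms is outside a trial's series")
    idx <- i0:n
    list(cw = cummax(abs(sig$angular_velocity[idx])),
         ca = cummax(abs(sig$angle[idx])),
         t_ms = (idx - 1) / sig$sample_rate * 1000,
         is_turn = trial$path_label != "straight",
         ref = trial$reference_onset_ms)
  })
}

surface_from_terms <- function(trials, config) {
  w <- config$error_weights
  tol <- config$tolerance_ms
  use_g <- config$criterion %in% c("combined", "gyro_only")
  use_a <- config$criterion %in% c("combined", "angle_only")
  w_fn <- w[["false_negative"]]; w_pl <- w[["premature_late"]]
  w_fp <- w[["false_positive"]]
  # gyr, angle: equal-length vectors of candidate pairs -> vector of costs
  function(gyr, angle) {
    m <- max(length(gyr), length(angle))
    total <- numeric(m)
    for (tr in trials) {
      k <- length(tr$cw)
      # first index with running max strictly above the threshold
      if (use_g && use_a) j <- pmin(findInterval(gyr, tr$cw), findInterval(angle, tr$ca)) + 1L
      else if (use_g) j <- findInterval(gyr, tr$cw) + 1L
      else j <- findInterval(angle, tr$ca) + 1L
      if (tr$is_turn) {
        pen <- rep.int(w_fn, m)
        d <- which(j <= k)
        adiff <- abs(tr$t_ms[j[d]] - tr$ref)
        pen[d] <- w_pl * (adiff > tol)
        total <- total + pen
      } else {
        total <- total + w_fp * (j <= k)
      }
    }
    total
  }
}

cost_surface <- function(database, location, config) {
  surface_from_terms(surface_terms(database, location, config), config)
}

# Log-spaced reference grid over the search bounds (50 points per enabled
# dimension). Disabled dimensions are pinned at NA.
threshold_grid <- function(config, n = 50L) {
  logspace <- function(b) exp(seq(log(b[1]), log(b[2]), length.out = n))
  switch(config$criterion,
         gyro_only = list(gyr = logspace(config$gyr_bounds), angle = NA_real_),
         angle_only = list(gyr = NA_real_, angle = logspace(config$angle_bounds)),
         combined = list(gyr = logspace(config$gyr_bounds),
                         angle = logspace(config$angle_bounds)))
}

#' Minimum cost over a log-spaced reference grid
#'
#' Evaluates the error-counting cost on a log-spaced grid over the search
#' bounds (`n` points per enabled threshold dimension) and returns the
#' minimising point. Serves as a transparent reference against which
#' [optimize_thresholds()] can be checked: the optimiser must never return
#' a cost above this grid minimum.
#'
#' @inheritParams detection_cost
#' @param n Grid points per dimension (default 50).
#' @return List with `thresholds` (a [threshold_pair]) and `cost`.
#' @export
grid_search_thresholds <- function(database, location,
                                   config = training_config(), n = 50L) {
  surf <- cost_surface(database, location, config)
  g <- threshold_grid(config, n)
  if (config$criterion == "combined") {
    pairs <- expand.grid(gyr = g$gyr, angle = g$angle)
    costs <- surf(pairs$gyr, pairs$angle)
    best <- which.min(costs)
    tp <- threshold_pair(pairs$gyr[best], pairs$angle[best], "combined")
  } else if (config$criterion == "gyro_only") {
    costs <- surf(g$gyr, rep(NA_real_, length(g$gyr)))
    best <- which.min(costs)
    tp <- threshold_pair(g$gyr[best], NA, "gyro_only")
  } else {
    costs <- surf(rep(NA_real_, length(g$angle)), g$angle)
    best <- which.min(costs)
    tp <- threshold_pair(NA, g$angle[best], "angle_only")
  }
  list(thresholds = tp, cost = costs[best])
}

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Train detection thresholds by cost minimisation
#'
#' Minimises the error-counting cost of [detection_cost()] over the search
#' bounds. The cost surface is piecewise constant, so gradient methods do
#' not apply. For the single-threshold criteria the minimisation is exact:
#' every plateau of the step function is enumerated via the breakpoints of
#' the per-trial running maxima. For the combined criterion a seeded
#' differential-evolution optimiser (population-based, derivative-free,
#' elitist) searches the two-dimensional surface in log-threshold space,
#' initialised from a coarse lattice plus uniform draws. The cost surface
#' has wide flat minima; ties on the count are broken deterministically to
#' the centre (log scale) of the minimising plateau — the max-margin
#' choice, farthest from behaving differently on unseen data (see the
#' methods vignette). Deterministic given `config$optimizer_seed`.
#'
#' @inheritParams detection_cost
#' @param .terms Internal: precomputed per-trial surface terms, used by
#'   [crossvalidate()] to avoid rebuilding them per fold.
#' @return List with `thresholds` (a [threshold_pair]) and `cost` (its
#'   error count on `database`).
#' @seealso [grid_search_thresholds()] for the reference grid;
#'   [turn_detector()] for the model-fitting interface.
#' @export
optimize_thresholds <- function(database, location, config = training_config(),
                                .terms = NULL) {
  stopifnot(inherits(config, "training_config"))
  if (is.null(.terms) && !length(database))
    stop("cannot optimise thresholds on an empty database")
  terms <- if (is.null(.terms)) surface_terms(database, location, config) else .terms
  surf <- surface_from_terms(terms, config)

  # One-dimensional criteria: the cost is a step function whose jumps all
  # lie at values taken by the trials' running maxima, so evaluating one
  # representative per plateau (midpoints between consecutive breakpoints,
  # plus the bounds) is an exact global minimisation. Ties on the count
  # are broken to the centre (log scale) of the widest minimising
  # plateau: the threshold farthest from firing differently on data it
  # has not seen.
  if (config$criterion != "combined") {
    field <- if (config$criterion == "gyro_only") "cw" else "ca"
    bounds <- if (config$criterion == "gyro_only") config$gyr_bounds else config$angle_bounds
    bp <- sort(unique(unlist(lapply(terms, `[[`, field))))
    bp <- bp[bp > bounds[1] & bp < bounds[2]]
    edges <- c(bounds[1], bp, bounds[2])       # K plateaus between K+1 edges
    mids <- (edges[-1] + edges[-length(edges)]) / 2
    costs <- if (config$criterion == "gyro_only") surf(mids, rep(NA_real_, length(mids)))
             else surf(rep(NA_real_, length(mids)), mids)
    cmin <- min(costs)
    runs <- rle(costs == cmin)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    widest <- which(runs$values)[which.max(
      (log(edges[ends + 1L]) - log(edges[starts]))[runs$values])]
    x <- sqrt(edges[starts[widest]] * edges[ends[widest] + 1L])
    tp <- if (config$criterion == "gyro_only") threshold_pair(x, NA, "gyro_only")
          else threshold_pair(NA, x, "angle_only")
    return(list(thresholds = tp, cost = cmin))
  }
  use_g <- config$criterion %in% c("combined", "gyro_only")
  use_a <- config$criterion %in% c("combined", "angle_only")
  lo <- log(c(if (use_g) config$gyr_bounds[1], if (use_a) config$angle_bounds[1]))
  hi <- log(c(if (use_g) config$gyr_bounds[2], if (use_a) config$angle_bounds[2]))
  d <- length(lo)
  eval_pop <- function(pop) {  # pop: d x NP matrix in log space
    if (config$criterion == "combined") surf(exp(pop[1, ]), exp(pop[2, ]))
    else if (config$criterion == "gyro_only") surf(exp(pop[1, ]), rep(NA_real_, ncol(pop)))
    else surf(rep(NA_real_, ncol(pop)), exp(pop[1, ]))
  }
  run <- function() {
    # coarse lattice seeds diversity on the plateaued surface
    lat <- lapply(seq_len(d), function(i) seq(lo[i], hi[i], length.out = if (d == 2) 5 else 12))
    lattice <- t(as.matrix(expand.grid(lat)))
    nrand <- max(config$pop_size, 4L * d)
    rand <- matrix(stats::runif(d * nrand, lo, hi), nrow = d)
    pop <- cbind(lattice, rand)
    np <- ncol(pop)
    cost <- eval_pop(pop)
    f_weight <- 0.7; cr <- 0.9
    for (gen in seq_len(config$generations)) {
      r1 <- sample.int(np, np, replace = TRUE)
      r2 <- sample.int(np, np, replace = TRUE)
      r3 <- sample.int(np, np, replace = TRUE)
      mut <- pop[, r1, drop = FALSE] +
        f_weight * (pop[, r2, drop = FALSE] - pop[, r3, drop = FALSE])
      cross <- matrix(stats::runif(d * np) < cr, nrow = d)
      force_row <- cbind(sample.int(d, np, replace = TRUE), seq_len(np))
      cross[force_row] <- TRUE
      trial_pop <- ifelse(cross, mut, pop)
      trial_pop <- pmin(pmax(trial_pop, lo), hi)
      trial_cost <- eval_pop(trial_pop)
      improved <- trial_cost <= cost
      pop[, improved] <- trial_pop[, improved]
      cost[improved] <- trial_cost[improved]
    }
    best <- which.min(cost)
    list(x = pop[, best], cost = cost[best])
  }
  res <- with_local_seed(config$optimizer_seed, run)

  # Centre the solution on its cost plateau, one axis at a time (the same
  # max-margin tie-break as in the one-dimensional exact path): scan a
  # fine log grid along the axis, find the contiguous run of equal-cost
  # points containing the solution, and move to its geometric centre.
  centre_axis <- function(x, axis) {
    grid <- sort(unique(c(seq(lo[axis], hi[axis], length.out = 160), x[axis])))
    cand <- matrix(rep(x, length(grid)), nrow = d)
    cand[axis, ] <- grid
    costs <- eval_pop(cand)
    i0 <- which(grid == x[axis])[1]
    ok <- costs == costs[i0]
    lo_i <- i0; while (lo_i > 1L && ok[lo_i - 1L]) lo_i <- lo_i - 1L
    hi_i <- i0; while (hi_i < length(grid) && ok[hi_i + 1L]) hi_i <- hi_i + 1L
    x[axis] <- (grid[lo_i] + grid[hi_i]) / 2
    x
  }
  x <- res$x
  for (pass in 1:2) for (axis in seq_len(d)) {
    x_new <- centre_axis(x, axis)
    if (eval_pop(matrix(x_new, ncol = 1)) <= res$cost) x <- x_new
  }
  x <- exp(x)
  tp <- threshold_pair(x[1], x[2], "combined")
  list(thresholds = tp, cost = surf(x[1], x[2]))
}
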