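#' @include AllClasses.R accessors.R
NULL

# ---- seeds ------------------------------------------------------------------

# derive a per-stage seed from the master seed; kept below 2^31
.deriveSeed <- function(master, stage) {
  s <- (as.numeric(master) * 48271 + as.numeric(stage) * 7919) %% 2147483629
  as.integer(s) + 1L
}

# ---- geometry ---------------------------------------------------------------

# vertices every `spacing` cm along straight segments between waypoints
.densify <- function(waypoints, spacing = 1) {
  out <- waypoints[1, , drop = FALSE]
  for (i in seq_len(nrow(waypoints) - 1)) {
    a <- waypoints[i, ]; b <- waypoints[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, round(len / spacing))
    frac <- seq_len(n) / n
    seg <- cbind(a[1] + frac * (b[1] - a[1]), a[2] + frac * (b[2] - a[2]))
    out <- rbind(out, seg)
  }
  dimnames(out) <- NULL
  out
}

#' Construct the figure-eight maze geometry
#'
#' Builds the maze footprint, the named zones (central stem, upper
#' junction/decision point, reward zones, delay zones) and the four ideal
#' journey paths. A journey runs from the origin-side reward zone along the
#' bottom rail to the stem base, up the central stem, across the top to the
#' destination side and down that rail to its reward zone; all four paths
#' share the central-stem vertices verbatim and have equal arc length.
#'
#' @param outerWidth,outerHeight outer footprint (cm).
#' @param pathWidth running-path width (cm).
#' @return a [MazeGeometry-class].
#' @examples
#' g <- mazeGeometry()
#' g
#' head(idealPath(g, "RL"))
#' @export
mazeGeometry <- function(outerWidth = 100, outerHeight = 140, pathWidth = 20) {
  m <- pathWidth / 2
  xL <- m; xR <- outerWidth - m; stemX <- outerWidth / 2
  yBot <- m; yTop <- outerHeight - m

  stemBlock <- .densify(rbind(c(stemX, yBot), c(stemX, yTop)))
  mkPath <- function(xo, xd) {
    pre  <- .densify(rbind(c(xo, yBot), c(stemX, yBot)))
    post <- .densify(rbind(c(stemX, yTop), c(xd, yTop), c(xd, yBot)))
    rbind(pre[-nrow(pre), , drop = FALSE], stemBlock,
          post[-1, , drop = FALSE])
  }
  sideX <- c(L = xL, R = xR)
  paths <- list(RL = mkPath(sideX["R"], sideX["L"]),
                LR = mkPath(sideX["L"], sideX["R"]),
                LL = mkPath(sideX["L"], sideX["L"]),
                RR = mkPath(sideX["R"], sideX["R"]))
  preArc <- abs(sideX["R"] - stemX)             # origin RZ -> stem base
  pathLength <- preArc + (yTop - yBot) + preArc + (yTop - yBot)

  zones <- list(
    stem     = c(stemX - m, stemX + m, pathWidth, outerHeight - pathWidth),
    junction = c(stemX - m, stemX + m, outerHeight - pathWidth, outerHeight),
    RZ_L = c(0, pathWidth, 0, pathWidth),
    RZ_R = c(outerWidth - pathWidth, outerWidth, 0, pathWidth),
    DZ_L = c(pathWidth, 2 * pathWidth, 0, pathWidth),
    DZ_R = c(outerWidth - 2 * pathWidth, outerWidth - pathWidth, 0, pathWidth))

  stemArc <- unname(preArc + c(zones$stem[3] - yBot, zones$stem[4] - yBot))
  new("MazeGeometry", outerWidth = outerWidth, outerHeight = outerHeight,
      pathWidth = pathWidth, zones = zones, idealPaths = paths,
      pathLength = unname(pathLength), stemArc = stemArc)
}

#' Ideal path of a journey
#'
#' @param geometry a [MazeGeometry-class].
#' @param journey one of "RL", "LR", "LL", "RR".
#' @return two-column matrix of polyline vertices at 1-cm spacing.
#' @export
idealPath <- function(geometry, journey) {
  p <- geometry@idealPaths[[journey]]
  if (is.null(p)) stop("unknown journey: ", journey)
  p
}

#' Zone membership test
#'
#' @param geometry a [MazeGeometry-class].
#' @param zone zone name (see [MazeGeometry-class]).
#' @param x,y coordinates (cm).
#' @return logical vector.
#' @export
inZone <- function(geometry, zone, x, y) {
  z <- geometry@zones[[zone]]
  if (is.null(z)) stop("unknown zone: ", zone)
  x >= z[1] & x <= z[2] & y >= z[3] & y <= z[4]
}

# point on a 1-cm-spaced polyline at arc length s (vectorized)
.pathPoint <- function(path, s) {
  arc <- seq_len(nrow(path)) - 1
  cbind(stats::approx(arc, path[, 1], xout = s, rule = 2)$y,
        stats::approx(arc, path[, 2], xout = s, rule = 2)$y)
}

# unit tangent of the polyline at arc length s (per-segment, vectorized)
.pathTangent <- function(path, s) {
  i <- pmin(pmax(floor(s) + 1, 1), nrow(path) - 1)
  d <- path[i + 1, , drop = FALSE] - path[i, , drop = FALSE]
  d / sqrt(rowSums(d^2))
}

# ---- schedule ---------------------------------------------------------------

#' Default block structure of the session
#'
#' Eight alternating blocks: VD (20), SA (20), VD (10), DA (20), VD (20),
#' SA (20), VD (10), DA (20) -- 140 laps in total.
#'
#' @return data.frame with columns `subtask`, `n_laps`.
#' @export
defaultBlocks <- function() {
  data.frame(subtask = c("VD", "SA", "VD", "DA", "VD", "SA", "VD", "DA"),
             n_laps  = c(20L, 20L, 10L, 20L, 20L, 20L, 10L, 20L),
             stringsAsFactors = FALSE)
}

#' Generate a lap schedule
#'
#' Produces the ordered lap list for the session. On visually guided (VD)
#' laps the cue side is drawn uniformly; on alternation laps (SA, DA) the
#' correct choice is the side opposite the previous lap's destination, so
#' error-free alternation blocks strictly alternate R-to-L and L-to-R
#' journeys. With probability `errorRate` a lap's chosen destination is
#' flipped and the lap flagged incorrect; SA/DA error laps can yield
#' same-side journeys whose trial type is undefined (NA) and such laps are
#' excluded from all downstream analyses.
#'
#' @param blocks data.frame with columns `subtask` and `n_laps`
#'   (default [defaultBlocks()]).
#' @param errorRate per-lap probability of a choice error, in \[0, 1\].
#' @param startSide side ("L" or "R") the rat starts from.
#' @param seed integer seed.
#' @return a [LapSchedule-class].
#' @examples
#' sch <- generateSchedule(seed = 7)
#' table(scheduleTable(sch)$subtask)
#' @export
generateSchedule <- function(blocks = defaultBlocks(), errorRate = 0.01,
                             startSide = "R", seed = 1L) {
  if (!is.data.frame(blocks) || !all(c("subtask", "n_laps") %in% names(blocks)))
    stop("configuration error: blocks must have columns subtask, n_laps")
  if (!all(blocks$subtask %in% c("VD", "SA", "DA")) ||
      any(blocks$n_laps < 1))
    stop("configuration error: invalid block structure")
  if (errorRate < 0 || errorRate > 1)
    stop("configuration error: errorRate must lie in [0, 1]")
  set.seed(seed)
  flip <- function(s) ifelse(s == "L", "R", "L")
  subtasks <- rep(blocks$subtask, blocks$n_laps)
  n <- length(subtasks)
  origin <- destination <- cue_state <- character(n)
  correct <- logical(n)
  side <- startSide
  for (i in seq_len(n)) {
    origin[i] <- side
    if (subtasks[i] == "VD") {
      cue <- sample(c("L", "R"), 1)
      cue_state[i] <- c(L = "left", R = "right")[cue]
      want <- cue
    } else {
      cue_state[i] <- "both"
      want <- flip(side)
    }
    err <- stats::runif(1) < errorRate
    destination[i] <- if (err) flip(want) else want
    correct[i] <- !err
    side <- destination[i]
  }
  journey <- paste0(origin, destination)
  tb <- data.frame(lap = seq_len(n), subtask = subtasks,
                   cue_state = cue_state, origin = origin,
                   destination = destination, journey = journey,
                   trial_type = .trialTypeOf(subtasks, journey),
                   correct = correct, delay = subtasks == "DA",
                   stringsAsFactors = FALSE)
  new("LapSchedule", table = tb)
}

# ---- tuning -----------------------------------------------------------------

#' Build a ground-truth place-cell tuning model
#'
#' Each tuned cell gets one isotropic Gaussian place field per journey.
#' With `journeyMode = "global"` field centers are drawn independently per
#' journey (global remapping between journeys); with `"none"` a single
#' center is shared by all journeys. With `demandMode = "rate"` the field
#' location is shared across subtasks within a journey and only the peak
#' rate is scaled per subtask (rate remapping between task-demands); with
#' `"none"` all scales are 1. Untuned cells fire uniformly at
#' `untunedRate`.
#'
#' @param nCells number of tuned place cells.
#' @param geometry a [MazeGeometry-class].
#' @param journeyMode "global" or "none".
#' @param demandMode "rate" or "none".
#' @param demandScales named numeric vector `c(VD=, SA=, DA=)` or an
#'   `nCells x 3` matrix of per-cell scales; ignored when
#'   `demandMode = "none"`.
#' @param fieldWidth Gaussian field SD (cm).
#' @param peakRange range the per-cell peak rate (Hz) is drawn from.
#' @param background uniform background rate (Hz) of tuned cells.
#' @param nUntuned number of additional untuned cells.
#' @param untunedRate uniform rate (Hz) of untuned cells.
#' @param prospectiveGain scalar g >= 0: each cell receives a signed gain
#'   (sign drawn per cell) multiplying its stem-region rate by (1 + g) on
#'   laps toward L and (1 - g) toward R -- destination-dependent
#'   (prospective) rate modulation before the turn.
#' @param seed integer seed.
#' @return a [TuningModel-class].
#' @export
makeTuningModel <- function(nCells = 50, geometry = mazeGeometry(),
                            journeyMode = c("global", "none"),
                            demandMode = c("rate", "none"),
                            demandScales = c(VD = 1, SA = 0.5, DA = 0.75),
                            fieldWidth = 8, peakRange = c(5, 25),
                            background = 0.1, nUntuned = 0,
                            untunedRate = 0.5, prospectiveGain = 0,
                            seed = 1L) {
  journeyMode <- match.arg(journeyMode)
  demandMode <- match.arg(demandMode)
  set.seed(seed)
  total <- nCells + nUntuned
  journeys <- c("RL", "LR", "LL", "RR")
  centers <- array(NA_real_, dim = c(total, 4L, 2L),
                   dimnames = list(NULL, journeys, c("x", "y")))
  L <- geometry@pathLength
  for (i in seq_len(nCells)) {
    if (journeyMode == "global") {
      for (j in journeys) {
        pt <- .pathPoint(geometry@idealPaths[[j]], stats::runif(1, 0, L))
        centers[i, j, ] <- pt
      }
    } else {
      pt <- .pathPoint(geometry@idealPaths[["RL"]], stats::runif(1, 0, L))
      centers[i, , 1] <- pt[1]; centers[i, , 2] <- pt[2]
    }
  }
  if (nUntuned > 0) centers[nCells + seq_len(nUntuned), , ] <- 0

  if (demandMode == "none") {
    scales <- matrix(1, total, 3)
  } else if (is.matrix(demandScales)) {
    if (nrow(demandScales) != nCells || ncol(demandScales) != 3)
      stop("demandScales matrix must be nCells x 3")
    scales <- rbind(demandScales,
                    matrix(1, nUntuned, 3))
  } else {
    if (!all(c("VD", "SA", "DA") %in% names(demandScales)))
      stop("demandScales must name VD, SA and DA")
    scales <- matrix(rep(demandScales[c("VD", "SA", "DA")], each = total),
                     total, 3)
  }
  colnames(scales) <- c("VD", "SA", "DA")

  gain <- rep(0, total)
  if (prospectiveGain != 0)
    gain[seq_len(nCells)] <- prospectiveGain *
      sample(c(-1, 1), nCells, replace = TRUE)

  new("TuningModel",
      nCells = as.integer(total),
      centers = centers,
      width = rep(fieldWidth, total),
      peak = c(stats::runif(nCells, peakRange[1], peakRange[2]),
               rep(0, nUntuned)),
      background = c(rep(background, nCells), rep(untunedRate, nUntuned)),
      demandScales = scales,
      prospectiveGain = gain,
      tuned = c(rep(TRUE, nCells), rep(FALSE, nUntuned)),
      journeyMode = journeyMode, demandMode = demandMode)
}

# ---- tracking ---------------------------------------------------------------

#' Simulate head-position tracking for a schedule
#'
#' A virtual rat traverses each lap's ideal path at a per-lap speed drawn
#' from a Gaussian, with Ornstein-Uhlenbeck lateral jitter around the path
#' centerline and Gaussian head-direction noise around the path tangent.
#' Delayed-alternation laps include a `delayDuration`-second near-stationary
#' epoch at the delay barrier (20 cm before the stem entrance). Samples are
#' produced at `rateHz` on a single session clock; laps are contiguous.
#'
#' @param schedule a [LapSchedule-class].
#' @param geometry a [MazeGeometry-class].
#' @param speed mean running speed (cm/s); must be positive.
#' @param speedSD per-lap SD of running speed (cm/s).
#' @param jitterSD stationary SD of the lateral OU jitter (cm).
#' @param jitterTau OU time constant (s).
#' @param hdNoiseSD head-direction noise SD (degrees).
#' @param delayDuration delay-epoch duration on DA laps (s).
#' @param delayJitterSD positional jitter during the delay epoch (cm).
#' @param rateHz sampling rate (Hz).
#' @param seed integer seed.
#' @return a [TrackingSeries-class].
#' @export
simulateTracking <- function(schedule, geometry, speed = 30, speedSD = 3,
                             jitterSD = 1.5, jitterTau = 0.5, hdNoiseSD = 5,
                             delayDuration = 5, delayJitterSD = 0.01,
                             rateHz = 60, seed = 1L) {
  if (speed <= 0) stop("configuration error: mean speed must be positive")
  set.seed(seed)
  tb <- scheduleTable(schedule)
  dt <- 1 / rateHz
  L <- geometry@pathLength
  delayArc <- geometry@pathWidth         # barrier 20 cm before stem entrance
  xs <- ys <- hds <- vector("list", nrow(tb))
  lapIdx <- vector("list", nrow(tb))
  for (k in seq_len(nrow(tb))) {
    path <- geometry@idealPaths[[tb$journey[k]]]
    v <- max(speed / 5, stats::rnorm(1, speed, speedSD))
    nStep <- ceiling(L / (v * dt))
    arc <- pmin(seq_len(nStep) * v * dt, L)
    delay <- rep(FALSE, length(arc))
    if (tb$delay[k] && delayDuration > 0) {
      at <- which(arc >= delayArc)[1]
      nd <- round(delayDuration * rateHz)
      arc <- append(arc, rep(delayArc, nd), after = at - 1)
      delay <- append(delay, rep(TRUE, nd), after = at - 1)
    }
    ctr <- .pathPoint(path, arc)
    tang <- .pathTangent(path, arc)
    # OU lateral offset, frozen during the delay epoch
    n <- length(arc)
    lat <- numeric(n)
    if (jitterSD > 0) {
      a <- exp(-dt / jitterTau)
      innov <- stats::rnorm(n, 0, jitterSD * sqrt(1 - a^2))
      lat[1] <- stats::rnorm(1, 0, jitterSD)
      for (s in 2:n) lat[s] <- a * lat[s - 1] + innov[s]
    }
    px <- ctr[, 1] + lat * tang[, 2]
    py <- ctr[, 2] - lat * tang[, 1]
    if (any(delay)) {
      px[delay] <- ctr[delay, 1] + stats::rnorm(sum(delay), 0, delayJitterSD)
      py[delay] <- ctr[delay, 2] + stats::rnorm(sum(delay), 0, delayJitterSD)
    }
    hd <- (atan2(tang[, 2], tang[, 1]) * 180 / pi +
             stats::rnorm(n, 0, hdNoiseSD)) %% 360
    xs[[k]] <- px; ys[[k]] <- py; hds[[k]] <- hd
    lapIdx[[k]] <- rep(k, n)
  }
  x <- unlist(xs); y <- unlist(ys); hd <- unlist(hds)
  lap <- as.integer(unlist(lapIdx))
  new("TrackingSeries", t = seq_along(x) * dt, x = x, y = y, hd = hd,
      rateHz = rateHz, lap = lap)
}

# ---- spikes -----------------------------------------------------------------

# per-sample expected rate (Hz) of one cell given the tuning model
.cellRate <- function(cell, tuningModel, tracking, schedule, geometry) {
  tb <- scheduleTable(schedule)
  lap <- tracking@lap
  if (!tuningModel@tuned[cell])
    return(rep(tuningModel@background[cell], length(lap)))
  jIdx <- match(tb$journey[lap], c("RL", "LR", "LL", "RR"))
  cx <- tuningModel@centers[cell, , 1][jIdx]
  cy <- tuningModel@centers[cell, , 2][jIdx]
  w <- tuningModel@width[cell]
  scl <- tuningModel@demandScales[cell, ][
    match(tb$subtask[lap], c("VD", "SA", "DA"))]
  d2 <- (tracking@x - cx)^2 + (tracking@y - cy)^2
  lam <- tuningModel@peak[cell] * scl * exp(-d2 / (2 * w^2))
  g <- tuningModel@prospectiveGain[cell]
  if (g != 0) {
    # destination-dependent modulation restricted to the stem column
    # (central stem + upper junction), i.e. before the turn
    z <- geometry@zones$stem
    inStem <- tracking@x >= z[1] & tracking@x <= z[2] &
      tracking@y >= geometry@pathWidth
    destSign <- ifelse(tb$destination[lap] == "L", 1, -1)
    lam <- lam * ifelse(inStem, pmax(0, 1 + g * destSign), 1)
  }
  lam + tuningModel@background[cell]
}

#' Simulate spike trains by inhomogeneous-Poisson thinning
#'
#' Each cell's instantaneous rate is its trial-type-specific field mixture
#' evaluated at the tracked position (piecewise constant per tracking
#' sample); spikes are drawn by thinning a homogeneous Poisson process at
#' the rate maximum.
#'
#' @param tracking a [TrackingSeries-class].
#' @param schedule the [LapSchedule-class] the tracking was generated from.
#' @param tuningModel a [TuningModel-class] covering every trial type in the
#'   schedule.
#' @param geometry a [MazeGeometry-class].
#' @param seed integer seed.
#' @return a [SpikeTrains-class].
#' @export
simulateSpikes <- function(tracking, schedule, tuningModel,
                           geometry = mazeGeometry(), seed = 1L) {
  tb <- scheduleTable(schedule)
  if (max(tracking@lap) != nrow(tb))
    stop("alignment error: tracking laps do not match the schedule")
  set.seed(seed)
  t0 <- tracking@t[1]; t1 <- tracking@t[length(tracking@t)]
  times <- vector("list", tuningModel@nCells)
  for (cell in seq_len(tuningModel@nCells)) {
    lam <- .cellRate(cell, tuningModel, tracking, schedule, geometry)
    lamMax <- max(lam)
    if (lamMax <= 0) { times[[cell]] <- numeric(0); next }
    nCand <- stats::rpois(1, lamMax * (t1 - t0))
    cand <- sort(stats::runif(nCand, t0, t1))
    idx <- pmax(1L, findInterval(cand, tracking@t))
    keep <- stats::runif(nCand) < lam[idx] / lamMax
    times[[cell]] <- cand[keep]
  }
  ids <- sprintf("c%03d", seq_len(tuningModel@nCells))
  names(times) <- ids
  units <- data.frame(unit_id = ids,
                      spike_width_ms = stats::runif(tuningModel@nCells,
                                                    0.5, 1.0),
                      class = "pyramidal", stringsAsFactors = FALSE)
  new("SpikeTrains", times = times, units = units)
}

# ---- full session -----------------------------------------------------------

#' Simulate a complete synthetic session
#'
#' Convenience wrapper deriving per-stage seeds from a single master seed
#' and running schedule, tuning, tracking and spike generation.
#'
#' @param nCells number of tuned place cells.
#' @param blocks block structure (see [generateSchedule()]).
#' @param errorRate per-lap choice-error probability.
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param geometry a [MazeGeometry-class].
#' @param tuningArgs,trackingArgs lists of extra arguments forwarded to
#'   [makeTuningModel()] and [simulateTracking()].
#' @return a [MazeSession-class].
#' @examples
#' s <- simulateSession(nCells = 4,
#'                      blocks = data.frame(subtask = c("VD", "SA"),
#'                                          n_laps = c(4L, 4L)),
#'                      seed = 1)
#' s
#' @export
simulateSession <- function(nCells = 50, blocks = defaultBlocks(),
                            errorRate = 0.01, seed = 1L,
                            geometry = mazeGeometry(),
                            tuningArgs = list(), trackingArgs = list()) {
  sch <- generateSchedule(blocks, errorRate = errorRate,
                          seed = .deriveSeed(seed, 1))
  tun <- do.call(makeTuningModel,
                 c(list(nCells = nCells, geometry = geometry,
                        seed = .deriveSeed(seed, 2)), tuningArgs))
  trk <- do.call(simulateTracking,
                 c(list(schedule = sch, geometry = geometry,
                        seed = .deriveSeed(seed, 3)), trackingArgs))
  spk <- simulateSpikes(trk, sch, tun, geometry,
                        seed = .deriveSeed(seed, 4))
  new("MazeSession", geometry = geometry, schedule = sch, tracking = trk,
      spikes = spk, tuning = tun, seed = as.integer(seed),
      params = list(nCells = nCells, errorRate = errorRate,
                    tuningArgs = tuningArgs, trackingArgs = trackingArgs))
}
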