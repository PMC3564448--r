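#' @include AllClasses.R taskmodel.R
NULL

# unwrap a sequence of angles in degrees (remove 360-degree jumps)
.unwrapDeg <- function(deg) {
  d <- diff(deg)
  d <- d - 360 * round(d / 360)
  c(deg[1], deg[1] + cumsum(d))
}

#' Per-sample running speed
#'
#' Speed of each tracking sample from finite displacement differences.
#'
#' @param tracking a [TrackingSeries-class].
#' @return numeric vector of speeds (cm/s), one per sample.
#' @export
sampleSpeed <- function(tracking) {
  n <- length(tracking@t)
  if (n < 2) return(rep(0, n))
  v <- sqrt(diff(tracking@x)^2 + diff(tracking@y)^2) / diff(tracking@t)
  c(v[1], v)
}

# project points onto a polyline: nearest-point arc length, signed lateral
# offset (positive to the right of travel) and distance to the path
.projectToPath <- function(px, py, path) {
  vx <- path[, 1]; vy <- path[, 2]
  nseg <- length(vx) - 1
  dx <- diff(vx); dy <- diff(vy)
  seglen <- sqrt(dx^2 + dy^2)
  ux <- dx / seglen; uy <- dy / seglen
  cum <- c(0, cumsum(seglen))
  # exact projection onto every segment (paths may be closed loops, so a
  # nearest-vertex shortcut would misassign points near the shared endpoint)
  DX <- outer(px, vx[seq_len(nseg)], "-")
  DY <- outer(py, vy[seq_len(nseg)], "-")
  TP <- sweep(DX, 2, ux, "*") + sweep(DY, 2, uy, "*")
  TP <- pmin(pmax(TP, 0), matrix(seglen, length(px), nseg, byrow = TRUE))
  RX <- DX - sweep(TP, 2, ux, "*")
  RY <- DY - sweep(TP, 2, uy, "*")
  D2 <- RX^2 + RY^2
  j <- max.col(-D2, ties.method = "first")
  im <- cbind(seq_along(px), j)
  list(d = sqrt(D2[im]),
       arc = cum[j] + TP[im],
       lat = RX[im] * uy[j] - RY[im] * ux[j],
       A = cum[matrix(seq_len(nseg), length(px), nseg, byrow = TRUE)] + TP,
       D2 = D2, RX = RX, RY = RY, ux = ux, uy = uy)
}

# monotone variant for lap slices: journeys that start and end at the same
# reward zone make the polyline a closed loop, so the globally nearest
# point is ambiguous near the shared endpoint; resolve it by requiring the
# arc length to progress within a +/- `window` cm band from sample to sample
.projectToPathMonotone <- function(px, py, path, window = 5) {
  pr <- .projectToPath(px, py, path)
  n <- length(px)
  arc <- pr$arc; d <- pr$d; lat <- pr$lat
  take <- function(i, j) {
    arc[i] <<- pr$A[i, j]
    d[i] <<- sqrt(pr$D2[i, j])
    lat[i] <<- pr$RX[i, j] * pr$uy[j] - pr$RY[i, j] * pr$ux[j]
  }
  # anchor: among near-minimal-distance segments of the first sample,
  # prefer the smallest arc (a lap starts at its origin)
  nearMin <- which(pr$D2[1, ] <= min(pr$D2[1, ]) + 1)
  take(1, nearMin[which.min(pr$A[1, nearMin])])
  # same-side journeys are closed loops whose start and end stretches
  # coincide near the reward zone; a lap starts at its origin, so an
  # anchor landing near the path end is re-anchored to the start region
  L <- max(pr$A)
  closed <- all(path[1, ] == path[nrow(path), ])
  if (closed && arc[1] > 0.75 * L) {
    startCand <- which(pr$A[1, ] < 0.25 * L)
    take(1, startCand[which.min(pr$D2[1, startCand])])
  }
  prev <- arc[1]
  for (i in seq_len(n)[-1]) {
    ok <- pr$A[i, ] >= prev - window & pr$A[i, ] <= prev + window
    if (any(ok))
      take(i, which(ok)[which.min(pr$D2[i, ok])])
    prev <- arc[i]
  }
  list(arc = arc, d = d, lat = lat)
}

#' Linearize one lap onto its journey's ideal path
#'
#' Projects each tracking sample of the lap onto the idealized path
#' (nearest point on the polyline), marks samples more than `maxDist` cm
#' off the path as excluded, and accumulates per-bin occupancy, speed
#' (bin length over traversal time), head direction and signed lateral
#' offset on an arc-length grid of ~0.35 cm pitch.
#'
#' @param tracking a [TrackingSeries-class].
#' @param sampleIdx integer indices of the lap's samples.
#' @param path ideal-path polyline of the lap's journey (see [idealPath()]).
#' @param pitch nominal bin pitch (cm); the effective pitch divides the
#'   path length exactly.
#' @param maxDist samples farther than this from the path are excluded (cm).
#' @param lap lap index stored in the result.
#' @return a [LinearizedLap-class].
#' @export
linearizeLap <- function(tracking, sampleIdx, path, pitch = 0.35,
                         maxDist = 5, lap = NA_integer_) {
  if (length(sampleIdx) == 0)
    stop("segmentation error: empty lap slice")
  px <- tracking@x[sampleIdx]; py <- tracking@y[sampleIdx]
  tt <- tracking@t[sampleIdx]
  hd <- tracking@hd[sampleIdx]
  pr <- .projectToPathMonotone(px, py, path)
  off <- pr$d > maxDist

  L <- sum(sqrt(rowSums(diff(path)^2)))
  m <- max(1L, round(L / pitch))
  pitchEff <- L / m
  edges <- (0:m) * pitchEff
  centers <- edges[-1] - pitchEff / 2

  on <- !off
  occupancy <- rep(0, m)
  hdC <- latC <- rep(NA_real_, m)
  if (sum(on) >= 2) {
    arcU <- cummax(pr$arc[on]) + seq_len(sum(on)) * 1e-9
    tRel <- tt[on] - tt[on][1]
    occupancy <- pmax(0, diff(stats::approx(arcU, tRel, xout = edges,
                                            rule = 2)$y))
    hdU <- .unwrapDeg(hd[on])
    hdC <- stats::approx(arcU, hdU, xout = centers, rule = 2)$y %% 360
    latC <- stats::approx(arcU, pr$lat[on], xout = centers, rule = 2)$y
  }
  visited <- occupancy > 1e-9
  speed <- ifelse(visited, pitchEff / occupancy, NA_real_)
  hdC[!visited] <- NA; latC[!visited] <- NA
  bins <- data.frame(bin = seq_len(m) - 1L, arc = centers,
                     occupancy = occupancy, speed = speed, hd = hdC,
                     lateral = latC, visited = visited)
  new("LinearizedLap", lap = as.integer(lap), pitch = pitchEff, bins = bins,
      sampleIdx = as.integer(sampleIdx), sampleArc = pr$arc,
      sampleLateral = pr$lat, sampleOff = off)
}

#' Segment session tracking into laps
#'
#' Recovers one contiguous sample slice per scheduled lap, with boundaries
#' at reward-zone entries: a lap ends at the first sample inside its
#' destination reward zone (after having left the origin zone when origin
#' and destination coincide), and the next lap starts at the following
#' sample.
#'
#' @param tracking a [TrackingSeries-class].
#' @param schedule a [LapSchedule-class].
#' @param geometry a [MazeGeometry-class].
#' @return data.frame with columns `lap`, `start`, `end` (sample indices).
#' @export
segmentLaps <- function(tracking, schedule, geometry) {
  tb <- scheduleTable(schedule)
  n <- length(tracking@t)
  inRZ <- list(L = which(inZone(geometry, "RZ_L", tracking@x, tracking@y)),
               R = which(inZone(geometry, "RZ_R", tracking@x, tracking@y)))
  outRZ <- list(
    L = which(!inZone(geometry, "RZ_L", tracking@x, tracking@y)),
    R = which(!inZone(geometry, "RZ_R", tracking@x, tracking@y)))
  firstAtOrAfter <- function(sorted, i) {
    p <- findInterval(i - 0.5, sorted) + 1
    if (p > length(sorted)) NA_integer_ else sorted[p]
  }
  start <- end <- integer(nrow(tb))
  cursor <- 1L
  for (k in seq_len(nrow(tb))) {
    from <- cursor
    if (tb$origin[k] == tb$destination[k]) {
      from <- firstAtOrAfter(outRZ[[tb$origin[k]]], cursor)
      if (is.na(from)) from <- n + 1L
    }
    hit <- firstAtOrAfter(inRZ[[tb$destination[k]]], from)
    if (is.na(hit)) {
      if (k == nrow(tb)) hit <- n
      else stop("alignment error: no reward-zone entry found for lap ", k)
    }
    start[k] <- cursor; end[k] <- hit
    cursor <- hit + 1L
    if (cursor > n && k < nrow(tb))
      stop("alignment error: tracking ends before lap ", k + 1)
  }
  end[nrow(tb)] <- n
  data.frame(lap = tb$lap, start = start, end = end)
}

#' Linearize every lap of a session
#'
#' @param session a [MazeSession-class].
#' @param pitch bin pitch (cm).
#' @param maxDist off-path exclusion distance (cm).
#' @param segments optional precomputed output of [segmentLaps()].
#' @return list of [LinearizedLap-class], one per lap.
#' @export
linearizeSession <- function(session, pitch = 0.35, maxDist = 5,
                             segments = NULL) {
  if (is.null(segments))
    segments <- segmentLaps(session@tracking, session@schedule,
                            session@geometry)
  tb <- scheduleTable(session)
  lapply(seq_len(nrow(segments)), function(k) {
    linearizeLap(session@tracking,
                 seq(segments$start[k], segments$end[k]),
                 idealPath(session@geometry, tb$journey[k]),
                 pitch = pitch, maxDist = maxDist, lap = segments$lap[k])
  })
}

#' Detect the turn-onset location of a lap
#'
#' The turn onset is the last location where the rat is in the central stem
#' or the upper junction and its head angular velocity is below the
#' threshold (default 0.12 rev/s). Angular velocity is the central
#' difference of the unwrapped head direction, boxcar-smoothed.
#'
#' @param tracking a [TrackingSeries-class].
#' @param sampleIdx integer indices of the lap's samples.
#' @param geometry a [MazeGeometry-class].
#' @param threshold angular-velocity threshold (revolutions per second).
#' @param window boxcar smoothing window (samples, odd).
#' @param path optional ideal-path polyline; when given, the onset's
#'   arc-length is included in the result.
#' @param lap lap index stored in the result.
#' @return list with elements `lap`, `found`, `x`, `y`, `index` (global
#'   sample index) and `arc` (NA without `path`).
#' @export
detectTurnOnset <- function(tracking, sampleIdx, geometry, threshold = 0.12,
                            window = 5, path = NULL, lap = NA_integer_) {
  x <- tracking@x[sampleIdx]; y <- tracking@y[sampleIdx]
  region <- inZone(geometry, "stem", x, y) |
    inZone(geometry, "junction", x, y)
  if (!any(region))
    stop("segmentation error: lap has no stem or junction samples")
  tt <- tracking@t[sampleIdx]
  rev <- .unwrapDeg(tracking@hd[sampleIdx]) / 360
  n <- length(rev)
  av <- numeric(n)
  if (n >= 3) {
    av[2:(n - 1)] <- (rev[3:n] - rev[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
    av[1] <- av[2]; av[n] <- av[n - 1]
  }
  if (window > 1 && n > window) {
    sm <- stats::filter(av, rep(1 / window, window), sides = 2)
    av <- ifelse(is.na(sm), av, as.numeric(sm))
  }
  qual <- region & abs(av) < threshold
  if (!any(qual))
    return(list(lap = lap, found = FALSE, x = NA_real_, y = NA_real_,
                index = NA_integer_, arc = NA_real_))
  i <- max(which(qual))
  arc <- NA_real_
  if (!is.null(path))
    arc <- .projectToPath(x[i], y[i], path)$arc
  list(lap = lap, found = TRUE, x = x[i], y = y[i],
       index = sampleIdx[i], arc = arc)
}

#' Remove spikes emitted during immobility
#'
#' Drops every spike whose nearest tracking sample has running speed below
#' the threshold (default 5 cm/s); spike ordering is preserved. This also
#' removes delay-period spikes on delayed-alternation laps.
#'
#' @param spikes a [SpikeTrains-class].
#' @param tracking a [TrackingSeries-class].
#' @param threshold speed threshold (cm/s), positive.
#' @return a filtered [SpikeTrains-class].
#' @export
filterImmobility <- function(spikes, tracking, threshold = 5) {
  if (threshold <= 0) stop("speed threshold must be positive")
  v <- sampleSpeed(tracking)
  tvec <- tracking@t
  n <- length(tvec)
  keepTimes <- lapply(spikes@times, function(st) {
    if (length(st) == 0) return(st)
    i <- pmax(1L, findInterval(st, tvec))
    j <- pmin(n, i + 1L)
    nearer <- abs(tvec[j] - st) < abs(st - tvec[i])
    idx <- ifelse(nearer, j, i)
    st[v[idx] >= threshold]
  })
  new("SpikeTrains", times = keepTimes, units = spikes@units)
}
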