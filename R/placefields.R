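#' @include AllClasses.R behavior.R
NULL

# ---- rate maps --------------------------------------------------------------

# Gaussian-kernel occupancy (denominator of the kernel-ratio estimator),
# raw occupancy time and visited mask on the 2-d grid; depends only on the
# tracking subset, so it is computed once per condition and shared by all
# cells
.occupancyGrid <- function(tracking, sampleIdx, geometry, binSize = 5,
                           h = 5, maxDist = 5) {
  x <- tracking@x[sampleIdx]; y <- tracking@y[sampleIdx]
  tt <- tracking@t[sampleIdx]
  if (length(x) == 0) stop("input error: empty tracking")
  md <- 1 / tracking@rateHz
  dt <- c(md, diff(tt))
  dt[dt > 3 * md] <- md                       # bridge lap-subset gaps
  xm <- seq(binSize / 2, geometry@outerWidth - binSize / 2, by = binSize)
  ym <- seq(binSize / 2, geometry@outerHeight - binSize / 2, by = binSize)
  nx <- length(xm); ny <- length(ym)
  den <- occ <- matrix(0, nx, ny)
  visited <- matrix(FALSE, nx, ny)
  # raw occupancy by bin assignment
  bx <- pmin(pmax(ceiling(x / binSize), 1L), nx)
  by <- pmin(pmax(ceiling(y / binSize), 1L), ny)
  flat <- (by - 1L) * nx + bx
  agg <- rowsum(dt, flat)
  occ[as.integer(rownames(agg))] <- agg[, 1]
  h2 <- 2 * h^2
  for (j in seq_len(ny)) {
    dy2 <- (y - ym[j])^2
    for (i in seq_len(nx)) {
      d2 <- (x - xm[i])^2 + dy2
      den[i, j] <- sum(dt * exp(-d2 / h2))
      visited[i, j] <- min(d2) <= maxDist^2
    }
  }
  list(den = den, occ = occ, visited = visited, xmids = xm, ymids = ym,
       binSize = binSize, h = h, totalTime = sum(dt))
}

#' Compute an occupancy-normalized kernel rate map
#'
#' Implements the kernel-ratio estimator: at each bin center x the rate is
#' the Gaussian-kernel sum over spike positions divided by the kernel-
#' weighted occupancy integral, with kernel width `h` (default 5 cm) on a
#' `binSize` (default 5 cm) grid. Bins farther than `maxDist` from any
#' tracked position are unvisited and carry no rate. Spikes are assigned
#' the position of their nearest tracking sample; when `sampleIdx` is
#' given, only spikes whose nearest sample belongs to the subset
#' contribute, restricting the map to those laps.
#'
#' @param spikeTimes numeric vector of (immobility-filtered) spike times.
#' @param tracking a [TrackingSeries-class].
#' @param geometry a [MazeGeometry-class] (grid extent).
#' @param sampleIdx optional tracking-sample subset (condition laps).
#' @param binSize,h,maxDist bin size, kernel width, visited cutoff (cm).
#' @param occGrid optional precomputed occupancy grid (internal reuse
#'   across cells of the same condition).
#' @return a [RateMap-class].
#' @export
computeRateMap <- function(spikeTimes, tracking, geometry = mazeGeometry(),
                           sampleIdx = NULL, binSize = 5, h = 5,
                           maxDist = 5, occGrid = NULL) {
  if (length(tracking@t) == 0) stop("input error: empty tracking")
  if (is.null(sampleIdx)) sampleIdx <- seq_along(tracking@t)
  if (is.null(occGrid))
    occGrid <- .occupancyGrid(tracking, sampleIdx, geometry, binSize, h,
                              maxDist)
  if (sum(occGrid$occ) <= 0) stop("input error: zero occupancy everywhere")

  member <- logical(length(tracking@t))
  member[sampleIdx] <- TRUE
  sx <- sy <- numeric(0)
  if (length(spikeTimes) > 0) {
    i <- pmax(1L, findInterval(spikeTimes, tracking@t))
    j <- pmin(length(tracking@t), i + 1L)
    idx <- ifelse(abs(tracking@t[j] - spikeTimes) <
                    abs(spikeTimes - tracking@t[i]), j, i)
    idx <- idx[member[idx]]
    sx <- tracking@x[idx]; sy <- tracking@y[idx]
  }
  xm <- occGrid$xmids; ym <- occGrid$ymids
  num <- matrix(0, length(xm), length(ym))
  if (length(sx) > 0) {
    h2 <- 2 * occGrid$h^2
    for (j in seq_along(ym)) {
      dy2 <- (sy - ym[j])^2
      for (i in seq_along(xm))
        num[i, j] <- sum(exp(-((sx - xm[i])^2 + dy2) / h2))
    }
  }
  ok <- occGrid$visited & occGrid$den > 0
  rate <- matrix(NA_real_, length(xm), length(ym))
  rate[ok] <- num[ok] / occGrid$den[ok]
  prob <- occGrid$occ[ok] / sum(occGrid$occ[ok])
  meanRate <- sum(prob * rate[ok])
  new("RateMap", rate = rate, occupancy = occGrid$occ, visited = ok,
      xmids = xm, ymids = ym, binSize = occGrid$binSize, h = occGrid$h,
      meanRate = meanRate,
      peakRate = if (any(ok)) max(rate[ok]) else 0,
      nSpikes = length(sx))
}

#' Skaggs spatial information of a rate map
#'
#' Bits per spike: the occupancy-probability-weighted sum of
#' (R_i / R) log2(R_i / R) over visited bins, where R_i is the bin rate and
#' R the occupancy-weighted mean rate; zero-rate bins contribute 0.
#'
#' @param map a [RateMap-class].
#' @return spatial information (bits/spike), non-negative.
#' @examples
#' # two equally occupied bins, one silent: 1 bit/spike
#' @export
spatialInformation <- function(map) {
  R <- map@meanRate
  if (!is.finite(R) || R <= 0)
    stop("spatial information undefined: mean rate is zero")
  Ri <- map@rate[map@visited]
  Pi <- map@occupancy[map@visited]
  Pi <- Pi / sum(Pi)
  pos <- Ri > 0
  sum(Pi[pos] * (Ri[pos] / R) * log2(Ri[pos] / R))
}

# ---- unit selection ---------------------------------------------------------

#' Classify units as pyramidal, interneuron or excluded
#'
#' `unitClass()` applies the criteria to vectors of spike width and mean
#' rate: units below `minRate` are excluded; units with wide spikes
#' (>= 0.4 ms) and low rates (<= 5 Hz) are putative pyramidal cells; the
#' remainder are putative fast-spiking interneurons. `classifyUnits()`
#' computes each unit's session mean rate and stores the class (and rate)
#' in the units table.
#'
#' @param spikeWidth spike width (ms).
#' @param meanRate session mean firing rate (Hz).
#' @param widthThreshold,rateThreshold pyramidal criteria (ms, Hz).
#' @param minRate exclusion threshold (Hz).
#' @return `unitClass()`: character vector in
#'   `c("pyramidal", "interneuron", "excluded")`. `classifyUnits()`: the
#'   [SpikeTrains-class] with `class` and `mean_rate_hz` columns updated.
#' @export
unitClass <- function(spikeWidth, meanRate, widthThreshold = 0.4,
                      rateThreshold = 5, minRate = 0.1) {
  if (any(is.na(spikeWidth)) || any(is.na(meanRate)))
    stop("input error: missing spike width or mean rate")
  out <- ifelse(spikeWidth >= widthThreshold & meanRate <= rateThreshold,
                "pyramidal", "interneuron")
  out[meanRate < minRate] <- "excluded"
  out
}

#' @rdname unitClass
#' @param spikes a [SpikeTrains-class].
#' @param tracking a [TrackingSeries-class] (defines the session duration).
#' @export
classifyUnits <- function(spikes, tracking, widthThreshold = 0.4,
                          rateThreshold = 5, minRate = 0.1) {
  dur <- diff(range(tracking@t))
  rate <- lengths(spikes@times) / dur
  units <- spikes@units
  units$mean_rate_hz <- unname(rate)
  units$class <- unitClass(units$spike_width_ms, units$mean_rate_hz,
                           widthThreshold, rateThreshold, minRate)
  new("SpikeTrains", times = spikes@times, units = units)
}

#' Select place cells by spatial information
#'
#' A cell is retained if its spatial information exceeds the threshold in
#' at least one trial type.
#'
#' @param si numeric matrix of spatial information (cells x trial types;
#'   NA allowed for conditions where the cell never fired).
#' @param threshold bits/spike (default 1.0).
#' @return character vector of retained cell ids (rownames of `si`).
#' @export
selectPlaceCells <- function(si, threshold = 1.0) {
  stopifnot(is.matrix(si))
  best <- apply(si, 1, function(z) if (all(is.na(z))) -Inf else
    max(z, na.rm = TRUE))
  rownames(si)[best > threshold]
}

# ---- similarity -------------------------------------------------------------

#' Central-stem mask on the rate-map grid
#'
#' @param geometry a [MazeGeometry-class].
#' @param binSize rate-map bin size (cm).
#' @return logical matrix marking bins whose centers lie in the stem zone.
#' @export
stemMask <- function(geometry, binSize = 5) {
  xm <- seq(binSize / 2, geometry@outerWidth - binSize / 2, by = binSize)
  ym <- seq(binSize / 2, geometry@outerHeight - binSize / 2, by = binSize)
  z <- geometry@zones$stem
  outer(xm >= z[1] & xm <= z[2], ym >= z[3] & ym <= z[4], "&")
}

#' Spatial similarity of two rate maps
#'
#' Rank (Spearman, default) or Pearson correlation between the two maps
#' over the bins of the region of interest that are visited in both; rank
#' correlation makes the measure independent of any rank-preserving rate
#' rescaling, dissociating it from rate similarity.
#'
#' @param mapA,mapB [RateMap-class] objects on the same grid.
#' @param roi optional logical matrix (e.g. [stemMask()]); default all bins.
#' @param method "spearman" (default) or "pearson".
#' @param minBins minimum number of jointly visited ROI bins.
#' @return correlation in \[-1, 1\], or NA (with a warning) when fewer than
#'   `minBins` joint bins exist or either map has zero variance.
#' @export
spatialSimilarity <- function(mapA, mapB, roi = NULL,
                              method = c("spearman", "pearson"),
                              minBins = 3) {
  method <- match.arg(method)
  stopifnot(identical(dim(mapA@rate), dim(mapB@rate)))
  joint <- mapA@visited & mapB@visited
  if (!is.null(roi)) joint <- joint & roi
  a <- mapA@rate[joint]; b <- mapB@rate[joint]
  if (length(a) < minBins) {
    warning("spatial similarity undefined: fewer than ", minBins,
            " jointly visited bins")
    return(NA_real_)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("spatial similarity undefined: zero variance in a map")
    return(NA_real_)
  }
  stats::cor(a, b, method = method)
}

#' Rate similarity index
#'
#' One minus the unsigned rate difference divided by the rate sum:
#' identical rates score 1, a silent condition scores the asymptotic
#' floor 0. Symmetric and invariant to common rescaling.
#'
#' @param a,b non-negative rates (Hz).
#' @return score in \[0, 1\], or NA (with a warning) when both rates are 0.
#' @export
rateSimilarity <- function(a, b) {
  stopifnot(a >= 0, b >= 0)
  if (a + b == 0) {
    warning("rate similarity undefined: both rates are zero")
    return(NA_real_)
  }
  1 - abs(a - b) / (a + b)
}

#' Occupancy-weighted mean rate inside a region of interest
#'
#' @param map a [RateMap-class].
#' @param roi logical matrix (e.g. [stemMask()]).
#' @return mean rate (Hz) over visited ROI bins, occupancy-weighted.
#' @export
roiMeanRate <- function(map, roi) {
  sel <- map@visited & roi
  if (!any(sel)) return(NA_real_)
  w <- map@occupancy[sel]
  if (sum(w) == 0) return(NA_real_)
  sum(map@rate[sel] * w) / sum(w)
}

# ---- ANCOVA screen ----------------------------------------------------------

#' One-way ANCOVA screen for condition-dependent firing
#'
#' Fits firing rate on the condition factor plus running speed, head
#' direction and lateral position as linear covariates, and returns the
#' F test of the condition factor after covariate adjustment.
#'
#' @param data data.frame with columns `rate`, `condition` (factor or
#'   character, >= 2 levels with >= 2 observations each), `speed`, `hd`,
#'   `lateral`.
#' @param alpha significance level.
#' @return one-row data.frame: `F`, `df1`, `df2`, `p`, `significant`.
#' @export
ancovaScreen <- function(data, alpha = 0.05) {
  need <- c("rate", "condition", "speed", "hd", "lateral")
  if (!all(need %in% names(data)))
    stop("input error: data must have columns ",
         paste(need, collapse = ", "))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  data$condition <- factor(data$condition)
  if (nlevels(data$condition) < 2 || any(table(data$condition) < 2))
    stop("input error: need >= 2 conditions with >= 2 observations each")
  reduced <- stats::lm(rate ~ speed + hd + lateral, data = data)
  full <- stats::lm(rate ~ speed + hd + lateral + condition, data = data)
  if (any(is.na(stats::coef(full)[grep("^condition", names(stats::coef(full)))])))
    stop("rank-deficient design: condition aliased with covariates")
  an <- stats::anova(reduced, full)
  p <- an[["Pr(>F)"]][2]
  data.frame(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = p,
             significant = p < alpha)
}

# ---- stem observation table -------------------------------------------------

# spike counts of each cell in the arc-length bins of one linearized lap
.lapCellCounts <- function(spikes, tracking, lin, cellIds) {
  m <- nrow(lin@bins)
  idx <- lin@sampleIdx
  tmin <- tracking@t[idx[1]]; tmax <- tracking@t[idx[length(idx)]]
  out <- matrix(0, m, length(cellIds))
  localT <- tracking@t[idx]
  for (ci in seq_along(cellIds)) {
    st <- spikes@times[[cellIds[ci]]]
    st <- st[st >= tmin & st <= tmax]
    if (length(st) == 0) next
    i <- pmax(1L, findInterval(st, localT))
    j <- pmin(length(localT), i + 1L)
    nearer <- abs(localT[j] - st) < abs(st - localT[i])
    s <- ifelse(nearer, j, i)
    keep <- !lin@sampleOff[s]
    if (!any(keep)) next
    b <- pmin(m, pmax(1L, floor(lin@sampleArc[s][keep] / lin@pitch) + 1L))
    tab <- tabulate(b, nbins = m)
    out[, ci] <- tab
  }
  colnames(out) <- cellIds
  out
}

# Gaussian smoothing of the columns of a matrix, zero-padded, kernel
# normalized to unit sum (preserves column totals away from the edges)
.gaussSmoothCols <- function(mat, sdBins) {
  half <- max(1L, ceiling(4 * sdBins))
  k <- stats::dnorm(seq(-half, half), sd = sdBins)
  k <- k / sum(k)
  pad <- matrix(0, half, ncol(mat))
  padded <- rbind(pad, mat, pad)
  sm <- stats::filter(padded, k, sides = 2)
  out <- as.matrix(sm[(half + 1):(half + nrow(mat)), , drop = FALSE])
  out[is.na(out)] <- 0
  dimnames(out) <- dimnames(mat)
  out
}

#' Per-bin stem observations for the ANCOVA screen
#'
#' For every correct lap with a defined trial type, computes each cell's
#' smoothed firing rate (bin spike count over bin traversal time, convolved
#' with a Gaussian of SD `sd` cm) in every central-stem bin, together with
#' the behavioral covariates of that traversal (speed, head direction,
#' signed lateral position).
#'
#' @param session a [MazeSession-class].
#' @param linearized output of [linearizeSession()].
#' @param spikes immobility-filtered [SpikeTrains-class].
#' @param cells unit ids to include (default: all units in `spikes`).
#' @param sd smoothing SD (cm).
#' @param binStride keep every `binStride`-th stem bin (1 = all).
#' @return list with `covariates` (data.frame: lap, trial_type, journey,
#'   subtask, bin, arc, speed, hd, lateral) and `rates` (matrix, one
#'   column per cell, rows aligned with `covariates`).
#' @export
stemObservations <- function(session, linearized, spikes, cells = NULL,
                             sd = 5, binStride = 1L) {
  if (is.null(cells)) cells <- session@spikes@units$unit_id
  tb <- scheduleTable(session)
  arcRange <- session@geometry@stemArc
  covList <- list(); rateList <- list()
  for (k in seq_len(nrow(tb))) {
    if (!tb$correct[k] || is.na(tb$trial_type[k])) next
    lin <- linearized[[k]]
    bins <- lin@bins
    stemIdx <- which(bins$arc >= arcRange[1] & bins$arc <= arcRange[2] &
                       bins$visited)
    if (length(stemIdx) == 0) next
    stemIdx <- stemIdx[seq(1, length(stemIdx), by = binStride)]
    counts <- .lapCellCounts(spikes, session@tracking, lin, cells)
    occ <- bins$occupancy
    rate <- counts / ifelse(occ > 0, occ, Inf)
    rate <- .gaussSmoothCols(rate, sd / lin@pitch)
    covList[[length(covList) + 1]] <- data.frame(
      lap = tb$lap[k], trial_type = tb$trial_type[k],
      journey = tb$journey[k], subtask = tb$subtask[k],
      bin = bins$bin[stemIdx], arc = bins$arc[stemIdx],
      speed = bins$speed[stemIdx], hd = bins$hd[stemIdx],
      lateral = bins$lateral[stemIdx], stringsAsFactors = FALSE)
    rateList[[length(rateList) + 1]] <- rate[stemIdx, , drop = FALSE]
  }
  list(covariates = do.call(rbind, covList),
       rates = do.call(rbind, rateList))
}

#' Differential-firing screen over journeys and task-demands
#'
#' For every cell, runs the ANCOVA screen between different journeys within
#' each subtask and between different task-demands within each cross
#' journey, and flags cells with a significant condition effect in at
#' least one comparison.
#'
#' @param obs output of [stemObservations()].
#' @param alpha significance level.
#' @return list with `results` (data.frame: cell, comparison, F, p,
#'   significant) and `differential` (named logical per cell).
#' @export
differentialFiringScreen <- function(obs, alpha = 0.05) {
  cov <- obs$covariates
  cells <- colnames(obs$rates)
  comparisons <- list()
  for (st in unique(cov$subtask)) {
    rows <- which(cov$subtask == st)
    if (length(unique(cov$journey[rows])) >= 2)
      comparisons[[paste0("journeys|", st)]] <-
        list(rows = rows, condition = cov$journey[rows])
  }
  for (j in c("RL", "LR")) {
    rows <- which(cov$journey == j)
    if (length(unique(cov$subtask[rows])) >= 2)
      comparisons[[paste0("demands|", j)]] <-
        list(rows = rows, condition = cov$subtask[rows])
  }
  res <- list()
  for (cell in cells) {
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      df <- data.frame(rate = obs$rates[cmp$rows, cell],
                       condition = cmp$condition,
                       speed = cov$speed[cmp$rows],
                       hd = cov$hd[cmp$rows],
                       lateral = cov$lateral[cmp$rows])
      out <- tryCatch(ancovaScreen(df, alpha), error = function(e) NULL)
      if (is.null(out)) next
      res[[length(res) + 1]] <- cbind(data.frame(cell = cell,
                                                 comparison = nm),
                                      out)
    }
  }
  results <- do.call(rbind, res)
  differential <- vapply(cells, function(cl)
    any(results$significant[results$cell == cl]), logical(1))
  list(results = results, differential = differential)
}

# ---- condition rate maps and remapping similarity ---------------------------

#' Rate maps per condition for all cells
#'
#' @param session a [MazeSession-class].
#' @param spikes immobility-filtered [SpikeTrains-class].
#' @param conditions named list of lap-index vectors.
#' @param segments output of [segmentLaps()].
#' @param cells unit ids (default all).
#' @param binSize,h rate-map parameters (cm).
#' @return nested list: `maps[[condition]][[cell]]` of [RateMap-class].
#' @export
conditionRateMaps <- function(session, spikes, conditions, segments,
                              cells = NULL, binSize = 5, h = 5) {
  if (is.null(cells)) cells <- spikes@units$unit_id
  out <- list()
  for (nm in names(conditions)) {
    laps <- conditions[[nm]]
    sampleIdx <- unlist(lapply(laps, function(k)
      seq(segments$start[k], segments$end[k])))
    og <- .occupancyGrid(session@tracking, sampleIdx, session@geometry,
                         binSize, h)
    out[[nm]] <- lapply(stats::setNames(cells, cells), function(cl)
      computeRateMap(spikes@times[[cl]], session@tracking,
                     session@geometry, sampleIdx, binSize, h,
                     occGrid = og))
  }
  out
}

#' Spatial information per cell and trial type
#'
#' @param maps output of [conditionRateMaps()] keyed by trial type.
#' @return matrix (cells x conditions) of bits/spike; NA where the cell's
#'   mean rate in that condition is zero.
#' @export
spatialInformationMatrix <- function(maps) {
  cells <- names(maps[[1]])
  si <- sapply(maps, function(byCell) vapply(byCell, function(m)
    tryCatch(spatialInformation(m), error = function(e) NA_real_),
    numeric(1)))
  si <- matrix(si, nrow = length(cells),
               dimnames = list(cells, names(maps)))
  si
}

#' Quantify remapping: spatial and rate similarity by comparison class
#'
#' Builds trial-type rate maps (and split-half maps within trial types)
#' restricted to correct laps, then computes the spatial similarity r_s and
#' rate similarity r_r in the central stem for three comparison classes:
#' `within_type` (first vs second half of the same trial type's laps,
#' i.e. repeated exposures), `cross_journey` (different journeys within a
#' subtask) and `cross_demand` (different subtasks within a journey).
#'
#' @param session a [MazeSession-class].
#' @param spikes immobility-filtered [SpikeTrains-class].
#' @param segments output of [segmentLaps()].
#' @param cells unit ids to analyze (e.g. selected place cells).
#' @param minLaps minimum laps per split half / condition.
#' @param method correlation method for r_s.
#' @param minRate pair-level validity floor (Hz): a cell contributes a
#'   similarity pair only when its ROI mean rate reaches `minRate` in both
#'   conditions -- rank correlations between near-silent maps measure
#'   sampling noise, not remapping. Mirrors restricting the comparison to
#'   cells that actually fire on the common stem.
#' @param binSize,h rate-map parameters (cm).
#' @return data.frame: `cell`, `class`, `pair`, `r_s`, `r_r` (NA rows are
#'   pairs below the validity floor or with undefined correlation).
#' @export
remappingSimilarity <- function(session, spikes, segments, cells = NULL,
                                minLaps = 3, method = "spearman",
                                minRate = 0.5, binSize = 5, h = 5) {
  tb <- scheduleTable(session)
  ok <- tb$correct & !is.na(tb$trial_type)
  roi <- stemMask(session@geometry, binSize)
  ttPresent <- names(which(table(tb$trial_type[ok]) >= minLaps))

  conditions <- list()
  for (tt in ttPresent) {
    laps <- tb$lap[ok & tb$trial_type == tt]
    conditions[[tt]] <- laps
    if (length(laps) >= 2 * minLaps) {
      half <- floor(length(laps) / 2)
      conditions[[paste0(tt, ".h1")]] <- laps[seq_len(half)]
      conditions[[paste0(tt, ".h2")]] <- laps[(half + 1):length(laps)]
    }
  }
  maps <- conditionRateMaps(session, spikes, conditions, segments, cells,
                            binSize, h)

  ttInfo <- trialTypes()
  pairs <- list()
  addPair <- function(class, a, b) {
    if (a %in% names(maps) && b %in% names(maps))
      pairs[[length(pairs) + 1]] <<- list(class = class, a = a, b = b)
  }
  for (tt in ttPresent)
    addPair("within_type", paste0(tt, ".h1"), paste0(tt, ".h2"))
  for (st in unique(ttInfo$subtask)) {
    tts <- intersect(ttInfo$trial_type[ttInfo$subtask == st], ttPresent)
    if (length(tts) >= 2) {
      cmb <- utils::combn(tts, 2)
      for (q in seq_len(ncol(cmb)))
        addPair("cross_journey", cmb[1, q], cmb[2, q])
    }
  }
  for (j in c("RL", "LR")) {
    tts <- intersect(ttInfo$trial_type[ttInfo$journey == j], ttPresent)
    if (length(tts) >= 2) {
      cmb <- utils::combn(tts, 2)
      for (q in seq_len(ncol(cmb)))
        addPair("cross_demand", cmb[1, q], cmb[2, q])
    }
  }

  cellIds <- names(maps[[1]])
  rows <- list()
  for (pr in pairs) {
    for (cl in cellIds) {
      mA <- maps[[pr$a]][[cl]]; mB <- maps[[pr$b]][[cl]]
      ra <- roiMeanRate(mA, roi); rb <- roiMeanRate(mB, roi)
      valid <- !is.na(ra) && !is.na(rb) && ra >= minRate && rb >= minRate
      rs <- if (valid)
        suppressWarnings(spatialSimilarity(mA, mB, roi, method)) else
          NA_real_
      rr <- if (valid && ra + rb > 0) rateSimilarity(ra, rb) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        cell = cl, class = pr$class, pair = paste(pr$a, pr$b, sep = ":"),
        r_s = rs, r_r = rr, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Median similarity by comparison class
#'
#' @param sim output of [remappingSimilarity()].
#' @return data.frame: class, median r_s, median r_r, n pairs.
#' @export
similaritySummary <- function(sim) {
  cls <- unique(sim$class)
  data.frame(
    class = cls,
    median_r_s = vapply(cls, function(cl)
      stats::median(sim$r_s[sim$class == cl], na.rm = TRUE), numeric(1)),
    median_r_r = vapply(cls, function(cl)
      stats::median(sim$r_r[sim$class == cl], na.rm = TRUE), numeric(1)),
    n = vapply(cls, function(cl)
      sum(sim$class == cl & (!is.na(sim$r_s) | !is.na(sim$r_r))),
      integer(1)),
    row.names = NULL)
}
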