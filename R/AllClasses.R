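#' @import methods
NULL

#' Maze geometry for the figure-eight task
#'
#' Axis-aligned description of the figure-eight maze: outer footprint,
#' path width, named zones (central stem, upper junction / decision point,
#' reward zones, delay zones) and one idealized path polyline per journey.
#' Coordinates are in cm with the origin at the lower-left outer corner,
#' x rightward and y upward.
#'
#' @slot outerWidth,outerHeight outer footprint of the maze (cm).
#' @slot pathWidth width of the running path (cm).
#' @slot zones named list of axis-aligned rectangles
#'   `c(xmin, xmax, ymin, ymax)` in cm: `stem`, `junction`, `RZ_L`, `RZ_R`,
#'   `DZ_L`, `DZ_R`.
#' @slot idealPaths named list (`RL`, `LR`, `LL`, `RR`) of two-column
#'   matrices of polyline vertices at 1-cm spacing; the central-stem
#'   vertices are byte-identical across journeys.
#' @slot pathLength arc length of every journey's ideal path (cm).
#' @slot stemArc two-element arc-length range (cm) of the central-stem
#'   region of interest, identical for all journeys.
#'
#' @seealso [mazeGeometry()]
#' @export
setClass("MazeGeometry",
         representation(outerWidth = "numeric", outerHeight = "numeric",
                        pathWidth = "numeric", zones = "list",
                        idealPaths = "list", pathLength = "numeric",
                        stemArc = "numeric"))

setValidity("MazeGeometry", function(object) {
  msg <- character()
  if (object@pathWidth <= 0) msg <- c(msg, "path width must be positive")
  for (nm in names(object@zones)) {
    z <- object@zones[[nm]]
    if (length(z) != 4)
      msg <- c(msg, sprintf("zone '%s' is not a 4-vector", nm))
    else if (z[1] < 0 || z[2] > object@outerWidth ||
             z[3] < 0 || z[4] > object@outerHeight)
      msg <- c(msg, sprintf("zone '%s' lies outside the outer rectangle", nm))
  }
  if (length(object@idealPaths) > 0) {
    stemX <- object@outerWidth / 2
    stem <- .stemVertices(object@idealPaths[[1]], stemX)
    for (p in object@idealPaths[-1])
      if (!identical(stem, .stemVertices(p, stemX)))
        msg <- c(msg, "central stem vertices differ between journeys")
  }
  if (length(msg)) msg else TRUE
})

# vertices of a path lying on the stem centerline
.stemVertices <- function(path, stemX)
  path[path[, 1] == stemX, , drop = FALSE]

#' Ordered lap schedule of the figure-eight task
#'
#' One row per lap with the subtask (VD, SA or DA), cue state, journey
#' (origin and destination side), derived trial type, correctness and
#' delay flag.
#'
#' @slot table data.frame with columns `lap`, `subtask`, `cue_state`,
#'   `origin`, `destination`, `journey`, `trial_type`, `correct`, `delay`.
#' @seealso [generateSchedule()]
#' @export
setClass("LapSchedule", representation(table = "data.frame"))

setValidity("LapSchedule", function(object) {
  need <- c("lap", "subtask", "cue_state", "origin", "destination",
            "journey", "trial_type", "correct", "delay")
  tb <- object@table
  if (!all(need %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(need, names(tb)), collapse = ", ")))
  msg <- character()
  if (!all(tb$subtask %in% c("VD", "SA", "DA")))
    msg <- c(msg, "subtask must be VD, SA or DA")
  if (!identical(tb$delay, tb$subtask == "DA"))
    msg <- c(msg, "delay flag must hold exactly on DA laps")
  if (!all((tb$cue_state == "both") == (tb$subtask %in% c("SA", "DA"))))
    msg <- c(msg, "cue_state must be 'both' exactly on SA/DA laps")
  ok <- tb$correct & tb$subtask %in% c("SA", "DA")
  if (any(!tb$journey[ok] %in% c("RL", "LR")))
    msg <- c(msg, "correct SA/DA laps must be RL or LR journeys")
  if (length(msg)) msg else TRUE
})

#' Head-position tracking series
#'
#' Timestamped head position and direction samples at a nominal 60 Hz,
#' spanning the whole session. The `lap` slot carries the generator's
#' ground-truth lap index per sample (analysis code re-derives laps with
#' [segmentLaps()]).
#'
#' @slot t,x,y,hd numeric vectors: time (s), position (cm) and head
#'   direction (degrees).
#' @slot rateHz nominal sampling rate (Hz).
#' @slot lap integer ground-truth lap index per sample.
#' @seealso [simulateTracking()]
#' @export
setClass("TrackingSeries",
         representation(t = "numeric", x = "numeric", y = "numeric",
                        hd = "numeric", rateHz = "numeric", lap = "integer"))

setValidity("TrackingSeries", function(object) {
  n <- length(object@t)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@hd) != n || length(object@lap) != n)
    return("t, x, y, hd and lap must have equal length")
  if (n > 1 && any(diff(object@t) <= 0))
    return("timestamps must be strictly increasing")
  TRUE
})

#' Spike trains of simultaneously monitored units
#'
#' @slot times named list of sorted spike-time vectors (s), one per unit.
#' @slot units data.frame with one row per unit: `unit_id`,
#'   `spike_width_ms` and (after classification) `class`.
#' @seealso [simulateSpikes()], [classifyUnits()]
#' @export
setClass("SpikeTrains",
         representation(times = "list", units = "data.frame"))

setValidity("SpikeTrains", function(object) {
  if (length(object@times) != nrow(object@units))
    return("one spike-time vector per unit row required")
  if (!identical(names(object@times), as.character(object@units$unit_id)))
    return("names(times) must match units$unit_id")
  for (v in object@times)
    if (is.unsorted(v)) return("spike times must be sorted ascending")
  TRUE
})

#' Ground-truth place-cell tuning of a synthetic ensemble
#'
#' Each cell carries one isotropic Gaussian field per journey (identical
#' across journeys when `journeyMode = "none"`, drawn independently when
#' `"global"`), a per-subtask rate scale (rate remapping across
#' task-demands), a uniform background rate and an optional
#' destination-dependent prospective gain applied on the stem.
#'
#' @slot nCells number of units.
#' @slot centers numeric array `nCells x 4 x 2` of field centers (cm),
#'   journeys RL, LR, LL, RR in the second dimension.
#' @slot width,peak,background per-cell field width (cm), peak rate (Hz)
#'   and background rate (Hz).
#' @slot demandScales `nCells x 3` matrix of rate scales, columns VD, SA, DA.
#' @slot prospectiveGain per-cell signed gain g: stem-region rate is
#'   multiplied by (1 + g) on laps toward L and (1 - g) toward R.
#' @slot tuned logical per cell; untuned cells fire at `background` only.
#' @slot journeyMode,demandMode remapping modes used to build the model.
#' @seealso [makeTuningModel()]
#' @export
setClass("TuningModel",
         representation(nCells = "integer", centers = "array",
                        width = "numeric", peak = "numeric",
                        background = "numeric", demandScales = "matrix",
                        prospectiveGain = "numeric", tuned = "logical",
                        journeyMode = "character", demandMode = "character"))

setValidity("TuningModel", function(object) {
  n <- object@nCells
  if (!identical(dim(object@centers), c(n, 4L, 2L)))
    return("centers must be nCells x 4 x 2")
  if (any(object@peak < 0)) return("peak rates must be >= 0")
  if (!identical(colnames(object@demandScales), c("VD", "SA", "DA")))
    return("demandScales columns must be VD, SA, DA")
  TRUE
})

# rate remapping preserves field location across task-demands: the
# representation keys centers by journey only, so that invariant holds by
# construction and needs no runtime check
setClassUnion("TuningModelOrNULL", members = c("TuningModel", "NULL"))

#' Occupancy-normalized kernel firing-rate map
#'
#' Two-dimensional rate map on a 5 cm x 5 cm grid computed with the
#' Gaussian kernel-ratio estimator; carries the raw occupancy used for
#' spatial information and a visited mask (bins farther than 5 cm from
#' any tracked position are unvisited and carry no rate).
#'
#' @slot rate,occupancy matrices (x bins in rows, y bins in columns) of
#'   firing rate (Hz) and occupancy time (s); rate is NA on unvisited bins.
#' @slot visited logical matrix.
#' @slot xmids,ymids bin-center coordinates (cm).
#' @slot binSize,h bin size and kernel width (cm).
#' @slot meanRate occupancy-weighted mean rate R (Hz).
#' @slot peakRate maximum rate over visited bins (Hz).
#' @slot nSpikes number of spikes contributing.
#' @seealso [computeRateMap()], [spatialInformation()]
#' @export
setClass("RateMap",
         representation(rate = "matrix", occupancy = "matrix",
                        visited = "matrix", xmids = "numeric",
                        ymids = "numeric", binSize = "numeric",
                        h = "numeric", meanRate = "numeric",
                        peakRate = "numeric", nSpikes = "numeric"))

setValidity("RateMap", function(object) {
  r <- object@rate[object@visited]
  if (any(r < 0, na.rm = TRUE)) return("rates must be >= 0")
  if (any(!is.na(object@rate[!object@visited])))
    return("unvisited bins must carry no rate")
  TRUE
})

#' Linearized lap
#'
#' A lap's tracking projected onto its journey's idealized path: per-bin
#' occupancy, speed, head direction and signed lateral offset at a ~0.35 cm
#' arc-length pitch, plus the per-sample projection used to assign spikes.
#'
#' @slot lap lap index.
#' @slot pitch bin pitch (cm).
#' @slot bins data.frame with columns `bin`, `arc`, `occupancy`, `speed`,
#'   `hd`, `lateral`, `visited`.
#' @slot sampleIdx indices of the lap's samples in the session tracking.
#' @slot sampleArc,sampleLateral per-sample arc length and lateral offset.
#' @slot sampleOff logical, samples more than 5 cm off the path (excluded).
#' @seealso [linearizeLap()]
#' @export
setClass("LinearizedLap",
         representation(lap = "integer", pitch = "numeric",
                        bins = "data.frame", sampleIdx = "integer",
                        sampleArc = "numeric", sampleLateral = "numeric",
                        sampleOff = "logical"))

#' Ensemble state-space trajectories
#'
#' Per-lap `m x n` matrices of Gaussian-smoothed spike counts (m location
#' bins along the linearized path, n cells), stacked into an array, with
#' the lap metadata and the central-stem region of interest used by the
#' distance classifiers.
#'
#' @slot counts numeric array `m x n x L` of smoothed spike counts.
#' @slot arc bin-center arc lengths (cm).
#' @slot pitch bin pitch (cm).
#' @slot cells unit identifiers (length n).
#' @slot laps data.frame with one row per lap: `lap`, `trial_type`,
#'   `journey`, `subtask`, `destination`, `correct`.
#' @slot roi integer indices of the central-stem bins.
#' @slot sd smoothing SD (cm).
#' @seealso [buildTrajectories()], [classifyLaps()]
#' @export
setClass("TrajectorySet",
         representation(counts = "array", arc = "numeric", pitch = "numeric",
                        cells = "character", laps = "data.frame",
                        roi = "integer", sd = "numeric"))

setValidity("TrajectorySet", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3) return("counts must be a 3-d array")
  if (d[2] != length(object@cells)) return("cell roster mismatch")
  if (d[3] != nrow(object@laps)) return("lap metadata mismatch")
  if (d[1] != length(object@arc)) return("bin arc mismatch")
  if (any(object@counts < 0)) return("smoothed counts must be >= 0")
  TRUE
})

#' A complete (synthetic or loaded) recording session
#'
#' Container tying together geometry, schedule, tracking, spike trains and
#' (for synthetic sessions) the ground-truth tuning model.
#'
#' @slot geometry a [MazeGeometry-class].
#' @slot schedule a [LapSchedule-class].
#' @slot tracking a [TrackingSeries-class].
#' @slot spikes a [SpikeTrains-class].
#' @slot tuning a [TuningModel-class] or NULL for real/loaded data.
#' @slot seed master seed the session was generated from (NA if loaded).
#' @slot params list of generator parameters.
#' @seealso [simulateSession()]
#' @export
setClass("MazeSession",
         representation(geometry = "MazeGeometry", schedule = "LapSchedule",
                        tracking = "TrackingSeries", spikes = "SpikeTrains",
                        tuning = "TuningModelOrNULL", seed = "integer",
                        params = "list"))
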