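#' @include AllClasses.R
NULL

#' Accessors for session components and schedules
#'
#' `scheduleTable()` returns the lap table of a [LapSchedule-class] (or of a
#' session's schedule); `nLaps()` the number of laps; `schedule()`,
#' `tracking()`, `spikeTrains()`, `geometry()` and `tuning()` extract the
#' corresponding slot of a [MazeSession-class]; `trialTypes()` enumerates
#' the eight trial types of the task.
#'
#' @param object a [LapSchedule-class] or [MazeSession-class].
#' @return See each generic's description.
#' @name accessors
#' @aliases scheduleTable nLaps schedule tracking spikeTrains geometry tuning
#' @examples
#' sch <- generateSchedule(seed = 1)
#' nLaps(sch)
#' head(scheduleTable(sch))
NULL

#' @rdname accessors
#' @export
setGeneric("scheduleTable", function(object) standardGeneric("scheduleTable"))
#' @rdname accessors
#' @export
setMethod("scheduleTable", "LapSchedule", function(object) object@table)
#' @rdname accessors
#' @export
setMethod("scheduleTable", "MazeSession", function(object) object@schedule@table)

#' @rdname accessors
#' @export
setGeneric("nLaps", function(object) standardGeneric("nLaps"))
#' @rdname accessors
#' @export
setMethod("nLaps", "LapSchedule", function(object) nrow(object@table))
#' @rdname accessors
#' @export
setMethod("nLaps", "MazeSession", function(object) nrow(object@schedule@table))

#' @rdname accessors
#' @export
setGeneric("schedule", function(object) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setMethod("schedule", "MazeSession", function(object) object@schedule)

#' @rdname accessors
#' @export
setGeneric("tracking", function(object) standardGeneric("tracking"))
#' @rdname accessors
#' @export
setMethod("tracking", "MazeSession", function(object) object@tracking)

#' @rdname accessors
#' @export
setGeneric("spikeTrains", function(object) standardGeneric("spikeTrains"))
#' @rdname accessors
#' @export
setMethod("spikeTrains", "MazeSession", function(object) object@spikes)

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "MazeSession", function(object) object@geometry)

#' @rdname accessors
#' @export
setGeneric("tuning", function(object) standardGeneric("tuning"))
#' @rdname accessors
#' @export
setMethod("tuning", "MazeSession", function(object) object@tuning)

#' Enumerate the eight trial types
#'
#' Trial types are journey x subtask combinations: the visually guided
#' subtask admits all four journeys (VD1 = R to L, VD2 = L to L,
#' VD3 = L to R, VD4 = R to R) while the alternation subtasks admit only
#' the two cross journeys (SA1/DA1 = R to L, SA2/DA2 = L to R).
#'
#' @return data.frame with columns `trial_type`, `subtask`, `journey`.
#' @examples
#' trialTypes()
#' 1 / nrow(trialTypes())   # chance level of the 8-way classifier
#' @export
trialTypes <- function() {
  data.frame(
    trial_type = c("VD1", "VD2", "VD3", "VD4", "SA1", "SA2", "DA1", "DA2"),
    subtask    = c("VD", "VD", "VD", "VD", "SA", "SA", "DA", "DA"),
    journey    = c("RL", "LL", "LR", "RR", "RL", "LR", "RL", "LR"),
    stringsAsFactors = FALSE)
}

# journey key ("RL") from origin/destination sides
.journeyKey <- function(origin, destination) paste0(origin, destination)

# trial type from subtask + journey; NA when the combination is not one of
# the eight admissible trial types (possible only on SA/DA error laps)
.trialTypeOf <- function(subtask, journey) {
  tt <- trialTypes()
  key <- paste(tt$subtask, tt$journey)
  out <- tt$trial_type[match(paste(subtask, journey), key)]
  out
}

setMethod("show", "MazeGeometry", function(object) {
  cat(sprintf("MazeGeometry: %g x %g cm, path width %g cm\n",
              object@outerWidth, object@outerHeight, object@pathWidth))
  cat(sprintf("  journeys: %s; path length %g cm; stem arc [%g, %g] cm\n",
              paste(names(object@idealPaths), collapse = ", "),
              object@pathLength, object@stemArc[1], object@stemArc[2]))
  cat(sprintf("  zones: %s\n", paste(names(object@zones), collapse = ", ")))
})

setMethod("show", "LapSchedule", function(object) {
  tb <- object@table
  cat(sprintf("LapSchedule: %d laps (%d correct)\n",
              nrow(tb), sum(tb$correct)))
  print(table(factor(tb$trial_type, levels = trialTypes()$trial_type),
              useNA = "ifany"))
})

setMethod("show", "TrackingSeries", function(object) {
  cat(sprintf("TrackingSeries: %d samples at %g Hz, %.1f s\n",
              length(object@t), object@rateHz,
              diff(range(object@t))))
})

setMethod("show", "SpikeTrains", function(object) {
  cat(sprintf("SpikeTrains: %d units, %d spikes\n",
              nrow(object@units), sum(lengths(object@times))))
})

setMethod("show", "TuningModel", function(object) {
  cat(sprintf(
    "TuningModel: %d cells (%d tuned), journey remapping '%s', demand remapping '%s'\n",
    object@nCells, sum(object@tuned), object@journeyMode, object@demandMode))
})

setMethod("show", "RateMap", function(object) {
  cat(sprintf(
    "RateMap: %d x %d bins (%g cm), h = %g cm; mean %.3f Hz, peak %.2f Hz, %d spikes\n",
    nrow(object@rate), ncol(object@rate), object@binSize, object@h,
    object@meanRate, object@peakRate, object@nSpikes))
})

setMethod("show", "LinearizedLap", function(object) {
  cat(sprintf("LinearizedLap %d: %d bins at %.3f cm pitch, %d samples\n",
              object@lap, nrow(object@bins), object@pitch,
              length(object@sampleIdx)))
})

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "TrajectorySet: %d bins x %d cells x %d laps (pitch %.3f cm, SD %g cm)\n",
    d[1], d[2], d[3], object@pitch, object@sd))
  cat(sprintf("  ROI: %d central-stem bins\n", length(object@roi)))
})

setMethod("show", "MazeSession", function(object) {
  cat("MazeSession\n")
  cat(sprintf("  %d laps, %d units, %.1f s of tracking\n",
              nLaps(object), nrow(object@spikes@units),
              diff(range(object@tracking@t))))
  if (!is.null(object@tuning))
    cat(sprintf("  synthetic (seed %d), journey '%s' / demand '%s' remapping\n",
                object@seed, object@tuning@journeyMode,
                object@tuning@demandMode))
})
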