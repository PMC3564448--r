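# Shared synthetic fixtures, built once per test run and cached.
# The "study" session reproduces the task's study conditions: the standard
# 140-lap block structure, ~50 place cells, global journey remapping and
# rate remapping across task-demands (VD = 1, SA = 0.5, DA = 0.75).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

studySession <- function() fixture("study", function()
  simulateSession(nCells = 50, seed = 42))

studySegments <- function() fixture("studySeg", function() {
  s <- studySession()
  segmentLaps(s@tracking, s@schedule, s@geometry)
})

studyFiltered <- function() fixture("studySpk", function() {
  s <- studySession()
  filterImmobility(classifyUnits(spikeTrains(s), tracking(s)),
                   tracking(s))
})

studyLinearized <- function() fixture("studyLin", function()
  linearizeSession(studySession(), segments = studySegments()))

studyTraj <- function() fixture("studyTraj", function()
  buildTrajectories(studySession(), studyFiltered(), studyLinearized()))

# 128-cell roster with the same remapping structure (generalization tests)
bigSession <- function() fixture("big", function()
  simulateSession(nCells = 128, seed = 43))

bigTraj <- function() fixture("bigTraj", function() {
  s <- bigSession()
  seg <- segmentLaps(s@tracking, s@schedule, s@geometry)
  spk <- filterImmobility(spikeTrains(s), tracking(s))
  buildTrajectories(s, spk, linearizeSession(s, segments = seg))
})

# VD-only session with tuning shared across trial types; destination-
# dependent stem modulation controlled by `gain`
vdSession <- function(gain) {
  fixture(paste0("vd", gain), function()
    simulateSession(nCells = 40,
                    blocks = data.frame(subtask = "VD", n_laps = 60L),
                    errorRate = 0, seed = 21,
                    tuningArgs = list(journeyMode = "none",
                                      demandMode = "none",
                                      prospectiveGain = gain)))
}

vdTraj <- function(gain) {
  fixture(paste0("vdTraj", gain), function() {
    s <- vdSession(gain)
    seg <- segmentLaps(s@tracking, s@schedule, s@geometry)
    spk <- filterImmobility(spikeTrains(s), tracking(s))
    buildTrajectories(s, spk, linearizeSession(s, segments = seg))
  })
}

# a small session for cheap structural tests
smallSession <- function() fixture("small", function()
  simulateSession(nCells = 8,
                  blocks = data.frame(subtask = c("VD", "SA", "DA"),
                                      n_laps = c(6L, 6L, 6L)),
                  errorRate = 0, seed = 3))

# hand-built tracking: stationary or scripted, for analytic oracles
makeTracking <- function(x, y, hd = NULL, rateHz = 60) {
  n <- length(x)
  if (is.null(hd)) hd <- rep(0, n)
  new("TrackingSeries", t = seq_len(n) / rateHz, x = x, y = y, hd = hd,
      rateHz = rateHz, lap = rep(1L, n))
}
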