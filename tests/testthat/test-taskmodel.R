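test_that("default schedule follows the block structure and lap count", {
  sch <- generateSchedule(seed = 1)
  tb <- scheduleTable(sch)
  expect_equal(nLaps(sch), 140L)
  blocks <- rle(tb$subtask)
  expect_equal(blocks$values, c("VD", "SA", "VD", "DA", "VD", "SA", "VD",
                                "DA"))
  expect_equal(blocks$lengths, c(20L, 20L, 10L, 20L, 20L, 20L, 10L, 20L))
  expect_true(all(tb$delay == (tb$subtask == "DA")))
  expect_true(all((tb$cue_state == "both") ==
                    (tb$subtask %in% c("SA", "DA"))))
  expect_true(validObject(sch))
})

test_that("error-free alternation blocks strictly alternate journeys", {
  tb <- scheduleTable(generateSchedule(errorRate = 0, seed = 5))
  blk <- cumsum(c(TRUE, tb$subtask[-1] != tb$subtask[-nrow(tb)]))
  for (b in unique(blk[tb$subtask %in% c("SA", "DA")])) {
    d <- tb$destination[blk == b]
    expect_true(all(d[-1] != d[-length(d)]))
    expect_true(all(tb$journey[blk == b] %in% c("RL", "LR")))
  }
  # physical continuity: each lap starts where the previous ended
  expect_true(all(tb$origin[-1] == tb$destination[-nrow(tb)]))
})

test_that("schedules are deterministic under a fixed seed", {
  a <- generateSchedule(seed = 99, errorRate = 0.05)
  b <- generateSchedule(seed = 99, errorRate = 0.05)
  expect_identical(scheduleTable(a), scheduleTable(b))
  c <- generateSchedule(seed = 100, errorRate = 0.05)
  expect_false(identical(scheduleTable(a)$cue_state,
                         scheduleTable(c)$cue_state))
})

test_that("injected errors are flagged and can break trial-type coverage", {
  tb <- scheduleTable(generateSchedule(errorRate = 0.3, seed = 7))
  expect_gt(sum(!tb$correct), 0)
  expect_true(all(is.na(tb$trial_type[!tb$correct & tb$subtask != "VD" &
                                        tb$origin == tb$destination])))
  expect_true(all(!is.na(tb$trial_type[tb$correct])))
})

test_that("invalid block structure raises a configuration error", {
  expect_error(generateSchedule(data.frame(subtask = "XX", n_laps = 5L)),
               "configuration error")
  expect_error(generateSchedule(errorRate = 1.5), "configuration error")
  expect_error(simulateTracking(generateSchedule(seed = 1), mazeGeometry(),
                                speed = 0), "configuration error")
})

test_that("geometry invariants hold: zones inside, shared stem, equal arc", {
  g <- mazeGeometry()
  expect_true(validObject(g))
  lens <- vapply(g@idealPaths, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  expect_true(all(abs(lens - g@pathLength) < 1e-9))
  stem <- g@idealPaths$RL[g@idealPaths$RL[, 1] == 50, ]
  for (j in c("LR", "LL", "RR"))
    expect_identical(stem, g@idealPaths[[j]][g@idealPaths[[j]][, 1] == 50, ])
})

test_that("noise-free tracking lies exactly on the ideal polyline", {
  sch <- generateSchedule(data.frame(subtask = "VD", n_laps = 3L),
                          errorRate = 0, seed = 2)
  g <- mazeGeometry()
  trk <- simulateTracking(sch, g, speedSD = 0, jitterSD = 0, hdNoiseSD = 0,
                          seed = 1)
  tb <- scheduleTable(sch)
  for (k in seq_len(nrow(tb))) {
    idx <- which(trk@lap == k)
    pr <- episodecode:::.projectToPath(trk@x[idx], trk@y[idx],
                                       idealPath(g, tb$journey[k]))
    expect_lt(max(pr$d), 1e-9)
  }
})

test_that("DA laps contain a >= 5 s near-stationary epoch in the delay zone", {
  sch <- generateSchedule(data.frame(subtask = "DA", n_laps = 4L),
                          errorRate = 0, seed = 3)
  g <- mazeGeometry()
  trk <- simulateTracking(sch, g, seed = 4)
  v <- sampleSpeed(trk)
  for (k in 1:4) {
    idx <- which(trk@lap == k)
    still <- v[idx] < 5            # near-stationary samples
    runs <- rle(still)
    ends <- cumsum(runs$lengths)
    long <- which(runs$values & runs$lengths >= 5 * trk@rateHz - 2)
    expect_length(long, 1)
    ep <- idx[(ends[long] - runs$lengths[long] + 1):ends[long]]
    # contiguous epoch of >= 5 s with < 1 cm displacement in the delay zone
    expect_lt(max(dist(cbind(trk@x[ep], trk@y[ep]))), 1)
    side <- scheduleTable(sch)$origin[k]
    expect_true(all(inZone(g, paste0("DZ_", side), trk@x[ep], trk@y[ep])))
  }
})

test_that("per-lap mean stem speed matches the configured speed", {
  # sampling oracle: lap speeds are Gaussian(speed, speedSD); the mean of
  # 100 per-lap stem speeds must fall within 3 SD of the mean
  g <- mazeGeometry()
  sch <- generateSchedule(data.frame(subtask = "VD", n_laps = 1L),
                          errorRate = 0, seed = 1)
  path <- idealPath(g, "RL")
  stemArc <- g@stemArc
  speeds <- vapply(1:100, function(s) {
    trk <- simulateTracking(sch, g, speed = 30, speedSD = 2, seed = s)
    lin <- linearizeLap(trk, seq_along(trk@t), path, lap = 1L)
    b <- lin@bins
    mean(b$speed[b$visited & b$arc >= stemArc[1] & b$arc <= stemArc[2]])
  }, numeric(1))
  expect_lt(abs(mean(speeds) - 30), 3 * 2 / sqrt(100))
})

test_that("session duration matches path length over speed plus delays", {
  s <- smallSession()
  tb <- scheduleTable(s)
  v <- s@params$trackingArgs$speed
  expected <- nrow(tb) * s@geometry@pathLength / 30 + 5 * sum(tb$delay)
  expect_lt(abs(diff(range(s@tracking@t)) - expected) / expected, 0.1)
})

test_that("zero peak rates produce zero spikes", {
  sch <- generateSchedule(data.frame(subtask = "VD", n_laps = 2L),
                          errorRate = 0, seed = 1)
  g <- mazeGeometry()
  trk <- simulateTracking(sch, g, seed = 1)
  tun <- makeTuningModel(nCells = 3, geometry = g, background = 0, seed = 1)
  tun@peak[] <- 0
  spk <- simulateSpikes(trk, sch, tun, g, seed = 1)
  expect_equal(sum(lengths(spk@times)), 0)
})

test_that("constant-rate simulation recovers the Poisson mean count", {
  # oracle: a 10 Hz homogeneous cell over T = 100 s emits Poisson(1000)
  # spikes; the mean over 200 seeds lies within 3 sqrt(1000) of 1000
  n <- 6000
  trk <- makeTracking(x = seq(25, 75, length.out = n),
                      y = rep(15, n))  # T = 100 s at 60 Hz
  sch <- new("LapSchedule",
             table = data.frame(lap = 1L, subtask = "VD",
                                cue_state = "left", origin = "R",
                                destination = "L", journey = "RL",
                                trial_type = "VD1", correct = TRUE,
                                delay = FALSE))
  tun <- makeTuningModel(nCells = 0, nUntuned = 1, untunedRate = 10,
                         seed = 1)
  counts <- vapply(1:200, function(s)
    length(simulateSpikes(trk, sch, tun, mazeGeometry(),
                          seed = s)@times[[1]]), numeric(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000))
})

test_that("a demand scale of 0.5 halves the stem rate between VD and SA", {
  g <- mazeGeometry()
  sch <- generateSchedule(data.frame(subtask = c("VD", "SA"),
                                     n_laps = c(14L, 14L)),
                          errorRate = 0, seed = 9)
  trk <- simulateTracking(sch, g, seed = 9)
  tun <- makeTuningModel(nCells = 1, geometry = g, background = 0,
                         demandScales = c(VD = 1, SA = 0.5, DA = 0.5),
                         journeyMode = "none", seed = 1)
  tun@centers[1, , 1] <- 50; tun@centers[1, , 2] <- 70  # field on the stem
  spk <- simulateSpikes(trk, sch, tun, g, seed = 2)
  tb <- scheduleTable(sch)
  st <- spk@times[[1]]
  lapOf <- trk@lap[pmax(1L, findInterval(st, trk@t))]
  stemTime <- function(laps) sum(trk@lap %in% laps &
                                   inZone(g, "stem", trk@x, trk@y)) / 60
  vd <- tb$lap[tb$subtask == "VD" & tb$journey %in% c("RL", "LR")]
  sa <- tb$lap[tb$subtask == "SA"]
  rateVD <- sum(lapOf %in% vd) / stemTime(vd)
  rateSA <- sum(lapOf %in% sa) / stemTime(sa)
  expect_lt(abs(rateVD / rateSA - 2), 0.4)
})

test_that("global journey remapping separates field centers across journeys", {
  tun <- tuning(studySession())
  tuned <- which(tun@tuned)
  dRL_LR <- sqrt((tun@centers[tuned, "RL", 1] - tun@centers[tuned, "LR", 1])^2 +
                   (tun@centers[tuned, "RL", 2] - tun@centers[tuned, "LR", 2])^2)
  expect_gt(mean(dRL_LR > tun@width[tuned]), 0.9)
})

test_that("sessions are reproducible from the master seed", {
  a <- simulateSession(nCells = 3,
                       blocks = data.frame(subtask = "VD", n_laps = 3L),
                       seed = 17)
  b <- simulateSession(nCells = 3,
                       blocks = data.frame(subtask = "VD", n_laps = 3L),
                       seed = 17)
  expect_identical(scheduleTable(a), scheduleTable(b))
  expect_identical(a@tracking@x, b@tracking@x)
  expect_identical(a@spikes@times, b@spikes@times)
})
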