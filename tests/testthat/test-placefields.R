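# hand-built RateMap on a 1 x 2 grid for analytic spatial-information cases
twoBinMap <- function(rates, occ = c(1, 1)) {
  rate <- matrix(rates, 1, 2)
  occm <- matrix(occ, 1, 2)
  vis <- matrix(TRUE, 1, 2)
  R <- sum(occ / sum(occ) * rates)
  new("RateMap", rate = rate, occupancy = occm, visited = vis,
      xmids = 2.5, ymids = c(2.5, 7.5), binSize = 5, h = 5,
      meanRate = R, peakRate = max(rates), nSpikes = 10)
}

test_that("a stationary rat yields rate n/T by kernel cancellation", {
  n <- 3001
  trk <- makeTracking(x = rep(25, n), y = rep(15, n))
  Tdur <- n / 60
  m <- computeRateMap(seq(1, 49, length.out = 100), trk)
  expect_lt(abs(m@rate[5, 3] - 100 / Tdur) / (100 / Tdur), 0.01)
  # every visited bin carries the same ratio
  expect_lt(diff(range(m@rate[m@visited])) / (100 / Tdur), 1e-6)
})

test_that("zero spikes give zero rate on all visited bins", {
  n <- 1200
  trk <- makeTracking(x = seq(5, 95, length.out = n), y = rep(10, n))
  m <- computeRateMap(numeric(0), trk)
  expect_true(all(m@rate[m@visited] == 0))
  expect_true(all(is.na(m@rate[!m@visited])))
  expect_equal(m@meanRate, 0)
})

test_that("kernel rate map matches direct quadrature of the formula", {
  # oracle: plain double-loop evaluation of
  # f(x) = sum_i w((s_i - x)/h) / integral w((y(t) - x)/h) dt
  n <- 1200
  trk <- makeTracking(x = seq(5, 95, length.out = n), y = rep(10, n))
  spikeT <- trk@t[c(300, 600, 601, 900)]
  m <- computeRateMap(spikeT, trk, h = 5)
  sx <- trk@x[c(300, 600, 601, 900)]; sy <- trk@y[c(300, 600, 601, 900)]
  dt <- 1 / 60
  h <- 5
  for (i in seq_along(m@xmids)) {
    for (j in 1:3) {
      if (!m@visited[i, j]) next
      cx <- m@xmids[i]; cy <- m@ymids[j]
      num <- 0
      for (q in seq_along(sx))
        num <- num + exp(-((sx[q] - cx)^2 + (sy[q] - cy)^2) / (2 * h^2))
      den <- 0
      for (q in seq_len(n))
        den <- den + dt * exp(-((trk@x[q] - cx)^2 +
                                  (trk@y[q] - cy)^2) / (2 * h^2))
      expect_lt(abs(m@rate[i, j] - num / den) / max(num / den, 1e-12),
                0.01)
    }
  }
  # uniform traversal: the profile around an isolated spike falls off as
  # the Gaussian kernel does
  prof <- m@rate[, 2][m@visited[, 2]]
  xs <- m@xmids[m@visited[, 2]]
  k <- which.min(abs(xs - trk@x[900]))
  expect_gt(prof[k], prof[k + 2])
})

test_that("kernel-ratio conservation: rate x occupancy recovers spike count", {
  s <- smallSession()
  spk <- filterImmobility(spikeTrains(s), tracking(s))
  for (cell in c("c001", "c004")) {
    m <- computeRateMap(spk@times[[cell]], tracking(s), s@geometry)
    expect_lt(abs(sum(m@rate * m@occupancy, na.rm = TRUE) - m@nSpikes) /
                max(m@nSpikes, 1), 0.05)
  }
})

test_that("spatial information reproduces the analytic cases", {
  # uniform firing: 0 bits/spike
  expect_equal(spatialInformation(twoBinMap(c(3, 3))), 0)
  # half occupancy, single active bin at twice the mean: 1 bit/spike
  expect_equal(spatialInformation(twoBinMap(c(4, 0))), 1)
  # invariant to rate rescaling
  expect_equal(spatialInformation(twoBinMap(c(5, 1))),
               spatialInformation(twoBinMap(c(50, 10))))
  # undefined for a silent cell
  expect_error(spatialInformation(twoBinMap(c(0, 0))), "undefined")
  expect_gte(spatialInformation(twoBinMap(c(1, 5), occ = c(3, 1))), 0)
})

test_that("unit classification applies width, rate and exclusion criteria", {
  expect_equal(unitClass(0.6, 1.5), "pyramidal")
  expect_equal(unitClass(0.2, 12), "interneuron")
  expect_equal(unitClass(0.6, 0.05), "excluded")
  expect_equal(unitClass(0.4, 5), "pyramidal")       # boundary inclusive
  expect_equal(unitClass(0.39, 5.1), "interneuron")
  expect_error(unitClass(NA, 1), "input error")
  spk <- studyFiltered()
  expect_true(all(spk@units$class %in%
                    c("pyramidal", "interneuron", "excluded")))
})

test_that("spatial similarity is a rank correlation over joint ROI bins", {
  n <- 1200
  trk <- makeTracking(x = seq(5, 95, length.out = n), y = rep(10, n))
  a <- computeRateMap(trk@t[seq(100, 1100, by = 7)], trk)
  expect_equal(spatialSimilarity(a, a), 1)
  # rank-reversing transform: -1
  b <- a
  mx <- max(a@rate, na.rm = TRUE)
  b@rate[b@visited] <- mx + 1 - b@rate[b@visited]
  expect_equal(spatialSimilarity(a, b), -1)
  # doubling all rates preserves ranks (r_s = 1) but not rate similarity
  d <- a
  d@rate <- a@rate * 2
  d@meanRate <- a@meanRate * 2
  expect_equal(spatialSimilarity(a, d), 1)
  expect_lt(rateSimilarity(mean(a@rate[a@visited]),
                           mean(d@rate[d@visited])), 1)
  # symmetry
  expect_equal(spatialSimilarity(a, b), spatialSimilarity(b, a))
  # too few joint bins or zero variance: NA with a warning
  roi0 <- matrix(FALSE, length(a@xmids), length(a@ymids))
  expect_warning(r0 <- spatialSimilarity(a, b, roi = roi0), "undefined")
  expect_true(is.na(r0))
  z <- a; z@rate[z@visited] <- 1
  expect_warning(rz <- spatialSimilarity(z, a), "undefined")
  expect_true(is.na(rz))
})

test_that("rate similarity matches its closed form and floor", {
  expect_equal(rateSimilarity(2, 2), 1)
  expect_equal(rateSimilarity(3, 1), 0.5)
  expect_equal(rateSimilarity(4, 0), 0)
  expect_equal(rateSimilarity(1, 3), rateSimilarity(3, 1))
  expect_equal(rateSimilarity(3, 1), rateSimilarity(30, 10))
  expect_warning(r <- rateSimilarity(0, 0), "undefined")
  expect_true(is.na(r))
})

test_that("place-cell selection keeps tuned cells and drops untuned ones", {
  # a full-length session: the plug-in information estimator is biased
  # upward on short recordings, so the discrimination needs realistic
  # sampling (the task's standard 140-lap schedule)
  s <- simulateSession(nCells = 30, errorRate = 0, seed = 31,
                       tuningArgs = list(nUntuned = 20))
  seg <- segmentLaps(s@tracking, s@schedule, s@geometry)
  spk <- filterImmobility(spikeTrains(s), tracking(s))
  tb <- scheduleTable(s)
  ok <- tb$correct & !is.na(tb$trial_type)
  maps <- conditionRateMaps(s, spk, split(tb$lap[ok], tb$trial_type[ok]),
                            seg)
  si <- spatialInformationMatrix(maps)
  kept <- selectPlaceCells(si, threshold = 1.0)
  tunedIds <- s@spikes@units$unit_id[tuning(s)@tuned]
  untunedIds <- setdiff(s@spikes@units$unit_id, tunedIds)
  expect_length(intersect(kept, untunedIds), 0)
  expect_gte(length(intersect(kept, tunedIds)), 24)
  # direct threshold logic
  m <- matrix(c(0.2, 0.4, 1.3, 0.1,
                0.9, 0.8, 1.0, 0.7), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(selectPlaceCells(m), "a")
})

test_that("ANCOVA screen has power and removes speed confounds", {
  set.seed(11)
  mkObs <- function(rateFun, speedBy = 0) {
    n <- 40; b <- 30
    cond <- rep(c("A", "B"), each = n / 2 * b)
    speed <- stats::rnorm(n * b, 30 + speedBy * (cond == "B"), 2)
    data.frame(rate = rateFun(cond, speed), condition = cond,
               speed = speed, hd = stats::runif(n * b, 0, 360),
               lateral = stats::rnorm(n * b, 0, 1.5))
  }
  # 50% rate offset between conditions, covariates balanced: power > 95%
  pow <- mean(replicate(200, ancovaScreen(
    mkObs(function(cond, speed)
      ifelse(cond == "A", 2, 3) + stats::rnorm(length(cond))))$significant))
  expect_gt(pow, 0.95)
  # rate difference purely through a speed-rate dependence with speed
  # differing by condition: flagged in at most ~alpha of simulations
  conf <- mean(replicate(200, ancovaScreen(
    mkObs(function(cond, speed)
      0.3 * speed + stats::rnorm(length(cond)), speedBy = 4))$significant))
  expect_lt(conf, 0.10)
  # structural errors
  expect_error(ancovaScreen(data.frame(rate = 1:4, condition = "A",
                                       speed = 1, hd = 1, lateral = 1)),
               "input error")
  aliased <- mkObs(function(cond, speed) stats::rnorm(length(cond)))
  aliased$speed <- ifelse(aliased$condition == "A", 1, 2)
  expect_error(ancovaScreen(aliased), "rank-deficient")
})

test_that("differential-firing screen flags remapped cells on real sessions", {
  s <- studySession()
  spk <- studyFiltered()
  cells <- spk@units$unit_id[1:6]
  obs <- stemObservations(s, studyLinearized(), spk, cells = cells,
                          binStride = 8)
  out <- differentialFiringScreen(obs)
  expect_true(all(c("cell", "comparison", "p", "significant") %in%
                    names(out$results)))
  expect_true(all(out$results$p >= 0 & out$results$p <= 1))
  # journey comparisons exist for every subtask, demand comparisons for
  # both cross journeys
  expect_setequal(unique(out$results$comparison),
                  c("journeys|VD", "journeys|SA", "journeys|DA",
                    "demands|RL", "demands|LR"))
  # globally remapped ensembles: most cells fire differentially
  expect_gt(mean(out$differential), 0.5)
})
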