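#' @include AllClasses.R behavior.R placefields.R
NULL

#' Build ensemble state-space trajectories
#'
#' For each included lap, bins every cell's spikes on the lap's linearized
#' arc-length grid (~0.35 cm pitch) and convolves the counts with a
#' Gaussian (SD = 5 cm by default); the resulting m-bins x n-cells matrix
#' is one point per location bin in the n-dimensional ensemble state space.
#'
#' @param session a [MazeSession-class].
#' @param spikes immobility-filtered [SpikeTrains-class].
#' @param linearized output of [linearizeSession()] (computed if NULL).
#' @param cells unit ids to include (default: all units in `spikes`).
#' @param sd smoothing SD (cm).
#' @param correctOnly drop error laps and laps with undefined trial type.
#' @return a [TrajectorySet-class].
#' @export
buildTrajectories <- function(session, spikes, linearized = NULL,
                              cells = NULL, sd = 5, correctOnly = TRUE) {
  if (is.null(linearized)) linearized <- linearizeSession(session)
  if (is.null(cells)) cells <- spikes@units$unit_id
  if (!all(cells %in% names(spikes@times)))
    stop("input error: roster mismatch between cells and spike trains")
  tb <- scheduleTable(session)
  keep <- if (correctOnly) which(tb$correct & !is.na(tb$trial_type))
          else seq_len(nrow(tb))
  m <- nrow(linearized[[keep[1]]]@bins)
  for (k in keep)
    if (nrow(linearized[[k]]@bins) != m)
      stop("input error: laps linearized on different grids")
  sdBins <- sd / linearized[[keep[1]]]@pitch
  counts <- array(0, dim = c(m, length(cells), length(keep)))
  for (q in seq_along(keep)) {
    k <- keep[q]
    raw <- .lapCellCounts(spikes, session@tracking, linearized[[k]], cells)
    counts[, , q] <- .gaussSmoothCols(raw, sdBins)
  }
  arc <- linearized[[keep[1]]]@bins$arc
  stemArc <- session@geometry@stemArc
  new("TrajectorySet", counts = counts, arc = arc,
      pitch = linearized[[keep[1]]]@pitch, cells = as.character(cells),
      laps = tb[keep, c("lap", "trial_type", "journey", "subtask",
                        "destination", "correct")],
      roi = which(arc >= stemArc[1] & arc <= stemArc[2]),
      sd = sd)
}

# resolve a labels argument: either a laps-column name or a vector
.lapLabels <- function(traj, labels) {
  if (is.character(labels) && length(labels) == 1 &&
      labels %in% names(traj@laps))
    return(traj@laps[[labels]])
  if (length(labels) != nrow(traj@laps))
    stop("input error: labels must name a lap column or have one entry per lap")
  as.character(labels)
}

# drop laps whose label is NA or has fewer than minLaps laps
.usableLaps <- function(labels, minLaps = 2, lapSel = NULL, warn = TRUE) {
  sel <- if (is.null(lapSel)) seq_along(labels) else lapSel
  sel <- sel[!is.na(labels[sel])]
  cnt <- table(labels[sel])
  bad <- names(cnt)[cnt < minLaps]
  if (length(bad) > 0) {
    if (warn)
      warning("excluding label(s) with fewer than ", minLaps, " laps: ",
              paste(bad, collapse = ", "))
    sel <- sel[!labels[sel] %in% bad]
  }
  sel
}

# majority vote over per-bin labels; ties are marked (lap counted incorrect)
.majorityVote <- function(predMat, K) {
  cnt <- vapply(seq_len(K), function(g) rowSums(predMat == g),
                numeric(nrow(predMat)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = nrow(predMat))
  top <- do.call(pmax, lapply(seq_len(K), function(g) cnt[, g]))
  pred <- max.col(cnt, ties.method = "first")
  tie <- rowSums(cnt == top) > 1
  list(pred = pred, tie = tie)
}

#' Distance-to-mean-trajectory classification with LOOCV
#'
#' Classifies each lap at each region-of-interest location bin by the
#' Euclidean distance (across cells) from the lap's ensemble state to the
#' mean trajectory of every candidate label, computed excluding the test
#' lap (leave-one-out cross-validation). The bin is assigned the nearest
#' mean's label (exact ties broken toward the lexicographically first
#' label); the lap-level label is the most frequent per-bin label over the
#' ROI (majority ties are marked and counted incorrect).
#'
#' @param traj a [TrajectorySet-class].
#' @param labels a column of the lap table ("trial_type", "journey",
#'   "subtask", "destination") or a per-lap label vector.
#' @param roi bin indices used for distances and the vote (default: the
#'   central-stem bins).
#' @param laps optional subset of lap rows to classify.
#' @param minLaps labels with fewer laps are excluded with a warning.
#' @return list with `lapTable` (lap, label, predicted, correct),
#'   `binAccuracy` (arc, accuracy, p from a one-sided binomial test against
#'   chance), `accuracy` (lap-level), `chance`, `nTies`, `candidates`.
#' @export
classifyLaps <- function(traj, labels = "trial_type", roi = NULL,
                         laps = NULL, minLaps = 2) {
  lab <- .lapLabels(traj, labels)
  sel <- .usableLaps(lab, minLaps, laps)
  if (is.null(roi)) roi <- traj@roi
  lab <- lab[sel]
  cand <- sort(unique(lab))
  K <- length(cand)
  if (K < 2) stop("input error: need at least two candidate labels")
  X <- traj@counts[roi, , sel, drop = FALSE]
  B <- length(roi); L <- length(sel)
  labIdx <- match(lab, cand)
  sums <- lapply(seq_len(K), function(g)
    rowSums(X[, , labIdx == g, drop = FALSE], dims = 2))
  kcnt <- tabulate(labIdx, K)
  predMat <- matrix(0L, L, B)
  for (i in seq_len(L)) {
    Xi <- X[, , i]
    D <- matrix(0, B, K)
    for (g in seq_len(K)) {
      mu <- if (g == labIdx[i]) (sums[[g]] - Xi) / (kcnt[g] - 1)
            else sums[[g]] / kcnt[g]
      D[, g] <- rowSums((Xi - mu)^2)
    }
    predMat[i, ] <- max.col(-D, ties.method = "first")
  }
  vote <- .majorityVote(predMat, K)
  correct <- !vote$tie & vote$pred == labIdx
  binAcc <- colMeans(predMat == matrix(labIdx, L, B))
  binP <- vapply(round(binAcc * L), function(k)
    binomialTest(k, L, 1 / K, side = "greater")$p, numeric(1))
  list(lapTable = data.frame(lap = traj@laps$lap[sel], label = lab,
                             predicted = ifelse(vote$tie, NA_character_,
                                                cand[vote$pred]),
                             correct = correct),
       binAccuracy = data.frame(arc = traj@arc[roi], accuracy = binAcc,
                                p = binP),
       accuracy = mean(correct), chance = 1 / K, nTies = sum(vote$tie),
       candidates = cand)
}

# ---- Gram-matrix classification engine --------------------------------------
# Squared Euclidean distances to group means depend on the data only through
# lap-by-lap dot products at each bin, so the per-bin Gram matrices are
# computed once and every label permutation is classified by two small
# matrix products. Identical in output to the direct classifier (asserted
# in the test suite).

# stacked cross-Gram: rows are (bin-major) test laps, columns train laps
.stackedGram <- function(traj, roi, testIdx, trainIdx) {
  X <- traj@counts[roi, , , drop = FALSE]
  B <- length(roi)
  LA <- length(testIdx); LB <- length(trainIdx)
  G <- matrix(0, B * LA, LB)
  for (b in seq_len(B)) {
    A <- X[b, , testIdx, drop = FALSE]; dim(A) <- c(dim(X)[2], LA)
    Btr <- X[b, , trainIdx, drop = FALSE]; dim(Btr) <- c(dim(X)[2], LB)
    G[(b - 1) * LA + seq_len(LA), ] <- crossprod(A, Btr)
  }
  G
}

# classify test laps against group-mean templates of train laps, given
# Gram matrices; handles LOOCV when train == test
.gramClassify <- function(Gte, Gtr, trainLabIdx, testLabIdx, K, B,
                          loocv = FALSE, dvec = NULL) {
  LA <- length(testLabIdx); LB <- length(trainLabIdx)
  Z <- matrix(0, LB, K)
  Z[cbind(seq_len(LB), trainLabIdx)] <- 1
  kcnt <- colSums(Z)
  P <- Gte %*% Z                                   # x_i . S_g per bin
  Ptr <- if (loocv) P else Gtr %*% Z
  ZexpTr <- Z[rep(seq_len(LB), times = B), , drop = FALSE]
  Tg <- rowsum(Ptr * ZexpTr, rep(seq_len(B), each = LB))   # ||S_g||^2 per bin
  Texp <- Tg[rep(seq_len(B), each = LA), , drop = FALSE]
  D <- sweep(P, 2, kcnt, "/") * (-2) + sweep(Texp, 2, kcnt^2, "/")
  if (loocv) {
    rows <- seq_len(B * LA)
    ownIdx <- rep(testLabIdx, times = B)
    im <- cbind(rows, ownIdx)
    k0 <- kcnt[ownIdx]
    Pown <- P[im]; Town <- Texp[im]
    D[im] <- -2 * (Pown - dvec) / (k0 - 1) +
      (Town - 2 * Pown + dvec) / (k0 - 1)^2
  }
  predMat <- matrix(max.col(-D, ties.method = "first"), nrow = LA)
  vote <- .majorityVote(predMat, K)
  correct <- !vote$tie & vote$pred == testLabIdx
  list(correct = correct, pred = vote$pred, tie = vote$tie,
       predMat = predMat)
}

#' Label-shuffle null distribution of classifier accuracy
#'
#' Randomizes the assignment of labels to laps `nShuffles` times and
#' recomputes the full LOOCV distance classification (templates rebuilt
#' from the permuted groups) each time, yielding the null distribution of
#' lap-level ROI-majority accuracy.
#'
#' @param traj a [TrajectorySet-class].
#' @param labels see [classifyLaps()].
#' @param roi ROI bin indices (default central stem).
#' @param laps optional lap subset.
#' @param nShuffles number of permutations.
#' @param seed integer seed.
#' @param permute set FALSE to keep the original labels (then every
#'   "shuffle" equals the unshuffled classification; used for
#'   cross-checking against [classifyLaps()]).
#' @param minLaps labels with fewer laps are excluded.
#' @return list with `accuracies`, `mean`, `sd`, `quantiles`, `nLaps`,
#'   `chance`.
#' @export
shuffleControl <- function(traj, labels = "trial_type", roi = NULL,
                           laps = NULL, nShuffles = 1000, seed = 1L,
                           permute = TRUE, minLaps = 2) {
  if (nShuffles < 1) stop("nShuffles must be >= 1")
  lab <- .lapLabels(traj, labels)
  sel <- .usableLaps(lab, minLaps, laps)
  if (is.null(roi)) roi <- traj@roi
  lab <- lab[sel]
  cand <- sort(unique(lab))
  K <- length(cand)
  B <- length(roi); L <- length(sel)
  G <- .stackedGram(traj, roi, sel, sel)
  dvec <- G[cbind(seq_len(B * L), rep(seq_len(L), times = B))]
  labIdx <- match(lab, cand)
  set.seed(seed)
  acc <- numeric(nShuffles)
  for (s in seq_len(nShuffles)) {
    li <- if (permute) sample(labIdx) else labIdx
    res <- .gramClassify(G, NULL, li, li, K, B, loocv = TRUE, dvec = dvec)
    acc[s] <- mean(res$correct)
  }
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
       quantiles = stats::quantile(acc, c(0.005, 0.025, 0.5, 0.975, 0.995)),
       nLaps = L, chance = 1 / K)
}

#' Cross-subtask journey generalization
#'
#' Computes the mean right-to-left and left-to-right journey trajectories
#' in a reference subtask and classifies every lap of the target subtasks
#' by the nearer reference template (ROI majority vote). When the
#' reference equals the target the analysis degenerates to LOOCV journey
#' classification within that subtask. Optional lap-label shuffling
#' permutes the journey labels jointly over reference and target laps and
#' recomputes templates and accuracy.
#'
#' @param traj a [TrajectorySet-class].
#' @param reference reference subtask ("VD", "SA" or "DA").
#' @param targets target subtasks (default: the other two).
#' @param roi ROI bin indices (default central stem).
#' @param cells optional cell-id subset.
#' @param nShuffles if > 0, also compute the shuffle null.
#' @param seed integer seed for the shuffles.
#' @return list with `accuracy`, `lapTable`, `chance`, `nLaps` and (when
#'   shuffled) `shuffle` (accuracies, mean, sd).
#' @export
generalizeJourney <- function(traj, reference, targets = NULL, roi = NULL,
                              cells = NULL, nShuffles = 0, seed = 1L) {
  tb <- traj@laps
  if (is.null(targets))
    targets <- setdiff(unique(tb$subtask), reference)
  if (is.null(roi)) roi <- traj@roi
  if (reference %in% targets || length(targets) == 0)
    return(classifyLaps(traj, labels = "journey", roi = roi,
                        laps = which(tb$subtask == reference &
                                       tb$journey %in% c("RL", "LR"))))
  refIdx <- which(tb$subtask == reference & tb$journey %in% c("RL", "LR"))
  tgtIdx <- which(tb$subtask %in% targets & tb$journey %in% c("RL", "LR"))
  if (!all(c("RL", "LR") %in% tb$journey[refIdx]))
    stop("input error: reference subtask lacks a journey")
  cellSel <- if (is.null(cells)) seq_along(traj@cells)
             else match(cells, traj@cells)
  X <- traj@counts[roi, cellSel, , drop = FALSE]
  B <- length(roi)
  refLab <- tb$journey[refIdx]; tgtLab <- tb$journey[tgtIdx]
  cand <- c("LR", "RL")
  mu <- lapply(cand, function(g)
    rowSums(X[, , refIdx[refLab == g], drop = FALSE], dims = 2) /
      sum(refLab == g))
  predMat <- matrix(0L, length(tgtIdx), B)
  for (q in seq_along(tgtIdx)) {
    Xi <- X[, , tgtIdx[q]]
    D <- vapply(seq_along(cand), function(g) rowSums((Xi - mu[[g]])^2),
                numeric(B))
    predMat[q, ] <- max.col(-D, ties.method = "first")
  }
  vote <- .majorityVote(predMat, length(cand))
  tgtLabIdx <- match(tgtLab, cand)
  correct <- !vote$tie & vote$pred == tgtLabIdx
  out <- list(accuracy = mean(correct),
              lapTable = data.frame(lap = tb$lap[tgtIdx], label = tgtLab,
                                    predicted = ifelse(vote$tie, NA,
                                                       cand[vote$pred]),
                                    correct = correct),
              chance = 1 / length(cand), nLaps = length(tgtIdx))
  if (nShuffles > 0) {
    sub <- new("TrajectorySet", counts = X, arc = traj@arc[roi],
               pitch = traj@pitch, cells = traj@cells[cellSel],
               laps = tb, roi = seq_len(B), sd = traj@sd)
    Gte <- .stackedGram(sub, seq_len(B), tgtIdx, refIdx)
    Gtr <- .stackedGram(sub, seq_len(B), refIdx, refIdx)
    allLab <- c(refLab, tgtLab)
    nRef <- length(refIdx)
    set.seed(seed)
    acc <- numeric(nShuffles)
    for (s in seq_len(nShuffles)) {
      pl <- sample(allLab)
      ri <- match(pl[seq_len(nRef)], cand)
      ti <- match(pl[(nRef + 1):length(pl)], cand)
      res <- .gramClassify(Gte, Gtr, ri, ti, length(cand), B)
      acc[s] <- mean(res$correct)
    }
    out$shuffle <- list(accuracies = acc, mean = mean(acc),
                        sd = stats::sd(acc))
  }
  out
}

#' Generalization accuracy as a function of ensemble size
#'
#' For each roster size, draws random cell subsets and recomputes the
#' cross-subtask journey generalization accuracy, returning the mean and
#' SD over draws. The full roster is a single deterministic evaluation.
#'
#' @param traj a [TrajectorySet-class].
#' @param reference,targets see [generalizeJourney()].
#' @param sizes roster sizes to evaluate.
#' @param nDraws random subsets per size.
#' @param roi ROI bin indices.
#' @param seed integer seed.
#' @return data.frame: `n_cells`, `mean_accuracy`, `sd_accuracy`, `n_draws`.
#' @export
cellCountCurve <- function(traj, reference, targets = NULL,
                           sizes = c(8, 16, 32, 64), nDraws = 1000,
                           roi = NULL, seed = 1L) {
  n <- length(traj@cells)
  if (any(sizes > n))
    stop("input error: roster size exceeds available cells")
  tb <- traj@laps
  if (is.null(targets))
    targets <- setdiff(unique(tb$subtask), reference)
  if (is.null(roi)) roi <- traj@roi
  refIdx <- which(tb$subtask == reference & tb$journey %in% c("RL", "LR"))
  tgtIdx <- which(tb$subtask %in% targets & tb$journey %in% c("RL", "LR"))
  refLab <- tb$journey[refIdx]; tgtLab <- tb$journey[tgtIdx]
  cand <- c("LR", "RL")
  B <- length(roi); Lt <- length(tgtIdx)
  X <- traj@counts[roi, , , drop = FALSE]
  # full-roster templates; any cell subset just selects their columns
  MU <- lapply(cand, function(g)
    rowSums(X[, , refIdx[refLab == g], drop = FALSE], dims = 2) /
      sum(refLab == g))
  # test laps stacked bin-major: row (b-1)*Lt + q
  TX <- matrix(aperm(X[, , tgtIdx, drop = FALSE], c(3, 1, 2)),
               B * Lt, dim(X)[2])
  MUexp <- lapply(MU, function(m) m[rep(seq_len(B), each = Lt), ,
                                    drop = FALSE])
  tgtLabIdx <- match(tgtLab, cand)
  evalSubset <- function(selCells) {
    D1 <- rowSums((TX[, selCells, drop = FALSE] -
                     MUexp[[1]][, selCells, drop = FALSE])^2)
    D2 <- rowSums((TX[, selCells, drop = FALSE] -
                     MUexp[[2]][, selCells, drop = FALSE])^2)
    pred <- ifelse(D1 < D2, 1L, ifelse(D2 < D1, 2L, 1L))
    predMat <- matrix(pred, nrow = Lt)
    vote <- .majorityVote(predMat, 2L)
    mean(!vote$tie & vote$pred == tgtLabIdx)
  }
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    if (sz == n) {
      a <- evalSubset(seq_len(n))
      data.frame(n_cells = sz, mean_accuracy = a, sd_accuracy = 0,
                 n_draws = 1L)
    } else {
      a <- vapply(seq_len(nDraws), function(d)
        evalSubset(sample(n, sz)), numeric(1))
      data.frame(n_cells = sz, mean_accuracy = mean(a),
                 sd_accuracy = stats::sd(a), n_draws = nDraws)
    }
  })
  do.call(rbind, rows)
}

# TX row (b-1)*Lt + q corresponds to predMat[q, b]: aperm gives lap-major
# within bin blocks, matching .majorityVote's matrix(pred, nrow = Lt)

#' Binary classification suite: journeys, task-demands, trial types
#'
#' Lap-level ROI-majority accuracies of three binary LOOCV classification
#' categories: a pair of journeys irrespective of subtask (laps of VD1,
#' SA1, DA1 vs laps of VD3, SA2, DA2), each pair of task-demands
#' irrespective of journey (VD vs SA, VD vs DA, SA vs DA) and every pair
#' of the eight trial types.
#'
#' @param traj a [TrajectorySet-class].
#' @param roi ROI bin indices (default central stem).
#' @param minLaps minimum laps per class.
#' @return list with `summary` (category, mean accuracy, n comparisons)
#'   and `details` (per-comparison accuracies).
#' @export
binarySuite <- function(traj, roi = NULL, minLaps = 2) {
  tb <- traj@laps
  if (is.null(roi)) roi <- traj@roi
  present <- unique(tb$trial_type)
  acc1 <- NA_real_
  grpA <- c("VD1", "SA1", "DA1"); grpB <- c("VD3", "SA2", "DA2")
  if (all(c(grpA, grpB) %in% present)) {
    sel <- which(tb$trial_type %in% c(grpA, grpB))
    lab <- ifelse(tb$trial_type[sel] %in% grpA, "journeyRL", "journeyLR")
    acc1 <- classifyLaps(traj, labels = replace(rep(NA_character_,
                                                    nrow(tb)), sel, lab),
                         roi = roi, minLaps = minLaps)$accuracy
  } else warning("journeys category skipped: missing trial type")
  demandPairs <- list(c("VD", "SA"), c("VD", "DA"), c("SA", "DA"))
  dAcc <- vapply(demandPairs, function(pr) {
    sel <- which(tb$subtask %in% pr)
    if (length(unique(tb$subtask[sel])) < 2) return(NA_real_)
    classifyLaps(traj, labels = "subtask", roi = roi, laps = sel,
                 minLaps = minLaps)$accuracy
  }, numeric(1))
  ttp <- utils::combn(sort(present), 2)
  tAcc <- vapply(seq_len(ncol(ttp)), function(q) {
    sel <- which(tb$trial_type %in% ttp[, q])
    tryCatch(classifyLaps(traj, labels = "trial_type", roi = roi,
                          laps = sel, minLaps = minLaps)$accuracy,
             error = function(e) NA_real_)
  }, numeric(1))
  details <- list(
    journeys = data.frame(pair = "VD1+SA1+DA1 vs VD3+SA2+DA2",
                          accuracy = acc1),
    demands = data.frame(pair = vapply(demandPairs, paste, collapse = " vs ",
                                       FUN.VALUE = character(1)),
                         accuracy = dAcc),
    trialTypePairs = data.frame(pair = apply(ttp, 2, paste,
                                             collapse = " vs "),
                                accuracy = tAcc))
  list(summary = data.frame(
         category = c("journeys", "task_demands", "trial_types"),
         accuracy = c(acc1, mean(dAcc, na.rm = TRUE),
                      mean(tAcc, na.rm = TRUE)),
         n = c(1L, sum(!is.na(dAcc)), sum(!is.na(tAcc)))),
       details = details)
}

#' PCA projection of ensemble trajectories
#'
#' Fits principal components on the pooled location-bin states of all laps
#' and projects each lap's trajectory onto the leading components; a
#' visualization aid only, never used for classification.
#'
#' @param traj a [TrajectorySet-class].
#' @param nComponents number of components (default 3).
#' @param roi bin indices to project (default: all bins).
#' @return list with `scores` (array bins x laps x components),
#'   `explained` (fraction of variance per component), `rotation`, `arc`.
#' @export
pcaProject <- function(traj, nComponents = 3, roi = NULL) {
  if (length(traj@cells) < nComponents)
    stop("input error: fewer cells than requested components")
  if (is.null(roi)) roi <- seq_along(traj@arc)
  X <- traj@counts[roi, , , drop = FALSE]
  d <- dim(X)
  flat <- matrix(aperm(X, c(1, 3, 2)), d[1] * d[3], d[2])
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  nz <- sum(pc$sdev > 1e-10)
  if (nz < nComponents) {
    warning("degenerate covariance: returning ", nz, " components")
    nComponents <- nz
  }
  scores <- array(pc$x[, seq_len(nComponents), drop = FALSE],
                  dim = c(d[1], d[3], nComponents))
  list(scores = scores,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)],
       rotation = pc$rotation[, seq_len(nComponents), drop = FALSE],
       arc = traj@arc[roi])
}
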