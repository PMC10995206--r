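# Two-step linear-assignment tracking: frame-to-frame linking into segments,
# segment joining with gap closing and a linking-angle gate, and a minimum
# persistence filter.

# Solve a gated min-cost one-to-one assignment between two point sets.
# Returns an integer vector: for each row of A, the matched index in B or NA.
# Pairs with cost > gate are forbidden; leaving a point unmatched costs
# `gate` on each side, so every feasible pair that lowers the total cost is
# matched (maximum matching with minimum summed distance).
gatedAssign <- function(cost, gate) {
  nA <- nrow(cost); nB <- ncol(cost)
  if (nA == 0) return(integer(0))
  if (nB == 0) return(rep(NA_integer_, nA))
  big <- 1e30
  C <- matrix(big, nA + nB, nA + nB)
  cc <- cost
  cc[cc > gate] <- big
  C[seq_len(nA), seq_len(nB)] <- cc
  C[cbind(seq_len(nA), nB + seq_len(nA))] <- gate   # A_i unmatched
  C[cbind(nA + seq_len(nB), seq_len(nB))] <- gate   # B_j unmatched
  C[nA + seq_len(nB), nB + seq_len(nA)] <- 0
  sol <- cpp_lap(C) + 1L  # 0-based -> 1-based columns
  match <- sol[seq_len(nA)]
  match[match > nB] <- NA_integer_
  match
}

#' Frame-to-frame localization linking
#'
#' Optimal one-to-one assignment between the localizations of two
#' consecutive frames, minimizing summed Euclidean distance among pairs
#' within `maxDist`; unmatched localizations start or terminate segments.
#'
#' @param locsA,locsB data.frames with `row`, `col` columns.
#' @param maxDist gating distance (same units as the coordinates), > 0.
#' @return integer vector of length `nrow(locsA)`: matched row index in
#'   `locsB`, or NA.
#' @export
linkFrames <- function(locsA, locsB, maxDist) {
  stopIfNot(maxDist > 0, "maxDist must be positive")
  if (nrow(locsA) == 0) return(integer(0))
  if (nrow(locsB) == 0) return(rep(NA_integer_, nrow(locsA)))
  cost <- sqrt(outer(locsA$row, locsB$row, "-")^2 +
               outer(locsA$col, locsB$col, "-")^2)
  gatedAssign(cost, maxDist)
}

# build initial segments from per-frame localizations (list indexed by frame)
buildSegments <- function(locs, maxDist) {
  frames <- sort(unique(locs$frame))
  segs <- list()          # each: data.frame frame,row,col,brightness...
  active <- list()        # open segments, index into segs
  prevDet <- NULL
  prevSegIdx <- integer(0)
  for (f in frames) {
    cur <- locs[locs$frame == f, , drop = FALSE]
    rownames(cur) <- NULL
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prevDet) && nrow(prevDet) > 0 && nrow(cur) > 0 &&
        f == prevDet$frame[1] + 1) {
      m <- linkFrames(prevDet, cur, maxDist)
      for (i in seq_along(m)) {
        if (!is.na(m[i])) {
          si <- prevSegIdx[i]
          segs[[si]] <- rbind(segs[[si]], cur[m[i], , drop = FALSE])
          assigned[m[i]] <- si
        }
      }
    }
    for (j in seq_len(nrow(cur))) {
      if (is.na(assigned[j])) {
        segs[[length(segs) + 1L]] <- cur[j, , drop = FALSE]
        assigned[j] <- length(segs)
      }
    }
    prevDet <- cur
    prevSegIdx <- assigned
  }
  segs
}

segmentVelocity <- function(seg) {
  n <- nrow(seg)
  k <- min(3L, n - 1L)
  if (k < 1) return(c(0, 0))
  c(seg$row[n] - seg$row[n - k], seg$col[n] - seg$col[n - k]) / k
}

#' Join track segments across gaps
#'
#' Candidate joins connect the end of one segment to the start of another
#' with frame gap in `[1, maxGap]` and distance at most `maxDist * gap`; the
#' angle between the first segment's terminal velocity and the joining
#' displacement must not exceed `maxAngle` degrees (links requiring sharper
#' turns are unreliable and rejected). Joins are chosen by linear assignment
#' on distance, at most one join per segment end and per segment start.
#'
#' @param segments list of segment data.frames (columns `frame`, `row`,
#'   `col`, ...), each time-ordered.
#' @param maxDist per-frame gating distance.
#' @param maxGap maximum frame gap (default 2).
#' @param maxAngle maximum linking angle in degrees (default 45).
#' @return list of track data.frames (concatenated segments).
#' @export
linkSegments <- function(segments, maxDist, maxGap = 2L, maxAngle = 45) {
  n <- length(segments)
  if (n <= 1) return(segments)
  ends <- t(vapply(segments, function(s)
    c(s$frame[nrow(s)], s$row[nrow(s)], s$col[nrow(s)]), numeric(3)))
  starts <- t(vapply(segments, function(s)
    c(s$frame[1], s$row[1], s$col[1]), numeric(3)))
  vel <- lapply(segments, segmentVelocity)
  big <- 1e30
  cost <- matrix(big, n, n)
  cosGate <- cos(maxAngle * pi / 180)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      gap <- starts[b, 1] - ends[a, 1]
      if (gap < 1 || gap > maxGap) next
      dvec <- c(starts[b, 2] - ends[a, 2], starts[b, 3] - ends[a, 3])
      d <- sqrt(sum(dvec^2))
      if (d > maxDist * gap) next
      v <- vel[[a]]
      nv <- sqrt(sum(v^2)); nd <- d
      if (nv > 1e-12 && nd > 1e-12) {
        cosang <- sum(v * dvec) / (nv * nd)
        if (cosang < cosGate - 1e-12) next
      }
      cost[a, b] <- d
    }
  }
  if (!any(cost < big)) return(segments)
  joinTo <- gatedAssign(cost, gate = maxDist * maxGap)
  # forbid joins that the gate padding may have allowed through cost==big
  joinTo[!is.na(joinTo) &
         cost[cbind(seq_len(n), ifelse(is.na(joinTo), 1L, joinTo))] >= big] <- NA
  # chain-merge: follow joins from segments that are not a join target
  isTarget <- rep(FALSE, n)
  isTarget[stats::na.omit(joinTo)] <- TRUE
  tracks <- list()
  for (a in seq_len(n)) {
    if (isTarget[a]) next
    cur <- segments[[a]]
    nxt <- joinTo[a]
    while (!is.na(nxt)) {
      cur <- rbind(cur, segments[[nxt]])
      nxt <- joinTo[nxt]
    }
    tracks[[length(tracks) + 1L]] <- cur
  }
  tracks
}

#' Minimum-persistence track filter
#'
#' Removes tracks spanning fewer than `minPersistence` frames (span =
#' last frame - first frame + 1, so closed gaps count toward persistence).
#'
#' @param tracks list of track data.frames.
#' @param minPersistence minimum span in frames (default 10).
#' @return filtered list.
#' @export
filterTracks <- function(tracks, minPersistence = 10L) {
  keep <- vapply(tracks, function(tr)
    tr$frame[nrow(tr)] - tr$frame[1] + 1 >= minPersistence, logical(1))
  tracks[keep]
}

#' Track localizations across a sequence
#'
#' Full two-step tracking: frame-to-frame linking into segments, gap-closing
#' segment joins with the angle gate, and the minimum-persistence filter.
#' The default gating distance is 1.5 times the displacement of the fastest
#' expected bubble (25 mm/s) per frame, expressed in the coordinate grid's
#' pixels.
#'
#' @param locs data.frame with `frame` (integer), `row`, `col` columns
#'   (fine-grid coordinates unless `pixelUm` says otherwise).
#' @param cfg an [ImagingConfig-class] (frame rate and pixel size for the
#'   default gate and derived speeds).
#' @param maxDist gating distance in pixels (default from `cfg`).
#' @param maxGap maximum closed gap in frames.
#' @param maxAngle linking-angle gate in degrees.
#' @param minPersistence minimum track span in frames.
#' @param pixelUm pixel pitch of the localization coordinates (defaults to
#'   the fine pixel).
#' @return data.frame `track`, `frame`, `row`, `col` (+ carried columns),
#'   one row per track point.
#' @export
trackLocalizations <- function(locs, cfg, maxDist = NULL, maxGap = 2L,
                               maxAngle = 45, minPersistence = 10L,
                               pixelUm = NULL) {
  if (is.null(pixelUm)) pixelUm <- cfg@finePixelUm
  if (is.null(maxDist))
    maxDist <- 1.5 * SPEED_RANGE_MM_S[2] * 1000 / cfg@frameRate / pixelUm
  if (nrow(locs) == 0)
    return(cbind(track = integer(0), locs))
  segs <- buildSegments(locs, maxDist)
  tracks <- linkSegments(segs, maxDist, maxGap, maxAngle)
  tracks <- filterTracks(tracks, minPersistence)
  if (length(tracks) == 0)
    return(cbind(track = integer(0), locs[0, , drop = FALSE]))
  out <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(track = i, tracks[[i]])))
  rownames(out) <- NULL
  out
}

#' Per-track summary statistics
#'
#' Mean speed (mm/s, from mean step length) and axial direction sign
#' (+1 for net motion toward the transducer, i.e. decreasing row).
#'
#' @param tracks track data.frame from [trackLocalizations()].
#' @param cfg an [ImagingConfig-class].
#' @param pixelUm pixel pitch of the coordinates (default fine pixel).
#' @return data.frame `track`, `nPoints`, `meanSpeed`, `directionSign`.
#' @export
trackSummary <- function(tracks, cfg, pixelUm = NULL) {
  if (is.null(pixelUm)) pixelUm <- cfg@finePixelUm
  ids <- unique(tracks$track)
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track == id, , drop = FALSE]
    n <- nrow(tr)
    if (n < 2)
      return(data.frame(track = id, nPoints = n, meanSpeed = NA_real_,
                        directionSign = 0))
    dr <- diff(tr$row); dc <- diff(tr$col); df <- diff(tr$frame)
    stepUm <- sqrt(dr^2 + dc^2) * pixelUm
    speed <- mean(stepUm / df) * cfg@frameRate / 1000  # mm/s
    data.frame(track = id, nPoints = n, meanSpeed = speed,
               directionSign = ifelse(sum(dr) < 0, 1, -1))
  }))
}
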