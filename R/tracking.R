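## Frame-to-frame detection linking and track velocity for time-lapse
## migration assays (e.g. nuclear-stain imaging every 30 min for 20 h).

#' Link per-frame detections into tracks
#'
#' Mutual-nearest-neighbor linking: a detection joins an active track only
#' if each is the other's nearest candidate and the distance is at most
#' \code{maxDisplacement} per elapsed frame (a track bridging a gap of g
#' missing frames may move up to \code{maxDisplacement * (g + 1)}).
#' Unmatched tracks stay active for up to \code{maxGap} missing frames;
#' unmatched detections start new tracks.  Ties are broken by the lowest
#' detection index, so linking is deterministic for sorted input.
#'
#' @param detections data.frame with columns \code{frame}, \code{t},
#'   \code{x}, \code{y}, sorted by frame.
#' @param maxDisplacement maximum per-frame displacement in um.
#' @param maxGap maximum number of missing frames bridged (default 0).
#' @return the detections data.frame with a \code{track_id} column.
#' @export
linkDetections <- function(detections, maxDisplacement, maxGap = 0L) {
  need <- c("frame", "t", "x", "y")
  if (!all(need %in% names(detections)))
    stop("detections must have columns frame, t, x, y")
  det <- detections[order(detections$frame), , drop = FALSE]
  if (anyDuplicated(det[, c("frame", "x", "y")]))
    stop("duplicate (frame, position) detections")
  det$track_id <- NA_integer_
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  ## active tracks: id, last x/y, last frame
  act <- data.frame(id = integer(), x = numeric(), y = numeric(),
                    frame = numeric())
  next_id <- 1L
  assign_col <- integer(nrow(det))
  for (f in frames) {
    rows <- which(det$frame == f)
    act <- act[f - act$frame <= maxGap + 1L, , drop = FALSE]
    linked_det <- rep(FALSE, length(rows))
    linked_trk <- rep(FALSE, nrow(act))
    if (nrow(act) && length(rows)) {
      dx <- outer(act$x, det$x[rows], "-")
      dy <- outer(act$y, det$y[rows], "-")
      D <- sqrt(dx^2 + dy^2)
      allowed <- D <= maxDisplacement * (f - act$frame)
      D[!allowed] <- Inf
      repeat {
        if (!any(is.finite(D))) break
        ## mutual nearest neighbors among unlinked pairs
        found <- FALSE
        for (ti in seq_len(nrow(act))) {
          if (linked_trk[ti]) next
          j <- which.min(D[ti, ])            # lowest index wins ties
          if (!is.finite(D[ti, j])) next
          if (which.min(D[, j]) == ti) {
            assign_col[det$.row[rows[j]]] <- act$id[ti]
            act$x[ti] <- det$x[rows[j]]; act$y[ti] <- det$y[rows[j]]
            act$frame[ti] <- f
            linked_trk[ti] <- TRUE; linked_det[j] <- TRUE
            D[ti, ] <- Inf; D[, j] <- Inf
            found <- TRUE
          }
        }
        if (!found) break
      }
    }
    for (j in which(!linked_det)) {
      assign_col[det$.row[rows[j]]] <- next_id
      act <- rbind(act, data.frame(id = next_id, x = det$x[rows[j]],
                                   y = det$y[rows[j]], frame = f))
      next_id <- next_id + 1L
    }
  }
  det$track_id <- assign_col[det$.row]
  det$.row <- NULL
  det
}

#' Track statistics: path length, duration and mean speed
#'
#' Mean speed is the mean instantaneous path speed — total path length
#' (sum of consecutive Euclidean steps) divided by elapsed time — matching
#' the "track velocity" convention of standard trackers.  Net-displacement
#' speed (straight-line distance / time) is available via
#' \code{netSpeed = TRUE}.
#'
#' @param track data.frame with \code{t}, \code{x}, \code{y} rows of one
#'   track, ordered by time.
#' @param minFrames minimum detections required (default 5; transient cells
#'   are excluded).
#' @param netSpeed also report net-displacement speed.
#' @return one-row data.frame: \code{n_frames}, \code{duration_h},
#'   \code{path_length_um}, \code{mean_speed_um_h} (and
#'   \code{net_speed_um_h} if requested).
#' @export
trackSpeed <- function(track, minFrames = 5L, netSpeed = FALSE) {
  if (nrow(track) < minFrames)
    stop(sprintf("track has %d detections; at least %d required",
                 nrow(track), minFrames))
  track <- track[order(track$t), , drop = FALSE]
  dur <- track$t[nrow(track)] - track$t[1L]
  if (dur <= 0) stop("track duration must be positive")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  out <- data.frame(n_frames = nrow(track), duration_h = dur,
                    path_length_um = sum(steps),
                    mean_speed_um_h = sum(steps) / dur)
  if (netSpeed) {
    net <- sqrt((track$x[nrow(track)] - track$x[1L])^2 +
                (track$y[nrow(track)] - track$y[1L])^2)
    out$net_speed_um_h <- net / dur
  }
  out
}

#' Per-track speeds for a linked detection table
#'
#' @param tracked data.frame from [linkDetections()] (or any table with a
#'   \code{track_id} column); tracks shorter than \code{minFrames} are
#'   dropped.
#' @inheritParams trackSpeed
#' @return data.frame with one row per retained track, including
#'   \code{track_id}.
#' @export
trackSpeeds <- function(tracked, minFrames = 5L, netSpeed = FALSE) {
  ids <- unique(tracked$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracked[tracked$track_id == id, , drop = FALSE]
    if (nrow(tr) < minFrames) return(NULL)
    cbind(track_id = id, trackSpeed(tr, minFrames, netSpeed))
  })
  do.call(rbind, out)
}

#' Per-animal mean track speed and group comparison
#'
#' Averages track speeds within each animal (each animal contributes one
#' value — "each dot is one animal") and compares the two groups' animal
#' means with a two-tailed Mann-Whitney test.
#'
#' @param stats data.frame with \code{mean_speed_um_h} and \code{track_id}.
#' @param mapping data.frame with \code{track_id}, \code{animal},
#'   \code{group}.
#' @return list with \code{animal_means} and \code{test}
#'   (a Mann-Whitney result, NULL if fewer than two groups).
#' @export
summarizeByAnimal <- function(stats, mapping) {
  m <- merge(stats, mapping, by = "track_id")
  if (nrow(m) < nrow(stats))
    stop("every track must be mapped to an animal")
  counts <- table(mapping$animal[mapping$animal %in% m$animal])
  empty <- setdiff(unique(mapping$animal), m$animal)
  if (length(empty))
    warning(sprintf("animal(s) with no tracks excluded: %s",
                    paste(empty, collapse = ", ")))
  am <- aggregate(mean_speed_um_h ~ group + animal, data = m, FUN = mean)
  gs <- unique(am$group)
  test <- if (length(gs) == 2L)
    mannWhitneyTwoTailed(am$mean_speed_um_h[am$group == gs[1L]],
                         am$mean_speed_um_h[am$group == gs[2L]]) else NULL
  list(animal_means = am, test = test)
}
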