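#' Link localizations into tracks
#'
#' For every pair of consecutive frames, the localizations of the later
#' frame are matched one-to-one against the open track ends of the
#' earlier frame by a globally optimal (minimum total distance)
#' assignment, considering only pairs within `max_link_distance`
#' (default 320 nm, two pixels). Unmatched localizations start new
#' tracks; unmatched track ends terminate. There is no gap closing: a
#' particle that disappears for one frame starts a new track when it
#' reappears.
#'
#' Track ids are assigned in order of first appearance (frame, then
#' position order within the frame), which makes the output
#' deterministic for a given input ordering.
#'
#' @param localizations data.frame with at least `frame`, `x_nm`,
#'   `y_nm`; any further columns are carried through.
#' @param max_link_distance Gate distance in nm.
#' @return data.frame: the input rows (reordered by `(track_id, frame)`)
#'   with a `track_id` column prepended.
#' @export
link_localizations <- function(localizations, max_link_distance = 320) {
  stopifnot(is.data.frame(localizations),
            all(c("frame", "x_nm", "y_nm") %in% names(localizations)),
            max_link_distance > 0)
  n <- nrow(localizations)
  if (n == 0) return(cbind(track_id = integer(0), localizations))
  loc <- localizations[order(localizations$frame), , drop = FALSE]
  frames <- sort(unique(loc$frame))
  idx_by_frame <- split(seq_len(n), loc$frame)

  track_id <- integer(n)
  next_id <- 1L
  first <- idx_by_frame[[1]]
  track_id[first] <- seq_len(length(first))
  next_id <- length(first) + 1L
  open <- first # row indices of current track ends

  for (k in seq_along(frames)[-1]) {
    cur <- idx_by_frame[[k]]
    if (frames[k] != frames[k - 1] + 1 || length(open) == 0) {
      # non-consecutive frame: every localization starts a new track
      track_id[cur] <- next_id + seq_along(cur) - 1L
      next_id <- next_id + length(cur)
      open <- cur
      next
    }
    d <- sqrt(outer(loc$x_nm[open], loc$x_nm[cur], "-")^2 +
              outer(loc$y_nm[open], loc$y_nm[cur], "-")^2)
    m <- gated_assignment(d, max_link_distance)
    linked_cur <- integer(0)
    if (nrow(m)) {
      track_id[cur[m[, 2]]] <- track_id[open[m[, 1]]]
      linked_cur <- m[, 2]
    }
    new <- setdiff(seq_along(cur), linked_cur)
    if (length(new)) {
      track_id[cur[new]] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    open <- cur
  }

  out <- cbind(track_id = track_id, loc)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Minimum-cost one-to-one matching of a gated distance matrix.
# Disallowed pairs (d > gate) get a large constant cost, and the matrix
# is padded square, so the solver first maximizes the number of gated
# links and then minimizes their total distance. Returns a 2-column
# matrix of (row, col) indices of accepted links.
gated_assignment <- function(d, gate) {
  big <- 1e9
  nr <- nrow(d); nc <- ncol(d)
  k <- max(nr, nc)
  cost <- matrix(big, k, k)
  cost[seq_len(nr), seq_len(nc)] <- ifelse(d <= gate, d, big)
  sol <- clue::solve_LSAP(cost)
  rows <- seq_len(nr)
  cols <- as.integer(sol)[rows]
  ok <- cols <= nc & cost[cbind(rows, cols)] < big
  cbind(rows[ok], cols[ok])
}

#' Retain tracks inside a length window
#'
#' Keeps tracks whose frame count lies in `[min_frames, max_frames]`
#' (both inclusive; default 4-12 frames, i.e. 0.4-1.2 s at 10 Hz).
#' Longer tracks are rejected whole, never truncated. The counts of
#' rejected tracks are attached as attribute `rejected`
#' (`too_short`, `too_long`).
#'
#' @param tracks data.frame with `track_id` (output of
#'   [link_localizations()]).
#' @param min_frames,max_frames Inclusive bounds on track length in
#'   frames.
#' @return Filtered data.frame with attribute `rejected`.
#' @export
filter_track_lengths <- function(tracks, min_frames = 4, max_frames = 12) {
  stopifnot(is.data.frame(tracks))
  if (nrow(tracks) == 0) {
    out <- tracks
    attr(out, "rejected") <- c(too_short = 0L, too_long = 0L)
    return(out)
  }
  len <- table(tracks$track_id)
  keep_ids <- names(len)[len >= min_frames & len <= max_frames]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(too_short = sum(len < min_frames),
                             too_long = sum(len > max_frames))
  out
}

#' Track durations in seconds
#'
#' By the retention-window convention, an n-frame track is reported as
#' lasting `n * frame_interval` seconds, so the 4-12-frame window at
#' 10 Hz reads 0.4-1.2 s.
#'
#' @param tracks data.frame with `track_id`.
#' @param frame_interval Frame interval in seconds.
#' @return Named numeric vector of durations, one per track.
#' @export
track_durations <- function(tracks, frame_interval = 0.1) {
  len <- table(tracks$track_id)
  stats::setNames(as.numeric(len) * frame_interval, names(len))
}
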