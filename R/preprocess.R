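# Extraction of fixed-length swimming segments from raw trajectories.
# A fish is "swimming" when its (smoothed) speed exceeds u_min; brief dips
# below threshold shorter than tau_s are treated as part of the same bout;
# surviving bouts are cut into equal windows of tau_l seconds.

#' Segmentation configuration
#'
#' @param u_min speed threshold in body lengths per second; default 1 BL/s.
#' @param body_length body length in cm; default 3 cm (adult zebrafish).
#' @param tau_s gap-joining threshold in seconds: a dip below threshold
#'   strictly shorter than `tau_s` does not split a bout. Default 2 s.
#' @param tau_l segment length in seconds; default 60 s.
#' @param smooth_window moving-average window (odd number of samples) used
#'   only for thresholding; default 3.
#' @return A list of class `"fw_seg_config"`.
#' @export
seg_config <- function(u_min = 1, body_length = 3, tau_s = 2, tau_l = 60,
                       smooth_window = 3L) {
  stopifnot(u_min > 0, body_length > 0, tau_s >= 0, tau_l > 0,
            smooth_window >= 1)
  if (smooth_window %% 2 == 0) stop("smooth_window must be odd")
  structure(list(u_min = u_min, body_length = body_length, tau_s = tau_s,
                 tau_l = tau_l, smooth_window = as.integer(smooth_window)),
            class = "fw_seg_config")
}

#' Centred moving average of a speed series
#'
#' Used only to decide which samples count as swimming; downstream analysis
#' always uses the original unsmoothed data. Edges use shrunken (one-sided)
#' windows so the output has the same length as the input.
#'
#' @param u numeric speed series.
#' @param window odd window length in samples.
#' @return Smoothed series, same length as `u`.
#' @export
smooth_speed <- function(u, window = 3L) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(u)
  if (window > n) stop("window longer than series")
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, u))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract fixed-length swimming segments
#'
#' Applies the three segmentation rules in order: (1) find contiguous runs
#' where the smoothed speed is strictly above the threshold; (2) join runs
#' separated by a below-threshold gap strictly shorter than `tau_s` (a gap
#' of exactly `tau_s` splits); (3) cut each joined run, anchored at its
#' start, into consecutive non-overlapping windows of exactly `tau_l`
#' seconds, discarding the remainder. Returned segments carry the original
#' unsmoothed samples.
#'
#' @param traj an `fw_trajectory`.
#' @param cfg an `fw_seg_config`.
#' @return A list of `fw_trajectory` slices, each with attributes
#'   `source_id`, `start_index` (1-based offset into the parent) and
#'   `label` (`"S1"`, `"S2"`, ... in temporal order). May be empty.
#' @export
segment_swimming <- function(traj, cfg = seg_config()) {
  stopifnot(inherits(traj, "fw_trajectory"), inherits(cfg, "fw_seg_config"))
  dt <- attr(traj, "dt")
  u <- compute_speed(traj)
  us <- smooth_speed(u, cfg$smooth_window)
  thr <- cfg$u_min * cfg$body_length       # BL/s -> cm/s
  above <- us > thr

  runs <- run_bounds(above)
  if (nrow(runs) == 0L) return(list())

  # join runs across gaps strictly shorter than tau_s
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2L:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt
      if (gap < cfg$tau_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }

  len <- round(cfg$tau_l / dt)             # samples per segment
  segs <- list()
  for (i in seq_len(nrow(merged))) {
    s <- merged$start[i]
    n_run <- merged$end[i] - s + 1L
    k <- n_run %/% len
    for (j in seq_len(k)) {
      i0 <- s + (j - 1L) * len
      idx <- i0:(i0 + len - 1L)
      seg <- trajectory(traj$t[idx], traj$x[idx], traj$y[idx],
                        traj$vx[idx], traj$vy[idx],
                        subject_id = attr(traj, "subject_id"))
      attr(seg, "source_id") <- attr(traj, "subject_id")
      attr(seg, "start_index") <- i0
      segs[[length(segs) + 1L]] <- seg
    }
  }
  for (k in seq_along(segs)) attr(segs[[k]], "label") <- paste0("S", k)
  segs
}

# start/end indices of runs of TRUE
run_bounds <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
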