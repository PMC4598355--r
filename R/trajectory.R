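#' Construct a planar trajectory
#'
#' A trajectory is a uniformly sampled planar position/velocity time series,
#' the common currency of the package: tracked fish data comes in as a
#' trajectory, and the random-walker simulator produces one.
#'
#' @param t numeric vector of times (s), strictly increasing with uniform
#'   step.
#' @param x,y numeric vectors of positions (cm).
#' @param vx,vy numeric vectors of velocities (cm/s). If omitted, velocities
#'   are reconstructed by the backwards difference
#'   `v[k] = (x[k] - x[k-1]) / dt`, with the first sample copied from the
#'   second (the backwards difference is undefined there).
#' @param subject_id character label for the tracked subject.
#'
#' @return A `data.frame` of class `"fw_trajectory"` with columns
#'   `t, x, y, vx, vy` and attributes `dt` (sampling step, s) and
#'   `subject_id`.
#'
#' @details All samples must be finite and the sampling step uniform to a
#'   relative tolerance of 1e-9; violations are errors that name the
#'   offending rows, since silent resampling would corrupt every kinematic
#'   quantity derived downstream.
#'
#' @examples
#' tr <- trajectory(t = seq(0, 1, by = 0.2), x = seq(0, 5, by = 1),
#'                  y = rep(0, 6))
#' attr(tr, "dt")
#' @export
trajectory <- function(t, x, y, vx = NULL, vy = NULL, subject_id = "subject") {
  n <- length(t)
  if (n < 2L) stop("trajectory needs at least 2 samples")
  if (length(x) != n || length(y) != n)
    stop("t, x, y must have equal length")

  bad <- which(!is.finite(t) | !is.finite(x) | !is.finite(y) |
                 (if (is.null(vx)) FALSE else !is.finite(vx)) |
                 (if (is.null(vy)) FALSE else !is.finite(vy)))
  if (length(bad))
    stop("non-finite samples at rows: ", paste(utils::head(bad, 10L), collapse = ", "))

  steps <- diff(t)
  dt <- stats::median(steps)
  if (dt <= 0) stop("time must be strictly increasing")
  off <- which(abs(steps - dt) > 1e-9 * max(abs(dt), 1))
  if (length(off))
    stop("non-uniform sampling at indices: ",
         paste(utils::head(off, 10L), collapse = ", "))

  if (is.null(vx) != is.null(vy))
    stop("provide both vx and vy or neither")
  if (is.null(vx)) {
    vx <- c(NA_real_, diff(x)) / dt
    vy <- c(NA_real_, diff(y)) / dt
    vx[1L] <- vx[2L]
    vy[1L] <- vy[2L]
  }
  if (length(vx) != n || length(vy) != n)
    stop("velocity columns must match positions in length")

  out <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    vx = as.numeric(vx), vy = as.numeric(vy))
  structure(out,
            dt = dt,
            subject_id = as.character(subject_id),
            class = c("fw_trajectory", "data.frame"))
}

#' @export
print.fw_trajectory <- function(x, ...) {
  cat(sprintf("<fw_trajectory> %s: %d samples, dt = %g s, duration = %g s\n",
              attr(x, "subject_id"), nrow(x), attr(x, "dt"),
              nrow(x) * attr(x, "dt")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a trajectory from a CSV file
#'
#' Reads the comma-separated dialect used for tracked-fish data: an optional
#' leading comment line starting with `#` (units), a header row, then either
#' `t,x,y,vx,vy` columns or `frame,x,y` columns. When a `frame` column is
#' present the sampling rate `fs` converts frame numbers to seconds; when
#' velocity columns are absent they are reconstructed by backwards
#' difference (see [trajectory()]).
#'
#' @param path path to a CSV file.
#' @param fs sampling rate in Hz, required when the file stores frame
#'   numbers rather than times. Default 5 Hz, the acquisition rate of the
#'   tracking setup this dialect emulates.
#' @param subject_id label; defaults to the file name without extension.
#' @return An `fw_trajectory`.
#' @seealso [write_trajectory()]
#' @export
read_trajectory <- function(path, fs = 5, subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  names(df) <- tolower(names(df))
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))

  if ("t" %in% names(df)) {
    t <- df$t
  } else if ("frame" %in% names(df)) {
    if (is.null(fs) || fs <= 0) stop("frame column requires a positive fs")
    t <- df$frame / fs
  } else stop("no time or frame column in ", path)

  if (!all(c("x", "y") %in% names(df)))
    stop("columns x and y are required in ", path)

  nan_rows <- which(!stats::complete.cases(df))
  if (length(nan_rows))
    stop("NaN/missing values at rows: ",
         paste(utils::head(nan_rows, 10L), collapse = ", "))

  has_v <- all(c("vx", "vy") %in% names(df))
  trajectory(t, df$x, df$y,
             vx = if (has_v) df$vx else NULL,
             vy = if (has_v) df$vy else NULL,
             subject_id = subject_id)
}

#' Write a trajectory to CSV
#'
#' Emits the same dialect [read_trajectory()] consumes, so a write/read
#' round trip reproduces every field.
#'
#' @param traj an `fw_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fw_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: t s, x y cm, vx vy cm/s", con)
  # 17 significant digits so doubles survive the text round trip exactly
  fmt <- vapply(as.data.frame(traj), function(col) sprintf("%.17g", col),
                character(nrow(traj)))
  writeLines(c(paste(names(traj), collapse = ","),
               apply(matrix(fmt, nrow = nrow(traj)), 1L,
                     paste, collapse = ",")), con)
  invisible(path)
}
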