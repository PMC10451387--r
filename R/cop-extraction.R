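#' Pressure-grid geometry
#'
#' Geometry of a grid pressure mat. The default matches a 68 x 48 cell
#' flexible mat sampled at 23 Hz. The nominal sensor cell is
#' 21 mm x 36 mm; the default centre-to-centre pitch (22.5 mm x 37.9 mm)
#' is chosen so that the full grid spans the mat's stated outer size of
#' 1530 mm x 1820 mm, and is configurable because cell pitch and cell
#' size need not coincide.
#'
#' Axis mapping: grid columns run along the package's x (anterior-
#' posterior) axis and rows along y (medio-lateral); the origin is the
#' grid centre.
#'
#' @param n_cols,n_rows Number of cell columns / rows.
#' @param pitch_x,pitch_y Cell pitch in mm along columns / rows.
#' @param fs Frame rate in Hz.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_cols = 68, n_rows = 48,
                          pitch_x = 22.5, pitch_y = 37.9, fs = 23) {
  stopifnot(n_cols >= 1, n_rows >= 1, pitch_x > 0, pitch_y > 0, fs > 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 pitch_x = pitch_x, pitch_y = pitch_y, fs = fs),
            class = "grid_geometry")
}

# Cell-centre coordinates in cm, origin at the grid centre.
grid_cell_centers <- function(geom) {
  list(x = (seq_len(geom$n_cols) - (geom$n_cols + 1) / 2) * geom$pitch_x / 10,
       y = (seq_len(geom$n_rows) - (geom$n_rows + 1) / 2) * geom$pitch_y / 10)
}

#' Pressure-frame series
#'
#' A sequence of pressure-grid frames. Frames are supplied either as a
#' 3-d array with dimensions `(n_frames, n_rows, n_cols)` or as a list of
#' `n_rows x n_cols` matrices; values are cell forces in kgf and must be
#' non-negative.
#'
#' @param frames Frame data (3-d array or list of matrices).
#' @param geometry A [grid_geometry()].
#' @param time Frame times in seconds; defaults to `0:(n-1) / fs`.
#' @return An object of class `pressure_frames` with the frames stored as
#'   an `(n_frames, n_rows, n_cols)` array.
#' @export
pressure_frames <- function(frames, geometry = grid_geometry(), time = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  if (is.list(frames)) {
    nf <- length(frames)
    arr <- array(0, dim = c(nf, geometry$n_rows, geometry$n_cols))
    for (i in seq_len(nf)) {
      m <- frames[[i]]
      if (!is.matrix(m) || nrow(m) != geometry$n_rows ||
          ncol(m) != geometry$n_cols)
        stop("pressure_frames: frame ", i, " is not an ",
             geometry$n_rows, " x ", geometry$n_cols, " matrix",
             call. = FALSE)
      arr[i, , ] <- m
    }
    frames <- arr
  }
  if (length(dim(frames)) != 3L ||
      dim(frames)[2] != geometry$n_rows || dim(frames)[3] != geometry$n_cols)
    stop("pressure_frames: frames must have dim (n_frames, n_rows, n_cols)",
         call. = FALSE)
  if (any(frames < 0))
    stop("pressure_frames: negative cell forces", call. = FALSE)
  nf <- dim(frames)[1]
  if (is.null(time)) time <- (seq_len(nf) - 1) / geometry$fs
  if (length(time) != nf)
    stop("pressure_frames: time length must equal frame count", call. = FALSE)
  structure(list(geometry = geometry, frames = frames, time = time),
            class = "pressure_frames")
}

#' Read pressure frames from long-format delimited text
#'
#' Expects columns `time_s`, `row`, `col`, `force_kgf`; cells absent from
#' the file are zero. Each distinct `time_s` value becomes one frame.
#'
#' @param path Path to the file.
#' @param geometry A [grid_geometry()].
#' @return A [pressure_frames()] series.
#' @export
read_pressure_frames <- function(path, geometry = grid_geometry()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "row", "col", "force_kgf")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_pressure_frames: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  times <- sort(unique(d$time_s))
  arr <- array(0, dim = c(length(times), geometry$n_rows, geometry$n_cols))
  fi <- match(d$time_s, times)
  if (any(d$row < 1 | d$row > geometry$n_rows |
          d$col < 1 | d$col > geometry$n_cols))
    stop("read_pressure_frames: cell index outside the grid", call. = FALSE)
  arr[cbind(fi, d$row, d$col)] <- d$force_kgf
  pressure_frames(arr, geometry, time = times)
}

#' Center of pressure from pressure-grid frames
#'
#' Per frame, the CoP is the force-weighted centroid of the loaded cell
#' centres, in cm with origin at the grid centre. Frames whose total load
#' falls below `min_total_load` are invalid: a contiguous run of invalid
#' frames at the start or end of the series is dropped (and the trial
#' re-timed from the first retained frame), interior gaps of up to
#' `max_gap` frames are filled by linear interpolation of the CoP, and
#' longer interior gaps raise an error. This keeps the returned trial
#' uniformly sampled.
#'
#' @param frames A [pressure_frames()] series.
#' @param min_total_load Minimum per-frame total load in kgf (default 10,
#'   the lower end of the mat's working force range).
#' @param max_gap Longest interior invalid run to interpolate over.
#' @param condition,subject_id Passed to the returned trial.
#' @return A [cop_trial()].
#' @export
cop_from_grid <- function(frames, min_total_load = 10, max_gap = 3,
                          condition = NA_character_,
                          subject_id = NA_character_) {
  stopifnot(inherits(frames, "pressure_frames"))
  geom <- frames$geometry
  cc <- grid_cell_centers(geom)
  nf <- dim(frames$frames)[1]
  flat <- matrix(frames$frames, nrow = nf)  # column-major: (row, col) cells
  # coordinate of each flattened cell: cell (i,j) sits at index (j-1)*n_rows+i
  cx <- rep(cc$x, each = geom$n_rows)
  cy <- rep(cc$y, times = geom$n_cols)
  total <- rowSums(flat)
  valid <- total >= min_total_load
  if (!any(valid))
    stop("cop_from_grid: all frames below the load threshold (empty trial)",
         call. = FALSE)
  x <- as.numeric(flat %*% cx) / total
  y <- as.numeric(flat %*% cy) / total
  keep <- seq(which(valid)[1], which(valid)[length(which(valid))])
  if (length(keep) < 2L)
    stop("cop_from_grid: fewer than 2 usable frames", call. = FALSE)
  x <- x[keep]; y <- y[keep]; v <- valid[keep]
  tm <- frames$time[keep]; tm <- tm - tm[1]
  if (any(!v)) {
    runs <- rle(v)
    if (max(runs$lengths[!runs$values]) > max_gap)
      stop("cop_from_grid: interior gap of more than ", max_gap,
           " sub-threshold frames", call. = FALSE)
    x[!v] <- stats::approx(tm[v], x[v], xout = tm[!v])$y
    y[!v] <- stats::approx(tm[v], y[v], xout = tm[!v])$y
  }
  cop_trial(tm, x, y, fs = geom$fs, condition = condition,
            subject_id = subject_id)
}

#' Four-corner load-cell series
#'
#' Force signals from the four load cells of a board-type force plate
#' (top-left, top-right, bottom-left, bottom-right when viewed from
#' above, with "top" towards positive y and "right" towards positive x).
#'
#' @param tl,tr,bl,br Corner force signals in kgf, equal length.
#' @param board_length Board extent along x, in cm (default 43.3).
#' @param board_width Board extent along y, in cm (default 22.8).
#' @param fs Sampling rate in Hz.
#' @param time Optional explicit sample times (seconds).
#' @return An object of class `corner_loads`.
#' @export
corner_loads <- function(tl, tr, bl, br, board_length = 43.3,
                         board_width = 22.8, fs = 23, time = NULL) {
  n <- length(tl)
  if (n < 1L || length(tr) != n || length(bl) != n || length(br) != n)
    stop("corner_loads: corner signals must have equal positive length",
         call. = FALSE)
  stopifnot(board_length > 0, board_width > 0, fs > 0)
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  structure(list(tl = tl, tr = tr, bl = bl, br = br,
                 board_length = board_length, board_width = board_width,
                 fs = fs, time = time),
            class = "corner_loads")
}

#' Center of pressure from four-corner load cells
#'
#' Standard lever-arm formula for a rectangular plate on four load cells:
#' `x = (L/2) * ((tr + br) - (tl + bl)) / total` and
#' `y = (W/2) * ((tl + tr) - (bl + br)) / total`, with `L` the board
#' length and `W` its width.
#'
#' @param loads A [corner_loads()] series.
#' @param condition,subject_id Passed to the returned trial.
#' @return A [cop_trial()].
#' @export
cop_from_corners <- function(loads, condition = NA_character_,
                             subject_id = NA_character_) {
  stopifnot(inherits(loads, "corner_loads"))
  total <- loads$tl + loads$tr + loads$bl + loads$br
  if (any(total <= 0))
    stop("cop_from_corners: degenerate frame with total load <= 0",
         call. = FALSE)
  x <- (loads$board_length / 2) *
    ((loads$tr + loads$br) - (loads$tl + loads$bl)) / total
  y <- (loads$board_width / 2) *
    ((loads$tl + loads$tr) - (loads$bl + loads$br)) / total
  cop_trial(loads$time, x, y, fs = loads$fs, condition = condition,
            subject_id = subject_id)
}
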