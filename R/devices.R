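#' Board geometry for the four-corner device
#'
#' @param length_cm Board extent along x (AP), cm.
#' @param width_cm Board extent along y (ML), cm.
#' @return List with the two dimensions.
#' @export
corner_board <- function(length_cm = 43.3, width_cm = 22.8) {
  stopifnot(length_cm > 0, width_cm > 0)
  list(length_cm = length_cm, width_cm = width_cm)
}

# Newton placement of a 1-d Gaussian footprint profile on a cell grid so
# that its discrete centroid equals the target coordinate exactly.
# `targets` is a vector (one per frame); returns the weight matrix
# (frames x cells). `centers2` optionally adds a second, offset profile
# (the second foot) sharing the same correction.
place_profile <- function(targets, cells, sd, offset = 0, iters = 8) {
  mu <- targets
  profile <- function(mu) {
    exp(-(outer(mu + offset, cells, "-"))^2 / (2 * sd^2)) +
      exp(-(outer(mu - offset, cells, "-"))^2 / (2 * sd^2))
  }
  for (it in seq_len(iters)) {
    w <- profile(mu)
    cent <- as.numeric(w %*% cells) / rowSums(w)
    mu <- mu + (targets - cent)
  }
  w <- profile(mu)
  cent <- as.numeric(w %*% cells) / rowSums(w)
  list(w = w, err = max(abs(cent - targets)))
}

#' Emulate the pressure-grid mat and the four-corner board for one trial
#'
#' Both emulated devices observe the same underlying CoP trajectory.
#' The grid device places a two-foot bivariate-Gaussian pressure
#' footprint (feet separated medio-laterally) whose discrete force-
#' weighted centroid is positioned on the trial CoP; with zero sensor
#' noise, [cop_from_grid()] recovers the input CoP almost exactly. The
#' corner device solves the four-load-cell lever equations for the same
#' CoP and total load, so [cop_from_corners()] inverts it exactly up to
#' noise.
#'
#' @param trial A [cop_trial()]; its CoP must stay within both devices'
#'   active areas.
#' @param grid A [grid_geometry()].
#' @param board A [corner_board()].
#' @param load_kgf Total body load in kgf (default 60, within the mat's
#'   10-100 kg working range).
#' @param grid_noise_sd Additive per-cell force noise SD (kgf).
#' @param corner_noise_sd Additive per-corner force noise SD (kgf).
#' @param foot_sep Medio-lateral distance between foot centres, cm.
#' @param foot_sd AP / ML spread of each foot's pressure blob, cm.
#' @param seed Integer seed for the sensor noise.
#' @return List with elements `grid` (a [pressure_frames()]) and
#'   `corners` (a [corner_loads()]).
#' @export
emulate_devices <- function(trial, grid = grid_geometry(),
                            board = corner_board(), load_kgf = 60,
                            grid_noise_sd = 0.002, corner_noise_sd = 0.05,
                            foot_sep = 16, foot_sd = c(4, 2.5), seed = 1) {
  stopifnot(inherits(trial, "cop_trial"))
  cc <- grid_cell_centers(grid)
  half_x <- grid$n_cols * grid$pitch_x / 20  # cm
  half_y <- grid$n_rows * grid$pitch_y / 20
  if (any(abs(trial$x) > half_x - 2 * foot_sd[1]) ||
      any(abs(trial$y) > half_y - foot_sep / 2 - 2 * foot_sd[2]))
    stop("emulate_devices: CoP outside the grid's usable area",
         call. = FALSE)
  if (any(abs(trial$x) > board$length_cm / 2) ||
      any(abs(trial$y) > board$width_cm / 2))
    stop("emulate_devices: CoP outside the corner board", call. = FALSE)
  nf <- length(trial$time)
  px <- place_profile(trial$x, cc$x, foot_sd[1])
  py <- place_profile(trial$y, cc$y, foot_sd[2], offset = foot_sep / 2)
  # frames[f, i, j] = load * wy[f, i] * wx[f, j] / norm
  wx <- px$w / rowSums(px$w)
  wy <- py$w / rowSums(py$w)
  frames <- array(0, dim = c(nf, grid$n_rows, grid$n_cols))
  for (i in seq_len(grid$n_rows))
    frames[, i, ] <- load_kgf * wy[, i] * wx
  total <- trial$x * 0 + load_kgf
  out <- with_seed(seed, {
    if (grid_noise_sd > 0)
      frames <- pmax(frames + stats::rnorm(length(frames), 0,
                                           grid_noise_sd), 0)
    a <- total * (0.5 + trial$x / board$length_cm)  # tr + br
    b <- total - a                                  # tl + bl
    cd <- total * (2 * trial$y / board$width_cm)    # (tl+tr) - (bl+br)
    tr <- a / 2 + cd / 4
    br <- a / 2 - cd / 4
    tl <- b / 2 + cd / 4
    bl <- b / 2 - cd / 4
    if (corner_noise_sd > 0) {
      tr <- tr + stats::rnorm(nf, 0, corner_noise_sd)
      br <- br + stats::rnorm(nf, 0, corner_noise_sd)
      tl <- tl + stats::rnorm(nf, 0, corner_noise_sd)
      bl <- bl + stats::rnorm(nf, 0, corner_noise_sd)
    }
    list(grid = pressure_frames(frames, grid, time = trial$time),
         corners = corner_loads(tl, tr, bl, br,
                                board_length = board$length_cm,
                                board_width = board$width_cm,
                                fs = trial$fs, time = trial$time))
  })
  out
}
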