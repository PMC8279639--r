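# Generalized vibrational modes from the mass-weighted velocity covariance.
#
# The working representation of a trajectory's velocities is an
# nframes x 3N matrix in atom-major flattening: columns are
# (x1, y1, z1, x2, y2, z2, ...). All operations below fix this order.

.cross3 <- function(a, b) {
  # row-wise cross product of N x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Mass-weighted velocity matrix of a trajectory
#'
#' Scales each atomic velocity component by the square root of the atomic
#' mass, which makes the kinetic-energy metric Euclidean: the squared norm of
#' a row equals twice the kinetic energy of that frame (amu Angstrom^2/fs^2).
#'
#' @param traj a [trajectory()]
#' @return nframes x 3N matrix; column 3(i-1)+d holds sqrt(m_i) v_{i,d}
#' @export
mass_weight <- function(traj) {
  n <- traj$natoms
  sm <- sqrt(traj$masses)
  out <- matrix(0, traj$nframes, 3 * n)
  for (d in 1:3) out[, seq(d, 3 * n, by = 3)] <-
    traj$velocities[, , d, drop = TRUE] * rep(sm, each = traj$nframes)
  if (traj$nframes == 1) { # drop=TRUE collapsed the frame dimension
    out <- matrix(0, 1, 3 * n)
    for (d in 1:3) out[1, seq(d, 3 * n, by = 3)] <- traj$velocities[1, , d] * sm
  }
  out
}

#' Remove global translation and rotation from a trajectory
#'
#' Per frame, subtracts the center-of-mass velocity, then the rigid-rotation
#' field omega x r with the angular velocity obtained from the instantaneous
#' inertia tensor and angular momentum about the center of mass. Positions
#' are re-centered on the center of mass. For (near-)collinear
#' configurations the inertia tensor is inverted on its well-conditioned
#' eigen-axes only (moments below \code{sing_tol} times the largest are
#' dropped), so only the well-defined rotation axes are projected; the
#' number of frames where an axis was dropped is reported in the
#' \code{"dropped_axis_frames"} attribute.
#'
#' After this operation the total linear momentum and the total angular
#' momentum about the center of mass vanish frame by frame (to round-off,
#' modulo dropped axes).
#'
#' @param traj a [trajectory()] with at least 2 atoms
#' @param sing_tol relative eigenvalue threshold for the inertia tensor
#' @return a [trajectory()] with cleaned velocities
#' @export
remove_global_motion <- function(traj, sing_tol = 1e-10) {
  if (traj$natoms < 2) stop("need at least 2 atoms")
  m <- traj$masses; M <- sum(m)
  pos <- traj$positions; vel <- traj$velocities
  dropped <- 0L
  for (f in seq_len(traj$nframes)) {
    r <- matrix(pos[f, , ], ncol = 3)
    v <- matrix(vel[f, , ], ncol = 3)
    rc <- colSums(m * r) / M
    vc <- colSums(m * v) / M
    r <- sweep(r, 2, rc)
    v <- sweep(v, 2, vc)
    # angular momentum and inertia tensor about the COM
    L <- colSums(m * .cross3(r, v))
    I <- diag(sum(m * rowSums(r^2)), 3) - t(r * m) %*% r
    eig <- eigen(I, symmetric = TRUE)
    keep <- eig$values > sing_tol * max(eig$values)
    if (!all(keep)) dropped <- dropped + 1L
    Vk <- eig$vectors[, keep, drop = FALSE]
    omega <- Vk %*% ((t(Vk) %*% L) / eig$values[keep])
    v <- v - .cross3(matrix(omega, nrow(r), 3, byrow = TRUE), r)
    pos[f, , ] <- r
    vel[f, , ] <- v
  }
  out <- trajectory(traj$elements, pos, vel, traj$dt, masses = traj$masses)
  attr(out, "dropped_axis_frames") <- dropped
  out
}

#' Time-averaged covariance of mass-weighted velocities
#'
#' K_ij is the time average over frames of qdot_i qdot_j, after per-column
#' mean centering (means are already near zero once global motion has been
#' removed; centering makes K a true covariance). The result is exactly
#' symmetric by construction.
#'
#' @param mwvel nframes x 3N mass-weighted velocity matrix from
#'   [mass_weight()]
#' @param center mean-center columns first (default TRUE)
#' @return 3N x 3N symmetric matrix, amu Angstrom^2/fs^2
#' @export
compute_K <- function(mwvel, center = TRUE) {
  if (nrow(mwvel) < 2) stop("need at least 2 frames to average")
  if (center) mwvel <- sweep(mwvel, 2, colMeans(mwvel))
  K <- crossprod(mwvel) / nrow(mwvel)
  (K + t(K)) / 2
}

#' Diagonalize a velocity covariance matrix into a mode basis
#'
#' Eigenvalues are sorted descending; each eigenvector's sign is fixed so
#' that its largest-magnitude component is positive, making the output
#' deterministic. \code{n_zero} counts eigenvalues below
#' \code{rel_tol * max(eigenvalue)} — for a trajectory whose global
#' translation and rotation have been projected out, these are the 6
#' translational/rotational coordinates (5 for a linear molecule) plus any
#' unexcited internal direction. Eigenvectors spanning that near-zero block
#' are individually arbitrary (only their span is defined); the block is
#' reported via the \code{degenerate} flag vector.
#'
#' @param K symmetric matrix from [compute_K()]
#' @param rel_tol relative threshold for the near-zero count
#' @param sym_tol relative tolerance on symmetry of the input
#' @return object of class \code{mode_basis}: list with \code{K}, \code{L}
#'   (columns are modes), \code{eigenvalues}, \code{n_zero},
#'   \code{degenerate}
#' @export
diagonalize <- function(K, rel_tol = 1e-8, sym_tol = 1e-8) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  scale <- max(abs(K), .Machine$double.xmin)
  if (max(abs(K - t(K))) > sym_tol * scale)
    stop("K is not symmetric to tolerance")
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)   # already sorted descending
  L <- eig$vectors
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  lam <- eig$values
  nz <- sum(lam < rel_tol * max(lam))
  structure(list(K = K, L = L, eigenvalues = lam, n_zero = nz,
                 degenerate = lam < rel_tol * max(lam)),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  cat(sprintf("mode_basis: %d generalized modes, %d near-zero (global)\n",
              length(x$eigenvalues), x$n_zero))
  cat("leading eigenvalues (amu A^2/fs^2):",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' Project mass-weighted velocities onto a mode basis
#'
#' Computes per frame Qdot(f) = t(L) qdot(f). The basis is typically built
#' from a ground-state trajectory and applied to excited-state velocities:
#' near the Franck-Condon region the ground-state mode composition is
#' assumed to still hold. Since L is orthogonal the per-frame Euclidean norm
#' is preserved (Parseval).
#'
#' @param basis a \code{mode_basis} from [diagonalize()]
#' @param mwvel nframes x 3N matrix from [mass_weight()]
#' @return object of class \code{mode_velocity_series}: list with
#'   \code{Qdot} (nframes x 3N), \code{dt} (fs, if supplied),
#'   \code{mode_labels}
#' @param dt timestep in fs, carried along for spectral analysis
#' @param mode_labels optional character tags per mode
#' @export
project_modes <- function(basis, mwvel, dt = NULL, mode_labels = NULL) {
  if (ncol(mwvel) != ncol(basis$L))
    stop("dimension mismatch: velocities have ", ncol(mwvel),
         " coordinates, basis has ", ncol(basis$L))
  structure(list(Qdot = mwvel %*% basis$L, dt = dt,
                 mode_labels = mode_labels),
            class = "mode_velocity_series")
}

#' Power spectrum of a mode-velocity signal
#'
#' Spectral estimate of the velocity autocorrelation by the
#' Wiener-Khinchin route: the periodogram of the (windowed, zero-padded,
#' mean-removed) signal, which equals the Fourier transform of the
#' autocorrelation up to the windowing. Frequencies are reported in cm^-1
#' up to the Nyquist frequency.
#'
#' @param series numeric vector, one mode's velocity over time
#' @param dt timestep, fs
#' @param window \code{"hann"} (default) or \code{"none"}
#' @param zero_pad zero-padding factor (default 4)
#' @return object of class \code{power_spectrum}: list with
#'   \code{frequencies} (cm^-1, strictly increasing) and \code{power}
#'   (arbitrary units, >= 0)
#' @export
power_spectrum <- function(series, dt, window = "hann", zero_pad = 4) {
  n <- length(series)
  if (n < 32) stop("series too short for spectral estimation (need >= 32 frames)")
  x <- series - mean(series)
  w <- switch(window,
              hann = signal::hanning(n),
              none = rep(1, n),
              stop("unknown window: ", window))
  xw <- x * w
  nfft <- stats::nextn(n * max(1, round(zero_pad)), 2)
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  half <- seq_len(nfft %/% 2)
  freq <- (half - 1) / (nfft * dt)          # cycles/fs
  structure(list(frequencies = cycles_fs_to_cm1(freq),
                 power = Mod(X[half])^2),
            class = "power_spectrum")
}

#' Export a mode basis to plain text
#'
#' Header lines record the dimension and sort order, then one line of
#' eigenvalues, then L row-major (one row per line), all at 17 significant
#' digits.
#'
#' @param basis a \code{mode_basis}
#' @param path output path
#' @return invisibly, \code{path}
#' @export
write_mode_basis <- function(basis, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(basis$eigenvalues)
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  writeLines(c(sprintf("# mode_basis n=%d sort=descending n_zero=%d", n, basis$n_zero),
               sprintf("# eigenvalues_amu_A2_fs-2: %s", fmt(basis$eigenvalues))), con)
  for (i in seq_len(n)) writeLines(fmt(basis$L[i, ]), con)
  invisible(path)
}

#' Read a mode basis written by [write_mode_basis()]
#'
#' @param path file path
#' @return a \code{mode_basis} (with \code{K} reconstructed as
#'   L diag(lambda) t(L))
#' @export
read_mode_basis <- function(path) {
  lines <- readLines(path)
  if (!grepl("^# mode_basis", lines[1])) stop("not a mode basis file: ", path)
  n <- as.integer(sub(".*n=(\\d+).*", "\\1", lines[1]))
  nz <- as.integer(sub(".*n_zero=(\\d+).*", "\\1", lines[1]))
  lam <- as.numeric(strsplit(trimws(sub("^[^:]*:", "", lines[2])), "\\s+")[[1]])
  body <- lines[!startsWith(lines, "#")]
  L <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (!identical(dim(L), c(n, n)) || length(lam) != n)
    stop("corrupt mode basis file: ", path)
  structure(list(K = L %*% (lam * t(L)), L = L, eigenvalues = lam,
                 n_zero = nz, degenerate = lam < 1e-8 * max(lam)),
            class = "mode_basis")
}

#' Average power fields across an ensemble
#'
#' Averages the \code{power} field of spectra or spectrograms computed from
#' independent trajectories (ensemble averaging after projection; averaging
#' raw velocities across unsynchronized trajectories would cancel the
#' oscillations).
#'
#' @param xs list of \code{power_spectrum} or \code{spectrogram} objects on
#'   identical grids
#' @return object of the same class with averaged \code{power}
#' @export
ensemble_average <- function(xs) {
  if (length(xs) == 0) stop("empty ensemble")
  ref <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(class(x), class(ref)))
      stop("ensemble members have different classes")
    if (!isTRUE(all.equal(dim(as.matrix(x$power)), dim(as.matrix(ref$power)))))
      stop("ensemble members are on different grids")
  }
  out <- ref
  out$power <- Reduce(`+`, lapply(xs, `[[`, "power")) / length(xs)
  out
}
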