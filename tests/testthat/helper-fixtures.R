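# Shared synthetic fixtures, built in code.

CM1 <- 33356.40952  # cycles/fs -> cm^-1

# bent (water-like) triatomic: O + 2 H, mirror-symmetric about the y axis
bent_geometry <- function() rbind(c(0, 0.587, 0), c(0.757, 0, 0), c(-0.757, 0, 0))
bent_masses <- function() c(15.999, 1.008, 1.008)

# collinear (CO2-like) triatomic along x
linear_geometry <- function() rbind(c(-1.16, 0, 0), c(0, 0, 0), c(1.16, 0, 0))
linear_masses <- function() c(15.999, 12.011, 15.999)

# harmonic trajectory of a bent triatomic with all 3 internal modes excited
bent_harmonic <- function(amplitudes = rep(1e-5, 3),
                          frequencies = c(500, 1200, 1800),
                          dt = 0.4, nframes = 6000, seed = 11) {
  geom <- bent_geometry(); m <- bent_masses()
  mv <- internal_mode_vectors(geom, m, length(frequencies), seed = seed)
  spec <- harmonic_spec(geom, m, mv, frequencies, amplitudes,
                        phases = seq(0.3, by = 0.8, length.out = length(frequencies)))
  make_harmonic(spec, dt, nframes)
}

linear_harmonic <- function(amplitudes = rep(1e-5, 4),
                            frequencies = c(600, 700, 1300, 2300),
                            dt = 0.4, nframes = 6000, seed = 7) {
  geom <- linear_geometry(); m <- linear_masses()
  mv <- internal_mode_vectors(geom, m, length(frequencies), seed = seed)
  spec <- harmonic_spec(geom, m, mv, frequencies, amplitudes,
                        phases = seq(0, by = 0.7, length.out = length(frequencies)))
  make_harmonic(spec, dt, nframes)
}

# a single-pair static trajectory at a fixed separation (Angstrom)
static_pair <- function(sep, nframes = 5) {
  pos <- array(0, c(nframes, 2, 3)); pos[, 2, 1] <- sep
  trajectory(c("X", "X"), pos, array(0, dim(pos)), dt = 1, masses = c(1, 1))
}

# four-atom single-frame trajectory realizing a target dihedral (degrees)
dihedral_geometry <- function(ang_deg) {
  a <- ang_deg * pi / 180
  rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(cos(a), 0, sin(a)))
}

dihedral_traj <- function(geoms) {
  # geoms: list of 4x3 matrices, one per frame
  nf <- length(geoms)
  pos <- array(0, c(nf, 4, 3))
  for (f in seq_len(nf)) pos[f, , ] <- geoms[[f]]
  trajectory(rep("C", 4), pos, array(0, dim(pos)), dt = 1, masses = rep(12, 4))
}

# independent brute-force proton-assignment oracle: plain loops, no shared
# code with the package internals
oracle_assignments <- function(traj, ih, io, r_bond) {
  out <- matrix(NA_integer_, traj$nframes, length(ih))
  for (f in seq_len(traj$nframes)) {
    for (hj in seq_along(ih)) {
      dbest <- Inf; best <- NA_integer_
      for (o in io) {
        d <- sqrt(sum((traj$positions[f, ih[hj], ] - traj$positions[f, o, ])^2))
        if (d < dbest) { dbest <- d; best <- o }
      }
      if (dbest <= r_bond) out[f, hj] <- best
    }
  }
  out
}

write_tmp_xyz <- function(traj) {
  path <- tempfile(fileext = ".xyz")
  write_extxyz(traj, path)
  path
}
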