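# Synthetic trajectory generators: harmonic molecules with known modes,
# uniform droplets for RDF null models, and scripted proton-hop
# trajectories. All generators are seed-deterministic and produce ordinary
# trajectory objects, so the full analysis pipeline can be validated
# against analytic ground truth.

#' Specification of a synthetic harmonic molecule
#'
#' Defines a reference geometry and a set of orthonormal mass-weighted
#' displacement patterns, each oscillating at a known frequency with a
#' given amplitude, phase and (optional) exponential amplitude damping.
#'
#' @param geometry N x 3 reference coordinates, Angstrom
#' @param masses N masses, amu
#' @param mode_vectors 3N x k matrix of orthonormal mass-weighted
#'   displacement patterns (atom-major flattening)
#' @param frequencies k mode frequencies, cm^-1 (> 0)
#' @param amplitudes k amplitudes in mass-weighted displacement units
#'   (sqrt(amu) Angstrom)
#' @param dampings k amplitude time constants tau, fs (Inf = undamped);
#'   note the power of a damped mode decays twice as fast as its amplitude
#' @param phases k phases, radians
#' @param elements optional element symbols (defaults to "X" pseudo-atoms)
#' @return object of class \code{harmonic_spec}
#' @export
harmonic_spec <- function(geometry, masses, mode_vectors, frequencies,
                          amplitudes, dampings = Inf, phases = 0,
                          elements = NULL) {
  geometry <- as.matrix(geometry)
  n <- nrow(geometry)
  mode_vectors <- as.matrix(mode_vectors)
  k <- ncol(mode_vectors)
  if (nrow(mode_vectors) != 3 * n) stop("mode_vectors must be 3N x k")
  if (any(frequencies <= 0)) stop("frequencies must be > 0")
  if (length(frequencies) != k || length(amplitudes) != k)
    stop("frequencies/amplitudes must have one value per mode")
  dampings <- rep_len(dampings, k)
  phases <- rep_len(phases, k)
  gram <- crossprod(mode_vectors)
  if (max(abs(gram - diag(k))) > 1e-8)
    stop("mode_vectors must be orthonormal")
  if (is.null(elements)) elements <- rep("X", n)
  structure(list(geometry = geometry, masses = masses,
                 mode_vectors = mode_vectors, frequencies = frequencies,
                 amplitudes = amplitudes, dampings = dampings,
                 phases = phases, elements = elements),
            class = "harmonic_spec")
}

#' Orthonormal internal mode vectors for a reference geometry
#'
#' Draws k random mass-weighted displacement patterns, projects out the
#' global translations and rotations of the reference geometry (rotation
#' generators with negligible norm — the axis of a linear molecule — are
#' skipped), and orthonormalizes. The result spans purely internal motion
#' at linear order, so a harmonic trajectory built on it carries no net
#' momentum or angular momentum.
#'
#' @param geometry N x 3 reference coordinates, Angstrom
#' @param masses N masses, amu
#' @param k number of internal modes (at most 3N minus the number of global
#'   degrees of freedom)
#' @param seed RNG seed
#' @return 3N x k orthonormal matrix
#' @export
internal_mode_vectors <- function(geometry, masses, k, seed = 1) {
  n <- nrow(geometry)
  sm <- sqrt(masses)
  com <- colSums(masses * geometry) / sum(masses)
  rr <- sweep(geometry, 2, com)
  glob <- list()
  for (d in 1:3) {                      # translations
    v <- matrix(0, n, 3); v[, d] <- sm
    glob[[length(glob) + 1L]] <- as.vector(t(v))
  }
  for (d in 1:3) {                      # rotations: sqrt(m) (e_d x r)
    e <- numeric(3); e[d] <- 1
    v <- t(apply(rr, 1, function(r) c(e[2] * r[3] - e[3] * r[2],
                                      e[3] * r[1] - e[1] * r[3],
                                      e[1] * r[2] - e[2] * r[1])))
    v <- v * sm
    if (sqrt(sum(v^2)) > 1e-8 * sqrt(sum(rr^2) * sum(masses)))
      glob[[length(glob) + 1L]] <- as.vector(t(v))
  }
  G <- qr.Q(qr(do.call(cbind, glob)))
  n_glob <- ncol(G)
  if (k > 3 * n - n_glob)
    stop("k exceeds the number of internal degrees of freedom (",
         3 * n - n_glob, ")")
  set.seed(seed)
  X <- matrix(stats::rnorm(3 * n * k), 3 * n, k)
  X <- X - G %*% (t(G) %*% X)
  qr.Q(qr(X))[, seq_len(k), drop = FALSE]
}

#' Synthesize a harmonic trajectory
#'
#' Mass-weighted displacement
#' s(t) = sum_k A_k L_k cos(2 pi nu_k t + phi_k) exp(-t/tau_k), with
#' analytically consistent velocities; Cartesian coordinates are
#' s_i/sqrt(m_i) about the reference geometry. No global translation or
#' rotation is injected.
#'
#' @param spec a [harmonic_spec()]
#' @param dt timestep, fs
#' @param nframes number of frames
#' @return a [trajectory()]
#' @export
make_harmonic <- function(spec, dt, nframes) {
  if (!inherits(spec, "harmonic_spec")) stop("spec must be a harmonic_spec()")
  nyq <- cycles_fs_to_cm1(1 / (2 * dt))
  if (any(spec$frequencies >= nyq))
    stop(sprintf("mode frequency above the Nyquist frequency (%g cm^-1) for dt = %g fs",
                 nyq, dt))
  n <- nrow(spec$geometry)
  tgrid <- (seq_len(nframes) - 1) * dt
  S <- matrix(0, nframes, 3 * n)     # mass-weighted displacements
  V <- matrix(0, nframes, 3 * n)     # mass-weighted velocities
  for (k in seq_along(spec$frequencies)) {
    w <- 2 * pi * cm1_to_cycles_fs(spec$frequencies[k])
    tau <- spec$dampings[k]
    env <- if (is.finite(tau)) exp(-tgrid / tau) else rep(1, nframes)
    ph <- w * tgrid + spec$phases[k]
    q <- spec$amplitudes[k] * env * cos(ph)
    qd <- spec$amplitudes[k] * env *
      (-w * sin(ph) - (if (is.finite(tau)) cos(ph) / tau else 0))
    S <- S + q %o% spec$mode_vectors[, k]
    V <- V + qd %o% spec$mode_vectors[, k]
  }
  sm <- rep(sqrt(spec$masses), each = 3)   # atom-major: (x1,y1,z1,...)
  pos <- array(0, c(nframes, n, 3)); vel <- array(0, c(nframes, n, 3))
  ref <- as.vector(t(spec$geometry))
  for (f in seq_len(nframes)) {
    pos[f, , ] <- matrix(ref + S[f, ] / sm, n, 3, byrow = TRUE)
    vel[f, , ] <- matrix(V[f, ] / sm, n, 3, byrow = TRUE)
  }
  trajectory(spec$elements, pos, vel, dt,
             masses = spec$masses)
}

#' Uniform random droplet of pseudo-atoms
#'
#' Points uniform in a sphere (RDF ideal-gas null model). Velocities are
#' zero. With \code{nframes > 1}, each frame is an independent draw, which
#' sharpens frame-averaged RDF statistics.
#'
#' @param n_points number of points (>= 2)
#' @param radius sphere radius, Angstrom (default 19, a typical
#'   microsolvation droplet)
#' @param seed RNG seed
#' @param nframes number of independent frames (default 1)
#' @param center_atom prepend one fixed atom at the origin (a convenient
#'   RDF reference site; default FALSE)
#' @return a [trajectory()] of unit-mass "X" pseudo-atoms, dt = 1 fs
#' @export
make_droplet <- function(n_points, radius = 19, seed = 1, nframes = 1,
                         center_atom = FALSE) {
  if (n_points < 2) stop("need at least 2 points")
  set.seed(seed)
  ntot <- n_points + as.integer(center_atom)
  pos <- array(0, c(nframes, ntot, 3))
  for (f in seq_len(nframes)) {
    u <- matrix(stats::rnorm(3 * n_points), n_points, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * stats::runif(n_points)^(1 / 3)
    pts <- u * r
    pos[f, , ] <- if (center_atom) rbind(c(0, 0, 0), pts) else pts
  }
  trajectory(rep("X", ntot), pos, array(0, dim(pos)), dt = 1,
             masses = rep(1, ntot))
}

#' Scripted proton-hop trajectory
#'
#' Heavy atoms ("O") sit static on the x axis, 2.6 Angstrom apart. Each
#' scripted hydrogen is bonded 1.0 Angstrom from its current parent toward
#' the partner heavy atom; at \code{t_hop} it switches to the acceptor site
#' and, if \code{return_after} is finite, switches back that many fs later.
#' The geometry guarantees the covalent assignment (1.0 Angstrom to the
#' parent, 1.6 Angstrom to the partner) flips exactly at the scripted
#' frame, so detectors can be checked frame-exactly.
#'
#' @param events list of hop scripts, each a list with \code{hydrogen}
#'   (1-based id among the scripted hydrogens), \code{from}, \code{to}
#'   (1-based heavy-atom ids), \code{t_hop} (fs), \code{return_after}
#'   (fs or Inf for no return)
#' @param dt timestep, fs
#' @param nframes number of frames
#' @param n_heavy number of heavy atoms (default: largest id referenced)
#' @return a [trajectory()] with heavy atoms first, then hydrogens;
#'   selections are attached as attributes \code{"heavy"} and
#'   \code{"hydrogens"}
#' @export
make_pt_script <- function(events, dt, nframes, n_heavy = NULL) {
  if (length(events) == 0) stop("no events scripted")
  get <- function(e, f) if (is.null(e[[f]])) stop("event missing field ", f) else e[[f]]
  hyd_ids <- vapply(events, get, numeric(1), "hydrogen")
  n_h <- max(hyd_ids)
  if (is.null(n_heavy))
    n_heavy <- max(vapply(events, function(e) max(get(e, "from"), get(e, "to")), numeric(1)))
  # overlapping scripts for one hydrogen are a user error
  for (h in unique(hyd_ids)) {
    es <- events[hyd_ids == h]
    iv <- t(vapply(es, function(e) {
      ra <- if (is.null(e$return_after)) Inf else e$return_after
      c(e$t_hop, if (is.finite(ra)) e$t_hop + ra else Inf)
    }, numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-nrow(iv), 2] >= iv[-1, 1]))
      stop("overlapping hop scripts for hydrogen ", h)
    if (any(iv[, 1] < 0 | iv[, 1] > (nframes - 1) * dt))
      stop("hop time outside the trajectory window for hydrogen ", h)
  }
  heavy_pos <- cbind((seq_len(n_heavy) - 1) * 2.6, 0, 0)
  site <- function(parent, partner) {
    u <- heavy_pos[partner, ] - heavy_pos[parent, ]
    heavy_pos[parent, ] + u / sqrt(sum(u^2))
  }
  tgrid <- (seq_len(nframes) - 1) * dt
  ntot <- n_heavy + n_h
  pos <- array(0, c(nframes, ntot, 3))
  for (f in seq_len(nframes)) pos[f, seq_len(n_heavy), ] <- heavy_pos
  for (h in seq_len(n_h)) {
    es <- events[hyd_ids == h]
    if (length(es) == 0) stop("hydrogen ", h, " has no script")
    ord <- order(vapply(es, get, numeric(1), "t_hop"))
    es <- es[ord]
    e0 <- es[[1]]
    cur <- matrix(site(e0$from, e0$to), nframes, 3, byrow = TRUE)
    for (e in es) {
      ra <- if (is.null(e$return_after)) Inf else e$return_after
      at_to <- tgrid >= e$t_hop & (!is.finite(ra) | tgrid < e$t_hop + ra)
      cur[at_to, ] <- matrix(site(e$to, e$from), sum(at_to), 3, byrow = TRUE)
      if (is.finite(ra))
        cur[tgrid >= e$t_hop + ra, ] <-
          matrix(site(e$from, e$to), sum(tgrid >= e$t_hop + ra), 3, byrow = TRUE)
    }
    pos[, n_heavy + h, ] <- cur
  }
  traj <- trajectory(c(rep("O", n_heavy), rep("H", n_h)), pos,
                     array(0, dim(pos)), dt)
  attr(traj, "heavy") <- atom_selection(seq_len(n_heavy), "heavy")
  attr(traj, "hydrogens") <- atom_selection(n_heavy + seq_len(n_h), "hydrogens")
  traj
}
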