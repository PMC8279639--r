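# Solvation-structure and proton-transfer diagnostics: finite-droplet RDFs,
# coordination numbers, distance/dihedral series, proton-hop and hydronium
# event detection. All criteria are distance-based (no angular
# hydrogen-bond terms).

.frame_coords <- function(traj, f) matrix(traj$positions[f, , ], ncol = 3)

#' Radial distribution function between two atom selections
#'
#' Histograms A-B distances over all frames and normalizes per A atom by the
#' ideal-gas shell count rho0 4 pi r^2 dr. The system is a finite droplet,
#' not a periodic box: with \code{rho0 = "auto"} the reference density is
#' count(B) divided by the volume of the bounding sphere of B's time-mean
#' positions, and g(r) decays to zero near the droplet edge (no
#' excluded-volume correction is applied).
#'
#' @param traj a [trajectory()]
#' @param selA,selB [atom_selection()]s (or index vectors); must be disjoint
#'   or identical
#' @param r_max histogram range, Angstrom
#' @param bin_width bin width, Angstrom
#' @param rho0 reference number density in Angstrom^-3, or \code{"auto"}
#' @return object of class \code{rdf_result}: list with \code{r} (bin
#'   centers), \code{g}, \code{n} (running coordination number),
#'   \code{rho0}
#' @export
rdf <- function(traj, selA, selB, r_max, bin_width, rho0 = "auto") {
  ia <- .sel_indices(selA, traj$natoms)
  ib <- .sel_indices(selB, traj$natoms)
  identical_sel <- setequal(ia, ib)
  if (!identical_sel && length(intersect(ia, ib)) > 0)
    stop("selections must be disjoint or identical")
  if (r_max <= bin_width) stop("r_max must exceed bin_width")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (f in seq_len(traj$nframes)) {
    co <- .frame_coords(traj, f)
    a <- co[ia, , drop = FALSE]; b <- co[ib, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    d <- sqrt(pmax(d2, 0))
    if (identical_sel) d[cbind(seq_along(ia), seq_along(ia))] <- NA
    d <- d[!is.na(d) & d < edges[nb + 1L]]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges, left.open = TRUE), nb)
  }
  if (identical(rho0, "auto")) {
    # bounding-sphere radius of the B selection, averaged over frames
    # (a single static frame reduces to the spread of the mean structure).
    # The sphere is centered on the per-axis midrange, a cheap and nearly
    # unbiased approximation to the minimal enclosing sphere.
    R <- mean(vapply(seq_len(traj$nframes), function(f) {
      b <- .frame_coords(traj, f)[ib, , drop = FALSE]
      ctr <- (apply(b, 2, max) + apply(b, 2, min)) / 2
      max(sqrt(rowSums(sweep(b, 2, ctr)^2)))
    }, numeric(1)))
    if (R <= 0) stop("cannot auto-estimate rho0 from a degenerate B selection")
    rho0 <- length(ib) / (4 / 3 * pi * R^3)
  }
  r_mid <- (edges[-1] + edges[-(nb + 1L)]) / 2
  shell <- rho0 * 4 * pi * r_mid^2 * bin_width
  per_a <- counts / (traj$nframes * length(ia))
  g <- per_a / shell
  structure(list(r = r_mid, g = g, n = cumsum(per_a), rho0 = rho0),
            class = "rdf_result")
}

#' Coordination number from an RDF
#'
#' Evaluates the running integral n(r) of the RDF at \code{r_cut} by linear
#' interpolation; this is the paper-style "integrate the first peak" count
#' of neighbours within the cutoff.
#'
#' @param rdfres an \code{rdf_result}
#' @param r_cut cutoff radius, Angstrom; must lie within the histogram range
#' @return average neighbour count (waters) within \code{r_cut}
#' @export
coordination_number <- function(rdfres, r_cut) {
  if (r_cut < 0 || r_cut > max(rdfres$r) + (rdfres$r[2] - rdfres$r[1]) / 2)
    stop("r_cut outside the RDF range")
  # n is cumulative at the right edge of each bin
  dr <- rdfres$r[2] - rdfres$r[1]
  edges <- rdfres$r + dr / 2
  stats::approx(c(0, edges), c(0, rdfres$n), xout = r_cut, rule = 2)$y
}

#' Interatomic distance time series
#'
#' @param traj a [trajectory()]
#' @param i,j distinct 1-based atom indices
#' @return numeric vector, Angstrom per frame
#' @export
distance_series <- function(traj, i, j) {
  if (i == j) stop("i and j must differ")
  if (any(c(i, j) < 1 | c(i, j) > traj$natoms)) stop("atom index out of range")
  d <- traj$positions[, i, , drop = FALSE] - traj$positions[, j, , drop = FALSE]
  sqrt(rowSums(matrix(d, ncol = 3)^2))
}

# signed IUPAC dihedral (degrees) of one frame; NA when a triple is collinear
.dihedral1 <- function(p1, p2, p3, p4, tol = 1e-10) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < tol * nb2 || sqrt(sum(n2^2)) < tol * nb2) return(NA_real_)
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(cr * b2) / nb2, sum(n1 * n2)) * 180 / pi
}

#' Unwrap an angle series across the +-180 degree seam
#'
#' Minimal-jump continuation: each value is shifted by a multiple of 360 so
#' consecutive differences stay below 180 degrees in magnitude. NA values
#' (undefined frames) are passed through and the continuation resumes from
#' the last defined value.
#'
#' @param deg angle series in degrees
#' @return unwrapped series, degrees
#' @export
unwrap_angles <- function(deg) {
  out <- deg
  last <- NA_real_
  for (i in seq_along(deg)) {
    if (is.na(deg[i])) next
    if (!is.na(last)) out[i] <- deg[i] + 360 * round((last - deg[i]) / 360)
    last <- out[i]
  }
  out
}

#' Dihedral angle time series
#'
#' Signed IUPAC dihedral (cis = 0, trans = +-180) of atoms i-j-k-l per
#' frame, unwrapped with minimal-jump continuation so a series oscillating
#' about planarity reports a mean near 180 degrees instead of jumping
#' between +180 and -180. Frames with a collinear triple yield NA and are
#' flagged, not dropped.
#'
#' @param traj a [trajectory()]
#' @param i,j,k,l four distinct 1-based atom indices
#' @return object of class \code{dihedral_series}: list with \code{atoms},
#'   \code{values} (degrees, unwrapped), \code{raw} (wrapped degrees),
#'   \code{undefined} (logical per frame)
#' @export
dihedral_series <- function(traj, i, j, k, l) {
  idx <- c(i, j, k, l)
  if (anyDuplicated(idx)) stop("the four atom indices must be distinct")
  if (any(idx < 1 | idx > traj$natoms)) stop("atom index out of range")
  raw <- vapply(seq_len(traj$nframes), function(f) {
    co <- .frame_coords(traj, f)
    .dihedral1(co[i, ], co[j, ], co[k, ], co[l, ])
  }, numeric(1))
  structure(list(atoms = idx, values = unwrap_angles(raw), raw = raw,
                 undefined = is.na(raw)),
            class = "dihedral_series")
}

#' Assign each hydrogen to its nearest heavy atom
#'
#' @param coords N x 3 coordinate matrix of one frame, Angstrom
#' @param hydrogens,heavy [atom_selection()]s (or index vectors)
#' @param r_bond covalent-bond cutoff, Angstrom; a hydrogen farther than
#'   this from every heavy atom is left unassigned (NA)
#' @return data.frame with columns \code{hydrogen}, \code{heavy} (NA if
#'   unassigned), \code{distance}; ties go to the lowest heavy-atom index
#' @export
assign_protons <- function(coords, hydrogens, heavy, r_bond = 1.3) {
  n <- nrow(coords)
  ih <- .sel_indices(hydrogens, n)
  io <- .sel_indices(heavy, n)
  hpos <- coords[ih, , drop = FALSE]; opos <- coords[io, , drop = FALSE]
  d2 <- outer(rowSums(hpos^2), rowSums(opos^2), `+`) - 2 * hpos %*% t(opos)
  d <- sqrt(pmax(d2, 0))
  best <- apply(d, 1, which.min)   # which.min takes the first (lowest index) on ties
  dist <- d[cbind(seq_along(ih), best)]
  assigned <- io[best]
  assigned[dist > r_bond] <- NA_integer_
  data.frame(hydrogen = ih, heavy = assigned, distance = dist)
}

# per-frame nearest-heavy assignment matrix (nframes x nH); NA beyond r_bond
.assignment_matrix <- function(traj, hydrogens, heavy, r_bond) {
  ih <- .sel_indices(hydrogens, traj$natoms)
  A <- vapply(seq_len(traj$nframes), function(f)
    assign_protons(.frame_coords(traj, f), hydrogens, heavy, r_bond)$heavy,
    integer(length(ih)))
  t(matrix(A, nrow = length(ih)))
}

#' Detect proton-transfer events in a trajectory
#'
#' Tracks the nearest-heavy-atom assignment of each hydrogen frame by frame
#' (cutoff \code{r_bond}; frames where a hydrogen is momentarily beyond the
#' cutoff of every heavy atom, as happens mid-hop, inherit the previous
#' assignment). An event opens when the assignment changes and closes when
#' it changes again or the trajectory ends; a hop that returns to its donor
#' is one round-trip event, not two. An event is \code{"permanent"} when
#' the new assignment persists at least \code{t_permanent} and ends either
#' with the trajectory or with an onward transfer to a third heavy atom; a
#' return to the donor, or a shorter stay, is \code{"transient"}.
#'
#' @param traj a [trajectory()]
#' @param hydrogens,heavy [atom_selection()]s (or index vectors)
#' @param r_bond covalent cutoff, Angstrom (default 1.3)
#' @param t_permanent persistence threshold, fs (default 100, the
#'   hydronium-lifetime scale)
#' @return data.frame with columns \code{hydrogen}, \code{from_atom},
#'   \code{to_atom}, \code{t_start}, \code{t_end} (fs), \code{kind};
#'   ordered by \code{t_start}. Zero rows when no reassignment occurs.
#' @export
detect_pt_events <- function(traj, hydrogens, heavy, r_bond = 1.3,
                             t_permanent = 100) {
  A <- .assignment_matrix(traj, hydrogens, heavy, r_bond)
  tgrid <- frame_times(traj)
  ih <- .sel_indices(hydrogens, traj$natoms)
  ev <- list()
  for (h in seq_along(ih)) {
    a <- A[, h]
    for (f in seq_along(a)[-1]) if (is.na(a[f])) a[f] <- a[f - 1]
    if (is.na(a[1])) {
      first <- which(!is.na(a))[1]
      if (is.na(first)) next
      a[seq_len(first)] <- a[first]
    }
    ch <- which(a[-1] != a[-length(a)]) + 1L   # frames where assignment changes
    if (length(ch) == 0) next
    # excursion tracking: a change away from the current home atom opens an
    # event; a change back closes it as a round trip (transient), an onward
    # change closes it and opens the next leg
    home <- a[1]
    open_f <- NA_integer_
    close_event <- function(f_close, ended_by_end, onward) {
      from <- a[open_f - 1L]; to <- a[open_f]
      dur <- tgrid[if (ended_by_end) length(a) else f_close] - tgrid[open_f]
      kind <- if (dur >= t_permanent && (ended_by_end || onward))
        "permanent" else "transient"
      data.frame(hydrogen = ih[h], from_atom = from, to_atom = to,
                 t_start = tgrid[open_f],
                 t_end = tgrid[if (ended_by_end) length(a) else f_close],
                 kind = kind)
    }
    for (f0 in ch) {
      if (is.na(open_f)) {            # leaving home
        open_f <- f0
      } else if (a[f0] == home) {     # round trip back to the donor
        ev[[length(ev) + 1L]] <- close_event(f0, FALSE, FALSE)
        open_f <- NA_integer_
      } else {                        # onward transfer: new home is the donor
        ev[[length(ev) + 1L]] <- close_event(f0, FALSE, TRUE)
        home <- a[open_f]
        open_f <- f0
      }
    }
    if (!is.na(open_f))
      ev[[length(ev) + 1L]] <- close_event(length(a), TRUE, FALSE)
  }
  if (length(ev) == 0)
    return(data.frame(hydrogen = integer(), from_atom = integer(),
                      to_atom = integer(), t_start = numeric(),
                      t_end = numeric(), kind = character()))
  out <- do.call(rbind, ev)
  out[order(out$t_start, out$hydrogen), , drop = FALSE]
}

#' Hydronium occupancy and lifetimes
#'
#' An oxygen is a hydronium at a frame iff exactly three hydrogens are
#' assigned to it (nearest heavy atom within \code{r_bond}). Lifetimes are
#' the maximal consecutive hydronium runs times the timestep.
#'
#' @param traj a [trajectory()]
#' @param oxygens,hydrogens [atom_selection()]s (or index vectors)
#' @param r_bond covalent cutoff, Angstrom (default 1.3)
#' @return list with \code{is_hydronium} (nframes x n_oxygens logical
#'   matrix, columns named by oxygen index) and \code{lifetimes}
#'   (data.frame: \code{oxygen}, \code{t_start} fs, \code{lifetime} fs)
#' @export
hydronium_series <- function(traj, oxygens, hydrogens, r_bond = 1.3) {
  io <- .sel_indices(oxygens, traj$natoms)
  A <- .assignment_matrix(traj, hydrogens, oxygens, r_bond)
  flags <- vapply(io, function(o) rowSums(A == o, na.rm = TRUE) == 3,
                  logical(traj$nframes))
  flags <- matrix(flags, nrow = traj$nframes,
                  dimnames = list(NULL, as.character(io)))
  lt <- list()
  for (k in seq_along(io)) {
    r <- rle(flags[, k])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      lt[[length(lt) + 1L]] <- data.frame(
        oxygen = io[k], t_start = (starts[j] - 1) * traj$dt,
        lifetime = r$lengths[j] * traj$dt)
    }
  }
  lifetimes <- if (length(lt)) do.call(rbind, lt) else
    data.frame(oxygen = integer(), t_start = numeric(), lifetime = numeric())
  list(is_hydronium = flags,
       lifetimes = lifetimes[order(lifetimes$t_start), , drop = FALSE])
}
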