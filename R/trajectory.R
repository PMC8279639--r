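# Trajectory container and extended-XYZ input/output.

# Standard atomic weights (amu) for elements commonly found in organic
# photoacid / aqueous-cluster simulations.
.ATOMIC_MASSES <- c(
  H = 1.008, D = 2.014, He = 4.002602,
  Li = 6.94, Be = 9.0121831, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998403, Ne = 20.1797,
  Na = 22.98976928, Mg = 24.305, Al = 26.9815385, Si = 28.085,
  P = 30.973762, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.0983, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  Br = 79.904, I = 126.90447
)

#' Look up standard atomic weights
#'
#' @param elements character vector of element symbols
#' @param override optional named numeric vector of masses (amu) that takes
#'   precedence over the built-in table; use it for custom site labels
#'   (e.g. \code{c(Ow = 15.9994)})
#' @return numeric vector of masses in amu
#' @export
atomic_masses <- function(elements, override = NULL) {
  tab <- .ATOMIC_MASSES
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop("mass override table must be a named numeric vector")
    tab[names(override)] <- override
  }
  m <- unname(tab[elements])
  if (anyNA(m)) {
    bad <- unique(elements[is.na(m)])
    stop("no mass known for element(s): ", paste(bad, collapse = ", "),
         " (supply an override table)")
  }
  m
}

#' Read a plain-text mass override table
#'
#' Each non-comment line holds an element label and a mass in amu,
#' whitespace separated.
#'
#' @param path file path
#' @return named numeric vector of masses
#' @export
read_mass_table <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  vapply(parts, function(p) {
    if (length(p) < 2) stop("malformed mass table line: ", paste(p, collapse = " "))
    stats::setNames(as.numeric(p[2]), p[1])
  }, numeric(1)) -> m
  names(m) <- vapply(parts, `[[`, character(1), 1)
  m
}

#' Construct a trajectory object
#'
#' A \code{trajectory} holds per-frame Cartesian positions (Angstrom) and
#' velocities (Angstrom/fs) for a fixed set of atoms, together with the
#' timestep (fs) and per-atom masses (amu).
#'
#' @param elements character vector of N element symbols
#' @param positions numeric array of dim (nframes, N, 3), Angstrom
#' @param velocities numeric array of dim (nframes, N, 3), Angstrom/fs
#' @param dt timestep in fs (> 0)
#' @param masses optional numeric vector of N masses in amu; looked up from
#'   \code{elements} when omitted
#' @param mass_override optional named vector passed to [atomic_masses()]
#' @return object of class \code{trajectory}
#' @export
trajectory <- function(elements, positions, velocities, dt,
                       masses = NULL, mass_override = NULL) {
  if (length(dim(positions)) != 3 || length(dim(velocities)) != 3)
    stop("positions and velocities must be (nframes, N, 3) arrays")
  if (!identical(dim(positions), dim(velocities)))
    stop("positions and velocities must have identical shape")
  n <- dim(positions)[2]
  if (dim(positions)[3] != 3) stop("last dimension must be 3 (x, y, z)")
  if (length(elements) != n)
    stop("element list length (", length(elements),
         ") does not match atom count (", n, ")")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a single value > 0")
  if (dim(positions)[1] < 1) stop("trajectory needs at least one frame")
  if (is.null(masses)) masses <- atomic_masses(elements, mass_override)
  if (length(masses) != n) stop("masses length does not match atom count")
  if (any(masses <= 0)) stop("all masses must be > 0")
  structure(list(
    elements = as.character(elements),
    masses = as.numeric(masses),
    positions = positions,
    velocities = velocities,
    dt = dt,
    nframes = dim(positions)[1],
    natoms = n
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, dt = %g fs (%g fs total)\n",
              x$nframes, x$natoms, x$dt, (x$nframes - 1) * x$dt))
  cat("elements:", paste(utils::head(x$elements, 10), collapse = " "),
      if (x$natoms > 10) "..." else "", "\n")
  invisible(x)
}

#' Frame times of a trajectory
#'
#' @param traj a [trajectory()]
#' @return numeric vector, fs; frame f is at (f-1)*dt
#' @export
frame_times <- function(traj) (seq_len(traj$nframes) - 1) * traj$dt

#' An atom selection
#'
#' @param indices 1-based atom indices
#' @param label free-text role tag (e.g. "O_pyr")
#' @param n optional atom count for bounds checking
#' @return object of class \code{atom_selection}
#' @export
atom_selection <- function(indices, label = "", n = NULL) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (any(indices < 1)) stop("selection indices must be >= 1")
  if (!is.null(n) && any(indices > n))
    stop("selection index out of range (N = ", n, ")")
  structure(list(indices = indices, label = label), class = "atom_selection")
}

.sel_indices <- function(sel, n) {
  if (inherits(sel, "atom_selection")) idx <- sel$indices else idx <- as.integer(sel)
  if (length(idx) == 0) stop("empty atom selection")
  if (any(idx < 1 | idx > n)) stop("selection index out of range (N = ", n, ")")
  idx
}

# parse a Properties=species:S:1:pos:R:3:vel:R:3 descriptor into column slots
.parse_properties <- function(comment) {
  m <- regmatches(comment, regexpr("Properties=\\S+", comment))
  if (length(m) == 0) return(NULL)
  fields <- strsplit(sub("Properties=", "", m), ":")[[1]]
  if (length(fields) %% 3 != 0) return(NULL)
  col <- 1L
  slots <- list()
  for (k in seq(1, length(fields), by = 3)) {
    nm <- fields[k]; w <- as.integer(fields[k + 2])
    slots[[nm]] <- col:(col + w - 1L)
    col <- col + w
  }
  slots
}

#' Read an extended-XYZ trajectory with velocities
#'
#' Each frame block is: atom count, comment line, then one line per atom.
#' When the comment line carries a \code{Properties=} descriptor the
#' \code{species}/\code{pos}/\code{vel} (or \code{velo}/\code{velocities})
#' columns are honored; otherwise atom lines are read positionally as
#' element, x, y, z (Angstrom), vx, vy, vz (Angstrom/fs). Velocities are
#' required. The timestep is never inferred from the file.
#'
#' @param path file path
#' @param dt timestep in fs
#' @param mass_override optional named vector of masses (amu) overriding the
#'   standard-atomic-weight lookup
#' @return a [trajectory()]
#' @export
read_extxyz <- function(path, dt, mass_override = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) < 3) stop("not an extended-XYZ file: ", path)
  pos_list <- list(); vel_list <- list()
  elements <- NULL
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1)
      stop("bad atom count at line ", i, " of ", path)
    frame <- frame + 1L
    if (i + 1L + nat > length(lines))
      stop("truncated frame ", frame, " in ", path)
    comment <- lines[i + 1L]
    slots <- .parse_properties(comment)
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol <- unique(lengths(toks))
    if (length(ncol) != 1)
      stop("ragged atom lines in frame ", frame, " of ", path)
    if (is.null(slots)) {
      if (ncol < 7)
        stop("missing velocity columns in frame ", frame,
             " (need element + 3 position + 3 velocity columns)")
      sp_col <- 1L; pos_cols <- 2:4; vel_cols <- 5:7
    } else {
      vel_key <- intersect(c("vel", "velo", "velocities"), names(slots))
      if (length(vel_key) == 0)
        stop("missing velocity columns in frame ", frame,
             " (no vel property declared)")
      sp_col <- slots[["species"]][1]
      pos_cols <- slots[["pos"]]
      vel_cols <- slots[[vel_key[1]]]
      if (is.null(sp_col) || length(pos_cols) != 3 || length(vel_cols) != 3)
        stop("unsupported Properties layout in frame ", frame)
      if (ncol < max(vel_cols, pos_cols, sp_col))
        stop("missing velocity columns in frame ", frame)
    }
    el <- vapply(toks, `[[`, character(1), sp_col)
    if (is.null(elements)) {
      elements <- el
    } else {
      if (nat != length(elements))
        stop("inconsistent atom count in frame ", frame, " (", nat,
             " vs ", length(elements), " in frame 1)")
      if (!identical(el, elements))
        stop("atom ordering changes in frame ", frame)
    }
    num <- vapply(toks, function(tk) as.numeric(tk[c(pos_cols, vel_cols)]),
                  numeric(6))
    pos_list[[frame]] <- t(num[1:3, , drop = FALSE])
    vel_list[[frame]] <- t(num[4:6, , drop = FALSE])
    i <- i + 2L + nat
  }
  nat <- length(elements)
  pos <- array(0, c(frame, nat, 3)); vel <- array(0, c(frame, nat, 3))
  for (f in seq_len(frame)) { pos[f, , ] <- pos_list[[f]]; vel[f, , ] <- vel_list[[f]] }
  trajectory(elements, pos, vel, dt, mass_override = mass_override)
}

#' Write a trajectory to extended-XYZ
#'
#' Emits a \code{Properties=species:S:1:pos:R:3:vel:R:3} header per frame and
#' prints coordinates/velocities with 17 significant digits so that
#' \code{read_extxyz(write_extxyz(traj))} round-trips to full precision.
#'
#' @param traj a [trajectory()]
#' @param path output file path
#' @return invisibly, \code{path}
#' @export
write_extxyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- "Properties=species:S:1:pos:R:3:vel:R:3"
  for (f in seq_len(traj$nframes)) {
    writeLines(as.character(traj$natoms), con)
    writeLines(sprintf("%s Time=%.10g", hdr, (f - 1) * traj$dt), con)
    pv <- cbind(traj$positions[f, , , drop = TRUE], traj$velocities[f, , , drop = TRUE])
    if (traj$natoms == 1) pv <- matrix(pv, nrow = 1)
    writeLines(paste(traj$elements,
                     apply(pv, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))),
               con)
  }
  invisible(path)
}
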