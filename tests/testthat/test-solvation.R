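test_that("rdf of a delta-distance pair lands in one bin and n(r) counts it", {
  tr <- static_pair(2.65)
  res <- rdf(tr, 1, 2, r_max = 4, bin_width = 0.1, rho0 = 0.03)
  hot <- which(res$g > 0)
  expect_length(hot, 1)
  expect_true(res$r[hot] - 0.05 <= 2.65 && 2.65 <= res$r[hot] + 0.05)
  expect_equal(coordination_number(res, 3.0), 1.0)
  expect_error(rdf(tr, integer(0), 2, 4, 0.1, 0.03), "empty")
  expect_error(rdf(tr, 1:2, 2, 4, 0.1, 0.03), "disjoint")
  expect_error(coordination_number(res, 10), "range")
})

test_that("uniform droplet with auto density gives g ~ 1 in inner bins", {
  tr <- make_droplet(4000, radius = 19, seed = 5, nframes = 150,
                     center_atom = TRUE)
  res <- rdf(tr, 1, 2:4001, r_max = 10, bin_width = 0.5)
  expect_equal(res$rho0, 4000 / (4 / 3 * pi * 19^3), tolerance = 0.05)
  inner <- res$r > 4 & res$r < 9.5
  expect_gt(sum(inner), 5)
  expect_lt(max(abs(res$g[inner] - 1)), 0.05)
})

test_that("n(r) equals the exact neighbour count for fixed configurations", {
  # k fixed neighbours at distinct radii inside the cutoff
  k <- 4
  pos <- array(0, c(3, k + 1, 3))
  radii <- c(1.1, 1.9, 2.4, 3.2)
  for (j in seq_len(k)) pos[, j + 1, 1] <- radii[j]
  tr <- trajectory(rep("X", k + 1), pos, array(0, dim(pos)), 1,
                   masses = rep(1, k + 1))
  res <- rdf(tr, 1, 2:(k + 1), r_max = 5, bin_width = 0.1, rho0 = 0.05)
  expect_equal(coordination_number(res, 4.0), k)
  expect_equal(coordination_number(res, 2.0), 2)

  # Poisson-placed neighbours: n(R) ~ rho * 4/3 pi R^3
  tr2 <- make_droplet(3000, radius = 12, seed = 21, nframes = 50,
                      center_atom = TRUE)
  rho <- 3000 / (4 / 3 * pi * 12^3)
  res2 <- rdf(tr2, 1, 2:3001, r_max = 8, bin_width = 0.2, rho0 = rho)
  expect_equal(coordination_number(res2, 6), rho * 4 / 3 * pi * 6^3,
               tolerance = 0.03)
})

test_that("distance series are exact and reject degenerate input", {
  tr <- static_pair(1.78)
  expect_equal(distance_series(tr, 1, 2), rep(1.78, tr$nframes))
  expect_error(distance_series(tr, 2, 2), "differ")

  nf <- 10
  pos <- array(0, c(nf, 2, 3))
  pos[, 2, 1] <- 1 + 0.1 * (0:(nf - 1))
  tr2 <- trajectory(c("X", "X"), pos, array(0, dim(pos)), 1, masses = c(1, 1))
  expect_equal(distance_series(tr2, 1, 2), 1 + 0.1 * (0:(nf - 1)))
})

test_that("dihedral angles match constructed geometries and bio3d's sign", {
  for (ang in c(0, 180, 60, -60, 123.4)) {
    tr <- dihedral_traj(list(dihedral_geometry(ang)))
    got <- dihedral_series(tr, 1, 2, 3, 4)$values
    want <- if (ang == 180) 180 else ang   # unwrap leaves the seam at +180
    expect_equal(abs(got), abs(want), tolerance = 1e-6)
    # independent oracle for the sign convention
    ref <- bio3d::torsion.xyz(as.vector(t(dihedral_geometry(ang))), atm.inc = 4)
    expect_equal(((got - ref + 180) %% 360) - 180, 0, tolerance = 1e-6)
  }

  # mirror image negates the dihedral (chirality check)
  g <- dihedral_geometry(47)
  gm <- g; gm[, 3] <- -gm[, 3]
  d1 <- dihedral_series(dihedral_traj(list(g)), 1, 2, 3, 4)$values
  d2 <- dihedral_series(dihedral_traj(list(gm)), 1, 2, 3, 4)$values
  expect_equal(d1, -d2, tolerance = 1e-10)

  # unwrapping continues across the +-180 seam
  tr2 <- dihedral_traj(list(dihedral_geometry(179), dihedral_geometry(-179)))
  ds <- dihedral_series(tr2, 1, 2, 3, 4)
  expect_equal(ds$values, c(179, 181), tolerance = 1e-6)
  expect_equal(unwrap_angles(c(179, -179)), c(179, 181))

  # collinear triple is flagged, not dropped
  gcol <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  ds2 <- dihedral_series(dihedral_traj(list(gcol, dihedral_geometry(30))),
                         1, 2, 3, 4)
  expect_identical(ds2$undefined, c(TRUE, FALSE))
  expect_true(is.na(ds2$values[1]))
  expect_error(dihedral_series(tr2, 1, 2, 3, 3), "distinct")
})

test_that("protons are assigned to the nearest heavy atom with tie-breaks", {
  co <- rbind(c(0, 0, 0), c(2.6, 0, 0), c(1.0, 0, 0), c(1.3, 2.5, 0))
  out <- assign_protons(co, hydrogens = 3:4, heavy = 1:2, r_bond = 1.3)
  expect_equal(out$heavy[1], 1)          # 1.0 A from atom 1, 1.6 from atom 2
  expect_true(is.na(out$heavy[2]))       # beyond r_bond everywhere
  # equidistant -> lowest heavy index
  co2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))
  expect_equal(assign_protons(co2, 3, 1:2, r_bond = 1.3)$heavy, 1)
})

test_that("scripted hops are detected frame-exactly and classified", {
  tr <- make_pt_script(list(list(hydrogen = 1, from = 1, to = 2,
                                 t_hop = 800, return_after = Inf)),
                       dt = 0.2, nframes = 5001)
  ev <- detect_pt_events(tr, attr(tr, "hydrogens"), attr(tr, "heavy"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_start, 800)
  expect_equal(ev$kind, "permanent")
  expect_equal(ev$from_atom, 1)
  expect_equal(ev$to_atom, 2)

  tr2 <- make_pt_script(list(list(hydrogen = 1, from = 1, to = 2,
                                  t_hop = 300, return_after = 20)),
                        dt = 0.2, nframes = 5001)
  ev2 <- detect_pt_events(tr2, attr(tr2, "hydrogens"), attr(tr2, "heavy"))
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$kind, "transient")

  # three brief hops then none
  tr3 <- make_pt_script(list(
    list(hydrogen = 1, from = 1, to = 2, t_hop = 300, return_after = 12),
    list(hydrogen = 1, from = 1, to = 2, t_hop = 620, return_after = 18),
    list(hydrogen = 1, from = 1, to = 2, t_hop = 850, return_after = 8)),
    dt = 0.2, nframes = 6001)
  ev3 <- detect_pt_events(tr3, attr(tr3, "hydrogens"), attr(tr3, "heavy"))
  expect_equal(nrow(ev3), 3)
  expect_equal(ev3$t_start, c(300, 620, 850))
  expect_true(all(ev3$kind == "transient"))

  # no reassignment -> empty table
  ev0 <- detect_pt_events(static_pair(2.0), 2, 1)
  expect_equal(nrow(ev0), 0)
})

test_that("event assignments agree with a brute-force oracle", {
  tr <- make_pt_script(list(
    list(hydrogen = 1, from = 1, to = 2, t_hop = 100, return_after = 30),
    list(hydrogen = 2, from = 2, to = 3, t_hop = 250, return_after = Inf),
    list(hydrogen = 1, from = 1, to = 2, t_hop = 400, return_after = Inf)),
    dt = 0.5, nframes = 1201)
  ih <- attr(tr, "hydrogens")$indices
  io <- attr(tr, "heavy")$indices
  A <- oracle_assignments(tr, ih, io, r_bond = 1.3)
  ev <- detect_pt_events(tr, ih, io)
  # every event boundary must coincide with an oracle assignment change
  for (r in seq_len(nrow(ev))) {
    h <- match(ev$hydrogen[r], ih)
    f0 <- round(ev$t_start[r] / tr$dt) + 1
    expect_equal(A[f0, h], ev$to_atom[r])
    expect_equal(A[f0 - 1, h], ev$from_atom[r])
  }
  expect_equal(nrow(ev), 3)
  expect_equal(ev$hydrogen, ih[c(1, 2, 1)])
  expect_equal(ev$to_atom, c(2, 3, 2))
  expect_equal(ev$kind, c("transient", "permanent", "permanent"))
})

test_that("hydronium occupancy and lifetimes follow run-length arithmetic", {
  # O with 3 H at 1.0 A for 500 frames, dt = 0.2 -> one 100 fs lifetime
  p <- array(0, c(500, 4, 3))
  p[, 2, 1] <- 1.0; p[, 3, 2] <- 1.0; p[, 4, 3] <- 1.0
  tr <- trajectory(c("O", "H", "H", "H"), p, array(0, dim(p)), 0.2)
  hs <- hydronium_series(tr, 1, 2:4)
  expect_true(all(hs$is_hydronium[, 1]))
  expect_equal(hs$lifetimes$lifetime, 100)

  # water (2 H) never flags
  hs2 <- hydronium_series(tr, 1, 2:3)
  expect_false(any(hs2$is_hydronium))
  expect_equal(nrow(hs2$lifetimes), 0)

  # two disjoint runs of 10 and 20 frames at dt = 0.2 -> 2 and 4 fs
  p3 <- array(0, c(50, 4, 3))
  p3[, 2, 1] <- 1.0; p3[, 3, 2] <- 1.0
  p3[, 4, 3] <- 5.0                       # third H far away by default
  p3[11:20, 4, 3] <- 1.0
  p3[31:50, 4, 3] <- 1.0
  tr3 <- trajectory(c("O", "H", "H", "H"), p3, array(0, dim(p3)), 0.2)
  hs3 <- hydronium_series(tr3, 1, 2:4)
  expect_equal(hs3$lifetimes$lifetime, c(2, 4))
  expect_equal(hs3$lifetimes$t_start, c(2, 6))
})
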