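test_that("minimum-image distances handle direct and wrapped separations", {
  mol <- rbind(c(0, 0, 5), c(1.4, 0, 5), c(0, 1.4, 5))
  surf <- rbind(c(0, 0, 1))
  fr <- make_test_frame(mol, surf, box = c(1000, 1000, 1000))
  expect_equal(min_surface_distance(fr), 4.0)
  # wraparound across the 41.44 A axis
  mol2 <- rbind(c(1, 5, 5), c(2.4, 5, 5), c(1, 6.4, 5))
  surf2 <- rbind(c(40.44, 5, 5))
  fr2 <- make_test_frame(mol2, surf2, box = c(41.44, 35.88, 62.5))
  expect_equal(min_surface_distance(fr2), 2.0)
})

test_that("distance and charge agree with the all-images brute-force oracle", {
  set.seed(13)
  for (i in 1:25) {
    fr <- random_frame()
    expect_lt(abs(min_surface_distance(fr) -
                    brute_min_surface_distance(fr)), 1e-10)
    expect_lt(abs(as.numeric(complex_charge(fr)) -
                    brute_complex_charge(fr)), 1e-10)
  }
})

test_that("the adsorption cutoff is inclusive and tilt decides the sub-state", {
  surf <- as.matrix(expand.grid(seq(0, 39, 3), seq(0, 33, 3)))
  surf <- cbind(surf, 1)
  at <- function(d, tilt) {
    ring <- ring_coords(c(6, 6, 1 + d + 1.2 * sin(tilt * pi / 180) * 0),
                        tilt_deg = tilt)
    # lift so the lowest ring atom is exactly d above the surface plane
    ring[, 3] <- ring[, 3] - min(ring[, 3]) + 1 + d
    ring[which.min(ring[, 3]), 1:2] <- c(6, 6)  # above the atom at (6,6)
    make_test_frame(ring, surf)
  }
  # exactly at 4.0 A: adsorbed (inclusive rule), flat ring -> parallel
  cl <- classify_state(at(4.0, 0))
  expect_equal(cl$state, 2L)
  expect_equal(cl$min_dist, 4.0)
  expect_lt(cl$tilt, 1e-6)
  # just above the cutoff: free
  expect_equal(classify_state(at(4.05, 0))$state, 0L)
  # perpendicular ring at 3 A: adsorbed non-parallel
  cl1 <- classify_state(at(3, 90))
  expect_equal(cl1$state, 1L)
  expect_gt(cl1$tilt, 89)
  # collinear ring atoms are rejected
  line <- cbind(seq(0, 4, length.out = 5), 0, 8)
  fr_line <- make_test_frame(line, surf)
  expect_error(classify_state(fr_line), "collinear")
})

test_that("classification is invariant to atom order and box translations", {
  tr <- gen_trajectory(3, "na", n_frames = 4, jitter = 0)
  fr <- tr$frames[[2]]
  base <- classify_state(fr)
  # permute atoms
  perm <- sample(nrow(fr$coords))
  inv <- order(perm)
  fr_p <- traj_frame(fr$time, fr$box, fr$coords[perm, ], fr$roles[perm],
                     fr$charges[perm], ring_atoms = inv[fr$ring_atoms],
                     elements = fr$elements[perm])
  expect_equal(classify_state(fr_p)$state, base$state)
  expect_equal(classify_state(fr_p)$min_dist, base$min_dist)
  # rigid translation by whole box vectors
  fr_t <- fr
  fr_t$coords <- sweep(fr$coords, 2, 2 * fr$box, "+")
  expect_equal(classify_state(fr_t)$min_dist, base$min_dist,
               tolerance = 1e-9)
  expect_equal(classify_state(fr_t)$state, base$state)
})

test_that("complex charge follows the declared counting convention", {
  surf <- cbind(as.matrix(expand.grid(seq(0, 12, 3), seq(0, 12, 3))), 1)
  ring <- ring_coords(c(6, 6, 10))
  # three monovalent cations within 4 A of ring atoms, molecule net -2
  ions <- rbind(c(6, 6, 12.5), c(7, 6, 12), c(5, 6, 12))
  fr <- make_test_frame(ring, surf, ion_xyz = ions,
                        ion_charge = c(1, 1, 1))
  expect_equal(as.numeric(complex_charge(fr)), -2 + 3)
  # same ions parked far away: molecule charge only
  fr2 <- make_test_frame(ring, surf, ion_xyz = ions + 25,
                         ion_charge = c(1, 1, 1))
  expect_equal(as.numeric(complex_charge(fr2)), -2)
  expect_match(attr(complex_charge(fr), "convention"), "ion_cutoff")
})

test_that("duration ratio counts adsorbed versus free frames", {
  surf <- cbind(as.matrix(expand.grid(seq(0, 12, 3), seq(0, 12, 3))), 1)
  near <- ring_coords(c(6, 6, 4))   # min dist 3 A -> adsorbed
  far <- ring_coords(c(6, 6, 16))   # 15 A -> free
  frames <- c(
    lapply(1:40, function(i) make_test_frame(near, surf)),
    lapply(1:100, function(i) make_test_frame(far, surf)))
  frames <- Map(function(f, t) { f$time <- t * 0.05; f }, frames,
                seq_along(frames))
  ss <- state_series(frames)
  expect_equal(ss$duration_ratio, 0.4)
  expect_false(ss$ratio_infinite)
  # all adsorbed -> infinite ratio with flag
  ss2 <- state_series(lapply(1:5, function(i) make_test_frame(near, surf)))
  expect_true(ss2$ratio_infinite)
  expect_identical(ss2$duration_ratio, Inf)
})

test_that("short dwell segments can be relabelled to the flanking state", {
  surf <- cbind(as.matrix(expand.grid(seq(0, 12, 3), seq(0, 12, 3))), 1)
  near <- ring_coords(c(6, 6, 4)); far <- ring_coords(c(6, 6, 16))
  seqs <- c(rep(list(near), 10), list(far), rep(list(near), 10))
  frames <- lapply(seqs, function(m) make_test_frame(m, surf))
  raw <- state_series(frames)
  expect_equal(sum(raw$frames$state == 0), 1)
  sm <- state_series(frames, min_dwell_frames = 3)
  expect_equal(sum(sm$frames$state == 0), 0)
  expect_equal(nrow(sm$dwell), 1)
})

test_that("per-state charges average with frame weights", {
  surf <- cbind(as.matrix(expand.grid(seq(0, 12, 3), seq(0, 12, 3))), 1)
  near <- ring_coords(c(6, 6, 4))
  frames <- lapply(1:6, function(i) make_test_frame(near, surf))
  ss <- state_series(frames)
  tab <- per_state_charge(ss)
  # constant charge: every visited state mean is that charge, sd 0
  expect_equal(tab$mean_charge[tab$n > 0], rep(-2, sum(tab$n > 0)))
  expect_equal(tab$sd_charge[tab$n > 0], rep(0, sum(tab$n > 0)))
  # unvisited states carry n = 0 and undefined mean
  expect_true(all(is.na(tab$mean_charge[tab$n == 0])))
  # two equal-length replicates with different charges average evenly
  ss2 <- ss
  ss2$frames$complex_charge <- ss$frames$complex_charge + 2
  tab2 <- per_state_charge(list(ss, ss2))
  st <- which(tab$n > 0)[1]
  expect_equal(tab2$mean_charge[st], -1)  # (a + b) / 2
})

test_that("trajectories round-trip through the XYZ writer and reader", {
  tr <- gen_trajectory(8, "ca", n_frames = 3)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  roles <- withr::local_tempfile(fileext = ".csv")
  write_xyz_trajectory(tr$frames, xyz, roles)
  back <- read_xyz_trajectory(xyz, roles)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$coords[, 1], tr$frames[[i]]$coords[, 1])
    expect_identical(back[[i]]$box, tr$frames[[i]]$box)
    expect_identical(back[[i]]$roles, tr$frames[[i]]$roles)
    expect_identical(back[[i]]$charges, tr$frames[[i]]$charges)
    expect_identical(back[[i]]$ring_atoms, tr$frames[[i]]$ring_atoms)
  }
  # malformed trajectory is rejected with a line diagnostic
  writeLines(c("1", "no box here", "C 0 0 0"), xyz)
  expect_error(read_xyz_trajectory(xyz, roles), "line 2")
  # triclinic-looking box is rejected
  writeLines(c("1", "time_ns=0 box=10 10 10 90 90 60", "C 0 0 0"), xyz)
  expect_error(read_xyz_trajectory(xyz, roles), "unsupported geometry")
})
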