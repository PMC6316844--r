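# Independent brute-force oracles and small fixture builders used across
# the suite.

# minimum molecule-surface distance by explicit enumeration of all atom
# pairs and all 27 periodic images
brute_min_surface_distance <- function(frame) {
  mol <- frame$coords[frame$roles == "molecule", , drop = FALSE]
  surf <- frame$coords[frame$roles == "surface", , drop = FALSE]
  images <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (i in seq_len(nrow(mol))) {
    for (j in seq_len(nrow(surf))) {
      d0 <- mol[i, ] - surf[j, ]
      shifted <- sweep(images, 2, frame$box, "*") +
        matrix(d0, nrow(images), 3, byrow = TRUE)
      best <- min(best, sqrt(min(rowSums(shifted^2))))
    }
  }
  best
}

# complex charge by the same enumeration: molecule charges plus formal
# charges of ions with any atom within cutoff of any molecule atom
brute_complex_charge <- function(frame, ion_cutoff = 4.0) {
  mol_i <- which(frame$roles == "molecule")
  ion_i <- which(frame$roles %in% c("cation", "anion"))
  images <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  q <- sum(frame$charges[mol_i])
  for (k in ion_i) {
    bound <- FALSE
    for (m in mol_i) {
      d0 <- frame$coords[k, ] - frame$coords[m, ]
      shifted <- sweep(images, 2, frame$box, "*") +
        matrix(d0, nrow(images), 3, byrow = TRUE)
      if (sqrt(min(rowSums(shifted^2))) <= ion_cutoff) { bound <- TRUE; break }
    }
    if (bound) q <- q + frame$charges[k]
  }
  q
}

# a small hand-posed frame: molecule triangle ring + extra atom, flat
# surface patch, optional ions at given positions/charges
make_test_frame <- function(mol_xyz, surf_xyz,
                            ion_xyz = NULL, ion_charge = numeric(),
                            mol_charge = NULL,
                            box = c(41.44, 35.88, 62.5),
                            ring = seq_len(min(nrow(mol_xyz), 5))) {
  n_mol <- nrow(mol_xyz); n_surf <- nrow(surf_xyz)
  n_ion <- if (is.null(ion_xyz)) 0 else nrow(ion_xyz)
  if (is.null(mol_charge)) mol_charge <- rep(-2 / n_mol, n_mol)
  traj_frame(
    time = 0, box = box,
    coords = rbind(mol_xyz, surf_xyz, ion_xyz),
    roles = c(rep("molecule", n_mol), rep("surface", n_surf),
              rep(ifelse(ion_charge > 0, "cation", "anion"), length.out = n_ion)),
    charges = c(mol_charge, rep(0, n_surf), ion_charge),
    ring_atoms = ring)
}

# planar 5-ring centered at `center`, tilted by `tilt_deg` about x
ring_coords <- function(center, tilt_deg = 0, radius = 1.2) {
  ang <- 2 * pi * (0:4) / 5
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  a <- tilt_deg * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                3, 3, byrow = TRUE)
  sweep(ring %*% t(rot), 2, center, "+")
}

# a random frame with <= 200 atoms for oracle comparisons
random_frame <- function(box = c(20, 17, 30)) {
  n_mol <- sample(4:8, 1); n_surf <- sample(5:40, 1)
  n_ion <- sample(0:20, 1)
  coords <- matrix(runif((n_mol + n_surf + n_ion) * 3), ncol = 3) %*%
    diag(box * 1.4) - 0.2 * matrix(box, n_mol + n_surf + n_ion, 3,
                                   byrow = TRUE)
  # make the first three molecule atoms non-collinear
  shift <- runif(3) * box
  coords[1:3, ] <- matrix(c(0, 0, 0, 1.4, 0, 0, 0, 1.4, 0),
                          3, 3, byrow = TRUE) +
    matrix(shift, 3, 3, byrow = TRUE)
  roles <- c(rep("molecule", n_mol), rep("surface", n_surf),
             if (n_ion > 0) sample(c("cation", "anion"), n_ion,
                                   replace = TRUE))
  charges <- c(runif(n_mol, -0.5, 0), rep(0, n_surf),
               if (n_ion > 0) ifelse(roles[(n_mol + n_surf + 1):
                                           (n_mol + n_surf + n_ion)] ==
                                       "cation", sample(1:2, n_ion, TRUE),
                                     -1))
  traj_frame(time = 0, box = box, coords = coords, roles = roles,
             charges = charges, ring_atoms = 1:3)
}
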