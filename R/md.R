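#' One MD trajectory frame
#'
#' Coordinates of a nucleotide + clay-slab + ion system in an orthorhombic
#' periodic box, with per-atom roles and charges. Triclinic boxes are not
#' supported and are rejected.
#'
#' @param time Frame time, ns.
#' @param box Orthorhombic box edge lengths `(Lx, Ly, Lz)`, Angstrom.
#' @param coords Numeric n x 3 matrix of atom positions, Angstrom.
#' @param roles Character vector, one of `"molecule"`, `"surface"`,
#'   `"cation"`, `"anion"`, `"solvent"` per atom.
#' @param charges Per-atom charge in elementary units: partial charges for
#'   molecule atoms, formal charges for ions.
#' @param ring_atoms Indices (into the atom list) of the nucleobase ring
#'   atoms, at least 3, all of role `"molecule"`.
#' @param elements Optional element symbols (for XYZ output).
#' @return A list of class `"traj_frame"`.
#' @export
traj_frame <- function(time, box, coords, roles, charges, ring_atoms,
                       elements = NULL) {
  coords <- as.matrix(coords)
  if (length(box) != 3)
    stop("unsupported geometry: only orthorhombic boxes (3 edge lengths)")
  if (any(!is.finite(box)) || any(box <= 0)) stop("box edges must be > 0")
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3, length(roles) == n, length(charges) == n)
  ok_roles <- c("molecule", "surface", "cation", "anion", "solvent")
  if (!all(roles %in% ok_roles))
    stop("unknown role(s): ", paste(setdiff(roles, ok_roles), collapse = ", "))
  ring_atoms <- as.integer(ring_atoms)
  if (length(ring_atoms) < 3 || any(ring_atoms < 1 | ring_atoms > n))
    stop("ring_atoms must index at least 3 atoms")
  if (!all(roles[ring_atoms] == "molecule"))
    stop("ring_atoms must all be molecule atoms")
  if (is.null(elements)) elements <- rep("X", n)
  structure(list(time = time, box = as.numeric(box), coords = coords,
                 roles = roles, charges = as.numeric(charges),
                 ring_atoms = ring_atoms, elements = elements),
            class = "traj_frame")
}

# minimum-image displacement components for an orthorhombic box
min_image <- function(d, L) d - L * round(d / L)

# all minimum-image distances between two coordinate sets (na x nb matrix)
pair_dists <- function(a, b, box) {
  dx <- min_image(outer(a[, 1], b[, 1], "-"), box[1])
  dy <- min_image(outer(a[, 2], b[, 2], "-"), box[2])
  dz <- min_image(outer(a[, 3], b[, 3], "-"), box[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Minimum molecule-surface distance in a frame
#'
#' Minimum over all molecule-surface atom pairs of the orthorhombic
#' minimum-image Euclidean distance.
#'
#' @param frame A [traj_frame()].
#' @return Distance in Angstrom.
#' @export
min_surface_distance <- function(frame) {
  stopifnot(inherits(frame, "traj_frame"))
  mol <- frame$coords[frame$roles == "molecule", , drop = FALSE]
  surf <- frame$coords[frame$roles == "surface", , drop = FALSE]
  if (nrow(mol) == 0) stop("frame has no molecule atoms")
  if (nrow(surf) == 0) stop("frame has no surface atoms")
  min(pair_dists(mol, surf, frame$box))
}

#' Tilt of the nucleobase ring relative to the surface plane
#'
#' Fits a least-squares plane through the ring atoms (unwrapped by minimum
#' image around the first ring atom so a molecule crossing the periodic
#' boundary is handled) and returns the angle in degrees between that plane
#' and the surface plane, folded into `[0, 90]`. The surface plane is taken
#' normal to `surface_axis`; the default is the longest box axis, matching a
#' clay-slab geometry where the slab spans the two short axes.
#'
#' @param frame A [traj_frame()].
#' @param surface_axis 1, 2, or 3; default `which.max(frame$box)`.
#' @return Tilt angle, degrees.
#' @export
ring_tilt <- function(frame, surface_axis = NULL) {
  stopifnot(inherits(frame, "traj_frame"))
  if (is.null(surface_axis)) surface_axis <- which.max(frame$box)
  ring <- frame$coords[frame$ring_atoms, , drop = FALSE]
  ref <- ring[1, ]
  for (k in 1:3)
    ring[, k] <- ref[k] + min_image(ring[, k] - ref[k], frame$box[k])
  centered <- sweep(ring, 2, colMeans(ring))
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    stop("ring atoms are collinear; cannot define a ring plane")
  normal <- sv$v[, 3]
  surf_normal <- c(0, 0, 0); surf_normal[surface_axis] <- 1
  cosang <- abs(sum(normal * surf_normal))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Classify the adsorption state of a frame
#'
#' Three states, following the convention of residence analyses of a
#' nucleotide at a clay surface: the molecule is adsorbed when any of its
#' atoms lies within `cutoff` (inclusive) of a surface atom; adsorbed frames
#' split into a parallel configuration (ring tilt at most
#' `parallel_max_tilt`) and a non-parallel one.
#'
#' \itemize{
#'   \item state 0 — free: minimum molecule-surface distance > `cutoff`;
#'   \item state 1 — adsorbed, non-parallel;
#'   \item state 2 — adsorbed, parallel.
#' }
#'
#' @param frame A [traj_frame()].
#' @param cutoff Adsorption distance threshold, Angstrom (default 4.0,
#'   inclusive).
#' @param parallel_max_tilt Maximum ring tilt (degrees) still counted as
#'   parallel (default 30; the tilt itself is always returned so other
#'   thresholds can be applied afterwards).
#' @param surface_axis Surface normal axis; see [ring_tilt()].
#' @return List with `state` (0/1/2), `min_dist` (Angstrom) and `tilt`
#'   (degrees).
#' @export
classify_state <- function(frame, cutoff = 4.0, parallel_max_tilt = 30,
                           surface_axis = NULL) {
  stopifnot(cutoff > 0)
  d <- min_surface_distance(frame)
  tilt <- ring_tilt(frame, surface_axis)
  state <- if (d > cutoff) 0L else if (tilt <= parallel_max_tilt) 2L else 1L
  list(state = state, min_dist = d, tilt = tilt)
}

#' Net charge of the molecule-ion complex in a frame
#'
#' Sum of the molecule's atomic charges plus the formal charges of every ion
#' (cation or anion) having any atom within `ion_cutoff` (minimum image) of
#' any molecule atom. This is the "global charge" of the complexed molecule:
#' a multiply charged cation cloud can overcompensate the nucleotide's
#' negative phosphate charge and turn the complex attractive to a negatively
#' charged basal surface (cationic bridging). The counting convention is
#' recorded in the `convention` attribute of the result.
#'
#' @param frame A [traj_frame()] with charges for molecule and ion atoms.
#' @param ion_cutoff Complexation radius, Angstrom (default 4.0, the same as
#'   the adsorption cutoff).
#' @return Net charge in elementary units, with attribute `convention`.
#' @export
complex_charge <- function(frame, ion_cutoff = 4.0) {
  stopifnot(inherits(frame, "traj_frame"), ion_cutoff > 0)
  mol_idx <- frame$roles == "molecule"
  ion_idx <- frame$roles %in% c("cation", "anion")
  if (!any(mol_idx)) stop("frame has no molecule atoms")
  if (any(!is.finite(frame$charges[mol_idx | ion_idx])))
    stop("missing charges for molecule or ion atoms")
  q <- sum(frame$charges[mol_idx])
  if (any(ion_idx)) {
    dmat <- pair_dists(frame$coords[ion_idx, , drop = FALSE],
                       frame$coords[mol_idx, , drop = FALSE], frame$box)
    bound <- apply(dmat, 1, min) <= ion_cutoff
    q <- q + sum(frame$charges[ion_idx][bound])
  }
  structure(q, convention =
    "molecule partial charges + formal charges of ions within ion_cutoff")
}

# merge runs shorter than min_len into the preceding run (first run merges
# forward); operates on an integer label vector
smooth_runs <- function(labels, min_len) {
  if (min_len <= 1L) return(labels)
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    if (!length(short) || length(r$lengths) == 1L) return(labels)
    i <- short[1]
    r$values[i] <- if (i > 1) r$values[i - 1] else r$values[i + 1]
    labels <- inverse.rle(r)
  }
}

#' Classify a whole trajectory into a state series
#'
#' Applies [classify_state()] frame by frame and derives dwell segments and
#' the adsorbed/free duration ratio
#' `(frames in states 1 or 2) / (frames in state 0)`. Optionally, dwell
#' segments shorter than `min_dwell_frames` are relabelled to the flanking
#' state — first on the adsorbed/free dichotomy, then between the two
#' adsorbed sub-states. The default is no smoothing, matching raw state
#' traces.
#'
#' @param trajectory List of [traj_frame()] objects (>= 2 frames).
#' @param cutoff,parallel_max_tilt,surface_axis See [classify_state()].
#' @param min_dwell_frames Minimum dwell length kept as its own segment.
#' @param ion_cutoff Complexation radius for the per-frame complex charge.
#' @return A list of class `"state_series"`: data frame `frames`
#'   (`time_ns`, `min_dist_A`, `tilt_deg`, `state`, `complex_charge`),
#'   `dwell` (run-length segments), `duration_ratio`,
#'   `ratio_infinite` flag, and the parameters used.
#' @export
state_series <- function(trajectory, cutoff = 4.0, parallel_max_tilt = 30,
                         surface_axis = NULL, min_dwell_frames = 1L,
                         ion_cutoff = 4.0) {
  stopifnot(length(trajectory) >= 2)
  cls <- lapply(trajectory, classify_state, cutoff = cutoff,
                parallel_max_tilt = parallel_max_tilt,
                surface_axis = surface_axis)
  states <- vapply(cls, `[[`, integer(1), "state")
  if (min_dwell_frames > 1L) {
    ads <- as.integer(states > 0L)
    ads <- smooth_runs(ads, min_dwell_frames)
    # frames flipped to adsorbed inherit the nearest adsorbed sub-state
    sub <- states
    sub[states == 0L & ads == 1L] <- NA_integer_
    sub[ads == 0L] <- 0L
    if (anyNA(sub)) {
      filled <- zoo_na_fill(ifelse(sub == 0L, NA_integer_, sub))
      sub[is.na(sub)] <- filled[is.na(sub)]
    }
    adsorbed_sub <- sub
    adsorbed_sub[ads == 1L] <- smooth_runs(sub[ads == 1L], min_dwell_frames)
    states <- ifelse(ads == 0L, 0L, adsorbed_sub)
  }
  charge <- vapply(trajectory, function(f)
    as.numeric(complex_charge(f, ion_cutoff)), numeric(1))
  df <- data.frame(
    time_ns = vapply(trajectory, `[[`, numeric(1), "time"),
    min_dist_A = vapply(cls, `[[`, numeric(1), "min_dist"),
    tilt_deg = vapply(cls, `[[`, numeric(1), "tilt"),
    state = states,
    complex_charge = charge)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  dwell <- data.frame(state = r$values,
                      start = c(1L, utils::head(ends, -1) + 1L),
                      end = ends)
  n_free <- sum(states == 0L); n_ads <- sum(states > 0L)
  ratio_inf <- n_free == 0L
  structure(list(frames = df, dwell = dwell,
                 duration_ratio = if (ratio_inf) Inf else n_ads / n_free,
                 ratio_infinite = ratio_inf,
                 cutoff = cutoff, parallel_max_tilt = parallel_max_tilt,
                 ion_cutoff = ion_cutoff,
                 min_dwell_frames = min_dwell_frames),
            class = "state_series")
}

# nearest-non-NA fill (both directions, previous first)
zoo_na_fill <- function(x) {
  n <- length(x)
  last <- NA_integer_
  for (i in seq_len(n)) {
    if (!is.na(x[i])) last <- x[i] else x[i] <- last
  }
  nxt <- NA_integer_
  for (i in rev(seq_len(n))) {
    if (!is.na(x[i])) nxt <- x[i] else x[i] <- nxt
  }
  x
}

#' @export
print.state_series <- function(x, ...) {
  tab <- table(factor(x$frames$state, levels = 0:2))
  cat(sprintf("<state_series> %d frames: free %d / non-parallel %d / parallel %d\n",
              nrow(x$frames), tab[1], tab[2], tab[3]))
  cat(sprintf("  adsorbed/free duration ratio: %s\n",
              if (x$ratio_infinite) "Inf (never free)"
              else sprintf("%.3f", x$duration_ratio)))
  invisible(x)
}

#' Per-state complex-charge table
#'
#' Frame-weighted mean and sd of the complex charge in each adsorption
#' state. With several replicate simulations the cross-replicate average is
#' the frame-count-weighted mean (replicates with more frames in a state
#' weigh more). Unvisited states get `n = 0` and `NA` means.
#'
#' @param series A [state_series()] or a list of them (replicates).
#' @return Data frame with columns `state`, `mean_charge`, `sd_charge`, `n`.
#' @export
per_state_charge <- function(series) {
  if (inherits(series, "state_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "state_series")))
  st <- unlist(lapply(series, function(s) s$frames$state))
  ch <- unlist(lapply(series, function(s) s$frames$complex_charge))
  out <- do.call(rbind, lapply(0:2, function(k) {
    sel <- st == k
    data.frame(state = k,
               mean_charge = if (any(sel)) mean(ch[sel]) else NA_real_,
               sd_charge = if (sum(sel) > 1) stats::sd(ch[sel]) else
                 if (any(sel)) 0 else NA_real_,
               n = sum(sel))
  }))
  out
}
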