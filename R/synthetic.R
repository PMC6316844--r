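# Seeded generators for every input the pipeline consumes, with ground truth
# carried alongside. Each generator restores the caller's RNG state, so the
# same (seed, parameters) always yields identical output regardless of
# context.

local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    fn <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    fn <- function() rm(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  fn
}

#' Bundle a synthetic scenario
#'
#' A seeded ground-truth parameter bundle for one of the generators; call
#' [generate()] to materialize it. Identical `(seed, parameters)` give
#' identical output.
#'
#' @param kind One of `"isotherm"`, `"homologous_family"`, `"grain_pair"`,
#'   `"gas_isotherm"`, `"trajectory"`.
#' @param seed Integer RNG seed.
#' @param ... Parameters forwarded to the corresponding `gen_*` function.
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(kind = c("isotherm", "homologous_family",
                                        "grain_pair", "gas_isotherm",
                                        "trajectory"),
                               seed, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed), params = list(...)),
            class = "synthetic_scenario")
}

#' Materialize a synthetic scenario
#' @param scenario A [synthetic_scenario()].
#' @return The corresponding generator's output (data plus `truth`).
#' @export
generate <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  fn <- switch(scenario$kind,
               isotherm = gen_isotherm,
               homologous_family = gen_homologous_family,
               grain_pair = gen_grain_pair,
               gas_isotherm = gen_gas_isotherm,
               trajectory = gen_trajectory)
  do.call(fn, c(list(seed = scenario$seed), scenario$params))
}

# placeholder solute/mineral constants for synthetic testing only; the
# pipeline takes real values from the user
synthetic_nucleotide <- function(name = "synGMP", solubility = 0.02) {
  nucleotide_spec(name, molecular_weight = 363.2, solubility = solubility,
                  pka_values = c(2.9, 6.3, 9.4),
                  extinction_coefficient = 12000, wavelength = 253)
}

#' Generate batch-adsorption samples with Langmuir ground truth
#'
#' Emulates a batch experiment: an initial-concentration grid over the
#' working range (default 0-3.5 mM, 1 mL solution, 40 mg mineral — a 40 g/L
#' solid load sized so that plateau-level uptake depletes an appreciable
#' fraction of the solute, as a batch design requires), with the
#' equilibrium concentration solved self-consistently from the chosen
#' isotherm model and mass balance (bisection to 1e-12), then multiplicative
#' Gaussian noise on the equilibrium concentration. Mass balance closes
#' exactly before noise injection.
#'
#' @param seed Integer seed.
#' @param model `"classic"` or `"modified"` Langmuir truth.
#' @param q_max True capacity, mol/g.
#' @param k True classic constant, L/mol.
#' @param k_ml True modified (dimensionless) constant.
#' @param nucleotide A [nucleotide_spec()]; its solubility is the modified
#'   model's `c_s`.
#' @param mineral A [mineral_spec()].
#' @param n_points Number of initial concentrations.
#' @param c0_max Top of the initial-concentration grid, mol/L.
#' @param volume,mass Solution volume (L) and mineral mass (g) per sample.
#' @param noise Relative sd of the multiplicative noise on `Ceq`.
#' @param n_replicates Replicates per concentration.
#' @param conditions List `(ph, temperature, salts)`; default seawater
#'   analog (0.5 M NaCl + 0.05 M MgCl2), pH 7, 25 C.
#' @return List with `samples` (list of [batch_sample()]), `nucleotide`,
#'   `mineral`, and `truth` (model, parameters, resample count).
#' @export
gen_isotherm <- function(seed, model = c("classic", "modified"),
                         q_max = 5e-5, k = 2000, k_ml = 40,
                         nucleotide = synthetic_nucleotide(),
                         mineral = synthetic_mineral("fine"),
                         n_points = 20, c0_max = 3.5e-3,
                         volume = 1e-3, mass = 0.040,
                         noise = 0.02, n_replicates = 1,
                         conditions = list(ph = 7, temperature = 25,
                                           salts = c(NaCl = 0.5,
                                                     MgCl2 = 0.05))) {
  model <- match.arg(model)
  restore <- local_seed(seed); on.exit(restore())
  params <- if (model == "classic") list(q_max = q_max, k = k)
            else list(q_max = q_max, k_ml = k_ml,
                      c_s = nucleotide$solubility)
  q_of_c <- function(ce) if (q_max == 0) 0 else
    langmuir_eval(model, params, ce)
  c0_grid <- seq(c0_max / n_points, c0_max, length.out = n_points)
  n_resampled <- 0L
  samples <- list()
  for (c0 in c0_grid) {
    # mass balance: Ceq + q(Ceq) m/V = C0, bisection on [0, C0]
    f <- function(ce) ce + q_of_c(ce) * mass / volume - c0
    lo <- 0; hi <- c0
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < 1e-12 * max(c0, 1e-30)) break
    }
    # fixed-point polish so the pre-noise balance closes to machine precision
    ceq_true <- c0 - q_of_c((lo + hi) / 2) * mass / volume
    for (r in seq_len(n_replicates)) {
      repeat {
        ceq <- ceq_true * (1 + stats::rnorm(1, sd = noise))
        if (ceq >= 0 || ceq_true == 0) break
        n_resampled <- n_resampled + 1L
      }
      ceq <- max(ceq, 0)
      samples[[length(samples) + 1L]] <- batch_sample(
        c0 = c0, ceq = ceq, volume = volume, mass = mass,
        ph = conditions$ph, temperature = conditions$temperature,
        salts = conditions$salts, replicate_id = r)
    }
  }
  if (n_resampled > 0)
    warning(n_resampled, " noisy Ceq draw(s) below 0 were resampled")
  list(samples = samples, nucleotide = nucleotide, mineral = mineral,
       truth = c(list(model = model, noise = noise,
                      n_resampled = n_resampled), params))
}

# shared reduced-axis density shape used by the family and grain generators
reduced_shape <- function(x, d_max, k_x) d_max * k_x * x / (1 + k_x * x)

#' Generate a homologous family of isotherms
#'
#' Several nucleotides sharing one reduced-axis shape `d(x)` (Langmuir in
#' the reduced concentration `x = Ceq/S`) but with different solubilities:
#' each curve is materialized at `c_eq = x * S_i` with multiplicative noise,
#' so collapse on the solubility-reduced axis holds by construction while
#' the raw-concentration curves diverge.
#'
#' @param seed Integer seed.
#' @param solubilities Named vector of molar solubilities (>= 2, distinct).
#' @param q_max Shared plateau, mol/g.
#' @param k_x Shared affinity on the reduced axis (dimensionless).
#' @param x_range Reduced-concentration range (log-spaced grid).
#' @param n_points Points per curve.
#' @param noise Relative noise on the ordinate.
#' @param mineral A [mineral_spec()] shared by all curves.
#' @return List with `isotherms` (list of [isotherm()]) and `truth`.
#' @export
gen_homologous_family <- function(seed,
                                  solubilities = c(synA = 0.005,
                                                   synB = 0.011,
                                                   synC = 0.025),
                                  q_max = 5e-5, k_x = 50,
                                  x_range = c(0.002, 0.15),
                                  n_points = 15, noise = 0.02,
                                  mineral = synthetic_mineral("fine")) {
  if (length(solubilities) < 2)
    stop("need at least 2 nucleotides for a family")
  if (anyDuplicated(solubilities))
    warning("non-distinct solubilities: curves will coincide on both axes")
  restore <- local_seed(seed); on.exit(restore())
  x <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_points))
  d <- reduced_shape(x, q_max, k_x)
  isos <- lapply(names(solubilities), function(nm) {
    s <- solubilities[[nm]]
    q <- d * (1 + stats::rnorm(n_points, sd = noise))
    isotherm(x * s, q, nucleotide = synthetic_nucleotide(nm, s),
             mineral = mineral)
  })
  names(isos) <- names(solubilities)
  list(isotherms = isos,
       truth = list(q_max = q_max, k_x = k_x, noise = noise,
                    solubilities = solubilities))
}

synthetic_mineral <- function(grain = c("fine", "coarse")) {
  grain <- match.arg(grain)
  if (grain == "fine")
    mineral_spec("synClay-fine", swelling = TRUE, ssa_total = 92,
                 ssa_basal = 80, ssa_edge = 12)
  else
    mineral_spec("synClay-coarse", swelling = TRUE, ssa_total = 80,
                 ssa_basal = 76, ssa_edge = 4)
}

#' Generate a coarse/fine grain pair with edge-proportional uptake
#'
#' Two powders of the same mineralogy that differ in grain size: the fine
#' grains expose more lateral (edge) area per gram. Per-gram uptake is
#' proportional to the edge area at every reduced concentration, emulating
#' adsorption localized on the lateral faces, so only the edge-basis density
#' curves coincide; basal- and total-basis densities do not.
#'
#' @param seed Integer seed.
#' @param edge_density Shared edge-basis density shape plateau, mol/m^2.
#' @param k_x Shared affinity on the reduced axis.
#' @param solubility Nucleotide solubility, mol/L.
#' @param x_range,n_points Reduced-concentration grid.
#' @param noise Relative ordinate noise.
#' @param minerals List of two [mineral_spec()] differing in `ssa_edge`.
#' @return List with `isotherms` (length 2), `minerals`, and `truth`.
#' @export
gen_grain_pair <- function(seed, edge_density = 2e-6, k_x = 50,
                           solubility = 0.02, x_range = c(0.002, 0.15),
                           n_points = 15, noise = 0.02,
                           minerals = list(synthetic_mineral("fine"),
                                           synthetic_mineral("coarse"))) {
  stopifnot(length(minerals) == 2)
  restore <- local_seed(seed); on.exit(restore())
  x <- exp(seq(log(x_range[1]), log(x_range[2]), length.out = n_points))
  dens <- reduced_shape(x, edge_density, k_x)  # mol per m^2 of edge face
  isos <- lapply(minerals, function(m) {
    q <- dens * m$ssa_edge * (1 + stats::rnorm(n_points, sd = noise))
    isotherm(x * solubility, q,
             nucleotide = synthetic_nucleotide("synGMP", solubility),
             mineral = m)
  })
  list(isotherms = isos, minerals = minerals,
       truth = list(edge_density = edge_density, k_x = k_x, noise = noise,
                    ssa_edge = vapply(minerals, `[[`, numeric(1),
                                      "ssa_edge")))
}

#' Generate a low-pressure argon adsorption isotherm from known domains
#'
#' Sums the adsorbed volumes of the supplied local domains on a log-spaced
#' relative-pressure grid within the monolayer regime and adds noise
#' proportional to the local signal. The default truth holds a high-energy
#' edge domain and a lower-energy basal domain (30/70 of the monolayer).
#'
#' @param seed Integer seed.
#' @param domains List of [local_domain()] truth domains.
#' @param n_points Grid size.
#' @param p_range Relative-pressure range (default `(1e-7, 0.05]`).
#' @param noise Relative noise on adsorbed volumes.
#' @return List with `gas` (a [gas_isotherm()]) and `truth` (domains, noise,
#'   `edge_fraction`).
#' @export
gen_gas_isotherm <- function(seed,
                             domains = list(
                               local_domain(3, -12, 1.5, label = "edge"),
                               local_domain(7, -5, 2.0, label = "basal")),
                             n_points = 150, p_range = c(1e-7, 0.05),
                             noise = 0.01) {
  restore <- local_seed(seed); on.exit(restore())
  u <- seq(log(p_range[1]), log(p_range[2]), length.out = n_points)
  v <- domains_v_ads(domains, u)
  v_noisy <- v * (1 + stats::rnorm(n_points, sd = noise))
  v_m <- vapply(domains, `[[`, numeric(1), "v_m")
  lab <- vapply(domains, `[[`, character(1), "label")
  gas <- gas_isotherm(exp(u), v_noisy, noise_tol = max(0.02, 6 * noise))
  list(gas = gas,
       truth = list(domains = domains, noise = noise,
                    total_v_m = sum(v_m),
                    edge_fraction = if (sum(v_m) > 0)
                      sum(v_m[lab == "edge"]) / sum(v_m) else NA_real_))
}

# rigid toy molecule: planar 5-ring (radius 1.2 A) + glycosidic carbon +
# phosphorus; net charge -2
toy_molecule <- function() {
  ang <- 2 * pi * (0:4) / 5
  ring <- cbind(1.2 * cos(ang), 1.2 * sin(ang), 0)
  extra <- rbind(c(2.6, 0, 0.4),    # sugar-like carbon
                 c(4.0, 0, 0.9))    # phosphate P
  coords <- rbind(ring, extra)
  list(coords = coords,
       charges = c(rep(-0.1, 5), -0.55, -0.95),  # sums to -2
       elements = c("C", "N", "C", "N", "C", "C", "P"),
       ring = 1:5)
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

#' Generate a two-state Markov trajectory of a molecule at a clay slab
#'
#' A rigid toy nucleotide (planar 5-atom ring + 2 atoms, net charge -2)
#' above a static surface slab in an orthorhombic periodic box. Frame by
#' frame, an adsorbed/free two-state Markov chain (transition probabilities
#' `p_fa`, `p_af`; stationary adsorbed fraction `p_fa/(p_fa+p_af)`) decides
#' the state; adsorbed frames are parallel (state 2) with probability
#' `p_parallel`. The molecule is posed so its closest atom sits exactly at
#' the drawn minimum distance above a surface atom: adsorbed frames draw the
#' distance uniformly in `[2.5, 4.0]` Angstrom, free frames in `(4.5, 20]`;
#' ring tilt is drawn inside the sub-state's band (parallel `[0, 20]` deg,
#' non-parallel `[45, 85]` deg, free unconstrained). Bound cation counts are
#' Poisson per state (Na-like: mean 2.8 monovalent; Ca-like: mean 2.5
#' divalent), realized by placing that many cations within the complexation
#' cutoff of molecule atoms and parking the remaining ions far away.
#' Positional Gaussian jitter is applied last.
#'
#' @param seed Integer seed.
#' @param scenario `"na"` (monovalent cations, mostly free) or `"ca"`
#'   (divalent cations, mostly adsorbed); sets the defaults below.
#' @param n_frames Number of frames.
#' @param p_fa,p_af Free->adsorbed and adsorbed->free transition
#'   probabilities per frame. Defaults: Na-like 0.02/0.05 (stationary
#'   adsorbed fraction 2/7, duration ratio 0.4); Ca-like 0.06/0.02
#'   (fraction 0.75, ratio 3).
#' @param p_parallel Probability that an adsorbed frame is parallel.
#' @param bound_mean Poisson mean of cations bound when adsorbed.
#' @param bound_mean_free Poisson mean of cations bound when free (defaults
#'   to `bound_mean`: complexation persists in solution).
#' @param cation_charge Formal cation charge (+1 Na-like, +2 Ca-like).
#' @param n_cations,n_anions Ion pool sizes.
#' @param jitter Positional Gaussian jitter as root-mean-square displacement
#'   magnitude per atom, Angstrom (default 0.1; 0 for noise-free frames).
#'   Each coordinate receives independent Gaussian noise with sd
#'   `jitter/sqrt(3)` so the expected squared displacement is `jitter^2`.
#' @param box Box edge lengths, Angstrom.
#' @param dt_ns Frame spacing, ns.
#' @param cutoff,ion_cutoff,parallel_max_tilt Classifier settings the
#'   geometry must respect.
#' @return List with `frames` (list of [traj_frame()]) and `truth`
#'   (per-frame states, bound counts, parameters, expected duration ratio
#'   and adsorbed-state complex charge).
#' @export
gen_trajectory <- function(seed, scenario = c("na", "ca"), n_frames = 2000,
                           p_fa = NULL, p_af = NULL, p_parallel = 0.5,
                           bound_mean = NULL, bound_mean_free = NULL,
                           cation_charge = NULL,
                           n_cations = 14, n_anions = 8,
                           jitter = 0.1,
                           box = c(41.44, 35.88, 62.5), dt_ns = 0.05,
                           cutoff = 4.0, ion_cutoff = 4.0,
                           parallel_max_tilt = 30) {
  scenario <- match.arg(scenario)
  if (is.null(p_fa)) p_fa <- if (scenario == "na") 0.02 else 0.06
  if (is.null(p_af)) p_af <- if (scenario == "na") 0.05 else 0.02
  if (is.null(bound_mean)) bound_mean <- if (scenario == "na") 2.8 else 2.5
  if (is.null(bound_mean_free)) bound_mean_free <- bound_mean
  if (is.null(cation_charge)) cation_charge <- if (scenario == "na") 1 else 2
  if (cutoff < 4.0 || ion_cutoff <= 3.2)
    stop("configuration error: adsorbed offsets [2.5, 4.0] A and bound-ion ",
         "placement require cutoff >= 4 and ion_cutoff > 3.2")
  restore <- local_seed(seed); on.exit(restore())

  mol <- toy_molecule()
  n_mol <- nrow(mol$coords)
  # static surface slab: square grid on the two short axes at low height
  z_axis <- which.max(box)
  lat <- setdiff(1:3, z_axis)
  nx <- 6
  gx <- (seq_len(nx) - 0.5) * box[lat[1]] / nx
  gy <- (seq_len(nx) - 0.5) * box[lat[2]] / nx
  surf_grid <- as.matrix(expand.grid(gx, gy))
  z_surf <- 2.0
  surf <- matrix(0, nrow(surf_grid), 3)
  surf[, lat[1]] <- surf_grid[, 1]
  surf[, lat[2]] <- surf_grid[, 2]
  surf[, z_axis] <- z_surf
  n_surf <- nrow(surf)

  roles <- c(rep("molecule", n_mol), rep("surface", n_surf),
             rep("cation", n_cations), rep("anion", n_anions))
  charges <- c(mol$charges, rep(0, n_surf),
               rep(cation_charge, n_cations), rep(-1, n_anions))
  elements <- c(mol$elements, rep("Si", n_surf),
                rep(if (scenario == "na") "Na" else "Ca", n_cations),
                rep("Cl", n_anions))

  # Markov chain over adsorbed(1)/free(0)
  pi_ads <- p_fa / (p_fa + p_af)
  ads <- integer(n_frames)
  ads[1] <- stats::rbinom(1, 1, pi_ads)
  for (t in 2:n_frames) {
    p <- if (ads[t - 1] == 1) 1 - p_af else p_fa
    ads[t] <- stats::rbinom(1, 1, p)
  }
  parallel <- stats::rbinom(n_frames, 1, p_parallel)
  states <- ifelse(ads == 0, 0L, ifelse(parallel == 1, 2L, 1L))

  place_far <- function(n_pts, mol_xyz) {
    out <- matrix(0, n_pts, 3)
    for (i in seq_len(n_pts)) {
      repeat {
        p <- stats::runif(3) * box
        if (min(pair_dists(matrix(p, 1), mol_xyz, box)) >= 8) break
      }
      out[i, ] <- p
    }
    out
  }

  frames <- vector("list", n_frames)
  bound_counts <- integer(n_frames)
  for (t in seq_len(n_frames)) {
    st <- states[t]
    tilt <- switch(as.character(st),
                   "0" = stats::runif(1, 0, 90),
                   "1" = stats::runif(1, 45, 85),
                   "2" = stats::runif(1, 0, 20)) * pi / 180
    m <- mol$coords %*% t(rot_z(stats::runif(1, 0, 2 * pi)))
    m <- m %*% t(rot_x(tilt))
    # map molecule frame (x,y,z) onto (lat1, lat2, z_axis)
    mm <- matrix(0, n_mol, 3)
    mm[, lat[1]] <- m[, 1]; mm[, lat[2]] <- m[, 2]; mm[, z_axis] <- m[, 3]
    d_min <- if (st == 0) stats::runif(1, 4.5 + 1e-6, 20)
             else stats::runif(1, 2.5, 4.0)
    anchor <- which.min(mm[, z_axis])
    # lift so the lowest atom sits at z_surf + d_min, and snap its lateral
    # position onto a surface atom so the minimum distance equals d_min
    mm[, z_axis] <- mm[, z_axis] - mm[anchor, z_axis] + z_surf + d_min
    site <- surf[sample.int(n_surf, 1), ]
    mm[, lat[1]] <- mm[, lat[1]] - mm[anchor, lat[1]] + site[lat[1]]
    mm[, lat[2]] <- mm[, lat[2]] - mm[anchor, lat[2]] + site[lat[2]]

    mean_b <- if (st == 0) bound_mean_free else bound_mean
    b <- min(stats::rpois(1, mean_b), n_cations)
    bound_counts[t] <- b
    cations <- matrix(0, n_cations, 3)
    if (b > 0) {
      host <- sample.int(n_mol, b, replace = TRUE)
      for (i in seq_len(b)) {
        dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
        cations[i, ] <- mm[host[i], ] + dirv * stats::runif(1, 2.0, 3.0)
      }
    }
    if (b < n_cations)
      cations[(b + 1):n_cations, ] <- place_far(n_cations - b, mm)
    anions <- place_far(n_anions, mm)

    xyz <- rbind(mm, surf, cations, anions)
    if (jitter > 0)
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter / sqrt(3)),
                          ncol = 3)
    frames[[t]] <- traj_frame(time = (t - 1) * dt_ns, box = box,
                              coords = xyz, roles = roles,
                              charges = charges, ring_atoms = mol$ring,
                              elements = elements)
  }
  list(frames = frames,
       truth = list(states = states, bound_counts = bound_counts,
                    scenario = scenario, p_fa = p_fa, p_af = p_af,
                    p_parallel = p_parallel, pi_ads = pi_ads,
                    expected_duration_ratio = pi_ads / (1 - pi_ads),
                    bound_mean = bound_mean,
                    bound_mean_free = bound_mean_free,
                    cation_charge = cation_charge,
                    expected_adsorbed_charge = -2 +
                      cation_charge * bound_mean,
                    jitter = jitter))
}
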