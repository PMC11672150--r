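# One-bead-per-residue HPS coarse-grained model with explicit multi-bead
# FRET dyes, propagated by BAOAB Langevin dynamics (compiled core in src/).
# Energies in kJ/mol, lengths in nm, times in ps, masses in amu.

KB_KJ <- 0.00831446261815324  # kJ/mol/K

#' Default HPS bead-type table
#'
#' Average-volume bead diameters (nm) and residue masses (amu) of the HPS
#' lineage; the lambda column holds the shipped starting stickiness values
#' (user-replaceable; the dye rows are placeholders refined by grid search
#' and force balance).
#'
#' @return `data.frame` with columns `type`, `lambda`, `sigma`, `q`,
#'   `mass` for the 20 residues plus Neg/Neu/Pos/Lin dye bead types.
#' @export
hps_default_table <- function() {
  tab <- data.frame(
    type = c("A","R","N","D","C","Q","E","G","H","I",
             "L","K","M","F","P","S","T","V","W","Y",
             "Neg","Neu","Pos","Lin"),
    lambda = c(0.2743, 0.7307, 0.4255, 0.0416, 0.5615, 0.3934, 0.0006,
               0.7058, 0.4663, 0.5423, 0.6440, 0.1790, 0.5308, 0.8672,
               0.3593, 0.4625, 0.3713, 0.2083, 0.9893, 0.9774,
               0.5, 0.5, 0.5, 0.2),
    sigma = c(0.504, 0.656, 0.568, 0.558, 0.548, 0.602, 0.592, 0.450,
              0.608, 0.618, 0.618, 0.636, 0.618, 0.636, 0.556, 0.518,
              0.562, 0.586, 0.678, 0.646,
              0.55, 0.55, 0.55, 0.45),
    q = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0,
          0, 1, 0, 0, 0, 0, 0, 0, 0, 0,
          -1, 0, 1, 0),
    mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12,
             57.05, 137.14, 113.16, 113.16, 128.17, 131.19, 147.18,
             97.12, 87.08, 101.10, 99.13, 186.21, 163.18,
             100, 100, 100, 100),
    stringsAsFactors = FALSE)
  rownames(tab) <- tab$type
  tab
}

#' HPS parameter set
#'
#' Per-bead-type stickiness \eqn{\lambda}, diameter \eqn{\sigma} (nm),
#' charge (e) and mass (amu) for the 20 amino acids plus the four dye
#' bead roles (Neg, Neu, Pos, Lin), together with the global interaction
#' settings.
#'
#' @param table Bead-type table (defaults to the shipped set); must have
#'   columns `type`, `lambda`, `sigma`, `q`, `mass`.
#' @param eps Short-range energy scale \eqn{\epsilon} (kJ/mol); default
#'   0.8368 (0.2 kcal/mol).
#' @param cutoff Short-range cutoff (nm).
#' @param dh_cutoff Debye-Hueckel cutoff (nm).
#' @param ionic_strength Ionic strength (mM).
#' @param temperature Temperature (K).
#' @param eps_r Relative dielectric constant.
#' @return Object of class `hps_params`.
#' @export
hps_params <- function(table = hps_default_table(), eps = 0.8368,
                       cutoff = 2.0, dh_cutoff = 3.5,
                       ionic_strength = 185, temperature = 300,
                       eps_r = 80) {
  stopifnot(all(c("type", "lambda", "sigma", "q", "mass") %in% names(table)))
  stopifnot(all(table$sigma > 0), all(is.finite(table$lambda)))
  rownames(table) <- table$type
  structure(list(table = table, eps = eps, cutoff = cutoff,
                 dh_cutoff = dh_cutoff, ionic_strength = ionic_strength,
                 temperature = temperature, eps_r = eps_r),
            class = "hps_params")
}

#' @export
print.hps_params <- function(x, ...) {
  cat(sprintf(
    "<hps_params> %d bead types, eps = %.4f kJ/mol, I = %g mM, T = %g K\n",
    nrow(x$table), x$eps, x$ionic_strength, x$temperature))
  invisible(x)
}

#' Set stickiness values on a parameter set or topology
#'
#' @param x An `hps_params` or `cg_topology`.
#' @param lambda Named numeric vector of \eqn{\lambda} values by bead type.
#' @return The updated object.
#' @export
set_lambda <- function(x, lambda) {
  if (inherits(x, "hps_params")) {
    stopifnot(all(names(lambda) %in% x$table$type))
    x$table[names(lambda), "lambda"] <- unname(lambda)
    return(x)
  }
  if (inherits(x, "cg_topology")) {
    hit <- x$beads$type %in% names(lambda)
    x$beads$lambda[hit] <- unname(lambda[x$beads$type[hit]])
    return(x)
  }
  stop("unsupported object")
}

#' Debye screening length
#'
#' \eqn{\lambda_D = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}}.
#'
#' @param ionic_strength Ionic strength (mM).
#' @param temperature Temperature (K).
#' @param eps_r Relative dielectric constant.
#' @return Debye length in nm.
#' @export
debye_length <- function(ionic_strength, temperature = 300, eps_r = 80) {
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  e <- 1.602176634e-19; NA_ <- 6.02214076e23
  I <- ionic_strength  # mM == mol/m^3
  sqrt(eps0 * eps_r * kB * temperature / (2 * NA_ * e^2 * I)) * 1e9
}

#' Ashbaugh-Hatch + screened-Coulomb pair energy
#'
#' Reference (pure R) evaluation of the HPS pair potential between two
#' bead types: with \eqn{\lambda_{ij}} and \eqn{\sigma_{ij}} the
#' arithmetic means and \eqn{\Phi_{LJ} = 4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6]},
#' \eqn{U = \Phi_{LJ} + (1 - \lambda_{ij})\epsilon} for
#' \eqn{r \le 2^{1/6}\sigma_{ij}} and \eqn{\lambda_{ij}\Phi_{LJ}} beyond
#' (zero past the cutoff), plus a Debye-Hueckel term
#' \eqn{q_i q_j e^2 \exp(-r/\lambda_D) / (4\pi\epsilon_0\epsilon_r r)}
#' within its own cutoff.
#'
#' @param r Distance(s) in nm (> 0).
#' @param type_i,type_j Bead type names.
#' @param params An [hps_params()].
#' @return Energy in kJ/mol, same length as `r`.
#' @export
pair_energy <- function(r, type_i, type_j, params = hps_params()) {
  if (any(r <= 0)) stop("r must be positive")
  ti <- params$table[type_i, ]; tj <- params$table[type_j, ]
  lam <- (ti$lambda + tj$lambda) / 2
  sij <- (ti$sigma + tj$sigma) / 2
  s6 <- (sij / r)^6
  phi <- 4 * params$eps * (s6^2 - s6)
  rmin <- 2^(1 / 6) * sij
  u <- ifelse(r <= rmin, phi + (1 - lam) * params$eps, lam * phi)
  u[r >= params$cutoff] <- 0
  if (ti$q != 0 && tj$q != 0) {
    lD <- debye_length(params$ionic_strength, params$temperature,
                       params$eps_r)
    dh <- 138.935458 / params$eps_r * ti$q * tj$q * exp(-r / lD) / r
    dh[r >= params$dh_cutoff] <- 0
    u <- u + dh
  }
  u
}

# ---- dye specifications ----------------------------------------------------

#' Built-in coarse-grained dye specifications
#'
#' Each dye is a small bead tree attached at a labeling cysteine: three
#' linker beads (`Lin`) followed by a three-bead chromophore core with one
#' branch bead. Charges sit on the core beads and give the net charges
#' Alexa 488 and Alexa 594: -2; Cy3B: 0; CF660R: -1. The chromophore
#' geometry is an approximation (bead counts and branch placement are not
#' uniquely determined by the model); the designated FRET distance
#' reference is the central core bead. Specifications are plain lists and
#' fully user-editable; see [write_dye_spec()].
#'
#' @return Named list of dye specifications.
#' @export
default_dye_specs <- function() {
  core <- function(name, types) {
    list(
      name = name,
      beads = data.frame(
        label = c("L1", "L2", "L3", "C1", "C2", "C3", "B1"),
        type = c("Lin", "Lin", "Lin", types),
        stringsAsFactors = FALSE),
      bonds = data.frame(
        from = c("ATT", "L1", "L2", "L3", "C1", "C2", "C2"),
        to   = c("L1", "L2", "L3", "C1", "C2", "C3", "B1"),
        stringsAsFactors = FALSE),
      angles = data.frame(
        a = c("L3", "C1", "C1", "C3"),
        b = c("C1", "C2", "C2", "C2"),
        c = c("C2", "C3", "B1", "B1"),
        theta0 = c(pi, pi, pi / 2, pi / 2),
        stringsAsFactors = FALSE),
      center = "C2")
  }
  list(
    A488   = core("A488",   c("Neg", "Neu", "Neg", "Neu")),
    A594   = core("A594",   c("Neg", "Neu", "Neg", "Neu")),
    Cy3B   = core("Cy3B",   c("Neu", "Neu", "Neu", "Neu")),
    CF660R = core("CF660R", c("Neg", "Neu", "Neu", "Neu")))
}

#' Write / read a dye specification as YAML
#'
#' @param spec A dye specification (see [default_dye_specs()]).
#' @param path File path.
#' @return `read_dye_spec()` returns the specification list.
#' @export
write_dye_spec <- function(spec, path) {
  yaml::write_yaml(lapply(spec, function(x)
    if (is.data.frame(x)) as.list(x) else x), path, precision = 15)
  invisible(path)
}

#' @rdname write_dye_spec
#' @export
read_dye_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- list(name = raw$name,
               beads = data.frame(raw$beads, stringsAsFactors = FALSE),
               bonds = data.frame(raw$bonds, stringsAsFactors = FALSE),
               angles = if (length(raw$angles$a))
                 data.frame(raw$angles, stringsAsFactors = FALSE)
               else data.frame(a = character(), b = character(),
                               c = character(), theta0 = numeric()),
               center = raw$center)
  spec
}

#' A FRET-labeled construct
#'
#' @param seq Amino-acid sequence ([sequence_record()] or string),
#'   including any flanking overhangs; beads are built for every residue.
#' @param sites Two 1-based residue indices carrying the dyes.
#' @param dyes Two dye names resolvable in `dye_specs`.
#' @param R0 Forster radius (nm) for the pair.
#' @param id Construct identifier.
#' @return Object of class `fret_construct`.
#' @export
fret_construct <- function(seq, sites, dyes = c("Cy3B", "CF660R"),
                           R0 = 6.0, id = NULL) {
  rec <- as_sequence_record(seq)
  if (!is.null(id)) rec$id <- id
  stopifnot(length(sites) == 2, length(dyes) == 2)
  structure(list(record = rec, sites = as.integer(sites), dyes = dyes,
                 R0 = R0), class = "fret_construct")
}

#' Build a coarse-grained topology
#'
#' One bead per residue linked by harmonic bonds (r0 = 0.38 nm, k = 481.4
#' kJ nm^-2 mol^-1 with \eqn{U = (k/2)(r - r_0)^2}), plus a dye bead tree
#' at each labeling site. Harmonic angle terms (k = 48.14 kJ rad^-2
#' mol^-1) are applied only to chromophore (non-linker) dye beads, with
#' equilibrium angle pi/2 at branch points and pi elsewhere.
#'
#' @param construct A [fret_construct()], or a bare sequence for an
#'   unlabeled chain (then no dyes are added).
#' @param dye_specs Named list of dye specifications.
#' @param params An [hps_params()] used to resolve per-bead values.
#' @param on_noncys What to do when a labeling site is not Cys:
#'   `"warn"` (default), `"error"`, or `"ignore"`.
#' @return Object of class `cg_topology` with elements `beads`
#'   (data.frame: label, type, lambda, sigma, q, mass), `bonds`
#'   (i, j, r0, k), `angles` (i, j, k_idx, theta0, k), `dye_center`
#'   (two bead indices or `NULL`), `n_residues`.
#' @export
build_topology <- function(construct, dye_specs = default_dye_specs(),
                           params = hps_params(),
                           on_noncys = c("warn", "error", "ignore")) {
  on_noncys <- match.arg(on_noncys)
  if (!inherits(construct, "fret_construct")) {
    rec <- as_sequence_record(construct)
    construct <- NULL
  } else rec <- construct$record
  chars <- rec$chars
  n_res <- length(chars)
  bad <- which(!(chars %in% AA1))
  if (length(bad)) stop("non-canonical residue at position ", bad[1])
  tab <- params$table
  beads <- data.frame(label = paste0(chars, seq_len(n_res)), type = chars,
                      stringsAsFactors = FALSE)
  bonds <- if (n_res > 1)
    data.frame(i = seq_len(n_res - 1), j = 2:n_res) else
      data.frame(i = integer(), j = integer())
  angles <- data.frame(i = integer(), j = integer(), k_idx = integer(),
                       theta0 = numeric())
  dye_center <- integer(0)

  if (!is.null(construct)) {
    for (s in seq_along(construct$sites)) {
      site <- construct$sites[s]
      if (site < 1 || site > n_res) stop("labeling site out of range")
      if (chars[site] != "C") {
        msg <- sprintf("labeling site %d is %s, not Cys", site, chars[site])
        if (on_noncys == "error") stop(msg)
        if (on_noncys == "warn") warning(msg)
      }
      spec <- dye_specs[[construct$dyes[s]]]
      if (is.null(spec)) stop("unknown dye '", construct$dyes[s], "'")
      if (!all(c("beads", "bonds", "center") %in% names(spec)) ||
          !all(spec$beads$type %in% tab$type))
        stop("malformed dye specification '", construct$dyes[s], "'")
      off <- nrow(beads)
      idx <- setNames(off + seq_len(nrow(spec$beads)), spec$beads$label)
      lab <- function(l) if (l == "ATT") site else unname(idx[l])
      beads <- rbind(beads, data.frame(
        label = paste0(spec$name, "_", spec$beads$label, "_", s),
        type = spec$beads$type, stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(
        i = vapply(spec$bonds$from, lab, 0L),
        j = vapply(spec$bonds$to, lab, 0L)))
      if (nrow(spec$angles))
        angles <- rbind(angles, data.frame(
          i = vapply(spec$angles$a, lab, 0L),
          j = vapply(spec$angles$b, lab, 0L),
          k_idx = vapply(spec$angles$c, lab, 0L),
          theta0 = spec$angles$theta0))
      dye_center <- c(dye_center, unname(idx[spec$center]))
    }
  }
  beads$lambda <- tab[beads$type, "lambda"]
  beads$sigma <- tab[beads$type, "sigma"]
  beads$q <- tab[beads$type, "q"]
  beads$mass <- tab[beads$type, "mass"]
  bonds$r0 <- rep(0.38, nrow(bonds))
  bonds$k <- rep(481.4, nrow(bonds))
  angles$k <- rep(48.14, nrow(angles))
  structure(list(beads = beads, bonds = bonds, angles = angles,
                 dye_center = if (length(dye_center)) dye_center else NULL,
                 n_residues = n_res,
                 R0 = if (!is.null(construct)) construct$R0 else NA_real_,
                 id = rec$id),
            class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %s: %d beads (%d residues), %d bonds, %d angles\n",
              x$id, nrow(x$beads), x$n_residues, nrow(x$bonds),
              nrow(x$angles)))
  if (!is.null(x$dye_center))
    cat("  dye-center beads:", paste(x$dye_center, collapse = ", "), "\n")
  invisible(x)
}

# initial configuration: extended chain along z for the residue backbone;
# dye beads grow outward in the x-y plane, each child of a parent taking a
# fresh direction so no two beads coincide
initial_coords <- function(top, spacing = 0.38) {
  n <- nrow(top$beads)
  x <- matrix(0, n, 3)
  x[seq_len(top$n_residues), 3] <- (seq_len(top$n_residues) - 1) * spacing
  if (n > top$n_residues) {
    kids <- integer(n)  # children already placed per parent
    for (i in (top$n_residues + 1):n) {
      nb <- c(top$bonds$i[top$bonds$j == i], top$bonds$j[top$bonds$i == i])
      nb <- nb[nb < i][1]
      theta <- kids[nb] * 2.51 + (i %% 7) * 0.05  # ~144 deg per sibling
      kids[nb] <- kids[nb] + 1L
      x[i, ] <- x[nb, ] + spacing * c(cos(theta), sin(theta), 0.15)
    }
  }
  x
}

#' Propagate Langevin dynamics of an HPS topology
#'
#' BAOAB-discretized Langevin dynamics at fixed temperature. The first
#' `equil_frac` of the run is discarded as equilibration; the remaining
#' frames, saved every `stride` steps, form the returned trajectory.
#' Identical seeds give bit-identical trajectories.
#'
#' @param topology A [build_topology()] result.
#' @param params An [hps_params()].
#' @param steps Number of integration steps.
#' @param dt_fs Time step (fs); default 10.
#' @param friction Friction coefficient (1/ps); default 1.0.
#' @param temperature Temperature (K); defaults to the parameter set's.
#' @param seed Mandatory RNG seed.
#' @param stride Save a frame every this many steps.
#' @param equil_frac Fraction of the run discarded as equilibration.
#' @param x0 Optional n_beads x 3 starting coordinates (nm).
#' @param energy_abort Abort when |U| exceeds this (kJ/mol).
#' @param minimize_steps Displacement-capped steepest-descent steps
#'   relaxing the starting structure before dynamics.
#' @return Object of class `cg_trajectory`: `frames` (array
#'   frames x beads x 3, nm), `potential`, `kinetic` (kJ/mol per frame),
#'   `mean_kinetic`, metadata.
#' @export
run_langevin <- function(topology, params = hps_params(), steps,
                         dt_fs = 10, friction = 1.0, temperature = NULL,
                         seed, stride = 1000L, equil_frac = 1 / 6,
                         x0 = NULL, energy_abort = 1e7,
                         minimize_steps = 500L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(temperature)) temperature <- params$temperature
  b <- topology$beads
  if (is.null(x0)) x0 <- initial_coords(topology)
  lD <- debye_length(params$ionic_strength, temperature, params$eps_r)
  res <- hps_run_langevin(
    x0, b$lambda, b$sigma, b$q, b$mass,
    as.matrix(topology$bonds[, c("i", "j")]), topology$bonds$r0,
    topology$bonds$k,
    if (nrow(topology$angles))
      as.matrix(topology$angles[, c("i", "j", "k_idx")]) else
        matrix(0L, 0, 3),
    topology$angles$k, topology$angles$theta0,
    params$eps, params$cutoff, params$dh_cutoff,
    138.935458 / params$eps_r, lD, temperature, dt_fs / 1000,
    friction, steps, as.integer(stride), seed, energy_abort,
    as.integer(minimize_steps))
  nf <- res$n_frames
  frames <- aperm(array(res$frames, c(3, nrow(b), nf)), c(3, 2, 1))
  keep <- seq_len(nf) > floor(equil_frac * nf)
  structure(list(frames = frames[keep, , , drop = FALSE],
                 potential = res$potential[keep],
                 kinetic = res$kinetic[keep],
                 mean_kinetic = res$mean_kinetic,
                 n_equil_dropped = sum(!keep),
                 dt_fs = dt_fs, stride = stride, friction = friction,
                 temperature = temperature, seed = seed,
                 topology = topology, params = params),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[1]
  cat(sprintf(
    "<cg_trajectory> %d frames x %d beads (stride %d x %g fs; seed %s)\n",
    nf, dim(x$frames)[2], x$stride, x$dt_fs, format(x$seed)))
  cat(sprintf("  sampled time %.3f ns (+%d equilibration frames dropped)\n",
              nf * x$stride * x$dt_fs * 1e-6, x$n_equil_dropped))
  invisible(x)
}

# frames array -> the (3, N, F) layout used by the compiled accumulators
frames_flat <- function(frames) {
  stopifnot(length(dim(frames)) == 3)
  out <- aperm(frames, c(3, 2, 1))
  dim(out) <- c(3L, dim(frames)[2], dim(frames)[1])
  out
}

#' FRET observables from a trajectory
#'
#' Per-frame transfer efficiency \eqn{E = 1/(1 + (r/R_0)^6)} with `r` the
#' distance between the two designated dye-center beads, and its
#' unweighted mean over the (post-equilibration) frames.
#'
#' @param traj A [run_langevin()] trajectory.
#' @param dye_pair Two bead indices; defaults to the topology's
#'   `dye_center`.
#' @param R0 Forster radius (nm); defaults to the construct's.
#' @return List with `E` (per frame), `mean_E`, `r` (per-frame distance).
#' @export
fret_from_trajectory <- function(traj, dye_pair = NULL, R0 = NULL) {
  if (is.null(dye_pair)) dye_pair <- traj$topology$dye_center
  if (is.null(dye_pair) || length(dye_pair) != 2)
    stop("trajectory has no designated dye-center beads")
  if (is.null(R0)) R0 <- traj$topology$R0
  if (!is.finite(R0)) stop("no Forster radius available")
  d <- traj$frames[, dye_pair[1], , drop = FALSE] -
    traj$frames[, dye_pair[2], , drop = FALSE]
  r <- sqrt(rowSums(matrix(d, nrow = dim(traj$frames)[1])^2))
  E <- 1 / (1 + (r / R0)^6)
  list(E = E, mean_E = mean(E), r = r)
}

#' Convert a trajectory to a weighted ensemble
#'
#' @param traj A `cg_trajectory`.
#' @param sites `"residue"` (default: the protein beads only) or `"all"`.
#' @return A [conformational_ensemble()] with uniform weights.
#' @export
as_ensemble <- function(traj, sites = c("residue", "all")) {
  sites <- match.arg(sites)
  idx <- if (sites == "residue") seq_len(traj$topology$n_residues) else
    seq_len(dim(traj$frames)[2])
  conformational_ensemble(traj$frames[, idx, , drop = FALSE],
                          labels = traj$topology$beads$type[idx])
}

#' Write / read a trajectory as xyz text plus JSON metadata
#'
#' @param traj A `cg_trajectory`.
#' @param path Output `.xyz` path; metadata goes to `paste0(path, ".json")`.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  labs <- traj$topology$beads$label
  nf <- dim(traj$frames)[1]
  for (f in seq_len(nf)) {
    writeLines(c(as.character(length(labs)), sprintf("frame %d", f)), con)
    xyz <- traj$frames[f, , ]
    writeLines(sprintf("%s %.6f %.6f %.6f", labs, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  jsonlite::write_json(
    list(seed = traj$seed, dt_fs = traj$dt_fs, stride = traj$stride,
         friction = traj$friction, temperature = traj$temperature,
         n_frames = nf, n_equil_dropped = traj$n_equil_dropped),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_xyz
#' @return `read_trajectory_xyz()` returns an array frames x beads x 3.
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  block <- n + 2L
  nf <- length(lines) %/% block
  out <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    rows <- lines[((f - 1) * block + 3):((f - 1) * block + 2 + n)]
    m <- do.call(rbind, lapply(strsplit(rows, " +"), function(p)
      as.numeric(p[2:4])))
    out[f, , ] <- m
  }
  out
}
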