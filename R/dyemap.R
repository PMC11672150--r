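# Rotamer-library dye attachment to ensemble frames with steric clash
# rejection, and per-frame FRET efficiencies from the surviving dye-pair
# distances (in-silico fluorophore placement on simulated conformations).

#' An atomistic (or pseudo-atomistic) frame
#'
#' @param coords Atoms x 3 matrix (nm).
#' @param residue Integer residue index per atom.
#' @param name Atom name per atom (e.g. `"CB"`, `"SG"`).
#' @return List of class `structure_frame`.
#' @export
structure_frame <- function(coords, residue, name) {
  stopifnot(nrow(coords) == length(residue), length(residue) == length(name))
  structure(list(coords = coords, residue = as.integer(residue),
                 name = as.character(name)), class = "structure_frame")
}

# rotation taking unit +z onto unit vector a (Rodrigues)
rotation_z_to <- function(a) {
  a <- a / sqrt(sum(a^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  c_ <- sum(z * a)
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))  # antiparallel
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# anchor (Sgamma) position and outward Cbeta -> Sgamma axis for a site
attachment_geometry <- function(frame, site, frame_id = NA) {
  at <- which(frame$residue == site)
  sg <- at[frame$name[at] == "SG"]
  cb <- at[frame$name[at] == "CB"]
  if (length(sg) != 1 || length(cb) != 1)
    stop(sprintf("frame %s: residue %d lacks resolvable CB/SG atoms",
                 format(frame_id), site))
  anchor <- frame$coords[sg, ]
  axis <- anchor - frame$coords[cb, ]
  list(anchor = anchor, axis = axis, atoms = at)
}

place_rotamer <- function(rot, anchor, axis) {
  R <- rotation_z_to(axis)
  sweep(rot %*% t(R), 2, anchor, "+")
}

any_clash <- function(a, b, radius) {
  # any pair of rows of a and b closer than radius
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    if (any(d2 < radius^2)) return(TRUE)
  }
  FALSE
}

#' Attach dye rotamers to one frame with clash rejection
#'
#' For each labeling site, up to `n_trials` rotamers are drawn (with
#' replacement) from the library, placed with ideal gamma-sulfur geometry
#' along the Cbeta-Sgamma axis, and rejected if any dye atom comes within
#' `clash_radius` of any protein atom outside the attachment residue. If
#' both sites reach `min_success` accepted placements, all cross pairs
#' are formed, mutually clashing dye pairs are discarded (same radius),
#' and the surviving center-to-center distances are recorded; otherwise
#' the frame is rejected.
#'
#' @param frame A [structure_frame()].
#' @param site1,site2 Residue indices of the labeling sites.
#' @param library A rotamer library (see [gen_rotamer_library()]): per
#'   dye, a list of rotamer coordinate matrices (local frame, anchor at
#'   the origin, attachment axis +z) and a `center` atom index.
#' @param dyes Names of the two dyes in `library`.
#' @param n_trials Rotamer draws per site.
#' @param clash_radius Steric clash distance (nm); default 0.5 (5 A).
#' @param min_success Minimum accepted placements per site.
#' @param seed RNG seed (deterministic placement).
#' @param frame_id Identifier used in error messages.
#' @return List: `accepted` (logical), `distances` (nm, possibly empty),
#'   `n1`, `n2` (accepted placements per site).
#' @export
attach_dyes <- function(frame, site1, site2, library,
                        dyes = names(library)[1:2], n_trials = 50,
                        clash_radius = 0.5, min_success = 20, seed = 1,
                        frame_id = NA) {
  g1 <- attachment_geometry(frame, site1, frame_id)
  g2 <- attachment_geometry(frame, site2, frame_id)
  with_seed(seed, {
    place_site <- function(geom, dye) {
      lib <- library[[dye]]
      excl <- geom$atoms
      prot <- frame$coords[-excl, , drop = FALSE]
      keep <- list()
      for (t in seq_len(n_trials)) {
        rot_i <- sample.int(length(lib$rotamers), 1)
        xyz <- place_rotamer(lib$rotamers[[rot_i]], geom$anchor, geom$axis)
        if (nrow(prot) == 0 || !any_clash(xyz, prot, clash_radius))
          keep[[length(keep) + 1]] <- list(xyz = xyz,
                                           center = xyz[lib$center, ])
      }
      keep
    }
    k1 <- place_site(g1, dyes[1])
    k2 <- place_site(g2, dyes[2])
    if (length(k1) < min_success || length(k2) < min_success)
      return(list(accepted = FALSE, distances = numeric(0),
                  n1 = length(k1), n2 = length(k2)))
    dists <- numeric(0)
    for (a in k1) for (b in k2) {
      if (!any_clash(a$xyz, b$xyz, clash_radius))
        dists <- c(dists, sqrt(sum((a$center - b$center)^2)))
    }
    list(accepted = length(dists) > 0, distances = dists,
         n1 = length(k1), n2 = length(k2))
  })
}

#' Mean FRET efficiency of one frame from dye-pair distances
#'
#' \eqn{E = \mathrm{mean}_r\, 1/(1 + (r/R_0)^6)} over the surviving dye
#' pair distances of the frame.
#'
#' @param distances Center-to-center dye distances (nm).
#' @param R0 Forster radius (nm); default 6.
#' @return Scalar in (0, 1); `NA` for an empty distance set.
#' @export
frame_mean_efficiency <- function(distances, R0 = 6) {
  if (!length(distances)) return(NA_real_)
  mean(1 / (1 + (distances / R0)^6))
}

#' Per-frame dye-mapped efficiencies for an ensemble
#'
#' Runs [attach_dyes()] on every frame and summarizes the accepted
#' frames, producing the per-frame observable table consumed by
#' [maxent()].
#'
#' @param frames List of [structure_frame()]s (or a
#'   `conformational_ensemble` of bead coordinates, converted with
#'   pseudo CB/SG atoms via [cg_frames()]).
#' @inheritParams attach_dyes
#' @param R0 Forster radius (nm).
#' @param seed Base seed; each frame uses `seed + frame index`.
#' @return `data.frame`: `frame`, `n_pairs`, `E_frame` (NA for rejected
#'   frames).
#' @export
ensemble_dye_efficiencies <- function(frames, site1, site2, library,
                                      dyes = names(library)[1:2],
                                      R0 = 6, n_trials = 50,
                                      clash_radius = 0.5,
                                      min_success = 20, seed = 1) {
  rows <- lapply(seq_along(frames), function(f) {
    res <- attach_dyes(frames[[f]], site1, site2, library, dyes,
                       n_trials, clash_radius, min_success,
                       seed = seed + f, frame_id = f)
    data.frame(frame = f,
               n_pairs = length(res$distances),
               E_frame = if (res$accepted)
                 frame_mean_efficiency(res$distances, R0) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Pseudo-atomistic frames from bead coordinates
#'
#' Gives each bead a `CB` atom at the bead position and an `SG` atom
#' displaced `sg_offset` nm perpendicular to the local chain direction,
#' so that bead-model ensembles can be dye-mapped with [attach_dyes()].
#'
#' @param ens A [conformational_ensemble()] (one site per residue).
#' @param sg_offset Pseudo-Sgamma displacement from the bead (nm).
#' @return List of [structure_frame()]s.
#' @export
cg_frames <- function(ens, sg_offset = 0.18) {
  nf <- dim(ens$coords)[1]; n <- dim(ens$coords)[2]
  lapply(seq_len(nf), function(f) {
    x <- ens$coords[f, , ]
    # local chain tangent; perpendicular offset for the pseudo-Sgamma
    tang <- rbind(x[2, ] - x[1, ], x[-1, , drop = FALSE] -
                    x[-n, , drop = FALSE])
    perp <- t(vapply(seq_len(n), function(i) {
      v <- tang[i, ]
      p <- c(-v[2], v[1], 0)
      if (sum(p^2) < 1e-12) p <- c(1, 0, 0)
      p / sqrt(sum(p^2))
    }, numeric(3)))
    coords <- rbind(x, x + sg_offset * perp)
    structure_frame(coords, rep(seq_len(n), 2),
                    c(rep("CB", n), rep("SG", n)))
  })
}
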