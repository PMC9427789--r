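#' Two-sphere toy structure
#'
#' Two single-atom chains (carbon CA atoms) at a given separation, for which
#' SASA and buried surface area have closed forms: when two expanded spheres
#' of radius R overlap at centre distance d < 2R, each loses a spherical cap
#' of area `2*pi*R*(R - d/2)`.
#'
#' @param separation centre-centre distance in Angstrom (> 0).
#' @return a [structure_model()] with chains `"A"` and `"B"`.
#' @export
make_sphere_pair <- function(separation) {
  .assert(separation > 0, "separation must be positive")
  atoms <- data.frame(
    chain = c("A", "B"), resno = c(1L, 1L), icode = "", resid = "ALA",
    eleno = 1:2, elety = "CA", element = "C",
    x = c(0, separation), y = 0, z = 0, o = 1, alt = "",
    hydrogen = FALSE, stringsAsFactors = FALSE)
  structure_model(atoms, metadata = list(generator = "sphere_pair",
                                         separation = separation))
}

#' Spherical-cap area lost by each of two overlapping spheres
#'
#' @param R sphere radius (already probe-expanded).
#' @param d centre distance (< 2R for overlap).
#' @return cap area in A^2 (0 when d >= 2R).
#' @export
sphere_cap_area <- function(R, d) {
  ifelse(d >= 2 * R, 0, 2 * pi * R * (R - d / 2))
}

# x slot of antigen residue number r in the toy complex layout
.slot_x <- function(resno) 4 * (resno - 39)

.toy_resnames <- function(n) {
  rep(c("SER", "TYR", "ASP", "ARG", "ASN", "THR", "GLU", "LYS", "LEU", "VAL"),
      length.out = n)
}

.toy_chain_atoms <- function(chain, resno, x, y, z, eleno_start, resid = NULL,
                             cb_dz = -1.8) {
  n <- length(resno)
  resid <- resid %||% .toy_resnames(n)
  data.frame(
    chain = chain, resno = rep(resno, each = 2L), icode = "",
    resid = rep(resid, each = 2L),
    eleno = eleno_start + seq_len(2L * n) - 1L,
    elety = rep(c("CA", "CB"), n), element = "C",
    x = rep(x, each = 2L), y = rep(y, each = 2L),
    z = as.numeric(rbind(z, z + cb_dz)),
    o = 1, alt = "", hydrogen = FALSE, stringsAsFactors = FALSE)
}

#' Synthetic Fv-antigen complex with known interface
#'
#' Builds a miniature antigen (30 residues, numbered 40-69, CA plus one
#' pseudo-side-chain CB atom per residue) docked against a miniature
#' two-chain Fv carrying Chothia-compatible residue numbers. Eleven antibody
#' residues -- spread over all six CDRs plus two framework positions flanking
#' them -- are placed in contact with eleven antigen residues (numbers
#' 45-55); the constructed contact sets are returned as ground truth. A
#' matching reference antigen-receptor complex is also returned, in which a
#' pseudo-receptor chain `"R"` occupies the same antigen footprint, for
#' receptor-blockage analysis.
#'
#' @param seed RNG seed for the small coordinate jitter.
#' @param jitter_sd coordinate jitter in Angstrom (default 0.15).
#' @return list with `pose` (a [pose()], antigen chain `"A"`, antibody chains
#'   `"H"`/`"L"`), `annotation` (an [annotate_fv()] result), `truth` (list
#'   `epitope`, `paratope` of residue keys), and `reference_complex` (a
#'   [structure_model()] with chains `"A"` and `"R"`).
#' @export
make_fv_complex <- function(seed = 1, jitter_sd = 0.15) {
  set.seed(.substream_seed(seed, "fv_complex"))
  # antigen: a line of residues at z = 4.2, side chains pointing away (+z)
  ag_resno <- 40:69
  ag <- .toy_chain_atoms("A", ag_resno, x = .slot_x(ag_resno), y = 0, z = 4.2,
                         eleno_start = 1L, cb_dz = +2.0)
  # paratope design: contacts across all CDRs plus two framework flanks
  para_h <- c(31L, 33L, 53L, 95L, 98L, 101L)
  para_l <- c(32L, 49L, 50L, 91L, 96L)
  epi_resno <- 45:55 # 11 antigen residues, one per paratope contact
  contact_x <- .slot_x(epi_resno)
  h_resno <- c(24:60, 90:106)
  l_resno <- c(22:58, 87:99)
  place <- function(chain, resno, para, y_off, slot_from) {
    x <- 20 + 1.8 * seq_along(resno)
    y <- rep(y_off, length(resno))
    z <- rep(-6, length(resno))
    hit <- match(para, resno)
    x[hit] <- contact_x[slot_from + seq_along(para)]
    y[hit] <- 0
    z[hit] <- 0
    list(x = x, y = y, z = z)
  }
  ph <- place("H", h_resno, para_h, -4, 0L)
  pl <- place("L", l_resno, para_l, +4, length(para_h))
  hv <- .toy_chain_atoms("H", h_resno, ph$x, ph$y, ph$z,
                         eleno_start = max(ag$eleno) + 1L)
  lt <- .toy_chain_atoms("L", l_resno, pl$x, pl$y, pl$z,
                         eleno_start = max(ag$eleno) + 2L * length(h_resno) + 1L)
  atoms <- rbind(ag, hv, lt)
  atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(atoms), 0, jitter_sd), ncol = 3)
  cx <- structure_model(atoms, metadata = list(generator = "fv_complex", seed = seed))
  p <- pose(cx, antigen_chains = "A", antibody_chains = c("H", "L"),
            pose_id = "reference")
  ann <- annotate_fv(cx, heavy = "H", light = "L")
  truth <- list(epitope = residue_key("A", epi_resno),
                paratope = c(residue_key("H", para_h), residue_key("L", para_l)))
  # reference receptor complex: pseudo-receptor occupies the same footprint
  rec <- .toy_chain_atoms("R", seq_along(epi_resno), contact_x, 0, 0,
                          eleno_start = max(ag$eleno) + 1L)
  ref_atoms <- rbind(ag, rec)
  ref_atoms[, c("x", "y", "z")] <- ref_atoms[, c("x", "y", "z")] +
    matrix(stats::rnorm(3 * nrow(ref_atoms), 0, jitter_sd), ncol = 3)
  ref <- structure_model(ref_atoms,
                         metadata = list(generator = "receptor_complex", seed = seed))
  list(pose = p, annotation = ann, truth = truth, reference_complex = ref)
}

# random small rotation matrix: uniform axis, normal angle (degrees)
.small_rotation <- function(sd_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, sd_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.move_antibody <- function(p, rot, shift) {
  a <- p$complex$atoms
  ab <- a$chain %in% p$antibody_chains
  xyz <- as.matrix(a[ab, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, ctr + shift, `+`)
  a[ab, c("x", "y", "z")] <- xyz
  p$complex <- structure_model(a, p$complex$metadata)
  p
}

#' Generate a pose set from a reference complex
#'
#' Near-native poses are small random rigid perturbations of the antibody;
#' decoys re-dock the antibody on the wrong face (flipped 180 degrees so its
#' framework back contacts the antigen, with a random lateral shift). Each
#' pose carries its ground-truth label in attribute `"label"` and a synthetic
#' binding energy (near-natives drawn lower than decoys).
#'
#' @param reference a [pose()] (e.g. from [make_fv_complex()]).
#' @param n number of poses (>= 2).
#' @param trans_sd,rot_sd_deg near-native perturbation magnitudes.
#' @param decoy_fraction fraction of decoys in [0, 1].
#' @param seed RNG seed.
#' @return list of [pose()]s; `attr(pose, "label")` is `"near_native"` or
#'   `"decoy"`.
#' @export
make_pose_set <- function(reference, n = 20, trans_sd = 0.5, rot_sd_deg = 5,
                          decoy_fraction = 0.5, seed = 1) {
  .assert(n >= 2, "need at least 2 poses")
  .assert(decoy_fraction >= 0 && decoy_fraction <= 1,
          "decoy_fraction outside [0, 1]")
  set.seed(.substream_seed(seed, "pose_set"))
  n_decoy <- round(n * decoy_fraction)
  labels <- c(rep("near_native", n - n_decoy), rep("decoy", n_decoy))
  a0 <- reference$complex$atoms
  ab_sel <- a0$chain %in% reference$antibody_chains
  out <- vector("list", n)
  for (k in seq_len(n)) {
    if (labels[k] == "near_native") {
      p <- .move_antibody(reference, .small_rotation(rot_sd_deg),
                          stats::rnorm(3, 0, trans_sd))
      energy <- stats::rnorm(1, -100, 5)
    } else {
      # flip about the x axis through the antibody centroid, then raise the
      # (framework) back face to the contact plane and shift sideways
      flip <- diag(c(1, -1, -1))
      p <- .move_antibody(reference, flip, c(stats::runif(1, -8, 8), 0, 0))
      az <- p$complex$atoms
      dz <- max(a0$z[ab_sel]) - max(az$z[az$chain %in% reference$antibody_chains])
      p <- .move_antibody(p, diag(3), c(0, 0, dz))
      energy <- stats::rnorm(1, -60, 5)
    }
    p$pose_id <- sprintf("pose%03d", k)
    p$binding_energy <- energy
    attr(p, "label") <- labels[k]
    out[[k]] <- p
  }
  out
}

#' Simulate an ELISA dilution panel
#'
#' Generates 4PL-shaped binding curves for a panel of mutants with known true
#' Kd values, on a three-fold dilution series (default: 8 points from 9
#' downward, emulating the standard indirect-ELISA design). The fold-change
#' ground truth is `kd_mut / kd_wt`.
#'
#' @param true_kds named numeric vector of true Kd values (same unit as the
#'   concentrations) including `"WT"`.
#' @param concentrations dilution series (default `9 * (1/3)^(0:7)`).
#' @param noise_sd gaussian A450 noise (default 0.02).
#' @param seed RNG seed.
#' @param bottom,top,hill true curve parameters.
#' @param unit concentration unit label.
#' @return named list of [binding_curve()]s; attribute `"true_fold"` holds
#'   the ground-truth fold changes.
#' @export
make_elisa_panel <- function(true_kds, concentrations = 9 * (1 / 3)^(0:7),
                             noise_sd = 0.02, seed = 1,
                             bottom = 0.05, top = 2.0, hill = 1,
                             unit = "ug/mL") {
  .assert("WT" %in% names(true_kds), "panel must include 'WT'")
  set.seed(.substream_seed(seed, "elisa_panel"))
  x <- sort(concentrations)
  curves <- lapply(names(true_kds), function(id) {
    mu <- bottom + (top - bottom) / (1 + (true_kds[[id]] / x)^hill)
    binding_curve(id, x, mu + stats::rnorm(length(x), 0, noise_sd), unit = unit)
  })
  names(curves) <- names(true_kds)
  attr(curves, "true_fold") <- true_kds / true_kds[["WT"]]
  curves
}

#' Simulate an ortholog sequence pair with planted differences
#'
#' Random reference sequence; the query is identical except at the planted
#' positions, where it carries the given letters. Reference letters at those
#' positions can be forced with `ref_override` (e.g. to plant a specific
#' back-mutation landscape).
#'
#' @param length sequence length.
#' @param planted_query named character vector: reference position ->
#'   query letter.
#' @param ref_override named character vector: reference position ->
#'   reference letter.
#' @param seed RNG seed.
#' @return list with `ref_seq` and `query_seq` (strings).
#' @export
make_ortholog_pair <- function(length = 180, planted_query = character(0),
                               ref_override = character(0), seed = 1) {
  set.seed(.substream_seed(seed, "ortholog_pair"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pos_q <- as.integer(names(planted_query))
  pos_r <- as.integer(names(ref_override))
  .assert(!anyDuplicated(pos_q), "duplicate planted positions")
  .assert(all(c(pos_q, pos_r) >= 1) && all(c(pos_q, pos_r) <= length),
          "planted positions outside sequence length")
  ref <- sample(aa, length, replace = TRUE)
  ref[pos_r] <- ref_override
  query <- ref
  query[pos_q] <- planted_query
  # planted positions must actually differ; nudge the reference when the
  # random draw collides (deterministic choice: next letter in the alphabet)
  coll <- pos_q[ref[pos_q] == query[pos_q] & !(pos_q %in% pos_r)]
  for (p in coll) ref[p] <- aa[(match(ref[p], aa) %% 20) + 1]
  .assert(all(ref[pos_q] != query[pos_q]),
          "planted difference conflicts with ref_override")
  list(ref_seq = paste(ref, collapse = ""),
       query_seq = paste(query, collapse = ""))
}
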