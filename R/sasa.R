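#' Van der Waals radii
#'
#' Radii (Angstrom) for the elements found in protein structures, after
#' Bondi-style compilations; `"*"` is the fallback for anything unlisted.
#' Remove the fallback entry to make unknown elements an error.
#'
#' @return named numeric vector.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
    SE = 1.90, "*" = 1.80)
}

#' SASA parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom sphere (>= 60); more points,
#'   smaller quadrature error.
#' @param radii_set named element -> radius map; see [default_vdw_radii()].
#' @return object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_points = 960,
                        radii_set = default_vdw_radii()) {
  .assert(probe_radius > 0, "probe_radius must be positive")
  .assert(n_points >= 60, "n_points must be at least 60")
  .assert(all(radii_set > 0), "all radii must be positive")
  structure(list(probe_radius = probe_radius, n_points = as.integer(n_points),
                 radii_set = radii_set), class = "sasa_params")
}

# deterministic quasi-uniform sphere lattice (golden-angle spiral); no RNG so
# repeated runs are bit-identical
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements, radii_set) {
  r <- unname(radii_set[elements])
  if (anyNA(r)) {
    if ("*" %in% names(radii_set)) {
      r[is.na(r)] <- radii_set[["*"]]
    } else {
      stop("no radius for element(s): ",
           paste(unique(elements[is.na(r)]), collapse = ", "), call. = FALSE)
    }
  }
  r
}

.sasa_result <- function(model, per_atom, se = NULL) {
  a <- model$atoms
  key <- residue_key(a$chain, a$resno, a$icode)
  per_res <- tapply(per_atom, key, sum)
  # keep residue file order
  per_res <- per_res[unique(key)]
  out <- list(per_atom = per_atom, per_residue = per_res,
              total = sum(per_atom), se = se)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: total", round(x$total, 2), "A^2 over",
      length(x$per_residue), "residues\n")
  invisible(x)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-counting SASA: each atom's van der Waals sphere is expanded
#' by the probe radius, covered with a deterministic quasi-uniform lattice of
#' `n_points` test points, and the accessible area is
#' `4*pi*(r+probe)^2 * exposed/n_points`, a point being exposed when it lies
#' outside every neighbouring expanded sphere. Hydrogens are ignored by
#' default.
#'
#' @param model a [structure_model()].
#' @param params a [sasa_params()].
#' @param include_hydrogens include flagged hydrogen atoms (default FALSE).
#' @return a `sasa_result` with per-atom areas (named by atom row), per-residue
#'   areas (named by residue key) and the total, all in Angstrom^2.
#' @export
shrake_rupley <- function(model, params = sasa_params(),
                          include_hydrogens = FALSE) {
  a <- model$atoms
  if (!include_hydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  .assert(nrow(a) > 0, "model has no (heavy) atoms")
  sub <- structure_model(a, model$metadata)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .atom_radii(a$element, params$radii_set) + params$probe_radius
  pts <- golden_spiral_points(params$n_points)
  n <- nrow(a)
  per_atom <- numeric(n)
  maxr <- max(rad)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < rad[i] + rad[nb]]
    full <- 4 * pi * rad[i]^2
    if (length(nb) == 0L) { per_atom[i] <- full; next }
    P <- sweep(pts * rad[i], 2, xyz[i, ], `+`)       # n_points x 3
    exposed <- rep(TRUE, params$n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (P[exposed, 1] - xyz[j, 1])^2 + (P[exposed, 2] - xyz[j, 2])^2 +
             (P[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj2 >= rad[j]^2
    }
    per_atom[i] <- full * sum(exposed) / params$n_points
  }
  .sasa_result(sub, per_atom)
}

#' Monte-Carlo SASA (testing oracle)
#'
#' Unbiased estimate of the same quantity as [shrake_rupley()] by uniform
#' random sampling on each expanded sphere, with a per-atom binomial standard
#' error. Used as an independent cross-check of the deterministic lattice.
#'
#' @inheritParams shrake_rupley
#' @param n_samples random directions per atom (>= 100).
#' @param seed RNG seed; same seed, same result.
#' @return a `sasa_result`; `$se` holds per-atom standard errors.
#' @export
monte_carlo_sasa <- function(model, params = sasa_params(), n_samples = 10000,
                             seed = 1, include_hydrogens = FALSE) {
  .assert(n_samples >= 100, "n_samples must be at least 100")
  a <- model$atoms
  if (!include_hydrogens) a <- a[!a$hydrogen, , drop = FALSE]
  .assert(nrow(a) > 0, "model has no (heavy) atoms")
  sub <- structure_model(a, model$metadata)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .atom_radii(a$element, params$radii_set) + params$probe_radius
  n <- nrow(a)
  per_atom <- numeric(n); se <- numeric(n)
  set.seed(as.integer(seed))
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    P <- sweep(u * rad[i], 2, xyz[i, ], `+`)
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rad[i] + rad & seq_len(n) != i)
    exposed <- rep(TRUE, n_samples)
    for (j in nb) {
      dj2 <- (P[, 1] - xyz[j, 1])^2 + (P[, 2] - xyz[j, 2])^2 +
             (P[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj2 >= rad[j]^2
    }
    p <- mean(exposed)
    full <- 4 * pi * rad[i]^2
    per_atom[i] <- full * p
    se[i] <- full * sqrt(p * (1 - p) / n_samples)
  }
  .sasa_result(sub, per_atom, se = se)
}

#' Reference maximum accessible areas
#'
#' Theoretical per-residue maximum solvent accessibilities (Angstrom^2) from
#' extended Gly-X-Gly tripeptides (Tien et al. 2013, "theoretical" column),
#' the denominator for relative solvent accessibility.
#'
#' @return named numeric vector (3-letter residue codes).
#' @export
max_asa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

#' Relative solvent accessibility
#'
#' RSA = 100 * absolute SASA / reference maximum. Two reference modes:
#' `"theoretical"` uses the published Gly-X-Gly maxima
#' ([max_asa_reference()]); `"structure_max"` normalises by the largest
#' observed area of the same residue type within this structure. Residue
#' types with no reference are flagged and excluded.
#'
#' @param sasa a `sasa_result` from [shrake_rupley()] or [monte_carlo_sasa()].
#' @param model the `structure_model` the SASA was computed on.
#' @param reference_set `"theoretical"` or `"structure_max"`.
#' @return an `rsa_table`: data.frame with `chain`, `resno`, `icode`,
#'   `resname`, `abs_sasa_A2`, `ref_max_A2`, `rsa_percent`, `key`; attribute
#'   `reference_set_name` records the mode; excluded residues in attribute
#'   `excluded`.
#' @export
relative_accessibility <- function(sasa, model,
                                   reference_set = c("theoretical", "structure_max")) {
  reference_set <- match.arg(reference_set)
  res <- residues_of(model)
  res <- res[res$key %in% names(sasa$per_residue), , drop = FALSE]
  abs_sasa <- unname(sasa$per_residue[res$key])
  if (reference_set == "theoretical") {
    ref <- unname(max_asa_reference()[res$resid])
  } else {
    ref <- unname(tapply(abs_sasa, res$resid, max)[res$resid])
    ref[ref <= 0] <- NA_real_
  }
  known <- !is.na(ref)
  excluded <- res$key[!known]
  out <- data.frame(chain = res$chain[known], resno = res$resno[known],
                    icode = res$icode[known], resname = res$resid[known],
                    abs_sasa_A2 = abs_sasa[known], ref_max_A2 = ref[known],
                    rsa_percent = 100 * abs_sasa[known] / ref[known],
                    key = res$key[known], stringsAsFactors = FALSE)
  attr(out, "reference_set_name") <- reference_set
  attr(out, "excluded") <- excluded
  class(out) <- c("rsa_table", "data.frame")
  out
}

#' Select solvent-exposed residues
#'
#' Residues with RSA strictly greater than the threshold ("more than 20%"
#' read as strict), optionally intersected with a restriction set, ordered by
#' chain then residue number.
#'
#' @param rsa an `rsa_table` from [relative_accessibility()].
#' @param threshold_percent exposure cutoff (default 20).
#' @param restrict_to optional character vector of residue keys.
#' @return character vector of residue keys.
#' @export
select_exposed <- function(rsa, threshold_percent = 20, restrict_to = NULL) {
  .assert(nrow(rsa) > 0, "empty RSA table")
  sel <- rsa[rsa$rsa_percent > threshold_percent, , drop = FALSE]
  if (!is.null(restrict_to)) sel <- sel[sel$key %in% restrict_to, , drop = FALSE]
  sel <- sel[order(sel$chain, sel$resno, sel$icode), , drop = FALSE]
  sel$key
}

#' Export an RSA table as CSV
#'
#' @param rsa an `rsa_table`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_rsa_csv <- function(rsa, path) {
  utils::write.csv(rsa[, c("chain", "resno", "icode", "resname",
                           "abs_sasa_A2", "ref_max_A2", "rsa_percent")],
                   path, row.names = FALSE)
  invisible(path)
}
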