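#' Docking pose
#'
#' One candidate rigid arrangement of antibody relative to antigen: a complex
#' model plus the chain-role assignment. The binding energy (e.g. a docking
#' score) is input metadata and is never computed here.
#'
#' @param complex a [structure_model()] containing all chains.
#' @param antigen_chains,antibody_chains disjoint, non-empty chain-id sets.
#' @param pose_id pose label.
#' @param binding_energy optional number, lower = better.
#' @return object of class `pose`.
#' @export
pose <- function(complex, antigen_chains, antibody_chains, pose_id,
                 binding_energy = NULL) {
  .assert(length(antigen_chains) > 0 && length(antibody_chains) > 0,
          "both chain sets must be non-empty")
  .assert(length(intersect(antigen_chains, antibody_chains)) == 0,
          "antigen and antibody chain sets overlap")
  present <- unique(complex$atoms$chain)
  .assert(all(c(antigen_chains, antibody_chains) %in% present),
          "chain(s) missing from the complex model")
  structure(list(pose_id = pose_id, complex = complex,
                 antigen_chains = antigen_chains,
                 antibody_chains = antibody_chains,
                 binding_energy = binding_energy), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("pose", x$pose_id, ": antigen [", paste(x$antigen_chains, collapse = " "),
      "] vs antibody [", paste(x$antibody_chains, collapse = " "), "]",
      if (!is.null(x$binding_energy)) paste0(", energy ", signif(x$binding_energy, 4)),
      "\n")
  invisible(x)
}

# SASA of complex and of each side in isolation; everything downstream
# (interface residues, BSA, partition) derives from this one computation
.pose_sasa <- function(pose, params) {
  ag <- subset_chains(pose$complex, pose$antigen_chains)
  ab <- subset_chains(pose$complex, pose$antibody_chains)
  both <- subset_chains(pose$complex, c(pose$antigen_chains, pose$antibody_chains))
  list(ag = shrake_rupley(ag, params), ab = shrake_rupley(ab, params),
       complex = shrake_rupley(both, params))
}

.delta_table <- function(ps, pose, delta_threshold) {
  per_res_iso <- c(ps$ag$per_residue, ps$ab$per_residue)
  per_res_cx <- ps$complex$per_residue
  keys <- names(per_res_iso)
  delta <- per_res_iso - per_res_cx[keys]
  pk <- parse_residue_key(keys)
  side <- ifelse(pk$chain %in% pose$antigen_chains, "antigen", "antibody")
  d <- data.frame(key = keys, chain = pk$chain, resno = pk$resno,
                  icode = pk$icode, side = side, delta_sasa = unname(delta),
                  stringsAsFactors = FALSE)
  d[d$delta_sasa >= delta_threshold, , drop = FALSE]
}

#' Interface residues of a pose
#'
#' PISA-style interface membership by loss of solvent accessibility:
#' a residue is at the interface when
#' `dSASA = SASA(side alone) - SASA(in complex)` is at least
#' `delta_threshold` (default 0.1 A^2, which suppresses quadrature noise).
#'
#' @param pose a [pose()].
#' @param params a [sasa_params()].
#' @param delta_threshold minimum dSASA in A^2.
#' @return data.frame: `key`, `chain`, `resno`, `icode`, `side`,
#'   `delta_sasa`.
#' @export
interface_residues <- function(pose, params = sasa_params(),
                               delta_threshold = 0.1) {
  d <- .delta_table(.pose_sasa(pose, params), pose, delta_threshold)
  rownames(d) <- NULL
  d
}

#' Buried surface area of a pose
#'
#' Half-sum (PISA "interface area") convention:
#' `BSA = (SASA_antigen + SASA_antibody - SASA_complex) / 2`.
#'
#' @inheritParams interface_residues
#' @return buried surface area in A^2.
#' @export
buried_surface_area <- function(pose, params = sasa_params()) {
  ps <- .pose_sasa(pose, params)
  (ps$ag$total + ps$ab$total - ps$complex$total) / 2
}

#' Per-region interface area partition
#'
#' Percent of the antibody-side buried area contributed by each CDR and by
#' framework. Antigen-side residues are ignored for this partition, so
#' `CDR_total + FWR = 100` by construction and H1..L3 sum to `CDR_total`.
#'
#' @param interface interface-residue table from [interface_residues()].
#' @param annotation an [annotate_fv()] annotation covering the antibody side.
#' @return named numeric: `H1`, `H2`, `H3`, `L1`, `L2`, `L3`, `CDR_total`,
#'   `FWR` (percent).
#' @export
region_contributions <- function(interface, annotation) {
  ab <- interface[interface$side == "antibody", , drop = FALSE]
  out <- c(H1 = 0, H2 = 0, H3 = 0, L1 = 0, L2 = 0, L3 = 0,
           CDR_total = 0, FWR = 0)
  if (nrow(ab) == 0) return(out)
  reg <- region_of(annotation, ab$key)
  tot <- sum(ab$delta_sasa)
  by_reg <- tapply(ab$delta_sasa, reg, sum)
  cdrs <- c("H1", "H2", "H3", "L1", "L2", "L3")
  for (r in cdrs) if (!is.na(by_reg[r])) out[r] <- 100 * by_reg[r] / tot
  out["CDR_total"] <- sum(out[cdrs])
  fw <- sum(by_reg[names(by_reg) %in% c("FW_H", "FW_L")], na.rm = TRUE)
  out["FWR"] <- 100 * fw / tot
  out
}

#' Full interface report for a pose
#'
#' Computes the SASA of the complex and of each isolated side once, and
#' derives buried surface area, the interface residue list, and (when an Fv
#' annotation is given) the per-region partition.
#'
#' @inheritParams interface_residues
#' @param annotation optional [annotate_fv()] annotation for the antibody.
#' @return an `interface_report`: list with `pose_id`, `bsa`,
#'   `interface_residues`, `region_percent` (or NULL).
#' @export
interface_report <- function(pose, params = sasa_params(), annotation = NULL,
                             delta_threshold = 0.1) {
  ps <- .pose_sasa(pose, params)
  ir <- .delta_table(ps, pose, delta_threshold)
  rownames(ir) <- NULL
  rp <- if (!is.null(annotation)) region_contributions(ir, annotation) else NULL
  structure(list(pose_id = pose$pose_id,
                 bsa = (ps$ag$total + ps$ab$total - ps$complex$total) / 2,
                 interface_residues = ir, region_percent = rp),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat("interface_report [", x$pose_id, "]: BSA", round(x$bsa, 1), "A^2,",
      nrow(x$interface_residues), "interface residues\n")
  if (!is.null(x$region_percent))
    cat("  CDR", round(x$region_percent["CDR_total"], 2), "% / FWR",
        round(x$region_percent["FWR"], 2), "%\n")
  invisible(x)
}

# atom dictionaries for the geometric contact classifier
.hbond_atoms <- function(element) element %in% c("N", "O")
.neg_atoms <- data.frame(
  resid = c("ASP", "ASP", "GLU", "GLU"),
  elety = c("OD1", "OD2", "OE1", "OE2"), stringsAsFactors = FALSE)
.pos_atoms <- data.frame(
  resid = c("LYS", "ARG", "ARG", "ARG", "HIS", "HIS"),
  elety = c("NZ", "NE", "NH1", "NH2", "ND1", "NE2"), stringsAsFactors = FALSE)

.charge_class <- function(atoms) {
  neg <- paste(.neg_atoms$resid, .neg_atoms$elety)
  pos <- paste(.pos_atoms$resid, .pos_atoms$elety)
  k <- paste(atoms$resid, atoms$elety)
  ifelse(k %in% neg, -1L, ifelse(k %in% pos, 1L, 0L)) +
    ifelse(atoms$elety == "OXT", -1L, 0L)
}

#' Geometric classification of cross-molecule contacts
#'
#' Distance-based typing of antigen-antibody atom pairs. Each pair within a
#' cutoff is reported once with the most specific applicable type:
#' `salt_bridge` (opposite formal charges within `cutoffs$salt`) >
#' `hydrogen_bond` (two N/O atoms within `cutoffs$hbond`) >
#' `attractive_charge` (opposite charges within `cutoffs$charge`; ring-system
#' pi interactions are folded into this class) > `nonpolar` (two carbons
#' within `cutoffs$nonpolar`).
#'
#' @param pose a [pose()].
#' @param cutoffs named list of distances in Angstrom.
#' @return data.frame: antigen/antibody residue keys and atom names,
#'   `distance`, `type`.
#' @export
classify_contacts <- function(pose, cutoffs = list(hbond = 3.5, salt = 4.0,
                                                   charge = 5.6, nonpolar = 4.5)) {
  a <- pose$complex$atoms
  a <- a[!a$hydrogen, , drop = FALSE]
  ag <- a[a$chain %in% pose$antigen_chains, , drop = FALSE]
  ab <- a[a$chain %in% pose$antibody_chains, , drop = FALSE]
  empty <- data.frame(antigen_key = character(0), antigen_atom = character(0),
                      antibody_key = character(0), antibody_atom = character(0),
                      distance = numeric(0), type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ag) == 0 || nrow(ab) == 0) return(empty)
  maxcut <- max(unlist(cutoffs))
  xg <- as.matrix(ag[, c("x", "y", "z")]); xb <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(xg^2), rowSums(xb^2), `+`) - 2 * xg %*% t(xb)
  hit <- which(d2 <= maxcut^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  i <- hit[, 1]; j <- hit[, 2]
  dist <- sqrt(pmax(d2[hit], 0))
  cg <- .charge_class(ag)[i]; cb <- .charge_class(ab)[j]
  opp <- cg * cb < 0
  polar <- .hbond_atoms(ag$element[i]) & .hbond_atoms(ab$element[j])
  carbon <- ag$element[i] == "C" & ab$element[j] == "C"
  type <- rep(NA_character_, length(i))
  type[carbon & dist <= cutoffs$nonpolar] <- "nonpolar"
  type[opp & dist <= cutoffs$charge] <- "attractive_charge"
  type[polar & dist <= cutoffs$hbond] <- "hydrogen_bond"
  type[opp & dist <= cutoffs$salt] <- "salt_bridge"
  keep <- !is.na(type)
  out <- data.frame(
    antigen_key = residue_key(ag$chain[i], ag$resno[i], ag$icode[i])[keep],
    antigen_atom = ag$elety[i][keep],
    antibody_key = residue_key(ab$chain[j], ab$resno[j], ab$icode[j])[keep],
    antibody_atom = ab$elety[j][keep],
    distance = dist[keep], type = type[keep], stringsAsFactors = FALSE)
  out[order(out$antigen_key, out$antibody_key, out$distance), , drop = FALSE]
}

#' Export an interface report
#'
#' Writes the residue table as CSV and a JSON summary (pose id, BSA, region
#' percents).
#'
#' @param report an `interface_report`.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, NULL.
#' @export
write_interface_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$interface_residues, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(pose_id = report$pose_id, bsa_A2 = report$bsa,
                              region_percent = as.list(report$region_percent)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
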