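#' Chothia CDR boundaries
#'
#' The standard Chothia spans, stored as data so they can be overridden:
#' H1 26-32, H2 52-56, H3 95-102 on the heavy chain; L1 24-34, L2 50-56,
#' L3 89-97 on the light chain. Residues with insertion codes inside a span
#' (e.g. H52A) belong to the span.
#'
#' @return data.frame with columns `region`, `chain_type`, `start`, `end`.
#' @export
chothia_cdr_table <- function() {
  data.frame(
    region = c("H1", "H2", "H3", "L1", "L2", "L3"),
    chain_type = c("H", "H", "H", "L", "L", "L"),
    start = c(26L, 52L, 95L, 24L, 50L, 89L),
    end = c(32L, 56L, 102L, 34L, 56L, 97L),
    stringsAsFactors = FALSE
  )
}

#' Annotate an Fv model with CDR/framework regions
#'
#' Assigns every residue of the heavy and light chains to exactly one region:
#' a Chothia CDR (H1-H3, L1-L3) or framework (FW_H, FW_L). Residue numbers
#' are taken as already being in the Chothia scheme (supply `numbering_table`
#' to remap author numbering first); automatic renumbering is out of scope.
#'
#' @param model a [structure_model()], or a data.frame with columns `chain`,
#'   `resno`, `icode`.
#' @param heavy,light chain identifiers of the heavy and light chain.
#' @param numbering_table optional data.frame `chain`, `resno`, `icode`,
#'   `scheme_resno`, `scheme_icode` mapping author to scheme numbering.
#' @param spans CDR span table, default [chothia_cdr_table()].
#' @param max_resno residues above this number are considered outside a
#'   plausible Fv and raise an error.
#' @return an `fv_annotation`: list with `heavy`, `light`, `residues`
#'   (data.frame `chain`, `resno`, `icode`, `key`, `region`) and `regions`
#'   (region -> ordered key list).
#' @export
annotate_fv <- function(model, heavy, light, numbering_table = NULL,
                        spans = chothia_cdr_table(), max_resno = 130L) {
  res <- if (inherits(model, "structure_model")) residues_of(model) else {
    r <- as.data.frame(model)
    r$icode <- r$icode %||% ""
    r$key <- residue_key(r$chain, r$resno, r$icode)
    r
  }
  .assert(heavy %in% res$chain, "heavy chain '", heavy, "' not in model")
  .assert(light %in% res$chain, "light chain '", light, "' not in model")
  res <- res[res$chain %in% c(heavy, light), , drop = FALSE]
  if (!is.null(numbering_table)) {
    nt_key <- residue_key(numbering_table$chain, numbering_table$resno,
                          numbering_table$icode %||% "")
    i <- match(res$key, nt_key)
    .assert(!anyNA(i), "numbering_table does not cover all Fv residues")
    res$resno <- numbering_table$scheme_resno[i]
    res$icode <- (numbering_table$scheme_icode %||% rep("", nrow(numbering_table)))[i]
  }
  .assert(all(res$resno >= 1 & res$resno <= max_resno),
          "residue numbers outside plausible Fv range 1..", max_resno)
  ctype <- ifelse(res$chain == heavy, "H", "L")
  region <- ifelse(ctype == "H", "FW_H", "FW_L")
  for (k in seq_len(nrow(spans))) {
    hit <- ctype == spans$chain_type[k] &
      res$resno >= spans$start[k] & res$resno <= spans$end[k]
    region[hit] <- spans$region[k]
  }
  res$region <- region
  res <- res[order(match(res$chain, c(heavy, light)), res$resno, res$icode), ]
  rownames(res) <- NULL
  regions <- split(res$key, res$region)
  all_regions <- c("H1", "H2", "H3", "L1", "L2", "L3", "FW_H", "FW_L")
  regions <- stats::setNames(lapply(all_regions, function(r) regions[[r]] %||% character(0)),
                             all_regions)
  structure(list(heavy = heavy, light = light,
                 residues = res[, c("chain", "resno", "icode", "key", "region")],
                 regions = regions, scheme = "chothia"),
            class = "fv_annotation")
}

#' @export
print.fv_annotation <- function(x, ...) {
  sizes <- vapply(x$regions, length, 1L)
  cat("fv_annotation (", x$scheme, "): H=", x$heavy, " L=", x$light, "\n  ",
      paste(names(sizes), sizes, sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Region of a residue
#'
#' @param annotation an `fv_annotation`.
#' @param residue a residue key (see [residue_key()]).
#' @return the region label.
#' @export
region_of <- function(annotation, residue) {
  i <- match(residue, annotation$residues$key)
  .assert(!anyNA(i), "residue(s) not annotated: ",
          paste(residue[is.na(i)], collapse = ", "))
  annotation$residues$region[i]
}

# formal side-chain charges at neutral pH; histidine configurable
.aa_charges <- function(histidine_charge = 0) {
  c(D = -1, E = -1, K = 1, R = 1, H = histidine_charge,
    A = 0, C = 0, F = 0, G = 0, I = 0, L = 0, M = 0, N = 0, P = 0,
    Q = 0, S = 0, T = 0, V = 0, W = 0, Y = 0)
}

#' Net formal charge of a CDR
#'
#' Sum of side-chain formal charges (D,E -> -1; K,R -> +1; H configurable,
#' default 0) over the residues of a region.
#'
#' @param annotation an `fv_annotation`.
#' @param sequence named character vector, residue key -> 1-letter code.
#' @param region region label (e.g. `"H3"`).
#' @param histidine_charge charge assigned to histidine (default 0).
#' @return signed integer net charge.
#' @export
cdr_charge <- function(annotation, sequence, region, histidine_charge = 0) {
  keys <- annotation$regions[[region]]
  .assert(!is.null(keys) && length(keys) > 0, "region '", region, "' is empty or unknown")
  aa <- sequence[keys]
  .assert(!anyNA(aa), "no sequence letter for: ",
          paste(keys[is.na(aa)], collapse = ", "))
  ch <- .aa_charges(histidine_charge)[aa]
  .assert(!anyNA(ch), "unknown amino-acid letter(s): ",
          paste(unique(aa[is.na(ch)]), collapse = ", "))
  as.integer(round(sum(ch)))
}

#' Per-CDR sequence statistics
#'
#' Length, net formal charge, and the percentage of polar or charged residues
#' (set {D,E,K,R,H,N,Q,S,T,Y,W,C}, recorded here because published
#' percentages rarely state their set).
#'
#' @inheritParams cdr_charge
#' @return data.frame with `region`, `length`, `net_charge`,
#'   `polar_charged_fraction`.
#' @export
cdr_stats <- function(annotation, sequence, region, histidine_charge = 0) {
  keys <- annotation$regions[[region]]
  aa <- sequence[keys]
  polar <- c("D", "E", "K", "R", "H", "N", "Q", "S", "T", "Y", "W", "C")
  data.frame(region = region, length = length(keys),
             net_charge = cdr_charge(annotation, sequence, region, histidine_charge),
             polar_charged_fraction = 100 * mean(aa %in% polar),
             stringsAsFactors = FALSE)
}

#' Propose alanine-scan positions
#'
#' Scan design over the paratope: solvent-exposed residues within the CDRs,
#' plus up to `flank` framework residues on each side of every CDR (also
#' required to be exposed). Alanine, glycine and proline positions are
#' excluded (self-mutation is vacuous; G/P are structural).
#'
#' @param annotation an `fv_annotation`.
#' @param rsa an `rsa_table` covering the Fv chains.
#' @param threshold_percent exposure cutoff (strict >), default 20.
#' @param flank framework residues to include on each side of each CDR.
#' @return ordered character vector of residue keys.
#' @export
select_scan_positions <- function(annotation, rsa, threshold_percent = 20,
                                  flank = 2L) {
  res <- annotation$residues
  exposed <- select_exposed(rsa, threshold_percent)
  in_cdr <- res$key[res$region %in% c("H1", "H2", "H3", "L1", "L2", "L3")]
  cand <- intersect(in_cdr, exposed)
  if (flank > 0) {
    for (ch in unique(res$chain)) {
      rc <- res[res$chain == ch, , drop = FALSE]
      cdr_idx <- which(rc$region %in% c("H1", "H2", "H3", "L1", "L2", "L3"))
      if (length(cdr_idx) == 0) next
      runs <- split(cdr_idx, cumsum(c(1, diff(cdr_idx) != 1)))
      for (run in runs) {
        lo <- max(1, min(run) - flank):(min(run) - 1)
        hi <- (max(run) + 1):min(nrow(rc), max(run) + flank)
        fl <- unique(c(lo[lo >= 1 & lo < min(run)], hi[hi <= nrow(rc) & hi > max(run)]))
        cand <- c(cand, intersect(rc$key[fl], exposed))
      }
    }
  }
  cand <- unique(cand)
  # drop A/G/P using the residue names carried by the RSA table
  nm <- stats::setNames(rsa$resname, rsa$key)
  three <- nm[cand]
  keep <- !(three %in% c("ALA", "GLY", "PRO"))
  cand <- cand[keep]
  ord <- res[match(cand, res$key), , drop = FALSE]
  cand[order(match(ord$chain, c(annotation$heavy, annotation$light)),
             ord$resno, ord$icode)]
}

#' Export an Fv annotation as CSV
#'
#' @param annotation an `fv_annotation`.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_annotation_csv <- function(annotation, path) {
  utils::write.csv(annotation$residues[, c("chain", "resno", "icode", "region")],
                   path, row.names = FALSE)
  invisible(path)
}
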