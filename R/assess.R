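#' Receptor blockage of a pose
#'
#' Quantifies how much of the antigen's receptor-binding footprint the
#' antibody occludes. The pose's antigen is superposed onto the antigen of a
#' reference antigen-receptor complex (Kabsch on shared C-alpha atoms by
#' default); the receptor footprint is the set of antigen residues at the
#' antigen-receptor interface of the reference, the antibody footprint the
#' set of antigen residues at the pose's interface. The overlap fraction
#' `|intersection| / |receptor footprint|` (matched by residue number, the
#' antigen being the same molecule in both structures) is graded; steric
#' clashes between antibody and receptor after superposition are counted and
#' reported but do not enter the default grade.
#'
#' @param pose a [pose()].
#' @param reference_complex a [structure_model()] containing the antigen and
#'   the receptor.
#' @param ref_antigen_chains,receptor_chains chain roles in the reference.
#' @param params a [sasa_params()].
#' @param superpose_atoms atom names used for superposition (default
#'   `"CA"`).
#' @param delta_threshold interface dSASA threshold in A^2.
#' @param clash_cutoff atom-pair distance counted as a clash (default 2.5 A).
#' @param grade_thresholds overlap fractions at or above which the grade is
#'   `high` / `medium` (defaults 0.5 / 0.2; below: `low`).
#' @param pose_interface optional precomputed [interface_residues()] table
#'   for the pose, to avoid recomputing SASA.
#' @return a `blockage_report`: list with `pose_id`, `receptor_footprint`,
#'   `antibody_footprint` (antigen residue keys), `overlap_fraction`,
#'   `clash_count`, `grade`, `superposition_rmsd`.
#' @export
receptor_blockage <- function(pose, reference_complex, ref_antigen_chains,
                              receptor_chains, params = sasa_params(),
                              superpose_atoms = "CA", delta_threshold = 0.1,
                              clash_cutoff = 2.5,
                              grade_thresholds = c(high = 0.5, medium = 0.2),
                              pose_interface = NULL) {
  ref_pose <- pose(reference_complex, ref_antigen_chains, receptor_chains,
                   pose_id = "reference")
  ref_if <- interface_residues(ref_pose, params, delta_threshold)
  receptor_fp <- ref_if$key[ref_if$side == "antigen"]
  .assert(length(receptor_fp) > 0, "reference complex has no antigen-receptor interface")
  if (is.null(pose_interface))
    pose_interface <- interface_residues(pose, params, delta_threshold)
  antibody_fp <- pose_interface$key[pose_interface$side == "antigen"]
  # footprints are compared on (resno, icode): the antigen is the same
  # molecule in pose and reference even if its chain id differs
  strip <- function(k) { p <- parse_residue_key(k); paste0(p$resno, p$icode) }
  ov <- length(intersect(strip(antibody_fp), strip(receptor_fp))) /
    length(receptor_fp)
  ag_pose <- subset_chains(pose$complex, pose$antigen_chains)
  ag_ref <- subset_chains(reference_complex, ref_antigen_chains)
  # chain-id-agnostic CA pairing on residue number
  ca_p <- ag_pose$atoms[ag_pose$atoms$elety %in% superpose_atoms, , drop = FALSE]
  ca_r <- ag_ref$atoms[ag_ref$atoms$elety %in% superpose_atoms, , drop = FALSE]
  kp <- paste(ca_p$resno, ca_p$icode); kr <- paste(ca_r$resno, ca_r$icode)
  shared <- intersect(kp, kr)
  .assert(length(shared) >= 3, "fewer than 3 shared superposition atoms")
  sup <- kabsch_superpose(as.matrix(ca_p[match(shared, kp), c("x", "y", "z")]),
                          as.matrix(ca_r[match(shared, kr), c("x", "y", "z")]))
  ab <- subset_chains(pose$complex, pose$antibody_chains)
  ab_xyz <- apply_transform(as.matrix(ab$atoms[!ab$atoms$hydrogen, c("x", "y", "z")]),
                            sup$transform)
  rc <- subset_chains(reference_complex, receptor_chains)
  rc_xyz <- as.matrix(rc$atoms[!rc$atoms$hydrogen, c("x", "y", "z")])
  d2 <- outer(rowSums(ab_xyz^2), rowSums(rc_xyz^2), `+`) - 2 * ab_xyz %*% t(rc_xyz)
  clash_count <- sum(d2 < clash_cutoff^2)
  grade <- if (ov >= grade_thresholds[["high"]]) "high"
           else if (ov >= grade_thresholds[["medium"]]) "medium" else "low"
  structure(list(pose_id = pose$pose_id, receptor_footprint = receptor_fp,
                 antibody_footprint = antibody_fp, overlap_fraction = ov,
                 clash_count = clash_count, grade = grade,
                 superposition_rmsd = sup$rmsd),
            class = "blockage_report")
}

#' @export
print.blockage_report <- function(x, ...) {
  cat("blockage_report [", x$pose_id, "]: overlap",
      round(x$overlap_fraction, 3), "->", x$grade, "(",
      x$clash_count, "clashes )\n")
  invisible(x)
}

#' Concordance of a pose with paratope alanine scanning
#'
#' Each tested paratope residue is experimentally positive when its
#' fold-change bin is at least `positive_bin`, and predicted positive when it
#' appears on the antibody side of the pose's interface. The percent
#' correlation is the balanced agreement `100 * (TP + TN) / tested`.
#'
#' @param pose_interface an `interface_report` or an [interface_residues()]
#'   table.
#' @param hotspots a [hotspot_table()] whose `mutant_id`s are antibody
#'   residue keys (or carry a `residue_key` column).
#' @param positive_bin minimum bin counted as experimentally positive
#'   (default `"star"`, i.e. at least 2-fold).
#' @return a `concordance_report`: list with `pose_id`, `table` (per-residue),
#'   `tp`, `tn`, `fp`, `fn`, `percent_correlation`, `mode`.
#' @export
paratope_concordance <- function(pose_interface, hotspots,
                                 positive_bin = "star") {
  if (inherits(pose_interface, "interface_report")) {
    pid <- pose_interface$pose_id
    ifr <- pose_interface$interface_residues
  } else {
    pid <- NA_character_
    ifr <- pose_interface
  }
  .assert(nrow(hotspots) > 0, "empty hotspot table")
  keys <- if ("residue_key" %in% names(hotspots)) hotspots$residue_key else hotspots$mutant_id
  bins <- factor(as.character(hotspots$bin),
                 levels = c("none", "star", "star2", "star3"), ordered = TRUE)
  exp_pos <- bins >= positive_bin
  pred_pos <- keys %in% ifr$key[ifr$side == "antibody"]
  tab <- data.frame(residue = keys, bin = as.character(bins),
                    experimental_positive = exp_pos,
                    predicted_at_interface = pred_pos, stringsAsFactors = FALSE)
  tp <- sum(exp_pos & pred_pos); tn <- sum(!exp_pos & !pred_pos)
  fp <- sum(!exp_pos & pred_pos); fn <- sum(exp_pos & !pred_pos)
  structure(list(pose_id = pid, table = tab, tp = tp, tn = tn, fp = fp, fn = fn,
                 percent_correlation = 100 * (tp + tn) / nrow(tab),
                 mode = "balanced_agreement"),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report [", x$pose_id, "]:",
      round(x$percent_correlation, 2), "% (tp", x$tp, "tn", x$tn,
      "fp", x$fp, "fn", x$fn, ")\n")
  invisible(x)
}

#' Assemble the seven-criterion table
#'
#' One row per pose with the seven assessment criteria: blockage grade,
#' binding energy (input metadata; NA when absent, never defaulted),
#' percent correlation with paratope scanning, buried surface area, and the
#' %FWR / %CDR / %H3 interface partitions.
#'
#' @param poses list of [pose()]s.
#' @param interface_reports,blockage_reports,concordance_reports lists of the
#'   corresponding reports; pose ids must match one-to-one.
#' @return a `criteria_table` data.frame with columns `pose_id`, `blockage`,
#'   `binding_energy`, `pct_correlation`, `bsa_A2`, `pct_fwr`, `pct_cdr`,
#'   `pct_h3`.
#' @export
assemble_criteria <- function(poses, interface_reports, blockage_reports,
                              concordance_reports) {
  ids <- vapply(poses, function(p) p$pose_id, "")
  find <- function(reports, what) {
    rid <- vapply(reports, function(r) r$pose_id, "")
    i <- match(ids, rid)
    .assert(!anyNA(i), "missing ", what, " report for pose(s): ",
            paste(ids[is.na(i)], collapse = ", "))
    reports[i]
  }
  ir <- find(interface_reports, "interface")
  br <- find(blockage_reports, "blockage")
  cr <- find(concordance_reports, "concordance")
  rows <- do.call(rbind, lapply(seq_along(poses), function(k) {
    rp <- ir[[k]]$region_percent
    .assert(!is.null(rp), "interface report for ", ids[k], " lacks region percents")
    data.frame(pose_id = ids[k], blockage = br[[k]]$grade,
               binding_energy = poses[[k]]$binding_energy %||% NA_real_,
               pct_correlation = cr[[k]]$percent_correlation,
               bsa_A2 = ir[[k]]$bsa, pct_fwr = rp[["FWR"]],
               pct_cdr = rp[["CDR_total"]], pct_h3 = rp[["H3"]],
               stringsAsFactors = FALSE)
  }))
  class(rows) <- c("criteria_table", "data.frame")
  rows
}

#' Build a criteria table from precomputed values
#'
#' Bypass constructor for when the seven criteria are already known (e.g. a
#' published assessment table) and only filtering/ranking is needed.
#'
#' @param df data.frame with columns `pose_id`, `blockage`, `binding_energy`,
#'   `pct_correlation`, `bsa_A2`, `pct_fwr`, `pct_cdr`, `pct_h3`.
#' @return a `criteria_table`.
#' @export
criteria_table <- function(df) {
  need <- c("pose_id", "blockage", "binding_energy", "pct_correlation",
            "bsa_A2", "pct_fwr", "pct_cdr", "pct_h3")
  miss <- setdiff(need, names(df))
  .assert(length(miss) == 0, "missing criteria column(s): ",
          paste(miss, collapse = ", "))
  .assert(!anyDuplicated(df$pose_id), "duplicate pose ids")
  .assert(all(df$blockage %in% c("low", "medium", "high")),
          "blockage must be low/medium/high")
  df <- as.data.frame(df)[, need]
  class(df) <- c("criteria_table", "data.frame")
  df
}

#' Filter and rank poses on the seven criteria
#'
#' Poses failing any filter (minimum buried surface area, %CDR range,
#' minimum blockage grade) are set aside with the list of failed filters.
#' Survivors are ordered lexicographically: percent correlation (desc),
#' blockage grade (high > medium > low), binding energy (asc; poses without
#' one sort after otherwise-equal poses that have it), BSA (desc), and
#' finally pose id (asc) as the documented deterministic tie-break.
#'
#' @param rows a `criteria_table`.
#' @param filters list with `min_bsa` (A^2, strict >; default 800),
#'   `cdr_percent_range` (inclusive; default `c(50, 95)`), `min_blockage`
#'   (default `"low"`, i.e. no blockage filter).
#' @return a `pose_ranking`: list with `passed` (pose ids, best first),
#'   `failed` (pose id -> failed filter names), `ordering_key_trace`
#'   (data.frame of sort keys), `table` (survivor rows in rank order).
#' @export
rank_poses <- function(rows, filters = list(min_bsa = 800,
                                            cdr_percent_range = c(50, 95),
                                            min_blockage = "low")) {
  .assert(nrow(rows) >= 1, "empty criteria table")
  glevels <- c(low = 1L, medium = 2L, high = 3L)
  gr <- glevels[rows$blockage]
  fails <- lapply(seq_len(nrow(rows)), function(i) {
    f <- character(0)
    if (!is.null(filters$min_bsa) && rows$bsa_A2[i] <= filters$min_bsa)
      f <- c(f, "min_bsa")
    if (!is.null(filters$cdr_percent_range) &&
        (rows$pct_cdr[i] < filters$cdr_percent_range[1] ||
         rows$pct_cdr[i] > filters$cdr_percent_range[2]))
      f <- c(f, "cdr_percent_range")
    if (!is.null(filters$min_blockage) && gr[i] < glevels[[filters$min_blockage]])
      f <- c(f, "min_blockage")
    f
  })
  failed_idx <- which(vapply(fails, length, 1L) > 0)
  passed_idx <- setdiff(seq_len(nrow(rows)), failed_idx)
  trace <- data.frame(pose_id = rows$pose_id,
                      k1_pct_correlation = rows$pct_correlation,
                      k2_blockage = unname(gr),
                      k3_binding_energy = rows$binding_energy,
                      k4_bsa = rows$bsa_A2, stringsAsFactors = FALSE)
  if (length(passed_idx) > 0) {
    tr <- trace[passed_idx, , drop = FALSE]
    e <- tr$k3_binding_energy
    ord <- order(-tr$k1_pct_correlation, -tr$k2_blockage,
                 is.na(e), ifelse(is.na(e), 0, e),
                 -tr$k4_bsa, tr$pose_id)
    passed_idx <- passed_idx[ord]
  }
  structure(list(passed = rows$pose_id[passed_idx],
                 failed = stats::setNames(fails[failed_idx],
                                          rows$pose_id[failed_idx]),
                 ordering_key_trace = trace,
                 table = rows[passed_idx, , drop = FALSE]),
            class = "pose_ranking")
}

#' @export
print.pose_ranking <- function(x, ...) {
  cat("pose_ranking:", length(x$passed), "passed,",
      length(x$failed), "filtered\n")
  if (length(x$passed)) cat("  best:", x$passed[1], "\n")
  if (length(x$failed))
    for (id in names(x$failed))
      cat("  failed", id, ":", paste(x$failed[[id]], collapse = ", "), "\n")
  invisible(x)
}

#' Export criteria and ranking
#'
#' @param rows a `criteria_table`.
#' @param ranking a `pose_ranking`.
#' @param csv_path,json_path output paths (NULL to skip).
#' @return invisibly, NULL.
#' @export
write_assessment <- function(rows = NULL, ranking = NULL, csv_path = NULL,
                             json_path = NULL) {
  if (!is.null(csv_path) && !is.null(rows))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(ranking))
    jsonlite::write_json(list(passed = ranking$passed, failed = ranking$failed,
                              ordering_key_trace = ranking$ordering_key_trace),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
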