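#' Default run configuration
#'
#' All tunable thresholds of the workflow in one nested list, with defaults
#' anchored to the published protocol where one is stated: RSA exposure
#' threshold 20% (strict), fold-change censoring bound 100, minimum
#' acceptable interface area 800 A^2, interface dSASA threshold 0.1 A^2,
#' blockage grade cut-points 0.5/0.2.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    sasa = list(probe_radius = 1.4, n_points = 960),
    rsa = list(threshold_percent = 20, reference_set = "theoretical"),
    scan = list(flank = 2, censor_bound = 100, hotspot_threshold_bin = "star2",
                spot_concentration = 1.2),
    interface = list(delta_threshold = 0.1),
    blockage = list(grade_high = 0.5, grade_medium = 0.2, clash_cutoff = 2.5,
                    superpose_atoms = "CA"),
    ranking = list(min_bsa = 800, cdr_percent_min = 50, cdr_percent_max = 95,
                   min_blockage = "low", positive_bin = "star"),
    alignment = list(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5)
  )
}

#' Read / write a run configuration
#'
#' YAML round-trip of the configuration list; unspecified values fall back
#' to [default_config()].
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return `read_config` returns the merged configuration list.
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (sec in names(user))
    for (k in names(user[[sec]])) base[[sec]][[k]] <- user[[sec]][[k]]
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Assess and rank a set of docking poses
#'
#' The full assessment stage in one call: for every pose it computes the
#' interface report (BSA, interface residues, region partition), the
#' receptor-blockage report against a reference antigen-receptor complex,
#' and the concordance with a paratope alanine-scanning hotspot table; it
#' then assembles the seven-criterion table and filters/ranks the poses.
#'
#' @param poses list of [pose()]s.
#' @param annotation an [annotate_fv()] annotation of the antibody chains.
#' @param hotspots a [hotspot_table()] keyed by antibody residue keys.
#' @param reference_complex a [structure_model()] holding antigen + receptor.
#' @param ref_antigen_chains,receptor_chains chain roles in the reference.
#' @param params a [sasa_params()].
#' @param config configuration list, see [default_config()].
#' @return list with `criteria` (a `criteria_table`), `ranking`
#'   (a `pose_ranking`), and the three report lists.
#' @export
assess_poses <- function(poses, annotation, hotspots, reference_complex,
                         ref_antigen_chains = "A", receptor_chains = "R",
                         params = sasa_params(), config = default_config()) {
  dth <- config$interface$delta_threshold
  ir <- lapply(poses, interface_report, params = params,
               annotation = annotation, delta_threshold = dth)
  br <- lapply(seq_along(poses), function(k)
    receptor_blockage(poses[[k]], reference_complex, ref_antigen_chains,
                      receptor_chains, params = params,
                      delta_threshold = dth,
                      clash_cutoff = config$blockage$clash_cutoff,
                      superpose_atoms = config$blockage$superpose_atoms,
                      grade_thresholds = c(high = config$blockage$grade_high,
                                           medium = config$blockage$grade_medium),
                      pose_interface = ir[[k]]$interface_residues))
  cr <- lapply(ir, paratope_concordance, hotspots = hotspots,
               positive_bin = config$ranking$positive_bin)
  rows <- assemble_criteria(poses, ir, br, cr)
  ranking <- rank_poses(rows, filters = list(
    min_bsa = config$ranking$min_bsa,
    cdr_percent_range = c(config$ranking$cdr_percent_min,
                          config$ranking$cdr_percent_max),
    min_blockage = config$ranking$min_blockage))
  list(criteria = rows, ranking = ranking, interface_reports = ir,
       blockage_reports = br, concordance_reports = cr)
}
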