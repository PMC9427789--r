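# Receptor blockage, scan concordance, criteria assembly, ranking

test_that("receptor blockage measures footprint overlap on constructed toys", {
  fx <- make_fv_complex(seed = 2)
  params <- sasa_params(n_points = 240)
  # the pseudo-receptor occupies exactly the true epitope: a native pose
  # blocks (almost) all of it
  br <- receptor_blockage(fx$pose, fx$reference_complex, "A", "R",
                          params = params)
  expect_equal(br$pose_id, "reference")
  expect_gte(br$overlap_fraction, 0.9)
  expect_equal(br$grade, "high")
  # pose and reference carry independent coordinate noise, so the antigen
  # superposition lands near, not at, zero
  expect_lt(br$superposition_rmsd, 1)

  # pose moved to the far end of the antigen: disjoint footprint, low grade
  a <- fx$pose$complex$atoms
  ab <- a$chain %in% c("H", "L")
  a$x[ab] <- a$x[ab] + 80
  far <- pose(structure_model(a), "A", c("H", "L"), "far")
  br2 <- receptor_blockage(far, fx$reference_complex, "A", "R", params = params)
  expect_lt(br2$overlap_fraction, 0.2)
  expect_equal(br2$grade, "low")
})

test_that("half-covered receptor footprints grade as medium overlap", {
  fx <- make_fv_complex(seed = 2)
  params <- sasa_params(n_points = 240)
  ir <- interface_residues(fx$pose, params)
  fp <- ir[ir$side == "antigen", ]
  # synthetic pose interface covering exactly half (rounded down) of the
  # receptor footprint: overlap counted, not estimated
  ref_if <- interface_residues(pose(fx$reference_complex, "A", "R", "ref"),
                               params)
  rec_fp <- ref_if$key[ref_if$side == "antigen"]
  half <- rec_fp[seq_len(ceiling(length(rec_fp) * 0.4))]
  fake_if <- data.frame(key = half, chain = "A",
                        resno = parse_residue_key(half)$resno, icode = "",
                        side = "antigen", delta_sasa = 5,
                        stringsAsFactors = FALSE)
  br <- receptor_blockage(fx$pose, fx$reference_complex, "A", "R",
                          params = params, pose_interface = fake_if)
  expect_equal(br$overlap_fraction, length(half) / length(rec_fp))
  expect_equal(br$grade, "medium")
})

test_that("concordance counts agreement between scan bins and the interface", {
  # 56 tested residues, 5 experimental positives; the pose interface holds
  # 4 of the positives plus 3 false positives: 100*(4+48)/56
  tested <- residue_key("H", 1:56)
  pos <- tested[1:5]
  hs <- hotspot_table(data.frame(
    mutant_id = tested, mode = "kd_ratio",
    fold = ifelse(tested %in% pos, 50, 1), censored = FALSE,
    censor_bound = 100, bin = classify_bins(ifelse(tested %in% pos, 50, 1)),
    stringsAsFactors = FALSE))
  iface <- data.frame(key = c(pos[1:4], tested[6:8]),
                      chain = "H", resno = c(1:4, 6:8), icode = "",
                      side = "antibody", delta_sasa = 10,
                      stringsAsFactors = FALSE)
  cr <- paratope_concordance(iface, hs, positive_bin = "star")
  expect_equal(cr$tp, 4); expect_equal(cr$fn, 1)
  expect_equal(cr$fp, 3); expect_equal(cr$tn, 48)
  expect_equal(cr$tp + cr$tn + cr$fp + cr$fn, 56)
  expect_equal(cr$percent_correlation, 100 * 52 / 56, tolerance = 1e-9)

  # perfect and fully wrong predictions hit the bounds
  all_right <- data.frame(key = pos, chain = "H", resno = 1:5, icode = "",
                          side = "antibody", delta_sasa = 10)
  expect_equal(paratope_concordance(all_right, hs)$percent_correlation, 100)
  all_wrong <- data.frame(key = setdiff(tested, pos), chain = "H",
                          resno = 6:56, icode = "", side = "antibody",
                          delta_sasa = 10)
  expect_equal(paratope_concordance(all_wrong, hs)$percent_correlation, 0)
  expect_error(paratope_concordance(all_right, hs[0, ]), "empty")
})

test_that("adding a correctly-predicted residue never lowers concordance", {
  tested <- residue_key("H", 1:12)
  for (seed in 1:20) {
    set.seed(seed)
    pos <- sample(tested, 4)
    hs <- hotspot_table(data.frame(
      mutant_id = tested, mode = "kd_ratio",
      fold = ifelse(tested %in% pos, 20, 1), censored = FALSE,
      censor_bound = 100,
      bin = classify_bins(ifelse(tested %in% pos, 20, 1))))
    in_if <- sample(tested, 5)
    mk <- function(keys) data.frame(key = keys, chain = "H",
                                    resno = parse_residue_key(keys)$resno,
                                    icode = "", side = "antibody",
                                    delta_sasa = 1)
    base <- paratope_concordance(mk(in_if), hs)$percent_correlation
    missing_pos <- setdiff(pos, in_if)
    if (length(missing_pos) > 0) {
      more <- paratope_concordance(mk(c(in_if, missing_pos[1])), hs)$percent_correlation
      expect_gte(more, base)
    }
  }
})

fig2e_rows <- function() {
  criteria_table(data.frame(
    pose_id = c("pose27", "pose39", "pose180"),
    blockage = c("high", "medium", "high"),
    binding_energy = c(-120, -110, -105),
    pct_correlation = c(92, 85, 80),
    bsa_A2 = c(906.7, 859.3, 920.8),
    pct_fwr = c(22.23, 13.47, 13.96),
    pct_cdr = c(77.77, 86.53, 86.04),
    pct_h3 = c(22.21, 15.91, 14.05),
    stringsAsFactors = FALSE))
}

test_that("the published-style assessment table ranks the expected pose first", {
  rk <- rank_poses(fig2e_rows())
  expect_equal(rk$passed[1], "pose27")
  expect_length(rk$failed, 0)
  expect_equal(sort(c(rk$passed, names(rk$failed))),
               sort(fig2e_rows()$pose_id))
})

test_that("filters remove poses with reasons and never leak them to passed", {
  rows <- fig2e_rows()
  rows <- criteria_table(rbind(rows, data.frame(
    pose_id = "pose700", blockage = "high", binding_energy = -200,
    pct_correlation = 99, bsa_A2 = 700, pct_fwr = 20, pct_cdr = 80,
    pct_h3 = 20)))
  rk <- rank_poses(rows)
  expect_true("pose700" %in% names(rk$failed))
  expect_true("min_bsa" %in% rk$failed$pose700)
  expect_false("pose700" %in% rk$passed)

  rows2 <- criteria_table(rbind(fig2e_rows(), data.frame(
    pose_id = "poseFW", blockage = "high", binding_energy = -200,
    pct_correlation = 99, bsa_A2 = 900, pct_fwr = 70, pct_cdr = 30,
    pct_h3 = 5)))
  rk2 <- rank_poses(rows2)
  expect_true("cdr_percent_range" %in% rk2$failed$poseFW)
})

test_that("ranking is deterministic, permutation-invariant, with documented tie-breaks", {
  rows <- fig2e_rows()
  rk <- rank_poses(rows)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rk_p <- rank_poses(criteria_table(rows[perm, ]))
    expect_equal(rk_p$passed, rk$passed)
  }
  # identical criteria except id: alphabetical order decides
  twin <- criteria_table(data.frame(
    pose_id = c("poseB", "poseA"), blockage = "high", binding_energy = -100,
    pct_correlation = 90, bsa_A2 = 900, pct_fwr = 20, pct_cdr = 80,
    pct_h3 = 20))
  expect_equal(rank_poses(twin)$passed, c("poseA", "poseB"))
  # a pose lacking binding energy sorts after an otherwise equal pose
  nae <- criteria_table(data.frame(
    pose_id = c("poseNA", "poseE"), blockage = "high",
    binding_energy = c(NA, -100), pct_correlation = 90, bsa_A2 = 900,
    pct_fwr = 20, pct_cdr = 80, pct_h3 = 20))
  expect_equal(rank_poses(nae)$passed, c("poseE", "poseNA"))
  expect_error(rank_poses(fig2e_rows()[0, ]), "empty")
})

test_that("criteria assembly joins reports by pose id and flags gaps", {
  fx <- make_fv_complex(seed = 4)
  params <- sasa_params(n_points = 240)
  poses <- make_pose_set(fx$pose, n = 3, decoy_fraction = 0, seed = 5)
  hs <- truth_hotspots(fx)
  ir <- lapply(poses, interface_report, params = params,
               annotation = fx$annotation)
  br <- lapply(poses, receptor_blockage, reference_complex = fx$reference_complex,
               ref_antigen_chains = "A", receptor_chains = "R", params = params)
  cr <- lapply(ir, paratope_concordance, hotspots = hs)
  rows <- assemble_criteria(poses, ir, br, cr)
  expect_equal(nrow(rows), 3)
  expect_false(anyNA(rows$pct_correlation))
  expect_false(anyNA(rows$bsa_A2))
  expect_error(assemble_criteria(poses, ir, br[-2], cr), "pose002")

  f <- withr::local_tempfile(fileext = ".csv")
  write_assessment(rows, csv_path = f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$pose_id, rows$pose_id)
  expect_equal(back$bsa_A2, rows$bsa_A2, tolerance = 1e-9)
})
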