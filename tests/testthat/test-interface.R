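# Interface residues, buried surface area, region partition, contacts

sphere_pose <- function(separation) {
  pose(make_sphere_pair(separation), antigen_chains = "A",
       antibody_chains = "B", pose_id = paste0("d", separation))
}

test_that("separated chains have no interface and zero BSA", {
  p <- sphere_pose(100)
  expect_equal(nrow(interface_residues(p)), 0)
  expect_equal(buried_surface_area(p), 0, tolerance = 1e-9)
})

test_that("the two-sphere complex matches the spherical-cap oracle", {
  R <- 1.7 + 1.4
  d <- R # expanded spheres overlap: each loses cap area 2*pi*R*(R - d/2)
  p <- sphere_pose(d)
  ir <- interface_residues(p, sasa_params(n_points = 5000))
  expect_equal(nrow(ir), 2)
  expect_setequal(ir$side, c("antigen", "antibody"))
  cap <- sphere_cap_area(R, d)
  expect_equal(ir$delta_sasa[1], cap, tolerance = 0.01)
  expect_equal(ir$delta_sasa[1], ir$delta_sasa[2], tolerance = 0.01)
  # half-sum BSA equals the per-sphere cap loss
  expect_equal(buried_surface_area(p, sasa_params(n_points = 5000)), cap,
               tolerance = 0.01)
  # raising the threshold above the maximum dSASA empties the list
  expect_equal(nrow(interface_residues(p, delta_threshold = cap * 2)), 0)
})

test_that("bsa is nonnegative and zero exactly when no residue is interfacial", {
  for (d in c(2, 4, 6.5, 20)) {
    p <- sphere_pose(d)
    bsa <- buried_surface_area(p)
    ir <- interface_residues(p)
    expect_gte(bsa, -1e-9)
    if (nrow(ir) == 0) expect_lt(bsa, 0.2) else expect_gt(bsa, 0)
  }
})

test_that("region partition is a percentage decomposition of the antibody side", {
  ann <- annotate_fv(rbind(
    data.frame(chain = "H", resno = 1:110, icode = ""),
    data.frame(chain = "L", resno = 1:107, icode = "")),
    heavy = "H", light = "L")
  iface <- data.frame(
    key = c("H:96", "H:97", "H:30", "A:5"),
    chain = c("H", "H", "H", "A"), resno = c(96, 97, 30, 5), icode = "",
    side = c("antibody", "antibody", "antibody", "antigen"),
    delta_sasa = c(20, 10, 10, 99), stringsAsFactors = FALSE)
  rp <- region_contributions(iface, ann)
  expect_equal(unname(rp["H3"]), 75)       # 30 of 40
  expect_equal(unname(rp["H1"]), 25)
  expect_equal(unname(rp["CDR_total"]), 100)
  expect_equal(unname(rp["FWR"]), 0)

  iface$key[3] <- "H:10"; iface$resno[3] <- 10  # framework now
  rp2 <- region_contributions(iface, ann)
  expect_equal(unname(rp2["CDR_total"]), 75)
  expect_equal(unname(rp2["FWR"]), 25)
  expect_equal(unname(rp2["CDR_total"] + rp2["FWR"]), 100, tolerance = 1e-6)
  expect_equal(unname(sum(rp2[c("H1","H2","H3","L1","L2","L3")])),
               unname(rp2["CDR_total"]), tolerance = 1e-6)

  iface$key[1] <- "H:200"
  expect_error(region_contributions(iface, ann), "not annotated")
})

test_that("interface_report bundles BSA, residues and partition consistently", {
  fx <- make_fv_complex(seed = 3)
  rep <- interface_report(fx$pose, sasa_params(n_points = 240), fx$annotation)
  expect_equal(rep$bsa,
               buried_surface_area(fx$pose, sasa_params(n_points = 240)),
               tolerance = 1e-9)
  expect_equal(unname(rep$region_percent["CDR_total"] +
                        rep$region_percent["FWR"]), 100, tolerance = 1e-6)
  ab <- sum(rep$interface_residues$delta_sasa[rep$interface_residues$side == "antibody"])
  ag <- sum(rep$interface_residues$delta_sasa[rep$interface_residues$side == "antigen"])
  expect_gt(ab, 0)
  expect_gt(ag, 0)
})

test_that("contact classification picks the most specific geometric type", {
  # Asp side-chain oxygen vs Arg guanidinium nitrogen at 3.0 A: salt bridge
  m <- atoms_model(
    atom_spec("A", 1, "ASP", "OD1", "O", 0, 0, 0),
    atom_spec("B", 1, "ARG", "NH1", "N", 3.0, 0, 0))
  p <- pose(m, "A", "B", "salt")
  ct <- classify_contacts(p)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$type, "salt_bridge")

  # Ser hydroxyl vs backbone carbonyl at 3.2 A: hydrogen bond
  m2 <- atoms_model(
    atom_spec("A", 1, "SER", "OG", "O", 0, 0, 0),
    atom_spec("B", 1, "GLY", "O", "O", 3.2, 0, 0))
  ct2 <- classify_contacts(pose(m2, "A", "B", "hb"))
  expect_equal(ct2$type, "hydrogen_bond")

  # opposite charges at 5.0 A: beyond salt cutoff, still attractive
  m3 <- atoms_model(
    atom_spec("A", 1, "GLU", "OE1", "O", 0, 0, 0),
    atom_spec("B", 1, "LYS", "NZ", "N", 5.0, 0, 0))
  ct3 <- classify_contacts(pose(m3, "A", "B", "chg"))
  expect_equal(ct3$type, "attractive_charge")

  # two carbons at 4.0 A: nonpolar
  m4 <- atoms_model(
    atom_spec("A", 1, "LEU", "CD1", "C", 0, 0, 0),
    atom_spec("B", 1, "VAL", "CG1", "C", 4.0, 0, 0))
  ct4 <- classify_contacts(pose(m4, "A", "B", "np"))
  expect_equal(ct4$type, "nonpolar")

  # far apart: nothing
  m5 <- atoms_model(
    atom_spec("A", 1, "SER", "OG", "O", 0, 0, 0),
    atom_spec("B", 1, "GLY", "O", "O", 8, 0, 0))
  expect_equal(nrow(classify_contacts(pose(m5, "A", "B", "far"))), 0)
})

test_that("contact classification is symmetric in the molecule roles", {
  m <- atoms_model(
    atom_spec("A", 1, "ASP", "OD2", "O", 0, 0, 0),
    atom_spec("A", 2, "LEU", "CD1", "C", 0, 4, 0),
    atom_spec("B", 5, "ARG", "NH2", "N", 2.8, 0, 0),
    atom_spec("B", 6, "VAL", "CG1", "C", 0, 7.5, 0))
  fwd <- classify_contacts(pose(m, "A", "B", "f"))
  rev <- classify_contacts(pose(m, "B", "A", "r"))
  expect_equal(sort(fwd$type), sort(rev$type))
  expect_equal(sort(fwd$distance), sort(rev$distance), tolerance = 1e-12)
})

test_that("pose construction validates chain roles", {
  m <- make_sphere_pair(5)
  expect_error(pose(m, "A", "A", "x"), "overlap")
  expect_error(pose(m, "A", "C", "x"), "missing")
  expect_error(pose(m, character(0), "B", "x"), "non-empty")
})
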