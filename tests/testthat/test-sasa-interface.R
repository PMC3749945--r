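test_that("an isolated atom's SASA matches the analytic sphere", {
  m <- model_from_atoms(atom_row(), id = "one")
  s <- shrake_rupley(m, probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
})

test_that("two-sphere burial matches the spherical-cap closed form", {
  m <- two_sphere_model(d = 3.0)
  s <- shrake_rupley(m, probe = 1.4, n_points = 960)
  full <- 4 * pi * 3.1^2
  buried <- full - s$atoms$area
  expect_equal(buried[1], cap_buried_area(3.1, 3.0), tolerance = 0.01 * 31.16)
  expect_equal(buried[2], cap_buried_area(3.1, 3.0), tolerance = 0.01 * 31.16)
})

test_that("SASA converges with the sphere-point count", {
  m <- make_chain("helix", n = 50)
  s1 <- shrake_rupley(m, n_points = 960)
  s2 <- shrake_rupley(m, n_points = 1920)
  expect_lt(abs(s1$total - s2$total) / s2$total, 0.003)
})

test_that("per-residue SASA sums equal per-atom sums", {
  m <- make_toy_complex()
  s <- shrake_rupley(m)
  expect_equal(sum(s$residue$area), sum(s$atoms$area[s$atoms$std_aa]),
               tolerance = 1e-6)
  expect_true(all(s$atoms$area >= 0))
})

test_that("unknown elements without a fallback radius are an error", {
  bad <- atom_row(elety = "XX", elesy = "XX")
  expect_error(shrake_rupley(model_from_atoms(bad, id = "bad")), "radius")
  s <- shrake_rupley(model_from_atoms(bad, id = "bad"), default_radius = 1.7)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("total SASA agrees with an independent implementation within 2%", {
  for (m in list(make_toy_complex(),
                 make_chain("helix", n = 40, residue = "ALA"),
                 model_from_atoms(build_peptide(c("GLY", "TRP", "LYS", "GLU",
                                                  "GLY")), id = "pent"))) {
    mine <- shrake_rupley(m)$total
    theirs <- biotite_total_sasa(m)
    expect_lt(abs(mine - theirs) / theirs, 0.02)
  }
})

test_that("Gly-X-Gly references are self-normalising and size-ordered", {
  ref <- reference_gxg()
  expect_equal(names(ref), standard_aa())
  expect_true(all(ref > 0))
  expect_gt(ref[["TRP"]], ref[["GLY"]])
  expect_gt(ref[["PHE"]], ref[["ALA"]])
  # X inside its own reference tripeptide has rSASA exactly 1
  at <- build_peptide(c("GLY", "LEU", "GLY"))
  s <- shrake_rupley(model_from_atoms(at, id = "glg"))
  expect_equal(s$residue$area[2] / ref[["LEU"]], 1.0, tolerance = 1e-9)
})

test_that("Gly-X-Gly references agree with an independent SASA implementation", {
  ref <- reference_gxg()
  ind <- biotite_gxg()
  expect_true(all(abs(ref - ind[names(ref)]) / ind[names(ref)] < 0.15))
})

test_that("widely separated chains have no interface", {
  a <- make_chain("extended", n = 8, chain_id = "A")$atoms
  b <- make_chain("extended", n = 8, chain_id = "B")$atoms
  b$z <- b$z + 40
  m <- model_from_atoms(rbind(a, b), id = "apart")
  im <- interface_map(partition_complex(m, "A"))
  expect_equal(sum(im$residues$region != "none"), 0L)
  expect_equal(im$summary$interface_area, 0, tolerance = 1e-6)
})

test_that("two-sphere toy interface area matches the cap oracle", {
  im <- interface_map(partition_complex(two_sphere_model(3.0), "A"))
  expect_equal(im$summary$interface_area, cap_buried_area(3.1, 3.0),
               tolerance = 0.02 * cap_buried_area(3.1, 3.0))
})

test_that("delta-SASA is non-negative and regions partition the interface", {
  im <- interface_map(partition_complex(make_toy_complex(), "A"))
  r <- im$residues
  expect_true(all(r$dsasa >= -0.01))
  intf <- r$region != "none"
  expect_true(all(r$dsasa[intf] > 0))
  expect_setequal(unique(r$region[intf]), intersect(unique(r$region),
                                                    c("core", "rim", "support")))
  # disjoint by construction: one label per residue row
  expect_equal(sum(table(r$region)[c("core", "rim", "support")],
                   na.rm = TRUE), sum(intf))
})

test_that("the designed buried leucine is interface core", {
  im <- interface_map(partition_complex(make_toy_complex(), "A"))
  leu <- im$residues[im$residues$resid == "LEU" & im$residues$side == "segment", ]
  expect_equal(nrow(leu), 1L)
  expect_lte(leu$rsasa_bound, 0.25)
  expect_gt(leu$rsasa_free, 0.25)
  expect_equal(leu$region, "core")
  # and the >10 A gap-separated control residues never join the interface
  ctl <- im$residues[im$residues$resid == "GLY", ]
  expect_true(all(ctl$region == "none"))
})

test_that("interface area is symmetric in the choice of segment side", {
  m <- make_toy_complex()
  a1 <- interface_map(partition_complex(m, "A"))$summary$interface_area
  a2 <- interface_map(partition_complex(m, "B"))$summary$interface_area
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("composition profiles count, order, and difference correctly", {
  p <- composition_profile(c(rep("ALA", 4), rep("GLY", 6)))
  expect_equal(sum(p), 1)
  expect_equal(unname(p[["ALA"]]), 0.4)
  expect_equal(unname(p[["GLY"]]), 0.6)
  expect_equal(names(p), flexibility_order())
  expect_equal(unname(composition_enrichment(p, p)), rep(0, 20))
  expect_error(composition_profile(character(0)), "empty")
})

test_that("per-complex averaging differs from pooled counting on unequal complexes", {
  c1 <- c("ALA", "GLY")                       # 50% ALA
  c2 <- rep(c("ALA", rep("GLY", 9)), 10)      # 10% ALA, much larger
  avg <- average_composition(list(c1, c2))
  pooled <- composition_profile(c(c1, c2))
  # hand-computed: averaged ALA = (0.5 + 0.1)/2 = 0.3; pooled = 11/102
  expect_equal(unname(avg[["ALA"]]), 0.3)
  expect_equal(unname(pooled[["ALA"]]), 11 / 102)
  expect_false(isTRUE(all.equal(avg[["ALA"]], pooled[["ALA"]])))
})
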