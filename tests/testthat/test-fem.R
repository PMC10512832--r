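test_that("hex8 element matrix has rigid-body modes and linear size scaling", {
  mat <- material(10, 0.3)
  Ke <- hex8_element_stiffness(mat, 0.5)
  expect_equal(dim(Ke), c(24L, 24L))
  expect_equal(Ke, t(Ke), tolerance = 1e-12)
  # translations in x, y, z produce no force
  for (comp in 1:3) {
    u <- rep(0, 24); u[seq(comp, 24, by = 3)] <- 1
    expect_lt(max(abs(Ke %*% u)), 1e-12)
  }
  ev <- eigen(Ke, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6L)
  expect_true(all(ev > -1e-9 * max(ev)))
  expect_equal(hex8_element_stiffness(mat, 1.0), 2 * Ke, tolerance = 1e-12)
})

test_that("assembly shares nodes between face-adjacent voxels and drops islands", {
  one <- full_solid_model(R = 1)
  s1 <- assemble_system(one)
  expect_equal(length(s1$used_nodes), 8L)
  expect_equal(length(s1$used_dofs), 24L)

  two <- full_solid_model(R = 2)
  s2 <- assemble_system(two)
  expect_equal(length(s2$used_nodes), 27L)

  # a voxel touching the main block only at a corner is a floating island
  occ <- array(FALSE, c(4, 4, 4))
  occ[1:2, , ] <- TRUE
  occ[4, 4, 4] <- TRUE
  vm <- full_solid_model(R = 4); vm$occupancy <- occ
  s3 <- assemble_system(vm)
  expect_equal(s3$removed_voxels, 1L)
  lone <- tpmsdesign:::node_id(5L, 5L, 5L, 5L)  # far corner node of the island
  expect_false(lone %in% s3$used_nodes)
})

test_that("homogenization reproduces the isotropic closed form on a solid cube", {
  v <- full_solid_model(R = 8)
  C <- homogenize(v)
  iso <- iso_stiffness(material(10, 0.3))
  expect_equal(C[1, 1], iso[["C11"]], tolerance = 1e-10)
  expect_equal(C[2, 2], iso[["C11"]], tolerance = 1e-10)
  expect_equal(C[3, 3], iso[["C11"]], tolerance = 1e-10)
  expect_equal(C[1, 2], iso[["C12"]], tolerance = 1e-10)
  expect_equal(C[1, 3], iso[["C12"]], tolerance = 1e-10)
  expect_equal(C[4, 4], iso[["C44"]], tolerance = 1e-10)
  expect_equal(C[5, 5], iso[["C44"]], tolerance = 1e-10)
  expect_equal(C[6, 6], iso[["C44"]], tolerance = 1e-10)
  expect_equal(unclass(C)[1:3, 1:3], t(unclass(C)[1:3, 1:3]), tolerance = 1e-12)
})

test_that("the effective stiffness is independent of the applied displacement", {
  t <- calibrate_t(1, 3, 4, 3, 0.6, R = 13)
  v <- voxelize(tpms_config(1, 0.6, 3, 4, 3, t = t), 13)
  C1 <- homogenize(v, compression = "x", shear = "yz", d = 0.1)
  C2 <- homogenize(v, compression = "x", shear = "yz", d = 0.2)
  expect_equal(C1[1, 1], C2[1, 1], tolerance = 1e-9)
  expect_equal(C1[4, 4], C2[4, 4], tolerance = 1e-9)
})

test_that("porous diagonals respect the Voigt bound and fall with porosity", {
  iso <- iso_stiffness(material(10, 0.3))
  for (phi in c(0.5, 0.75)) {
    t <- calibrate_t(2, 3, 4, 5, phi, R = 17)
    v <- voxelize(tpms_config(2, phi, 3, 4, 5, t = t), 17)
    C <- homogenize(v, compression = "x", shear = "yz")
    sf <- mean(v$occupancy)
    expect_lt(C[1, 1], (1 - phi + 0.01) * iso[["C11"]])
    expect_gt(C[1, 1], 0)
    if (phi == 0.5) c11_lo <- C[1, 1] else expect_lt(C[1, 1], c11_lo)
  }
})

test_that("swapping two arrangement counts swaps the corresponding moduli", {
  t <- calibrate_t(2, 4, 6, 3, 0.62, R = 16)
  a <- voxelize(tpms_config(2, 0.62, 4, 6, 3, t = t), 16)
  b <- voxelize(tpms_config(2, 0.62, 6, 4, 3, t = t), 16)
  Ca <- homogenize(a, compression = "x", shear = character(0))
  Cb <- homogenize(b, compression = "y", shear = character(0))
  expect_equal(Ca[1, 1], Cb[2, 2], tolerance = 1e-6)
})

test_that("free-face loading yields softer apparent moduli than the affine mode", {
  t <- calibrate_t(1, 4, 4, 3, 0.6, R = 13)
  v <- voxelize(tpms_config(1, 0.6, 4, 4, 3, t = t), 13)
  Ck <- homogenize(v, compression = "x", shear = character(0), mode = "uniaxial")
  Cf <- homogenize(v, compression = "x", shear = character(0), mode = "free")
  expect_lt(Cf[1, 1], Ck[1, 1])
  expect_true(is.na(Cf[1, 2]))  # no lateral reactions without lateral constraints
})

test_that("load-case and material validation reject bad inputs", {
  expect_error(material(-1, 0.3), "positive")
  expect_error(material(10, 0.6), "Poisson|nu")
  expect_error(load_case("compression", "xy"), "invalid")
  expect_error(load_case("shear", "x"), "invalid")
})

test_that("resolution drift is small for well-resolved structures and warns when large", {
  cfg <- tpms_config(2, 0.55, 3, 3, 3)
  rd <- resolution_drift(cfg, R_coarse = 11, R_fine = 17)
  expect_named(rd, c("coarse", "fine", "drift"))
  expect_lt(rd$drift, 0.2)
  expect_warning(resolution_drift(cfg, R_coarse = 11, R_fine = 17,
                                  warn_above = 1e-9), "drifts")
})
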