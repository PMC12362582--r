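test_that("radius of gyration matches its direct definition to 1e-10", {
  expect_equal(radius_of_gyration(conformer("C", matrix(0, 1, 3))), 0)
  dumb <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(dumb), 1)

  set.seed(101)
  els <- sample(c("C", "N", "O", "H"), 50, replace = TRUE)
  xyz <- matrix(rnorm(150, sd = 4), ncol = 3)
  cf <- conformer(els, xyz)
  masses <- default_radii_table()$mass
  expect_equal(radius_of_gyration(cf),
               brute_rgyr(xyz, unname(masses[els])), tolerance = 1e-10)
  expect_equal(radius_of_gyration(cf, mass_weighted = FALSE),
               brute_rgyr(xyz, rep(1, 50)), tolerance = 1e-10)
  # exactly unchanged by centroid translation
  shifted <- conformer(els, sweep(xyz, 2, c(10, -20, 5), "+"))
  expect_equal(radius_of_gyration(cf), radius_of_gyration(shifted),
               tolerance = 1e-12)
  expect_error(radius_of_gyration(conformer("Xx", matrix(0, 1, 3))),
               "unknown element")
})

test_that("Shrake-Rupley reproduces closed-form areas for isolated and buried atoms", {
  o <- conformer("O", matrix(0, 1, 3))
  expect_equal(shrake_rupley_sasa(o, 1.4, 960), 4 * pi * (1.52 + 1.4)^2,
               tolerance = 1e-10)
  expect_equal(shrake_rupley_sasa(o, 0, 960), 4 * pi * 1.52^2,
               tolerance = 1e-10)
  expect_equal(shrake_rupley_sasa(o, 0, 64), 4 * pi * 1.52^2, tolerance = 1e-10)
  # central atom enclosed by a tight octahedral-plus shell
  shell <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1)) * 1.2
  buried <- conformer(rep(c("C", "O"), c(1, 6)), rbind(c(0, 0, 0), shell))
  expect_equal(shrake_rupley_sasa(buried, 0, 960)[1], 0)
  expect_error(shrake_rupley_sasa(conformer("Zz", matrix(0, 1, 3)), 1.4),
               "unknown element")
})

test_that("per-atom SASA is non-increasing as a neighbor approaches", {
  areas <- sapply(seq(6, 1.6, by = -0.4), function(d) {
    cf <- conformer(c("O", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
    shrake_rupley_sasa(cf, 1.4, 960)[1]
  })
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("SASA agrees with a dense Monte-Carlo occlusion oracle and converges with the lattice", {
  set.seed(202)
  for (rep in 1:3) {
    m <- toy_molecule(9)
    got <- sum(shrake_rupley_sasa(m, 1.4, 960))
    ref <- mc_sasa(m, 1.4, 2e5)
    expect_lt(abs(got - ref) / ref, 0.02)
  }
  # error versus a dense oracle shrinks as lattice points quadruple
  set.seed(203)
  m <- toy_molecule(8)
  ref <- mc_sasa(m, 1.4, 1e6)
  errs <- sapply(c(240, 960, 3840), function(np) {
    abs(sum(shrake_rupley_sasa(m, 1.4, np)) - ref) / ref
  })
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("descriptors are invariant under rigid rotation and translation", {
  set.seed(303)
  m <- toy_molecule(12)
  moved <- rigid_motion(m)
  expect_equal(shrake_rupley_sasa(moved, 1.4, 960),
               shrake_rupley_sasa(m, 1.4, 960), tolerance = 1e-8)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(m),
               tolerance = 1e-8)
  expect_equal(psa_3d(moved, 1.4), psa_3d(m, 1.4), tolerance = 1e-8)
})

test_that("3D PSA sums polar-atom SASA: zero for hydrocarbons, full surface for water", {
  hydro <- conformer(rep("C", 5), matrix(rnorm(15), ncol = 3))
  expect_equal(psa_3d(hydro, 0), 0)
  expect_equal(psa_3d(hydro, 1.4), 0)

  water <- conformer(c("O", "H", "H"),
                     rbind(c(0, 0, 0),
                           c(0.9572, 0, 0),
                           c(-0.2399872, 0.9266272, 0)),
                     bonds = rbind(c(1, 2), c(1, 3)))
  # every atom is polar, so 3D PSA equals total SASA; check both against MC
  expect_equal(psa_3d(water, 1.4, 960),
               sum(shrake_rupley_sasa(water, 1.4, 960)))
  set.seed(404)
  expect_lt(abs(psa_3d(water, 1.4, 960) - mc_sasa(water, 1.4, 3e5)) /
              mc_sasa(water, 1.4, 3e5), 0.01)

  # polar H detection needs bonds or the distance fallback equivalently
  water_nobonds <- conformer(water$elements, water$xyz)
  expect_equal(psa_3d(water_nobonds, 1.4, 960), psa_3d(water, 1.4, 960))

  # folding an N/C chain buries polar atoms
  els <- rep(c("N", "C"), 8)
  extended <- conformer(els, cbind(1.5 * (0:15), 0, 0))
  grid <- as.matrix(expand.grid(x = 1.5 * (0:3), y = 1.5 * (0:1), z = 1.5 * (0:1)))
  folded <- conformer(els, grid)
  expect_lt(psa_3d(folded, 1.4), psa_3d(extended, 1.4))

  # psa never exceeds total SASA
  set.seed(405)
  for (rep in 1:4) {
    m <- toy_molecule(10)
    expect_lte(psa_3d(m, 1.4, 240), sum(shrake_rupley_sasa(m, 1.4, 240)) + 1e-9)
  }
})

test_that("IMHB detection applies distance and angle criteria to donor-H...acceptor triples", {
  # linear O-H...O, H...A 1.9 A
  geom <- function(ha_dist, angle_deg) {
    ang <- angle_deg * pi / 180
    # donor at origin, H along +x, acceptor placed to give D-H...A angle
    h <- c(0.96, 0, 0)
    a <- h + ha_dist * c(-cos(ang), sin(ang), 0)
    conformer(c("O", "H", "O"), rbind(c(0, 0, 0), h, a),
              bonds = rbind(c(1, 2)))
  }
  expect_equal(nrow(find_imhb(geom(1.9, 180))), 1)
  expect_equal(nrow(find_imhb(geom(3.5, 180))), 0)
  expect_equal(nrow(find_imhb(geom(1.9, 90))), 0)
  # donor covalently bonded to acceptor is excluded
  bonded <- geom(1.9, 180)
  bonded$bonds <- rbind(bonded$bonds, c(1, 3))
  expect_equal(nrow(find_imhb(bonded)), 0)
  # no topology and no inferable H bonding
  naked <- conformer(c("C", "C"), rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_error(find_imhb(naked), "topology")
})

test_that("conformer_descriptors returns the full per-frame row", {
  set.seed(505)
  m <- toy_molecule(8)
  d <- conformer_descriptors(m, n_points = 240)
  expect_named(d, c("frame_id", "r_gyr", "psa_0", "psa_14", "sasa_total", "n_imhb"))
  expect_gte(d$psa_0, 0)
  expect_lte(d$psa_14, d$sasa_total + 1e-9)
  expect_equal(d$r_gyr, radius_of_gyration(m))
})
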