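test_that("ensemble summaries report medians, IQRs and the folded/low-polarity fraction", {
  same <- frame_table(rep(6.2, 7), rep(150, 7))
  s <- summarize_ensemble(same, "A", "water", "POLAR", "SMD")
  expect_equal(s$median_rgyr, 6.2)
  expect_equal(s$median_psa14, 150)
  expect_equal(s$iqr_rgyr, 0)
  expect_equal(s$fraction_folded_lowpolar, 1)  # (6.2, 150) is folded/low-polar

  odd <- frame_table(c(5, 6, 7, 8, 9), rep(250, 5))
  expect_equal(summarize_ensemble(odd)$median_rgyr, 7)

  expect_error(summarize_ensemble(frame_table(numeric(), numeric())), "empty")

  # order invariance and threshold monotonicity
  set.seed(31)
  fr <- frame_table(runif(60, 4, 10), runif(60, 100, 300))
  perm <- fr[sample(nrow(fr)), ]
  expect_equal(summarize_ensemble(fr)$median_psa14,
               summarize_ensemble(perm)$median_psa14)
  fracs <- sapply(seq(9, 5, by = -1), function(th) {
    summarize_ensemble(fr, rgyr_threshold = th)$fraction_folded_lowpolar
  })
  expect_true(all(diff(fracs) <= 0))
})

test_that("density maps conserve frames and break maximum ties deterministically", {
  one <- frame_table(6.1, 151)
  m1 <- density_map(one)
  expect_equal(sum(m1$counts), 1)
  expect_equal(max(m1$counts), 1)

  set.seed(32)
  big <- frame_table(rnorm(20, 5, 0.05), rnorm(20, 120, 1))
  small <- frame_table(rnorm(10, 9, 0.05), rnorm(10, 280, 1))
  both <- rbind(big, small)
  both$frame_id <- seq_len(30)
  m <- density_map(both)
  expect_equal(sum(m$counts), 30)
  # max bin sits in the 20-frame cluster (low r_gyr, low psa)
  expect_lt(m$x_edges[m$max_bin["i"]], 7)

  set.seed(33)
  rnd <- frame_table(runif(137, 3, 12), runif(137, 50, 350))
  expect_equal(sum(density_map(rnd)$counts), 137)

  # exact tie between two single-frame bins: lower psa wins, then lower r_gyr
  tie <- frame_table(c(5.1, 5.1, 9.1), c(280, 120, 120))
  mt <- density_map(tie)
  expect_equal(mt$counts[mt$max_bin["i"], mt$max_bin["j"]], 1L)
  expect_lt(mt$y_edges[mt$max_bin["j"]], 130)  # low-psa bin chosen
  expect_lt(mt$x_edges[mt$max_bin["i"]], 6)    # then low r_gyr

  expect_error(density_map(one, x_bin_width = 0), "binning")
})

test_that("the density-maximum conformer equals the brute-force nearest-to-center frame", {
  one <- frame_table(6.1, 151, frame_id = 42L)
  expect_equal(density_max_conformer(one, density_map(one)), 42L)

  set.seed(34)
  fr <- frame_table(c(rnorm(70, 5, 0.4), rnorm(30, 9, 0.4)),
                    c(rnorm(70, 120, 15), rnorm(30, 280, 15)))
  map <- density_map(fr)
  got <- density_max_conformer(fr, map)

  # exhaustive oracle: re-derive membership and standardized distances
  inbin <- which(map$bin_x == map$max_bin["i"] & map$bin_y == map$max_bin["j"])
  cx <- mean(map$x_edges[map$max_bin["i"] + 0:1])
  cy <- mean(map$y_edges[map$max_bin["j"] + 0:1])
  d2 <- ((fr$r_gyr[inbin] - cx) / sd(fr$r_gyr))^2 +
    ((fr$psa_14[inbin] - cy) / sd(fr$psa_14))^2
  expect_equal(got, min(fr$frame_id[inbin[d2 == min(d2)]]))
  expect_true(got %in% fr$frame_id[inbin])
})

test_that("chameleon contrast returns polar-minus-nonpolar median deltas, antisymmetric", {
  fr <- frame_table(runif(40, 4, 8), runif(40, 100, 250))
  a <- summarize_ensemble(fr, "C1", "water", "POLAR")
  b <- summarize_ensemble(fr, "C1", "toluene", "NONPOLAR")
  expect_equal(unname(chameleon_contrast(a, b)), c(0, 0))

  set.seed(35)
  fr2 <- frame_table(fr$r_gyr - 1.5, fr$psa_14 - 60)
  b2 <- summarize_ensemble(fr2, "C1", "toluene", "NONPOLAR")
  d <- chameleon_contrast(a, b2)
  expect_equal(unname(d), -unname(chameleon_contrast(b2, a)))
  expect_equal(unname(d["delta_median_psa14"]), 60)

  wrong <- summarize_ensemble(fr, "C2", "toluene", "NONPOLAR")
  expect_error(chameleon_contrast(a, wrong), "mismatch")
})

test_that("the water-folding generator yields the chameleonic property-space signature", {
  cfg <- generator_config(seed = 36, n_frames = 40, chain_length = 50)
  pol <- gen_ensemble(cfg, "polar")
  non <- gen_ensemble(cfg, "nonpolar")
  dp <- ensemble_descriptors(pol$frames, n_points = 60, imhb = FALSE)
  dn <- ensemble_descriptors(non$frames, n_points = 60, imhb = FALSE)
  sp <- summarize_ensemble(dp, "SYN-01", "water", "POLAR")
  sn <- summarize_ensemble(dn, "SYN-01", "toluene", "NONPOLAR")
  d <- chameleon_contrast(sp, sn)
  # polar compactness > nonpolar: folding in water lowers both medians
  expect_lt(d["delta_median_rgyr"], 0)
  expect_lt(d["delta_median_psa14"], 0)
})
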