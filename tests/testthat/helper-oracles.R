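# Independent oracles and small geometry builders shared across tests.

# Direct-definition radius of gyration: explicit loops, no matrix algebra.
brute_rgyr <- function(xyz, w) {
  ctr <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) ctr <- ctr + w[i] * xyz[i, ]
  ctr <- ctr / sum(w)
  s <- 0
  for (i in seq_len(nrow(xyz))) s <- s + w[i] * sum((xyz[i, ] - ctr)^2)
  sqrt(s / sum(w))
}

# Closed-form simple OLS (textbook formulas), independent of lm().
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Monte-Carlo occlusion SASA: random (not lattice) sphere points, n_total
# split evenly across atoms.
mc_sasa <- function(conf, probe, n_total = 1e6) {
  radii <- default_radii_table()$radius
  r <- unname(radii[conf$elements]) + probe
  n_atoms <- length(r)
  npt <- ceiling(n_total / n_atoms)
  total <- 0
  for (i in seq_len(n_atoms)) {
    u <- matrix(stats::rnorm(npt * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    p <- sweep(u * r[i], 2, conf$xyz[i, ], "+")
    acc <- rep(TRUE, npt)
    for (j in seq_len(n_atoms)[-i]) {
      acc <- acc & rowSums(sweep(p, 2, conf$xyz[j, ])^2) >= r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# Uniformly random rigid motion (rotation from QR of a Gaussian matrix,
# plus translation) applied to a conformer.
rigid_motion <- function(conf, shift = c(5, -3, 2)) {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  conformer(conf$elements, sweep(conf$xyz %*% rot, 2, shift, "+"),
            bonds = conf$bonds, frame_id = conf$frame_id)
}

# Small random "toy molecule": n atoms drawn from common organic elements,
# coordinates in a box sized so spheres overlap but rarely bury completely.
toy_molecule <- function(n = 10, box = 4) {
  els <- sample(c("C", "N", "O", "H", "S"), n, replace = TRUE,
                prob = c(0.4, 0.15, 0.15, 0.25, 0.05))
  conformer(els, matrix(stats::runif(n * 3, 0, box), ncol = 3))
}

# Analytic one-compartment curves (ng/mL for mg/kg doses, L/kg volume).
one_cmpt_iv <- function(t, dose, cl, v) 1000 * dose / v * exp(-(cl / v) * t)
one_cmpt_oral <- function(t, dose, f, cl, v, ka) {
  ke <- cl / v
  1000 * (f / 100) * dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# Descriptor frame table builder for ensemble tests.
frame_table <- function(r_gyr, psa_14, frame_id = seq_along(r_gyr)) {
  data.frame(frame_id = frame_id, r_gyr = r_gyr, psa_14 = psa_14)
}
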