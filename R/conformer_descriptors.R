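#' Van der Waals radii and atomic masses
#'
#' Bondi van der Waals radii (Angstrom) and standard atomic masses (Da)
#' for the elements the descriptor engine supports. Override by passing a
#' modified copy as the `radii` argument of the SASA functions.
#'
#' @return List with named numeric vectors `radius` and `mass`.
#' @export
default_radii_table <- function() {
  list(
    radius = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               F = 1.47, Cl = 1.75, P = 1.80, Br = 1.85, I = 1.98),
    mass = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             F = 18.998, Cl = 35.45, P = 30.974, Br = 79.904, I = 126.904)
  )
}

#' Construct a conformer
#'
#' A conformer is one 3D geometry of a molecule: element symbols, an
#' n x 3 coordinate matrix in Angstrom, optional bonds (2-column matrix of
#' 1-based atom indices) and a frame id.
#'
#' @param elements Character vector of element symbols.
#' @param xyz Numeric matrix, n x 3, Angstrom.
#' @param bonds Optional integer matrix with 2 columns.
#' @param frame_id Integer frame label.
#' @return Object of class `"conformer"`.
#' @export
conformer <- function(elements, xyz, bonds = NULL, frame_id = 1L) {
  xyz <- as.matrix(xyz)
  stopifnot(is.character(elements), length(elements) >= 1L,
            ncol(xyz) == 3L, nrow(xyz) == length(elements))
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    stopifnot(all(bonds >= 1L), all(bonds <= length(elements)))
  }
  structure(list(elements = elements, xyz = xyz, bonds = bonds,
                 frame_id = as.integer(frame_id)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("Conformer (frame %d): %d atoms [%s], %s bonds\n",
              x$frame_id, length(x$elements),
              paste(names(sort(table(x$elements), decreasing = TRUE)),
                    collapse = ","),
              if (is.null(x$bonds)) "no" else nrow(x$bonds)))
  invisible(x)
}

lookup_element <- function(elements, table, what) {
  v <- table[elements]
  if (any(is.na(v))) {
    stop("unknown element(s) in ", what, " table: ",
         paste(unique(elements[is.na(v)]), collapse = ", "), call. = FALSE)
  }
  unname(v)
}

#' Radius of gyration
#'
#' Compactness/sphericity measure: the root weighted mean squared distance
#' of the atoms from their weighted centroid, sqrt(sum w_i |r_i - rbar|^2
#' / sum w_i). Mass-weighted by default.
#'
#' @param conf A [conformer()].
#' @param mass_weighted If `FALSE`, all atoms weigh equally.
#' @param radii Radii/mass table, see [default_radii_table()].
#' @return R_gyr in Angstrom.
#' @export
radius_of_gyration <- function(conf, mass_weighted = TRUE,
                               radii = default_radii_table()) {
  stopifnot(inherits(conf, "conformer"))
  w <- if (mass_weighted) {
    lookup_element(conf$elements, radii$mass, "mass")
  } else rep(1, length(conf$elements))
  ctr <- colSums(conf$xyz * w) / sum(w)
  d2 <- rowSums(sweep(conf$xyz, 2L, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Deterministic golden-spiral points on the unit sphere
#'
#' Fibonacci-lattice placement: near-uniform coverage with no random
#' number generation, so every area that depends on it is bit-reproducible.
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1L)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)  # golden angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Canonical molecular frame: principal axes of the centered coordinates,
# with signs fixed by the third moment of the projections (falling back to
# the largest-magnitude component) and a right-handed third axis. Rotating
# the molecule rotates this frame with it, which makes lattice-based areas
# exactly invariant under rigid motion.
canonical_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(diag(3))
  x <- sweep(xyz, 2L, colMeans(xyz))
  v <- eigen(crossprod(x) / n, symmetric = TRUE)$vectors
  for (k in 1:2) {
    pr <- x %*% v[, k]
    s <- sum(pr^3)
    if (abs(s) < 1e-10) s <- pr[which.max(abs(pr))]
    if (s < 0) v[, k] <- -v[, k]
  }
  v[, 3L] <- c(v[2L, 1L] * v[3L, 2L] - v[3L, 1L] * v[2L, 2L],
               v[3L, 1L] * v[1L, 2L] - v[1L, 1L] * v[3L, 2L],
               v[1L, 1L] * v[2L, 2L] - v[2L, 1L] * v[1L, 2L])
  v
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point SASA: each atom's sphere of radius r_vdw + probe
#' is sampled with a deterministic golden-spiral lattice; a point is
#' accessible when it lies outside every other atom's inflated sphere, and
#' the atom's area is 4 pi (r_vdw + probe)^2 times the accessible
#' fraction. Probe 0 gives the exposed van der Waals surface, probe 1.4
#' the water-accessible surface.
#'
#' The lattice is expressed in the molecule's principal-axis frame, so the
#' computed areas are deterministic and exactly invariant under rigid
#' rotation and translation of the input coordinates.
#'
#' @param conf A [conformer()].
#' @param probe_radius Probe radius in Angstrom (>= 0).
#' @param n_points Lattice points per atom (>= 16; default 960).
#' @param radii Radii table, see [default_radii_table()].
#' @return Numeric vector of per-atom accessible areas (square Angstrom).
#' @export
shrake_rupley_sasa <- function(conf, probe_radius = 1.4, n_points = 960L,
                               radii = default_radii_table()) {
  stopifnot(inherits(conf, "conformer"), probe_radius >= 0, n_points >= 16L)
  r <- lookup_element(conf$elements, radii$radius, "radius") + probe_radius
  n <- length(r)
  pts <- golden_spiral_points(n_points) %*% t(canonical_frame(conf$xyz))
  xyz <- conf$xyz
  areas <- numeric(n)
  # neighbor cut: spheres i and j can only occlude if centers closer than r_i + r_j
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    full <- 4 * pi * r[i]^2
    if (!length(nb)) {
      areas[i] <- full
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
        (p[, 3L] - xyz[j, 3L])^2
      acc <- acc & dj2 >= r[j]^2
      if (!any(acc)) break
    }
    areas[i] <- full * sum(acc) / n_points
  }
  areas
}

infer_h_bonds <- function(conf, h_cut = 1.2) {
  # distance fallback when topology is absent: an H is bonded to the
  # nearest heavy atom within h_cut Angstrom
  els <- conf$elements
  hs <- which(els == "H")
  heavy <- which(els != "H")
  if (!length(hs) || !length(heavy)) return(NULL)
  out <- lapply(hs, function(h) {
    d2 <- rowSums(sweep(conf$xyz[heavy, , drop = FALSE], 2L, conf$xyz[h, ])^2)
    k <- which.min(d2)
    if (d2[k] < h_cut^2) c(heavy[k], h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) NULL else matrix(as.integer(out), ncol = 2L)
}

conformer_bonds <- function(conf) {
  if (!is.null(conf$bonds)) conf$bonds else infer_h_bonds(conf)
}

#' Polar atom selection for 3D PSA
#'
#' The classical polar surface area convention: nitrogen, oxygen, and
#' hydrogens bonded to either. Sulfur is excluded. H-heavy bonding comes
#' from the conformer's bond list or, when absent, from a < 1.2 Angstrom
#' distance fallback.
#'
#' @param conf A [conformer()].
#' @return Integer vector of polar atom indices.
#' @export
polar_atoms <- function(conf) {
  stopifnot(inherits(conf, "conformer"))
  els <- conf$elements
  polar <- which(els %in% c("N", "O"))
  bonds <- conformer_bonds(conf)
  if (!is.null(bonds)) {
    b <- rbind(bonds, bonds[, 2:1, drop = FALSE])
    polar_h <- unique(b[b[, 1L] %in% polar & els[b[, 2L]] == "H", 2L])
    polar <- sort(unique(c(polar, polar_h)))
  }
  polar
}

#' 3D polar surface area
#'
#' Solvent-accessible surface area summed over the polar atoms (N, O and
#' H bonded to N/O) at a given probe radius. Probe 0 is the exposed polar
#' van der Waals surface ("3D PSA 0"), probe 1.4 the water-accessible
#' polar surface ("3D PSA 1.4").
#'
#' @inheritParams shrake_rupley_sasa
#' @return 3D PSA in square Angstrom.
#' @export
psa_3d <- function(conf, probe_radius = 1.4, n_points = 960L,
                   radii = default_radii_table()) {
  idx <- polar_atoms(conf)
  if (!length(idx)) return(0)
  sum(shrake_rupley_sasa(conf, probe_radius, n_points, radii)[idx])
}

#' Intramolecular hydrogen bond detection
#'
#' Geometric criteria on donor-H...acceptor triples: the donor (N/O
#' covalently bonded to the H) and acceptor (any other N/O) form an IMHB
#' when the H...acceptor distance is at most `max_h_acceptor_dist` and the
#' D-H...A angle is at least `min_dha_angle`, and donor and acceptor are
#' not covalently bonded to each other.
#'
#' @param conf A [conformer()] with bond information (or H bonds inferable
#'   by distance).
#' @param max_h_acceptor_dist H...A cutoff, Angstrom (default 2.5).
#' @param min_dha_angle D-H...A angle cutoff, degrees (default 120).
#' @return Data frame with columns `donor`, `h`, `acceptor` (atom
#'   indices); zero rows when none found.
#' @export
find_imhb <- function(conf, max_h_acceptor_dist = 2.5, min_dha_angle = 120) {
  stopifnot(inherits(conf, "conformer"))
  bonds <- conformer_bonds(conf)
  if (is.null(bonds)) stop("no topology: bonds required for IMHB detection",
                           call. = FALSE)
  els <- conf$elements
  b <- rbind(bonds, bonds[, 2:1, drop = FALSE])
  bonded <- function(i, j) any(b[, 1L] == i & b[, 2L] == j)
  # donor-H pairs: H bonded to N/O
  dh <- b[els[b[, 1L]] %in% c("N", "O") & els[b[, 2L]] == "H", , drop = FALSE]
  acceptors <- which(els %in% c("N", "O"))
  hits <- list()
  for (k in seq_len(nrow(dh))) {
    dnr <- dh[k, 1L]
    h <- dh[k, 2L]
    for (acc in acceptors) {
      if (acc == dnr || bonded(dnr, acc)) next
      ha <- conf$xyz[acc, ] - conf$xyz[h, ]
      dist_ha <- sqrt(sum(ha^2))
      if (dist_ha > max_h_acceptor_dist) next
      hd <- conf$xyz[dnr, ] - conf$xyz[h, ]
      cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * dist_ha)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= min_dha_angle) {
        hits[[length(hits) + 1L]] <- c(donor = dnr, h = h, acceptor = acc)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(donor = integer(), h = integer(), acceptor = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

#' Full descriptor row for one conformer
#'
#' @param conf A [conformer()].
#' @param n_points SASA lattice points per atom.
#' @param radii Radii table.
#' @param imhb Compute IMHB count (needs bonds; `FALSE` to leave `NA`).
#' @return One-row data frame: `frame_id`, `r_gyr`, `psa_0`, `psa_14`,
#'   `sasa_total`, `n_imhb`.
#' @export
conformer_descriptors <- function(conf, n_points = 960L,
                                  radii = default_radii_table(),
                                  imhb = TRUE) {
  sasa14 <- shrake_rupley_sasa(conf, 1.4, n_points, radii)
  idx <- polar_atoms(conf)
  psa14 <- if (length(idx)) sum(sasa14[idx]) else 0
  psa0 <- psa_3d(conf, 0, n_points, radii)
  n_hb <- if (imhb && !is.null(conformer_bonds(conf))) {
    nrow(find_imhb(conf))
  } else NA_integer_
  data.frame(frame_id = conf$frame_id,
             r_gyr = radius_of_gyration(conf, radii = radii),
             psa_0 = psa0, psa_14 = psa14,
             sasa_total = sum(sasa14), n_imhb = n_hb)
}

#' Descriptor table for an ensemble of conformers
#'
#' @param frames List of [conformer()] objects.
#' @param ... Passed to [conformer_descriptors()].
#' @return Data frame with one row per frame.
#' @export
ensemble_descriptors <- function(frames, ...) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  out <- do.call(rbind, lapply(frames, conformer_descriptors, ...))
  rownames(out) <- NULL
  out
}
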