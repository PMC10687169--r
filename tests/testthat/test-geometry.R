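hexagon <- function(radius = 1.39, z = 0) {
  ang <- seq(0, 300, by = 60) * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), z)
}

test_that("fit_plane recovers centroid, normal and rms on ideal hexagons", {
  pl <- fit_plane(hexagon())
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$rms, 0, tolerance = 1e-12)
  pts <- sweep(hexagon(), 2, c(1, 2, 3), "+")
  pl2 <- fit_plane(pts)
  expect_equal(pl2$centroid, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(abs(pl2$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(sqrt(sum(pl2$normal^2)), 1, tolerance = 1e-9)
})

test_that("fit_plane rms equals an independent SVD of centered coordinates", {
  set.seed(11)
  pts <- hexagon()
  pts[, 3] <- pts[, 3] + sample(c(-0.01, 0.01), 6, replace = TRUE)
  pl <- fit_plane(pts)
  d <- svd(sweep(pts, 2, colMeans(pts)))$d
  expect_equal(pl$rms, d[3] / sqrt(nrow(pts)), tolerance = 1e-12)
})

test_that("fit_plane rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_plane(line), "collinear")
  expect_error(fit_plane(hexagon()[1:2, ]), "3 points")
})

test_that("ring_descriptor handles PHE, TRP and incomplete rings", {
  phe <- make_ring_pair(5, 0)$atoms
  phe <- phe[phe$chain == "A", ]
  rings <- ring_descriptor(phe)
  expect_length(rings, 1)
  expect_equal(rings[[1]]$ring_label, "six_membered")
  expect_length(rings[[1]]$atom_names, 6)

  trp <- make_trp_atoms()
  expect_length(ring_descriptor(trp), 2)

  no_cz <- phe[phe$name != "CZ", ]
  expect_warning(r0 <- ring_descriptor(no_cz), "CZ")
  expect_length(r0, 0)
})

test_that("pair_geometry measures coaxial and perpendicular rings exactly", {
  m <- make_ring_pair(5.0, 0)
  rings <- find_rings(m)
  g <- pair_geometry(rings[[1]], rings[[2]])
  expect_equal(g$r_cen, 5.0, tolerance = 1e-9)
  expect_equal(g$gamma, 0, tolerance = 1e-9)
  g90 <- do.call(pair_geometry, find_rings(make_ring_pair(5.0, 90)))
  expect_equal(g90$gamma, 90, tolerance = 1e-9)
})

test_that("pair_geometry is symmetric in its arguments", {
  rings <- find_rings(make_ring_pair(4.7, 37.3))
  g1 <- pair_geometry(rings[[1]], rings[[2]])
  g2 <- pair_geometry(rings[[2]], rings[[1]])
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("gamma and r_cen are invariant under rigid motions", {
  set.seed(42)
  m <- make_ring_pair(5.6, 41.2)
  ref <- find_pi_pi_contacts(m)
  for (i in 1:20) {
    mt <- transform_model(m, random_rotation(), stats::rnorm(3, sd = 20))
    got <- find_pi_pi_contacts(mt)
    expect_equal(got$r_cen, ref$r_cen, tolerance = 1e-9)
    expect_equal(got$gamma, ref$gamma, tolerance = 1e-9)
  }
})

test_that("ring-pair constructor and measurement round-trip to 1e-6", {
  grid <- expand.grid(r = seq(3, 8, by = 1), g = seq(0, 90, by = 15))
  for (k in seq_len(nrow(grid))) {
    rings <- find_rings(make_ring_pair(grid$r[k], grid$g[k]))
    got <- pair_geometry(rings[[1]], rings[[2]])
    expect_equal(got$r_cen, grid$r[k], tolerance = 1e-6)
    expect_equal(got$gamma, grid$g[k], tolerance = 1e-6)
  }
})

test_that("pi-pi classification bands are left-closed and configurable", {
  expect_equal(classify_pi_pi(5.5, 50.8), "t_shaped")
  expect_equal(classify_pi_pi(5.5, 44.9), "intermediate")
  expect_equal(classify_pi_pi(5.0, 5), "parallel")
  expect_equal(classify_pi_pi(8.0, 5), "none")
  # boundaries belong to the upper band
  expect_equal(classify_pi_pi(5.0, 30), "intermediate")
  expect_equal(classify_pi_pi(5.0, 50), "t_shaped")
  expect_equal(classify_pi_pi(5.0, 29.9999), "parallel")
  expect_equal(classify_pi_pi(5.0, 90), "t_shaped")
  # window edges are inclusive
  expect_equal(classify_pi_pi(3.0, 10), "parallel")
  expect_equal(classify_pi_pi(7.0, 60), "t_shaped")
  # custom thresholds move the boundaries
  th <- list(r_cen_min = 3, r_cen_max = 7, gamma_parallel = 20,
             gamma_tshaped = 70)
  expect_equal(classify_pi_pi(5.0, 25, th), "intermediate")
  expect_equal(classify_pi_pi(5.0, 65, th), "intermediate")
  expect_error(classify_pi_pi(5, 5, list(r_cen_min = 7, r_cen_max = 3,
                                         gamma_parallel = 30,
                                         gamma_tshaped = 50)),
               "non-monotone")
})

test_that("find_pi_pi_contacts reports classified, sorted, flagged contacts", {
  m <- make_ring_pair(5.5, 60)
  res <- find_pi_pi_contacts(m)
  expect_equal(nrow(res), 1)
  expect_equal(res$conformation, "t_shaped")
  expect_true(res$intermolecular)

  empty <- find_pi_pi_contacts(m, selection = m$atoms[0, ])
  expect_equal(nrow(empty), 0)

  # three stacked rings -> three pairs, sorted by r_cen
  a <- make_ring_pair(3.5, 0)$atoms
  extra <- a[a$chain == "B", ]
  extra$chain <- "C"; extra$z <- extra$z + 3.4
  m3 <- structure_model("stack3", rbind(a, extra))
  res3 <- find_pi_pi_contacts(m3)
  expect_equal(nrow(res3), 3)
  expect_equal(res3$r_cen, sort(res3$r_cen))
  # same-residue ring pairs (TRP) are excluded
  trp <- structure_model("trp", make_trp_atoms())
  expect_equal(nrow(find_pi_pi_contacts(trp)), 0)
})

make_ring_with_cation <- function(offset_deg, dist, kind = c("LYS", "ARG")) {
  kind <- match.arg(kind)
  ring <- make_ring_pair(5, 0)$atoms
  ring <- ring[ring$chain == "A",
               setdiff(names(ring), c("is_symmetry_copy", "sym_op"))]
  th <- offset_deg * pi / 180
  centre <- c(sin(th) * dist, 0, cos(th) * dist)
  if (kind == "LYS") {
    cat_atoms <- data.frame(
      eleno = NA_integer_, name = "NZ", alt = "", resid = "LYS", chain = "B",
      resno = 5L, x = centre[1], y = centre[2], z = centre[3], o = 1, b = 0,
      element = "N", het = FALSE, stringsAsFactors = FALSE)
  } else {
    offs <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0))
    cat_atoms <- data.frame(
      eleno = NA_integer_, name = c("NE", "CZ", "NH1", "NH2"), alt = "",
      resid = "ARG", chain = "B", resno = 5L,
      x = centre[1] + offs[, 1], y = centre[2] + offs[, 2],
      z = centre[3] + offs[, 3], o = 1, b = 0,
      element = c("N", "C", "N", "N"), het = FALSE, stringsAsFactors = FALSE)
  }
  structure_model("pi_cat", rbind(ring, cat_atoms))
}

test_that("pi-cation detection applies distance and offset-angle criteria", {
  on_axis <- find_pi_cation_contacts(make_ring_with_cation(0, 4.0, "LYS"))
  expect_equal(nrow(on_axis), 1)
  expect_equal(on_axis$offset_angle, 0, tolerance = 1e-9)
  expect_equal(on_axis$distance, 4.0, tolerance = 1e-9)

  far <- find_pi_cation_contacts(make_ring_with_cation(0, 8.0, "LYS"))
  expect_equal(nrow(far), 0)

  gdn <- find_pi_cation_contacts(make_ring_with_cation(45, 4.5, "ARG"))
  expect_equal(nrow(gdn), 1)
  expect_equal(gdn$offset_angle, 45, tolerance = 0.1)
  expect_match(gdn$cation, "guanidinium")

  # offset filter excludes the same geometry when tightened
  tight <- find_pi_cation_contacts(make_ring_with_cation(45, 4.5, "ARG"),
                                   max_offset = 30)
  expect_equal(nrow(tight), 0)
})
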