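test_that("Kabsch superposition recovers known transforms and is optimal", {
  set.seed(1)
  A <- matrix(rnorm(30), 10)
  k0 <- kabsch_superpose(A, A)
  expect_equal(k0$rmsd, 0, tolerance = 1e-12)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-10)

  R <- random_rotation(); tr <- c(1, -2, 3)
  B <- sweep(A %*% t(R), 2, tr, "+")
  k1 <- kabsch_superpose(A, B)
  expect_equal(k1$rmsd, 0, tolerance = 1e-8)
  expect_equal(k1$rotation, R, tolerance = 1e-8)

  # optimality: no random rotation beats the fitted one
  set.seed(2)
  noisy <- B + matrix(rnorm(30, sd = 0.3), 10)
  best <- kabsch_superpose(A, noisy)$rmsd
  A0 <- sweep(A, 2, colMeans(A))
  N0 <- sweep(noisy, 2, colMeans(noisy))
  for (rep in 1:1000) {
    rr <- sqrt(mean(rowSums((A0 %*% t(random_rotation()) - N0)^2)))
    expect_lte(best, rr + 1e-12)
  }

  coll <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(coll, coll), "degenerate-superposition")
})

test_that("Kabsch agrees with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(4)
  A <- matrix(rnorm(36), 12)
  B <- sweep(A %*% t(random_rotation()), 2, c(2, 0, -1), "+") +
    matrix(rnorm(36, sd = 0.2), 12)
  ours <- kabsch_superpose(A, B)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(B)), mobile = as.numeric(t(A))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("spatial density is exact weight bookkeeping on a voxel grid", {
  # all snapshots at one point: a single voxel holds everything
  ens <- toy_ensemble(matrix(rep(c(1.2, 2.3, 0.7), 5), ncol = 3, byrow = TRUE),
                      rep(1, 5))
  d <- spatial_density(ens, "ligand", spacing = 1)
  expect_equal(max(d$values), 1)
  expect_equal(sum(d$values > 0), 1)

  # two point-clusters with weights 0.5 / 0.5
  pts <- rbind(matrix(rep(c(0, 0, 0), 3), ncol = 3, byrow = TRUE),
               matrix(rep(c(8, 8, 8), 2), ncol = 3, byrow = TRUE))
  ens2 <- toy_ensemble(pts, c(1, 1, 1, 1.5, 1.5))
  d2 <- spatial_density(ens2, "ligand", spacing = 1)
  vals <- sort(d2$values[d2$values > 0])
  expect_equal(vals, c(0.5, 0.5))

  # random ensembles: voxel values always sum to 1; region mass equals the
  # weighted fraction of snapshots whose centre falls there
  set.seed(9)
  pts3 <- matrix(runif(60, 0, 10), ncol = 3)
  w3 <- runif(20)
  ens3 <- toy_ensemble(pts3, w3)
  d3 <- spatial_density(ens3, "ligand", spacing = 2)
  expect_equal(sum(d3$values), 1, tolerance = 1e-12)
  # mass in the voxel slabs left of a voxel boundary equals the weighted
  # fraction of snapshots whose centre falls there
  cut <- d3$origin[1] + 2 * 2   # after two voxel layers
  region_mass <- sum(d3$values[1:2, , ])
  expect_equal(region_mass, sum(w3[pts3[, 1] < cut]) / sum(w3),
               tolerance = 1e-12)
})

test_that("analyses are invariant to snapshot order and weight splitting", {
  set.seed(10)
  pts <- matrix(runif(30, 0, 6), ncol = 3)
  w <- runif(10)
  ens <- toy_ensemble(pts, w)
  # duplicate snapshot 4 with its weight split in half
  pts2 <- rbind(pts, pts[4, ])
  w2 <- c(w, w[4] / 2); w2[4] <- w[4] / 2
  ens2 <- toy_ensemble(pts2, w2)
  # and a permuted copy
  perm <- sample(10)
  ens3 <- toy_ensemble(pts[perm, , drop = FALSE], w[perm])

  grid_args <- list(spacing = 1, origin = c(-2, -2, -2), dims = c(12, 12, 12))
  d1 <- do.call(spatial_density, c(list(ens, "ligand"), grid_args))
  d2 <- do.call(spatial_density, c(list(ens2, "ligand"), grid_args))
  d3 <- do.call(spatial_density, c(list(ens3, "ligand"), grid_args))
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
  expect_equal(d1$values, d3$values, tolerance = 1e-12)

  s <- list(type = "atom_pair", i = 1, j = 2)
  expect_equal(distance_distribution(ens, s)$mean,
               distance_distribution(ens2, s)$mean, tolerance = 1e-12)
  expect_equal(contact_fraction(ens, "ligand_head", "ligand_tail", 3),
               contact_fraction(ens2, "ligand_head", "ligand_tail", 3),
               tolerance = 1e-12)
})

test_that("density clusters match a constructed flood-fill layout", {
  g <- list(origin = c(0, 0, 0), spacing = 1,
            values = array(0, c(10, 10, 10)), rho0 = 0.001,
            selection_label = "x", n_dropped = 0L)
  class(g) <- "density_grid"
  # blob 1: 2x2x2 block of mass 0.006; blob 2: single voxel of 0.002
  g$values[2:3, 2:3, 2:3] <- 0.006 / 8
  g$values[8, 8, 8] <- 0.002
  g$values[5, 5, 5] <- 0.992   # dominant background peak
  cr <- density_clusters(g, level_multiplier = 0.5)   # threshold 5e-4
  expect_equal(nrow(cr$clusters), 3)
  expect_equal(cr$clusters$mass[1], 0.992)
  expect_equal(sort(cr$clusters$mass[2:3]), c(0.002, 0.006))
  blob1 <- cr$members[[which(abs(cr$clusters$mass - 0.006) < 1e-12)]]
  expect_equal(nrow(blob1), 8)   # 26-connectivity joins the 2x2x2 block
  # threshold above the global maximum: no clusters
  expect_equal(nrow(density_clusters(g, 2000)$clusters), 0)
  # diagonal neighbours merge under 26-connectivity
  g2 <- g; g2$values[] <- 0
  g2$values[2, 2, 2] <- 0.5; g2$values[3, 3, 3] <- 0.5
  expect_equal(nrow(density_clusters(g2, 0.5)$clusters), 1)
})

test_that("minimum group distance equals the exhaustive double loop", {
  co <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 4.2, 0))
  expect_equal(min_group_distance(co, 2L, 3L), 4.2)
  expect_equal(min_group_distance(co, c(1L, 2L), c(2L, 3L)), 0)
  expect_error(min_group_distance(co, integer(0), 1L), "invalid-group")
  set.seed(14)
  for (rep in 1:5) {
    co <- matrix(rnorm(60, sd = 5), ncol = 3)
    g1 <- 1:10; g2 <- 11:20
    expect_equal(min_group_distance(co, g1, g2),
                 brute_min_distance(co, g1, g2), tolerance = 1e-12)
  }
})

test_that("the contact rule is a strict inequality at the cutoff", {
  expect_true(contact_indicator(3.9))
  expect_false(contact_indicator(4.1))
  expect_false(contact_indicator(4.0))   # r = 4.0 exactly: no contact
  ens <- toy_ensemble(matrix(0, 3, 3), c(1, 2, 3))
  expect_equal(contact_fraction(ens, "ligand_head", "ligand_tail", 4), 1)
})

test_that("distance distributions carry exact weighted moments", {
  # all distances equal: single occupied bin, SD = sd = 0
  ens <- toy_ensemble(matrix(rep(c(0, 0, 0), 4), ncol = 3, byrow = TRUE),
                      rep(1, 4))
  d <- distance_distribution(ens, list(type = "atom_pair", i = 1, j = 2),
                             bin_width = 0.5)
  expect_equal(sum(d$mass > 0), 1)
  expect_equal(d$SD, 0)
  expect_equal(d$sd, 0)

  # five stated weights/distances against hand-evaluated weighted formulas
  x <- c(2, 3, 5, 7, 11)
  w <- c(0.1, 0.3, 0.2, 0.25, 0.15)
  m_hand <- sum(w * x) / sum(w)
  sd_hand <- sqrt(sum(w * (x - m_hand)^2) / sum(w))
  sysless <- toy_ensemble(matrix(0, 5, 3), w)
  sysless$coords <- lapply(x, function(xi) rbind(c(0, 0, 0), c(xi, 0, 0)))
  d5 <- distance_distribution(sysless, list(type = "atom_pair", i = 1, j = 2),
                              bin_width = 0.5)
  expect_equal(d5$mean, m_hand, tolerance = 1e-12)
  expect_equal(d5$SD, sd_hand, tolerance = 1e-12)
  expect_equal(d5$sd, sd_hand / m_hand, tolerance = 1e-12)
  expect_equal(sum(d5$density * 0.5), 1, tolerance = 1e-12)
  # moments are invariant under bin-width changes (computed unbinned)
  d6 <- distance_distribution(sysless, list(type = "atom_pair", i = 1, j = 2),
                              bin_width = 1.7)
  expect_equal(d6$mean, d5$mean)
  expect_equal(d6$SD, d5$SD)
})

test_that("flexibility sd reproduces the published framework statistics", {
  expect_equal(flexibility_sd(7.12, 0.37), 5.20e-2)
  expect_equal(flexibility_sd(6.01, 0.14), 2.33e-2)
  expect_equal(flexibility_sd(13.15, 0.47), 3.57e-2)
  # scale invariance
  set.seed(15)
  for (rep in 1:10) {
    m <- runif(1, 1, 20); s <- runif(1, 0, 2); c <- runif(1, 0.1, 10)
    expect_equal(flexibility_sd(c * m, c * s), flexibility_sd(m, s))
  }
  expect_error(flexibility_sd(0, 1), "invalid-input")
})

test_that("orientation fields average unit vectors with exact limits", {
  # identically oriented snapshots: |<e>| = 1 everywhere
  pts <- matrix(rep(c(5, 5, 5), 6), ncol = 3, byrow = TRUE)
  ens <- toy_ensemble(pts, rep(1, 6))   # all e = +x
  of <- orientation_field(ens, "ligand_head", "ligand_tail", spacing = 2,
                          com_selection = "ligand")
  expect_equal(of$table$magnitude, rep(1, nrow(of$table)), tolerance = 1e-12)
  expect_true(all(of$table$class == "aligned"))

  # two antiparallel equal-weight populations in one cube cancel exactly
  ens2 <- toy_ensemble(pts[1:2, ], c(1, 1), head = 2L, tail = 1L)
  ens2$coords[[2]] <- ens2$coords[[2]][2:1, ]   # flip head and tail beads
  of2 <- orientation_field(ens2, "ligand_head", "ligand_tail", spacing = 2)
  expect_equal(of2$table$magnitude, 0, tolerance = 1e-12)
  expect_true(all(of2$table$class == "disordered"))

  # isotropic orientations: |<e>| below the Monte-Carlo null 99th percentile
  set.seed(16)
  n <- 200
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- lapply(seq_len(n), function(i)
    rbind(c(5, 5, 5) - dirs[i, ], c(5, 5, 5) + dirs[i, ]))
  ens3 <- canonical_ensemble(coords, rep(1, n),
                             system = toy_ensemble(pts, rep(1, 6))$system)
  of3 <- orientation_field(ens3, "ligand_head", "ligand_tail", spacing = 50)
  null_res <- replicate(2000, {
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    sqrt(sum(colMeans(u)^2))
  })
  expect_lt(of3$table$magnitude[1], quantile(null_res, 0.99))
  # convexity: magnitudes never exceed 1 on random weighted ensembles
  w <- runif(n)
  ens4 <- canonical_ensemble(coords, w, system = ens3$system)
  of4 <- orientation_field(ens4, "ligand_head", "ligand_tail", spacing = 3)
  expect_true(all(of4$table$magnitude <= 1 + 1e-12))

  # coincident head and tail centres are an error
  bad <- canonical_ensemble(list(rbind(c(0, 0, 0), c(0, 0, 0))), 1,
                            system = ens3$system)
  expect_error(orientation_field(bad, "ligand_head", "ligand_tail"),
               "zero-length-vector")
})
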