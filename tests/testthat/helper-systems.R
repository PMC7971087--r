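# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (double loops, exhaustive scans) and never call the
# package's compiled paths.

kB <- 0.0019872041

# naive R evaluation of the toy Hamiltonian (independent of the C++ core)
brute_energy <- function(sys, coords = sys$coords) {
  e <- 0
  for (m in seq_len(nrow(sys$bonds))) {
    r <- sqrt(sum((coords[sys$bonds$i[m], ] - coords[sys$bonds$j[m], ])^2))
    e <- e + sys$bonds$k[m] * (r - sys$bonds$r0[m])^2
  }
  for (m in seq_len(nrow(sys$angles))) {
    a <- coords[sys$angles$i[m], ] - coords[sys$angles$j[m], ]
    b <- coords[sys$angles$k[m], ] - coords[sys$angles$j[m], ]
    th <- acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
    e <- e + sys$angles$ka[m] * (th - sys$angles$theta0[m])^2
  }
  excl <- character(0)
  if (nrow(sys$bonds))
    excl <- c(excl, paste(pmin(sys$bonds$i, sys$bonds$j),
                          pmax(sys$bonds$i, sys$bonds$j)))
  if (nrow(sys$angles))
    excl <- c(excl, paste(pmin(sys$angles$i, sys$angles$k),
                          pmax(sys$angles$i, sys$angles$k)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  nbkey <- key(sys$nonbonded$type1, sys$nonbonded$type2)
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% excl) next
    m <- match(key(sys$bead_types[i], sys$bead_types[j]), nbkey)
    eps <- sys$nonbonded$eps[m]; sig <- sys$nonbonded$sigma[m]
    if (eps == 0) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  for (rs in sys$restraints)
    for (q in seq_along(rs$ids))
      e <- e + rs$k * sum((coords[rs$ids[q], ] - rs$anchors[q, ])^2)
  e
}

# exhaustive zone-membership scan (oracle for states_containing)
brute_states_containing <- function(lambda, grid) {
  all_states <- as.matrix(expand.grid(lapply(grid$axes, function(a)
    seq_len(a$n_vs)), KEEP.OUT.ATTRS = FALSE))
  hit <- apply(all_states, 1, function(st) {
    all(vapply(seq_len(grid$d), function(h) {
      iv <- grid$axes[[h]]$intervals[st[h], ]
      last <- st[h] == grid$axes[[h]]$n_vs
      lambda[h] >= iv[1] && (lambda[h] < iv[2] || (last && lambda[h] <= iv[2]))
    }, logical(1)))
  })
  unname(all_states[hit, , drop = FALSE])
}

brute_min_distance <- function(coords, g1, g2) {
  best <- Inf
  for (i in g1) for (j in g2)
    best <- min(best, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  best
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# the reduced validation system and its sampling settings
pair_fixture <- function() {
  list(sys = build_pair_system(bond_k = 0.5, r0 = 6),
       rc = list(rc_def("r", 1L, 2L, "geometric", c(3, 9))),
       grid = build_zone_grid(c(3, 9), n_vs = 3, overlap_fraction = 0.5),
       params = dynamics_params(temperature = 300, dt = 10, friction = 2))
}

# a tiny weighted ensemble of hand-placed two-bead "ligand" snapshots
toy_ensemble <- function(points, weights, head = 2L, tail = 1L) {
  sys <- build_pair_system()
  sys$groups <- list(ligand = c(1L, 2L), ligand_head = head, ligand_tail = tail)
  coords <- lapply(seq_len(nrow(points)), function(i)
    rbind(points[i, ] - c(1, 0, 0), points[i, ] + c(1, 0, 0)))
  canonical_ensemble(coords, weights, system = sys)
}

# expected-occupancy histogram stack over a known density (stitching oracle)
density_stack <- function(grid, p_linear, counts_per_zone = 1e4,
                          rounded = FALSE) {
  stack <- new_histogram_stack(grid)
  for (s in seq_len(n_states(grid))) {
    st <- state_from_id(s, grid)[1, ]
    bids <- vczone:::.state_bin_ids(st, grid)
    pz <- p_linear[bids] / sum(p_linear[bids])
    cc <- counts_per_zone * pz
    stack$counts[s, bids] <- if (rounded) round(cc) else cc
  }
  stack
}
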