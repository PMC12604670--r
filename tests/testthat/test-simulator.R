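test_that("potential terms match closed forms", {
  p <- sim_params()
  ## equilateral 3-bead ring with side r: per-bond FENE is the pure
  ## closed form; the bond WCA core and bending are booked separately
  r <- 1.2   # beyond the WCA cutoff so the pair terms vanish
  tri <- rbind(c(0, 0, 0), c(r, 0, 0), c(r / 2, r * sqrt(3) / 2, 0))
  st <- list(pos = tri, ring_len = 3L)
  e <- potential_energy(st, p)
  fene_exact <- -0.5 * 30 * 1.5^2 * log(1 - (r / 1.5)^2) * 3
  expect_equal(e$fene, fene_exact, tolerance = 1e-12)
  expect_equal(e$wca, 0)
  ## bending: interior angle 60 deg -> U = kb (1 + cos 60) per angle
  expect_equal(e$bend, 3 * 4 * (1 + cos(pi / 3)), tolerance = 1e-12)
})

test_that("FENE diverges near full extension and overstretch errors", {
  p <- sim_params()
  r <- 1.5 * (1 - 1e-6)
  tri <- rbind(c(0, 0, 0), c(r, 0, 0), c(r / 2, r * sqrt(3) / 2, 0))
  e <- potential_energy(list(pos = tri, ring_len = 3L), p)
  expect_gt(e$fene, 1e3)
  bad <- rbind(c(0, 0, 0), c(1.6, 0, 0), c(0.8, 1, 0))
  expect_error(potential_energy(list(pos = bad, ring_len = 3L), p),
               "overstretched")
})

test_that("a circular ring has the polygon bending energy", {
  net <- single_ring_network(40)
  p <- sim_params()
  e <- potential_energy(list(pos = net_positions(net), ring_len = 40L), p)
  ## regular m-gon: every interior angle gives 1 + cos(theta) = 1 - cos(2 pi/m)
  expect_equal(e$bend, 40 * 4 * (1 - cos(2 * pi / 40)), tolerance = 1e-10)
})

test_that("the thermostat reaches the target temperature", {
  net <- single_ring_network(60)
  p <- sim_params()
  st <- sim_state(net, p, seed = 2)
  st <- run_langevin(st, p, 1.5e5, seed = 3)
  expect_lt(abs(st$mean_temp - 1), 0.03)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  net <- single_ring_network(30)
  p <- sim_params()
  a <- run_langevin(sim_state(net, p, seed = 5), p, 2000, dump_every = 500,
                    seed = 6)
  b <- run_langevin(sim_state(net, p, seed = 5), p, 2000, dump_every = 500,
                    seed = 6)
  expect_identical(a$pos, b$pos)
  expect_identical(a$trajectory, b$trajectory)
})

test_that("zero temperature with strong damping dissipates energy", {
  net <- single_ring_network(30)
  p0 <- sim_params(temperature = 1e-12, gamma = 2)
  st <- sim_state(net, sim_params(), seed = 7)  # hot start
  e0 <- potential_energy(st, p0)$total + 0.5 * sum(st$vel^2)
  st <- run_langevin(st, p0, 5000, seed = 8)
  e1 <- potential_energy(st, p0)$total + 0.5 * sum(st$vel^2)
  expect_lt(e1, e0)
  expect_lt(0.5 * sum(st$vel^2) / (1.5 * nrow(st$pos)), 1e-3)
})

test_that("slit walls confine the network to the gap", {
  net <- build_mo(6, seed = 4)
  netc <- compress_to_disk(net, slit_gap = 4, ramp_steps = 2e4,
                           hold_steps = 1e4, seed = 5)
  expect_lt(max(abs(net_positions(netc)[, 3])), 2.6)  # gap/2 + soft-wall skin
  expect_true(verify_topology(netc)$ok)
})

test_that("the equilibration diagnostic accepts noise and rejects drift", {
  set.seed(11)
  good <- equilibration_report(rnorm(500, 10, 0.3))
  expect_true(good$pass)
  expect_equal(good$frac_within_2sd, 0.954, tolerance = 0.03)
  bad <- equilibration_report(seq(10, 12, length.out = 500) + rnorm(500, 0, 0.1))
  expect_false(bad$pass)
})

test_that("Kabsch alignment removes proper rigid motion but not mirrors", {
  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(X %*% t(R), 2, c(1, -2, 3), "+")
  expect_equal(kabsch_align(Y, X), X, tolerance = 1e-10)
  M <- X %*% diag(c(1, 1, -1))             # reflection
  aligned <- kabsch_align(M, X)
  expect_gt(mean(rowSums((aligned - X)^2)), 0.1)
})

test_that("observables report Rg and aligned ring centres", {
  ## analytic Rg of a 4-bead square of side s: Rg^2 = s^2 / 2
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2), tolerance = 1e-12)
  net <- build_mo(4, seed = 6)
  p <- sim_params()
  st <- sim_state(net, p, seed = 7)
  st <- run_langevin(st, p, 4000, dump_every = 1000, seed = 8)
  obs <- observables(st$trajectory, st$network)
  expect_equal(dim(obs$ring_com), c(4, 4, 3))
  ## rigid-body-moved copy aligns to zero displacement
  fr <- st$trajectory[[1]]
  th <- 0.3
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- sweep(fr %*% t(R), 2, c(3, 1, -2), "+")
  obs2 <- observables(list(fr, moved), st$network)
  expect_equal(obs2$aligned_com[2, , ], obs2$aligned_com[1, , ],
               tolerance = 1e-8)
})

test_that("maxicircle modes thread the intended minicircles", {
  net <- build_mo(16, seed = 31)
  netc <- compress_to_disk(net, slit_gap = 4, ramp_steps = 3e4,
                           hold_steps = 1e4, seed = 32)
  lb <- add_maxicircles(netc, mode = "LB", seed = 33)
  expect_true(verify_topology(lb)$ok)
  ## LB: every threaded minicircle lies on the rim
  expect_true(all(unlist(lb$threaded) %in% netc$boundary_ids))
  ## three maxicircles pairwise interlinked
  lm <- link_matrix(lb)
  n <- netc$n_mini
  expect_true(all(abs(lm[n + 1:3, n + 1:3][upper.tri(diag(3))]) == 1))
  ld <- add_maxicircles(netc, mode = "LD", seed = 34)
  expect_true(verify_topology(ld)$ok)
  ## LD threads sit further inside the disk than LB threads on average
  ctr <- colMeans(net_positions(netc))
  radial <- function(x, ids) {
    len <- ring_lengths(x); off <- c(0L, cumsum(len))
    pos <- net_positions(x)
    mean(vapply(ids, function(r) {
      cm <- colMeans(pos[(off[r] + 1):off[r + 1], , drop = FALSE])
      sqrt(sum((cm[1:2] - ctr[1:2])^2))
    }, 1.0))
  }
  expect_lt(radial(ld, unlist(ld$threaded)), radial(lb, unlist(lb$threaded)))
})
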