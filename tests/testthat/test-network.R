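test_that("Gauss linking number reproduces textbook cases", {
  a <- circle3d(60, 1, c(0, 0, 0), "xy")
  b <- circle3d(60, 1, c(1, 0, 0), "xz")
  expect_equal(abs(linking_number(a, b)), 1)
  expect_equal(linking_number(a, circle3d(60, 1, c(10, 0, 0), "xy")), 0)
  ## (2,4) torus link: two (1,2) curves on the same torus, |Lk| = 2
  t2 <- seq(0, 2 * pi, length.out = 201)[-201]
  tor <- function(k) cbind((2 + 0.5 * cos(2 * t2 + k * pi)) * cos(t2),
                           (2 + 0.5 * cos(2 * t2 + k * pi)) * sin(t2),
                           0.5 * sin(2 * t2 + k * pi))
  expect_equal(abs(linking_number(tor(0), tor(1))), 2)
})

test_that("linking number is symmetric and flips under orientation reversal", {
  a <- circle3d(48, 1, c(0, 0, 0), "xy")
  b <- circle3d(48, 1, c(1, 0, 0), "xz")
  lk <- linking_number(a, b)
  expect_equal(linking_number(b, a), lk)
  expect_equal(linking_number(a[nrow(a):1, ], b), -lk)
  expect_equal(linking_number(a, b[nrow(b):1, ]), -lk)
})

test_that("a two-ring build realises a Hopf pair", {
  net <- build_mo(2, seed = 1)
  expect_equal(abs(net$link_edges$lk), 1)
  expect_true(verify_topology(net)$ok)
})

test_that("honeycomb patches have valence 3 in the interior", {
  net <- build_mo(10, seed = 2)
  deg <- tabulate(c(net$graph$a, net$graph$b), nbins = 10)
  interior <- setdiff(seq_len(10), net$boundary_ids)
  expect_true(all(deg[interior] == 3))
  expect_true(all(deg <= 3))
  expect_true(verify_topology(net)$ok)
})

test_that("the realised link matrix matches the intended edges exactly", {
  net <- build_mo(20, seed = 5)
  vt <- verify_topology(net)
  expect_true(vt$ok)
  ## no spurious catenations anywhere
  expect_equal(sum(abs(vt$realised)) / 2, nrow(net$link_edges))
})

test_that("builds are reproducible and bad spacings are rejected", {
  a <- build_mo(10, seed = 9)
  b <- build_mo(10, seed = 9)
  expect_identical(net_positions(a), net_positions(b))
  expect_identical(a$chirality, b$chirality)
  expect_error(build_mo(10, spacing = 50, seed = 1), "spacing too large")
  expect_error(build_mo(10, spacing = 2, seed = 1), "spacing too small")
})

test_that("LAMMPS export writes consistent topology counts", {
  net <- build_mo(6, seed = 3)
  path <- tempfile(fileext = ".data")
  write_lammps_data(net, path)
  lines <- readLines(path)
  n_beads <- sum(ring_lengths(net))
  expect_true(any(grepl(sprintf("^%d atoms$", n_beads), lines)))
  expect_true(any(grepl(sprintf("^%d bonds$", n_beads), lines)))
  expect_true(any(grepl(sprintf("^%d angles$", n_beads), lines)))
  atoms <- grep("^Atoms", lines)
  first <- strsplit(lines[atoms + 2], " ")[[1]]
  expect_length(first, 6)  # id mol type x y z
})
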