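# Euclidean and solvent-accessible surface distances, satisfaction.

test_that("ca_distance is the Euclidean norm and is symmetric", {
  m <- toy_structure(list(A = data.frame(resno = 1:3,
                                         x = c(0, 3, 0), y = c(0, 4, 0),
                                         z = c(0, 0, 7))))
  expect_equal(ca_distance(m, c("A", 1), c("A", 1)), 0)
  expect_equal(ca_distance(m, c("A", 1), c("A", 2)), 5)
  expect_equal(ca_distance(m, c("A", 2), c("A", 1)),
               ca_distance(m, c("A", 1), c("A", 2)))
  expect_error(ca_distance(m, c("A", 9), c("A", 1)), "alpha-carbon")
})

test_that("ideal helix geometry gives ~3.8 A consecutive CA spacing", {
  spec <- synthetic_spec(chains = data.frame(chain_id = "A", length = 18L,
                                             fraction_helix = 1),
                         inter_chain_offsets = list(A = c(0, 0, 0)),
                         seed = 1)
  m <- make_structure(spec)
  d_consec <- vapply(1:17, function(i) {
    ca_distance(m, c("A", i), c("A", i + 1))
  }, numeric(1))
  expect_true(all(abs(d_consec - 3.8) < 0.05))
  # one-period lysine spacing inside a helix: ~2 turns away
  d7 <- ca_distance(m, c("A", 1), c("A", 8))
  expect_gt(d7, 10); expect_lt(d7, 12)
})

test_that("grid shortest path matches an independent Dijkstra oracle exactly", {
  set.seed(99)
  # random small masks
  for (k in 1:4) {
    dims <- c(9L, 8L, 7L)
    blocked <- array(stats::runif(prod(dims)) < 0.25, dims)
    blocked[1, 1, 1] <- FALSE
    blocked[dims[1], dims[2], dims[3]] <- FALSE
    got <- grid_shortest_path(blocked, c(1, 1, 1), dims, spacing = 1)
    want <- oracle_grid_path(blocked, c(1, 1, 1), dims, spacing = 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # a solid wall with a single gap forces a detour
  dims <- c(15L, 11L, 11L)
  blocked <- array(FALSE, dims)
  blocked[8, , ] <- TRUE
  blocked[8, 11, 11] <- FALSE
  got <- grid_shortest_path(blocked, c(1, 6, 6), c(15, 6, 6))
  want <- oracle_grid_path(blocked, c(1, 6, 6), c(15, 6, 6))
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 14)  # strictly longer than the straight line
  # fully separating wall -> unreachable
  blocked[8, 11, 11] <- TRUE
  expect_identical(grid_shortest_path(blocked, c(1, 6, 6), c(15, 6, 6)), Inf)
})

test_that("free-space SASD approaches the Euclidean distance", {
  m <- toy_structure(list(A = data.frame(resno = 1:2, x = c(0, 10),
                                         y = 0, z = 0)))
  cfg <- distance_config(cutoff = 15)
  s <- sasd(m, c("A", 1), c("A", 2), cfg)
  ed <- ca_distance(m, c("A", 1), c("A", 2))
  # within discretization (2 grid steps) plus 26-connectivity overhead (~8%)
  expect_gte(s, ed - 2 * cfg$grid_spacing)
  expect_lte(s, ed * 1.08 + 2 * cfg$grid_spacing)
})

test_that("a blocking wall makes SASD strictly exceed ED", {
  # endpoints on either side of a slab of dummy atoms, wall finite in +y
  wall <- expand.grid(x = 5, y = seq(-8, 8, by = 1.2),
                      z = seq(-8, 8, by = 1.2))
  coords <- list(
    A = data.frame(resno = 1:2, x = c(0, 10), y = 0, z = 0),
    W = data.frame(resno = seq_len(nrow(wall)) , x = wall$x, y = wall$y,
                   z = wall$z, resid = "ALA"))
  m <- toy_structure(coords)
  cfg <- distance_config(cutoff = 15)
  s <- sasd(m, c("A", 1), c("A", 2), cfg)
  ed <- ca_distance(m, c("A", 1), c("A", 2))
  expect_true(is.finite(s))
  expect_gt(s, ed * 1.15)
})

test_that("an endpoint sealed beyond the rescue radius is unreachable", {
  shell <- expand.grid(x = seq(-9, 9, by = 1.5), y = seq(-9, 9, by = 1.5),
                       z = seq(-9, 9, by = 1.5))
  keep <- sqrt(shell$x^2 + shell$y^2 + shell$z^2) <= 9
  keep <- keep & !(abs(shell$x) < 1 & abs(shell$y) < 1 & abs(shell$z) < 1)
  shell <- shell[keep, ]
  m <- toy_structure(list(
    A = data.frame(resno = 1:2, x = c(0, 30), y = 0, z = 0),
    S = data.frame(resno = seq_len(nrow(shell)), x = shell$x, y = shell$y,
                   z = shell$z, resid = "ALA")))
  cfg <- distance_config(cutoff = 15, max_search_radius = 3,
                         atom_radii = c(C = 1.7))
  expect_identical(sasd(m, c("A", 1), c("A", 2), cfg), Inf)
})

test_that("SASD dominates ED minus discretization and refines monotonically", {
  spec <- synthetic_spec(chains = data.frame(chain_id = "A", length = 25L,
                                             fraction_helix = 1),
                         inter_chain_offsets = list(A = c(0, 0, 0)), seed = 4)
  m <- make_structure(spec)
  cfg1 <- distance_config(cutoff = 16, atom_radii = c(C = 3.0))
  cfg2 <- distance_config(cutoff = 16, grid_spacing = 0.5,
                          atom_radii = c(C = 3.0))
  pairs <- list(c(1, 8), c(1, 15), c(8, 22))
  for (p in pairs) {
    ed <- ca_distance(m, c("A", p[1]), c("A", p[2]))
    s1 <- sasd(m, c("A", p[1]), c("A", p[2]), cfg1)
    expect_gte(s1, ed - 2 * cfg1$grid_spacing)
    # symmetric within a grid step
    s1r <- sasd(m, c("A", p[2]), c("A", p[1]), cfg1)
    expect_lt(abs(s1 - s1r), cfg1$grid_spacing + 1e-9)
    # refinement never increases the path beyond the coarse-grid value
    s2 <- sasd(m, c("A", p[1]), c("A", p[2]), cfg2)
    expect_lte(s2, s1 + 2 * cfg1$grid_spacing)
  }
})

test_that("measurement resolves homo-oligomer ambiguity by minimum ED", {
  # candidate EDs: A10-A30 = 50, A10-B30 = 15, B10-A30 = 150, B10-B30 = 185
  m <- toy_structure(list(
    A = data.frame(resno = c(10, 30), x = c(0, 50), y = 0, z = 0),
    B = data.frame(resno = c(10, 30), x = c(200, 15), y = 0, z = 0)))
  cm <- chain_map(c("P1", "P1"), c("A", "B"))
  u <- dedupe_crosslinks(toy_csms("P1", 10, "P1", 30))
  meas <- measure_crosslinks(m, map_crosslinks(u, cm, m))
  expect_equal(nrow(meas), 1L)
  expect_equal(meas$ed, 15)
  expect_setequal(c(meas$chain_a, meas$chain_b), c("A", "B"))
  expect_true(meas$satisfied)
})

test_that("satisfaction respects the cutoff and counts are cutoff-monotone", {
  m <- toy_structure(list(A = data.frame(resno = c(1, 2, 3, 4),
                                         x = c(0, 20, 45, 36), y = 0, z = 0)))
  cm <- chain_map("P1", "A")
  u <- dedupe_crosslinks(toy_csms(c("P1", "P1", "P1"), c(1, 1, 1),
                                  c("P1", "P1", "P1"), c(2, 3, 4)))
  mapped <- map_crosslinks(u, cm, m)
  m37 <- measure_crosslinks(m, mapped, distance_config(cutoff = 37))
  expect_equal(m37$satisfied[m37$position_b == 2], TRUE)   # 20 A
  expect_equal(m37$satisfied[m37$position_b == 3], FALSE)  # 45 A
  counts <- vapply(c(10, 21, 37, 50), function(cut) {
    sum(measure_crosslinks(m, mapped, distance_config(cutoff = cut))$satisfied)
  }, numeric(1))
  expect_false(is.unsorted(counts))
})

test_that("unmapped crosslinks are counted, not measured", {
  m <- toy_structure(list(A = data.frame(resno = c(1, 2), x = c(0, 5),
                                         y = 0, z = 0)))
  u <- dedupe_crosslinks(toy_csms(c("P1", "PX"), c(1, 1),
                                  c("P1", "PX"), c(2, 2)))
  meas <- measure_crosslinks(m, map_crosslinks(u, chain_map("P1", "A"), m))
  expect_equal(nrow(meas), 1L)
  expect_equal(attr(meas, "n_unmapped"), 1L)
})
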