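test_that("single cognate adjacency contributes exactly -E_X", {
  fx <- make_fixture("bridge-1")
  e <- total_energy(fx$state, fx$params)
  expect_equal(e$hetero_total, fx$expected$energy)  # alpha + gamma bonds
  expect_equal(e$homo_total, 0)
  expect_equal(e$total, e$hetero_total + e$homo_total)
})

test_that("an isolated molecule has zero energy", {
  p <- model_params(n = 1, L = 12, c = 1 / 12^3, E_X = 3, E_A = 2, E_B = 2)
  st <- make_fixture("stretched")$state
  st$mol_coords <- matrix(c(6L, 6L, 6L), 1)  # far from everything
  e <- total_energy(st, p)
  expect_equal(e$total, 0)
})

test_that("the valency cap limits counted bonds per molecule", {
  # a centre A molecule with 5 same-species neighbours, v = 4
  p <- model_params(n = 1, L = 12, c = 6 / 12^3, E_X = 0, E_A = 1, E_B = 1,
                    affinity = matrix(0, 2, 4))
  centre <- c(5L, 5L, 5L)
  nbrs <- rbind(c(4, 5, 5), c(6, 5, 5), c(5, 4, 5), c(5, 6, 5), c(5, 5, 4))
  st <- new_system_state(12, rbind(c(0, 0, 0), c(0, 0, 1)), c(4L, 4L),
                         c(1L, 1L), c(1L, 1L),
                         rbind(centre, nbrs), rep(1L, 6))
  e <- total_energy(st, p)
  expect_lte(e$per_molecule$homo_bonds[1], 4)
  # each neighbour pairs only with the centre; centre caps at 4 pairs
  expect_equal(e$homo_total, -4)
})

test_that("total energy matches the independent brute-force oracle", {
  for (s in 1:8) {
    ts <- random_test_state(seed = 100 + s, sweeps = 50)
    got <- total_energy(ts$state, ts$params)
    want <- oracle_energy(ts$state, ts$params)
    expect_equal(got$hetero_total, want$hetero, tolerance = 1e-12)
    expect_equal(got$homo_total, want$homo, tolerance = 1e-12)
  }
  # and with the homotypic-only cap scope
  ts <- random_test_state(seed = 200, sweeps = 50)
  ts$params$cap_scope <- "homo"
  expect_equal(total_energy(ts$state, ts$params)$total,
               oracle_energy(ts$state, ts$params)$total, tolerance = 1e-12)
})

test_that("energy is invariant under global lattice translation", {
  ts <- random_test_state(seed = 300, sweeps = 30)
  e0 <- total_energy(ts$state, ts$params)$total
  for (shift in list(c(1, 0, 0), c(3, 5, 2), c(7, 7, 7))) {
    st2 <- ts$state
    st2$bead_coords <- sweep(st2$bead_coords, 2, shift, `+`) %% st2$L
    st2$mol_coords <- sweep(st2$mol_coords, 2, shift, `+`) %% st2$L
    expect_equal(total_energy(st2, ts$params)$total, e0, tolerance = 1e-12)
  }
})

test_that("zero affinities give zero energy for any state", {
  ts <- random_test_state(seed = 400, E_X = 0, E_A = 0, E_B = 0, sweeps = 20)
  expect_equal(total_energy(ts$state, ts$params)$total, 0)
})

test_that("delta_energy equals the difference of total energies", {
  p <- model_params(n = 1, L = 10, c = 2 / 1000, E_X = 2.5)
  st <- new_system_state(
    10, cbind(0:8, 5L, 5L), c(1L, 4L, 1L, 4L, 3L, 4L, 2L, 4L, 2L),
    rep(1L, 9), 1:9, rbind(c(2, 2, 2), c(7, 7, 7)), c(1L, 2L)
  )
  # isolation -> isolation
  mv <- proposed_move("molecule_step", 1, c(2, 2, 3))
  expect_equal(delta_energy(st, mv, p), 0)
  # step into adjacency with a cognate alpha bead at (0,5,5)
  st$mol_coords[1, ] <- c(0L, 3L, 5L)
  mv2 <- proposed_move("molecule_step", 1, c(0, 4, 5))
  expect_equal(delta_energy(st, mv2, p), -2.5)
  # and the generic contract on random molecule steps
  ts <- random_test_state(seed = 500, sweeps = 40)
  for (j in c(1, 5, 9)) {
    to <- (ts$state$mol_coords[j, ] + c(1, 0, 0)) %% ts$state$L
    occ <- rbind(ts$state$bead_coords, ts$state$mol_coords)
    if (any(apply(occ, 1, function(r) all(r == to)))) next
    mv <- proposed_move("molecule_step", j, to)
    after <- apply_move(ts$state, mv)
    expect_equal(delta_energy(ts$state, mv, ts$params),
                 total_energy(after, ts$params)$total -
                   total_energy(ts$state, ts$params)$total)
  }
})
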