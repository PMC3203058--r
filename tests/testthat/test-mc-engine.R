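test_that("zero sweeps leave the state unchanged with an empty series", {
  ts <- random_test_state(seed = 600)
  run <- run_mc(ts$state, ts$params, sweeps = 0, seed = 1)
  expect_equal(nrow(run$series), 0)
  expect_identical(run$final_state, ts$state)
  expect_equal(run$energy$drift, 0)
})

test_that("trajectories are bitwise reproducible for equal seeds", {
  p <- model_params(n = 2, L = 10, c = 0.02, E_X = 2, E_A = 1, E_B = 1,
                    sweeps = 300, record_every = 50)
  st <- init_state(p, "open", seed = 9)
  r1 <- run_mc(st, p, seed = 11)
  r2 <- run_mc(st, p, seed = 11)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_state, r2$final_state)
  r3 <- run_mc(st, p, seed = 12)
  expect_false(identical(r1$final_state, r3$final_state))
})

test_that("a free molecule proposes each of the 6 directions uniformly", {
  p <- model_params(n = 1, L = 8, c = 1 / 512, E_X = 0)
  st <- new_system_state(8, matrix(integer(0), ncol = 3), integer(0),
                         integer(0), integer(0),
                         matrix(c(4L, 4L, 4L), 1), 1L)
  moves <- t(vapply(1:600, function(s) {
    fs <- run_mc(st, p, sweeps = 1, record_every = 1, seed = s)$final_state
    xicsim:::mi_diff(st$mol_coords[1, ], fs$mol_coords[1, ], 8)
  }, numeric(3)))
  # all displacements are unit steps (free neighbourhood, dE = 0, all accepted)
  expect_true(all(rowSums(abs(moves)) == 1))
  dir_id <- moves %*% c(1, 2, 3)   # six distinct signed codes
  counts <- table(factor(dir_id, levels = c(-3, -2, -1, 1, 2, 3)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("with all energies zero the polymer samples the SAW ensemble", {
  # 5-bead polymer alone; engine's long-run mean squared end-to-end distance
  # must match exact enumeration of all 5-bead self-avoiding walks
  p <- model_params(n = 1, L = 12, c = 1 / 12^3, E_X = 0)
  st <- new_system_state(12, cbind(0:4, 6L, 6L), rep(4L, 5), rep(1L, 5),
                         rep(1L, 5), matrix(c(0L, 0L, 0L), 1), 1L)
  run <- run_mc(st, p, sweeps = 60000, record_every = 20, seed = 13,
                frame_every = 20)
  r2 <- vapply(run$frames, function(f) {
    sum(xicsim:::mi_diff(f$state$bead_coords[1, ], f$state$bead_coords[5, ], 12)^2)
  }, numeric(1))
  exact <- oracle_saw_r2(5)
  expect_equal(mean(r2), exact, tolerance = 0.08)
})

test_that("the Metropolis rule accepts with probability min(1, exp(-dE))", {
  expect_true(all(vapply(1:50, function(i) metropolis_accept(0), logical(1))))
  expect_true(all(vapply(1:50, function(i) metropolis_accept(-3), logical(1))))
  set.seed(99)
  f <- mean(vapply(1:4000, function(i) metropolis_accept(log(2)), logical(1)))
  expect_lt(abs(f - 0.5), 0.03)
})

test_that("state invariants hold throughout interacting runs", {
  p <- model_params(n = 2, L = 10, c = 0.05, E_X = 3, E_A = 3, E_B = 3,
                    sweeps = 2000, record_every = 500)
  st <- init_state(p, "open", seed = 21)
  # validate_every makes the engine re-check invariants in-flight
  run <- run_mc(st, p, seed = 22, validate_every = 200)
  expect_true(validate_state(run$final_state, p))
  expect_true(all(run$acceptance$attempts > 0))
})

test_that("null moves are counted as attempts", {
  # a straight interior bead has no corner-flip move; crankshaft on a
  # straight quadruple is null too
  p <- model_params(n = 1, L = 12, c = 1 / 12^3, E_X = 0)
  st <- new_system_state(12, cbind(0:4, 6L, 6L), rep(4L, 5), rep(1L, 5),
                         rep(1L, 5), matrix(c(0L, 0L, 0L), 1), 1L)
  run <- run_mc(st, p, sweeps = 200, record_every = 200, seed = 31)
  acc <- run$acceptance
  expect_gt(acc$nulls[acc$kind == "crankshaft"], 0)
  expect_equal(sum(acc$attempts), 200 * 6)  # 5 beads + 1 molecule
})
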