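test_that("bridge fixtures produce the hand-enumerated contacts", {
  fx1 <- make_fixture("bridge-1")
  rc <- region_contact(fx1$state, fx1$params, "alpha", "gamma")
  expect_true(rc$contact[1])
  expect_equal(rc$n_bridges[1], 1)

  fx2 <- make_fixture("bridge-2")
  rc2 <- region_contact(fx2$state, fx2$params, "alpha", "gamma")
  expect_true(rc2$contact[1])
  expect_equal(rc2$n_bridges[1], 2)

  fx3 <- make_fixture("stretched")
  rep3 <- contact_report(fx3$state, fx3$params)
  expect_false(any(rep3$contact))
  expect_equal(sum(rep3$n_bridges), 0)

  expect_error(region_contact(fx1$state, fx1$params, "delta", "gamma"),
               "unknown region")
})

# the deterministic n = 1 looped chain, used as a hand-checkable conformation
looped1_chain <- function(L = 8, off = 4L) {
  ch <- rbind(c(0, 1, 1), c(-1, 1, 1), c(-1, 1, 0), c(-1, 0, 0), c(0, 0, 0),
              c(0, 0, 1), c(0, -1, 1), c(1, -1, 1), c(1, -1, 0)) + off
  types <- c(1L, 4L, 1L, 4L, 3L, 4L, 2L, 4L, 2L)
  list(coords = ch, types = types)
}

test_that("interaction parameter averages contacts over the window", {
  p <- model_params(n = 1, L = 8, c = 2 / 512, E_X = 2)
  lc <- looped1_chain()
  # alpha bridge molecule only: alpha-gamma in contact, beta-gamma not
  st_half <- new_system_state(8, lc$coords, lc$types, rep(1L, 9), 1:9,
                              rbind(c(4, 5, 4), c(0, 0, 0)), c(1L, 2L))
  ip <- interaction_parameter(list(st_half), params = p)
  expect_equal(ip$P_alpha, 1)
  expect_equal(ip$P_beta, 0)
  expect_equal(ip$P, 0.5)

  # both bridges present: P = 1; none: P = 0
  st_full <- new_system_state(8, lc$coords, lc$types, rep(1L, 9), 1:9,
                              rbind(c(4, 5, 4), c(4, 3, 4)), c(1L, 2L))
  expect_equal(interaction_parameter(list(st_full), params = p)$P, 1)
  st_none <- new_system_state(8, lc$coords, lc$types, rep(1L, 9), 1:9,
                              rbind(c(0, 0, 0), c(0, 0, 1)), c(1L, 2L))
  expect_equal(interaction_parameter(list(st_none), params = p)$P, 0)
  # a mixed window averages: (1 + 0) / 2
  expect_equal(interaction_parameter(list(st_full, st_none), params = p)$P, 0.5)
  expect_error(interaction_parameter(list(), params = p), "empty")
})

test_that("local density counts molecules in the union Chebyshev shell", {
  p <- model_params(n = 1, L = 12, c = 5 / 12^3, E_X = 2, shell_radius = 2)
  # single gamma bead: shell of 5^3 = 125 sites
  st <- new_system_state(12, matrix(c(5L, 5L, 5L), 1), 3L, 1L, 1L,
                         rbind(c(5, 5, 6), c(7, 7, 7), c(3, 3, 4),
                               c(5, 5, 9), c(0, 0, 0)),
                         c(1L, 1L, 1L, 1L, 2L))
  expect_equal(local_density(st, p, 1, "A"), 3 / 125)
  expect_equal(local_density(st, p, 1, "B"), 0 / 125)
  # two adjacent gamma beads: union shell of 125 + 25 = 150 sites
  st2 <- new_system_state(12, rbind(c(5, 5, 5), c(6, 5, 5)), c(3L, 3L),
                          c(1L, 1L), c(1L, 1L),
                          rbind(c(8, 5, 5), c(4, 4, 4)), c(1L, 1L))
  expect_equal(local_density(st2, p, 1, "A"), 2 / 150)
})

test_that("symmetry parameter has the normalised-difference arithmetic", {
  p <- model_params(n = 1, L = 16, c = 4 / 16^3, E_X = 2, shell_radius = 2)
  two_gammas <- function(mols, species) {
    new_system_state(16, rbind(c(3, 3, 3), c(12, 12, 12)), c(3L, 3L),
                     c(1L, 2L), c(1L, 2L), mols, species)
  }
  # equal densities -> S = 0
  st <- two_gammas(rbind(c(3, 3, 4), c(12, 12, 13)), c(1L, 1L))
  expect_equal(symmetry_parameter(st, p), 0)
  # all A on polymer 1 -> S = 1
  st <- two_gammas(rbind(c(3, 3, 4), c(3, 4, 3)), c(1L, 1L))
  expect_equal(symmetry_parameter(st, p), 1)
  # rho1 = 3 rho2 -> S = 0.5
  st <- two_gammas(rbind(c(3, 3, 4), c(3, 4, 3), c(2, 3, 3), c(12, 12, 13)),
                   rep(1L, 4))
  expect_equal(symmetry_parameter(st, p), 0.5)
  # no A molecules anywhere near -> S = 0 by convention
  st <- two_gammas(rbind(c(7, 7, 7), c(8, 8, 8)), c(1L, 1L))
  expect_equal(symmetry_parameter(st, p), 0)
  # antisymmetry under polymer relabelling
  st <- two_gammas(rbind(c(3, 3, 4), c(3, 4, 3), c(12, 12, 13)), rep(1L, 3))
  st_swap <- st
  st_swap$bead_poly <- c(2L, 1L)
  expect_equal(symmetry_parameter(st_swap, p), -symmetry_parameter(st, p))
})

test_that("largest cluster fractions match hand-built aggregates", {
  fx <- make_fixture("two-cluster")
  expect_equal(largest_cluster_fraction(fx$state, "A"), fx$expected$cluster_A)
  expect_equal(largest_cluster_fraction(fx$state, "B"), fx$expected$cluster_B)
  # one face-connected block -> 1
  st <- fx$state
  st$mol_coords <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1))
  st$mol_species <- rep(1L, 3)
  expect_equal(largest_cluster_fraction(st, "A"), 1)
  expect_error(largest_cluster_fraction(st, "B"), "no molecules")
})

test_that("R observables agree with the engine's recorded series", {
  p <- model_params(n = 2, L = 10, c = 0.04, E_X = 2.5, E_A = 2, E_B = 2,
                    sweeps = 300, record_every = 50)
  st <- init_state(p, "open", seed = 41)
  run <- run_mc(st, p, seed = 42, frame_every = 50)
  expect_equal(length(run$frames), nrow(run$series))
  for (i in seq_along(run$frames)) {
    fs <- run$frames[[i]]$state
    rep_i <- contact_report(fs, p)
    expect_equal(mean(rep_i$contact[rep_i$type == "alpha"]),
                 run$series$P_alpha[i])
    expect_equal(mean(rep_i$contact[rep_i$type == "beta"]),
                 run$series$P_beta[i])
    expect_equal(symmetry_parameter(fs, p), run$series$S[i])
    expect_equal(local_density(fs, p, 1, "A"), run$series$rho1[i])
    expect_equal(largest_cluster_fraction(fs, "A"), run$series$cluster_A[i])
    expect_equal(largest_cluster_fraction(fs, "B"), run$series$cluster_B[i])
    expect_equal(total_energy(fs, p)$total, run$series$energy[i])
  }
})
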