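test_that("polymer layout follows the canonical block architecture", {
  lay1 <- default_layout(1)
  expect_equal(nrow(lay1), 9)
  expect_equal(lay1$type, c("alpha", "inert", "alpha", "inert", "gamma",
                            "inert", "beta", "inert", "beta"))
  expect_equal(sum(lay1$length), 9)

  spec4 <- polymer_spec(4)
  expect_equal(spec4$n_beads, 36)
  expect_equal(sum(spec4$layout$length[spec4$layout$type == "alpha"]), 8)
  expect_equal(sum(spec4$layout$length[spec4$layout$type == "gamma"]), 4)

  expect_error(default_layout(0))
  expect_error(polymer_spec(layout = tibble::tibble(
    type = c("alpha", "gamma"), length = c(2L, 2L))),
    "two alpha")
})

test_that("open initial states have the right composition and no overlaps", {
  p <- model_params(n = 4, L = 16, c = 0.01)
  st <- init_state(p, "open", seed = 1)
  expect_equal(nrow(st$bead_coords), 72)
  expect_equal(n_molecules(p), 41)  # round(0.01 * 16^3) = round(40.96)
  expect_equal(sum(st$mol_species == 1), 41)
  expect_equal(sum(st$mol_species == 2), 41)
  expect_true(validate_state(st, p))
  # the two polymers start in separate octants
  h <- p$L %/% 2
  expect_true(all(st$bead_coords[st$bead_poly == 1, ] < h))
  expect_true(all(st$bead_coords[st$bead_poly == 2, ] >= h))
})

test_that("state construction is deterministic given the seed", {
  p <- model_params(n = 2, L = 12, c = 0.02)
  expect_identical(init_state(p, "open", seed = 7),
                   init_state(p, "open", seed = 7))
  expect_identical(init_state(p, "looped", seed = 7),
                   init_state(p, "looped", seed = 7))
  expect_false(identical(init_state(p, "open", seed = 7),
                         init_state(p, "open", seed = 8)))
})

test_that("over-dense configurations are rejected with a packing error", {
  expect_error(init_state(model_params(n = 1, L = 8, c = 0.5), "open"),
               "cannot pack")
})

test_that("looped states put every functional block in contact with gamma", {
  for (case in list(c(n = 1, L = 8), c(n = 2, L = 10), c(n = 4, L = 16),
                    c(n = 5, L = 16))) {
    p <- model_params(n = case["n"], L = case["L"], c = 0.02)
    st <- init_state(p, "looped", seed = 3)
    expect_true(validate_state(st, p))
    rep <- contact_report(st, p)
    expect_equal(nrow(rep), 8)
    expect_true(all(rep$contact),
                label = paste0("contacts for n=", case["n"], ", L=", case["L"]))
  }
  # too few molecules to seed the bridges
  expect_error(init_state(model_params(n = 4, L = 16, c = 0.0005), "looped"),
               "concentration too low")
})

test_that("periodic Manhattan distance is a metric on sampled triples", {
  set.seed(42)
  L <- 16
  a <- matrix(sample(0:(L - 1), 90, replace = TRUE), ncol = 3)
  b <- matrix(sample(0:(L - 1), 90, replace = TRUE), ncol = 3)
  cc <- matrix(sample(0:(L - 1), 90, replace = TRUE), ncol = 3)
  dab <- periodic_manhattan(a, b, L)
  expect_equal(dab, periodic_manhattan(b, a, L))        # symmetry
  expect_true(all(periodic_manhattan(a, a, L) == 0))    # identity
  expect_true(all(dab <= periodic_manhattan(a, cc, L) +
                    periodic_manhattan(cc, b, L)))      # triangle inequality
})

test_that("molecule counts and invariants are conserved through a run", {
  p <- model_params(n = 2, L = 10, c = 0.03, E_X = 2, E_A = 1, E_B = 1,
                    sweeps = 500, record_every = 100)
  st <- init_state(p, "open", seed = 5)
  run <- run_mc(st, p, seed = 6, validate_every = 100)
  fs <- run$final_state
  expect_true(validate_state(fs, p))
  expect_identical(fs$mol_species, st$mol_species)
  expect_identical(fs$bead_type, st$bead_type)
  expect_equal(nrow(fs$mol_coords), nrow(st$mol_coords))
})
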