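test_that("conformer filtering windows, caps and drops imaginary frequencies", {
  ens <- toy_ensemble("f", n = 2, energies = c(0, 1.0, 2.0))
  kept <- filter_conformers(ens, energy_window = 1.5)
  expect_equal(length(kept$conformers), 2L)

  big <- toy_ensemble("big", n = 2, energies = seq(0, 1.2, length.out = 120))
  capped <- filter_conformers(big, energy_window = 1.5, max_conformers = 100)
  expect_equal(length(capped$conformers), 100L)
  expect_equal(capped$conformers[[1]]$rel_energy, 0)

  ens2 <- toy_ensemble("im", n = 2, energies = c(0, 0.2))
  ens2$conformers[[1]]$has_imaginary_freq <- TRUE
  kept2 <- filter_conformers(ens2)
  expect_equal(length(kept2$conformers), 1L)
  expect_equal(kept2$conformers[[1]]$rel_energy, 0)  # re-referenced

  expect_error(filter_conformers(toy_ensemble("e", 2, energies = c(0, 5)),
                                 energy_window = -1), "survive")
})

test_that("Boltzmann weights normalize, shift-invariantly and monotonically", {
  expect_equal(boltzmann_weights(c(0, 0), T = 500), c(0.5, 0.5))
  expect_equal(boltzmann_weights(0), 1)
  w <- boltzmann_weights(c(0, 1.0), T = 298.15)
  expect_equal(w, c(0.8440, 0.1560), tolerance = 1e-3)
  set.seed(4)
  for (r in 1:20) {
    e <- stats::runif(5, 0, 4)
    w <- boltzmann_weights(e, T = 310)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, boltzmann_weights(e + 7.3, T = 310), tolerance = 1e-12)
    expect_true(all(diff(w[order(e)]) <= 1e-15))
  }
  expect_error(boltzmann_weights(numeric(0)), "empty")
})

test_that("ECMC construction: diagonal property, distances, bonds, C-H mask", {
  one <- toy_ensemble("one", n = 1, charges = -0.136)
  em <- build_ecmc(one, "c01")
  expect_equal(em$matrix, matrix(-0.136, 1, 1))

  tri <- toy_ensemble("tri", n = 2, coords = rbind(c(0, 0, 0), c(3, 4, 0)),
                      charges = c(0.1, -0.2))
  em2 <- build_ecmc(tri, "c01")
  expect_equal(em2$matrix[1, 2], 5.0)
  expect_equal(diag(em2$matrix), c(0.1, -0.2))

  ch <- toy_ensemble("ch", n = 3, elements = c("C", "H", "N"),
                     bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                        order = c(1.0, 1.0)))
  em3 <- build_ecmc(ch, "c01")
  expect_true(em3$mask[1, 2] && em3$mask[2, 1])   # C-H bond masked
  expect_false(em3$mask[2, 3])                    # N-H bond kept
  expect_equal(em3$matrix[2, 3], 1.0)             # bond order, not distance
  expect_equal(max(abs(em3$matrix - t(em3$matrix))), 0)
})

test_that("ECMC distances are invariant under rigid motions", {
  set.seed(11)
  for (r in 1:10) {
    X <- matrix(stats::rnorm(15), 5, 3)
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    shift <- stats::rnorm(3)
    e1 <- build_ecmc(toy_ensemble("a", 5, coords = X), "c01")
    e2 <- build_ecmc(toy_ensemble("a", 5,
                                  coords = X %*% Q + matrix(shift, 5, 3, byrow = TRUE)),
                     "c01")
    off <- upper.tri(e1$matrix)
    expect_equal(e1$matrix[off], e2$matrix[off], tolerance = 1e-10)
  }
})

test_that("submatrix matching: self-match, inclusive boundary, failures", {
  ref <- load_fixture("table2a")
  tol <- load_fixture("table2b")
  cand <- raw_ecmc(ref, elements = substr(rownames(ref), 1, 1))
  m <- match_submatrix(ref, tol, cand,
                       ref_elements = substr(rownames(ref), 1, 1))
  expect_true(m$matched)
  expect_equal(max(m$max_abs_deviation, na.rm = TRUE), 0)

  # exactly +tolerance on one element still matches (inclusive)
  pert <- ref; pert[1, 2] <- pert[1, 2] + tol[1, 2]
  pert[2, 1] <- pert[1, 2]
  m2 <- match_submatrix(ref, tol, raw_ecmc(pert, substr(rownames(ref), 1, 1)),
                        ref_elements = substr(rownames(ref), 1, 1))
  expect_true(m2$matched)

  # 2x tolerance fails and the element is reported
  pert2 <- ref; pert2[1, 2] <- pert2[1, 2] + 2 * tol[1, 2]
  pert2[2, 1] <- pert2[1, 2]
  m3 <- match_submatrix(ref, tol, raw_ecmc(pert2, substr(rownames(ref), 1, 1)),
                        ref_elements = substr(rownames(ref), 1, 1))
  expect_false(m3$matched)
  expect_false(is.null(m3$failing_elements))

  expect_error(match_submatrix(ref, tol[1:3, 1:3], cand), "shape")
})

test_that("zero tolerances only admit exact copies; enlarging never breaks a match", {
  set.seed(21)
  for (r in 1:25) {
    inst <- random_match_instance(n_cand = 6, k = 3)
    zero <- matrix(0, 3, 3)
    exact <- raw_ecmc(inst$candidate$matrix, inst$candidate$elements)
    sub <- match_submatrix(inst$candidate$matrix[1:3, 1:3], zero, exact,
                           ref_elements = inst$candidate$elements[1:3])
    expect_true(sub$matched)
    m1 <- match_submatrix(inst$reference, inst$tolerances, inst$candidate,
                          ref_elements = inst$ref_elements)
    m2 <- match_submatrix(inst$reference, inst$tolerances + 0.5, inst$candidate,
                          ref_elements = inst$ref_elements)
    if (m1$matched) expect_true(m2$matched)
  }
})

test_that("backtracking matcher agrees with the exhaustive oracle", {
  set.seed(77)
  for (r in 1:60) {
    inst <- random_match_instance(n_cand = sample(4:7, 1), k = sample(2:4, 1))
    a <- match_submatrix(inst$reference, inst$tolerances, inst$candidate,
                         ref_elements = inst$ref_elements)
    b <- brute_force_match(inst$reference, inst$tolerances, inst$candidate,
                           ref_elements = inst$ref_elements)
    expect_identical(a$matched, b$matched)
    if (a$matched) expect_identical(a$assignment, b$assignment)
  }
  expect_error(brute_force_match(matrix(0, 2, 2), matrix(0, 2, 2),
                                 raw_ecmc(diag(11))), "guard")
})

test_that("atom-map mapping fixes the assignment by skeleton label", {
  g <- gen_pharmacophore_set(synthetic_spec(seed = 6, pharmacophore_size = 3,
                                            n_active = 3, n_inactive = 3))
  ph <- g$pharmacophore
  id <- names(g$ensembles)[2]          # another active
  em <- build_ecmc(g$ensembles[[id]],
                   ecga4d:::lowest_energy_conformer(g$ensembles[[id]]))
  m <- match_submatrix(ph$reference_values, ph$tolerances, em,
                       ref_elements = ph$elements, ref_labels = ph$atom_labels,
                       mapping = g$atom_map)
  expect_true(m$matched)
  expect_equal(unname(m$assignment), ph$positions[[id]])
})
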