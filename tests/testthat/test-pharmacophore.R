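test_that("quality statistics reproduce the contingency formulas", {
  qs <- function(h1, h2, h3, h4) {
    pres <- c(rep(TRUE, h1), rep(FALSE, h2), rep(TRUE, h3), rep(FALSE, h4))
    cls <- c(rep("high", h1 + h2), rep("low", h3 + h4))
    names(pres) <- names(cls) <- sprintf("m%02d", seq_along(pres))
    quality_stats(pres, cls)
  }
  a <- qs(28, 0, 0, 26)
  expect_equal(a$P_a, 29 / 30)
  expect_equal(a$alpha_a, 1.0)
  b <- qs(25, 3, 5, 21)
  expect_equal(b$P_a, 26 / 30)
  expect_equal(b$alpha_a, 510 / sqrt(28 * 26 * 30 * 24), tolerance = 1e-12)
  expect_equal(b$alpha_a, 0.704, tolerance = 1e-3)
  # h1 h4 = h2 h3 gives independence
  expect_equal(qs(6, 3, 4, 2)$alpha_a, 0)
  # degenerate marginals error
  expect_error(qs(5, 0, 5, 0), "degenerate")
})

test_that("alpha_a is a bounded association and P_a is monotone", {
  set.seed(31)
  for (r in 1:100) {
    h <- stats::rpois(4, 5) + 1
    pres <- c(rep(TRUE, h[1]), rep(FALSE, h[2]), rep(TRUE, h[3]), rep(FALSE, h[4]))
    cls <- c(rep("high", h[1] + h[2]), rep("low", h[3] + h[4]))
    names(pres) <- names(cls) <- sprintf("m%03d", seq_along(pres))
    st <- quality_stats(pres, cls)
    expect_true(st$alpha_a >= -1 - 1e-12 && st$alpha_a <= 1 + 1e-12)
  }
  pa <- function(h1, h2) (h1 + 1) / (h1 + h2 + 2)
  expect_true(all(diff(sapply(1:10, pa, h2 = 3)) > 0))
  expect_true(all(diff(sapply(1:10, function(h2) pa(4, h2))) < 0))
})

test_that("planted pharmacophores are recovered exactly with alpha_a = 1", {
  for (k in c(3, 4)) {
    sp <- synthetic_spec(seed = 100 + k, pharmacophore_size = k,
                         n_active = 5, n_inactive = max(5, k))
    g <- gen_pharmacophore_set(sp)
    e <- find_ecsa(g$ensembles, g$activities,
                   g$pharmacophore$reference_compound,
                   init_tol = list(diag = g$pharmacophore$tol_diag,
                                   offdiag = g$pharmacophore$tol_offdiag),
                   size_range = c(3, 6))
    expect_setequal(e$atom_labels, g$pharmacophore$atom_labels)
    expect_equal(attr(e, "stats")$alpha_a, 1.0)
  }
})

test_that("an undifferentiated series yields no discriminating submatrix", {
  ens <- toy_ensemble("same1", n = 4, charges = c(0.1, -0.2, 0.3, 0.0))
  ens2 <- ens; ens2$compound_id <- "same2"
  acts <- activity_table(data.frame(compound_id = c("same1", "same2"),
                                    pic50 = c(9, 5)))
  expect_error(
    find_ecsa(list(same1 = ens, same2 = ens2), acts, "same1",
              size_range = c(2, 4)),
    "no discriminating")
})

test_that("the printed six-atom reference pattern is recovered from a planted series", {
  sc <- table2_scenario()
  e <- find_ecsa(sc$ensembles, sc$activities, "act01",
                 init_tol = list(diag = 0.25, offdiag = 1.30),
                 size_range = c(3, 6))
  expect_setequal(e$atom_labels, c("C1", "C7", "C9", "N1", "H9", "N2"))
  expect_equal(attr(e, "stats")$alpha_a, 1.0)
  # the recovered values are the printed ones (entries the mask keeps)
  ref <- load_fixture("table2a")
  keep <- !e$ref_mask
  ord <- match(rownames(ref), e$atom_labels)
  expect_equal(e$reference_values[ord, ord][keep[ord, ord]],
               ref[keep[ord, ord]])
})

test_that("screening flags conformers and compound presence is an OR", {
  g <- gen_pharmacophore_set(synthetic_spec(seed = 8, pharmacophore_size = 3,
                                            n_active = 4, n_inactive = 4))
  ph <- g$pharmacophore
  e <- ecsa(ph$reference_compound, "c01", 1:3, ph$atom_labels, ph$elements,
            ph$reference_values, ph$tolerances)
  mt <- screen(e, g$ensembles)
  pres <- compound_presence(mt)
  expect_true(all(pres[grep("^act", names(pres))] == 1))
  expect_true(all(pres[grep("^inact", names(pres))] == 0))
  # reference compound matches under its own tolerances
  expect_true(all(mt$delta[mt$compound_id == ph$reference_compound] == 1))

  # a two-conformer compound with one matching conformer is present
  sub <- mt[mt$compound_id == names(g$ensembles)[1], ]
  fake <- rbind(sub[1, ], transform(sub[2, ], delta = 0))
  class(fake) <- c("match_table", "data.frame")
  expect_equal(unname(compound_presence(fake)), 1)
})

test_that("derived tolerances are attained maxima and self-consistent", {
  g <- gen_pharmacophore_set(synthetic_spec(seed = 12, pharmacophore_size = 3,
                                            n_active = 6, n_inactive = 3,
                                            n_conformers = 4))
  ph <- g$pharmacophore
  e <- ecsa(ph$reference_compound, "c01", 1:3, ph$atom_labels, ph$elements,
            ph$reference_values, ph$tolerances)
  ref_conf <- ecga4d:::lowest_energy_conformer(g$ensembles[[ph$reference_compound]])
  self <- data.frame(compound_id = ph$reference_compound,
                     conformer_id = ref_conf)
  expect_equal(max(derive_tolerances(e, g$ensembles, self), na.rm = TRUE), 0)

  # growing the subset never shrinks a tolerance entry, and re-screening the
  # derivation subset with the derived tolerances matches everything
  act_ids <- grep("^act", names(g$ensembles), value = TRUE)
  mt <- screen(e, g$ensembles[act_ids])
  subsets <- lapply(seq_len(nrow(mt)), function(i) mt[seq_len(i), 1:2])
  prev <- NULL
  for (s in subsets) {
    tol <- derive_tolerances(e, g$ensembles, s)
    if (!is.null(prev)) expect_true(all(tol >= prev - 1e-12, na.rm = TRUE))
    prev <- tol
  }
  e2 <- e; e2$tolerances[!is.na(prev)] <- prev[!is.na(prev)]
  mt2 <- screen(e2, g$ensembles[act_ids])
  expect_true(all(mt2$delta == 1))

  # an unmatched conformer in the subset errors
  bad <- data.frame(compound_id = grep("^inact", names(g$ensembles), value = TRUE)[1],
                    conformer_id = "c01")
  expect_error(derive_tolerances(e, g$ensembles, bad), "does not match")
})
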