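# Shared in-code fixtures for the test suite. Everything is built
# programmatically; no binary data.

# minimal ensemble: n atoms on a line, one conformer, unit charges
toy_ensemble <- function(id = "toy", n = 3, energies = 0,
                         charges = NULL, coords = NULL, bonds = NULL,
                         elements = rep("C", n)) {
  atoms <- data.frame(index = seq_len(n), element = elements,
                      stringsAsFactors = FALSE)
  if (is.null(coords)) coords <- cbind(seq_len(n), 0, 0)
  if (is.null(charges)) charges <- rep(0.1, n)
  conformers <- lapply(seq_along(energies), function(k) {
    list(conformer_id = sprintf("c%02d", k), rel_energy = energies[k],
         has_imaginary_freq = FALSE, coords = coords,
         atomic_charge = charges)
  })
  conformer_ensemble(id, atoms, bonds, conformers)
}

# hand-built ECMC (bypasses geometry) for matcher-level tests
raw_ecmc <- function(M, elements = rep("C", nrow(M)), mask = NULL,
                     id = "raw", conformer = "c01") {
  M <- as.matrix(M)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(M), ncol(M))
  structure(list(compound_id = id, conformer_id = conformer,
                 atom_indices = seq_len(nrow(M)), elements = elements,
                 labels = rep(NA_character_, nrow(M)),
                 matrix = M, mask = mask),
            class = "ecmc")
}

# random symmetric "contiguity-like" matrix instance for the matcher oracle
# suite: diagonal charge-like, off-diagonal distance-like
random_match_instance <- function(n_cand = 5, k = 3, elements = c("C", "N", "O")) {
  el <- sample(elements, n_cand, replace = TRUE)
  M <- matrix(stats::runif(n_cand^2, 1, 6), n_cand)
  M <- (M + t(M)) / 2
  diag(M) <- stats::runif(n_cand, -0.5, 0.5)
  cand <- raw_ecmc(M, elements = el)
  pick <- sample(n_cand, k)
  R <- M[pick, pick, drop = FALSE] +
    matrix(stats::rnorm(k^2, 0, 0.15), k) * 0.5
  R <- (R + t(R)) / 2
  tol <- matrix(stats::runif(k^2, 0, 0.4), k)
  tol <- (tol + t(tol)) / 2
  list(candidate = cand, reference = R, tolerances = tol,
       ref_elements = el[pick])
}

# compound series carrying the printed 6-atom reference pattern verbatim:
# the six pattern atoms are declared mutually bonded with the printed values
# so the ECMC holds them exactly; decoy atoms live in a distant shell.
table2_scenario <- function(n_active = 6, n_inactive = 6, seed = 42) {
  set.seed(seed)
  ref <- load_fixture("table2a")
  labels <- rownames(ref)
  elements <- substr(labels, 1, 1)
  k <- 6
  make <- function(id, violate_atom = NA) {
    n_dec <- 2
    n <- k + n_dec
    atoms <- data.frame(index = seq_len(n),
                        element = c(elements, rep("C", n_dec)),
                        skeleton_label = c(labels, rep(NA, n_dec)),
                        stringsAsFactors = FALSE)
    pairs <- t(utils::combn(k, 2))
    bonds <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        order = ref[pairs])
    charges <- c(diag(ref), stats::runif(n_dec, 0.6, 1.5))
    if (!is.na(violate_atom)) {
      charges[violate_atom] <- charges[violate_atom] + 0.5
    }
    coords <- rbind(matrix(stats::runif(k * 3, 0, 5), k),
                    matrix(stats::runif(n_dec * 3, 30, 60), n_dec))
    conformer_ensemble(id, atoms, bonds, list(
      list(conformer_id = "c01", rel_energy = 0, has_imaginary_freq = FALSE,
           coords = coords, atomic_charge = charges)))
  }
  ensembles <- list()
  for (i in seq_len(n_active)) ensembles[[sprintf("act%02d", i)]] <- make(sprintf("act%02d", i))
  for (i in seq_len(n_inactive)) {
    id <- sprintf("inact%02d", i)
    ensembles[[id]] <- make(id, violate_atom = ((i - 1L) %% k) + 1L)
  }
  activities <- activity_table(data.frame(
    compound_id = names(ensembles),
    pic50 = c(9.301, stats::runif(n_active - 1, 8, 9.2),
              stats::runif(n_inactive, 5, 7))))
  list(ensembles = ensembles, activities = activities, labels = labels)
}
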