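# Seeded synthetic-data generators for every input the pipeline consumes:
# conformer ensembles with a planted pharmacophore submatrix, forward-model
# activity data with known shielding coefficients, and nonlinear feature
# tables for the ML stack. Each generator is a pure function of its spec:
# the same spec yields identical output.

#' Specification for the synthetic generators
#'
#' @param seed integer seed (required).
#' @param n_active,n_inactive compound counts per class.
#' @param pharmacophore_size number of planted pharmacophore atoms (k).
#' @param tolerance_scale fraction of the screening tolerance used for the
#'   within-class perturbations; values `<= 0.5` guarantee that any two
#'   active instances agree within one full tolerance.
#' @param n_conformers conformers per compound.
#' @param energy_scale mean of the exponential relative-energy distribution
#'   (kcal/mol).
#' @param tol_diag,tol_offdiag planted screening tolerances for diagonal
#'   (charge, e) and off-diagonal (distance, Angstrom) elements.
#' @param atom_range compound sizes, atoms (default 8-14).
#' @param kappa_true true shielding coefficients (default
#'   `c(0.8, -0.6, 0.4, -0.3)` recycled over `signal_indices`).
#' @param noise_sd Gaussian noise added to forward-model activities
#'   (pIC50 units).
#' @param p_descriptors number of descriptor columns.
#' @param signal_indices descriptor columns carrying true signal.
#' @param zero_delta_compounds number of compounds generated with no
#'   matching conformer (activity 0 + noise).
#' @param n_obs rows for the ML feature table.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_active = 8, n_inactive = 8,
                           pharmacophore_size = 4, tolerance_scale = 0.5,
                           n_conformers = 3, energy_scale = 0.5,
                           tol_diag = 0.1, tol_offdiag = 0.5,
                           atom_range = c(8, 14), kappa_true = NULL,
                           noise_sd = 0, p_descriptors = 8,
                           signal_indices = 1:4, zero_delta_compounds = 0,
                           n_obs = 200) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_active >= 1, n_inactive >= 1, pharmacophore_size >= 2,
            n_conformers >= 1, noise_sd >= 0, p_descriptors >= 1,
            all(signal_indices >= 1), all(signal_indices <= p_descriptors))
  if (is.null(kappa_true)) {
    kappa_true <- rep(c(0.8, -0.6, 0.4, -0.3),
                      length.out = length(signal_indices))
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

# random proper rotation matrix
rand_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a compound series with a planted pharmacophore submatrix
#'
#' Builds `n_active + n_inactive` compounds of 8-14 atoms. A k-atom
#' reference pattern (distinct charges in \[-0.4, 0.4\] e, pairwise
#' distances in \[1.2, 6\] Angstrom) is embedded in every conformer of every
#' active compound, rigidly rotated/translated and perturbed within
#' `tolerance_scale` times the screening tolerances. Every inactive
#' compound carries the same atoms but one planted atom's charge is shifted
#' at least 3 tolerances away; the violated atom cycles over the k planted
#' positions so no proper subset of the pattern separates the classes.
#' Decoy atoms are electronically distinct (charges in \[0.6, 1.5\] e) and
#' carry the compound's bonds, including C-H bonds that exercise masking.
#' The generator verifies separability by screening (all actives match, no
#' inactive does, under the planted tolerances) and regenerates an inactive
#' up to 60 times before failing.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ensembles` (named list), `activities`
#'   ([activity_table()]), `atom_map` ([atom_map()] of the planted atoms),
#'   and `pharmacophore` (labels, elements, the reference instance values,
#'   the true values, the tolerance matrix, reference compound id).
#' @export
gen_pharmacophore_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  k <- spec$pharmacophore_size
  ts <- spec$tolerance_scale

  # reference geometry: k points with pairwise distances in [1.2, 6]
  for (try in 1:200) {
    P <- matrix(stats::runif(3 * k, 0, 4.2), k, 3)
    d <- stats::dist(P)
    if (all(d >= 1.2 & d <= 6)) break
    if (try == 200) stop("infeasible geometry for the reference pattern")
  }
  ph_elements <- sample(c("C", "N", "O"), k, replace = TRUE)
  ph_charges <- stats::runif(k, -0.4, 0.4)
  ph_labels <- paste0(ph_elements, seq_len(k))

  jitter_coords <- function(X, max_norm) {
    dirs <- matrix(stats::rnorm(nrow(X) * 3), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    X + dirs * stats::runif(nrow(X), 0, max_norm)
  }

  make_compound <- function(id, violate_atom = NA) {
    n_atoms <- sample(spec$atom_range[1]:spec$atom_range[2], 1)
    n_dec <- n_atoms - k
    pos <- sort(sample(n_atoms, k))
    decoy_pos <- setdiff(seq_len(n_atoms), pos)
    elements <- character(n_atoms)
    elements[pos] <- ph_elements
    elements[decoy_pos] <- sample(c("C", "H"), n_dec, replace = TRUE)
    labels <- rep(NA_character_, n_atoms)
    labels[pos] <- ph_labels
    atoms <- data.frame(index = seq_len(n_atoms), element = elements,
                        skeleton_label = labels, stringsAsFactors = FALSE)
    bonds <- if (n_dec >= 2) {
      data.frame(i = decoy_pos[-n_dec], j = decoy_pos[-1],
                 order = 1.0)
    } else NULL
    if (!is.null(bonds)) {
      swap <- bonds$i > bonds$j
      tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    }
    conformers <- lapply(seq_len(spec$n_conformers), function(cix) {
      Qr <- rand_rotation()
      shift <- stats::runif(3, 0, 2)
      planted <- jitter_coords(P %*% t(Qr) +
                                 matrix(shift, k, 3, byrow = TRUE),
                               ts * spec$tol_offdiag / 2)
      coords <- matrix(stats::runif(n_atoms * 3, 0, 10), n_atoms, 3)
      coords[pos, ] <- planted
      charge <- numeric(n_atoms)
      charge[pos] <- ph_charges + stats::runif(k, -1, 1) * ts * spec$tol_diag
      charge[decoy_pos] <- stats::runif(n_dec, 0.6, 1.5)
      if (!is.na(violate_atom)) {
        charge[pos[violate_atom]] <- ph_charges[violate_atom] +
          sample(c(-1, 1), 1) * 3.5 * spec$tol_diag
      }
      list(conformer_id = sprintf("c%02d", cix),
           rel_energy = stats::rexp(1, 1 / spec$energy_scale),
           has_imaginary_freq = FALSE, coords = coords,
           atomic_charge = charge)
    })
    list(ens = conformer_ensemble(id, atoms, bonds, conformers), pos = pos)
  }

  ensembles <- list()
  positions <- list()
  for (i in seq_len(spec$n_active)) {
    id <- sprintf("act%02d", i)
    cp <- make_compound(id)
    ensembles[[id]] <- cp$ens
    positions[[id]] <- cp$pos
  }
  ref_id <- names(ensembles)[1]
  ref_pos <- positions[[ref_id]]
  ref_ecmc <- build_ecmc(ensembles[[ref_id]],
                         lowest_energy_conformer(ensembles[[ref_id]]))
  ref_vals <- ref_ecmc$matrix[ref_pos, ref_pos, drop = FALSE]
  ref_mask <- ref_ecmc$mask[ref_pos, ref_pos, drop = FALSE]
  Tm <- uniform_tolerance(k, spec$tol_diag, spec$tol_offdiag)

  matches_anywhere <- function(ens) {
    any(vapply(conformer_ids(ens), function(cid) {
      match_submatrix(ref_vals, Tm, build_ecmc(ens, cid),
                      ref_elements = ph_elements, ref_mask = ref_mask)$matched
    }, TRUE))
  }

  for (i in seq_along(ensembles)) {   # every active conformer must match
    ens <- ensembles[[i]]
    ok <- all(vapply(conformer_ids(ens), function(cid) {
      match_submatrix(ref_vals, Tm, build_ecmc(ens, cid),
                      ref_elements = ph_elements, ref_mask = ref_mask)$matched
    }, TRUE))
    if (!ok) stop("internal error: active compound fails the planted pattern")
  }

  for (i in seq_len(spec$n_inactive)) {
    id <- sprintf("inact%02d", i)
    va <- ((i - 1L) %% k) + 1L
    for (attempt in 1:60) {
      cp <- make_compound(id, violate_atom = va)
      if (!matches_anywhere(cp$ens)) break
      if (attempt == 60) stop("infeasible geometry: inactive keeps matching")
    }
    ensembles[[id]] <- cp$ens
    positions[[id]] <- cp$pos
  }

  pic50 <- c(9.301, stats::runif(spec$n_active - 1, 7.7, 9.2),
             stats::runif(spec$n_inactive, 5.0, 7.5))
  adf <- data.frame(compound_id = names(ensembles), pic50 = pic50,
                    stringsAsFactors = FALSE)
  activities <- activity_table(adf, threshold = 7.61)

  amap <- do.call(rbind, lapply(names(ensembles), function(id) {
    data.frame(compound_id = id, local_atom_index = positions[[id]],
               skeleton_label = ph_labels, stringsAsFactors = FALSE)
  }))

  true_vals <- as.matrix(stats::dist(P))
  diag(true_vals) <- ph_charges
  list(ensembles = ensembles, activities = activities,
       atom_map = atom_map(amap),
       pharmacophore = list(atom_labels = ph_labels, elements = ph_elements,
                            reference_compound = ref_id,
                            positions = positions,
                            reference_values = ref_vals,
                            true_values = true_vals,
                            tolerances = Tm,
                            tol_diag = spec$tol_diag,
                            tol_offdiag = spec$tol_offdiag))
}

#' Generate forward-model activity data with known shielding coefficients
#'
#' Per-conformer descriptors are standard normal; activities follow the
#' Boltzmann-weighted activity formula with `kappa_true` on the signal
#' columns, plus Gaussian noise. The true parameters are returned so
#' recovery can be tested against the generator.
#'
#' @param spec a [synthetic_spec()] (`n_active + n_inactive` compounds are
#'   produced; the class split is irrelevant here).
#' @return list with `data` (an `ecga_data` ready for fitting), `panel`,
#'   `match_table`, `activities`, `ensembles`, `kappa_true` (named by the
#'   signal columns), `signal_indices` and `A0`.
#' @export
gen_activity_data <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_active + spec$n_inactive
  m <- spec$n_conformers
  p <- spec$p_descriptors
  A0 <- 9.3
  ids <- sprintf("cmp%03d", seq_len(n))
  dnames <- sprintf("d%03d", seq_len(p))
  kappa <- spec$kappa_true

  panel_rows <- list(); mt_rows <- list(); ens <- list(); pic <- numeric(n)
  for (i in seq_len(n)) {
    E <- stats::rexp(m, 1 / spec$energy_scale)
    E <- E - min(E)
    delta <- if (i <= spec$zero_delta_compounds) rep(0, m) else rep(1, m)
    A <- matrix(stats::rnorm(m * p), m, p, dimnames = list(NULL, dnames))
    S <- as.numeric(A[, spec$signal_indices, drop = FALSE] %*% kappa)
    An <- predict_one(delta, E, S, A0)
    pic[i] <- An + stats::rnorm(1, 0, spec$noise_sd)
    cids <- sprintf("c%02d", seq_len(m))
    panel_rows[[i]] <- data.frame(compound_id = ids[i], conformer_id = cids,
                                  A, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    mt_rows[[i]] <- data.frame(compound_id = ids[i], conformer_id = cids,
                               delta = delta, stringsAsFactors = FALSE)
    atoms <- data.frame(index = 1L, element = "C",
                        skeleton_label = NA_character_)
    ens[[ids[i]]] <- conformer_ensemble(ids[i], atoms, NULL,
      lapply(seq_len(m), function(cix) {
        list(conformer_id = cids[cix], rel_energy = E[cix],
             has_imaginary_freq = FALSE,
             coords = matrix(0, 1, 3), atomic_charge = 0)
      }))
  }
  panel <- descriptor_panel(do.call(rbind, panel_rows))
  mt <- do.call(rbind, mt_rows)
  class(mt) <- c("match_table", "data.frame")
  activities <- activity_table(
    data.frame(compound_id = ids, pic50 = pic, stringsAsFactors = FALSE))
  data <- assemble_model_data(panel, mt, activities, ens)
  list(data = data, panel = panel, match_table = mt, activities = activities,
       ensembles = ens,
       kappa_true = stats::setNames(kappa, dnames[spec$signal_indices]),
       signal_indices = spec$signal_indices, A0 = A0)
}

#' Generate a nonlinear regression table for the ML stack
#'
#' `X` is standard normal; `y` combines a smooth term, a (deliberately
#' modest) interaction and a step over the signal columns, plus Gaussian
#' noise: `y = 2 sin(x_s1) + 0.5 x_s2 x_s3 + 1.5 [x_s4 > 0] + noise`.
#'
#' @param spec a [synthetic_spec()] (`n_obs`, `p_descriptors`,
#'   `signal_indices`, `noise_sd`).
#' @return list with matrix `X` (named columns) and numeric `y`.
#' @export
gen_ml_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  n <- spec$n_obs; p <- spec$p_descriptors
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("x%03d", seq_len(p))))
  s <- spec$signal_indices[((0:3) %% length(spec$signal_indices)) + 1L]
  y <- 2 * sin(X[, s[1]]) + 0.5 * X[, s[2]] * X[, s[3]] +
    1.5 * (X[, s[4]] > 0) + stats::rnorm(n, 0, spec$noise_sd)
  list(X = X, y = y)
}

## ---- packaged fixtures -----------------------------------------------------

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ecga4d")
  if (!nzchar(p)) stop(sprintf("fixture file '%s' not found", file))
  p
}

read_fixture_matrix <- function(file) {
  df <- utils::read.csv(fixture_path(file), row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Load a packaged reference fixture
#'
#' The package ships small verbatim transcriptions of the reference
#' compound series: the 54-compound activity table with its printed class
#' labels, the 6-atom pharmacophore submatrix (reference values and the
#' high / low / all-conformer tolerance matrices over atoms C1, C7, C9, N1,
#' H9, N2), the 12 selected molecular parameters with their shielding
#' coefficients, and the per-parameter E statistics.
#'
#' @param name one of `"table1"`, `"table2a"`, `"table2b"`, `"table2c"`,
#'   `"table2d"`, `"table3"`, `"table4_E"`.
#' @return `table1`: an [activity_table()] (verbatim labels, attribute
#'   `"A_calc"` holds the printed model predictions); `table2a`: symmetric
#'   6 x 6 reference-value matrix; `table2b/c/d`: 6 x 6 tolerance matrices;
#'   `table3` / `table4_E`: data.frames.
#' @export
load_fixture <- function(name = c("table1", "table2a", "table2b", "table2c",
                                  "table2d", "table3", "table4_E")) {
  name <- match.arg(name)
  if (name == "table1") {
    df <- utils::read.csv(fixture_path("table1_activities.csv"),
                          stringsAsFactors = FALSE)
    at <- activity_table(df[, c("compound_id", "pic50", "activity_class")],
                         threshold = 7.61, label_mode = "verbatim")
    attr(at, "A_calc") <- stats::setNames(df$pic50_calc, df$compound_id)
    return(at)
  }
  if (name %in% c("table2a", "table2b", "table2c", "table2d")) {
    return(read_fixture_matrix(sprintf("%s.csv", name)))
  }
  file <- if (name == "table3") "table3_kappa.csv" else "table4_E.csv"
  utils::read.csv(fixture_path(file), stringsAsFactors = FALSE)
}
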