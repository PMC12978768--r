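# Electron-conformational matrices of contiguity (ECMC): construction from a
# conformer's geometry and electronic properties, Boltzmann populations,
# conformer filtering, and tolerance-bounded submatrix matching with a
# brute-force oracle for small instances.

# gas constant in kcal mol^-1 K^-1
R_GAS <- 1.9872e-3

#' Filter a conformer ensemble by energy window and frequency flags
#'
#' Conformers with imaginary frequencies are removed first (they mark
#' incomplete optimizations), energies are re-referenced, conformers above
#' the energy window are dropped, and if more than `max_conformers` remain
#' only the lowest-energy ones are kept. Energies are re-referenced again at
#' the end so the retained minimum is 0.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param energy_window kcal/mol (default 1.5).
#' @param max_conformers cap on the retained count (default 100).
#' @param drop_imaginary drop conformers flagged with imaginary frequencies
#'   (default TRUE).
#' @return filtered [conformer_ensemble()].
#' @export
filter_conformers <- function(ensemble, energy_window = 1.5,
                              max_conformers = 100, drop_imaginary = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  cfs <- ensemble$conformers
  if (drop_imaginary) {
    cfs <- Filter(function(cf) !isTRUE(cf$has_imaginary_freq), cfs)
  }
  if (length(cfs) == 0L) stop("no conformers survive filtering")
  e <- vapply(cfs, `[[`, 0, "rel_energy")
  e <- e - min(e)
  keep <- which(e <= energy_window)
  if (length(keep) == 0L) stop("no conformers survive filtering")
  if (length(keep) > max_conformers) {
    keep <- keep[order(e[keep])][seq_len(max_conformers)]
    keep <- sort(keep)
  }
  cfs <- cfs[keep]
  e <- e[keep]
  for (k in seq_along(cfs)) cfs[[k]]$rel_energy <- e[k] - min(e)
  ensemble$conformers <- cfs
  ensemble
}

#' Boltzmann population weights
#'
#' `w_i = exp(-E_i / RT) / sum_j exp(-E_j / RT)` with the gas constant
#' R = 1.9872e-3 kcal mol^-1 K^-1. Invariant under a common energy shift.
#'
#' @param rel_energies numeric vector, kcal/mol.
#' @param T temperature in Kelvin (default 298.15).
#' @return numeric weights summing to 1.
#' @export
boltzmann_weights <- function(rel_energies, T = 298.15) {
  if (length(rel_energies) == 0L) stop("empty energy vector")
  if (any(!is.finite(rel_energies))) stop("energies must be finite")
  if (!is.finite(T) || T <= 0) stop("T must be positive")
  u <- exp(-(rel_energies - min(rel_energies)) / (R_GAS * T))
  u / sum(u)
}

#' Build the electron-conformational matrix of contiguity of one conformer
#'
#' The n x n symmetric matrix has the chosen atomic electronic property on
#' the diagonal (default: partial atomic charge), the chosen bond descriptor
#' (default: bond order) on bonded off-diagonal entries, and the interatomic
#' Euclidean distance in Angstrom on nonbonded entries. Bonded
#' carbon-hydrogen entries are masked from later comparisons when `mask_ch`
#' is set, since they contribute equally in every compound.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param conformer_id which conformer to use.
#' @param diag_property name of the per-atom property: `"charge"` (the
#'   conformer's `atomic_charge`) or any name in `atomic_props`.
#' @param bonded_property bond table column for bonded entries (`"order"`,
#'   `"wiberg"`, `"bond_energy"`, `"bond_polarizability"`).
#' @param mask_ch mask bonded C-H entries (default TRUE).
#' @return object of class `ecmc` with fields `matrix`, `mask`,
#'   `atom_indices`, `elements`, `labels`.
#' @export
build_ecmc <- function(ensemble, conformer_id, diag_property = "charge",
                       bonded_property = "order", mask_ch = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  ids <- conformer_ids(ensemble)
  k <- match(conformer_id, ids)
  if (is.na(k)) stop(sprintf("conformer '%s' not found in %s", conformer_id,
                             ensemble$compound_id))
  cf <- ensemble$conformers[[k]]
  n <- nrow(ensemble$atoms)

  diag_vals <- if (identical(diag_property, "charge")) {
    cf$atomic_charge
  } else {
    cf$atomic_props[[diag_property]]
  }
  if (is.null(diag_vals) || length(diag_vals) != n || any(!is.finite(diag_vals))) {
    stop(sprintf("atomic property '%s' missing or incomplete for conformer %s",
                 diag_property, conformer_id))
  }

  M <- as.matrix(stats::dist(cf$coords))
  dimnames(M) <- NULL
  diag(M) <- unname(diag_vals)
  mask <- matrix(FALSE, n, n)
  if (nrow(ensemble$bonds) > 0L) {
    bv <- ensemble$bonds[[bonded_property]]
    if (is.null(bv)) stop(sprintf("bond property '%s' not present", bonded_property))
    el <- ensemble$atoms$element
    for (r in seq_len(nrow(ensemble$bonds))) {
      i <- ensemble$bonds$i[r]; j <- ensemble$bonds$j[r]
      if (!is.finite(bv[r])) {
        stop(sprintf("bond property '%s' missing for bond %d-%d", bonded_property, i, j))
      }
      M[i, j] <- M[j, i] <- bv[r]
      if (mask_ch && setequal(c(el[i], el[j]), c("C", "H"))) {
        mask[i, j] <- mask[j, i] <- TRUE
      }
    }
  }
  structure(list(compound_id = ensemble$compound_id, conformer_id = conformer_id,
                 atom_indices = ensemble$atoms$index,
                 elements = ensemble$atoms$element,
                 labels = ensemble$atoms$skeleton_label,
                 matrix = M, mask = mask),
            class = "ecmc")
}

#' @export
print.ecmc <- function(x, ...) {
  cat(sprintf("<ecmc> %s/%s: %d atoms, %d masked entries\n", x$compound_id,
              x$conformer_id, nrow(x$matrix), sum(x$mask) / 2L))
  invisible(x)
}

## ---- submatrix matching ----------------------------------------------------

# element compatibility: reference element NA matches anything
compatible_elements <- function(ref_el, cand_el) {
  is.na(ref_el) | ref_el == cand_el
}

# inclusive tolerance comparison with an absolute floating-point guard, so a
# deviation of exactly one tolerance still matches
TOL_EPS <- 1e-9
exceeds_tol <- function(dev, tol) dev > tol + TOL_EPS

#' Match a reference submatrix into a candidate ECMC within tolerances
#'
#' Searches for an injective assignment of the k reference atoms onto
#' candidate atoms of compatible element such that every unmasked element of
#' the candidate submatrix deviates from the reference by at most the
#' (inclusive) elementwise tolerance. Candidate atoms are tried in
#' increasing index order and the first complete assignment wins, which
#' makes the result reproducible. With `mapping` (an [atom_map()]) the
#' assignment is fixed by skeleton labels instead of searched.
#'
#' @param reference_values k x k symmetric numeric matrix.
#' @param tolerances k x k non-negative half-widths (same shape).
#' @param candidate an `ecmc` (see [build_ecmc()]).
#' @param ref_elements optional length-k element symbols for the reference
#'   atoms (NA = wildcard).
#' @param ref_labels optional length-k skeleton labels (required with
#'   `mapping`).
#' @param ref_mask optional k x k logical mask of reference entries to skip.
#' @param mapping optional [atom_map()] fixing the assignment by label.
#' @return list of class `match_result`: `matched`, `assignment` (reference
#'   position -> candidate atom index), `max_abs_deviation` (k x k, for the
#'   found assignment), `failing_elements` (when unmatched).
#' @export
match_submatrix <- function(reference_values, tolerances, candidate,
                            ref_elements = NULL, ref_labels = NULL,
                            ref_mask = NULL, mapping = NULL) {
  R <- as.matrix(reference_values); Tm <- as.matrix(tolerances)
  k <- nrow(R)
  if (!all(dim(R) == dim(Tm))) stop("reference and tolerance shapes differ")
  if (any(Tm < 0)) stop("tolerances must be non-negative")
  stopifnot(inherits(candidate, "ecmc"))
  C <- candidate$matrix
  n <- nrow(C)
  if (is.null(ref_mask)) ref_mask <- matrix(FALSE, k, k)
  if (is.null(ref_elements)) ref_elements <- rep(NA_character_, k)

  skip <- function(s, t, cs, ct) ref_mask[s, t] || candidate$mask[cs, ct]

  check_full <- function(assign) {
    dev <- matrix(NA_real_, k, k)
    for (s in seq_len(k)) for (t in s:k) {
      if (skip(s, t, assign[s], assign[t])) next
      d <- abs(C[assign[s], assign[t]] - R[s, t])
      dev[s, t] <- dev[t, s] <- d
      if (exceeds_tol(d, Tm[s, t])) return(list(ok = FALSE, fail = c(s, t), dev = dev))
    }
    list(ok = TRUE, dev = dev)
  }

  if (!is.null(mapping)) {
    if (is.null(ref_labels)) stop("label mapping requires ref_labels")
    assign <- vapply(ref_labels, function(lb) {
      atom_map_lookup(mapping, candidate$compound_id, lb)
    }, 0L)
    if (any(is.na(assign))) {
      return(match_result(FALSE, NULL, NULL,
                          failing = list(unmapped = ref_labels[is.na(assign)])))
    }
    if (anyDuplicated(assign)) stop("atom map assignment is not injective")
    ok_el <- all(compatible_elements(ref_elements, candidate$elements[assign]))
    if (!ok_el) return(match_result(FALSE, NULL, NULL, failing = list(element = TRUE)))
    chk <- check_full(assign)
    return(match_result(chk$ok, if (chk$ok) assign, chk$dev,
                        failing = if (!chk$ok) list(element_at = chk$fail)))
  }

  # deterministic backtracking: place reference atoms in order, candidates in
  # increasing index order, pruning on every constraint against the partial
  # assignment (inclusive tolerance comparison)
  deepest <- 0L
  deepest_fail <- NULL
  assign <- integer(k)
  used <- logical(n)
  recurse <- function(t) {
    if (t > k) return(TRUE)
    for (ct in seq_len(n)) {
      if (used[ct]) next
      if (!compatible_elements(ref_elements[t], candidate$elements[ct])) next
      if (!(ref_mask[t, t] || candidate$mask[ct, ct])) {
        if (exceeds_tol(abs(C[ct, ct] - R[t, t]), Tm[t, t])) {
          if (t > deepest) { deepest <<- t; deepest_fail <<- c(t, t) }
          next
        }
      }
      ok <- TRUE
      if (t > 1L) for (s in seq_len(t - 1L)) {
        if (skip(s, t, assign[s], ct)) next
        if (exceeds_tol(abs(C[assign[s], ct] - R[s, t]), Tm[s, t])) {
          ok <- FALSE
          if (t > deepest) { deepest <<- t; deepest_fail <<- c(s, t) }
          break
        }
      }
      if (!ok) next
      assign[t] <<- ct; used[ct] <<- TRUE
      if (recurse(t + 1L)) return(TRUE)
      used[ct] <<- FALSE; assign[t] <<- 0L
    }
    FALSE
  }
  if (recurse(1L)) {
    chk <- check_full(assign)
    match_result(TRUE, assign, chk$dev)
  } else {
    match_result(FALSE, NULL, NULL,
                 failing = if (!is.null(deepest_fail)) list(element_at = deepest_fail))
  }
}

match_result <- function(matched, assignment, dev, failing = NULL) {
  structure(list(matched = matched, assignment = assignment,
                 max_abs_deviation = dev, failing_elements = failing),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat("<match_result> matched; assignment:",
        paste(x$assignment, collapse = " "), "\n")
  } else {
    cat("<match_result> unmatched\n")
  }
  invisible(x)
}

#' Exhaustive submatrix matching oracle
#'
#' Enumerates every injective, element-compatible assignment of the
#' reference atoms onto the candidate atoms (candidate limited to 10 atoms)
#' and checks the full tolerance constraint set for each. Returns the first
#' valid assignment in lexicographic order, so its verdict and assignment
#' agree with [match_submatrix()] by construction of the search order.
#'
#' @inheritParams match_submatrix
#' @export
brute_force_match <- function(reference_values, tolerances, candidate,
                              ref_elements = NULL, ref_mask = NULL) {
  R <- as.matrix(reference_values); Tm <- as.matrix(tolerances)
  k <- nrow(R)
  stopifnot(inherits(candidate, "ecmc"))
  n <- nrow(candidate$matrix)
  if (n > 10L) stop("brute_force_match size guard: candidate has > 10 atoms")
  if (is.null(ref_mask)) ref_mask <- matrix(FALSE, k, k)
  if (is.null(ref_elements)) ref_elements <- rep(NA_character_, k)
  C <- candidate$matrix

  check <- function(assign) {
    for (s in seq_len(k)) for (t in s:k) {
      if (ref_mask[s, t] || candidate$mask[assign[s], assign[t]]) next
      if (exceeds_tol(abs(C[assign[s], assign[t]] - R[s, t]), Tm[s, t])) return(NULL)
    }
    dev <- matrix(NA_real_, k, k)
    for (s in seq_len(k)) for (t in s:k) {
      if (ref_mask[s, t] || candidate$mask[assign[s], assign[t]]) next
      dev[s, t] <- dev[t, s] <- abs(C[assign[s], assign[t]] - R[s, t])
    }
    dev
  }

  # lexicographic enumeration of injective assignments
  assign <- integer(k)
  used <- logical(n)
  found <- NULL
  enumerate <- function(t) {
    if (!is.null(found)) return()
    if (t > k) {
      dev <- check(assign)
      if (!is.null(dev)) found <<- list(assign = assign, dev = dev)
      return()
    }
    for (ct in seq_len(n)) {
      if (used[ct]) next
      if (!compatible_elements(ref_elements[t], candidate$elements[ct])) next
      assign[t] <<- ct; used[ct] <<- TRUE
      enumerate(t + 1L)
      used[ct] <<- FALSE
      if (!is.null(found)) return()
    }
  }
  enumerate(1L)
  if (is.null(found)) {
    match_result(FALSE, NULL, NULL)
  } else {
    match_result(TRUE, found$assign, found$dev)
  }
}
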