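# ECSA (pharmacophore submatrix) discovery across a labelled compound
# series, class-wise tolerance derivation, and the contingency-based quality
# statistics P_a / alpha_a.

#' Construct an ECSA (electron-conformational submatrix of activity)
#'
#' @param reference_compound_id,reference_conformer_id provenance of the
#'   reference pattern.
#' @param atom_positions indices of the pharmacophore atoms in the reference
#'   ECMC.
#' @param atom_labels skeleton labels of those atoms (e.g. `"C1"`, `"N2"`).
#' @param elements element symbols of those atoms.
#' @param reference_values k x k symmetric submatrix of reference values.
#' @param tolerances k x k non-negative screening tolerance matrix.
#' @param ref_mask optional k x k logical mask (entries excluded from
#'   comparison).
#' @param class_tolerances optional named list of tolerance matrices
#'   (`high`, `low`, `all`).
#' @return object of class `ecsa`.
#' @export
ecsa <- function(reference_compound_id, reference_conformer_id,
                 atom_positions, atom_labels, elements,
                 reference_values, tolerances, ref_mask = NULL,
                 class_tolerances = NULL) {
  k <- length(atom_positions)
  if (k < 2L) stop("an ECSA needs at least 2 atoms")
  reference_values <- as.matrix(reference_values)
  tolerances <- as.matrix(tolerances)
  stopifnot(nrow(reference_values) == k, ncol(reference_values) == k)
  if (max(abs(reference_values - t(reference_values))) > 1e-12) {
    stop("reference_values must be symmetric")
  }
  if (any(tolerances < 0)) stop("tolerances must be non-negative")
  if (is.null(ref_mask)) ref_mask <- matrix(FALSE, k, k)
  structure(list(reference_compound_id = reference_compound_id,
                 reference_conformer_id = reference_conformer_id,
                 atom_positions = as.integer(atom_positions),
                 atom_labels = as.character(atom_labels),
                 elements = as.character(elements),
                 reference_values = reference_values,
                 tolerances = tolerances,
                 ref_mask = ref_mask,
                 class_tolerances = class_tolerances),
            class = "ecsa")
}

#' @export
print.ecsa <- function(x, ...) {
  cat(sprintf("<ecsa> %d atoms (%s) from %s/%s\n", length(x$atom_positions),
              paste(x$atom_labels, collapse = ","),
              x$reference_compound_id, x$reference_conformer_id))
  invisible(x)
}

uniform_tolerance <- function(k, diag = 0.25, offdiag = 1.30) {
  Tm <- matrix(offdiag, k, k)
  diag(Tm) <- diag
  Tm
}

lowest_energy_conformer <- function(ens) {
  e <- rel_energies(ens)
  conformer_ids(ens)[which.min(e)]
}

# fall-back label when the atoms table carries none: element + atom index
default_atom_labels <- function(elements, indices, labels) {
  ifelse(is.na(labels) | !nzchar(labels),
         paste0(elements, indices), labels)
}

#' Discover the pharmacophore submatrix separating actives from inactives
#'
#' The ECMC of the reference compound's lowest-energy conformer provides the
#' reference pattern. Candidate atom subsets are enumerated by deterministic
#' breadth-first growth (all seed pairs, each extended by atoms later in the
#' reference order) within `size_range`. Every candidate is scored by
#' screening the lowest-energy conformer of every compound under the initial
#' uniform tolerances and computing [quality_stats()]; the candidate with
#' the highest `alpha_a` wins, ties broken by higher `P_a`, then smaller
#' size, then lexicographic atom labels. Compounds that fail to match a
#' subset are never re-tested on its supersets (matching is antitone under
#' submatrix growth), which prunes the search without changing the result.
#'
#' @param ensembles named list of [conformer_ensemble()] (filtered).
#' @param activities an [activity_table()] covering the ensembles.
#' @param reference compound_id of a high-activity reference compound.
#' @param init_tol list with `diag` (default 0.25) and `offdiag` (default
#'   1.30): the initial uniform screening tolerances.
#' @param size_range integer vector `c(min, max)` of submatrix sizes to
#'   consider (default `c(3, 8)`).
#' @param diag_property,bonded_property,mask_ch passed to [build_ecmc()].
#' @return an [ecsa()] with attributes `"stats"` (the winning
#'   [quality_stats()]) and `"delta"` (compound-level presence flags).
#' @export
find_ecsa <- function(ensembles, activities, reference,
                      init_tol = list(diag = 0.25, offdiag = 1.30),
                      size_range = c(3, 8),
                      diag_property = "charge", bonded_property = "order",
                      mask_ch = TRUE) {
  stopifnot(inherits(activities, "activity_table"))
  cls <- stats::setNames(activities$activity_class, activities$compound_id)
  ids <- names(ensembles)
  if (is.null(ids) || !all(ids %in% activities$compound_id)) {
    stop("every ensemble needs an activity record")
  }
  if (!any(cls[ids] == "high") || !any(cls[ids] == "low")) {
    stop("need at least one high- and one low-activity compound")
  }
  if (!reference %in% ids) stop("reference compound not among ensembles")
  if (cls[[reference]] != "high") stop("reference must be a high-activity compound")

  ref_ens <- ensembles[[reference]]
  ref_conf <- lowest_energy_conformer(ref_ens)
  ref_ecmc <- build_ecmc(ref_ens, ref_conf, diag_property, bonded_property, mask_ch)
  nref <- nrow(ref_ecmc$matrix)
  labels_all <- default_atom_labels(ref_ecmc$elements, ref_ecmc$atom_indices,
                                    ref_ecmc$labels)
  # reference atom order for growth: label order (deterministic)
  ord <- order(labels_all)

  cand_ecmc <- lapply(ids, function(id) {
    build_ecmc(ensembles[[id]], lowest_energy_conformer(ensembles[[id]]),
               diag_property, bonded_property, mask_ch)
  })
  names(cand_ecmc) <- ids

  score_subset <- function(pos, active_mask) {
    # pos: atom positions in the reference ECMC; active_mask: compounds still
    # matching the parent subset (others are guaranteed non-matches)
    k <- length(pos)
    R <- ref_ecmc$matrix[pos, pos, drop = FALSE]
    msk <- ref_ecmc$mask[pos, pos, drop = FALSE]
    Tm <- uniform_tolerance(k, init_tol$diag, init_tol$offdiag)
    el <- ref_ecmc$elements[pos]
    delta <- stats::setNames(logical(length(ids)), ids)
    for (id in ids[active_mask]) {
      m <- match_submatrix(R, Tm, cand_ecmc[[id]], ref_elements = el,
                           ref_mask = msk)
      delta[[id]] <- m$matched
    }
    delta
  }

  best <- NULL
  consider <- function(pos, delta) {
    st <- tryCatch(quality_stats(delta, activities),
                   error = function(e) NULL)
    if (is.null(st)) return()
    lbl <- paste(sort(labels_all[pos]), collapse = ",")
    cand <- list(pos = pos, delta = delta, stats = st, k = length(pos), label = lbl)
    if (is.null(best)) { best <<- cand; return() }
    a <- c(st$alpha_a, st$P_a, -length(pos))
    b <- c(best$stats$alpha_a, best$stats$P_a, -best$k)
    for (i in seq_along(a)) {
      if (a[i] > b[i] + 1e-12) { best <<- cand; return() }
      if (a[i] < b[i] - 1e-12) return()
    }
    if (lbl < best$label) best <<- cand
  }

  kmin <- size_range[1]; kmax <- min(size_range[2], nref)
  # breadth-first growth over subsets of the label-ordered atom list
  grow <- function(pos_ord, delta) {
    size <- length(pos_ord)
    if (size >= kmin) consider(ord[pos_ord], delta)
    if (size >= kmax) return()
    last <- pos_ord[length(pos_ord)]
    if (last >= nref) return()
    for (nxt in (last + 1L):nref) {
      child <- c(pos_ord, nxt)
      d <- score_subset(ord[child], active_mask = delta)
      if (!any(d)) next  # nothing matches; no superset can score
      grow(child, d)
    }
  }
  all_match <- stats::setNames(rep(TRUE, length(ids)), ids)
  for (i in seq_len(nref - 1L)) {
    for (j in (i + 1L):nref) {
      d <- score_subset(ord[c(i, j)], active_mask = all_match)
      if (!any(d)) next
      grow(c(i, j), d)
    }
  }

  if (is.null(best) || best$stats$alpha_a <= 0) {
    stop("no discriminating submatrix (alpha_a > 0) found")
  }
  pos <- sort(best$pos)
  k <- length(pos)
  out <- ecsa(reference, ref_conf, atom_positions = pos,
              atom_labels = labels_all[pos],
              elements = ref_ecmc$elements[pos],
              reference_values = ref_ecmc$matrix[pos, pos, drop = FALSE],
              tolerances = uniform_tolerance(k, init_tol$diag, init_tol$offdiag),
              ref_mask = ref_ecmc$mask[pos, pos, drop = FALSE])
  attr(out, "stats") <- best$stats
  attr(out, "delta") <- best$delta
  out
}

#' Screen conformer ensembles against an ECSA
#'
#' Evaluates the pharmacophore-presence indicator for every retained
#' conformer of every compound via [match_submatrix()]. Compound-level
#' presence is the OR over a compound's conformers.
#'
#' @param ecsa an [ecsa()].
#' @param ensembles named list of [conformer_ensemble()].
#' @param tolerances tolerance matrix to screen with (default: the ECSA's
#'   own screening tolerances).
#' @param diag_property,bonded_property,mask_ch passed to [build_ecmc()].
#' @return data.frame of class `match_table` with columns `compound_id`,
#'   `conformer_id`, `delta`; the matched assignments are kept in the
#'   `"assignments"` attribute keyed by `"compound_id/conformer_id"`.
#' @export
screen <- function(ecsa, ensembles, tolerances = NULL,
                   diag_property = "charge", bonded_property = "order",
                   mask_ch = TRUE) {
  stopifnot(inherits(ecsa, "ecsa"))
  if (is.null(tolerances)) tolerances <- ecsa$tolerances
  rows <- list()
  assignments <- list()
  for (id in names(ensembles)) {
    ens <- ensembles[[id]]
    for (cid in conformer_ids(ens)) {
      em <- build_ecmc(ens, cid, diag_property, bonded_property, mask_ch)
      m <- match_submatrix(ecsa$reference_values, tolerances, em,
                           ref_elements = ecsa$elements,
                           ref_mask = ecsa$ref_mask)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = id, conformer_id = cid, delta = as.integer(m$matched),
        stringsAsFactors = FALSE)
      if (m$matched) assignments[[paste(id, cid, sep = "/")]] <- m$assignment
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("match_table", "data.frame")
  attr(out, "assignments") <- assignments
  out
}

#' Compound-level pharmacophore presence from a match table
#'
#' @param match_table a `match_table` from [screen()].
#' @return named integer vector (1 = some conformer matches).
#' @export
compound_presence <- function(match_table) {
  r <- tapply(match_table$delta, match_table$compound_id, max)
  stats::setNames(as.integer(r), names(r))
}

#' Derive attained-maximum tolerances from a set of matching conformers
#'
#' Per-element tolerance is the maximum over the subset of the absolute
#' deviation between the mapped candidate value and the reference value
#' (reported as a +/- half-width). Every conformer in the subset must match
#' the ECSA under its screening tolerances; the deterministic assignment
#' found by the matcher is the one measured.
#'
#' @param ecsa an [ecsa()].
#' @param ensembles named list of [conformer_ensemble()].
#' @param subset data.frame with columns `compound_id`, `conformer_id`.
#' @param diag_property,bonded_property,mask_ch passed to [build_ecmc()].
#' @return k x k tolerance matrix (masked entries `NA`).
#' @export
derive_tolerances <- function(ecsa, ensembles, subset,
                              diag_property = "charge",
                              bonded_property = "order", mask_ch = TRUE) {
  stopifnot(inherits(ecsa, "ecsa"))
  k <- nrow(ecsa$reference_values)
  tol <- matrix(0, k, k)
  seen <- matrix(FALSE, k, k)
  for (r in seq_len(nrow(subset))) {
    id <- subset$compound_id[r]; cid <- subset$conformer_id[r]
    em <- build_ecmc(ensembles[[id]], cid, diag_property, bonded_property, mask_ch)
    m <- match_submatrix(ecsa$reference_values, ecsa$tolerances, em,
                         ref_elements = ecsa$elements, ref_mask = ecsa$ref_mask)
    if (!m$matched) {
      stop(sprintf("conformer %s/%s does not match the ECSA", id, cid))
    }
    d <- m$max_abs_deviation
    upd <- !is.na(d)
    tol[upd] <- pmax(tol[upd], d[upd])
    seen <- seen | upd
  }
  tol[!seen] <- NA_real_
  dimnames(tol) <- list(ecsa$atom_labels, ecsa$atom_labels)
  tol
}

#' Pharmacophore quality statistics from a 2 x 2 contingency
#'
#' Counts the compounds by activity class and pharmacophore presence:
#' `h1` actives with the feature, `h2` actives without, `h3` low-activity
#' with, `h4` low-activity without; marginals `k1 = h1 + h2`,
#' `k2 = h3 + h4`, `k3 = h1 + h3`, `k4 = h2 + h4`. Then
#' `P_a = (h1 + 1) / (h1 + h2 + 2)` and
#' `alpha_a = (h1 h4 - h2 h3) / sqrt(k1 k2 k3 k4)` (a phi-type association
#' coefficient bounded in \[-1, 1\]).
#'
#' @param presence named logical/integer vector of compound-level presence,
#'   or a `match_table` from [screen()].
#' @param activities an [activity_table()] (or named character vector of
#'   `"high"`/`"low"` classes).
#' @return list of class `quality_stats` with the h/k counts, `P_a` and
#'   `alpha_a`.
#' @export
quality_stats <- function(presence, activities) {
  if (inherits(presence, "match_table")) presence <- compound_presence(presence)
  if (inherits(activities, "activity_table")) {
    cls <- stats::setNames(activities$activity_class, activities$compound_id)
  } else {
    cls <- activities
  }
  ids <- names(presence)
  if (is.null(ids) || !all(ids %in% names(cls))) {
    stop("every compound with a presence flag needs an activity class")
  }
  pres <- as.logical(presence)
  hi <- cls[ids] == "high"
  h1 <- sum(hi & pres);  h2 <- sum(hi & !pres)
  h3 <- sum(!hi & pres); h4 <- sum(!hi & !pres)
  k1 <- h1 + h2; k2 <- h3 + h4; k3 <- h1 + h3; k4 <- h2 + h4
  if (any(c(k1, k2, k3, k4) == 0)) {
    stop("degenerate marginal: alpha_a undefined (some k_i = 0)")
  }
  P_a <- (h1 + 1) / (h1 + h2 + 2)
  alpha_a <- (h1 * h4 - h2 * h3) / sqrt(prod(c(k1, k2, k3, k4)))
  structure(list(h1 = h1, h2 = h2, h3 = h3, h4 = h4,
                 k1 = k1, k2 = k2, k3 = k3, k4 = k4,
                 P_a = P_a, alpha_a = alpha_a),
            class = "quality_stats")
}

#' @export
print.quality_stats <- function(x, ...) {
  cat(sprintf("<quality_stats> h = (%d, %d, %d, %d); P_a = %.4f; alpha_a = %.4f\n",
              x$h1, x$h2, x$h3, x$h4, x$P_a, x$alpha_a))
  invisible(x)
}
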