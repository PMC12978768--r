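# Readers/writers for the external data the pipeline consumes: conformer
# ensembles (JSON, optionally SDF for geometry-only ingest), activity tables,
# atom-correspondence maps and per-conformer descriptor panels, plus the
# activity-unit conventions (IC50 nM -> pIC50, high/low classification).

#' Convert an IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so an IC50
#' given in nM maps to `9 - log10(ic50_nM)`.
#'
#' @param ic50_nM positive numeric vector of IC50 values in nanomolar.
#' @return numeric vector of pIC50 values (dimensionless, molar scale).
#' @examples
#' ic50_to_pic50(c(1000, 1, 0.5))  # 6, 9, 9.301
#' @export
ic50_to_pic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50_nM must be finite and strictly positive")
  }
  9 - log10(ic50_nM)
}

#' Classify compounds as high- or low-activity
#'
#' Compounds with pIC50 greater than or equal to the threshold are labelled
#' `"high"`, the rest `"low"`. The comparison is inclusive at the boundary.
#'
#' @param pic50 finite numeric vector of pIC50 values.
#' @param threshold activity cut-off on the pIC50 scale (default 7.61).
#' @return character vector of `"high"` / `"low"` labels.
#' @export
classify_activity <- function(pic50, threshold = 7.61) {
  if (!is.numeric(pic50) || any(!is.finite(pic50))) {
    stop("pic50 must be finite numeric")
  }
  ifelse(pic50 >= threshold, "high", "low")
}

## ---- conformer ensembles ---------------------------------------------------

#' Construct and validate a conformer ensemble
#'
#' A conformer ensemble holds one compound's atoms, bonds and conformers.
#' Relative energies are re-referenced so the minimum over conformers is 0.
#'
#' @param compound_id character scalar.
#' @param atoms data.frame with columns `index` (1-based, contiguous),
#'   `element` (symbol) and optionally `skeleton_label` (e.g. `"C7"`).
#' @param bonds data.frame with columns `i`, `j` (atom indices, `i < j`),
#'   `order` and optionally `wiberg`, `bond_energy`, `bond_polarizability`.
#'   May have zero rows.
#' @param conformers list; each element a list with `conformer_id`,
#'   `rel_energy` (kcal/mol), `has_imaginary_freq` (logical), `coords`
#'   (n_atoms x 3 matrix, Angstrom), `atomic_charge` (length n_atoms, e),
#'   optional `atomic_props` (named list of per-atom numeric vectors) and
#'   optional `descriptors` (named numeric vector of per-conformer values).
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(compound_id, atoms, bonds = NULL, conformers) {
  if (!is.character(compound_id) || length(compound_id) != 1L || !nzchar(compound_id)) {
    stop("compound_id must be a non-empty string")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(c("index", "element") %in% names(atoms))) {
    stop("atoms must have columns 'index' and 'element'")
  }
  atoms$index <- as.integer(atoms$index)
  n <- nrow(atoms)
  if (anyDuplicated(atoms$index)) stop("duplicate atom index in atoms table")
  if (!identical(sort(atoms$index), seq_len(n))) {
    stop("atom indices must be contiguous from 1")
  }
  atoms <- atoms[order(atoms$index), , drop = FALSE]
  if (!"skeleton_label" %in% names(atoms)) atoms$skeleton_label <- NA_character_

  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = numeric())
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(bonds) > 0L) {
    if (!all(c("i", "j") %in% names(bonds))) stop("bonds must have columns 'i' and 'j'")
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    for (r in seq_len(nrow(bonds))) {
      if (bonds$i[r] < 1L || bonds$i[r] > n || bonds$j[r] < 1L || bonds$j[r] > n) {
        stop(sprintf("bond %d references atom %d but the molecule has %d atoms",
                     r, max(bonds$i[r], bonds$j[r]), n))
      }
      if (bonds$i[r] >= bonds$j[r]) stop(sprintf("bond %d must have i < j", r))
    }
    if (!"order" %in% names(bonds)) bonds$order <- NA_real_
  }

  if (!is.list(conformers) || length(conformers) == 0L) {
    stop("conformers must be a non-empty list")
  }
  conformers <- lapply(seq_along(conformers), function(k) {
    cf <- conformers[[k]]
    if (is.null(cf$conformer_id)) cf$conformer_id <- sprintf("conf%03d", k)
    cf$conformer_id <- as.character(cf$conformer_id)
    if (is.null(cf$rel_energy) || !is.finite(cf$rel_energy)) {
      stop(sprintf("conformer %s: rel_energy missing or non-finite", cf$conformer_id))
    }
    cf$rel_energy <- as.numeric(cf$rel_energy)
    cf$has_imaginary_freq <- isTRUE(cf$has_imaginary_freq)
    cf$coords <- matrix(as.numeric(unlist(cf$coords)), ncol = 3L, byrow = is.list(cf$coords))
    if (nrow(cf$coords) != n) {
      stop(sprintf("conformer %s: %d coordinate triplets for %d atoms",
                   cf$conformer_id, nrow(cf$coords), n))
    }
    if (!is.null(cf$atomic_charge)) {
      cf$atomic_charge <- as.numeric(unlist(cf$atomic_charge))
      if (length(cf$atomic_charge) != n) {
        stop(sprintf("conformer %s: %d charges for %d atoms",
                     cf$conformer_id, length(cf$atomic_charge), n))
      }
    }
    if (!is.null(cf$descriptors)) {
      cf$descriptors <- unlist(cf$descriptors)
    }
    cf
  })
  ids <- vapply(conformers, `[[`, "", "conformer_id")
  if (anyDuplicated(ids)) stop("duplicate conformer_id")

  out <- structure(
    list(compound_id = compound_id, atoms = atoms, bonds = bonds,
         conformers = conformers),
    class = "conformer_ensemble"
  )
  rereference_energies(out)
}

# shift rel_energies so the ensemble minimum is exactly 0
rereference_energies <- function(ens) {
  e <- vapply(ens$conformers, `[[`, 0, "rel_energy")
  e0 <- min(e)
  ens$conformers <- lapply(ens$conformers, function(cf) {
    cf$rel_energy <- cf$rel_energy - e0
    cf
  })
  ens
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("<conformer_ensemble> %s: %d atoms, %d bonds, %d conformers\n",
              x$compound_id, nrow(x$atoms), nrow(x$bonds), length(x$conformers)))
  invisible(x)
}

rel_energies <- function(ens) vapply(ens$conformers, `[[`, 0, "rel_energy")
conformer_ids <- function(ens) vapply(ens$conformers, `[[`, "", "conformer_id")

#' Read a conformer ensemble from JSON or SDF
#'
#' The canonical interchange format is the versioned ensemble JSON schema
#' (`"ecqsar4d-ensemble/1"`, see the package vignette). SDF (V2000) ingest is
#' supported for geometry-only structures: atoms, bonds and coordinates are
#' taken from the first (or all) molecule records and electronic fields are
#' marked absent, not zero.
#'
#' @param path file path.
#' @param format `"json"` (default), `"sdf"`, or `"auto"` to guess from the
#'   file extension.
#' @return a [conformer_ensemble()] (energies re-referenced to min = 0).
#' @export
read_ensemble <- function(path, format = c("auto", "json", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf?$", path, ignore.case = TRUE)) "sdf" else "json"
  }
  if (format == "sdf") return(read_ensemble_sdf(path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$schema) || !identical(doc$schema, "ecqsar4d-ensemble/1")) {
    stop("ensemble JSON missing schema tag 'ecqsar4d-ensemble/1'")
  }
  for (field in c("compound_id", "atoms", "conformers")) {
    if (is.null(doc[[field]])) stop(sprintf("ensemble JSON: missing field '%s'", field))
  }
  atoms <- do.call(rbind, lapply(doc$atoms, function(a) {
    data.frame(index = as.integer(a$index), element = as.character(a$element),
               skeleton_label = if (is.null(a$skeleton_label)) NA_character_ else a$skeleton_label,
               stringsAsFactors = FALSE)
  }))
  bonds <- if (length(doc$bonds)) do.call(rbind, lapply(doc$bonds, function(b) {
    data.frame(i = as.integer(b$i), j = as.integer(b$j),
               order = if (is.null(b$order)) NA_real_ else as.numeric(b$order),
               wiberg = if (is.null(b$wiberg)) NA_real_ else as.numeric(b$wiberg),
               bond_energy = if (is.null(b$bond_energy)) NA_real_ else as.numeric(b$bond_energy),
               bond_polarizability = if (is.null(b$bond_polarizability)) NA_real_ else as.numeric(b$bond_polarizability),
               stringsAsFactors = FALSE)
  })) else NULL
  conformer_ensemble(doc$compound_id, atoms, bonds, doc$conformers)
}

read_ensemble_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("SDF ingest requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  if (length(sdf) == 0L) stop("SDF file contains no molecule records")
  first <- sdf[[1]]
  ab <- ChemmineR::atomblock(first)
  bb <- ChemmineR::bondblock(first)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(index = seq_len(nrow(ab)), element = elements,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  if (NROW(bb) > 0) {
    i <- pmin(bb[, 1], bb[, 2]); j <- pmax(bb[, 1], bb[, 2])
    bonds <- data.frame(i = i, j = j, order = as.numeric(bb[, 3]))
  }
  conformers <- lapply(seq_along(sdf@SDF), function(k) {
    abk <- ChemmineR::atomblock(sdf[[k]])
    list(conformer_id = sprintf("sdf%03d", k), rel_energy = 0,
         has_imaginary_freq = FALSE,
         coords = unname(abk[, 1:3, drop = FALSE]),
         atomic_charge = NULL)   # electronic fields absent on SDF ingest
  })
  id <- ChemmineR::sdfid(sdf)[1]
  if (is.na(id) || !nzchar(id)) id <- basename(path)
  conformer_ensemble(id, atoms, bonds, conformers)
}

#' Write a conformer ensemble to the canonical JSON schema
#'
#' @param ens a [conformer_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  doc <- list(
    schema = "ecqsar4d-ensemble/1",
    compound_id = ens$compound_id,
    atoms = lapply(seq_len(nrow(ens$atoms)), function(r) {
      a <- list(index = ens$atoms$index[r], element = ens$atoms$element[r])
      if (!is.na(ens$atoms$skeleton_label[r])) a$skeleton_label <- ens$atoms$skeleton_label[r]
      a
    }),
    bonds = lapply(seq_len(nrow(ens$bonds)), function(r) {
      b <- as.list(ens$bonds[r, , drop = FALSE])
      b[!vapply(b, function(v) is.na(v), TRUE)]
    }),
    conformers = lapply(ens$conformers, function(cf) {
      out <- list(conformer_id = cf$conformer_id, rel_energy = cf$rel_energy,
                  has_imaginary_freq = cf$has_imaginary_freq,
                  coords = apply(cf$coords, 1, as.numeric, simplify = FALSE))
      if (!is.null(cf$atomic_charge)) out$atomic_charge <- cf$atomic_charge
      if (!is.null(cf$atomic_props)) out$atomic_props <- cf$atomic_props
      if (!is.null(cf$descriptors)) out$descriptors <- as.list(cf$descriptors)
      out
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- activity tables -------------------------------------------------------

#' Read a compound activity table
#'
#' The CSV must contain `compound_id` and exactly one of `pic50` or
#' `ic50_nM`; optional columns `activity_class` and `split`
#' (train/test/unassigned) are honoured. In `label_mode = "compute"` the
#' class labels are derived from `threshold`; in `"verbatim"` the file's
#' printed labels are kept and any disagreement with the threshold is
#' reported in the `"mismatches"` attribute rather than silently fixed.
#'
#' @param path CSV path.
#' @param threshold pIC50 classification cut-off (default 7.61, inclusive).
#' @param label_mode `"compute"` or `"verbatim"`.
#' @return data.frame of class `activity_table` with columns `compound_id`,
#'   `pic50`, `activity_class`, `split`; attribute `"mismatches"` lists
#'   compounds whose verbatim label disagrees with the threshold.
#' @export
read_activity_table <- function(path, threshold = 7.61,
                                label_mode = c("compute", "verbatim")) {
  label_mode <- match.arg(label_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_table(df, threshold = threshold, label_mode = label_mode)
}

#' Build an activity table from a data.frame
#'
#' @inheritParams read_activity_table
#' @param df data.frame as described for [read_activity_table()].
#' @export
activity_table <- function(df, threshold = 7.61,
                           label_mode = c("compute", "verbatim")) {
  label_mode <- match.arg(label_mode)
  if (nrow(df) == 0L) stop("no records in activity table")
  if (!"compound_id" %in% names(df)) stop("activity table needs a compound_id column")
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) stop("duplicate compound_id in activity table")
  has_p <- "pic50" %in% names(df); has_n <- "ic50_nM" %in% names(df)
  if (has_p == has_n) {
    stop("activity table must have exactly one of 'pic50' or 'ic50_nM'")
  }
  pic50 <- if (has_p) as.numeric(df$pic50) else ic50_to_pic50(as.numeric(df$ic50_nM))
  if (any(!is.finite(pic50))) stop("non-finite pIC50 after conversion")
  computed <- classify_activity(pic50, threshold)
  mismatches <- character()
  if (label_mode == "verbatim") {
    if (!"activity_class" %in% names(df)) {
      stop("label_mode='verbatim' requires an activity_class column")
    }
    cls <- normalize_class_labels(df$activity_class)
    mismatches <- df$compound_id[cls != computed]
  } else {
    cls <- computed
  }
  split <- if ("split" %in% names(df)) as.character(df$split) else rep("unassigned", nrow(df))
  bad <- setdiff(unique(split), c("train", "test", "unassigned"))
  if (length(bad)) stop(sprintf("unknown split token(s): %s", paste(bad, collapse = ", ")))
  out <- data.frame(compound_id = df$compound_id, pic50 = pic50,
                    activity_class = cls, split = split,
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_table", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "label_mode") <- label_mode
  attr(out, "mismatches") <- mismatches
  out
}

normalize_class_labels <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[grepl("^high", x)] <- "high"
  x[grepl("^low", x)] <- "low"
  if (!all(x %in% c("high", "low"))) stop("unrecognised activity class label")
  x
}

## ---- atom maps -------------------------------------------------------------

#' Read an atom-correspondence (ATM) map
#'
#' Maps per-compound local atom indices to shared skeleton labels so that
#' pharmacophore atoms can be aligned by name across the series.
#'
#' @param path CSV with columns `compound_id`, `local_atom_index`,
#'   `skeleton_label`.
#' @return data.frame of class `atom_map`.
#' @export
read_atom_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  atom_map(df)
}

#' @rdname read_atom_map
#' @param df data.frame with the ATM columns.
#' @export
atom_map <- function(df) {
  need <- c("compound_id", "local_atom_index", "skeleton_label")
  if (!all(need %in% names(df))) {
    stop("atom map needs columns compound_id, local_atom_index, skeleton_label")
  }
  df$compound_id <- as.character(df$compound_id)
  df$local_atom_index <- as.integer(df$local_atom_index)
  df$skeleton_label <- as.character(df$skeleton_label)
  if (anyDuplicated(df[, c("compound_id", "local_atom_index")])) {
    stop("duplicate (compound_id, local_atom_index) in atom map")
  }
  if (anyDuplicated(df[, c("compound_id", "skeleton_label")])) {
    stop("duplicate (compound_id, skeleton_label) in atom map")
  }
  class(df) <- c("atom_map", "data.frame")
  df
}

#' Look up the local atom index of a skeleton label
#'
#' @param map an [atom_map()].
#' @param compound_id compound to query.
#' @param label skeleton label, e.g. `"N1"`.
#' @return integer local atom index, or `NA_integer_` when the label is not
#'   mapped for that compound (partial skeletons are allowed).
#' @export
atom_map_lookup <- function(map, compound_id, label) {
  stopifnot(inherits(map, "atom_map"))
  hit <- map$local_atom_index[map$compound_id == compound_id &
                              map$skeleton_label == label]
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

## ---- descriptor panels -----------------------------------------------------

#' Read a per-conformer descriptor panel
#'
#' CSV keyed by `compound_id`, `conformer_id` with numeric descriptor
#' columns. Column order is preserved as the descriptor index order
#' (index 1..p).
#'
#' @param path CSV path.
#' @return data.frame of class `descriptor_panel`.
#' @export
read_descriptor_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  descriptor_panel(df)
}

#' @rdname read_descriptor_panel
#' @param df data.frame with the panel columns.
#' @export
descriptor_panel <- function(df) {
  if (!all(c("compound_id", "conformer_id") %in% names(df))) {
    stop("descriptor panel needs compound_id and conformer_id columns")
  }
  df$compound_id <- as.character(df$compound_id)
  df$conformer_id <- as.character(df$conformer_id)
  dcols <- setdiff(names(df), c("compound_id", "conformer_id"))
  if (length(dcols) == 0L) stop("descriptor panel has no descriptor columns")
  if (anyDuplicated(dcols)) stop("duplicate descriptor names")
  for (col in dcols) {
    v <- df[[col]]
    if (!is.numeric(v)) stop(sprintf("descriptor '%s' is not numeric", col))
    if (any(!is.finite(v))) {
      r <- which(!is.finite(v))[1]
      stop(sprintf("missing/non-finite value at (compound %s, conformer %s, descriptor %s)",
                   df$compound_id[r], df$conformer_id[r], col))
    }
  }
  if (anyDuplicated(df[, c("compound_id", "conformer_id")])) {
    stop("duplicate (compound_id, conformer_id) row in descriptor panel")
  }
  class(df) <- c("descriptor_panel", "data.frame")
  df
}

#' Write a descriptor panel to CSV
#'
#' @param panel a [descriptor_panel()].
#' @param path output path.
#' @export
write_descriptor_panel <- function(panel, path) {
  stopifnot(inherits(panel, "descriptor_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

descriptor_names <- function(panel) {
  setdiff(names(panel), c("compound_id", "conformer_id"))
}
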