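FEATURE_TYPES <- c("A", "D", "H", "N", "P", "R")

# Types that may carry a direction vector. R always does (ring normal);
# H, N, P never do.
DIRECTED_TYPES <- c("A", "D", "R")

#' Construct a pharmacophore feature
#'
#' A typed pharmacophore site: one of acceptor (A), donor (D), hydrophobe (H),
#' negative ionizable (N), positive ionizable (P) or aromatic ring (R), placed
#' at a 3D point in Angstroms. Acceptors, donors and rings may carry a unit
#' direction vector (projected lone pair / H direction, or the ring-plane
#' normal); rings always do, and H/N/P never do.
#'
#' @param type Single letter in `A D H N P R`.
#' @param point Numeric length-3 coordinates (Angstrom).
#' @param direction Optional numeric length-3 vector; normalized internally.
#' @param member_atoms Optional integer vector of contributing atom indices
#'   (group features such as rings and hydrophobic patches).
#' @return An object of class `phk_feature`.
#' @export
phk_feature <- function(type, point, direction = NULL, member_atoms = NULL) {
  type <- as.character(type)
  if (!type %in% FEATURE_TYPES)
    stop("unknown feature type '", type, "' (expected one of ",
         paste(FEATURE_TYPES, collapse = ", "), ")")
  point <- as.numeric(point)
  if (length(point) != 3L || any(!is.finite(point)))
    stop("feature point must be 3 finite coordinates")
  if (!is.null(direction)) {
    if (!type %in% DIRECTED_TYPES)
      stop("feature type '", type, "' cannot carry a direction")
    direction <- as.numeric(direction)
    nrm <- sqrt(sum(direction^2))
    if (length(direction) != 3L || !is.finite(nrm) || nrm < 1e-12)
      stop("direction must be a nonzero 3-vector")
    direction <- direction / nrm
  }
  if (type == "R" && is.null(direction))
    stop("aromatic ring (R) features must carry a ring-normal direction")
  structure(list(type = type, point = point, direction = direction,
                 member_atoms = if (is.null(member_atoms)) NULL
                                else as.integer(member_atoms)),
            class = "phk_feature")
}

#' Construct a feature set
#'
#' All pharmacophore features perceived on one conformer of one molecule.
#'
#' @param molecule_id Non-empty molecule identifier.
#' @param conformer_id Integer conformer index (>= 0).
#' @param features List of [phk_feature] objects.
#' @return An object of class `phk_featureset`.
#' @export
feature_set <- function(molecule_id, conformer_id = 0L, features = list()) {
  molecule_id <- as.character(molecule_id)
  if (length(molecule_id) != 1L || !nzchar(molecule_id))
    stop("molecule_id must be a non-empty string")
  conformer_id <- as.integer(conformer_id)
  if (is.na(conformer_id) || conformer_id < 0L)
    stop("conformer_id must be a non-negative integer")
  if (!all(vapply(features, inherits, logical(1), "phk_feature")))
    stop("features must be a list of phk_feature objects")
  structure(list(molecule_id = molecule_id, conformer_id = conformer_id,
                 features = features),
            class = "phk_featureset")
}

#' @export
print.phk_featureset <- function(x, ...) {
  cat(sprintf("<phk_featureset> %s conformer %d: %d sites [%s]\n",
              x$molecule_id, x$conformer_id, length(x$features),
              paste(feature_types(x), collapse = "")))
  invisible(x)
}

#' Feature types of a set, sorted
#'
#' @param fs A [feature_set].
#' @param sorted Sort letters alphabetically (the variant convention)?
#' @return Character vector of single letters.
#' @export
feature_types <- function(fs, sorted = TRUE) {
  tys <- vapply(fs$features, function(f) f$type, character(1))
  if (sorted) sort(tys) else tys
}

#' Feature coordinates as a matrix
#'
#' @param fs A [feature_set].
#' @return Numeric n x 3 matrix of site coordinates (Angstrom).
#' @export
feature_coords <- function(fs) {
  if (length(fs$features) == 0L) return(matrix(numeric(0), 0L, 3L))
  do.call(rbind, lapply(fs$features, function(f) f$point))
}

#' Apply a rigid transform to a feature set
#'
#' Rotates and translates every site point, and rotates every direction
#' vector, by the same rigid motion `x -> R x + t`.
#'
#' @param fs A [feature_set].
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Numeric length-3 vector.
#' @return The transformed [feature_set].
#' @export
transform_feature_set <- function(fs, rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)))
  fs$features <- lapply(fs$features, function(f) {
    f$point <- as.numeric(rotation %*% f$point + translation)
    if (!is.null(f$direction))
      f$direction <- as.numeric(rotation %*% f$direction)
    f
  })
  fs
}

#' Read abstract site-set files
#'
#' Reads the canonical site-set JSON representation:
#' `{"molecules": [{"id", "conformers": [{"id", "sites":
#' [{"type", "xyz", "dir"}]}]}]}`. One [feature_set] is returned per
#' (molecule, conformer), in file order.
#'
#' @param path Path to a site-set JSON file.
#' @return List of [feature_set] objects.
#' @export
load_site_set <- function(path) {
  if (!file.exists(path)) stop("site-set file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed site-set JSON in '", path, "': ",
                             conditionMessage(e)))
  if (is.null(doc$molecules))
    stop("malformed site-set JSON: top-level 'molecules' array missing")
  out <- list()
  for (mol in doc$molecules) {
    if (is.null(mol$id) || !nzchar(as.character(mol$id)))
      stop("site-set molecule record without an 'id'")
    for (conf in mol$conformers) {
      feats <- lapply(conf$sites, function(s) {
        ty <- as.character(s$type)
        if (!ty %in% FEATURE_TYPES)
          stop("molecule '", mol$id, "': unknown feature type '", ty, "'")
        dir <- if (!is.null(s$dir)) unlist(s$dir) else NULL
        phk_feature(ty, unlist(s$xyz), direction = dir)
      })
      out[[length(out) + 1L]] <-
        feature_set(mol$id, as.integer(conf$id), feats)
    }
  }
  out
}

#' Write feature sets to a site-set JSON file
#'
#' Inverse of [load_site_set]; `load_site_set(write_site_set(x, f))`
#' reproduces `x` up to float formatting.
#'
#' @param sets List of [feature_set] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_set <- function(sets, path) {
  if (inherits(sets, "phk_featureset")) sets <- list(sets)
  ids <- unique(vapply(sets, function(s) s$molecule_id, character(1)))
  mols <- lapply(ids, function(id) {
    confs <- Filter(function(s) s$molecule_id == id, sets)
    list(id = id, conformers = lapply(confs, function(cf) {
      list(id = cf$conformer_id, sites = lapply(cf$features, function(f) {
        list(type = f$type, xyz = f$point,
             dir = if (is.null(f$direction)) NULL else f$direction)
      }))
    }))
  })
  jsonlite::write_json(list(molecules = mols), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
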