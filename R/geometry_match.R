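# Core geometric primitives: enumeration of variant-typed site subsets and
# backtracking search for type-preserving assignments whose inter-site
# distances match a reference within a tolerance. Shared by common-
# pharmacophore discovery and screen-database matching.

variant_letters <- function(variant) {
  lets <- strsplit(variant, "")[[1]]
  bad <- setdiff(lets, FEATURE_TYPES)
  if (length(bad)) stop("invalid variant letters: ", paste(bad, collapse = ""))
  sort(lets)
}

# all index subsets of fs whose type multiset equals the variant.
# Each subset is returned in canonical order: grouped by sorted type letter,
# within a type in increasing feature index. Returns list of integer vectors.
enumerate_typed_subsets <- function(fs, variant) {
  lets <- variant_letters(variant)
  need <- table(lets)
  tys <- vapply(fs$features, function(f) f$type, character(1))
  per_type <- list()
  for (ty in names(need)) {
    idx <- which(tys == ty)
    if (length(idx) < need[[ty]]) return(list())
    per_type[[ty]] <- utils::combn(idx, need[[ty]], simplify = FALSE)
  }
  subsets <- list(integer(0))
  for (ty in names(need)) {
    subsets <- unlist(lapply(subsets, function(acc) {
      lapply(per_type[[ty]], function(pick) c(acc, pick))
    }), recursive = FALSE)
  }
  subsets
}

# distance matrix of a coordinate matrix
coord_dist <- function(xyz) as.matrix(stats::dist(xyz))

# Find type-preserving assignments of features of `fs` onto the k reference
# sites (ref_types, ref_dmat = reference inter-site distance matrix) such
# that every pairwise distance agrees within `tol` Angstrom. Backtracking
# with incremental distance pruning. Returns a list of integer vectors
# (feature indices of fs, position i matching reference site i); when
# first_only = TRUE stops at the first valid assignment.
match_assignments <- function(ref_types, ref_dmat, fs, tol,
                              first_only = FALSE, max_assignments = 256L) {
  k <- length(ref_types)
  tys <- vapply(fs$features, function(f) f$type, character(1))
  cand <- lapply(ref_types, function(ty) which(tys == ty))
  if (any(vapply(cand, length, integer(1)) == 0L)) return(list())
  xyz <- feature_coords(fs)
  dmat <- if (nrow(xyz) >= 2L) coord_dist(xyz) else
    matrix(0, nrow(xyz), nrow(xyz))

  found <- list()
  assign_vec <- integer(k)
  used <- logical(length(fs$features))
  recurse <- function(i) {
    if (length(found) >= max_assignments) return()
    if (i > k) { found[[length(found) + 1L]] <<- assign_vec; return() }
    for (j in cand[[i]]) {
      if (used[j]) next
      ok <- TRUE
      if (i > 1L) {
        prev <- assign_vec[seq_len(i - 1L)]
        if (any(abs(dmat[j, prev] - ref_dmat[i, seq_len(i - 1L)]) > tol))
          ok <- FALSE
      }
      if (ok) {
        assign_vec[i] <<- j; used[j] <<- TRUE
        recurse(i + 1L)
        used[j] <<- FALSE
        if (first_only && length(found) > 0L) return()
      }
    }
  }
  recurse(1L)
  found
}

# Cheap sound prune: can fs possibly host an assignment for the reference?
# For every type pair needed, the reference distance must fall within the
# [min - tol, max + tol] envelope of distances available in fs for that
# type pair, and per-type site counts must suffice.
can_possibly_match <- function(ref_types, ref_dmat, fs, tol) {
  tys <- vapply(fs$features, function(f) f$type, character(1))
  need <- table(ref_types)
  have <- table(tys)
  for (ty in names(need))
    if (is.na(have[ty]) || have[ty] < need[[ty]]) return(FALSE)
  if (length(ref_types) < 2L) return(TRUE)
  xyz <- feature_coords(fs)
  dmat <- coord_dist(xyz)
  for (a in seq_len(length(ref_types) - 1L)) {
    for (b in (a + 1L):length(ref_types)) {
      ia <- which(tys == ref_types[a]); ib <- which(tys == ref_types[b])
      dd <- dmat[ia, ib, drop = FALSE]
      dd <- if (ref_types[a] == ref_types[b])
        as.numeric(dd[upper.tri(dd)]) else as.numeric(dd)
      if (length(dd) == 0L) return(FALSE)
      if (ref_dmat[a, b] < min(dd) - tol || ref_dmat[a, b] > max(dd) + tol)
        return(FALSE)
    }
  }
  TRUE
}
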