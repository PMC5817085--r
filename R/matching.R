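# Screen database construction and hypothesis matching with fitness scoring.

#' Build a conformer screen database
#'
#' Collects all conformer feature sets of the screened compounds, capping the
#' number of conformers per molecule (deterministically, in input order), and
#' precomputes a per-conformer index (site-type counts and per-type-pair
#' inter-site distance envelopes) used to prune candidates during matching.
#'
#' @param sets List of [feature_set] objects (all conformers, all molecules).
#' @param max_confs Maximum conformers kept per molecule (default 100).
#' @param per_rotatable Maximum conformers per rotatable bond (default 10);
#'   applied only when `rotatable_counts` supplies a per-molecule rotatable
#'   bond count.
#' @param rotatable_counts Optional named integer vector (molecule id ->
#'   rotatable bond count).
#' @return List of class `phk_screendb` with `entries` and `index`.
#' @export
build_screen_db <- function(sets, max_confs = 100L, per_rotatable = 10L,
                            rotatable_counts = NULL) {
  if (max_confs < 1L) stop("max_confs must be >= 1")
  mol_ids <- vapply(sets, function(s) s$molecule_id, character(1))
  keep <- logical(length(sets))
  seen <- integer(0)
  for (i in seq_along(sets)) {
    id <- mol_ids[i]
    n <- if (id %in% names(seen)) seen[[id]] else 0L
    cap <- max_confs
    if (!is.null(rotatable_counts) && id %in% names(rotatable_counts))
      cap <- min(cap, per_rotatable * max(1L, rotatable_counts[[id]]))
    if (n < cap) { keep[i] <- TRUE; seen[id] <- n + 1L }
  }
  entries <- sets[keep]
  index <- lapply(entries, function(fs) {
    tys <- vapply(fs$features, function(f) f$type, character(1))
    list(type_counts = table(tys))
  })
  structure(list(entries = entries, index = index),
            class = "phk_screendb")
}

#' @export
print.phk_screendb <- function(x, ...) {
  ids <- vapply(x$entries, function(e) e$molecule_id, character(1))
  cat(sprintf("<phk_screendb> %d conformers, %d molecules\n",
              length(x$entries), length(unique(ids))))
  invisible(x)
}

#' Fitness of a matched conformer
#'
#' `fitness = max(0, 1 - rmsd/dist_tol) + clip(vec_cos, 0, 1) +
#' clip(vol_jaccard, 0, 1)`, in \[0, 3\].
#'
#' @param alignment A `phk_alignment` (or anything with an `rmsd` element).
#' @param vec_cos Mean direction cosine of matched vector features.
#' @param vol_jaccard Sphere-overlap Jaccard between hypothesis and match.
#' @param dist_tol Distance tolerance used in the match (Angstrom).
#' @return Numeric fitness score.
#' @export
fitness_score <- function(alignment, vec_cos, vol_jaccard, dist_tol = 2.0) {
  rmsd <- if (is.list(alignment)) alignment$rmsd else alignment
  max(0, 1 - rmsd / dist_tol) + min(1, max(0, vec_cos)) +
    min(1, max(0, vol_jaccard))
}

#' Search a screen database for hypothesis matches
#'
#' A conformer matches when some type-preserving site assignment places every
#' inter-site distance within `dist_tol` of the hypothesis reference
#' distances. Matching conformers are superposed and fitness-scored; the best
#' conformer per molecule is kept and results are ranked by fitness
#' (ties: lower RMSD, then molecule id).
#'
#' @param db A [build_screen_db] result.
#' @param h A `phk_hypothesis`.
#' @param dist_tol Distance tolerance in Angstrom (default 2.0).
#' @param top_n Number of top molecules returned.
#' @return Data frame of class `phk_matches`: `molecule_id`, `conformer_id`,
#'   `rmsd`, `vec_cos`, `vol_jaccard`, `fitness`; attribute `"details"`
#'   holds the per-hit assignment and alignment.
#' @export
match_hypothesis <- function(db, h, dist_tol = 2.0, top_n = Inf) {
  if (dist_tol <= 0) stop("dist_tol must be positive")
  if (length(h$sites) < 3L)
    stop("hypothesis must have at least 3 sites for alignment")
  ref_xyz <- hypothesis_coords(h)
  ref_types <- hypothesis_types(h)
  ref_dmat <- coord_dist(ref_xyz)
  ref_dirs <- lapply(h$sites, `[[`, "direction")

  hits <- list()
  for (fs in db$entries) {
    if (!can_possibly_match(ref_types, ref_dmat, fs, dist_tol)) next
    asg <- match_assignments(ref_types, ref_dmat, fs, dist_tol)
    if (length(asg) == 0L) next
    best <- NULL
    for (a in asg) {
      mov <- feature_coords(fs)[a, , drop = FALSE]
      al <- align_to_reference(ref_xyz, mov)
      if (is.null(best) || al$rmsd < best$alignment$rmsd)
        best <- list(featureset = fs, assignment = a, alignment = al)
    }
    # direction cosines between hypothesis vectors and rotated match vectors
    cosines <- numeric(0)
    for (i in seq_along(h$sites)) {
      rd <- ref_dirs[[i]]
      md <- best$featureset$features[[best$assignment[i]]]$direction
      if (is.null(rd) || is.null(md)) next
      cs <- sum(rd * as.numeric(best$alignment$rotation %*% md))
      if (h$sites[[i]]$type == "R") cs <- abs(cs)
      cosines <- c(cosines, cs)
    }
    vec_cos <- if (length(cosines) == 0L) 1.0 else mean(cosines)
    vol <- volume_score(list(ref_xyz, aligned_site_coords(best)))
    fit <- fitness_score(best$alignment, vec_cos, vol, dist_tol)
    hits[[length(hits) + 1L]] <-
      list(molecule_id = fs$molecule_id, conformer_id = fs$conformer_id,
           rmsd = best$alignment$rmsd, vec_cos = vec_cos, vol_jaccard = vol,
           fitness = fit, assignment = best$assignment,
           alignment = best$alignment)
  }
  if (length(hits) == 0L) {
    out <- data.frame(molecule_id = character(0), conformer_id = integer(0),
                      rmsd = numeric(0), vec_cos = numeric(0),
                      vol_jaccard = numeric(0), fitness = numeric(0))
    class(out) <- c("phk_matches", class(out))
    return(out)
  }
  # best conformer per molecule
  ids <- vapply(hits, `[[`, character(1), "molecule_id")
  fit <- vapply(hits, `[[`, numeric(1), "fitness")
  rmsd <- vapply(hits, `[[`, numeric(1), "rmsd")
  best_idx <- vapply(split(seq_along(hits), ids), function(idx) {
    idx[order(-fit[idx], rmsd[idx])][1L]
  }, integer(1))
  hits <- hits[best_idx]
  fit <- fit[best_idx]; rmsd <- rmsd[best_idx]
  ids <- ids[best_idx]
  ord <- order(-fit, rmsd, ids)
  hits <- hits[ord]
  if (is.finite(top_n)) hits <- utils::head(hits, top_n)
  out <- do.call(rbind, lapply(hits, function(hh) {
    data.frame(molecule_id = hh$molecule_id, conformer_id = hh$conformer_id,
               rmsd = hh$rmsd, vec_cos = hh$vec_cos,
               vol_jaccard = hh$vol_jaccard, fitness = hh$fitness,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "details") <- lapply(hits, function(hh)
    hh[c("assignment", "alignment")])
  class(out) <- c("phk_matches", class(out))
  out
}
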