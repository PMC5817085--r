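# Common-pharmacophore hypothesis discovery, survival scoring and filtering.

#' Default survival-score weights
#'
#' Site, vector, volume and reward weights default to 1.0 and the
#' selectivity weight to 0.0. The matches reward is `w_rew * reward(m)`
#' where `m` is the number of matching actives minus one; `reward_mode`
#' `"linear"` uses `reward(m) = m` (the equation's literal reward term) and
#' `"unit"` uses `reward(m) = min(m, 1)`, which caps the contribution of the
#' reward at 1 for any hypothesis matched by at least two actives.
#'
#' @param w_site,w_vec,w_vol,w_sel,w_rew Component weights.
#' @param reward_mode `"linear"` (default) or `"unit"`.
#' @return List of class `phk_weights`.
#' @export
weight_set <- function(w_site = 1, w_vec = 1, w_vol = 1, w_sel = 0,
                       w_rew = 1, reward_mode = c("linear", "unit")) {
  reward_mode <- match.arg(reward_mode)
  structure(list(w_site = w_site, w_vec = w_vec, w_vol = w_vol,
                 w_sel = w_sel, w_rew = w_rew, reward_mode = reward_mode),
            class = "phk_weights")
}

reward_term <- function(m, mode) {
  if (m < 0) stop("match count m must be >= 0")
  switch(mode, linear = m, unit = min(m, 1), stop("unknown reward mode"))
}

#' Assemble a survival score from component scores
#'
#' `S = w_site*s_site + w_vec*s_vec + w_vol*s_vol + w_sel*s_sel +
#' w_rew*reward(m)`.
#'
#' @param s_site,s_vec,s_vol,s_sel Component scores.
#' @param m Number of matching actives minus one.
#' @param weights A [weight_set].
#' @return The survival score (numeric scalar).
#' @export
survival_score <- function(s_site, s_vec, s_vol, s_sel = 0, m = 0,
                           weights = weight_set()) {
  weights$w_site * s_site + weights$w_vec * s_vec + weights$w_vol * s_vol +
    weights$w_sel * s_sel + weights$w_rew * reward_term(m, weights$reward_mode)
}

new_hypothesis <- function(variant, sites, source_molecule, source_conformer,
                           feature_indices, matched_actives) {
  structure(list(variant = variant, sites = sites,
                 source_molecule = source_molecule,
                 source_conformer = source_conformer,
                 feature_indices = feature_indices,
                 matched_actives = matched_actives),
            class = "phk_hypothesis")
}

#' @export
print.phk_hypothesis <- function(x, ...) {
  cat(sprintf("<phk_hypothesis> %s from %s (conformer %d), %d matched actives\n",
              x$variant, x$source_molecule, x$source_conformer,
              length(x$matched_actives)))
  invisible(x)
}

hypothesis_coords <- function(h) do.call(rbind, lapply(h$sites, `[[`, "point"))
hypothesis_types <- function(h) vapply(h$sites, `[[`, character(1), "type")

#' Discover common pharmacophore arrangements for one variant
#'
#' Searches the active ligands for k-site subsets (k = nchar(variant), site
#' types matching the variant letters) whose inter-site distance pattern is
#' shared by at least `min_match` actives. Two arrangements are considered
#' shared when a type-preserving site assignment exists with every inter-site
#' distance agreeing within `bin_width` Angstrom (equivalent to binning
#' distances at `bin_width` with neighbor-bin probing, without the bin-edge
#' sensitivity). One feature set per molecule is expected (the best
#' conformer); if several conformers of a molecule are supplied only the
#' first is used.
#'
#' @param actives List of [feature_set] objects (one conformer per molecule).
#' @param variant Variant string, e.g. `"ADPRR"`.
#' @param min_match Minimum number of active molecules sharing the
#'   arrangement (the source molecule counts).
#' @param bin_width Distance tolerance / bin width in Angstrom.
#' @return List of `phk_hypothesis` objects (possibly empty).
#' @export
find_common_pharmacophores <- function(actives, variant, min_match,
                                       bin_width = 1.0) {
  if (bin_width <= 0) stop("bin_width must be positive")
  mol_ids <- vapply(actives, function(a) a$molecule_id, character(1))
  actives <- actives[!duplicated(mol_ids)]
  mol_ids <- mol_ids[!duplicated(mol_ids)]
  if (min_match > length(actives))
    stop("min_match exceeds the number of active molecules")
  lets <- variant_letters(variant)
  variant <- paste(lets, collapse = "")
  out <- list()
  for (si in seq_along(actives)) {
    src <- actives[[si]]
    subsets <- enumerate_typed_subsets(src, variant)
    if (length(subsets) == 0L) next
    xyz_all <- feature_coords(src)
    for (sub in subsets) {
      ref_xyz <- xyz_all[sub, , drop = FALSE]
      ref_dmat <- coord_dist(ref_xyz)
      matched <- character(0)
      # count molecules sharing this arrangement; early exit when even
      # matching all remaining molecules cannot reach min_match
      for (mi in seq_along(actives)) {
        remaining <- length(actives) - mi + 1L
        if (length(matched) + remaining < min_match) break
        fs <- actives[[mi]]
        if (mi == si) { matched <- c(matched, mol_ids[mi]); next }
        if (!can_possibly_match(lets, ref_dmat, fs, bin_width)) next
        hit <- match_assignments(lets, ref_dmat, fs, bin_width,
                                 first_only = TRUE)
        if (length(hit)) matched <- c(matched, mol_ids[mi])
      }
      if (length(matched) >= min_match) {
        sites <- src$features[sub]
        out[[length(out) + 1L]] <- new_hypothesis(
          variant, sites, src$molecule_id, src$conformer_id, sub, matched)
      }
    }
  }
  out
}

#' Align matched actives onto a hypothesis
#'
#' For each active that matches the hypothesis, finds the type-preserving
#' site assignment within `tol` minimizing the superposition RMSD, and
#' returns the Kabsch alignment together with the matched site features.
#'
#' @param h A `phk_hypothesis`.
#' @param actives List of [feature_set] objects.
#' @param tol Distance tolerance in Angstrom used for assignment search.
#' @return List of entries `list(featureset, assignment, alignment)`,
#'   one per active with at least one valid assignment.
#' @export
align_matched_actives <- function(h, actives, tol = 1.0) {
  ref_xyz <- hypothesis_coords(h)
  ref_types <- hypothesis_types(h)
  ref_dmat <- coord_dist(ref_xyz)
  out <- list()
  for (fs in actives) {
    asg <- match_assignments(ref_types, ref_dmat, fs, tol)
    if (length(asg) == 0L) next
    best <- NULL
    for (a in asg) {
      mov <- feature_coords(fs)[a, , drop = FALSE]
      al <- align_to_reference(ref_xyz, mov)
      if (is.null(best) || al$rmsd < best$alignment$rmsd)
        best <- list(featureset = fs, assignment = a, alignment = al)
    }
    out[[length(out) + 1L]] <- best
  }
  out
}

# matched site coordinates of an aligned active, mapped into the reference
# frame (rows paired with the hypothesis sites)
aligned_site_coords <- function(entry) {
  mov <- feature_coords(entry$featureset)[entry$assignment, , drop = FALSE]
  sweep(mov %*% t(entry$alignment$rotation), 2,
        -entry$alignment$translation)
}

# union-of-spheres occupancy on a shared grid; rows = structures
sphere_occupancy <- function(coord_list, radius = 1.7, spacing = 0.25) {
  all_pts <- do.call(rbind, coord_list)
  lo <- apply(all_pts, 2, min) - radius - spacing
  hi <- apply(all_pts, 2, max) + radius + spacing
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  r2 <- radius^2
  occ <- matrix(FALSE, length(coord_list), nrow(grid))
  for (i in seq_along(coord_list)) {
    pts <- coord_list[[i]]
    inside <- rep(FALSE, nrow(grid))
    for (p in seq_len(nrow(pts))) {
      d2 <- (grid[, 1] - pts[p, 1])^2 + (grid[, 2] - pts[p, 2])^2 +
        (grid[, 3] - pts[p, 3])^2
      inside <- inside | (d2 <= r2)
    }
    occ[i, ] <- inside
  }
  occ
}

# mean pairwise Jaccard of union-of-spheres volumes
volume_score <- function(coord_list, radius = 1.7, spacing = 0.25) {
  n <- length(coord_list)
  if (n < 2L) return(1.0)
  occ <- sphere_occupancy(coord_list, radius, spacing)
  jac <- numeric(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- sum(occ[i, ] & occ[j, ])
    uni <- sum(occ[i, ] | occ[j, ])
    jac <- c(jac, if (uni == 0L) 0 else inter / uni)
  }
  mean(jac)
}

#' Score a hypothesis with the survival function
#'
#' Component scores: `s_site` is the mean over aligned actives of
#' `max(0, 1 - rmsd/rmsd_cutoff)` (a linear ramp mapping superposition RMSD
#' to \[0,1\]); `s_vec` averages the cosine of the angles between paired
#' direction vectors of matched vector features after alignment, clipped to
#' \[0,1\]; `s_vol` is the mean pairwise Jaccard overlap of union-of-spheres
#' volumes (1.7 Angstrom spheres at the matched sites, 0.25 Angstrom grid);
#' `s_sel = max(0, -log10(fraction of background sets matching))` when a
#' background is supplied, else 0. The survival score is the weighted sum
#' plus the matches reward.
#'
#' @param h A `phk_hypothesis`.
#' @param aligned Output of [align_matched_actives] (must be non-empty).
#' @param weights A [weight_set].
#' @param rmsd_cutoff RMSD (Angstrom) at which the site score reaches 0.
#' @param background Optional list of [feature_set] objects used for the
#'   selectivity score (e.g. a decoy or universal set).
#' @param tol Assignment tolerance for the background match fraction.
#' @return List of class `phk_score` with the component scores, `m`,
#'   `survival` and `max_pairwise_rmsd` across aligned actives.
#' @export
score_hypothesis <- function(h, aligned, weights = weight_set(),
                             rmsd_cutoff = 2.0, background = NULL,
                             tol = 1.0) {
  if (length(aligned) == 0L)
    stop("cannot score a hypothesis with no aligned actives")
  rmsds <- vapply(aligned, function(e) e$alignment$rmsd, numeric(1))
  s_site <- mean(pmax(0, 1 - rmsds / rmsd_cutoff))

  # vector score: paired direction cosines after rotation into the ref frame
  ref_dirs <- lapply(h$sites, `[[`, "direction")
  cosines <- numeric(0)
  for (e in aligned) {
    rot <- e$alignment$rotation
    for (i in seq_along(h$sites)) {
      rd <- ref_dirs[[i]]
      md <- e$featureset$features[[e$assignment[i]]]$direction
      if (is.null(rd) || is.null(md)) next
      cs <- sum(rd * as.numeric(rot %*% md))
      # ring normals are sign-ambiguous: a ring plane matched upside down is
      # the same plane
      if (h$sites[[i]]$type == "R") cs <- abs(cs)
      cosines <- c(cosines, cs)
    }
  }
  s_vec <- if (length(cosines) == 0L) 1.0 else
    min(1, max(0, mean(cosines)))

  coords <- lapply(aligned, aligned_site_coords)
  s_vol <- volume_score(coords)

  s_sel <- 0
  if (!is.null(background) && length(background) > 0L) {
    ref_dmat <- coord_dist(hypothesis_coords(h))
    ref_types <- hypothesis_types(h)
    nm <- sum(vapply(background, function(fs) {
      can_possibly_match(ref_types, ref_dmat, fs, tol) &&
        length(match_assignments(ref_types, ref_dmat, fs, tol,
                                 first_only = TRUE)) > 0L
    }, logical(1)))
    # pseudo-count when nothing matches: selectivity is bounded by what the
    # background size can resolve
    frac <- max(nm, 0.5) / length(background)
    s_sel <- max(0, -log10(frac))
  }

  m <- length(h$matched_actives) - 1L

  # pairwise superposition spread across aligned actives in the ref frame
  maxp <- 0
  if (length(coords) >= 2L) {
    for (i in seq_len(length(coords) - 1L)) for (j in (i + 1L):length(coords))
      maxp <- max(maxp, paired_rmsd(coords[[i]], coords[[j]]))
  }

  structure(list(s_site = s_site, s_vec = s_vec, s_vol = s_vol, s_sel = s_sel,
                 m = m,
                 survival = survival_score(s_site, s_vec, s_vol, s_sel, m,
                                           weights),
                 max_pairwise_rmsd = maxp),
            class = "phk_score")
}

#' Filter and rank scored hypotheses
#'
#' Retains hypotheses whose aligned actives stay mutually superposable
#' (maximum pairwise RMSD below `rmsd_max`) and whose vector score exceeds
#' `svec_min`; ranks by survival score descending, ties broken by site score
#' then variant string.
#'
#' @param candidates List of entries `list(hypothesis, score)` (any extra
#'   elements are carried through).
#' @param rmsd_max RMSD retention threshold in Angstrom (default 1.20).
#' @param svec_min Vector-score retention threshold (default 0.50).
#' @return The retained entries, sorted.
#' @export
filter_hypotheses <- function(candidates, rmsd_max = 1.20, svec_min = 0.50) {
  if (length(candidates) == 0L) return(list())
  keep <- vapply(candidates, function(e) {
    e$score$max_pairwise_rmsd < rmsd_max && e$score$s_vec > svec_min
  }, logical(1))
  retained <- candidates[keep]
  if (length(retained) == 0L) return(list())
  surv <- vapply(retained, function(e) e$score$survival, numeric(1))
  site <- vapply(retained, function(e) e$score$s_site, numeric(1))
  var <- vapply(retained, function(e) e$hypothesis$variant, character(1))
  retained[order(-surv, -site, var)]
}

#' Run the full hypothesis pipeline
#'
#' Enumerates variants from the pooled per-type feature counts, searches for
#' common arrangements from the largest site count down (a hypothesis with
#' more sites is preferred; smaller variants are only considered when no
#' larger variant yields a retained hypothesis), aligns and scores the
#' candidates, and filters them.
#'
#' @param actives List of [feature_set] objects (best conformer per
#'   molecule).
#' @param k_min,k_max Minimum and maximum number of hypothesis sites
#'   (defaults 4 and 7).
#' @param min_match Minimum number of actives that must share an arrangement.
#' @param bin_width Distance tolerance (Angstrom) for arrangement sharing.
#' @param weights A [weight_set].
#' @param background Optional background sets for the selectivity score.
#' @param rmsd_max,svec_min Retention thresholds (see [filter_hypotheses]).
#' @return List of class `phk_hypotheses` with elements `results` (sorted
#'   retained entries) and `summary` (data frame: variant, source, matches,
#'   component scores, survival).
#' @export
discover_hypotheses <- function(actives, k_min = 4L, k_max = 7L, min_match,
                                bin_width = 1.0, weights = weight_set(),
                                background = NULL, rmsd_max = 1.20,
                                svec_min = 0.50) {
  counts_per <- lapply(actives, function(fs) table(feature_types(fs)))
  pooled <- integer(length(FEATURE_TYPES)); names(pooled) <- FEATURE_TYPES
  for (tb in counts_per)
    for (ty in names(tb)) pooled[ty] <- max(pooled[ty], tb[[ty]])

  results <- list()
  for (k in seq(k_max, k_min)) {
    variants <- enumerate_variants(pooled, k, k)
    cands <- list()
    for (v in variants) {
      hyps <- find_common_pharmacophores(actives, v, min_match, bin_width)
      # one hypothesis per source molecule per variant: keep the one whose
      # aligned actives superpose most tightly
      if (length(hyps) == 0L) next
      for (h in hyps) {
        aligned <- align_matched_actives(h, actives, tol = bin_width)
        sc <- score_hypothesis(h, aligned, weights, background = background,
                               tol = bin_width)
        cands[[length(cands) + 1L]] <-
          list(hypothesis = h, score = sc, aligned = aligned)
      }
    }
    cands <- dedup_per_source(cands)
    results <- filter_hypotheses(cands, rmsd_max, svec_min)
    if (length(results) > 0L) break
  }

  summary <- if (length(results) == 0L) {
    data.frame(variant = character(0), source_molecule = character(0),
               n_matched = integer(0), s_site = numeric(0),
               s_vec = numeric(0), s_vol = numeric(0), s_sel = numeric(0),
               m = integer(0), survival = numeric(0),
               max_pairwise_rmsd = numeric(0))
  } else {
    do.call(rbind, lapply(results, function(e) {
      data.frame(variant = e$hypothesis$variant,
                 source_molecule = e$hypothesis$source_molecule,
                 n_matched = length(e$hypothesis$matched_actives),
                 s_site = e$score$s_site, s_vec = e$score$s_vec,
                 s_vol = e$score$s_vol, s_sel = e$score$s_sel,
                 m = e$score$m, survival = e$score$survival,
                 max_pairwise_rmsd = e$score$max_pairwise_rmsd,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(results = results, summary = summary),
            class = "phk_hypotheses")
}

# keep, per (variant, source molecule), the candidate with the lowest
# mean alignment RMSD; different subsets of one molecule usually describe
# the same underlying arrangement
dedup_per_source <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  key <- vapply(cands, function(e)
    paste(e$hypothesis$variant, e$hypothesis$source_molecule), character(1))
  split_idx <- split(seq_along(cands), key)
  picked <- vapply(split_idx, function(idx) {
    meanr <- vapply(idx, function(i)
      mean(vapply(cands[[i]]$aligned, function(a) a$alignment$rmsd,
                  numeric(1))), numeric(1))
    idx[which.min(meanr)]
  }, integer(1))
  cands[sort(picked)]
}

#' @export
print.phk_hypotheses <- function(x, ...) {
  cat(sprintf("<phk_hypotheses> %d retained hypotheses\n", length(x$results)))
  if (nrow(x$summary)) print(utils::head(x$summary, 10))
  invisible(x)
}
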