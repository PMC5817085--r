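# Receptor-ligand interface annotation: hydrogen bonds by geometric
# criteria, hydrophobic contacts, and per-residue interaction tables in the
# style of docking reports.

POLAR_ELEMENTS <- c("N", "O", "S")

#' Parse a receptor-ligand complex from a PDB file
#'
#' Atoms are partitioned into receptor and ligand by the ligand selector
#' (a HETATM residue name, or a chain when `by = "chain"`). Elements are
#' taken from the element column when present and inferred from atom names
#' otherwise.
#'
#' @param pdb_file PDB path.
#' @param ligand_selector Residue name (e.g. `"LIG"`) or chain id.
#' @param by `"resid"` (default) or `"chain"`.
#' @return List of class `phk_complex` with data frames `receptor` and
#'   `ligand` (columns: eleno, elety, element, resid, resno, chain, x, y,
#'   z).
#' @export
parse_complex <- function(pdb_file, ligand_selector, by = c("resid",
                                                            "chain")) {
  by <- match.arg(by)
  pdb <- bio3d::read.pdb(pdb_file)
  at <- pdb$atom
  if (anyDuplicated(at$eleno))
    warning("duplicate atom serial numbers kept as-is")
  element <- at$elesy
  blank <- is.na(element) | element == ""
  # infer from the atom-name column: strip digits/primes, take the leading
  # letters; names like "CA" are carbon, " N" nitrogen
  infer <- function(nm) {
    nm <- gsub("[0-9']", "", trimws(nm))
    if (nchar(nm) == 0L) return(NA_character_)
    two <- substr(nm, 1, 2)
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN"))
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    substr(nm, 1, 1)
  }
  element[blank] <- vapply(at$elety[blank], infer, character(1))
  df <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                   element = toupper(trimws(element)), resid = at$resid,
                   resno = at$resno, chain = at$chain, x = at$x, y = at$y,
                   z = at$z, type = at$type, stringsAsFactors = FALSE)
  is_lig <- if (by == "resid") df$type == "HETATM" &
    df$resid == ligand_selector else df$chain == ligand_selector
  if (!any(is_lig))
    stop("no ligand atoms match selector '", ligand_selector, "'")
  structure(list(receptor = df[!is_lig, , drop = FALSE],
                 ligand = df[is_lig, , drop = FALSE]),
            class = "phk_complex")
}

#' @export
print.phk_complex <- function(x, ...) {
  cat(sprintf("<phk_complex> receptor %d atoms, ligand %d atoms\n",
              nrow(x$receptor), nrow(x$ligand)))
  invisible(x)
}

atom_xyz <- function(df) as.matrix(df[, c("x", "y", "z")])

residue_label <- function(df, i) {
  rn <- df$resid[i]
  # Arg224-style labels: title-case three-letter residue codes
  lab <- paste0(substr(rn, 1, 1), tolower(substr(rn, 2, nchar(rn))))
  paste0(lab, df$resno[i])
}

# bonded pairs within a set of atoms: input CONECT-style bonds are rare in
# complex files, so fall back on a distance heuristic
connectivity <- function(df, cutoff = 1.9) {
  xyz <- atom_xyz(df)
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(xyz))
  idx <- which(d > 0 & d <= cutoff, arr.ind = TRUE)
  idx[idx[, 1] < idx[, 2], , drop = FALSE]
}

hydrogens_bound_to <- function(df, bonds, i) {
  nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  nb[df$element[nb] == "H"]
}

#' Find interface hydrogen bonds
#'
#' Donor-H...acceptor pairs across the receptor/ligand interface with
#' heavy-atom (donor-acceptor) distance at most `d_max` and D-H...A angle at
#' least `angle_min` degrees. Donors are N/O/S atoms with a bound hydrogen;
#' acceptors are N/O/S heavy atoms. When the complex carries no explicit
#' hydrogens at all (an unprotonated file), the heavy-atom distance
#' criterion alone applies and records are flagged `no_h`; in a protonated
#' complex, polar atoms without a bound hydrogen act only as acceptors.
#'
#' @param cx A [parse_complex] result.
#' @param d_max Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param angle_min Minimum D-H...A angle in degrees (default 120).
#' @return Data frame of contact records: kind, residue, donor_side,
#'   distance, angle (NA when no hydrogen), no_h flag.
#' @export
find_hbonds <- function(cx, d_max = 3.5, angle_min = 120) {
  rec <- cx$receptor; lig <- cx$ligand
  has_h <- any(c(rec$element, lig$element) == "H")
  out <- list()
  sides <- list(list(don = rec, acc = lig, donor_side = "receptor"),
                list(don = lig, acc = rec, donor_side = "ligand"))
  for (s in sides) {
    don <- s$don; acc <- s$acc
    bonds <- connectivity(don)
    d_idx <- which(don$element %in% POLAR_ELEMENTS)
    a_idx <- which(acc$element %in% POLAR_ELEMENTS)
    if (!length(d_idx) || !length(a_idx)) next
    for (i in d_idx) {
      hs <- hydrogens_bound_to(don, bonds, i)
      for (j in a_idx) {
        dv <- c(acc$x[j] - don$x[i], acc$y[j] - don$y[i],
                acc$z[j] - don$z[i])
        dist <- sqrt(sum(dv^2))
        if (dist > d_max) next
        if (length(hs)) {
          for (h in hs) {
            hv <- c(don$x[h], don$y[h], don$z[h])
            v1 <- c(don$x[i], don$y[i], don$z[i]) - hv
            v2 <- c(acc$x[j], acc$y[j], acc$z[j]) - hv
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       sqrt(sum(v1^2) * sum(v2^2))))) *
              180 / pi
            if (ang >= angle_min) {
              ridx <- if (s$donor_side == "receptor") i else j
              rdf <- if (s$donor_side == "receptor") don else acc
              out[[length(out) + 1L]] <- data.frame(
                kind = "hbond", residue = residue_label(rdf, ridx),
                donor_side = s$donor_side, distance = dist, angle = ang,
                no_h = FALSE, stringsAsFactors = FALSE)
            }
          }
        } else if (!has_h) {
          ridx <- if (s$donor_side == "receptor") i else j
          rdf <- if (s$donor_side == "receptor") don else acc
          out[[length(out) + 1L]] <- data.frame(
            kind = "hbond", residue = residue_label(rdf, ridx),
            donor_side = s$donor_side, distance = dist, angle = NA_real_,
            no_h = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), residue = character(0),
                      donor_side = character(0), distance = numeric(0),
                      angle = numeric(0), no_h = logical(0)))
  res <- do.call(rbind, out)
  res[order(res$residue, res$distance), , drop = FALSE]
}

#' Find interface hydrophobic contacts
#'
#' Apolar carbon (and sulfur) atoms across the interface within `d_max`,
#' one record per atom pair. Carbons bonded to N or O (polar-adjacent) are
#' excluded, using input connectivity when present, otherwise a 1.9 Angstrom
#' bonding heuristic.
#'
#' @param cx A [parse_complex] result.
#' @param d_max Distance cutoff in Angstrom (default 4.5).
#' @return Data frame of contact records: kind, residue, distance.
#' @export
find_hydrophobic <- function(cx, d_max = 4.5) {
  apolar_idx <- function(df) {
    bonds <- connectivity(df)
    keep <- which(df$element %in% c("C", "S"))
    Filter(function(i) {
      nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
      !any(df$element[nb] %in% c("N", "O"))
    }, keep)
  }
  ri <- apolar_idx(cx$receptor)
  li <- apolar_idx(cx$ligand)
  out <- list()
  for (i in ri) for (j in li) {
    dv <- c(cx$ligand$x[j] - cx$receptor$x[i],
            cx$ligand$y[j] - cx$receptor$y[i],
            cx$ligand$z[j] - cx$receptor$z[i])
    dist <- sqrt(sum(dv^2))
    if (dist <= d_max)
      out[[length(out) + 1L]] <- data.frame(
        kind = "hydrophobic", residue = residue_label(cx$receptor, i),
        distance = dist, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(kind = character(0), residue = character(0),
                      distance = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$residue, res$distance), , drop = FALSE]
}

#' Summarize contacts per residue
#'
#' Deduplicates residues per contact kind and formats them in interaction-
#' table style ("Arg224, Asp397, ..."), sorted by residue number.
#'
#' @param records Data frame(s) from [find_hbonds] / [find_hydrophobic]
#'   (rbind-compatible subsets of their columns).
#' @return Data frame with one row per kind: kind, n_residues, residues.
#' @export
interaction_table <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, function(r)
      r[, c("kind", "residue"), drop = FALSE]))
  if (!nrow(records))
    return(data.frame(kind = character(0), n_residues = integer(0),
                      residues = character(0)))
  split_recs <- split(records$residue, records$kind)
  do.call(rbind, lapply(names(split_recs), function(k) {
    resn <- unique(split_recs[[k]])
    num <- as.integer(gsub("[^0-9]", "", resn))
    resn <- resn[order(num)]
    data.frame(kind = k, n_residues = length(resn),
               residues = paste(resn, collapse = ", "),
               stringsAsFactors = FALSE)
  }))
}
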