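# Chemistry adapter: perceive typed pharmacophore features on 3D molecules
# via SMARTS matching (OpenBabel through ChemmineOB) and geometry rules.
# The abstract site-set JSON is the canonical pipeline representation; this
# adapter turns SDF/SMILES input into it. Requires the suggested packages
# ChemmineR and ChemmineOB.

require_chemistry <- function() {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("feature perception requires the ChemmineOB package")
}

# SMARTS matching with atom maps. ChemmineOB exports only match counts, so
# the OpenBabel bindings are driven directly: returns a list of 1-based atom
# index vectors, one per symmetry-unique match, in OpenBabel order.
ob_smarts_matches <- function(molblock, smarts) {
  require_chemistry()
  ns <- getNamespace("ChemmineOB")
  conv <- get("OBConversion", ns)(get("istreamFromString", ns)(molblock))
  if (!get("OBConversion_SetInFormat", ns)(conv, "SDF"))
    stop("OpenBabel rejected the SDF input format")
  mol <- get("OBMol", ns)()
  if (!get("OBConversion_Read", ns)(conv, mol))
    stop("OpenBabel failed to read the molecule block")
  sp <- get("OBSmartsPattern", ns)()
  if (!get("OBSmartsPattern_Init", ns)(sp, smarts))
    stop("syntactically invalid SMARTS pattern: ", smarts)
  get("OBSmartsPattern_Match", ns)(sp, mol)
  maps <- get("OBSmartsPattern_GetUMapList", ns)(sp)
  lapply(maps, as.integer)
}

#' Load the default SMARTS feature table
#'
#' The table maps each feature type to one or more SMARTS patterns with a
#' geometry rule (`point`, `vector`, `group` or `ring`). It is a documented,
#' user-replaceable default.
#'
#' @param path JSON table path (default: the bundled table).
#' @return List of class `phk_smarts_table`.
#' @export
default_smarts_table <- function(path = system.file("extdata",
                                                    "feature_smarts.json",
                                                    package = "phorekin")) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(doc$entries, function(e) {
    if (!e$type %in% FEATURE_TYPES)
      stop("SMARTS table entry with unknown feature type: ", e$type)
    if (!e$geometry %in% c("point", "vector", "group", "ring"))
      stop("SMARTS table entry with unknown geometry rule: ", e$geometry)
    list(type = e$type, smarts = e$smarts, geometry = e$geometry,
         centroid_atoms = as.integer(unlist(e$centroid_atoms)))
  })
  missing <- setdiff(FEATURE_TYPES, vapply(entries, `[[`, character(1),
                                           "type"))
  if (length(missing))
    stop("SMARTS table lacks entries for types: ",
         paste(missing, collapse = ", "))
  structure(list(entries = entries), class = "phk_smarts_table")
}

new_molecule <- function(id, elements, xyz, bonds, molblock) {
  structure(list(id = id, elements = elements, xyz = xyz, bonds = bonds,
                 molblock = molblock),
            class = "phk_molecule")
}

#' @export
print.phk_molecule <- function(x, ...) {
  cat(sprintf("<phk_molecule> %s: %d atoms, %d bonds\n", x$id,
              nrow(x$xyz), nrow(x$bonds)))
  invisible(x)
}

# split an SDF file/text into per-molecule V2000 blocks
split_sdf_blocks <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) paste(lines[s:e], collapse = "\n"), starts, ends)
}

parse_molblock <- function(block, fallback_id) {
  ln <- strsplit(block, "\n")[[1]]
  id <- trimws(ln[1])
  if (!nzchar(id)) id <- fallback_id
  counts <- ln[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- ln[4 + seq_len(na)]
  xyz <- matrix(0, na, 3)
  elements <- character(na)
  for (i in seq_len(na)) {
    xyz[i, ] <- as.numeric(c(substr(atoms[i], 1, 10),
                             substr(atoms[i], 11, 20),
                             substr(atoms[i], 21, 30)))
    elements[i] <- trimws(substr(atoms[i], 31, 34))
  }
  bonds <- matrix(0L, nb, 2)
  if (nb > 0L) {
    brows <- ln[4 + na + seq_len(nb)]
    for (i in seq_len(nb))
      bonds[i, ] <- as.integer(c(substr(brows[i], 1, 3),
                                 substr(brows[i], 4, 6)))
  }
  new_molecule(id, elements, xyz, bonds, block)
}

#' Read molecules from a 3D SDF file
#'
#' @param path SDF (V2000) file; every record needs 3D coordinates.
#' @return List of `phk_molecule` objects.
#' @export
read_sdf_molecules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split_sdf_blocks(lines)
  mols <- Map(function(b, i) parse_molblock(b, sprintf("mol_%03d", i)),
              blocks, seq_along(blocks))
  unname(mols)
}

#' Build molecules from SMILES with generated 3D coordinates
#'
#' Embeds a single conformer per SMILES with OpenBabel's coordinate
#' generation. Conformer quality is not a goal of this adapter; for real
#' screening supply pre-generated multi-conformer SDF input.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Molecule ids (default `smi_1`, `smi_2`, ...).
#' @return List of `phk_molecule` objects.
#' @export
smiles_to_molecules <- function(smiles,
                                ids = sprintf("smi_%d", seq_along(smiles))) {
  require_chemistry()
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf <- ChemmineOB::convertFormat(
      "SMI", "SDF", smiles[i],
      options = data.frame(names = "gen3d", args = "",
                           stringsAsFactors = FALSE))
    out[[i]] <- parse_molblock(sdf, ids[i])
    out[[i]]$id <- ids[i]
  }
  out
}

mol_neighbors <- function(mol, i) {
  c(mol$bonds[mol$bonds[, 1] == i, 2], mol$bonds[mol$bonds[, 2] == i, 1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) NULL else v / n
}

# plane normal of a point set (smallest principal direction)
plane_normal <- function(pts) {
  c0 <- sweep(pts, 2, colMeans(pts))
  sv <- svd(c0)
  unit(sv$v[, 3])
}

#' Perceive pharmacophore features on a molecule
#'
#' Runs every SMARTS entry of the table against the molecule and converts
#' the matches to typed sites: `point` entries yield one feature per match
#' at the matched-atom centroid; `vector` entries add a direction (donors:
#' from the heavy atom through each attached explicit hydrogen, one feature
#' per hydrogen; acceptors: the idealized lone-pair bisector, opposite the
#' mean bond direction); `group` entries are clustered into bonded connected
#' components placed at their centroid; `ring` entries sit at the ring
#' centroid with the ring-plane normal as direction. Matched hydrogens never
#' carry features themselves. Output order follows the table, then the first
#' matched atom index, making perception deterministic.
#'
#' @param mol A `phk_molecule` with 3D coordinates.
#' @param table A [default_smarts_table] (or compatible) table.
#' @param conformer_id Conformer index recorded on the output.
#' @return A [feature_set] (possibly empty).
#' @export
perceive_features <- function(mol, table = default_smarts_table(),
                              conformer_id = 0L) {
  if (!inherits(mol, "phk_molecule"))
    stop("mol must be a phk_molecule (see read_sdf_molecules)")
  if (nrow(mol$xyz) > 1L && all(mol$xyz == 0))
    stop("molecule has no 3D coordinates (all-zero atom block)")
  feats <- list()
  add <- function(f) feats[[length(feats) + 1L]] <<- f

  for (entry in table$entries) {
    maps <- ob_smarts_matches(mol$molblock, entry$smarts)
    if (length(maps) == 0L) next
    maps <- maps[order(vapply(maps, `[[`, integer(1), 1L))]

    if (entry$geometry == "group" && length(entry$centroid_atoms) == 0L &&
        all(lengths(maps) == 1L)) {
      # cluster single-atom matches into bonded connected components
      atoms <- sort(unique(unlist(maps)))
      comp <- stats::setNames(seq_along(atoms), atoms)
      repeat {
        changed <- FALSE
        for (b in seq_len(nrow(mol$bonds))) {
          a1 <- as.character(mol$bonds[b, 1]); a2 <- as.character(mol$bonds[b, 2])
          if (a1 %in% names(comp) && a2 %in% names(comp) &&
              comp[a1] != comp[a2]) {
            comp[comp == comp[a2]] <- comp[a1]; changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (cc in unique(comp)) {
        idx <- as.integer(names(comp)[comp == cc])
        add(phk_feature(entry$type,
                        colMeans(mol$xyz[idx, , drop = FALSE]),
                        member_atoms = idx))
      }
      next
    }

    for (mp in maps) {
      cidx <- if (length(entry$centroid_atoms)) mp[entry$centroid_atoms]
              else mp
      centroid <- colMeans(mol$xyz[cidx, , drop = FALSE])
      if (entry$geometry == "ring") {
        nrm <- plane_normal(mol$xyz[mp, , drop = FALSE])
        if (is.null(nrm)) next
        add(phk_feature(entry$type, centroid, direction = nrm,
                        member_atoms = mp))
      } else if (entry$geometry == "vector") {
        atom <- mp[1L]
        nb <- mol_neighbors(mol, atom)
        hs <- nb[mol$elements[nb] == "H"]
        if (entry$type == "D" && length(hs)) {
          for (h in hs)
            add(phk_feature("D", mol$xyz[atom, ],
                            direction = unit(mol$xyz[h, ] - mol$xyz[atom, ]),
                            member_atoms = c(atom, h)))
        } else {
          dir <- NULL
          heavy <- nb[mol$elements[nb] != "H"]
          nb_all <- nb
          if (length(nb_all)) {
            vecs <- lapply(nb_all, function(j)
              unit(mol$xyz[j, ] - mol$xyz[atom, ]))
            vecs <- Filter(Negate(is.null), vecs)
            if (length(vecs)) dir <- unit(-Reduce(`+`, vecs))
          }
          add(phk_feature(entry$type, mol$xyz[atom, ], direction = dir,
                          member_atoms = atom))
        }
      } else {
        add(phk_feature(entry$type, centroid, member_atoms = cidx))
      }
    }
  }
  feature_set(mol$id, conformer_id, feats)
}

#' Apply a rigid transform to a molecule
#'
#' @param mol A `phk_molecule`.
#' @param rotation 3 x 3 proper rotation.
#' @param translation Length-3 vector.
#' @return The molecule with transformed coordinates (topology and the
#'   SMARTS-matching block are unchanged; matching is purely topological).
#' @export
transform_molecule <- function(mol, rotation, translation = c(0, 0, 0)) {
  mol$xyz <- sweep(mol$xyz %*% t(as.matrix(rotation)), 2, -translation)
  mol
}
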