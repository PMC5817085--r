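# Interface contact annotation on receptor-ligand complexes.

make_complex_lines <- function() {
  c(pdb_atom(1, "N", "ARG", "A", 224, 0, 0, 0, "N"),
    pdb_atom(2, "HN", "ARG", "A", 224, 1, 0, 0, "H"),
    pdb_atom(3, "CA", "ARG", "A", 224, -0.8, 1.2, 0, "C"),
    pdb_atom(4, "CB", "ARG", "A", 224, 0, 3, 0, "C"),
    pdb_atom(5, "O", "ARG", "A", 224, -2.2, 1.0, 0.8, "O"),
    pdb_atom(6, "C1", "LIG", "B", 1, 4.0, 3.0, 0, "C", het = TRUE),
    pdb_atom(7, "O1", "LIG", "B", 1, 2.9, 0, 0, "O", het = TRUE),
    pdb_atom(8, "C2", "LIG", "B", 1, 5.2, 3.8, 0.5, "C", het = TRUE))
}

test_that("complex parsing partitions atoms and infers elements", {
  f <- write_pdb(make_complex_lines())
  cx <- parse_complex(f, "LIG")
  expect_equal(nrow(cx$receptor), 5L)
  expect_equal(nrow(cx$ligand), 3L)
  expect_error(parse_complex(f, "XYZ"), "no ligand atoms")

  # blank element columns: inferred from atom names
  lines <- vapply(make_complex_lines(), function(l)
    paste0(substr(l, 1, 76), "  "), character(1))
  f2 <- write_pdb(lines)
  cx2 <- parse_complex(f2, "LIG")
  expect_equal(cx2$receptor$element, c("N", "H", "C", "C", "O"))
})

test_that("hydrogen bonds obey the distance and angle criteria", {
  f <- write_pdb(make_complex_lines())
  cx <- parse_complex(f, "LIG")
  hb <- find_hbonds(cx)
  expect_equal(nrow(hb), 1L)   # N-H...O1, collinear
  expect_equal(hb$residue, "Arg224")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  # acceptor beyond the cutoff
  lines <- make_complex_lines()
  lines[7] <- pdb_atom(7, "O1", "LIG", "B", 1, 4.0, 0, 0, "O", het = TRUE)
  hb2 <- find_hbonds(parse_complex(write_pdb(lines), "LIG"))
  expect_equal(nrow(hb2), 0L)

  # hydrogen displaced so the angle is 90 degrees
  lines <- make_complex_lines()
  lines[2] <- pdb_atom(2, "HN", "ARG", "A", 224, 0, 1, 0, "H")
  hb3 <- find_hbonds(parse_complex(write_pdb(lines), "LIG"))
  expect_equal(nrow(hb3), 0L)

  # unprotonated complex: distance-only records flagged no_h
  lines <- make_complex_lines()[-2]
  hb4 <- find_hbonds(parse_complex(write_pdb(lines), "LIG"))
  expect_gte(nrow(hb4), 1L)
  expect_true(all(hb4$no_h))
})

test_that("hydrophobic contacts respect the cutoff and polar adjacency", {
  f <- write_pdb(make_complex_lines())
  cx <- parse_complex(f, "LIG")
  hp <- find_hydrophobic(cx)
  # CB(0,3,0)-C1(4,3,0) at 4.0; CA is bonded to N -> excluded;
  # C2 is 5.3 from CB -> beyond cutoff
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$distance, 4.0, tolerance = 1e-6)

  lines <- make_complex_lines()
  lines[6] <- pdb_atom(6, "C1", "LIG", "B", 1, 5.0, 3, 0, "C", het = TRUE)
  lines[8] <- pdb_atom(8, "C2", "LIG", "B", 1, 9, 9, 9, "C", het = TRUE)
  hp2 <- find_hydrophobic(parse_complex(write_pdb(lines), "LIG"))
  expect_equal(nrow(hp2), 0L)
})

test_that("interaction tables deduplicate and sort by residue number", {
  recs <- data.frame(kind = c("hbond", "hbond", "hbond", "hydrophobic"),
                     residue = c("Arg224", "Arg224", "Asp397", "Leu96"))
  tab <- interaction_table(recs)
  expect_equal(tab$residues[tab$kind == "hbond"], "Arg224, Asp397")
  expect_equal(tab$n_residues[tab$kind == "hbond"], 2L)
  expect_equal(tab$residues[tab$kind == "hydrophobic"], "Leu96")
  expect_equal(nrow(interaction_table(recs[0, ])), 0L)
})

test_that("contact annotation is invariant under rigid motion of the complex", {
  f <- write_pdb(make_complex_lines())
  cx <- parse_complex(f, "LIG")
  hb1 <- find_hbonds(cx); hp1 <- find_hydrophobic(cx)

  R <- rotation_about_z(0.9); t <- c(5, -3, 7)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + t[1]; df$y <- xyz[, 2] + t[2]; df$z <- xyz[, 3] + t[3]
    df
  }
  cx2 <- cx; cx2$receptor <- move(cx$receptor); cx2$ligand <- move(cx$ligand)
  hb2 <- find_hbonds(cx2); hp2 <- find_hydrophobic(cx2)
  expect_equal(hb1$distance, hb2$distance, tolerance = 1e-9)
  expect_equal(hb1$angle, hb2$angle, tolerance = 1e-9)
  expect_equal(hp1$distance, hp2$distance, tolerance = 1e-9)
})

test_that("the bundled synthetic complex annotates as designed", {
  f <- system.file("extdata", "synthetic_complex.pdb", package = "phorekin")
  cx <- parse_complex(f, "LIG")
  tab <- interaction_table(list(find_hbonds(cx)[, c("kind", "residue")],
                                find_hydrophobic(cx)[, c("kind", "residue")]))
  expect_setequal(tab$kind, c("hbond", "hydrophobic"))
  expect_true(all(tab$residues == "Arg224"))
})
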