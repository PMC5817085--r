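# Screen database construction, geometric matching and fitness.

test_that("database construction counts and caps conformers", {
  sets <- unlist(lapply(1:3, function(m)
    lapply(0:1, function(c)
      random_fs(sprintf("mol%d", m), c("A", "D", "H"), conformer = c))),
    recursive = FALSE)
  db <- build_screen_db(sets)
  expect_length(db$entries, 6L)

  many <- lapply(seq_len(150) - 1L,
                 function(c) random_fs("big", c("A", "D"), conformer = c))
  db2 <- build_screen_db(many, max_confs = 100)
  expect_length(db2$entries, 100L)
  expect_equal(vapply(db2$entries, function(e) e$conformer_id, integer(1)),
               0:99)  # deterministic: input order

  # per-rotatable-bond cap applies only with supplied counts
  db3 <- build_screen_db(many, max_confs = 100,
                         rotatable_counts = c(big = 3L))
  expect_length(db3$entries, 30L)

  empty <- build_screen_db(list())
  expect_length(empty$entries, 0L)
})

test_that("a hypothesis matches its own source conformer perfectly", {
  actives <- lapply(1:3, function(i) {
    set.seed(i)
    fs_from_coords(sprintf("a%d", i), c("A", "D", "P", "R"),
                   rbind(c(0, 0, 0), c(4, 0, 0), c(1, 3, 0), c(2, 1, 3)) +
                     matrix(rnorm(12, 0, 0.05), 4, 3))
  })
  h <- find_common_pharmacophores(actives, "ADPR", 3, 1.0)[[1]]
  db <- build_screen_db(actives)
  res <- match_hypothesis(db, h, dist_tol = 2.0)
  expect_equal(nrow(res), 3L)
  self <- res[res$molecule_id == h$source_molecule, ]
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$fitness, 3.0, tolerance = 1e-9)
  expect_equal(res$fitness, sort(res$fitness, decreasing = TRUE))

  expect_error(match_hypothesis(db, list(sites = h$sites[1:2])),
               "at least 3")
})

test_that("matching against an empty database returns no hits", {
  fs <- fs_from_coords("m", c("A", "D", "P"),
                       rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  h <- find_common_pharmacophores(list(fs), "ADP", 1)[[1]]
  res <- match_hypothesis(build_screen_db(list()), h)
  expect_equal(nrow(res), 0L)
})

test_that("fitness combines alignment, vector and volume terms", {
  expect_equal(fitness_score(list(rmsd = 0), 1, 1, dist_tol = 2), 3.0)
  expect_equal(fitness_score(list(rmsd = 2), 0, 0, dist_tol = 2), 0.0)
  expect_equal(fitness_score(list(rmsd = 1), 0.5, 0.5, dist_tol = 2), 1.5)
  # clipping
  expect_equal(fitness_score(list(rmsd = 10), -0.3, 1.4, dist_tol = 2), 1.0)
})

test_that("matching is rigid-transform invariant and nests with tolerance", {
  set.seed(33)
  dat <- plant_pharmacophore(plant_spec(n_actives = 6, n_decoys = 10,
                                        seed = 33))
  hy <- discover_hypotheses(dat$actives, min_match = 6)
  h <- hy$results[[1]]$hypothesis
  db_sets <- c(dat$actives, dat$decoys)
  res1 <- match_hypothesis(build_screen_db(db_sets), h, dist_tol = 1.0)

  moved <- lapply(db_sets, function(fs)
    transform_feature_set(fs, phorekin:::random_rotation(),
                          runif(3, -10, 10)))
  res2 <- match_hypothesis(build_screen_db(moved), h, dist_tol = 1.0)
  expect_setequal(res1$molecule_id, res2$molecule_id)
  expect_equal(res1$rmsd[order(res1$molecule_id)],
               res2$rmsd[order(res2$molecule_id)], tolerance = 1e-6)

  # decreasing the tolerance never adds matches
  prev <- NULL
  for (tol in c(2.0, 1.5, 1.0, 0.5, 0.25)) {
    ids <- match_hypothesis(build_screen_db(db_sets), h,
                            dist_tol = tol)$molecule_id
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("matching equals brute-force assignment enumeration on small sets", {
  set.seed(8)
  for (rep in 1:10) {
    h_types <- c("A", "D", "P", "R")
    h_xyz <- matrix(runif(12, -4, 4), 4, 3)
    h <- list(variant = "ADPR",
              sites = lapply(1:4, function(i)
                phk_feature(h_types[i], h_xyz[i, ],
                            direction = if (h_types[i] == "R") c(0, 0, 1))),
              source_molecule = "ref", source_conformer = 0L,
              feature_indices = 1:4, matched_actives = "ref")
    class(h) <- "phk_hypothesis"
    sets <- lapply(1:8, function(i) {
      nty <- sample(4:8, 1)
      random_fs(sprintf("s%02d", i),
                sample(c("A", "D", "P", "R"), nty, replace = TRUE),
                box = 12)
    })
    got <- match_hypothesis(build_screen_db(sets), h, dist_tol = 2.0)
    want <- vapply(sets, function(fs)
      oracle_has_match(h_types, h_xyz, fs, 2.0), logical(1))
    expect_setequal(got$molecule_id,
                    vapply(sets, function(s) s$molecule_id,
                           character(1))[want])
  }
})
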