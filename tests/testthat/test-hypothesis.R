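# Common-pharmacophore discovery, survival scoring and filtering.

test_that("survival score assembles from its components", {
  # printed best-hypothesis components with the capped matches reward
  w_unit <- weight_set(reward_mode = "unit")
  s <- survival_score(0.71, 0.912, 0.604, 0, m = 9, weights = w_unit)
  expect_equal(s, 3.226, tolerance = 1e-12)
  expect_equal(survival_score(0, 0, 0, 0, m = 0), 0)
  expect_equal(survival_score(1, 1, 1, 0, m = 2,
                              weights = weight_set(reward_mode = "linear")),
               5.0)
})

test_that("survival is linear in each component with its weight", {
  base <- c(s_site = 0.4, s_vec = 0.6, s_vol = 0.3, s_sel = 0.2)
  w <- weight_set(w_site = 1.5, w_vec = 0.5, w_vol = 2, w_sel = 0.7)
  s0 <- survival_score(base[1], base[2], base[3], base[4], m = 1, weights = w)
  h <- 1e-3
  for (i in seq_along(base)) {
    pert <- base
    pert[i] <- pert[i] + h
    s1 <- survival_score(pert[1], pert[2], pert[3], pert[4], m = 1,
                         weights = w)
    wexp <- c(w$w_site, w$w_vec, w$w_vol, w$w_sel)[i]
    expect_equal(unname((s1 - s0) / h), wexp, tolerance = 1e-9)
  }
})

planted_set <- function(n = 6, noise = 0, seed = 1, extras = 0) {
  set.seed(seed)
  ref_xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(1, 4, 0), c(3, 2, 3),
                   c(-1, 2, 2))
  types <- c("A", "D", "P", "R", "R")
  lapply(seq_len(n), function(i) {
    xyz <- ref_xyz + matrix(rnorm(15, 0, noise), 5, 3)
    fs <- fs_from_coords(sprintf("act%02d", i), types, xyz)
    if (extras > 0) {
      more <- random_fs("tmp", sample(c("A", "D", "H"), extras,
                                      replace = TRUE))
      fs$features <- c(fs$features, more$features)
    }
    transform_feature_set(fs, phorekin:::random_rotation(), runif(3, -4, 4))
  })
}

test_that("a geometry planted in every active is found; random sets yield nothing", {
  actives <- planted_set(n = 6, noise = 0)
  hyps <- find_common_pharmacophores(actives, "ADPRR", min_match = 6,
                                     bin_width = 1.0)
  expect_gte(length(hyps), 1L)
  expect_true(all(vapply(hyps, function(h)
    length(h$matched_actives) == 6L, logical(1))))

  empty_seeds <- vapply(1:20, function(s) {
    set.seed(s)
    rand <- lapply(1:6, function(i)
      random_fs(sprintf("r%02d", i), c("A", "D", "P", "R", "R")))
    length(find_common_pharmacophores(rand, "ADPRR", min_match = 6,
                                      bin_width = 1.0)) == 0L
  }, logical(1))
  expect_gte(sum(empty_seeds), 19L)  # chance co-occurrence ~ never
})

test_that("a single two-site molecule trivially hosts its own AA arrangement", {
  fs <- fs_from_coords("m", c("A", "A"), rbind(c(0, 0, 0), c(3, 0, 0)))
  hyps <- find_common_pharmacophores(list(fs), "AA", min_match = 1)
  expect_length(hyps, 1L)
  expect_equal(hyps[[1]]$variant, "AA")
})

test_that("discovery is invariant under rigid transforms of any input", {
  actives <- planted_set(n = 5, noise = 0.05, seed = 3)
  h1 <- find_common_pharmacophores(actives, "ADPRR", 5, 1.0)
  actives2 <- actives
  actives2[[2]] <- transform_feature_set(actives2[[2]],
                                         rotation_about_z(1.1), c(8, -3, 2))
  h2 <- find_common_pharmacophores(actives2, "ADPRR", 5, 1.0)
  expect_equal(length(h1), length(h2))
  expect_equal(lapply(h1, `[[`, "matched_actives"),
               lapply(h2, `[[`, "matched_actives"))
})

test_that("discovery agrees with exhaustive subset enumeration on small inputs", {
  set.seed(21)
  for (rep in 1:10) {
    n_sites <- sample(5:8, 1)
    types <- sample(c("A", "D", "H", "P"), n_sites, replace = TRUE)
    mols <- lapply(1:4, function(i) random_fs(sprintf("m%d", i), types,
                                              box = 10))
    variant <- paste(sort(sample(types, 4)), collapse = "")
    got <- find_common_pharmacophores(mols, variant, min_match = 2,
                                      bin_width = 2.0)
    # oracle: enumerate every typed subset of every molecule, count matches
    # by exhaustive assignment search
    lets <- strsplit(variant, "")[[1]]
    expected_keys <- character(0)
    for (si in seq_along(mols)) {
      subs <- phorekin:::enumerate_typed_subsets(mols[[si]], variant)
      for (sub in subs) {
        ref_xyz <- feature_coords(mols[[si]])[sub, , drop = FALSE]
        n_hit <- sum(vapply(seq_along(mols), function(mi) {
          if (mi == si) TRUE
          else oracle_has_match(lets, ref_xyz, mols[[mi]], 2.0)
        }, logical(1)))
        if (n_hit >= 2)
          expected_keys <- c(expected_keys,
                             paste(si, paste(sub, collapse = ",")))
      }
    }
    got_keys <- vapply(got, function(h)
      paste(match(h$source_molecule, vapply(mols, function(m) m$molecule_id,
                                            character(1))),
            paste(h$feature_indices, collapse = ",")), character(1))
    expect_setequal(got_keys, unique(expected_keys))
  }
})

test_that("scoring behaves at the fixed points and rewards extra matches", {
  actives <- planted_set(n = 5, noise = 0)
  h <- find_common_pharmacophores(actives, "ADPRR", 5, 1.0)[[1]]
  aligned <- align_matched_actives(h, actives)
  sc <- score_hypothesis(h, aligned)
  expect_equal(sc$s_site, 1, tolerance = 1e-9)   # zero noise: rmsd 0
  expect_equal(sc$s_vec, 1, tolerance = 1e-9)
  expect_equal(sc$s_vol, 1, tolerance = 1e-9)
  expect_equal(sc$m, 4L)
  expect_equal(sc$survival, 3 + 4, tolerance = 1e-9)  # linear reward

  # monotonicity: an additional matching active never lowers survival
  more <- planted_set(n = 6, noise = 0)
  h6 <- find_common_pharmacophores(more, "ADPRR", 6, 1.0)[[1]]
  sc6 <- score_hypothesis(h6, align_matched_actives(h6, more))
  expect_gte(sc6$survival, sc$survival)

  expect_error(score_hypothesis(h, list()), "no aligned actives")
})

test_that("with zero selectivity weight the score ignores decoys", {
  actives <- planted_set(n = 5, noise = 0.05, seed = 9)
  h <- find_common_pharmacophores(actives, "ADPRR", 5, 1.0)[[1]]
  aligned <- align_matched_actives(h, actives)
  set.seed(1)
  decoys_a <- lapply(1:5, function(i) random_fs(sprintf("d%d", i),
                                                c("A", "D", "P", "R", "R")))
  set.seed(2)
  decoys_b <- lapply(1:5, function(i) random_fs(sprintf("d%d", i),
                                                c("A", "D", "P", "R", "R")))
  s_a <- score_hypothesis(h, aligned, background = decoys_a)
  s_b <- score_hypothesis(h, aligned, background = decoys_b)
  expect_equal(s_a$survival, s_b$survival, tolerance = 1e-12)

  # with positive selectivity weight the background matters
  w <- weight_set(w_sel = 1)
  s_c <- score_hypothesis(h, aligned, weights = w, background = decoys_a)
  expect_gt(s_c$s_sel, 0)
})

test_that("the retention filter applies both printed thresholds and sorts", {
  mk <- function(surv, rmsd, svec, s_site = 0.5, variant = "ADPRR") {
    list(hypothesis = list(variant = variant),
         score = list(survival = surv, max_pairwise_rmsd = rmsd,
                      s_vec = svec, s_site = s_site))
  }
  out <- filter_hypotheses(list(mk(3.0, 1.30, 0.9),    # rmsd too large
                                mk(2.5, 1.00, 0.60),   # retained
                                mk(2.8, 0.80, 0.40),   # vector score too low
                                mk(2.6, 1.19, 0.51)))  # retained
  expect_length(out, 2L)
  expect_equal(vapply(out, function(e) e$score$survival, numeric(1)),
               c(2.6, 2.5))
  expect_length(filter_hypotheses(list()), 0L)
})
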