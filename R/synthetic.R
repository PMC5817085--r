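# Synthetic data generators: ligand site-sets with a planted pharmacophore
# among decoys, matching activity tables, and noisy kinetic trajectories with
# known parameters for recovery studies. All generators are pure functions of
# their seed.

#' Specification of a planted-pharmacophore data set
#'
#' @param variant Variant string of the planted arrangement (>= 3 sites).
#' @param n_actives,n_decoys Numbers of active and decoy molecules.
#' @param noise_sigma Per-coordinate Gaussian positional noise on the planted
#'   sites of each active, in Angstrom.
#' @param extra_sites_range Integer range (length 2) of random extra sites
#'   added per molecule.
#' @param box_size Side of the cubic site box (Angstrom).
#' @param seed Integer seed.
#' @param reference_geometry Optional [feature_set] to plant; auto-generated
#'   when NULL.
#' @return List of class `phk_plantspec`.
#' @export
plant_spec <- function(variant = "ADPRR", n_actives = 10L, n_decoys = 20L,
                       noise_sigma = 0.1, extra_sites_range = c(2L, 4L),
                       box_size = 20, seed = 1L,
                       reference_geometry = NULL) {
  if (nchar(variant) < 3L) stop("planted variant needs at least 3 sites")
  if (n_actives < 1L) stop("n_actives must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(variant = paste(variant_letters(variant), collapse = ""),
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 noise_sigma = noise_sigma,
                 extra_sites_range = as.integer(extra_sites_range),
                 box_size = box_size, seed = as.integer(seed),
                 reference_geometry = reference_geometry),
            class = "phk_plantspec")
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# k well-separated points in a centered cube (rejection sampling)
spread_points <- function(k, box_size, min_sep = 3.0) {
  repeat {
    pts <- matrix(stats::runif(3 * k, -box_size / 2, box_size / 2), k, 3)
    if (k < 2L || min(stats::dist(pts)) >= min_sep) return(pts)
  }
}

random_feature <- function(ty, point) {
  phk_feature(ty, point,
              direction = if (ty %in% DIRECTED_TYPES) random_unit_vector())
}

#' Generate ligand sets with a planted pharmacophore among decoys
#'
#' Each active carries the reference arrangement with i.i.d. Gaussian
#' positional noise plus random extra sites, under a random rigid motion per
#' molecule; decoys carry the same site-type multiset (plus extras) at
#' uniform random positions. EC50 values are drawn so the default threshold
#' scheme labels actives active and decoys inactive.
#'
#' @param spec A [plant_spec].
#' @return List with `actives` and `decoys` (lists of [feature_set]),
#'   `activity` (data frame: compound_id, ec50), and `truth` (the planted
#'   reference [feature_set], variant and seed).
#' @export
plant_pharmacophore <- function(spec) {
  stopifnot(inherits(spec, "phk_plantspec"))
  set.seed(spec$seed)
  lets <- strsplit(spec$variant, "")[[1]]
  k <- length(lets)

  ref <- spec$reference_geometry
  if (is.null(ref)) {
    pts <- spread_points(k, spec$box_size * 0.6)
    ref <- feature_set("planted_reference", 0L,
                       lapply(seq_len(k), function(i)
                         random_feature(lets[i], pts[i, ])))
  }
  ref_xyz <- feature_coords(ref)

  make_extras <- function() {
    n_extra <- sample(spec$extra_sites_range[1]:spec$extra_sites_range[2], 1)
    if (n_extra == 0L) return(list())
    tys <- sample(FEATURE_TYPES, n_extra, replace = TRUE)
    lapply(seq_len(n_extra), function(i)
      random_feature(tys[i],
                     stats::runif(3, -spec$box_size / 2, spec$box_size / 2)))
  }

  actives <- lapply(seq_len(spec$n_actives), function(i) {
    feats <- lapply(seq_len(k), function(j) {
      f <- ref$features[[j]]
      f$point <- f$point + stats::rnorm(3, 0, spec$noise_sigma)
      f
    })
    fs <- feature_set(sprintf("active_%02d", i), 0L, c(feats, make_extras()))
    transform_feature_set(fs, random_rotation(), stats::runif(3, -5, 5))
  })

  decoys <- lapply(seq_len(spec$n_decoys), function(i) {
    feats <- lapply(seq_len(k), function(j)
      random_feature(lets[j],
                     stats::runif(3, -spec$box_size / 2, spec$box_size / 2)))
    feature_set(sprintf("decoy_%02d", i), 0L, c(feats, make_extras()))
  })

  activity <- data.frame(
    compound_id = c(vapply(actives, function(a) a$molecule_id, character(1)),
                    vapply(decoys, function(d) d$molecule_id, character(1))),
    ec50 = c(stats::runif(spec$n_actives, 0.04, 0.9),
             stats::runif(spec$n_decoys, 1e-4, 9e-4)),
    stringsAsFactors = FALSE)

  list(actives = actives, decoys = decoys, activity = activity,
       truth = list(variant = spec$variant, reference = ref,
                    seed = spec$seed))
}

#' Generate noisy observation tables from a kinetic model
#'
#' Simulates the model and multiplies every observation by `1 + e`,
#' `e ~ N(0, noise_sigma_rel^2)` (multiplicative noise: concentrations stay
#' positive and errors scale with the signal).
#'
#' @param model A `phk_model`.
#' @param t_end Horizon in seconds.
#' @param n_timepoints Number of observation times (uniform over (0, t_end]).
#' @param noise_sigma_rel Relative noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param species Observed species (default: all).
#' @return Data frame with column `time` and one column per observed
#'   species; attribute `"clean"` holds the noise-free table.
#' @export
generate_trajectories <- function(model, t_end = 600, n_timepoints = 50L,
                                  noise_sigma_rel = 0.01, seed = 1L,
                                  species = NULL) {
  if (noise_sigma_rel < 0) stop("noise_sigma_rel must be >= 0")
  if (n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (is.null(species)) species <- model$species
  set.seed(seed)
  times <- seq(0, t_end, length.out = n_timepoints + 1L)[-1L]
  traj <- simulate(model, times = times)
  clean <- traj$conc[traj$times > 0, species, drop = FALSE]
  eps <- matrix(stats::rnorm(length(clean), 0, noise_sigma_rel),
                nrow(clean), ncol(clean))
  noisy <- clean * (1 + eps)
  out <- data.frame(time = times, noisy, check.names = FALSE)
  attr(out, "clean") <- data.frame(time = times, clean, check.names = FALSE)
  out
}

set_model_params <- function(model, values) {
  for (nm in names(values)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    rid <- parts[1]; pname <- parts[2]
    if (!rid %in% names(model$reactions))
      stop("unknown reaction in parameter name: ", nm)
    if (!pname %in% names(model$reactions[[rid]]$params))
      stop("unknown parameter in name: ", nm)
    model$reactions[[rid]]$params[[pname]] <- values[[nm]]
  }
  refresh_runtime(model)
}

get_model_params <- function(model, names_) {
  vapply(names_, function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    model$reactions[[parts[1]]]$params[[parts[2]]]
  }, numeric(1))
}

#' Recover rate parameters from observation tables
#'
#' Least-squares minimization of relative residuals over log10-parameters
#' (rate constants span decades and must stay positive), using
#' Levenberg-Marquardt with seeded multi-start.
#'
#' @param model A `phk_model` giving the fitted topology.
#' @param observations Output of [generate_trajectories] (or a compatible
#'   data frame with a `time` column).
#' @param free_params Character vector of `"reaction_id.param"` names, e.g.
#'   `"r_pip2_hydrolysis.Vm"`.
#' @param bounds Two-row matrix (rows: lower, upper) with one column per
#'   free parameter, in natural units; default two decades around the
#'   model's current values.
#' @param n_starts Number of multi-start draws (default 5).
#' @param seed Integer seed for the start draws.
#' @return List: `estimates` (named vector), `residual` (root-mean-square
#'   relative residual of the best fit), `converged` (logical),
#'   `starts` (per-start diagnostics).
#' @export
fit_parameters <- function(model, observations, free_params, bounds = NULL,
                           n_starts = 5L, seed = 1L) {
  obs_species <- setdiff(names(observations), "time")
  missing <- setdiff(obs_species, model$species)
  if (length(missing))
    stop("observed species not in model: ", paste(missing, collapse = ", "))
  p0 <- get_model_params(model, free_params)
  if (any(p0 <= 0)) stop("free parameters must be positive")
  if (is.null(bounds))
    bounds <- rbind(p0 / 10, p0 * 10)
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])

  times <- observations$time
  obs <- as.matrix(observations[obs_species])
  # relative residuals, floored at 5% of each species' signal maximum so
  # near-zero observations cannot dominate the objective
  col_floor <- 0.05 * apply(abs(obs), 2, max)
  col_floor[col_floor == 0] <- 1e-6
  scale <- pmax(abs(obs), rep(col_floor, each = nrow(obs)))

  resid_fn <- function(theta) {
    vals <- stats::setNames(10^theta, free_params)
    mfit <- set_model_params(model, vals)
    tr <- tryCatch(
      suppressWarnings(simulate(mfit, times = times, rtol = 1e-6,
                                atol = 1e-8)),
      error = function(e) NULL)
    if (is.null(tr)) return(rep(1e3, length(obs)))
    sim <- tr$conc[tr$times > 0, obs_species, drop = FALSE]
    as.numeric((sim - obs) / scale)
  }

  # Candidate starts are drawn log-uniformly within the bounds (never the
  # model's current values: a recovery study must not start at the truth),
  # screened by a single residual evaluation, and the best n_starts seed the
  # Levenberg-Marquardt runs. The cheap screen avoids starts in the flat
  # far-from-fit region where the gradient is numerically dead.
  set.seed(seed)
  pool <- matrix(stats::runif(4L * n_starts * length(p0), lo, hi),
                 4L * n_starts, length(p0), byrow = TRUE)
  pool_rss <- apply(pool, 1, function(th) sum(resid_fn(th)^2))
  starts <- pool[order(pool_rss)[seq_len(n_starts)], , drop = FALSE]
  fits <- apply(starts, 1, function(th0) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 50,
                                                              ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(f)) return(list(ok = FALSE, rss = Inf, par = th0,
                                info = -1L))
    list(ok = f$info %in% 1:4, rss = sum(f$fvec^2), par = f$par,
         info = f$info)
  })
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  best <- fits[[which.min(rss)]]
  list(estimates = stats::setNames(10^best$par, free_params),
       residual = sqrt(min(rss) / length(obs)),
       converged = any(vapply(fits, `[[`, logical(1), "ok")),
       starts = data.frame(rss = rss,
                           info = vapply(fits, `[[`, integer(1), "info")))
}
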