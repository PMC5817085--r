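# Activity thresholding of EC50 tables into active / inactive / unlabeled.

#' Define an activity threshold scheme
#'
#' A scheme labels compounds by EC50 (in micromolar): on the default
#' direction (`"ge"`), a compound is active when its EC50 is at or above
#' `active_threshold` and inactive at or below `inactive_threshold`;
#' everything in between stays unlabeled. The `"le"` direction flips the
#' comparators for the conventional potency reading of EC50 (lower = more
#' potent); the default follows the literal dataset definitions the package
#' ships with, where actives sit above the activity threshold.
#'
#' @param active_threshold,inactive_threshold Positive EC50 bounds (uM),
#'   `inactive_threshold <= active_threshold` for direction `"ge"`.
#' @param min_match Minimum number of actives a hypothesis must match.
#' @param n_active_expected Expected number of actives (bookkeeping, may be
#'   NA).
#' @param direction `"ge"` (active at high values, default) or `"le"`.
#' @return List of class `phk_scheme`.
#' @export
threshold_scheme <- function(active_threshold, inactive_threshold,
                             min_match = 1L, n_active_expected = NA_integer_,
                             direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (min_match < 1L) stop("min_match must be >= 1")
  if (direction == "ge" && inactive_threshold > active_threshold)
    stop("inactive_threshold must not exceed active_threshold")
  if (direction == "le" && inactive_threshold < active_threshold)
    stop("for direction 'le', inactive_threshold must be >= active_threshold")
  structure(list(active_threshold = active_threshold,
                 inactive_threshold = inactive_threshold,
                 min_match = as.integer(min_match),
                 n_active_expected = as.integer(n_active_expected),
                 direction = direction),
            class = "phk_scheme")
}

#' Label compounds by EC50 under a threshold scheme
#'
#' @param records Data frame with columns `compound_id` and `ec50` (uM), or a
#'   two-column data frame coerced to those names.
#' @param scheme A [threshold_scheme].
#' @return The input data frame with an added factor column `label` in
#'   `active`, `inactive`, `unlabeled`, plus attributes `n_active`,
#'   `n_inactive`, `n_unlabeled`.
#' @export
partition_activity <- function(records, scheme) {
  records <- as.data.frame(records)
  if (!all(c("compound_id", "ec50") %in% names(records)))
    names(records)[1:2] <- c("compound_id", "ec50")
  ec50 <- records$ec50
  if (any(!is.finite(ec50)) || any(ec50 <= 0))
    stop("all EC50 values must be positive and finite")
  label <- if (scheme$direction == "ge") {
    ifelse(ec50 >= scheme$active_threshold, "active",
           ifelse(ec50 <= scheme$inactive_threshold, "inactive", "unlabeled"))
  } else {
    ifelse(ec50 <= scheme$active_threshold, "active",
           ifelse(ec50 >= scheme$inactive_threshold, "inactive", "unlabeled"))
  }
  records$label <- factor(label, levels = c("active", "inactive", "unlabeled"))
  attr(records, "n_active") <- sum(label == "active")
  attr(records, "n_inactive") <- sum(label == "inactive")
  attr(records, "n_unlabeled") <- sum(label == "unlabeled")
  records
}

#' The three GPR142 agonist dataset schemes
#'
#' Threshold schemes of the three training-set partitions used for the
#' GPR142 agonist series: (1) high affinity — active at/above 0.036 uM,
#' inactive at/below 0.001 uM, hypothesis must match 35 of 38 actives;
#' (2) medium affinity — active at/above 1.060, inactive at/below 1.000,
#' match 30 of 51; (3) low affinity — active at/above 0.036, inactive
#' at/below 0.035, match 20 of 60.
#'
#' @return Named list of three [threshold_scheme] objects.
#' @export
gpr142_schemes <- function() {
  list(high_affinity = threshold_scheme(0.036, 0.001, min_match = 35L,
                                        n_active_expected = 38L),
       medium_affinity = threshold_scheme(1.060, 1.000, min_match = 30L,
                                          n_active_expected = 51L),
       low_affinity = threshold_scheme(0.036, 0.035, min_match = 20L,
                                       n_active_expected = 60L))
}

#' Read an activity CSV
#'
#' Expects columns `compound_id` and `ec50_um`.
#'
#' @param path CSV path.
#' @return Data frame with columns `compound_id`, `ec50`.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "ec50_um") %in% names(df)))
    stop("activity CSV must have columns compound_id, ec50_um")
  data.frame(compound_id = as.character(df$compound_id),
             ec50 = as.numeric(df$ec50_um), stringsAsFactors = FALSE)
}

#' Enumerate feature-type variants
#'
#' Lists every sorted multiset of feature-type letters of size `k_min` to
#' `k_max` realizable from the available per-type counts. A variant string
#' such as `"ADPRR"` names the composition of a candidate hypothesis.
#'
#' @param type_counts Named integer vector or list, names in `A D H N P R`.
#' @param k_min,k_max Inclusive size bounds.
#' @return Character vector of variant strings, sorted.
#' @export
enumerate_variants <- function(type_counts, k_min, k_max) {
  if (k_min > k_max) stop("k_min must not exceed k_max")
  counts <- unlist(type_counts)
  if (any(counts < 0)) stop("type counts must be nonnegative")
  bad <- setdiff(names(counts), FEATURE_TYPES)
  if (length(bad)) stop("unknown feature types: ", paste(bad, collapse = ", "))
  types <- names(counts)[counts > 0]
  counts <- counts[counts > 0]
  res <- character(0)
  recurse <- function(i, remaining, acc) {
    if (remaining == 0L) { res[[length(res) + 1L]] <<- acc; return() }
    if (i > length(types)) return()
    for (take in 0:min(counts[[i]], remaining))
      recurse(i + 1L, remaining - take,
              paste0(acc, strrep(types[[i]], take)))
  }
  for (k in k_min:k_max) if (k >= 1L) recurse(1L, as.integer(k), "")
  sort(unique(res))
}
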