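#' Tidy a trajectory into its observables table
#'
#' @param x A `trajectory` from [run_simulation()].
#' @param ... Unused.
#' @return The observables tibble (`step`, `time`, `cavity_rest`,
#'   `packing_index`, `mean_degree`, `min_separation`, `energy`).
#' @export
tidy.trajectory <- function(x, ...) {
  x$observables
}

#' One-row summary of a trajectory
#'
#' Initial and final packing index and mean neighbour degree, and their
#' deltas — the quantities behind the model's compression prediction.
#'
#' @inheritParams tidy.trajectory
#' @return A one-row tibble.
#' @export
glance.trajectory <- function(x, ...) {
  obs <- x$observables
  first <- obs[1, ]
  last <- obs[nrow(obs), ]
  tibble(
    n_cells = nrow(x$snapshots[[1]]$positions),
    n_steps = x$config$n_steps,
    seed = x$seed,
    packing_initial = first$packing_index,
    packing_final = last$packing_index,
    packing_delta = last$packing_index - first$packing_index,
    degree_initial = first$mean_degree,
    degree_final = last$mean_degree,
    degree_delta = last$mean_degree - first$mean_degree,
    cavity_rest_final = last$cavity_rest
  )
}

#' Tidy a two-group test result
#'
#' @param x A `test_result` from [compare_two()].
#' @param ... Unused.
#' @return A one-row tibble: `test`, `statistic`, `p.value`, route and
#'   significance at the stored `alpha`.
#' @export
tidy.test_result <- function(x, ...) {
  tibble(
    comparison = paste(as.character(x$group_summaries$group), collapse = " vs "),
    test = x$test,
    statistic = x$statistic,
    p.value = x$p_value,
    parametric = x$parametric,
    significant = x$p_value < x$alpha
  )
}

#' @rdname tidy.test_result
#' @export
glance.test_result <- function(x, ...) tidy(x, ...)

#' Tidy a many-group test result into per-comparison rows
#'
#' @param x A `test_result_many` from [compare_many()].
#' @param ... Unused.
#' @return Tibble with one row per comparison against the control:
#'   `comparison`, `statistic`, `p_raw`, `p_adj`, `significant`.
#' @export
tidy.test_result_many <- function(x, ...) {
  x$comparisons
}

#' Omnibus-level summary of a many-group comparison
#'
#' @inheritParams tidy.test_result_many
#' @return A one-row tibble: omnibus test, statistic, p-value, post-hoc
#'   family and route.
#' @export
glance.test_result_many <- function(x, ...) {
  tibble(
    test = x$omnibus$test,
    statistic = x$omnibus$statistic,
    p.value = x$omnibus$p_value,
    posthoc = x$posthoc,
    control = x$control,
    parametric = x$parametric,
    n_comparisons = nrow(x$comparisons)
  )
}
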