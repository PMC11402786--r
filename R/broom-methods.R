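#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn compare_spatial_groups one-row tibble with `estimate`,
#'   `statistic`, `df`, `p.value`, `alternative`, `method`.
#' @param x a fitted comparison object.
#' @param ... unused.
#' @export
tidy.spatial_comparison <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p.value, n_a = x$n_a, n_b = x$n_b,
         alternative = x$alternative, method = x$method)
}

#' @describeIn compare_spatial_groups alias of `tidy()` for this model-free
#'   test object.
#' @export
glance.spatial_comparison <- function(x, ...) tidy.spatial_comparison(x)

#' @describeIn occupancy_test one-row tibble with `statistic`, `df`,
#'   `p.value`, `method`.
#' @param x an `occupancy_test` object.
#' @param ... unused.
#' @export
tidy.occupancy_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' @describeIn occupancy_test alias of `tidy()`.
#' @export
glance.occupancy_test <- function(x, ...) tidy.occupancy_test(x)

#' @describeIn build_null the null f values as a tibble with a
#'   `below_threshold` flag.
#' @param x a `structure_null` object.
#' @param ... unused.
#' @export
tidy.structure_null <- function(x, ...) {
  tibble(f = x$f_values, below_threshold = x$f_values < x$threshold)
}

#' @describeIn build_null one-row summary: `n`, `alpha`, `threshold`, and
#'   the fraction of null values strictly below the threshold.
#' @export
glance.structure_null <- function(x, ...) {
  tibble(n = x$n, alpha = x$alpha, threshold = x$threshold,
         frac_below = mean(x$f_values < x$threshold))
}
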