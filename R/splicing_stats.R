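#' Denominator exon chains of the length-normalized ESS model
#'
#' The six-category exon-skipping model normalizes each isoform's read count
#' by the summed length of the exons that uniquely evidence it: the full
#' exon chain for the non-skipping isoform, and the two exons flanking the
#' skipped block for each skipping isoform (e.g. E2+E4 for exon-3 skipping,
#' E4+E7 for skipping of exons 5-6).  Flanks are derived from the catalog's
#' chains, so any analogous panel works, not just the bundled one.
#'
#' @param catalog an [build_isoform_catalog()] object.
#' @param categories isoform labels of the model; the first must be the
#'   full-length (non-skipping) isoform.
#' @return tibble with `isoform`, `denom_exons` (list-column) and
#'   `denom_length`.
#' @export
ess_denominators <- function(catalog,
                             categories = c("noS", "E3S", "E5S", "E6S",
                                            "E56S", "E3456S")) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  missing <- setdiff(categories, catalog$isoforms$isoform)
  if (length(missing) > 0) {
    abort(paste0("Catalog lacks isoform(s): ", paste(missing, collapse = ", ")))
  }
  chains <- setNames(catalog$isoforms$chain, catalog$isoforms$isoform)
  full <- chains[[categories[1]]]
  denom <- purrr::map(categories, function(iso) {
    ch <- chains[[iso]]
    skipped <- setdiff(full, ch)
    if (length(skipped) == 0) return(full)
    pos <- match(skipped, full)
    if (any(diff(sort(pos)) != 1)) {
      abort(paste0("Skipped exons of `", iso,
                   "` are not a contiguous block of the full chain."))
    }
    lo <- min(pos); hi <- max(pos)
    if (lo == 1 || hi == length(full)) {
      abort(paste0("Skipped block of `", iso,
                   "` has no flanking exon on both sides."))
    }
    c(full[lo - 1], full[hi + 1])
  })
  tibble(
    isoform = categories,
    denom_exons = denom,
    denom_length = vapply(denom, function(e) exon_chain_length(catalog, e),
                          numeric(1))
  )
}

#' Length-normalized exon-skipping percentages
#'
#' Implements the printed percentage model for exon-skipping events: each
#' category's read count `R(iso)` is divided by its denominator exon length
#' `L(iso)` to give a read density, and the percentage is the density's
#' share of the summed densities,
#' `P(iso) = (R(iso)/L(iso)) / sum_j R(j)/L(j)`.  Percentages over the model
#' categories sum to 1 whenever any category has reads.  Isoforms observed
#' by the classifier but outside the model (e.g. E4S, E34S, E345S, E3a) are
#' reported with their counts but excluded from the normalization
#' (`in_model = FALSE`, `percentage = NA`).  Samples with all model counts
#' zero get `NA` percentages and a warning, never silent zeros.
#'
#' @param counts a `classification_counts` tibble (one or more samples), or
#'   a named count vector for a single sample.
#' @param catalog an [build_isoform_catalog()] object.
#' @param categories model isoform labels, full-length isoform first.
#' @return tibble of class `ess_profile`: `sample_id`, `isoform`, `reads`,
#'   `denom_length`, `density`, `percentage`, `in_model`.
#' @examples
#' cat <- default_gene_model()
#' counts <- tibble::tibble(
#'   sample_id = "cell1",
#'   category = c("noS", "E56S"),
#'   count = c(60, 20)
#' )
#' ess_percentages(counts, cat)
#' @export
ess_percentages <- function(counts, catalog,
                            categories = c("noS", "E3S", "E5S", "E6S",
                                           "E56S", "E3456S")) {
  if (!is.data.frame(counts)) {
    counts <- tibble(sample_id = "sample", category = names(counts),
                     count = as.numeric(counts))
  }
  stopifnot(all(c("sample_id", "category", "count") %in% names(counts)))
  den <- ess_denominators(catalog, categories)
  iso_all <- catalog$isoforms$isoform
  out <- purrr::map_dfr(split(counts, counts$sample_id), function(cnt) {
    cvec <- setNames(rep(0, length(iso_all)), iso_all)
    obs <- cnt$category[cnt$category %in% iso_all]
    cvec[obs] <- cnt$count[cnt$category %in% iso_all]
    r <- cvec[categories]
    dens <- r / den$denom_length
    tot <- sum(dens)
    if (tot > 0) {
      p <- dens / tot
    } else {
      warn(paste0("Sample `", cnt$sample_id[1],
                  "`: all model counts are zero; percentages undefined."))
      p <- rep(NA_real_, length(dens))
    }
    extra <- setdiff(iso_all[cvec > 0], categories)
    bind_rows(
      tibble(sample_id = cnt$sample_id[1], isoform = categories,
             reads = unname(r), denom_length = den$denom_length,
             density = unname(dens), percentage = unname(p),
             in_model = TRUE),
      tibble(sample_id = cnt$sample_id[1], isoform = extra,
             reads = unname(cvec[extra]), denom_length = NA_real_,
             density = NA_real_, percentage = NA_real_, in_model = FALSE)
    )
  })
  class(out) <- c("ess_profile", class(out))
  out
}

#' Simple alternative-vs-canonical splicing percentages
#'
#' For splicing events summarized as a two-way split (alternative vs
#' non-alternative), the percentages are plain read-count ratios:
#' `P(AS) = R(AS) / (R(noAS) + R(AS))` and `P(noAS) = 1 - P(AS)`.
#' Vectorized; rows with both counts zero are undefined (`NA`) with a
#' warning.
#'
#' @param r_noas,r_as read counts of the canonical and alternative events.
#' @return tibble with `p_noas` and `p_as`.
#' @export
as_percentage <- function(r_noas, r_as) {
  stopifnot(length(r_noas) == length(r_as))
  if (any(r_noas < 0 | r_as < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.")
  }
  tot <- r_noas + r_as
  if (any(tot == 0, na.rm = TRUE)) {
    warn("Both counts zero for some event(s); percentages undefined.")
  }
  p_as <- ifelse(tot > 0, r_as / tot, NA_real_)
  tibble(p_noas = 1 - p_as, p_as = p_as)
}

#' Spike-in scale factors and normalized abundances
#'
#' Each cell receives the same known amount of a synthetic spike-in RNA; the
#' ratio of expected to recovered spike-in reads calibrates per-cell
#' recovery.  The scale factor `s_c = expected / observed_spike_in(c)`
#' multiplies every isoform count into a normalized abundance.  Percentages
#' are ratio statistics and are unchanged by this scaling.  Cells with zero
#' spike-in reads cannot be calibrated and are excluded with a warning.
#'
#' @param counts a `classification_counts` tibble covering one or more
#'   cells (sample ids are cell ids).
#' @param sample_sheet data frame with `cell_id` and `spike_in_expected`
#'   (identical for all cells, as the same amount is added to each).
#' @return tibble with `sample_id`, `category`, `count`, `scale_factor`,
#'   `normalized` (spike-in and unclassified rows keep their raw counts with
#'   `normalized = NA`).
#' @export
spike_in_normalize <- function(counts, sample_sheet) {
  stopifnot(is.data.frame(counts), is.data.frame(sample_sheet))
  stopifnot(all(c("cell_id", "spike_in_expected") %in% names(sample_sheet)))
  if (length(unique(sample_sheet$spike_in_expected)) != 1) {
    abort("`spike_in_expected` must be identical across cells.")
  }
  expected <- sample_sheet$spike_in_expected[1]
  spike <- counts %>%
    filter(.data$category == "spike_in") %>%
    select(sample_id = "sample_id", spike_count = "count")
  zero <- spike$sample_id[spike$spike_count == 0]
  if (length(zero) > 0) {
    warn(paste0("Cell(s) with zero spike-in reads excluded: ",
                paste(zero, collapse = ", ")))
  }
  spike <- spike %>% filter(.data$spike_count > 0) %>%
    mutate(scale_factor = expected / .data$spike_count)
  counts %>%
    filter(.data$sample_id %in% spike$sample_id) %>%
    left_join(select(spike, "sample_id", "scale_factor"), by = "sample_id") %>%
    mutate(normalized = ifelse(
      .data$category %in% c("spike_in", "unclassified"),
      NA_real_, .data$scale_factor * .data$count))
}

#' Relative splicing / expression levels among blastomeres of an embryo
#'
#' For each cell the metric is either the total exon-skipping fraction
#' (`1 - P(noS)` from its ESS profile) or the spike-in-normalized total
#' transcript abundance; within each embryo, values are divided by the
#' embryo maximum, giving relative levels in `[0, 1]` with the top cell at
#' exactly 1.  Embryos where every cell's metric is zero get missing
#' relative levels.
#'
#' @param profiles an [ess_percentages()] result covering the embryo's cells
#'   (sample ids are cell ids).  Needed for `metric = "ESS"`.
#' @param sample_sheet data frame with `cell_id`, `embryo_id`,
#'   `spatial_label` and (for `metric = "expression"`) `spike_in_expected`.
#' @param counts the `classification_counts` tibble; required for
#'   `metric = "expression"`.
#' @param metric `"ESS"` or `"expression"`.
#' @return tibble of class `embryo_summary`: `embryo_id`, `cell_id`,
#'   `spatial_label`, `metric`, `value`, `relative_level`.
#' @export
relative_levels_within_embryo <- function(profiles, sample_sheet,
                                          counts = NULL,
                                          metric = c("ESS", "expression")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(sample_sheet))
  stopifnot(all(c("cell_id", "embryo_id") %in% names(sample_sheet)))
  sizes <- table(sample_sheet$embryo_id)
  if (any(sizes < 2)) {
    abort(paste0("Every embryo needs at least 2 cells; offending: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  if (metric == "ESS") {
    vals <- profiles %>%
      filter(.data$isoform == "noS", .data$in_model) %>%
      mutate(value = 1 - .data$percentage) %>%
      select(cell_id = "sample_id", "value")
  } else {
    if (is.null(counts)) abort("`counts` is required for metric = \"expression\".")
    norm <- spike_in_normalize(counts, sample_sheet)
    vals <- norm %>%
      filter(!.data$category %in% c("spike_in", "unclassified")) %>%
      group_by(cell_id = .data$sample_id) %>%
      summarise(value = sum(.data$normalized), .groups = "drop")
  }
  out <- sample_sheet %>%
    select("embryo_id", "cell_id",
           tidyr::any_of("spatial_label")) %>%
    left_join(vals, by = "cell_id") %>%
    group_by(.data$embryo_id) %>%
    mutate(relative_level = {
      mx <- max(.data$value, na.rm = TRUE)
      if (!is.finite(mx) || mx == 0) rep(NA_real_, n())
      else .data$value / mx
    }) %>%
    ungroup()
  class(out) <- c("embryo_summary", class(out))
  out
}

#' Two-sample Student's t comparison of spatial groups
#'
#' Classical equal-variance two-sample Student's t-test comparing a splicing
#' metric (e.g. total exon-skipping fraction) between two spatial groups of
#' blastomeres — attached vs not attached to the second polar body in
#' two-cell embryos, near vs far in four-cell embryos.  Degenerate inputs
#' with zero pooled variance return `t = 0, p = 1` when the means agree and
#' `|t| = Inf` when they do not.
#'
#' @param values_a,values_b numeric metric values of the two groups (each of
#'   length at least 2).
#' @param alternative `"two.sided"` (default, two-tailed), `"less"` or
#'   `"greater"` (one-tailed; direction refers to group a minus group b).
#' @param labels optional length-2 character vector naming the groups.
#' @return object of class `spatial_comparison` with `statistic`, `df`,
#'   `p.value`, `estimate` (mean difference a - b), group sizes and the
#'   alternative; supports `tidy()` and `glance()`.
#' @export
compare_spatial_groups <- function(values_a, values_b,
                                   alternative = c("two.sided", "less",
                                                   "greater"),
                                   labels = c("a", "b")) {
  alternative <- match.arg(alternative)
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  na <- length(values_a); nb <- length(values_b)
  df <- na + nb - 2
  diff <- mean(values_a) - mean(values_b)
  sp2 <- ((na - 1) * stats::var(values_a) + (nb - 1) * stats::var(values_b)) / df
  if (sp2 == 0) {
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- switch(alternative,
                two.sided = if (diff == 0) 1 else 0,
                less = if (diff < 0) 0 else 1,
                greater = if (diff > 0) 0 else 1)
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE,
                        alternative = alternative)
    tstat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(statistic = tstat, df = df, p.value = p, estimate = diff,
         n_a = na, n_b = nb, alternative = alternative, labels = labels,
         method = "Two-sample Student's t-test (equal variance)"),
    class = "spatial_comparison"
  )
}

#' @export
print.spatial_comparison <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s (n=%d) vs %s (n=%d): t = %.4g, df = %d, p = %.4g (%s)\n",
              x$labels[1], x$n_a, x$labels[2], x$n_b, x$statistic, x$df,
              x$p.value, x$alternative))
  invisible(x)
}

#' Chi-squared test of occupancy categories across spatial groups
#'
#' Pearson chi-squared test on a contingency table of occupancy categories
#' (e.g. how many gene loci of a cell are covered by RNA speckles: 2, 1 or
#' 0) by spatial group.  For the 3 x 2 design the degrees of freedom are
#' `(3 - 1)(2 - 1) = 2`.  No continuity correction is applied.
#'
#' @param contingency matrix (or table) of non-negative integer counts,
#'   categories in rows, groups in columns.
#' @return object of class `occupancy_test` with `statistic`, `df`,
#'   `p.value`, `observed`, `expected`; supports `tidy()` and `glance()`.
#' @export
occupancy_test <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || any(m != round(m))) {
    abort("Contingency table must contain non-negative integers.")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Every row and column of the table must have a positive sum.")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    abort("Some expected cell counts are zero; merge sparse categories before testing.")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value, observed = m, expected = expected,
         method = "Pearson chi-squared test (no continuity correction)"),
    class = "occupancy_test"
  )
}

#' @export
print.occupancy_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}
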