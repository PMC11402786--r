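#' Derive a reproducible sub-seed from a root seed and labels
#'
#' Each simulated unit (cell, embryo, source) gets its own deterministic RNG
#' substream: the labels are hashed with a base-31 polynomial and mixed with
#' the root seed, keeping the result a valid 32-bit R seed.  Identical
#' (root, labels) always give the same sub-seed.
#'
#' @param root integer root seed.
#' @param ... labels (coerced to character) identifying the unit.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root, ...) {
  m <- 2147483629  # largest prime below 2^31 - 1
  h <- as.numeric(root) %% m
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 31 + 7) %% m
  }
  as.integer(h)
}

#' Run code with a local, seeded RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Default isoform mixture of the simulator
#'
#' A realistic single-blastomere mixture: the canonical isoform dominates,
#' skipping of exons 5+6 is the most frequent skipping event, and the
#' remaining variants are minor.
#'
#' @return named numeric vector summing to 1 over the ten catalog isoforms.
#' @export
default_isoform_proportions <- function() {
  c(noS = 0.45, E3a = 0.02, E3S = 0.08, E4S = 0.02, E5S = 0.08,
    E6S = 0.08, E34S = 0.02, E56S = 0.15, E345S = 0.02, E3456S = 0.08)
}

#' Simulate paired-end amplicon reads for one cell
#'
#' Each read draws an isoform by the mixture proportions (or the spike-in
#' with probability `spike_in_fraction`), emits the full amplicon, cuts a
#' forward read of `read_len` nt from the 5' end and a reverse read
#' (reverse-complemented, as sequenced) of `read_len` nt from the 3' end,
#' and applies independent per-base substitution errors.  Amplicons shorter
#' than `read_len` yield full-length mates.  Fully reproducible from the
#' seed.
#'
#' @param catalog an [build_isoform_catalog()] object with a spike-in when
#'   `spike_in_fraction > 0`.
#' @param n_reads number of read pairs (default 2000).
#' @param read_len mate length in nt (default 300).
#' @param error_rate per-base substitution probability (default 0.01).
#' @param proportions named isoform mixture (must sum to 1 over catalog
#'   isoforms); default [default_isoform_proportions()].
#' @param spike_in_fraction fraction of reads drawn from the spike-in
#'   reference (default 0.05).
#' @param seed integer seed; the cell's substream is derived from it and
#'   `cell_id` via [derive_seed()].
#' @param cell_id sample label.
#' @return list with `reads` (tibble `read_id`, `fwd`, `rev`) and `truth`
#'   (tibble `read_id`, `isoform`), plus the resolved `proportions`.
#' @export
simulate_cell_reads <- function(catalog, n_reads = 2000, read_len = 300,
                                error_rate = 0.01,
                                proportions = default_isoform_proportions(),
                                spike_in_fraction = 0.05,
                                seed = 1, cell_id = "cell1") {
  stopifnot(inherits(catalog, "isoform_catalog"))
  iso <- catalog$isoforms$isoform
  unknown <- setdiff(names(proportions), iso)
  if (length(unknown) > 0) {
    abort(paste0("Proportions name unknown isoform(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    abort("Isoform proportions must sum to 1.")
  }
  if (spike_in_fraction < 0 || spike_in_fraction >= 1) {
    abort("`spike_in_fraction` must be in [0, 1).")
  }
  if (spike_in_fraction > 0 && is.null(catalog$spike_in)) {
    abort("Catalog has no spike-in reference but `spike_in_fraction` > 0.")
  }
  amps <- setNames(chartr("U", "T", catalog$isoforms$sequence), iso)
  if (!is.null(catalog$spike_in)) {
    amps <- c(amps, spike_in = chartr("U", "T", unname(catalog$spike_in)))
  }
  p <- setNames(rep(0, length(amps)), names(amps))
  p[names(proportions)] <- proportions * (1 - spike_in_fraction)
  if (spike_in_fraction > 0) p["spike_in"] <- spike_in_fraction
  with_seed(derive_seed(seed, cell_id), {
    truth_iso <- sample(names(amps), n_reads, replace = TRUE, prob = p)
    amp <- amps[truth_iso]
    L <- nchar(amp)
    fwd <- substr(amp, 1, pmin(read_len, L))
    rev <- revcomp(substr(amp, pmax(1, L - read_len + 1), L))
    if (error_rate > 0 && n_reads > 0) {
      fwd <- as.character(cpp_apply_substitutions(fwd, error_rate, "ACGT"))
      rev <- as.character(cpp_apply_substitutions(rev, error_rate, "ACGT"))
    }
    ids <- sprintf("%s_read%06d", cell_id, seq_len(n_reads))
    list(
      reads = tibble(read_id = ids, fwd = unname(fwd), rev = unname(rev)),
      truth = tibble(read_id = ids, isoform = unname(truth_iso)),
      proportions = p
    )
  })
}

#' Convert a target total-ESS fraction into isoform read proportions
#'
#' The planted per-cell truth is the total exon-skipping fraction on the
#' percentage scale (`1 - P(noS)`).  Because the percentages are
#' length-normalized densities, the corresponding *read* proportions are
#' `pi_i = P_i * L_i / sum_j P_j L_j`, with `L_i` the denominator chain
#' lengths — reads simulated with these proportions recover the planted
#' percentages in expectation.
#'
#' @param ess_total target total-ESS fraction in `[0, 1]`.
#' @param catalog an [build_isoform_catalog()] object.
#' @param skip_weights how the total ESS is divided among the skipping
#'   categories (named, sums to 1).
#' @param categories model categories, full-length isoform first.
#' @return named read-proportion vector over the model categories.
#' @export
ess_to_read_proportions <- function(ess_total, catalog,
                                    skip_weights = c(E3S = 0.15, E5S = 0.15,
                                                     E6S = 0.15, E56S = 0.40,
                                                     E3456S = 0.15),
                                    categories = c("noS", "E3S", "E5S", "E6S",
                                                   "E56S", "E3456S")) {
  if (ess_total < 0 || ess_total > 1) {
    abort("`ess_total` must lie in [0, 1].")
  }
  if (abs(sum(skip_weights) - 1) > 1e-8 ||
      !setequal(names(skip_weights), setdiff(categories, categories[1]))) {
    abort("`skip_weights` must cover the skipping categories and sum to 1.")
  }
  P <- setNames(numeric(length(categories)), categories)
  P[categories[1]] <- 1 - ess_total
  P[names(skip_weights)] <- ess_total * skip_weights
  L <- setNames(ess_denominators(catalog, categories)$denom_length, categories)
  pr <- P * L
  pr / sum(pr)
}

#' Simulate a panel of embryos with planted spatial ESS heterogeneity
#'
#' Emulates the single-blastomere study design: embryos of 2 cells (one
#' attached to the second polar body, `pB`, one not, `npB`) or 4 cells (two
#' near, `nB`, two far, `fB`).  Per-cell total-ESS truth is drawn normally
#' around the group mean — `npB`/`fB` at `base_ess`, `pB`/`nB` lower by
#' `ess_effect` — with s.d. `dispersion`, then converted to read
#' proportions via [ess_to_read_proportions()].  Reads can optionally be
#' emitted per cell.
#'
#' @param catalog an [build_isoform_catalog()] object.
#' @param n_embryos number of embryos (default 60).
#' @param cells_per_embryo 2 or 4.
#' @param base_ess mean total-ESS fraction of the high group (default 0.45).
#' @param ess_effect difference in mean total-ESS between groups (default
#'   0.2; the polar-body-proximal lineage is lower).  Group means must stay
#'   inside `[0, 1]`.
#' @param dispersion between-cell s.d. of the truth (default 0.15); draws
#'   are clipped to `[0.001, 0.999]`.
#' @param spike_in_expected nominal spike-in molecule count recorded in the
#'   sample sheet (default 1000).
#' @param n_reads,read_len,error_rate,spike_in_fraction read-level
#'   parameters, used when `emit_reads = TRUE`.
#' @param seed root seed; per-cell substreams derive from embryo and cell
#'   ids.
#' @param emit_reads if `TRUE`, simulate reads for every cell (slow for
#'   large panels); otherwise only truth and the sample sheet are returned.
#' @return list with `sample_sheet` (`cell_id`, `embryo_id`,
#'   `spatial_label`, `spike_in_expected`), `truth` (per-cell planted ESS
#'   and group), and, when `emit_reads`, `reads`/`read_truth` tibbles over
#'   all cells.
#' @export
simulate_embryo_panel <- function(catalog, n_embryos = 60,
                                  cells_per_embryo = 2,
                                  base_ess = 0.45, ess_effect = 0.2,
                                  dispersion = 0.15,
                                  spike_in_expected = 1000,
                                  n_reads = 2000, read_len = 300,
                                  error_rate = 0.01,
                                  spike_in_fraction = 0.05,
                                  seed = 1, emit_reads = FALSE) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  if (!cells_per_embryo %in% c(2, 4)) {
    abort("`cells_per_embryo` must be 2 or 4.")
  }
  lo_mean <- base_ess - ess_effect
  if (base_ess < 0 || base_ess > 1 || lo_mean < 0 || lo_mean > 1) {
    abort("`base_ess` and `base_ess - ess_effect` must lie in [0, 1].")
  }
  labels <- if (cells_per_embryo == 2) c("pB", "npB")
            else c("nB", "nB", "fB", "fB")
  low_group <- if (cells_per_embryo == 2) "pB" else "nB"
  design <- tidyr::expand_grid(embryo = seq_len(n_embryos),
                               slot = seq_len(cells_per_embryo)) %>%
    mutate(
      embryo_id = sprintf("embryo%03d", .data$embryo),
      spatial_label = labels[.data$slot],
      cell_id = sprintf("%s_c%d_%s", .data$embryo_id, .data$slot,
                        .data$spatial_label)
    )
  design$ess_truth <- vapply(seq_len(nrow(design)), function(i) {
    mu <- if (design$spatial_label[i] == low_group) lo_mean else base_ess
    with_seed(derive_seed(seed, design$embryo_id[i], design$cell_id[i],
                          "truth"),
              min(max(rnorm(1, mu, dispersion), 0.001), 0.999))
  }, numeric(1))
  truth <- design %>%
    select("embryo_id", "cell_id", "spatial_label", "ess_truth")
  sheet <- design %>%
    transmute_sheet(spike_in_expected)
  out <- list(sample_sheet = sheet, truth = truth)
  if (emit_reads) {
    sims <- purrr::map(seq_len(nrow(design)), function(i) {
      pr <- ess_to_read_proportions(design$ess_truth[i], catalog)
      full <- setNames(rep(0, nrow(catalog$isoforms)),
                       catalog$isoforms$isoform)
      full[names(pr)] <- pr
      simulate_cell_reads(catalog, n_reads = n_reads, read_len = read_len,
                          error_rate = error_rate, proportions = full,
                          spike_in_fraction = spike_in_fraction,
                          seed = seed, cell_id = design$cell_id[i])
    })
    out$reads <- purrr::map_dfr(seq_along(sims), function(i) {
      mutate(sims[[i]]$reads, cell_id = design$cell_id[i])
    })
    out$read_truth <- purrr::map_dfr(seq_along(sims), function(i) {
      mutate(sims[[i]]$truth, cell_id = design$cell_id[i])
    })
  }
  out
}

transmute_sheet <- function(design, spike_in_expected) {
  tibble(cell_id = design$cell_id, embryo_id = design$embryo_id,
         spatial_label = design$spatial_label,
         spike_in_expected = spike_in_expected)
}

#' Simulate RNA sources with one planted identical fragment
#'
#' Two random-composition RNA sequences that share a single identical
#' `planted_fragment_len`-nt stretch, placed on the fragmentation grid of
#' both sources so that [split_into_fragments()] recovers it exactly (its
#' pairwise f value is therefore 0); plus an independent pool of random
#' null fragments for [build_null()].
#'
#' @param seed integer seed.
#' @param lengths lengths of the two source sequences (each at least
#'   `planted_fragment_len`).
#' @param planted_fragment_len length of the shared fragment (default 500).
#' @param fragment_len,overlap fragmentation grid the planted offsets are
#'   aligned to (defaults 500 / 100).
#' @param n_null number of random null fragments (default 1000).
#' @return list with `sources` (tibble `source_id`, `sequence`), `planted`
#'   (offsets of the shared fragment in each source) and `null_fragments`
#'   (tibble `fragment_id`, `sequence`).
#' @export
simulate_rna_sources <- function(seed = 1, lengths = c(2000, 2600),
                                 planted_fragment_len = 500,
                                 fragment_len = 500, overlap = 100,
                                 n_null = 1000) {
  stopifnot(length(lengths) == 2)
  if (any(lengths < planted_fragment_len)) {
    abort("Source lengths must be at least `planted_fragment_len`.")
  }
  step <- fragment_len - overlap
  rna <- c("A", "C", "G", "U")
  with_seed(derive_seed(seed, "rna_sources"), {
    planted <- random_dna(planted_fragment_len, rna)
    seqs <- vapply(lengths, random_dna, character(1), alphabet = rna)
    starts <- vapply(lengths, function(L) {
      grid <- seq(0, L - fragment_len, by = step)
      grid[sample.int(length(grid), 1)]
    }, numeric(1))
    for (i in 1:2) {
      substr(seqs[i], starts[i] + 1,
             starts[i] + planted_fragment_len) <- planted
    }
    null_frags <- vapply(seq_len(n_null), function(i)
      random_dna(fragment_len, rna), character(1))
    list(
      sources = tibble(source_id = c("query", "reference"),
                       sequence = unname(seqs)),
      planted = tibble(source_id = c("query", "reference"),
                       start = as.integer(starts),
                       end = as.integer(starts + planted_fragment_len)),
      null_fragments = tibble(
        fragment_id = sprintf("null%05d", seq_len(n_null)),
        sequence = null_frags
      )
    )
  })
}

#' Write simulated reads as a FASTQ pair
#'
#' Four-line FASTQ records with constant quality; file names are
#' `<cell_id>_R1.fastq` and `<cell_id>_R2.fastq` under `dir`.
#'
#' @param reads tibble with `read_id`, `fwd`, `rev`.
#' @param dir output directory (created if needed).
#' @param cell_id file name stem.
#' @return invisible character vector of the two paths.
#' @export
write_fastq_pair <- function(reads, dir, cell_id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cell_id, c("_R1.fastq", "_R2.fastq")))
  emit <- function(seqs, ids, path) {
    qs <- strrep("I", nchar(seqs))
    readr::write_lines(
      as.vector(rbind(paste0("@", ids), seqs, "+", qs)), path)
  }
  emit(reads$fwd, reads$read_id, paths[1])
  emit(reads$rev, reads$read_id, paths[2])
  invisible(paths)
}
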