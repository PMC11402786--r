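#' End-to-end ESS analysis of a demultiplexed cell panel
#'
#' Runs the full splicing pipeline: reads the sample sheet, classifies every
#' cell's FASTQ pair against the gene model, computes per-cell
#' length-normalized ESS profiles, spike-in scale factors, per-embryo
#' relative levels, and the spatial-group comparisons (pB vs npB and/or nB
#' vs fB two-tailed Student's t on the total-ESS fraction).  All outputs are
#' written to `out_dir` as TSV/JSON together with the fully-resolved
#' configuration.
#'
#' @param sample_sheet path to a TSV with columns `cell_id`, `embryo_id`,
#'   `spatial_label`, `spike_in_expected`, or an equivalent data frame.
#' @param fastq_dir directory holding `<cell_id>_R1.fastq[.gz]` and
#'   `<cell_id>_R2.fastq[.gz]` for every cell in the sheet.
#' @param gene_model an [build_isoform_catalog()] object (default the
#'   bundled synthetic panel).
#' @param out_dir output directory.
#' @param force overwrite existing outputs (default `FALSE`).
#' @inheritParams count_sample
#' @return (invisibly) a list with `counts`, `profiles`, `normalized`,
#'   `embryo_summary`, `comparisons`.
#' @export
run_ess <- function(sample_sheet, fastq_dir, gene_model = default_gene_model(),
                    out_dir, force = FALSE,
                    min_overlap = 10, max_mismatch_frac = 0.1,
                    max_edit_frac = 0.1, min_margin = 2, k = 12) {
  sheet <- if (is.data.frame(sample_sheet)) as_tibble(sample_sheet)
           else readr::read_tsv(sample_sheet, show_col_types = FALSE,
                                progress = FALSE)
  need <- c("cell_id", "embryo_id", "spatial_label", "spike_in_expected")
  if (!all(need %in% names(sheet))) {
    abort(paste0("Sample sheet must have columns: ",
                 paste(need, collapse = ", ")))
  }
  find_fq <- function(cell, mate) {
    cands <- file.path(fastq_dir, paste0(cell, "_R", mate,
                                         c(".fastq", ".fastq.gz", ".fq")))
    hit <- cands[file.exists(cands)]
    if (length(hit) == 0) NA_character_ else hit[1]
  }
  f1 <- vapply(sheet$cell_id, find_fq, character(1), mate = 1)
  f2 <- vapply(sheet$cell_id, find_fq, character(1), mate = 2)
  missing <- sheet$cell_id[is.na(f1) | is.na(f2)]
  if (length(missing) > 0) {
    abort(paste0("No FASTQ pair found for cell(s): ",
                 paste(missing, collapse = ", ")))
  }
  prepare_out_dir(out_dir, force,
                  c("counts.tsv", "profiles.tsv", "normalized.tsv",
                    "embryo_summary.tsv", "group_comparisons.json",
                    "config.json"))
  counts <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
    pairs <- read_fastq_pairs(f1[i], f2[i])
    count_sample(pairs, gene_model, sample_id = sheet$cell_id[i],
                 min_overlap = min_overlap,
                 max_mismatch_frac = max_mismatch_frac,
                 max_edit_frac = max_edit_frac, min_margin = min_margin,
                 k = k)
  })
  profiles <- ess_percentages(counts, gene_model)
  normalized <- spike_in_normalize(counts, sheet)
  esum <- relative_levels_within_embryo(profiles, sheet, counts,
                                        metric = "ESS")
  ess_vals <- profiles %>%
    filter(.data$isoform == "noS", .data$in_model) %>%
    mutate(ess = 1 - .data$percentage) %>%
    select(cell_id = "sample_id", "ess") %>%
    left_join(sheet, by = "cell_id")
  comparisons <- list()
  for (pair in list(c("pB", "npB"), c("nB", "fB"))) {
    va <- ess_vals$ess[ess_vals$spatial_label == pair[1]]
    vb <- ess_vals$ess[ess_vals$spatial_label == pair[2]]
    if (length(va) >= 2 && length(vb) >= 2) {
      cmp <- compare_spatial_groups(va, vb, labels = pair)
      comparisons[[paste(pair, collapse = "_vs_")]] <- list(
        group_a = pair[1], group_b = pair[2],
        n_a = cmp$n_a, n_b = cmp$n_b,
        mean_a = mean(va), mean_b = mean(vb),
        statistic = cmp$statistic, df = cmp$df, p_value = cmp$p.value,
        alternative = cmp$alternative
      )
    }
  }
  readr::write_tsv(as_tibble(counts), file.path(out_dir, "counts.tsv"))
  readr::write_tsv(as_tibble(profiles), file.path(out_dir, "profiles.tsv"))
  readr::write_tsv(as_tibble(normalized), file.path(out_dir, "normalized.tsv"))
  readr::write_tsv(as_tibble(esum), file.path(out_dir, "embryo_summary.tsv"))
  jsonlite::write_json(comparisons, file.path(out_dir, "group_comparisons.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(pipeline = "run_ess", fastq_dir = fastq_dir,
         n_cells = nrow(sheet), gene_id = gene_model$gene_id,
         merge_limit_nt = gene_model$merge_limit_nt,
         min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac,
         max_edit_frac = max_edit_frac, min_margin = min_margin, k = k),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(counts = counts, profiles = profiles,
                 normalized = normalized, embryo_summary = esum,
                 comparisons = comparisons))
}

#' End-to-end structure-similarity comparison of two RNAs
#'
#' Fragments the query and reference RNAs into overlapping windows, folds
#' every fragment, computes all pairwise f values, builds the empirical
#' null from the supplied null fragments (reference fragments vs null
#' pool), and reports fragment pairs below the left-tail threshold.
#'
#' @param query_fasta,ref_fasta FASTA paths (or named character vectors) of
#'   the two RNAs.
#' @param null_fragments tibble with a `sequence` column (e.g. from
#'   [simulate_rna_sources()]), or a FASTA path of mRNA sequences that are
#'   fragmented on the same grid.
#' @param out_dir output directory.
#' @param fragment_len,overlap fragmentation parameters (defaults 500/100).
#' @param alpha left-tail fraction of the null (default 0.025).
#' @param folder structure predictor, see [fold()].
#' @param force overwrite existing outputs.
#' @return (invisibly) a list with `fragments`, `f_table`, `null`, `hits`.
#' @export
run_struct <- function(query_fasta, ref_fasta, null_fragments, out_dir,
                       fragment_len = 500, overlap = 100, alpha = 0.025,
                       folder = fold, force = FALSE) {
  read_src <- function(x, fallback_id) {
    if (is.character(x) && (length(x) == 0 || !any(nzchar(x)))) {
      abort("Sequence input is empty: need a FASTA path or a non-empty named character vector.")
    }
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      s <- Biostrings::readBStringSet(x)
      if (length(s) == 0) abort(paste0("Empty FASTA: ", x))
      setNames(as.character(s), names(s))
    } else if (is.character(x)) {
      if (is.null(names(x))) names(x) <- fallback_id
      x
    } else {
      abort("Sequence inputs must be FASTA paths or named character vectors.")
    }
  }
  q <- read_src(query_fasta, "query")
  r <- read_src(ref_fasta, "reference")
  if (is.character(null_fragments) && length(null_fragments) == 1 &&
      file.exists(null_fragments)) {
    nf <- split_into_fragments(read_src(null_fragments, "null"),
                               fragment_len, overlap)
  } else {
    nf <- as_tibble(null_fragments)
  }
  stopifnot("sequence" %in% names(nf))
  prepare_out_dir(out_dir, force,
                  c("fragments.tsv", "f_matrix.tsv", "null.json",
                    "similar_fragments.tsv", "config.json"))
  fq <- split_into_fragments(q, fragment_len, overlap)
  fr <- split_into_fragments(r, fragment_len, overlap)
  if (!"fragment_id" %in% names(nf)) {
    nf$fragment_id <- sprintf("null%05d", seq_len(nrow(nf)))
  }
  null_f <- pairwise_f_matrix(fr, nf, folder = folder)
  null <- build_null(null_f$f, alpha = alpha)
  ftab <- pairwise_f_matrix(fq, fr, folder = folder)
  hits <- find_similar_fragments(ftab, null)
  readr::write_tsv(bind_rows(fq, fr), file.path(out_dir, "fragments.tsv"))
  readr::write_tsv(as_tibble(ftab), file.path(out_dir, "f_matrix.tsv"))
  jsonlite::write_json(
    list(n = null$n, alpha = null$alpha, threshold = null$threshold),
    file.path(out_dir, "null.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(as_tibble(hits), file.path(out_dir, "similar_fragments.tsv"))
  jsonlite::write_json(
    list(pipeline = "run_struct", fragment_len = fragment_len,
         overlap = overlap, alpha = alpha,
         n_query_fragments = nrow(fq), n_ref_fragments = nrow(fr),
         n_null_fragments = nrow(nf)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(fragments = bind_rows(fq, fr), f_table = ftab,
                 null = null, hits = hits))
}

prepare_out_dir <- function(out_dir, force, files) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    return(invisible(out_dir))
  }
  clash <- files[file.exists(file.path(out_dir, files))]
  if (length(clash) > 0 && !force) {
    abort(paste0("Output file(s) already exist in `", out_dir,
                 "` (use force = TRUE to overwrite): ",
                 paste(clash, collapse = ", ")))
  }
  invisible(out_dir)
}
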