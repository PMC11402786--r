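#' Reverse-complement a character vector of DNA sequences
#' @noRd
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Merge paired-end amplicon reads by overlap consensus
#'
#' Scans all candidate overlaps of at least `min_overlap` nucleotides between
#' the forward read and the reverse-complemented reverse read and accepts the
#' longest overlap whose mismatch fraction does not exceed
#' `max_mismatch_frac`; pairs with no acceptable overlap are reported
#' unmerged.  The merged sequence has length
#' `nchar(fwd) + nchar(rev) - overlap`.  At overlap mismatches the forward
#' base is kept unless per-base qualities are supplied and the reverse base
#' is better.
#'
#' @param pairs data frame with columns `read_id`, `fwd`, `rev` (the reverse
#'   mate as sequenced, i.e. reverse-complement orientation) and optionally
#'   `qual_fwd`, `qual_rev` (phred strings).
#' @param min_overlap minimum acceptable overlap in nt (default 10).
#' @param max_mismatch_frac maximum fraction of mismatching bases within the
#'   overlap (default 0.1; must be below 0.5).
#' @param use_quality if `TRUE` and quality strings are present, overlap
#'   mismatches take the higher-quality base instead of the forward base.
#' @return tibble with `read_id`, `merged` (logical), `sequence`,
#'   `overlap_len`, `mismatches_in_overlap` (the last three `NA` for
#'   unmerged pairs).
#' @examples
#' amp <- paste(sample(c("A","C","G","T"), 450, TRUE), collapse = "")
#' pair <- tibble::tibble(
#'   read_id = "r1",
#'   fwd = substr(amp, 1, 300),
#'   rev = as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString(substr(amp, 151, 450))))
#' )
#' merge_read_pairs(pair)
#' @export
merge_read_pairs <- function(pairs, min_overlap = 10, max_mismatch_frac = 0.1,
                             use_quality = FALSE) {
  stopifnot(is.data.frame(pairs))
  if (min_overlap < 1) abort("`min_overlap` must be at least 1.")
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 0.5) {
    abort("`max_mismatch_frac` must be in [0, 0.5).")
  }
  if (nrow(pairs) == 0) {
    return(tibble(read_id = character(), merged = logical(),
                  sequence = character(), overlap_len = integer(),
                  mismatches_in_overlap = integer()))
  }
  if (any(!nzchar(pairs$fwd)) || any(!nzchar(pairs$rev)) ||
      anyNA(pairs$fwd) || anyNA(pairs$rev)) {
    abort("Both mates of every pair must be non-empty.")
  }
  rev_rc <- revcomp(pairs$rev)
  qf <- character(0); qr <- character(0)
  if (use_quality && all(c("qual_fwd", "qual_rev") %in% names(pairs))) {
    qf <- pairs$qual_fwd
    # reverse the reverse-mate qualities to match the reverse-complemented
    # sequence orientation
    qr <- vapply(pairs$qual_rev,
                 function(q) paste(rev(strsplit(q, "")[[1]]), collapse = ""),
                 character(1), USE.NAMES = FALSE)
  }
  res <- cpp_merge_pairs(pairs$fwd, rev_rc, as.integer(min_overlap),
                         max_mismatch_frac, qf, qr)
  tibble(read_id = pairs$read_id, merged = res$merged,
         sequence = as.character(res$sequence),
         overlap_len = res$overlap_len,
         mismatches_in_overlap = res$mismatches_in_overlap)
}

#' @rdname merge_read_pairs
#' @param fwd,rev single forward / reverse read sequences.
#' @return `merge_read_pair()` returns a one-row tibble of the same shape.
#' @export
merge_read_pair <- function(fwd, rev, min_overlap = 10,
                            max_mismatch_frac = 0.1) {
  merge_read_pairs(tibble(read_id = "read", fwd = fwd, rev = rev),
                   min_overlap = min_overlap,
                   max_mismatch_frac = max_mismatch_frac)
}

#' Classification references of a catalog
#'
#' All isoform references plus the spike-in, as a tibble.
#' @noRd
classification_references <- function(catalog) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  refs <- tibble(label = catalog$isoforms$isoform,
                 sequence = chartr("U", "T", catalog$isoforms$sequence),
                 long = catalog$isoforms$long)
  if (!is.null(catalog$spike_in)) {
    refs <- bind_rows(refs, tibble(label = "spike_in",
                                   sequence = chartr("U", "T", unname(catalog$spike_in)),
                                   long = FALSE))
  }
  refs$length <- nchar(refs$sequence)
  refs
}

#' Classify full-length reads against an isoform catalog
#'
#' Computes the global edit distance (Levenshtein; substitutions and gaps at
#' unit cost) from each read to every reference of the catalog — all isoform
#' references, including the long ones (so full-length single-molecule reads
#' classify on the same path), plus the spike-in — and assigns the unique
#' best reference when `best_distance <= max_edit_frac * reference_length`
#' and the runner-up is at least `min_margin` edits worse.  Ties and
#' sub-margin wins are reported unclassified, never broken at random.
#'
#' Distances are computed with a banded dynamic program capped just above the
#' largest admissible distance plus the margin, which leaves every
#' assignment decision identical to the full distance matrix.
#'
#' @param seqs character vector of read sequences (merged pairs or
#'   full-length single-molecule reads).
#' @param catalog an [build_isoform_catalog()] object.
#' @param max_edit_frac maximum distance as a fraction of the reference
#'   length (default 0.1).
#' @param min_margin minimum lead (in edits) of the best reference over the
#'   runner-up (default 2).
#' @return tibble with `label` (isoform, `"spike_in"`, or `"unclassified"`),
#'   `best_ref`, `best_distance` and `second_distance` (distances above the
#'   decision cap are reported as `NA`).
#' @export
classify_reads <- function(seqs, catalog, max_edit_frac = 0.1,
                           min_margin = 2) {
  refs <- classification_references(catalog)
  if (nrow(refs) == 0) abort("Catalog has no references.")
  n <- length(seqs)
  if (n == 0) {
    return(tibble(label = character(), best_ref = character(),
                  best_distance = integer(), second_distance = integer()))
  }
  maxd <- floor(max_edit_frac * refs$length)
  cap <- max(maxd) + min_margin
  seqs <- toupper(chartr("U", "T", seqs))
  d <- cpp_distance_matrix(seqs, refs$sequence, as.integer(cap))
  best_j <- max.col(-d, ties.method = "first")
  best <- d[cbind(seq_len(n), best_j)]
  d2 <- d
  d2[cbind(seq_len(n), best_j)] <- NA_integer_
  second <- if (ncol(d2) > 1) {
    do.call(pmin, c(lapply(seq_len(ncol(d2)), function(j) d2[, j]),
                    list(na.rm = TRUE)))
  } else {
    rep(NA_integer_, n)
  }
  second[is.na(second)] <- cap + 1L  # sole reference: margin trivially met
  tie <- rowSums(d == best) > 1
  ok <- !tie & best <= maxd[best_j] & (second - best) >= min_margin
  tibble(
    label = ifelse(ok, refs$label[best_j], "unclassified"),
    best_ref = refs$label[best_j],
    best_distance = ifelse(best > cap, NA_integer_, best),
    second_distance = ifelse(second > cap, NA_integer_, second)
  )
}

#' @rdname classify_reads
#' @param seq a single read sequence.
#' @return `classify_merged_read()` returns the assigned label as a length-1
#'   character vector.
#' @export
classify_merged_read <- function(seq, catalog, max_edit_frac = 0.1,
                                 min_margin = 2) {
  classify_reads(seq, catalog, max_edit_frac = max_edit_frac,
                 min_margin = min_margin)$label
}

#' Classify unmergeable read pairs between the long isoforms
#'
#' Pairs whose amplicon exceeds the merge limit (here the canonical noS and
#' the long-exon-4 E3a isoforms) never merge; their mates cover only the
#' amplicon ends.  A pair is accepted as long-amplicon evidence when the
#' forward mate matches the shared 5' prefix of a long-isoform reference and
#' the reverse-complemented reverse mate matches a 3' suffix, each within
#' `max_edit_frac` of the mate length.  The two long isoforms are then
#' separated by the diagnostic junction signature of the exon-4 extension
#' (the E4/E4ext junction 2k-mer): pairs carrying it in either mate are the
#' extension variant, pairs without it the canonical isoform.  The signature
#' search is edit-tolerant (up to `floor(max_edit_frac * 2k)` edits) so that
#' sequencing errors do not silently misroute extension reads.  Pairs
#' matching no long-isoform end are unclassified.
#'
#' @inheritParams merge_read_pairs
#' @param catalog an [build_isoform_catalog()] object whose long isoforms
#'   include a diagnostic extension junction (e.g. noS and E3a).
#' @param k signature flank length (default 12), see
#'   [junction_signatures()].
#' @param max_edit_frac per-mate distance tolerance as a fraction of mate
#'   length (default 0.1).
#' @return tibble with `read_id` and `label` (one of the long isoform
#'   labels or `"unclassified"`).
#' @export
classify_unmerged_pairs <- function(pairs, catalog, k = 12,
                                    max_edit_frac = 0.1) {
  stopifnot(is.data.frame(pairs), inherits(catalog, "isoform_catalog"))
  long <- catalog$isoforms[catalog$isoforms$long, ]
  if (nrow(long) == 0) {
    abort("Catalog defines no long isoforms; nothing to classify unmerged pairs against.")
  }
  if (nrow(pairs) == 0) {
    return(tibble(read_id = character(), label = character()))
  }
  sig <- junction_signatures(catalog, k = k)
  # signatures diagnostic of exactly one long isoform separate the variants
  diag_sig <- sig[sig$diagnostic & sig$isoform %in% long$isoform, ]
  refs <- chartr("U", "T", setNames(long$sequence, long$isoform))
  refs_rev <- vapply(refs, function(r)
    paste(rev(strsplit(r, "")[[1]]), collapse = ""), character(1))
  rev_rc <- revcomp(pairs$rev)
  fwd <- toupper(pairs$fwd)
  lab <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    tol_f <- floor(max_edit_frac * nchar(fwd[i]))
    tol_r <- floor(max_edit_frac * nchar(rev_rc[i]))
    pre_d <- vapply(refs, function(r)
      cpp_anchored_distance(fwd[i], r, FALSE, TRUE), integer(1))
    rrev <- paste(rev(strsplit(rev_rc[i], "")[[1]]), collapse = "")
    suf_d <- vapply(refs_rev, function(r)
      cpp_anchored_distance(rrev, r, FALSE, TRUE), integer(1))
    if (min(pre_d) > tol_f || min(suf_d) > tol_r) {
      lab[i] <- "unclassified"
      next
    }
    hit <- vapply(seq_len(nrow(diag_sig)), function(s) {
      sg <- diag_sig$signature[s]
      tol_s <- floor(max_edit_frac * nchar(sg))
      cpp_anchored_distance(sg, fwd[i], TRUE, TRUE) <= tol_s ||
        cpp_anchored_distance(sg, rev_rc[i], TRUE, TRUE) <= tol_s
    }, logical(1))
    hit_iso <- unique(diag_sig$isoform[hit])
    if (length(hit_iso) == 1) {
      lab[i] <- hit_iso
    } else if (length(hit_iso) > 1) {
      lab[i] <- "unclassified"  # conflicting diagnostic evidence
    } else {
      # no extension evidence: the remaining long isoform(s) without a
      # diagnostic signature of their own; unique -> assign, else ambiguous
      rest <- setdiff(long$isoform, unique(diag_sig$isoform))
      lab[i] <- if (length(rest) == 1) rest else "unclassified"
    }
  }
  tibble(read_id = pairs$read_id, label = lab)
}

#' @rdname classify_unmerged_pairs
#' @param fwd,rev single mate sequences.
#' @export
classify_unmerged_pair <- function(fwd, rev, catalog, k = 12,
                                   max_edit_frac = 0.1) {
  classify_unmerged_pairs(tibble(read_id = "read", fwd = fwd, rev = rev),
                          catalog, k = k, max_edit_frac = max_edit_frac)$label
}

#' Count classified reads for one sample
#'
#' The full read-classification stage: every pair is merged where possible;
#' merged reads (and single full-length reads) are classified against all
#' references by [classify_reads()]; unmergeable pairs are routed to the
#' long-isoform path ([classify_unmerged_pairs()]).  Counts are returned for
#' every isoform of the catalog plus `spike_in` and `unclassified`, and
#' conserve the number of input reads exactly.
#'
#' @param reads either a data frame with columns `read_id`, `fwd` and
#'   optionally `rev` (`NA` rev = full-length single read), or a character
#'   vector of full-length read sequences.
#' @param catalog an [build_isoform_catalog()] object.
#' @param sample_id label for the output.
#' @inheritParams merge_read_pairs
#' @inheritParams classify_reads
#' @param k signature flank length for the unmerged path.
#' @return tibble of class `classification_counts` with columns `sample_id`,
#'   `category` (isoform labels, `spike_in`, `unclassified`) and `count`.
#' @export
count_sample <- function(reads, catalog, sample_id = "sample",
                         min_overlap = 10, max_mismatch_frac = 0.1,
                         max_edit_frac = 0.1, min_margin = 2, k = 12) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)),
                    fwd = reads, rev = NA_character_)
  }
  stopifnot(is.data.frame(reads))
  refs <- classification_references(catalog)
  cats <- c(setdiff(refs$label, "spike_in"), "spike_in", "unclassified")
  labels <- character(nrow(reads))
  if (nrow(reads) > 0) {
    has_rev <- !is.na(reads$rev) & nzchar(reads$rev)
    if (any(has_rev)) {
      m <- merge_read_pairs(reads[has_rev, , drop = FALSE],
                            min_overlap = min_overlap,
                            max_mismatch_frac = max_mismatch_frac)
      merged_ok <- m$merged
      idx_pair <- which(has_rev)
      if (any(merged_ok)) {
        cl <- classify_reads(m$sequence[merged_ok], catalog,
                             max_edit_frac = max_edit_frac,
                             min_margin = min_margin)
        labels[idx_pair[merged_ok]] <- cl$label
      }
      if (any(!merged_ok)) {
        cu <- classify_unmerged_pairs(
          reads[idx_pair[!merged_ok], , drop = FALSE], catalog,
          k = k, max_edit_frac = max_edit_frac)
        labels[idx_pair[!merged_ok]] <- cu$label
      }
    }
    if (any(!has_rev)) {
      cl <- classify_reads(reads$fwd[!has_rev], catalog,
                           max_edit_frac = max_edit_frac,
                           min_margin = min_margin)
      labels[!has_rev] <- cl$label
    }
  }
  counts <- table(factor(labels, levels = cats))
  out <- tibble(sample_id = sample_id, category = cats,
                count = as.integer(counts))
  class(out) <- c("classification_counts", class(out))
  out
}

#' Read a pair of FASTQ files into a read-pair tibble
#'
#' @param file_fwd,file_rev paths to the forward and reverse FASTQ files
#'   (plain or gzipped); mate order must correspond.
#' @return tibble with `read_id`, `fwd`, `rev`.
#' @export
read_fastq_pairs <- function(file_fwd, file_rev) {
  fq <- function(path) {
    lines <- readr::read_lines(path, progress = FALSE)
    n <- length(lines)
    if (n %% 4 != 0) {
      abort(sprintf("Malformed FASTQ `%s`: truncated record %d.",
                    path, n %/% 4 + 1))
    }
    if (n == 0) {
      return(tibble(read_id = character(), seq = character()))
    }
    heads <- lines[seq(1, n, by = 4)]
    seps <- lines[seq(3, n, by = 4)]
    bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
    if (length(bad) > 0) {
      abort(sprintf("Malformed FASTQ `%s`: record %d.", path, bad[1]))
    }
    seqs <- lines[seq(2, n, by = 4)]
    quals <- lines[seq(4, n, by = 4)]
    if (any(nchar(seqs) != nchar(quals))) {
      abort(sprintf("Malformed FASTQ `%s`: record %d has mismatched quality length.",
                    path, which(nchar(seqs) != nchar(quals))[1]))
    }
    tibble(read_id = sub(" .*", "", substring(heads, 2)), seq = seqs)
  }
  f <- fq(file_fwd)
  r <- fq(file_rev)
  if (nrow(f) != nrow(r)) {
    abort(sprintf("Mate files differ in record count (%d vs %d).",
                  nrow(f), nrow(r)))
  }
  tibble(read_id = f$read_id, fwd = f$seq, rev = r$seq)
}

#' Write per-sample classification counts as TSV
#'
#' @param counts a `classification_counts` tibble (possibly several samples
#'   bound together).
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(counts)
}
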