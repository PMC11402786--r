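#' Build an isoform catalog for a skipping-prone amplicon
#'
#' An isoform catalog holds the exon table and the exon chains of every
#' splicing isoform of one amplicon, together with the concatenated reference
#' sequence of each isoform.  Isoforms whose amplicon is longer than
#' `merge_limit_nt` cannot be merged from paired-end reads and are flagged as
#' *long*; they are handled by the unmerged-pair classification route (see
#' [classify_unmerged_pairs()]).
#'
#' Coordinates are 0-based and half-open throughout; a junction position is
#' the index of the first base of the downstream exon.
#'
#' @param exons data frame with columns `exon_id` and `sequence` (one row per
#'   exon, in genomic order).
#' @param chains named list mapping isoform labels (e.g. `"noS"`, `"E56S"`) to
#'   character vectors of exon ids in transcript order.
#' @param merge_limit_nt amplicons strictly longer than this cannot be merged
#'   from paired-end reads and the isoform is flagged long.  Default 600 nt.
#' @param gene_id label for the gene model.
#' @param spike_in optional named character vector of length 1: a spike-in
#'   reference sequence (e.g. a synthetic Gfp fragment) classified alongside
#'   the isoforms.
#'
#' @return An object of class `isoform_catalog`: a list with tibbles `exons`
#'   (`exon_id`, `sequence`, `length`) and `isoforms` (`isoform`, `chain`
#'   list-column, `length`, `sequence`, `long`), plus `gene_id`,
#'   `merge_limit_nt` and `spike_in`.
#' @examples
#' exons <- tibble::tibble(
#'   exon_id  = c("E1", "E2", "E3"),
#'   sequence = c(strrep("A", 50), strrep("G", 50), strrep("C", 50))
#' )
#' cat <- build_isoform_catalog(
#'   exons,
#'   chains = list(full = c("E1", "E2", "E3"), skip = c("E1", "E3")),
#'   merge_limit_nt = 120
#' )
#' cat$isoforms
#' @export
build_isoform_catalog <- function(exons, chains, merge_limit_nt = 600,
                                  gene_id = "gene", spike_in = NULL) {
  stopifnot(is.data.frame(exons), is.list(chains))
  if (merge_limit_nt <= 0) abort("`merge_limit_nt` must be positive.")
  exons <- as_tibble(exons)
  if (!all(c("exon_id", "sequence") %in% names(exons))) {
    abort("`exons` needs columns `exon_id` and `sequence`.")
  }
  exons$sequence <- toupper(exons$sequence)
  exons$length <- nchar(exons$sequence)
  if (any(exons$length == 0)) abort("Every exon sequence must be non-empty.")
  if (anyDuplicated(exons$exon_id)) {
    abort("Exon ids must be unique within a gene model.")
  }
  labs <- names(chains)
  if (is.null(labs) || any(labs == "") || anyDuplicated(labs)) {
    abort("`chains` must be a uniquely named list of isoform chains.")
  }
  exon_rank <- setNames(seq_len(nrow(exons)), exons$exon_id)
  for (lab in labs) {
    ch <- chains[[lab]]
    unknown <- setdiff(ch, exons$exon_id)
    if (length(unknown) > 0) {
      abort(paste0("Isoform `", lab, "` references unknown exon(s): ",
                   paste(unknown, collapse = ", ")))
    }
    if (is.unsorted(exon_rank[ch], strictly = TRUE)) {
      abort(paste0("Exon chain of `", lab,
                   "` is not strictly increasing in genomic order."))
    }
  }
  seqs <- setNames(exons$sequence, exons$exon_id)
  iso <- tibble(
    isoform  = labs,
    chain    = unname(chains),
    sequence = unname(vapply(chains, function(ch)
      paste(seqs[ch], collapse = ""), character(1)))
  )
  iso$length <- nchar(iso$sequence)
  iso$long <- iso$length > merge_limit_nt
  if (!is.null(spike_in)) {
    stopifnot(is.character(spike_in), length(spike_in) == 1)
    if (is.null(names(spike_in))) names(spike_in) <- "spike_in"
    spike_in <- toupper(spike_in)
  }
  structure(
    list(gene_id = gene_id, exons = exons, isoforms = iso,
         merge_limit_nt = merge_limit_nt, spike_in = spike_in),
    class = "isoform_catalog"
  )
}

#' @export
print.isoform_catalog <- function(x, ...) {
  cat("<isoform_catalog> gene:", x$gene_id, "\n")
  cat("  exons:", nrow(x$exons), " isoforms:", nrow(x$isoforms),
      " merge limit:", x$merge_limit_nt, "nt\n")
  longs <- x$isoforms$isoform[x$isoforms$long]
  cat("  long (unmergeable) isoforms:",
      if (length(longs)) paste(longs, collapse = ", ") else "none", "\n")
  if (!is.null(x$spike_in)) {
    cat("  spike-in:", names(x$spike_in), sprintf("(%d nt)\n",
        nchar(x$spike_in)))
  }
  invisible(x)
}

#' Summed length of a set of exons
#'
#' Realizes the denominators of the length-normalized splicing percentages:
#' the total length `L` of the listed exons (for example `L(E2..E7)` for the
#' non-skipping isoform or `L(E4 + E7)` for the exons flanking a skipped
#' block).
#'
#' @param catalog an [build_isoform_catalog()] object.
#' @param exon_ids character vector of exon ids.  An empty vector returns 0
#'   with a warning: an empty exon set is never a valid denominator.
#' @return total length in nucleotides.
#' @export
exon_chain_length <- function(catalog, exon_ids) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  if (length(exon_ids) == 0) {
    warn("Empty exon list: length 0 is never a valid denominator.")
    return(0L)
  }
  unknown <- setdiff(exon_ids, catalog$exons$exon_id)
  if (length(unknown) > 0) {
    abort(paste0("Unknown exon id(s): ", paste(unknown, collapse = ", ")))
  }
  lens <- setNames(catalog$exons$length, catalog$exons$exon_id)
  sum(lens[exon_ids])
}

#' Exon-exon junction signatures of a catalog
#'
#' For every isoform, every exon-exon junction is described by its 0-based
#' offset in the isoform reference (the first base of the downstream exon)
#' and the flanking k-mers.  Signatures whose concatenated 2k-mer occurs in
#' exactly one isoform reference are marked *diagnostic*; the diagnostic
#' signature at the E4/E4ext junction is what separates the long-exon-4
#' variant from the canonical long isoform in unmerged read pairs.
#'
#' @param catalog an [build_isoform_catalog()] object.
#' @param k flank length in nucleotides (default 12, must be at least 6 and
#'   no longer than the shortest exon).
#' @return tibble with one row per junction per isoform: `isoform`,
#'   `junction` ("left|right" exon ids), `position`, `left_kmer`,
#'   `right_kmer`, `signature` (the 2k-mer) and `diagnostic`.
#' @export
junction_signatures <- function(catalog, k = 12) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  if (k < 6) abort("`k` must be at least 6.")
  short <- catalog$exons$exon_id[catalog$exons$length < k]
  if (length(short) > 0) {
    abort(paste0("Exon(s) shorter than k = ", k, ": ",
                 paste(short, collapse = ", ")))
  }
  lens <- setNames(catalog$exons$length, catalog$exons$exon_id)
  rows <- purrr::map_dfr(seq_len(nrow(catalog$isoforms)), function(i) {
    ch <- catalog$isoforms$chain[[i]]
    if (length(ch) < 2) return(tibble())
    ref <- catalog$isoforms$sequence[i]
    offs <- cumsum(lens[ch])[-length(ch)]
    tibble(
      isoform   = catalog$isoforms$isoform[i],
      junction  = paste(ch[-length(ch)], ch[-1], sep = "|"),
      position  = as.integer(offs),
      left_kmer  = substr(rep(ref, length(offs)), offs - k + 1, offs),
      right_kmer = substr(rep(ref, length(offs)), offs + 1, offs + k)
    )
  })
  rows$signature <- paste0(rows$left_kmer, rows$right_kmer)
  refs <- catalog$isoforms$sequence
  rows$diagnostic <- vapply(rows$signature, function(sig) {
    sum(vapply(refs, function(r) grepl(sig, r, fixed = TRUE), logical(1))) == 1
  }, logical(1), USE.NAMES = FALSE)
  rows
}

#' Read and write gene models
#'
#' A gene model lives on disk as a FASTA of exon sequences (headers are exon
#' ids, in genomic order) plus a tab-separated table
#' `isoform_id<TAB>comma-separated exon ids`.  The round trip is
#' bit-identical.
#'
#' @param catalog an [build_isoform_catalog()] object.
#' @param fasta path of the exon FASTA.
#' @param tsv path of the isoform chain table.
#' @param merge_limit_nt,gene_id,spike_in passed to
#'   [build_isoform_catalog()] when reading.
#' @return `read_gene_model()` returns an `isoform_catalog`;
#'   `write_gene_model()` returns the catalog invisibly.
#' @name gene_model_io
#' @export
write_gene_model <- function(catalog, fasta, tsv) {
  stopifnot(inherits(catalog, "isoform_catalog"))
  seqs <- Biostrings::DNAStringSet(
    setNames(chartr("U", "T", catalog$exons$sequence), catalog$exons$exon_id))
  Biostrings::writeXStringSet(seqs, fasta)
  readr::write_tsv(
    tibble(
      isoform = catalog$isoforms$isoform,
      exons = vapply(catalog$isoforms$chain, paste, character(1),
                     collapse = ",")
    ),
    tsv, col_names = FALSE
  )
  invisible(catalog)
}

#' @rdname gene_model_io
#' @export
read_gene_model <- function(fasta, tsv, merge_limit_nt = 600,
                            gene_id = "gene", spike_in = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  exons <- tibble(exon_id = names(seqs), sequence = as.character(seqs))
  tab <- readr::read_tsv(tsv, col_names = c("isoform", "exons"),
                         col_types = "cc", progress = FALSE)
  chains <- setNames(strsplit(tab$exons, ",", fixed = TRUE), tab$isoform)
  build_isoform_catalog(exons, chains, merge_limit_nt = merge_limit_nt,
                        gene_id = gene_id, spike_in = spike_in)
}

#' The bundled synthetic Carm1-like gene model
#'
#' A desk-scale stand-in for the exon 2-7 amplicon panel of a
#' skipping-prone gene: six exons E2..E7 (140, 130, 120, 80, 70 and 70 nt)
#' plus a 60 nt 3' extension of exon 4 (`E4ext`, the long-exon-4 variant),
#' ten isoforms (noS, E3a, E3S, E4S, E5S, E6S, E34S, E56S, E345S, E3456S)
#' and a synthetic Gfp-like spike-in fragment.  The canonical (noS, 610 nt)
#' and long-exon-4 (E3a, 670 nt) amplicons exceed the 600 nt merge limit
#' and are therefore routed through the unmerged-pair path, as in the assay
#' the panel emulates; the exon lengths place the whole E4 extension and
#' its junction flanks inside the reverse 300 nt mate of the E3a amplicon,
#' so unmerged pairs carry the diagnostic signature.  All sequences are
#' synthetic (fixed at package build time) and chosen so that pairwise
#' isoform reference distances are far larger than the classification
#' margin.
#'
#' @return an `isoform_catalog`.
#' @export
default_gene_model <- function() {
  dir <- system.file("extdata", package = "essplice")
  spike <- Biostrings::readDNAStringSet(file.path(dir, "gfp_spike_synthetic.fa"))
  read_gene_model(
    fasta = file.path(dir, "carm1_like_exons.fa"),
    tsv = file.path(dir, "carm1_like_isoforms.tsv"),
    merge_limit_nt = 600, gene_id = "Carm1_like",
    spike_in = setNames(as.character(spike[1]), names(spike)[1])
  )
}
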