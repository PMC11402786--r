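# Independent oracles used across the suite.  These deliberately use naive
# algorithms (exhaustive recursion, full distance matrices) so the package's
# dynamic programs are checked against a different formulation.

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# --- exhaustive maximum-pairing oracle (all loop-legal structures) ---------
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1, j)
    ks <- seq(i + min_loop + 1, j)
    ks <- ks[ks <= j & ks >= i + min_loop + 1]
    for (k in ks) {
      if (paste0(s[i], s[k]) %in% ok) {
        v <- 1L + rec(i + 1, k - 1) + rec(k + 1, j)
        if (v > best) best <- v
      }
    }
    best
  }
  n <- length(s)
  if (n == 0) 0L else rec(1L, n)
}

# --- brute-force ordered forest edit distance ------------------------------
# Nested-list trees; memoised recursion on serialized forest pairs.  Same
# edit model as the package (unit insert/delete/relabel) but a different
# algorithm than the keyroot dynamic program.
oracle_parse_tree <- function(db) {
  node <- function(label) list(label = label, children = list())
  root <- node("R")
  parse_forest <- function(chars, pos) {
    kids <- list()
    while (pos <= length(chars)) {
      ch <- chars[pos]
      if (ch == ".") {
        kids[[length(kids) + 1]] <- node("U")
        pos <- pos + 1
      } else if (ch == "(") {
        inner <- parse_forest(chars, pos + 1)
        p <- node("P")
        p$children <- inner$kids
        kids[[length(kids) + 1]] <- p
        pos <- inner$pos + 1  # skip ")"
      } else {
        break
      }
    }
    list(kids = kids, pos = pos)
  }
  chars <- if (nchar(db) > 0) strsplit(db, "")[[1]] else character(0)
  res <- parse_forest(chars, 1)
  root$children <- res$kids
  root
}

oracle_tree_edit <- function(db1, db2) {
  ser <- function(t) {
    paste0(t$label, "(",
           paste(vapply(t$children, ser, character(1)), collapse = ""), ")")
  }
  ser_f <- function(F) paste(vapply(F, ser, character(1)), collapse = "")
  size_f <- function(F) {
    if (length(F) == 0) return(0L)
    sum(vapply(F, function(t) 1L + size_f(t$children), integer(1)))
  }
  memo <- new.env(parent = emptyenv())
  fed <- function(F1, F2) {
    if (length(F1) == 0 && length(F2) == 0) return(0L)
    k <- paste0(ser_f(F1), "|", ser_f(F2))
    got <- memo[[k]]
    if (!is.null(got)) return(got)
    if (length(F1) == 0) {
      r <- size_f(F2)
    } else if (length(F2) == 0) {
      r <- size_f(F1)
    } else {
      t1 <- F1[[length(F1)]]; L1 <- F1[-length(F1)]
      t2 <- F2[[length(F2)]]; L2 <- F2[-length(F2)]
      r <- min(
        fed(c(L1, t1$children), F2) + 1L,
        fed(F1, c(L2, t2$children)) + 1L,
        fed(L1, L2) + fed(t1$children, t2$children) +
          as.integer(t1$label != t2$label)
      )
    }
    memo[[k]] <- r
    r
  }
  fed(list(oracle_parse_tree(db1)), list(oracle_parse_tree(db2)))
}

# --- random balanced dot-bracket strings -----------------------------------
random_dot_bracket <- function(n) {
  if (n == 0) return("")
  out <- character(n)
  open <- 0L
  for (i in seq_len(n)) {
    remaining <- n - i + 1L
    choices <- character(0)
    if (remaining > open) choices <- c(choices, ".")
    if (remaining > open + 1L) choices <- c(choices, "(")
    if (open > 0L) choices <- c(choices, ")")
    ch <- if (length(choices) == 1) choices else sample(choices, 1)
    if (ch == "(") open <- open + 1L
    if (ch == ")") open <- open - 1L
    out[i] <- ch
  }
  paste(out, collapse = "")
}

# all valid dot-bracket strings up to a given length (small)
all_dot_brackets <- function(max_len) {
  out <- ""
  grow <- function(prefix, open, len) {
    if (len > 0) out <<- c(out, if (open == 0) paste(prefix, collapse = ""))
    if (len == max_len) return()
    grow(c(prefix, "."), open, len + 1)
    grow(c(prefix, "("), open + 1, len + 1)
    if (open > 0) grow(c(prefix, ")"), open - 1, len + 1)
  }
  grow(character(0), 0L, 0L)
  unique(out[!is.na(out)])
}

# --- full-matrix classification oracle -------------------------------------
# Global Levenshtein via utils::adist against every reference, then the
# argmin + unique-best + margin rule, written independently of the package.
oracle_classify <- function(seqs, catalog, max_edit_frac = 0.1,
                            min_margin = 2) {
  refs <- c(setNames(chartr("U", "T", catalog$isoforms$sequence),
                     catalog$isoforms$isoform),
            if (!is.null(catalog$spike_in))
              c(spike_in = chartr("U", "T", unname(catalog$spike_in))))
  d <- utils::adist(seqs, refs)
  maxd <- max_edit_frac * nchar(refs)
  vapply(seq_along(seqs), function(i) {
    row <- d[i, ]
    b <- which.min(row)
    if (sum(row == row[b]) > 1) return("unclassified")
    second <- min(row[-b])
    if (row[b] <= maxd[b] && (second - row[b]) >= min_margin) {
      names(refs)[b]
    } else {
      "unclassified"
    }
  }, character(1))
}

# a small ad-hoc catalog used by several unit tests: equal 100 nt exons
toy_catalog <- function(exon_len = 100, merge_limit = 600, seed = 42,
                        spike = FALSE) {
  withr::with_seed(seed, {
    exons <- tibble::tibble(
      exon_id = paste0("E", 2:7),
      sequence = vapply(1:6, function(i) random_dna_str(exon_len),
                        character(1))
    )
    spk <- if (spike) c(Gfp = random_dna_str(200)) else NULL
    build_isoform_catalog(
      exons,
      chains = list(
        noS = paste0("E", 2:7),
        E3S = paste0("E", c(2, 4:7)),
        E5S = paste0("E", c(2:4, 6, 7)),
        E6S = paste0("E", c(2:5, 7)),
        E56S = paste0("E", c(2:4, 7)),
        E3456S = paste0("E", c(2, 7))
      ),
      merge_limit_nt = merge_limit, gene_id = "toy", spike_in = spk
    )
  })
}
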