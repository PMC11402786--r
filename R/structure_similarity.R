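#' Split RNA sequences into overlapping fragments
#'
#' Windows of `fragment_len` nucleotides starting at 0 with step
#' `fragment_len - overlap` (400 nt at the defaults, so adjacent fragments
#' overlap by 100 nt).  If the final window would overrun the sequence, one
#' extra end-anchored fragment (`start = L - fragment_len`) is emitted
#' unless it duplicates the previous one, so the fragments always cover the
#' whole sequence.  Sequences shorter than `fragment_len` yield a single
#' whole-sequence fragment.  Coordinates are 0-based, half-open.
#'
#' @param x sequences: a named character vector, a data frame with columns
#'   `source_id` and `sequence`, or a `Biostrings::XStringSet`.
#' @param fragment_len window length in nt (default 500).
#' @param overlap overlap between adjacent windows in nt (default 100; must
#'   be smaller than `fragment_len`).
#' @return tibble with `fragment_id`, `source_id`, `start`, `end`,
#'   `sequence`.
#' @examples
#' split_into_fragments(c(rna = strrep("ACGU", 250)))  # 1000 nt -> 3 fragments
#' @export
split_into_fragments <- function(x, fragment_len = 500, overlap = 100) {
  if (fragment_len <= overlap || overlap < 0) {
    abort("`fragment_len` must exceed `overlap` and `overlap` must be >= 0.")
  }
  if (methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- tibble(source_id = names(x), sequence = unname(x))
  }
  stopifnot(is.data.frame(x), all(c("source_id", "sequence") %in% names(x)))
  if (any(nchar(x$sequence) < 1)) abort("Sequences must be non-empty.")
  step <- fragment_len - overlap
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    s <- x$sequence[i]
    L <- nchar(s)
    if (L <= fragment_len) {
      starts <- 0L
      ends <- L
    } else {
      starts <- seq(0L, L - fragment_len, by = step)
      if (tail(starts, 1) + fragment_len < L) {
        anchored <- L - fragment_len
        if (anchored != tail(starts, 1)) starts <- c(starts, anchored)
      }
      ends <- starts + fragment_len
    }
    tibble(
      fragment_id = paste0(x$source_id[i], ":", starts, "-", ends),
      source_id = x$source_id[i],
      start = as.integer(starts), end = as.integer(ends),
      sequence = substr(rep(s, length(starts)), starts + 1, ends)
    )
  })
}

#' Predict an RNA secondary structure by base-pair maximization
#'
#' The built-in folder maximizes the number of Watson-Crick plus GU-wobble
#' base pairs (AU, UA, GC, CG, GU, UG) subject to hairpin loops of at least
#' `min_loop` unpaired bases, via the classic O(n^3) dynamic program; the
#' traceback is deterministic (prefer leaving a base unpaired, then the
#' leftmost pairing partner).  It is self-contained and reproducible; a
#' thermodynamic folder can be plugged into any function that takes a
#' `folder` argument, as any function mapping a sequence to a dot-bracket
#' string.
#'
#' @param seq a single RNA (or DNA; T is read as U) sequence.
#' @param min_loop minimum hairpin loop size (default 3).
#' @return a `dot_bracket` object: list with `sequence` (U-normalized) and
#'   `structure`.
#' @examples
#' fold("GGGAAACCC")   # (((...)))
#' fold("AAAA")        # ....
#' @export
fold <- function(seq, min_loop = 3) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  s <- chartr("Tt", "Uu", toupper(seq))
  if (grepl("[^ACGU]", s)) {
    abort("Sequence contains non-nucleotide characters (allowed: A, C, G, U/T).")
  }
  db <- cpp_nussinov(s, as.integer(min_loop))
  dot_bracket(s, db)
}

#' Dot-bracket secondary structure
#'
#' Constructor and validator for the bracket notation of an RNA secondary
#' structure: matched parentheses are base pairs, dots unpaired bases.
#' Brackets must balance and nest properly; if a sequence is given it must
#' match the structure length.
#'
#' @param sequence nucleotide sequence (optional, `NA` to omit).
#' @param structure dot-bracket string.
#' @return object of class `dot_bracket`.
#' @export
dot_bracket <- function(sequence = NA_character_, structure) {
  stopifnot(is.character(structure), length(structure) == 1)
  chars <- strsplit(structure, "")[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad) > 0) {
    abort(paste0("Invalid character in dot-bracket at position ", bad[1], "."))
  }
  depth <- cumsum(ifelse(chars == "(", 1L, ifelse(chars == ")", -1L, 0L)))
  if (any(depth < 0)) {
    abort(paste0("Unbalanced bracket at position ", which(depth < 0)[1], "."))
  }
  if (length(depth) > 0 && tail(depth, 1) != 0) {
    abort(paste0("Unbalanced brackets: ", tail(depth, 1),
                 " unclosed at end of string."))
  }
  if (!is.na(sequence) && nchar(sequence) != nchar(structure)) {
    abort("Sequence and structure lengths differ.")
  }
  structure(list(sequence = sequence, structure = structure),
            class = "dot_bracket")
}

#' @export
print.dot_bracket <- function(x, ...) {
  if (!is.na(x$sequence)) cat(x$sequence, "\n")
  cat(x$structure, "\n")
  invisible(x)
}

#' Convert a dot-bracket structure to its ordered tree form
#'
#' Each base pair becomes an internal `P` node nesting everything between
#' the brackets, each unpaired base a `U` leaf, all under a virtual root
#' `R`.  The mapping is bijective: [structure_tree_to_dot_bracket()]
#' reconstructs the string exactly.
#'
#' @param db a `dot_bracket` object or a dot-bracket string.
#' @return object of class `structure_tree`: postorder label vector
#'   (`"R"`, `"P"`, `"U"`), postorder index of each node's leftmost leaf,
#'   and the node count.
#' @export
to_structure_tree <- function(db) {
  if (inherits(db, "dot_bracket")) db <- db$structure
  db <- dot_bracket(structure = db)$structure  # validates
  chars <- if (nchar(db) > 0) strsplit(db, "")[[1]] else character(0)
  # build children lists with a stack; node 0 is the virtual root
  n_nodes <- sum(chars == "(") + sum(chars == ".") + 1L
  children <- vector("list", n_nodes)
  label <- character(n_nodes)
  label[1] <- "R"
  nxt <- 1L
  stack <- c(1L)
  for (ch in chars) {
    top <- stack[length(stack)]
    if (ch == "(") {
      nxt <- nxt + 1L
      label[nxt] <- "P"
      children[[top]] <- c(children[[top]], nxt)
      stack <- c(stack, nxt)
    } else if (ch == ".") {
      nxt <- nxt + 1L
      label[nxt] <- "U"
      children[[top]] <- c(children[[top]], nxt)
    } else {
      stack <- stack[-length(stack)]
    }
  }
  # postorder traversal (iterative)
  post <- integer(0)
  visit <- function(v) {
    for (c in children[[v]]) visit(c)
    post <<- c(post, v)
  }
  visit(1L)
  post_index <- integer(n_nodes)
  post_index[post] <- seq_len(n_nodes)
  lml <- integer(n_nodes)  # by postorder position
  for (i in seq_len(n_nodes)) {
    v <- post[i]
    kids <- children[[v]]
    lml[i] <- if (length(kids) == 0) i else lml[post_index[kids[1]]]
  }
  structure(
    list(labels = label[post], lml = lml, n = n_nodes,
         structure = db),
    class = "structure_tree"
  )
}

#' @rdname to_structure_tree
#' @param tree a `structure_tree`.
#' @export
structure_tree_to_dot_bracket <- function(tree) {
  stopifnot(inherits(tree, "structure_tree"))
  tree$structure
}

#' @export
print.structure_tree <- function(x, ...) {
  cat("<structure_tree>", x$n, "nodes;",
      sum(x$labels == "P"), "pairs,", sum(x$labels == "U"), "unpaired\n")
  invisible(x)
}

#' Tree edit distance between two secondary structures (f value)
#'
#' Dissimilarity of two bracket-format structures: the ordered tree edit
#' distance (insert, delete, relabel at unit cost) between their P/U trees,
#' computed exactly with the Zhang-Shasha dynamic program.  It is a metric:
#' symmetric, zero exactly for identical trees, and satisfying the triangle
#' inequality.  Smaller f means more similar structure.
#'
#' @param t1,t2 `structure_tree` objects, `dot_bracket` objects, or
#'   dot-bracket strings.
#' @return the f value (non-negative integer).
#' @examples
#' tree_edit_distance("(())", "()")  # 1: delete one pair node
#' tree_edit_distance("()", ".")    # 1: relabel P <-> U
#' @export
tree_edit_distance <- function(t1, t2) {
  as_tree <- function(t) {
    if (inherits(t, "structure_tree")) t else to_structure_tree(t)
  }
  a <- as_tree(t1); b <- as_tree(t2)
  code <- c(R = 0L, P = 1L, U = 2L)
  cpp_tree_edit_distance(code[a$labels], a$lml, code[b$labels], b$lml)
}

#' All pairwise f values between two fragment sets
#'
#' Folds every fragment once (memoized by sequence) with the supplied
#' folder and computes the tree edit distance for every cross pair.
#'
#' @param frags_a,frags_b fragment tibbles from [split_into_fragments()]
#'   (columns `fragment_id`, `sequence`; extra columns are carried along as
#'   `source_id`/`start`/`end` when present).
#' @param folder function mapping a sequence to a `dot_bracket` (or a
#'   dot-bracket string); default [fold()].
#' @return tibble of class `f_table` with `fragment_a`, `fragment_b`, `f`.
#' @export
pairwise_f_matrix <- function(frags_a, frags_b, folder = fold) {
  stopifnot(is.data.frame(frags_a), is.data.frame(frags_b))
  if (nrow(frags_a) == 0 || nrow(frags_b) == 0) {
    abort("Fragment lists must be non-empty.")
  }
  fold_all <- function(frags) {
    uniq <- unique(frags$sequence)
    trees <- lapply(uniq, function(s) {
      st <- tryCatch(folder(s), error = function(e) {
        abort(paste0("Folding failed for fragment starting `",
                     substr(s, 1, 12), "...`: ", conditionMessage(e)))
      })
      to_structure_tree(if (inherits(st, "dot_bracket")) st$structure else st)
    })
    trees[match(frags$sequence, uniq)]
  }
  ta <- fold_all(frags_a)
  tb <- fold_all(frags_b)
  grid <- tidyr::expand_grid(ia = seq_len(nrow(frags_a)),
                             ib = seq_len(nrow(frags_b)))
  code <- c(R = 0L, P = 1L, U = 2L)
  grid$f <- vapply(seq_len(nrow(grid)), function(r) {
    a <- ta[[grid$ia[r]]]; b <- tb[[grid$ib[r]]]
    cpp_tree_edit_distance(code[a$labels], a$lml, code[b$labels], b$lml)
  }, integer(1))
  out <- tibble(
    fragment_a = frags_a$fragment_id[grid$ia],
    fragment_b = frags_b$fragment_id[grid$ib],
    f = as.numeric(grid$f)
  )
  class(out) <- c("f_table", class(out))
  out
}

#' Empirical null distribution of f values
#'
#' Builds the data-driven significance threshold for structural similarity:
#' given f values from comparing real fragments against random mRNA-like
#' fragments, the threshold is the left-tail empirical quantile — the k-th
#' smallest value with `k = ceiling(alpha * n)`.  Fewer than a fraction
#' `alpha` of the null values fall strictly below it.  The threshold is a
#' property of the folder, the cost model and the null pool, so it is always
#' recomputed from the user's own null rather than imported from elsewhere.
#'
#' @param f_values numeric vector of null f values (at least
#'   `ceiling(1/alpha)` of them so the order statistic exists; 40 at the
#'   default alpha).
#' @param alpha left-tail fraction (default 0.025).
#' @return object of class `structure_null` with `f_values`, `n`, `alpha`,
#'   `threshold`; supports `tidy()`, `glance()` and `autoplot()`.
#' @export
build_null <- function(f_values, alpha = 0.025) {
  stopifnot(is.numeric(f_values), alpha > 0, alpha <= 1)
  n <- length(f_values)
  n_min <- max(ceiling(1 / alpha), 2)
  if (n < n_min) {
    abort(sprintf("Need at least %d null f values at alpha = %g (got %d).",
                  n_min, alpha, n))
  }
  k <- ceiling(alpha * n)
  threshold <- sort(f_values)[k]
  structure(
    list(f_values = f_values, n = n, alpha = alpha, threshold = threshold),
    class = "structure_null"
  )
}

#' @export
print.structure_null <- function(x, ...) {
  cat(sprintf("<structure_null> n = %d, alpha = %g, threshold = %g\n",
              x$n, x$alpha, x$threshold))
  invisible(x)
}

#' Report fragment pairs more similar than the null threshold
#'
#' Strict comparison: pairs with `f < threshold` are reported, sorted by f
#' ascending.  The f table must have been computed with the same folder as
#' the null.
#'
#' @param f_table a [pairwise_f_matrix()] result.
#' @param null a [build_null()] result.
#' @return the qualifying rows of `f_table`, sorted by `f`.
#' @export
find_similar_fragments <- function(f_table, null) {
  stopifnot(is.data.frame(f_table), inherits(null, "structure_null"))
  f_table %>%
    filter(.data$f < null$threshold) %>%
    arrange(.data$f)
}
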