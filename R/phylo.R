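#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric,
#' zero-diagonal distance matrix; negative branch lengths, which NJ can
#' produce on non-additive matrices, are clamped to 0. The result is an
#' unrooted `phylo` tree over all sample labels.
#'
#' @param d an `mpass_dist` from [build_distance_matrix()], a symmetric
#'   matrix, or a `dist`.
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(d) {
  m <- if (inherits(d, "mpass_dist")) d$S else as.matrix(d)
  if (nrow(m) < 3L) stop("need at least 3 samples for neighbor joining")
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("S", seq_len(nrow(m)))
  }
  if (any(!is.finite(m))) stop("distance matrix contains non-finite entries")
  if (any(m < 0)) stop("distance matrix contains negative entries")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(m)) > 1e-8)) stop("distance matrix diagonal must be zero")
  tr <- ape::nj(as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::unroot(tr)
}

#' Serialize a tree to Newick
#'
#' @param tree a `phylo`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Parse a Newick string or file
#'
#' Accepts quoted labels and missing branch lengths; unbalanced parentheses or
#' a missing terminal semicolon raise a parse error with the offending
#' position.
#'
#' @param x a Newick string, or the path of a file containing one or more
#'   Newick trees.
#' @return a `phylo` (or `multiPhylo` when a file holds several trees).
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("[();]", x)) {
    paste(readLines(x, warn = FALSE), collapse = "\n")
  } else x
  .check_newick_syntax(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("failed to parse Newick input")
  tr
}

.check_newick_syntax <- function(txt) {
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced parenthesis at position ", i, " of Newick input")
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses in Newick input (", depth, " unclosed)")
  if (!grepl(";", txt)) stop("Newick input lacks a terminating ';'")
  invisible(TRUE)
}

#' Non-trivial bipartitions of a tree
#'
#' Every internal edge of the unrooted tree splits the leaf set in two; the
#' set of these splits determines the topology. Trivial splits (one leaf
#' against the rest) are excluded. Splits are returned in a canonical string
#' encoding (the side not containing the alphabetically first leaf, labels
#' sorted and joined by `|`), plus the underlying leaf-set list.
#'
#' @param tree a `phylo` over >= 4 leaves (multifurcations allowed).
#' @return character vector of canonical split signatures; attribute
#'   `splits` holds the corresponding leaf-label sets.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  n <- length(tips)
  if (n < 4L) return(structure(character(0), splits = list()))
  ntot <- n + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  clade <- vector("list", ntot)
  for (i in seq_len(n)) clade[[i]] <- tips[i]
  # accumulate tip sets bottom-up; node numbering order is not guaranteed
  # across phylo producers, so sweep until all internal nodes resolve
  pending <- sort(unique(tree$edge[, 1L]), decreasing = TRUE)
  done <- rep(FALSE, ntot)
  done[seq_len(n)] <- TRUE
  while (any(!done[pending])) {
    progressed <- FALSE
    for (nd in pending) {
      if (done[nd]) next
      ch <- kids[[as.character(nd)]]
      if (all(done[ch])) {
        clade[[nd]] <- unlist(clade[ch], use.names = FALSE)
        done[nd] <- TRUE
        progressed <- TRUE
      }
    }
    if (!progressed) stop("malformed tree edge table")
  }
  internal <- tree$edge[, 2L][tree$edge[, 2L] > n]
  ref <- sort(tips)[1L]
  sig <- character(0)
  splits <- list()
  for (nd in internal) {
    side <- clade[[nd]]
    if (ref %in% side) side <- setdiff(tips, side)
    k <- length(side)
    if (k < 2L || k > n - 2L) next
    s <- paste(sort(side), collapse = "|")
    if (!(s %in% sig)) {
      sig <- c(sig, s)
      splits[[length(splits) + 1L]] <- sort(side)
    }
  }
  structure(sig, splits = splits)
}

#' Robinson-Foulds symmetric difference between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees (unweighted Robinson-Foulds distance). Zero means topologically
#' identical; for two binary trees on n leaves the maximum is `2 * (n - 3)`.
#' Multifurcating trees are compared on their bipartition sets as-is, without
#' forced resolution.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return integer symmetric difference.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2); only2 <- setdiff(l2, l1)
    stop("leaf sets differ; only in tree 1: {",
         paste(only1, collapse = ", "), "}; only in tree 2: {",
         paste(only2, collapse = ", "), "}")
  }
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Is a set of leaves monophyletic (a clade) in an unrooted tree?
#'
#' True when some edge of the tree separates exactly this leaf set from the
#' rest (or the set is trivial: size 1, n-1, or n).
#'
#' @param tree a `phylo`.
#' @param leaves character vector of leaf labels.
#' @return logical.
#' @export
is_clade <- function(tree, leaves) {
  tips <- tree$tip.label
  stopifnot(all(leaves %in% tips))
  k <- length(unique(leaves))
  n <- length(tips)
  if (k <= 1L || k >= n - 1L) return(TRUE)
  ref <- sort(tips)[1L]
  side <- sort(unique(leaves))
  if (ref %in% side) side <- sort(setdiff(tips, side))
  paste(side, collapse = "|") %in% bipartitions(tree)
}
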