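#' Read a phylogeny from Newick text or a file
#'
#' Accepts either a Newick string or a path to a file containing one tree.
#' Square-bracket comments are stripped, quoted labels and underscores are
#' handled by the underlying \pkg{ape} parser, and internal node labels are
#' kept as plain strings (support values are never interpreted). Before
#' parsing, the string is checked for balanced parentheses and a terminating
#' semicolon; a violation raises an error naming the character offset.
#'
#' @param x Newick string (must contain `(` or `;`) or a file path.
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()]
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (!grepl("[(;]", x)) {
    if (!file.exists(x)) stop("file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf(
      "Newick parse error: %d unclosed '(' at character %d", depth,
      length(chars)))
  if (!grepl(";\\s*$", txt))
    stop(sprintf("Newick parse error: missing ';' at character %d",
                 nchar(txt)))
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr))
    stop("Newick parse error: ape could not parse the tree string")
  if (anyDuplicated(tr$tip.label))
    stop("tip labels must be unique; duplicated: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label)))
    stop("tip labels must be non-empty")
  tr
}

#' Write a phylogeny as a Newick string
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; if `NULL` the string is returned.
#' @param digits significant digits for branch lengths (default 10, enough for
#'   lossless round-trips at the package's precision guarantees).
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Midpoint-root a phylogeny
#'
#' Places the root at the midpoint of the longest tip-to-tip path. The total
#' branch-length sum is conserved.
#'
#' @param tree a `"phylo"` object with at least 2 tips and branch lengths.
#' @return A rooted `"phylo"` object.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2) stop("midpoint rooting needs at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0)
    stop("zero-diameter tree: all branch lengths are zero")
  phangorn::midpoint(tree)
}

#' Resolve polytomies and replace zero-length branches
#'
#' Multifurcations are resolved deterministically (input order, no RNG) and
#' every branch of length zero -- including the branches introduced by the
#' arbitrary resolution -- is set to `eps`. All other branch lengths are left
#' untouched, so the output is strictly bifurcating with minimum branch
#' length `>= eps`.
#'
#' @param tree a rooted `"phylo"` object.
#' @param eps length assigned to zero-length branches (default `1e-6`).
#' @return A strictly bifurcating `"phylo"` object.
#' @export
resolve_polytomies <- function(tree, eps = 1e-6) {
  stopifnot(inherits(tree, "phylo"), eps > 0)
  out <- ape::multi2di(tree, random = FALSE)
  if (is.null(out$edge.length))
    out$edge.length <- numeric(nrow(out$edge))
  zero <- is.na(out$edge.length) | out$edge.length == 0
  out$edge.length[zero] <- eps
  out
}

#' Matrix of patristic (tip-to-tip path) distances
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @return A symmetric matrix with zero diagonal, rows/columns named and
#'   ordered by `tree$tip.label`.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  D <- as.matrix(stats::cophenetic(tree))
  D[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree; path lengths between kept tips are preserved
#' exactly.
#'
#' @param tree a `"phylo"` object.
#' @param keep character vector of tip labels to retain (at least 2, all
#'   present in the tree).
#' @return A `"phylo"` object on the kept tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"), is.character(keep))
  keep <- unique(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  ape::keep.tip(tree, keep)
}
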