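#' Read a rooted phylogeny from Newick text
#'
#' Thin wrapper around \code{\link[ape]{read.tree}} that first scans the
#' string for the syntax errors a malformed Newick most often carries
#' (unbalanced parentheses, missing terminating semicolon) and reports the
#' character position, then validates the parsed tree: unique terminal
#' labels and a single root.  Polytomies are preserved; methods that require
#' a strictly binary tree reject them themselves.  Branch lengths and quoted
#' labels are accepted and preserved, but every method in the package works
#' on the topology only.
#'
#' @param x a Newick string, or the path of a file containing one.
#' @return an object of class \code{"phylo"} (ape).
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' @export
read_newick <- function(x) {
  text <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  check_newick_syntax(text)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("Newick parse error: ape could not read the string")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    stop("duplicated terminal label(s): ", paste(dup, collapse = ", "))
  }
  tree
}

# minimal syntactic scan with character positions; ape's own parser does the
# real work afterwards
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  quoted <- FALSE
  semi <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") quoted <- !quoted
    if (quoted) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at character ", i)
      }
    }
    if (ch == ";" && is.na(semi)) semi <- i
  }
  if (quoted) stop("Newick parse error: unterminated quoted label")
  if (depth > 0L) {
    stop("Newick parse error: ", depth,
         " unclosed '(' at end of input (character ", length(chars), ")")
  }
  if (is.na(semi)) {
    stop("Newick parse error: missing terminating ';' at character ",
         length(chars))
  }
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param tree a \code{"phylo"} object.
#' @param file optional path; when \code{NULL} the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Is a tree strictly binary?
#'
#' TRUE when every internal node of the rooted tree has exactly two children.
#'
#' @param tree a \code{"phylo"} object.
#' @return logical scalar.
#' @export
is_binary_tree <- function(tree) {
  ch <- node_children(tree)
  inner <- ch[(ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)]
  all(vapply(inner, length, 1L) == 2L)
}

# common validation for the reconstruction methods
check_tree_ranges <- function(tree, ranges) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a \"phylo\" object")
  if (!inherits(ranges, "range_assignment")) {
    ranges <- range_assignment(ranges)
  }
  missing <- setdiff(tree$tip.label, names(ranges))
  if (length(missing)) {
    stop("terminal(s) missing from the range assignment: ",
         paste(missing, collapse = ", "))
  }
  ranges
}
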