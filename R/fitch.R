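#' Fitch down-pass on a taxon-area cladogram
#'
#' Runs the classical Fitch set operations from the tips towards the root:
#' each internal node receives the intersection of its children's sets when
#' that intersection is non-empty, otherwise their union, incrementing the
#' change count.  A terminal occupying several areas is seeded with its full
#' observed set (polymorphism), so any of its areas can be reached at no
#' cost.  Polytomies are folded pairwise in child order with a warning: at a
#' non-binary node the counted length can depend on child order.
#'
#' @param tree rooted \code{"phylo"} tree.
#' @param ranges a \code{\link{range_assignment}} (or named list) covering
#'   every terminal.
#' @return a list of class \code{"fitch_states"} with elements
#'   \code{states} (named list: node -> area codes), \code{length}
#'   (number of state changes), \code{areas}, and \code{tree}.
#' @seealso \code{\link{fitch_mpr}} for the most-parsimonious-reconstruction
#'   sets, \code{\link{fitch_areas}} for the full model object.
#' @export
fitch_downpass <- function(tree, ranges) {
  ranges <- check_tree_ranges(tree, ranges)
  areas <- attr(ranges, "areas")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- node_children(tree)
  if (!is_binary_tree(tree)) {
    warning("tree has polytomies: children are folded pairwise in input ",
            "order, and the Fitch length can depend on that order")
  }
  masks <- integer(nn)
  masks[seq_len(ntip)] <- encode_ranges(ranges, areas)[tree$tip.label]
  len <- 0L
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) next
    kids <- ch[[v]]
    acc <- masks[kids[1L]]
    for (k in kids[-1L]) {
      inter <- bitwAnd(acc, masks[k])
      if (inter != 0L) {
        acc <- inter
      } else {
        acc <- bitwOr(acc, masks[k])
        len <- len + 1L
      }
    }
    masks[v] <- acc
  }
  nm <- node_names(tree)
  states <- stats::setNames(lapply(masks, decode_mask, areas = areas), nm)
  structure(list(states = states, length = len, areas = areas, tree = tree),
            class = "fitch_states")
}

# unit-cost minimum-change DP (Sankoff with uniform substitution cost).
# Returns the per-node "down" cost matrix, the "up" matrix and the minimum
# length; polymorphic terminals cost 0 for any observed state.
fitch_dp <- function(tree, ranges) {
  areas <- attr(ranges, "areas")
  k <- length(areas)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- node_children(tree)
  par <- node_parents(tree)
  masks <- encode_ranges(ranges, areas)[tree$tip.label]

  down <- matrix(Inf, nn, k)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  for (t in seq_len(ntip)) {
    down[t, bitwAnd(masks[t], bits) != 0L] <- 0
  }
  # contribution of child c to its parent, per parent state:
  # min(down[c,s], min_t down[c,t] + 1)
  contrib <- matrix(0, nn, k)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) next
    acc <- numeric(k)
    for (c in ch[[v]]) {
      contrib[c, ] <- pmin(down[c, ], min(down[c, ]) + 1)
      acc <- acc + contrib[c, ]
    }
    down[v, ] <- acc
  }
  root <- ntip + 1L
  L <- min(down[root, ])

  up <- matrix(0, nn, k)
  for (v in preorder_nodes(tree)) {
    if (v <= ntip) next
    total <- colSums(contrib[ch[[v]], , drop = FALSE])
    for (c in ch[[v]]) {
      f <- up[v, ] + total - contrib[c, ]
      up[c, ] <- pmin(f, min(f) + 1)
    }
  }
  list(down = down, up = up, length = L, masks = masks)
}

#' Most-parsimonious-reconstruction (MPR) state sets
#'
#' For every node, the set of areas the node takes in at least one
#' reconstruction of minimal length, where a reconstruction assigns a single
#' area to every internal node and a terminal costs nothing for any area of
#' its observed range.  The MPR set at the root is the Fitch ancestral-area
#' answer.  Computed by an exact two-pass minimum-change dynamic programme,
#' so polytomies are handled at their true minimum length.  Terminal entries
#' are reported as the observed ranges (observations are not optimised).
#'
#' @inheritParams fitch_downpass
#' @return a list of class \code{"fitch_states"} with elements \code{states}
#'   (named list: node -> MPR area set), \code{length}, \code{areas},
#'   \code{tree}.
#' @export
fitch_mpr <- function(tree, ranges) {
  ranges <- check_tree_ranges(tree, ranges)
  areas <- attr(ranges, "areas")
  dp <- fitch_dp(tree, ranges)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  nm <- node_names(tree)
  states <- vector("list", nn)
  for (v in seq_len(nn)) {
    if (v <= ntip) {
      states[[v]] <- ranges[[tree$tip.label[v]]]
    } else {
      states[[v]] <- as.character(areas)[dp$down[v, ] + dp$up[v, ] <= dp$length]
    }
  }
  structure(list(states = stats::setNames(states, nm), length = dp$length,
                 areas = areas, tree = tree),
            class = "fitch_states")
}

#' @export
print.fitch_states <- function(x, ...) {
  cat("Fitch state sets (", x$length, " changes)\n", sep = "")
  inner <- x$states[(ape::Ntip(x$tree) + 1L):length(x$states)]
  for (nm in names(inner)) {
    cat("  ", format(nm, width = max(nchar(names(inner)))), " ",
        paste(inner[[nm]], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Fit Fitch parsimony ancestral areas
#'
#' The model-fitting interface to Fitch optimisation: runs the down-pass and
#' the exact MPR computation and returns one object carrying both, with
#' \code{print}, \code{summary} and \code{plot} methods.  The ancestral area
#' of the whole tree is the MPR set at the root; per-clade answers are
#' extracted with \code{\link{fitch_ancestral_areas}}.
#'
#' @inheritParams fitch_downpass
#' @return an object of class \code{"fitch_areas"}: list with
#'   \code{down} and \code{mpr} (both \code{"fitch_states"}),
#'   \code{length} (minimum number of changes), \code{root} (root MPR area
#'   set), \code{areas}, \code{tree}, \code{ranges}.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' ra <- range_assignment(list(A = "x", B = "x", C = "y", D = "y"))
#' fit <- fitch_areas(tr, ra)
#' fit$root   # c("x", "y")
#' @export
fitch_areas <- function(tree, ranges) {
  ranges <- check_tree_ranges(tree, ranges)
  down <- suppressWarnings(fitch_downpass(tree, ranges))
  mpr <- fitch_mpr(tree, ranges)
  root_nm <- node_names(tree)[ape::Ntip(tree) + 1L]
  structure(list(down = down, mpr = mpr, length = mpr$length,
                 root = mpr$states[[root_nm]],
                 areas = attr(ranges, "areas"), tree = tree, ranges = ranges),
            class = "fitch_areas")
}

#' @export
print.fitch_areas <- function(x, ...) {
  cat("Fitch parsimony ancestral areas\n")
  cat("  terminals:", ape::Ntip(x$tree), " areas:", length(x$areas), "\n")
  cat("  parsimony length:", x$length, "\n")
  cat("  root MPR set:", paste(x$root, collapse = ""), "\n")
  invisible(x)
}

#' @export
summary.fitch_areas <- function(object, ...) {
  print(object)
  cat("\nPer-node MPR sets:\n")
  print(object$mpr)
  invisible(object)
}

#' @export
plot.fitch_areas <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  ntip <- ape::Ntip(x$tree)
  lab <- vapply(x$mpr$states[(ntip + 1L):length(x$mpr$states)],
                paste, "", collapse = "")
  ape::nodelabels(lab, frame = "rect", bg = "lightyellow", cex = 0.8)
  invisible(x)
}

#' Ancestral areas of named clades under Fitch parsimony
#'
#' For each named clade (a list of terminal labels) the MPR set at the
#' clade's most recent common ancestor is returned.  Each clade must be
#' monophyletic in the tree; a single-terminal "clade" reports the terminal's
#' observed range.
#'
#' @inheritParams fitch_downpass
#' @param clades named list: clade name -> character vector of terminal
#'   labels.
#' @return named list: clade name -> area-code vector.
#' @export
fitch_ancestral_areas <- function(tree, ranges, clades) {
  ranges <- check_tree_ranges(tree, ranges)
  mpr <- fitch_mpr(tree, ranges)
  nm <- node_names(tree)
  out <- vector("list", length(clades))
  names(out) <- names(clades)
  for (cl in names(clades)) {
    tips <- clades[[cl]]
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad)) {
      stop("clade '", cl, "' names unknown terminal(s): ",
           paste(bad, collapse = ", "))
    }
    if (length(tips) == 1L) {
      out[[cl]] <- ranges[[tips]]
      next
    }
    node <- ape::getMRCA(tree, tips)
    if (!setequal(tips_under(tree, node), tips)) {
      stop("clade '", cl, "' is not monophyletic in the tree")
    }
    out[[cl]] <- mpr$states[[nm[node]]]
  }
  out
}
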