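# Weighted ancestral area analysis: directional gain/loss step counting with
# depth weights, yielding a per-area probability index (PI).
#
# The formulation implemented here is directional in both directions:
# gains are counted under an ancestor-absent (Camin-Sokal-like) model, losses
# under an ancestor-present (Dollo-like) model, and each step is weighted by
# the reciprocal of the level of the edge it falls on (the virtual origin
# edge above the root is level 1, the edges entering the root's children are
# level 2, and so on).  Deeper -- more plesiomorphic -- steps therefore weigh
# more, and an area occupied by many terminals accumulates more gain weight,
# which is exactly the double preference the weighting is meant to encode.
# Under each directional model the minimal placement is unique: one gain on
# the edge entering every maximal all-present clade (respectively one loss
# entering every maximal all-absent clade), which is also the deepest
# possible placement.

# minimal directional placement: sum of 1/level over the root edges of the
# maximal clades whose terminals all satisfy `state`
directional_weight <- function(tree, state) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- node_children(tree)
  par <- node_parents(tree)
  depth <- node_depths(tree)
  allin <- logical(nn)
  for (v in postorder_nodes(tree)) {
    allin[v] <- if (v <= ntip) state[v] else all(allin[ch[[v]]])
  }
  w <- 0
  for (v in seq_len(nn)) {
    if (allin[v] && (is.na(par[v]) || !allin[par[v]])) {
      w <- w + 1 / (depth[v] + 1)
    }
  }
  w
}

check_presence <- function(tree, presence) {
  if (is.null(names(presence))) {
    stop("`presence` must be named by terminal label")
  }
  missing <- setdiff(tree$tip.label, names(presence))
  if (length(missing)) {
    stop("terminal(s) missing from presence vector: ",
         paste(missing, collapse = ", "))
  }
  pres <- as.logical(presence[tree$tip.label])
  if (!any(pres)) stop("area is present in no terminal")
  pres
}

#' Weighted gain count for one area
#'
#' Minimum-gain placement of an area on the cladogram assuming absence on a
#' virtual origin edge above the root (gains only, no losses).  Each gain on
#' the edge entering node \code{v} contributes \code{1/level(v)}, with the
#' virtual origin edge at level 1 and the edges entering the root's children
#' at level 2.  The minimal placement puts one gain on the edge entering
#' every maximal clade whose terminals all carry the area -- the deepest
#' possible, and unique, minimal placement.
#'
#' @param tree rooted \code{"phylo"} tree.
#' @param presence named logical (or 0/1) vector over the terminals.
#' @return the weighted gain count (non-negative number).
#' @export
count_gains <- function(tree, presence) {
  pres <- check_presence(tree, presence)
  directional_weight(tree, pres)
}

#' Weighted loss count for one area
#'
#' Mirror image of \code{\link{count_gains}}: minimum-loss placement
#' assuming presence at the virtual origin (losses only), one loss on the
#' edge entering every maximal all-absent clade, weighted by reciprocal edge
#' level.  Zero when the area is present in every terminal.
#'
#' @inheritParams count_gains
#' @return the weighted loss count (non-negative number).
#' @export
count_losses <- function(tree, presence) {
  pres <- check_presence(tree, presence)
  if (all(pres)) return(0)
  directional_weight(tree, !pres)
}

#' Per-area probability index table
#'
#' For every area occurring in at least one terminal range, computes the
#' weighted gain count GW, the weighted loss count LW, the probability index
#' PI = GW/LW (infinite when the area is never lost), and a rescaled PI in
#' [0, 1] obtained by dividing by the largest finite PI; never-lost areas
#' receive rescaled PI 1 and are flagged.  Areas are ranked by PI
#' descending, infinite first, ties broken by GW descending then area code.
#'
#' @param tree rooted \code{"phylo"} tree.
#' @param ranges a \code{\link{range_assignment}} covering every terminal.
#' @return a data.frame of class \code{"pi_table"} with columns \code{area},
#'   \code{GW}, \code{LW}, \code{PI}, \code{rescaled_PI}, \code{never_lost},
#'   \code{rank}, ordered by rank.
#' @export
probability_index <- function(tree, ranges) {
  ranges <- check_tree_ranges(tree, ranges)
  areas <- attr(ranges, "areas")
  used <- as.character(areas)[areas %in% unlist(ranges, use.names = FALSE)]
  gw <- lw <- numeric(length(used))
  for (i in seq_along(used)) {
    pres <- vapply(ranges[tree$tip.label], function(r) used[i] %in% r, TRUE)
    gw[i] <- count_gains(tree, pres)
    lw[i] <- count_losses(tree, pres)
  }
  pi <- ifelse(lw > 0, gw / lw, Inf)
  fin <- pi[is.finite(pi)]
  rescaled <- if (length(fin)) pmin(pi / max(fin), Inf) else rep(Inf, length(pi))
  rescaled[!is.finite(rescaled)] <- 1
  ord <- order(-ifelse(is.infinite(pi), Inf, pi), -gw, used)
  tab <- data.frame(area = used, GW = gw, LW = lw, PI = pi,
                    rescaled_PI = rescaled, never_lost = !is.finite(pi),
                    stringsAsFactors = FALSE)[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("pi_table", "data.frame")
  tab
}

#' @export
print.pi_table <- function(x, digits = 4, ...) {
  cat("WAAA probability index (", nrow(x), " areas)\n", sep = "")
  y <- as.data.frame(x)
  y$GW <- round(y$GW, digits)
  y$LW <- round(y$LW, digits)
  y$PI <- round(y$PI, digits)
  y$rescaled_PI <- round(y$rescaled_PI, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Ancestral-area set from a probability index table
#'
#' Areas whose rescaled PI reaches the threshold.  The top-ranked area has
#' rescaled PI 1, so the result is never empty.  The threshold is
#' presentation only: the full ranked table remains the complete answer.
#'
#' @param pit a \code{"pi_table"} (or a \code{"waaa"} fit).
#' @param threshold fraction in (0, 1]; default 0.5.
#' @return character vector of area codes, in rank order.
#' @export
waaa_ancestral_set <- function(pit, threshold = 0.5) {
  if (inherits(pit, "waaa")) pit <- pit$pi
  stopifnot(threshold > 0, threshold <= 1)
  pit$area[pit$rescaled_PI >= threshold]
}

#' Fit a weighted ancestral area analysis
#'
#' The model-fitting interface to WAAA: computes the probability index table
#' (\code{\link{probability_index}}) and the ancestral-area set at the given
#' threshold, returning one object with \code{print} and \code{summary}
#' methods.
#'
#' @inheritParams probability_index
#' @param threshold rescaled-PI cutoff for the reported ancestral set.
#' @return an object of class \code{"waaa"}: list with \code{pi} (the
#'   \code{"pi_table"}), \code{ancestral} (area codes), \code{threshold},
#'   \code{tree}, \code{ranges}.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' ra <- range_assignment(list(A = c("x", "y"), B = "x", C = "x", D = "x"))
#' fit <- waaa(tr, ra)
#' fit$ancestral
#' @export
waaa <- function(tree, ranges, threshold = 0.5) {
  ranges <- check_tree_ranges(tree, ranges)
  pit <- probability_index(tree, ranges)
  structure(list(pi = pit, ancestral = waaa_ancestral_set(pit, threshold),
                 threshold = threshold, tree = tree, ranges = ranges),
            class = "waaa")
}

#' @export
print.waaa <- function(x, ...) {
  cat("Weighted ancestral area analysis\n")
  cat("  ancestral set (rescaled PI >= ", x$threshold, "): ",
      paste(x$ancestral, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
summary.waaa <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$pi)
  invisible(object)
}

# WAAA for one clade: the analysis restricted to the clade's subtree
# (terminals outside the clade are ignored, per the subtree-consistency
# property of the probability index)
waaa_clade <- function(tree, ranges, tips, threshold = 0.5) {
  if (length(tips) == 1L) return(ranges[[tips]])
  sub <- ape::keep.tip(tree, tips)
  waaa(sub, range_assignment(ranges[tips], attr(ranges, "areas")),
       threshold = threshold)$ancestral
}
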