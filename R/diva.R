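# Exact dispersal-vicariance analysis (DIVA).
#
# Cost model: at a node whose ancestor occupies a single area, both children
# inherit that area (duplication, free); a widespread ancestor must split by
# vicariance into two disjoint non-empty parts (free).  Each child then pays
# one dispersal per area it has that its inherited part lacks, and one
# extinction per inherited area it lost -- i.e. the symmetric difference
# between the inherited part and the child's range, at cost one per area.
# Optimal reconstructions minimise the total event cost; terminal ranges are
# fixed to the observations.
#
# The optimisation is an exact bottom-up dynamic programme over all
# non-empty area subsets, using a hypercube distance transform so that each
# node costs O(3^k) submask work rather than (2^k)^3 triple enumeration.

# cost of one cladogenetic transition, on bit masks
split_cost_mask <- function(anc, left, right) {
  if (popcount(anc) == 1L) {
    return(popcount(bitwXor(anc, left)) + popcount(bitwXor(anc, right)))
  }
  best <- Inf
  sub <- bitwAnd(anc - 1L, anc)
  while (sub > 0L) {
    val <- popcount(bitwXor(sub, left)) +
      popcount(bitwXor(bitwXor(anc, sub), right))
    if (val < best) best <- val
    sub <- bitwAnd(sub - 1L, anc)
  }
  best
}

#' DIVA cost of a single ancestor-to-children transition
#'
#' Vicariance (splitting a widespread ancestral range into two disjoint
#' non-empty parts) and duplication (both children inheriting a single-area
#' ancestor) are free; each child then costs one dispersal per area gained
#' relative to its inherited part and one extinction per inherited area
#' lost.  The minimum over all admissible inheritances is returned.
#'
#' @param ancestor,left,right non-empty character vectors of area codes.
#' @return non-negative integer event cost.
#' @examples
#' split_cost(c("a", "b"), "a", "b")       # pure vicariance: 0
#' split_cost("a", "a", c("a", "b"))        # one dispersal: 1
#' split_cost("a", "b", "a")                # 2 (dispersal + extinction)
#' @export
split_cost <- function(ancestor, left, right) {
  if (!length(ancestor) || !length(left) || !length(right)) {
    stop("ancestor and child ranges must be non-empty")
  }
  areas <- sort(unique(c(ancestor, left, right)))
  m <- function(x) encode_areas(x, areas)
  as.integer(split_cost_mask(m(ancestor), m(left), m(right)))
}

# g[I] = min over non-empty subsets C of cost[C] + |I xor C|, for all I,
# via the standard per-dimension hypercube distance transform
g_from_cost <- function(cost, k) {
  g <- cost
  idx <- seq_along(g) - 1L
  for (b in seq_len(k) - 1L) {
    p <- bitwXor(idx, bitwShiftL(1L, b)) + 1L
    g <- pmin(g, g[p] + 1)
  }
  g
}

# all (left-inherited, right-inherited) partitions of mask S admissible at a
# node: the single duplication pair for |S| = 1, otherwise every ordered
# two-block partition
partitions_of <- function(S) {
  if (popcount(S) == 1L) return(matrix(c(S, S), ncol = 2L))
  subs <- integer(0)
  sub <- bitwAnd(S - 1L, S)
  while (sub > 0L) {
    subs <- c(subs, sub)
    sub <- bitwAnd(sub - 1L, S)
  }
  cbind(subs, bitwXor(S, subs), deparse.level = 0L)
}

# child subset pairs (Cl, Cr) occurring in >= 1 optimal resolution of node v
# fixed to subset S; returned sorted by (Cl, Cr)
diva_valid_pairs <- function(S, cvS, gl, gr, costl, costr, pc_xor) {
  parts <- partitions_of(S)
  pairs <- NULL
  for (i in seq_len(nrow(parts))) {
    Il <- parts[i, 1L]
    Ir <- parts[i, 2L]
    if (gl[Il + 1L] + gr[Ir + 1L] != cvS) next
    Cl <- which(costl + pc_xor(Il) == gl[Il + 1L]) - 1L
    Cr <- which(costr + pc_xor(Ir) == gr[Ir + 1L]) - 1L
    pairs <- rbind(pairs, as.matrix(expand.grid(Cl = Cl, Cr = Cr)))
  }
  pairs <- unique(pairs)
  dimnames(pairs) <- NULL
  pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
}

#' Fit an exact dispersal-vicariance analysis
#'
#' Dynamic programming over all non-empty subsets of the areas present in
#' the terminal ranges, on a strictly binary rooted tree.  Returns the
#' global minimal event cost, every optimal root range, the subsets each
#' internal node takes in at least one optimal reconstruction, and the
#' optimal reconstructions themselves enumerated deterministically up to the
#' \code{hold} cap (the exact count of optima is always reported, so the
#' truncation flag is exact).
#'
#' @param tree strictly binary rooted \code{"phylo"} tree (polytomies are an
#'   error, as in classical DIVA software).
#' @param ranges a \code{\link{range_assignment}} covering every terminal.
#' @param maxareas maximum number of areas allowed in any ancestral range;
#'   \code{Inf} (default) for unconstrained.  Must be at least the size of
#'   the largest terminal range.
#' @param hold cap on the number of stored reconstructions (default 32767).
#' @param weight,age accepted for fidelity to classical DIVA settings, but
#'   only the neutral value 1 is supported; any other value is an error.
#' @return an object of class \code{"diva"}: list with \code{cost},
#'   \code{root_optima} (list of area-code vectors), \code{node_optima}
#'   (named list: node -> list of area-code vectors), \code{reconstructions}
#'   (list of lists with \code{nodes} and \code{cost}), \code{n_optimal}
#'   (exact number of optimal reconstructions), \code{truncated},
#'   \code{hold}, \code{maxareas}, \code{areas}, \code{tree}, \code{ranges}.
#' @examples
#' tr <- read_newick("((t1,t2),t3);")
#' ra <- range_assignment(list(t1 = "a", t2 = "b", t3 = "a"))
#' fit <- diva(tr, ra)
#' fit$cost          # 1
#' fit$root_optima   # {a} and {a,b}
#' @export
diva <- function(tree, ranges, maxareas = Inf, hold = 32767L,
                 weight = 1, age = 1) {
  ranges <- check_tree_ranges(tree, ranges)
  if (!is_binary_tree(tree)) {
    stop("DIVA requires a strictly binary tree: resolve polytomies first")
  }
  if (weight != 1 || age != 1) {
    stop("only the neutral settings weight = 1 and age = 1 are supported")
  }
  if (hold < 1L) stop("`hold` must be at least 1")
  hold <- as.integer(hold)

  full_areas <- attr(ranges, "areas")
  used <- as.character(full_areas)[full_areas %in%
                                     unlist(ranges, use.names = FALSE)]
  areas <- area_set(used)
  k <- length(areas)
  if (k > 16L) {
    stop("exact DIVA optimisation over ", k, " areas is infeasible ",
         "(the programme enumerates all 2^k area subsets); merge areas first")
  }
  nsub <- bitwShiftL(1L, k)
  pc <- popcount(0:(nsub - 1L))
  pc_xor <- function(I) pc[bitwXor(0:(nsub - 1L), I) + 1L]

  tmasks <- encode_ranges(ranges, areas)[tree$tip.label]
  if (is.finite(maxareas)) {
    if (maxareas < 1) stop("`maxareas` must be at least 1")
    big <- tree$tip.label[pc[tmasks + 1L] > maxareas]
    if (length(big)) {
      stop("`maxareas` is smaller than the range of terminal(s): ",
           paste(big, collapse = ", "))
    }
  }

  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- node_children(tree)
  cost <- vector("list", nn)
  gmat <- vector("list", nn)
  for (t in seq_len(ntip)) {
    v <- rep(Inf, nsub)
    v[tmasks[t] + 1L] <- 0
    cost[[t]] <- v
  }
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) next
    l <- ch[[v]][1L]
    r <- ch[[v]][2L]
    gmat[[l]] <- g_from_cost(cost[[l]], k)
    gmat[[r]] <- g_from_cost(cost[[r]], k)
    gl <- gmat[[l]]
    gr <- gmat[[r]]
    cv <- rep(Inf, nsub)
    for (S in seq_len(nsub - 1L)) {
      if (pc[S + 1L] > maxareas) next
      if (pc[S + 1L] == 1L) {
        cv[S + 1L] <- gl[S + 1L] + gr[S + 1L]
      } else {
        best <- Inf
        sub <- bitwAnd(S - 1L, S)
        while (sub > 0L) {
          val <- gl[sub + 1L] + gr[bitwXor(S, sub) + 1L]
          if (val < best) best <- val
          sub <- bitwAnd(sub - 1L, S)
        }
        cv[S + 1L] <- best
      }
    }
    cost[[v]] <- cv
  }

  root <- ntip + 1L
  minc <- min(cost[[root]])
  root_masks <- which(cost[[root]] == minc) - 1L

  # mark every (node, subset) occurring in >= 1 optimal reconstruction
  opt_masks <- vector("list", nn)
  seen <- vector("list", nn)
  work <- lapply(root_masks, function(S) c(root, S))
  while (length(work)) {
    item <- work[[length(work)]]
    work[[length(work)]] <- NULL
    v <- item[1L]
    S <- item[2L]
    if (S %in% seen[[v]]) next
    seen[[v]] <- c(seen[[v]], S)
    opt_masks[[v]] <- sort(c(opt_masks[[v]], S))
    if (v <= ntip) next
    l <- ch[[v]][1L]
    r <- ch[[v]][2L]
    pairs <- diva_valid_pairs(S, cost[[v]][S + 1L], gmat[[l]], gmat[[r]],
                              cost[[l]], cost[[r]], pc_xor)
    for (i in seq_len(nrow(pairs))) {
      work[[length(work) + 1L]] <- c(l, pairs[i, 1L])
      work[[length(work) + 1L]] <- c(r, pairs[i, 2L])
    }
  }

  # exact count of optimal reconstructions (product DP over valid pairs)
  count_memo <- new.env(parent = emptyenv())
  count_at <- function(v, S) {
    if (v <= ntip) return(if (S == tmasks[v]) 1 else 0)
    key <- paste(v, S)
    if (!is.null(count_memo[[key]])) return(count_memo[[key]])
    l <- ch[[v]][1L]
    r <- ch[[v]][2L]
    pairs <- diva_valid_pairs(S, cost[[v]][S + 1L], gmat[[l]], gmat[[r]],
                              cost[[l]], cost[[r]], pc_xor)
    n <- 0
    for (i in seq_len(nrow(pairs))) {
      n <- n + count_at(l, pairs[i, 1L]) * count_at(r, pairs[i, 2L])
    }
    count_memo[[key]] <- n
    n
  }
  n_optimal <- sum(vapply(root_masks, function(S) count_at(root, S), 0))

  # deterministic enumeration: depth-first, nodes in pre-order, subset masks
  # ascending, capped at `hold`
  enum_memo <- new.env(parent = emptyenv())
  enum_subtree <- function(v, S, limit) {
    if (limit <= 0L) return(list())
    if (v <= ntip) return(list(stats::setNames(integer(0), character(0))))
    key <- paste(v, S)
    cached <- enum_memo[[key]]
    if (!is.null(cached) && length(cached) >= min(limit, count_at(v, S))) {
      return(cached[seq_len(min(limit, length(cached)))])
    }
    l <- ch[[v]][1L]
    r <- ch[[v]][2L]
    pairs <- diva_valid_pairs(S, cost[[v]][S + 1L], gmat[[l]], gmat[[r]],
                              cost[[l]], cost[[r]], pc_xor)
    res <- list()
    for (Cl in unique(pairs[, 1L])) {
      las <- enum_subtree(l, Cl, limit - length(res))
      partners <- pairs[pairs[, 1L] == Cl, 2L]
      for (la in las) {
        for (Cr in partners) {
          ras <- enum_subtree(r, Cr, limit - length(res))
          for (ra in ras) {
            res[[length(res) + 1L]] <-
              c(stats::setNames(S, as.character(v)), la, ra)
            if (length(res) >= limit) break
          }
          if (length(res) >= limit) break
        }
        if (length(res) >= limit) break
      }
      if (length(res) >= limit) break
    }
    if (count_at(v, S) <= 4096) enum_memo[[key]] <- res
    res
  }
  recon_raw <- list()
  for (S in root_masks) {
    if (length(recon_raw) >= hold) break
    recon_raw <- c(recon_raw, enum_subtree(root, S, hold - length(recon_raw)))
  }
  truncated <- n_optimal > hold

  nm <- node_names(tree)
  mask_list <- function(masks) lapply(masks, decode_mask, areas = areas)
  reconstructions <- lapply(recon_raw, function(a) {
    nodes <- stats::setNames(mask_list(unname(a)), nm[as.integer(names(a))])
    nodes <- c(nodes, lapply(ranges[tree$tip.label], identity))
    list(nodes = nodes, cost = minc)
  })
  node_optima <- stats::setNames(lapply(opt_masks, mask_list), nm)

  structure(list(cost = minc,
                 root_optima = mask_list(root_masks),
                 node_optima = node_optima,
                 reconstructions = reconstructions,
                 n_optimal = n_optimal,
                 truncated = truncated,
                 hold = hold, maxareas = maxareas,
                 areas = areas, tree = tree, ranges = ranges),
            class = "diva")
}

#' @export
print.diva <- function(x, ...) {
  cat("Dispersal-vicariance analysis (exact)\n")
  cat("  terminals:", ape::Ntip(x$tree), " areas:", length(x$areas), "\n")
  cat("  minimal cost (dispersals + extinctions):", x$cost, "\n")
  cat("  optimal root range(s):",
      paste(vapply(x$root_optima, paste, "", collapse = ""), collapse = " "),
      "\n")
  cat("  optimal reconstructions:", format(x$n_optimal, big.mark = ","),
      if (x$truncated) paste0("(", length(x$reconstructions),
                              " stored; hold = ", x$hold, ")") else "",
      "\n")
  invisible(x)
}

#' @export
summary.diva <- function(object, ...) {
  print(object)
  cat("\nPer-node optimal range sets:\n")
  ntip <- ape::Ntip(object$tree)
  inner <- object$node_optima[(ntip + 1L):length(object$node_optima)]
  for (nm in names(inner)) {
    cat("  ", format(nm, width = max(nchar(names(inner)))), " ",
        paste(vapply(inner[[nm]], paste, "", collapse = ""),
              collapse = " "), "\n", sep = "")
  }
  invisible(object)
}

#' @export
plot.diva <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  ntip <- ape::Ntip(x$tree)
  lab <- vapply(x$node_optima[(ntip + 1L):length(x$node_optima)],
                function(s) paste(vapply(s, paste, "", collapse = ""),
                                  collapse = "/"), "")
  ape::nodelabels(lab, frame = "rect", bg = "lightyellow", cex = 0.7)
  invisible(x)
}

#' Ancestral area from a DIVA fit
#'
#' @param x a \code{"diva"} fit.
#' @param mode \code{"union"} (default) returns the union of all optimal
#'   root ranges; \code{"per-reconstruction"} returns each optimal root
#'   range separately.
#' @return character vector of area codes, or a list of them.
#' @export
diva_ancestral_area <- function(x, mode = c("union", "per-reconstruction")) {
  stopifnot(inherits(x, "diva"))
  mode <- match.arg(mode)
  if (mode == "union") {
    ord <- as.character(x$areas)
    ord[ord %in% unlist(x$root_optima, use.names = FALSE)]
  } else {
    x$root_optima
  }
}

# re-score a reconstruction (named list node -> area vector, terminals
# included) by summing split_cost over internal nodes; used to verify that
# enumerated reconstructions attain the reported cost
diva_rescore <- function(tree, nodes) {
  ch <- node_children(tree)
  nm <- node_names(tree)
  ntip <- ape::Ntip(tree)
  total <- 0L
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    kids <- ch[[v]]
    total <- total + split_cost(nodes[[nm[v]]],
                                nodes[[nm[kids[1L]]]],
                                nodes[[nm[kids[2L]]]])
  }
  total
}
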