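# Independent brute-force oracles for the reconstruction methods, written
# against plain character sets and exhaustive enumeration.  They share no
# code path with the package internals they check.

# --- tree plumbing (on ape's edge matrix) -----------------------------------

tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  ch
}

tree_postorder <- function(tree) {
  ch <- tree_children(tree)
  out <- integer(0)
  walk <- function(v) {
    for (c in ch[[v]]) walk(c)
    out <<- c(out, v)
  }
  walk(ape::Ntip(tree) + 1L)
  out
}

tree_depths <- function(tree) {
  ch <- tree_children(tree)
  d <- integer(ape::Ntip(tree) + tree$Nnode)
  walk <- function(v, dep) {
    d[v] <<- dep
    for (c in ch[[v]]) walk(c, dep + 1L)
  }
  walk(ape::Ntip(tree) + 1L, 0L)
  d
}

tips_in_subtree <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  ch <- tree_children(tree)
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= ntip) acc <- c(acc, tree$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  acc
}

# --- DIVA oracle ------------------------------------------------------------

.oracle_carr_cache <- new.env(parent = emptyenv())

# transition cost by direct enumeration over inheritances, character sets
oracle_split_cost <- function(anc, left, right) {
  pay <- function(inh, child) {
    length(setdiff(child, inh)) + length(setdiff(inh, child))
  }
  if (length(anc) == 1) return(pay(anc, left) + pay(anc, right))
  best <- Inf
  n <- length(anc)
  for (code in 1:(2^n - 2)) {
    inl <- anc[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    inr <- setdiff(anc, inl)
    best <- min(best, pay(inl, left) + pay(inr, right))
  }
  best
}

all_subsets <- function(areas) {
  k <- length(areas)
  lapply(1:(2^k - 1), function(code) {
    areas[bitwAnd(code, 2^(seq_len(k) - 1)) > 0]
  })
}

# exhaustive minimisation over every assignment of non-empty subsets to the
# internal nodes; returns minimal cost and the optimal root subsets (as a
# list of sorted character vectors) plus per-node optimal subsets
oracle_diva <- function(tree, ranges) {
  areas <- sort(unique(unlist(ranges)))
  subsets <- all_subsets(areas)
  ns <- length(subsets)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- tree_children(tree)
  internal <- (ntip + 1):nn
  root <- ntip + 1L

  # transition-cost table over subset indices; depends only on the subset
  # lattice, so cache it per area count
  cache_key <- paste0("k", length(areas))
  carr <- .oracle_carr_cache[[cache_key]]
  if (is.null(carr)) {
    canon <- all_subsets(seq_along(areas))
    carr <- array(0L, c(ns, ns, ns))
    for (a in 1:ns) for (l in 1:ns) for (r in 1:ns) {
      carr[a, l, r] <- oracle_split_cost(canon[[a]], canon[[l]], canon[[r]])
    }
    .oracle_carr_cache[[cache_key]] <- carr
  }
  sub_index <- function(set) {
    which(vapply(subsets, function(s) setequal(s, set), TRUE))[1]
  }
  tip_idx <- vapply(tree$tip.label, function(t) sub_index(ranges[[t]]), 1L)

  grid <- as.matrix(expand.grid(rep(list(1:ns), length(internal))))
  colnames(grid) <- as.character(internal)
  idx_of <- function(v, A) {
    if (v <= ntip) rep(tip_idx[v], nrow(A)) else A[, as.character(v)]
  }
  total <- numeric(nrow(grid))
  for (v in internal) {
    kids <- ch[[v]]
    total <- total + carr[cbind(idx_of(v, grid), idx_of(kids[1], grid),
                                idx_of(kids[2], grid))]
  }
  minc <- min(total)
  opt <- grid[total == minc, , drop = FALSE]
  node_opt <- lapply(internal, function(v) {
    lapply(sort(unique(opt[, as.character(v)])),
           function(i) sort(subsets[[i]]))
  })
  names(node_opt) <- as.character(internal)
  list(cost = minc,
       root_optima = node_opt[[as.character(root)]],
       node_optima = node_opt)
}

# --- Fitch oracle -----------------------------------------------------------

# exhaustive minimisation over single-area assignments to internal nodes;
# a terminal edge is free when the parent's state lies in the terminal's
# observed range.  Returns length, root MPR set and per-node MPR sets.
oracle_fitch <- function(tree, ranges) {
  areas <- sort(unique(unlist(ranges)))
  k <- length(areas)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- tree_children(tree)
  internal <- (ntip + 1):nn
  root <- ntip + 1L
  grid <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
  colnames(grid) <- as.character(internal)
  allowed <- vapply(tree$tip.label,
                    function(t) areas %in% ranges[[t]], logical(k))
  total <- numeric(nrow(grid))
  for (v in internal) {
    for (c in ch[[v]]) {
      pv <- grid[, as.character(v)]
      total <- total + if (c <= ntip) {
        1 - allowed[pv, c]
      } else {
        pv != grid[, as.character(c)]
      }
    }
  }
  minc <- min(total)
  opt <- grid[total == minc, , drop = FALSE]
  mpr <- lapply(internal, function(v) {
    sort(areas[unique(opt[, as.character(v)])])
  })
  names(mpr) <- as.character(internal)
  list(length = minc, root_mpr = mpr[[as.character(root)]], mpr = mpr)
}

# --- WAAA oracle ------------------------------------------------------------

# exhaustive directional placement: choose a set of edges (each edge named
# by the node it enters; the root's entering edge is the virtual origin) so
# that a terminal carries the area exactly when some chosen edge lies on its
# root path; minimise the number of steps, break ties towards maximal total
# weight (deepest placement), return the weight sum 1/level.
oracle_directional <- function(tree, flag) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- tree_children(tree)
  depth <- tree_depths(tree)
  cover <- matrix(FALSE, ntip, nn)
  for (v in 1:nn) {
    tips <- if (v <= ntip) v else {
      acc <- integer(0)
      stack <- v
      while (length(stack)) {
        x <- stack[length(stack)]
        stack <- stack[-length(stack)]
        if (x <= ntip) acc <- c(acc, x) else stack <- c(stack, ch[[x]])
      }
      acc
    }
    cover[tips, v] <- TRUE
  }
  w <- 1 / (depth + 1)
  for (size in 1:nn) {
    combs <- utils::combn(nn, size)
    best <- -Inf
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      reach <- rowSums(cover[, sel, drop = FALSE]) > 0
      if (all(reach == flag)) best <- max(best, sum(w[sel]))
    }
    if (is.finite(best)) return(best)
  }
  stop("no valid directional placement")
}

oracle_gains <- function(tree, presence) {
  oracle_directional(tree, as.logical(presence[tree$tip.label]))
}

oracle_losses <- function(tree, presence) {
  p <- as.logical(presence[tree$tip.label])
  if (all(p)) return(0)
  oracle_directional(tree, !p)
}

# --- random instances -------------------------------------------------------

rand_ranges <- function(tree, k_areas, seed = NULL, singleton = FALSE) {
  areas <- letters[seq_len(k_areas)]
  gen <- function() {
    r <- lapply(tree$tip.label, function(t) {
      size <- if (singleton) 1L else sample(1:k_areas, 1, prob = k_areas:1)
      sort(sample(areas, size))
    })
    names(r) <- tree$tip.label
    # make sure every area is used so used-area sets match across routes
    missing <- setdiff(areas, unlist(r))
    for (a in missing) {
      t <- sample(tree$tip.label, 1)
      r[[t]] <- if (singleton) a else sort(unique(c(r[[t]], a)))
    }
    r
  }
  if (is.null(seed)) gen() else ancarea:::with_seed(seed, gen())
}

set_list_equal <- function(a, b) {
  norm <- function(l) sort(vapply(l, function(s) paste(sort(s), collapse = ""),
                                  ""))
  identical(norm(a), norm(b))
}
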