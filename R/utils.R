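# Internal helpers shared across modules.

# bit mask for the i-th area (1-based position in the area set)
bit_for <- function(i) bitwShiftL(1L, as.integer(i) - 1L)

# vectorised population count; masks never exceed 2^28 so the loop is short
popcount <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x != 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

# children of every node, in cladewise (input) order; index = ape node number
node_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    ch[[e[i, 1L]]] <- c(ch[[e[i, 1L]]], e[i, 2L])
  }
  ch
}

node_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p[ape::Ntip(tree) + 1L] <- NA_integer_
  p
}

# pre-order node sequence (root first, children in input order)
preorder_nodes <- function(tree) {
  ch <- node_children(tree)
  root <- ape::Ntip(tree) + 1L
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- ch[[v]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  out
}

# post-order: reverse pre-order visits every parent after its children
postorder_nodes <- function(tree) rev(preorder_nodes(tree))

node_depths <- function(tree) {
  par <- node_parents(tree)
  depth <- integer(length(par))
  for (v in preorder_nodes(tree)) {
    depth[v] <- if (is.na(par[v])) 0L else depth[par[v]] + 1L
  }
  depth
}

# display names: tip labels for tips, node labels (or "node_<k>") for internals
node_names <- function(tree) {
  ntip <- ape::Ntip(tree)
  inner <- if (!is.null(tree$node.label) &&
               all(nzchar(tree$node.label)) &&
               anyDuplicated(tree$node.label) == 0L) {
    tree$node.label
  } else {
    paste0("node_", ntip + seq_len(tree$Nnode))
  }
  c(tree$tip.label, inner)
}

# tip labels descending from each node
tips_under <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  ch <- node_children(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= ntip) out <- c(out, tree$tip.label[v]) else stack <- c(stack, ch[[v]])
  }
  sort(out)
}
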