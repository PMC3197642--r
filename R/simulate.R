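# Synthetic trees, range histories with known ancestral ranges, and gridded
# occurrences, so every stage of the workflow can be validated against a
# known truth.

#' Simulate a rooted binary tree
#'
#' Random sequential coalescence: starting from \code{n} labelled lineages
#' (t1..tn), two uniformly chosen lineages are joined repeatedly until one
#' remains.  Reproducible per seed.
#'
#' @param n_terminals number of terminals (at least 2).
#' @param seed RNG seed.
#' @return a strictly binary rooted \code{"phylo"} tree.
#' @export
simulate_tree <- function(n_terminals, seed = NULL) {
  if (n_terminals < 2L) stop("`n_terminals` must be at least 2")
  with_seed(seed, {
    lineages <- paste0("t", seq_len(n_terminals))
    while (length(lineages) > 1L) {
      i <- sample.int(length(lineages), 2L)
      joined <- paste0("(", lineages[i[1L]], ",", lineages[i[2L]], ")")
      lineages <- c(lineages[-i], joined)
    }
    read_newick(paste0(lineages, ";"))
  })
}

#' Simulate a biogeographic range history on a tree
#'
#' Evolves area ranges from a root range of known size down a tree.  At each
#' internal node with a range of two or more areas, the range splits by
#' vicariance (a uniformly chosen ordered partition into two non-empty
#' parts) with probability \code{p_vicariance}, otherwise both daughters
#' inherit the full range (duplication); single-area ranges always
#' duplicate.  Along every branch, Poisson numbers of dispersal events (add
#' a uniformly chosen absent area) and extinction events (remove a
#' uniformly chosen present area, never emptying the range) are applied in
#' random order, with means equal to the respective rates (branch lengths
#' are ignored: all downstream methods are cladogram-only).  The true range
#' of every node and the complete event log are recorded.
#'
#' @param tree strictly binary rooted \code{"phylo"} tree.
#' @param k_areas number of areas (codes "A", "B", ...).
#' @param root_range_size size of the root range, sampled uniformly among
#'   subsets of that size.
#' @param p_vicariance probability of vicariance at a widespread node.
#' @param dispersal_rate,extinction_rate mean event counts per branch.
#' @param seed RNG seed.
#' @return an object of class \code{"sim_history"}: list with \code{tree},
#'   \code{ranges} (a \code{\link{range_assignment}} for the terminals),
#'   \code{node_ranges} (named list over all nodes, true ranges),
#'   \code{root_range}, \code{events} (data.frame: node, event, area),
#'   \code{areas}, \code{seed}.
#' @export
simulate_range_history <- function(tree, k_areas, root_range_size,
                                   p_vicariance = 1, dispersal_rate = 0,
                                   extinction_rate = 0, seed = NULL) {
  if (root_range_size < 1L || root_range_size > k_areas) {
    stop("`root_range_size` must be between 1 and `k_areas`")
  }
  if (p_vicariance < 0 || p_vicariance > 1) {
    stop("`p_vicariance` must be a probability")
  }
  if (dispersal_rate < 0 || extinction_rate < 0) {
    stop("rates must be non-negative")
  }
  areas <- area_set(LETTERS[seq_len(k_areas)])
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ch <- node_children(tree)
  nm <- node_names(tree)

  with_seed(seed, {
    node_ranges <- vector("list", nn)
    ev_node <- character(0)
    ev_type <- character(0)
    ev_area <- character(0)
    log_event <- function(node, type, area) {
      ev_node <<- c(ev_node, nm[node])
      ev_type <<- c(ev_type, type)
      ev_area <<- c(ev_area, area)
    }

    root <- ntip + 1L
    node_ranges[[root]] <- sort(sample(as.character(areas), root_range_size))

    # range arriving at the top of the branch into `child`, then anagenetic
    # events along the branch
    evolve_branch <- function(child, inherited) {
      r <- inherited
      nd <- stats::rpois(1L, dispersal_rate)
      ne <- stats::rpois(1L, extinction_rate)
      kinds <- sample(c(rep("dispersal", nd), rep("extinction", ne)))
      for (kind in kinds) {
        if (kind == "dispersal") {
          absent <- setdiff(as.character(areas), r)
          if (!length(absent)) next
          a <- absent[sample.int(length(absent), 1L)]
          r <- sort(c(r, a))
          log_event(child, "dispersal", a)
        } else {
          if (length(r) <= 1L) next
          a <- r[sample.int(length(r), 1L)]
          r <- setdiff(r, a)
          log_event(child, "extinction", a)
        }
      }
      r
    }

    for (v in preorder_nodes(tree)) {
      if (v <= ntip) next
      r <- node_ranges[[v]]
      kids <- ch[[v]]
      if (length(r) >= 2L && stats::runif(1L) < p_vicariance) {
        repeat {
          side <- stats::runif(length(r)) < 0.5
          if (any(side) && !all(side)) break
        }
        parts <- list(r[side], r[!side])
        kind <- "vicariance"
      } else {
        parts <- list(r, r)
        kind <- "duplication"
      }
      for (i in 1:2) {
        # the cladogenetic event is logged on the child branch with the part
        # that child inherited, so the log alone determines the replay
        log_event(kids[i], kind, paste(parts[[i]], collapse = ""))
        node_ranges[[kids[i]]] <- evolve_branch(kids[i], parts[[i]])
      }
    }

    ranges <- range_assignment(
      stats::setNames(node_ranges[seq_len(ntip)], tree$tip.label), areas)
    structure(list(tree = tree, ranges = ranges,
                   node_ranges = stats::setNames(node_ranges, nm),
                   root_range = node_ranges[[root]],
                   events = data.frame(node = ev_node, event = ev_type,
                                       area = ev_area,
                                       stringsAsFactors = FALSE),
                   areas = areas, seed = seed),
              class = "sim_history")
  })
}

#' @export
print.sim_history <- function(x, ...) {
  cat("Simulated range history:", ape::Ntip(x$tree), "terminals,",
      length(x$areas), "areas\n")
  cat("  true root range:", paste(x$root_range, collapse = ""), "\n")
  cat("  events:", nrow(x$events), "\n")
  invisible(x)
}

#' Replay the event log of a simulated history
#'
#' Recomputes every node range by replaying the recorded cladogenetic and
#' anagenetic events downward from the root range, using only the event log.
#' Used as an internal-consistency check: the replayed ranges must equal the
#' recorded ones exactly, and the cladogenetic events must be coherent
#' (vicariant parts are non-empty disjoint blocks of the parent range whose
#' union is the parent range; duplicated parts equal the parent range).
#'
#' @param sim a \code{"sim_history"}.
#' @return named list of replayed node ranges, in the same layout as
#'   \code{sim$node_ranges}.
#' @export
replay_history <- function(sim) {
  stopifnot(inherits(sim, "sim_history"))
  tree <- sim$tree
  ntip <- ape::Ntip(tree)
  ch <- node_children(tree)
  nm <- node_names(tree)
  ev <- sim$events
  out <- vector("list", ntip + tree$Nnode)
  out[[ntip + 1L]] <- sim$root_range
  for (v in preorder_nodes(tree)) {
    if (v <= ntip) next
    r <- out[[v]]
    kids <- ch[[v]]
    parts <- vector("list", 2L)
    for (i in 1:2) {
      child <- kids[i]
      branch <- ev[ev$node == nm[child], , drop = FALSE]
      clad <- branch[branch$event %in% c("vicariance", "duplication"), ,
                     drop = FALSE]
      if (nrow(clad) != 1L) stop("event log corrupt at node ", nm[child])
      inherited <- strsplit(clad$area, "")[[1L]]
      if (clad$event == "duplication") {
        if (!setequal(inherited, r)) {
          stop("duplicated part at node ", nm[child],
               " does not equal the parent range")
        }
      } else if (!length(inherited) || !all(inherited %in% r)) {
        stop("vicariant part at node ", nm[child],
             " is not a non-empty block of the parent range")
      }
      parts[[i]] <- inherited
      r2 <- inherited
      ana <- branch[branch$event %in% c("dispersal", "extinction"), ,
                    drop = FALSE]
      for (j in seq_len(nrow(ana))) {
        r2 <- if (ana$event[j] == "dispersal") {
          sort(c(r2, ana$area[j]))
        } else {
          setdiff(r2, ana$area[j])
        }
      }
      out[[child]] <- r2
    }
    if (!setequal(parts[[1L]], parts[[2L]]) &&
        (length(intersect(parts[[1L]], parts[[2L]])) > 0L ||
         !setequal(c(parts[[1L]], parts[[2L]]), r))) {
      stop("vicariant parts at node ", nm[v], " do not partition the range")
    }
  }
  stats::setNames(out, nm)
}

#' Generate gridded point occurrences for simulated species
#'
#' Gives every species \code{points_per_species} occurrence points placed
#' uniformly inside the grid cells of its areas; a \code{noise_fraction} of
#' points is instead placed uniformly anywhere in the bounding box of all
#' area cells.  Feeds \code{\link{build_grid}}.
#'
#' @param ranges a \code{\link{range_assignment}} (species -> areas).
#' @param area_cells named list: area code -> two-column matrix of
#'   (col, row) cell indices; cell sets must be non-empty and disjoint.
#' @param points_per_species points per species (0 gives an empty table).
#' @param noise_fraction fraction of points placed uniformly in the overall
#'   bounding box (default 0).
#' @param origin,cell_size grid geometry, as in \code{\link{build_grid}}.
#' @param seed RNG seed.
#' @return data.frame with columns \code{species}, \code{lon}, \code{lat}.
#' @export
generate_occurrences <- function(ranges, area_cells, points_per_species,
                                 noise_fraction = 0, origin = c(-80, 5),
                                 cell_size = 0.75, seed = NULL) {
  if (!inherits(ranges, "range_assignment")) ranges <- range_assignment(ranges)
  if (any(vapply(area_cells, nrow, 1L) == 0L)) {
    stop("every area needs at least one cell")
  }
  ids <- lapply(area_cells, function(m) cell_id(m[, 1L], m[, 2L]))
  if (anyDuplicated(unlist(ids, use.names = FALSE))) {
    stop("area cell sets must be disjoint")
  }
  missing <- setdiff(unique(unlist(ranges, use.names = FALSE)),
                     names(area_cells))
  if (length(missing)) {
    stop("no cells declared for area(s): ", paste(missing, collapse = ", "))
  }
  allcells <- do.call(rbind, unname(area_cells))
  if (points_per_species == 0L) {
    return(data.frame(species = character(0), lon = numeric(0),
                      lat = numeric(0)))
  }
  with_seed(seed, {
    rows <- lapply(names(ranges), function(sp) {
      cells <- do.call(rbind, unname(area_cells[ranges[[sp]]]))
      noise <- stats::runif(points_per_species) < noise_fraction
      pick <- cells[sample.int(nrow(cells), points_per_species,
                               replace = TRUE), , drop = FALSE]
      # noise points: any cell of the overall bounding box
      if (any(noise)) {
        cr <- range(allcells[, 1L])
        rr <- range(allcells[, 2L])
        pick[noise, 1L] <- sample(cr[1L]:cr[2L], sum(noise), replace = TRUE)
        pick[noise, 2L] <- sample(rr[1L]:rr[2L], sum(noise), replace = TRUE)
      }
      u <- stats::runif(points_per_species)
      v <- stats::runif(points_per_species)
      data.frame(species = sp,
                 lon = origin[1L] + (pick[, 1L] + u) * cell_size,
                 lat = origin[2L] - (pick[, 2L] + v) * cell_size,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
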