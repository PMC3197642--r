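# Grid-based areas-of-endemism search: occurrence gridding, an explicit
# two-factor endemicity score, one-cell-swap hill-climbing from seed cell
# sets, superfluous-set filtering, and a similarity consensus.

# cells are encoded as single integers; columns/rows are small, so offset
# into the positive range and combine
CELL_OFF <- 4096L
CELL_KEY <- 16384L

cell_id <- function(col, row) (col + CELL_OFF) * CELL_KEY + (row + CELL_OFF)

cell_colrow <- function(id) {
  col <- id %/% CELL_KEY - CELL_OFF
  row <- id %% CELL_KEY - CELL_OFF
  cbind(col = col, row = row)
}

#' Grid point occurrences into cells
#'
#' Assigns every occurrence record to exactly one grid cell.  Cell
#' \code{(c, r)} covers the half-open box
#' \code{[x0 + c*s, x0 + (c+1)*s)} in longitude and
#' \code{(y0 - (r+1)*s, y0 - r*s]} in latitude, where \code{(x0, y0)} is the
#' grid origin (north-west corner) and \code{s} the cell size, so boundary
#' points are assigned deterministically.  Rows count southward from the
#' origin latitude.
#'
#' @param occurrences data.frame with columns species, longitude, latitude
#'   (first three columns, in that order), in decimal degrees.
#' @param origin numeric length-2: origin longitude and latitude
#'   (default \code{c(-80, 5)}).
#' @param cell_size cell side in degrees (default 0.75).
#' @return an object of class \code{"endemism_grid"}: list with
#'   \code{origin}, \code{cell_size}, \code{species} (named list of sorted
#'   cell-id vectors), \code{n_records}.
#' @export
build_grid <- function(occurrences, origin = c(-80, 5), cell_size = 0.75) {
  occ <- as.data.frame(occurrences)
  if (ncol(occ) < 3L) {
    stop("occurrence table needs columns: species, longitude, latitude")
  }
  sp <- as.character(occ[[1L]])
  lon <- suppressWarnings(as.numeric(occ[[2L]]))
  lat <- suppressWarnings(as.numeric(occ[[3L]]))
  bad <- (!is.na(occ[[2L]]) & is.na(lon)) | (!is.na(occ[[3L]]) & is.na(lat))
  if (any(bad)) stop("non-numeric coordinates in occurrence table")
  keep <- !is.na(lon) & !is.na(lat)
  dropped <- setdiff(unique(sp), unique(sp[keep]))
  if (length(dropped)) {
    warning("species with no valid records dropped: ",
            paste(dropped, collapse = ", "))
  }
  sp <- sp[keep]
  lon <- lon[keep]
  lat <- lat[keep]
  col <- floor((lon - origin[1L]) / cell_size)
  row <- floor((origin[2L] - lat) / cell_size)
  ids <- cell_id(as.integer(col), as.integer(row))
  species <- lapply(split(ids, sp), function(x) sort(unique(x)))
  species <- species[order(names(species))]
  structure(list(origin = origin, cell_size = cell_size,
                 species = species, n_records = length(ids)),
            class = "endemism_grid")
}

#' @export
print.endemism_grid <- function(x, ...) {
  cells <- sort(unique(unlist(x$species, use.names = FALSE)))
  cat("Endemism grid:", length(x$species), "species,", x$n_records,
      "records,", length(cells), "occupied cells\n")
  cat("  origin (", x$origin[1L], ", ", x$origin[2L], "), cell size ",
      x$cell_size, " degrees\n", sep = "")
  invisible(x)
}

#' Endemicity score of one species against a candidate area
#'
#' A two-factor score in [0, 1]: coverage of the area times containment of
#' the species,
#' \deqn{score = (o/|A|) \times (o/(o+u))}
#' where \code{o} is the number of the species' cells inside the area,
#' \code{|A|} the number of area cells, and \code{u} the number of species
#' cells outside.  The score is 1 exactly when the species' cell set equals
#' the area's cell set.
#'
#' @param area_cells,species_cells cell sets: integer cell ids (as stored in
#'   an \code{"endemism_grid"}) or two-column matrices of (col, row).
#' @return score in [0, 1].
#' @export
endemicity_score <- function(area_cells, species_cells) {
  if (is.matrix(area_cells)) {
    area_cells <- cell_id(area_cells[, 1L], area_cells[, 2L])
  }
  if (is.matrix(species_cells)) {
    species_cells <- cell_id(species_cells[, 1L], species_cells[, 2L])
  }
  if (!length(area_cells)) stop("candidate area has no cells")
  if (!length(species_cells)) stop("species has no cells")
  o <- sum(species_cells %in% area_cells)
  u <- length(species_cells) - o
  (o / length(area_cells)) * (o / (o + u))
}

# score a candidate cell set against every species of the grid
score_area <- function(cells, grid, species_threshold) {
  scores <- vapply(grid$species, function(sp) {
    o <- sum(sp %in% cells)
    if (o == 0L) return(0)
    (o / length(cells)) * (o / length(sp))
  }, 0)
  endemics <- names(scores)[scores >= species_threshold]
  list(cells = sort(cells), species_scores = scores, endemics = endemics,
       score = sum(scores[endemics]))
}

# 8-neighbourhood of a set of cell ids
neighbour_cells <- function(cells) {
  cr <- cell_colrow(cells)
  dd <- expand.grid(dc = -1L:1L, dr = -1L:1L)
  out <- unlist(lapply(seq_len(nrow(dd)), function(i) {
    cell_id(cr[, 1L] + dd$dc[i], cr[, 2L] + dd$dr[i])
  }))
  sort(setdiff(unique(out), cells))
}

# deterministic first-improvement hill climb on single-cell moves:
# removals (lexicographic col, row) first, then additions
climb_area <- function(cells, grid, species_threshold) {
  cur <- score_area(sort(unique(cells)), grid, species_threshold)
  repeat {
    improved <- FALSE
    moves <- list()
    if (length(cur$cells) > 1L) {
      for (cid in cur$cells) moves[[length(moves) + 1L]] <- c(-1L, cid)
    }
    for (cid in neighbour_cells(cur$cells)) {
      moves[[length(moves) + 1L]] <- c(1L, cid)
    }
    for (mv in moves) {
      cand_cells <- if (mv[1L] < 0L) {
        setdiff(cur$cells, mv[2L])
      } else {
        c(cur$cells, mv[2L])
      }
      cand <- score_area(cand_cells, grid, species_threshold)
      if (cand$score > cur$score) {
        cur <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) return(cur)
  }
}

# keep a candidate only if, against every better-or-equal kept candidate, at
# least half of its endemic species are unique
filter_superfluous <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  ord <- order(-vapply(cands, `[[`, 0, "score"),
               vapply(cands, function(a) paste(a$cells, collapse = ","), ""))
  cands <- cands[ord]
  kept <- list()
  for (a in cands) {
    redundant <- any(vapply(kept, function(b) {
      n_unique <- length(setdiff(a$endemics, b$endemics))
      n_unique / length(a$endemics) < 0.5
    }, TRUE))
    if (!redundant) kept[[length(kept) + 1L]] <- a
  }
  kept
}

#' Search for candidate areas of endemism
#'
#' Hill-climbs from seed cell sets -- every species' occupied-cell set plus
#' a random sample of single-occupied-cell 3x3 neighbourhoods -- adding or
#' removing one cell at a time while the area score strictly increases
#' (first-improvement, moves evaluated in lexicographic cell order).
#' Candidates supported by at least \code{min_species} endemic species
#' (per-species endemicity score at or above \code{species_threshold}) and
#' with area score at or above \code{min_score} are kept; duplicates and
#' superfluous sets (fewer than half of their endemic species unique
#' relative to a better-scoring candidate) are discarded.  Deterministic
#' under \code{seed}.
#'
#' @param grid an \code{"endemism_grid"}.
#' @param species_threshold minimum per-species endemicity score to count a
#'   species as endemic (default 0.5).
#' @param min_score minimum area score (default 1.5).
#' @param min_species minimum number of endemic species (default 2).
#' @param seeds optional list of extra seed cell sets (integer cell ids).
#' @param max_cell_seeds number of randomly sampled occupied-cell
#'   neighbourhood seeds per search (default 15).
#' @param seed RNG seed for the neighbourhood-seed sample.
#' @return list of \code{"candidate_area"} objects, sorted by score
#'   (descending) then cells; possibly empty.
#' @export
search_areas <- function(grid, species_threshold = 0.5, min_score = 1.5,
                         min_species = 2L, seeds = NULL,
                         max_cell_seeds = 15L, seed = NULL) {
  stopifnot(inherits(grid, "endemism_grid"))
  if (length(grid$species) < 2L) return(list())
  starts <- unname(grid$species)
  occupied <- sort(unique(unlist(grid$species, use.names = FALSE)))
  picked <- with_seed(seed, {
    if (length(occupied) > max_cell_seeds) {
      sort(sample(occupied, max_cell_seeds))
    } else {
      occupied
    }
  })
  for (cid in picked) {
    block <- sort(c(cid, neighbour_cells(cid)))
    starts[[length(starts) + 1L]] <- block
  }
  if (!is.null(seeds)) starts <- c(starts, lapply(seeds, as.integer))

  found <- list()
  seen <- character(0)
  for (s in starts) {
    a <- climb_area(s, grid, species_threshold)
    key <- paste(a$cells, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (length(a$endemics) >= min_species && a$score >= min_score) {
      found[[length(found) + 1L]] <- structure(a, class = "candidate_area")
    }
  }
  found <- filter_superfluous(found)
  ord <- order(-vapply(found, `[[`, 0, "score"),
               vapply(found, function(a) paste(a$cells, collapse = ","), ""))
  found[ord]
}

#' @export
print.candidate_area <- function(x, ...) {
  cat("Candidate area of endemism: ", length(x$cells), " cells, score ",
      round(x$score, 4), "\n", sep = "")
  cat("  endemic species:", paste(x$endemics, collapse = ", "), "\n")
  invisible(x)
}

#' Cell coordinates of a candidate area
#'
#' @param x a \code{"candidate_area"} (or integer cell ids).
#' @return two-column integer matrix of (col, row) indices.
#' @export
area_cells <- function(x) {
  ids <- if (inherits(x, "candidate_area")) x$cells else as.integer(x)
  cell_colrow(ids)
}

#' Consensus of candidate areas across search replicates
#'
#' Removes exact duplicates (identical cell sets), then groups candidates so
#' that every member of a group shares at least \code{cutoff} species
#' similarity (Jaccard on endemic-species sets) with all other members of
#' the group; each group is replaced by the union of its cell sets,
#' rescored on the grid.
#'
#' @param candidates list of \code{"candidate_area"} objects, typically
#'   pooled over several \code{\link{search_areas}} replicates.
#' @param cutoff similarity cutoff in (0, 1]; default 0.40.
#' @param grid the \code{"endemism_grid"} the candidates came from (needed
#'   to rescore merged areas).
#' @param species_threshold endemic threshold used when rescoring.
#' @return list of consensus \code{"candidate_area"} objects.
#' @export
consensus_areas <- function(candidates, cutoff = 0.40, grid,
                            species_threshold = 0.5) {
  if (!length(candidates)) return(list())
  keys <- vapply(candidates, function(a) paste(a$cells, collapse = ","), "")
  candidates <- candidates[!duplicated(keys)]
  ord <- order(-vapply(candidates, `[[`, 0, "score"),
               vapply(candidates, function(a) paste(a$cells, collapse = ","),
                      ""))
  candidates <- candidates[ord]
  groups <- list()
  for (a in candidates) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      ok <- all(vapply(groups[[gi]], function(b) {
        jaccard(a$endemics, b$endemics) >= cutoff
      }, TRUE))
      if (ok) {
        groups[[gi]][[length(groups[[gi]]) + 1L]] <- a
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- list(a)
  }
  lapply(groups, function(g) {
    cells <- sort(unique(unlist(lapply(g, `[[`, "cells"))))
    structure(score_area(cells, grid, species_threshold),
              class = "candidate_area")
  })
}
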