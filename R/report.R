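# Comparison report: run all three reconstruction methods on one input and
# assemble a per-clade table of ancestral-area answers with agreement
# metrics.

#' Jaccard similarity of two area sets
#'
#' \code{|a n b| / |a u b|}; defined as 1 when both sets are empty.
#'
#' @param a,b character vectors.
#' @return value in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Run all three ancestral-area methods and compare them per clade
#'
#' Fits Fitch parsimony, weighted ancestral area analysis and
#' dispersal-vicariance analysis on one tree and range assignment, and
#' reports, for every named clade, the three ancestral-area answers plus
#' pairwise Jaccard agreement.  Fitch and DIVA answer at the clade's most
#' recent common ancestor of the full-tree analysis (DIVA: the union of the
#' node's optimal subsets, flagged when several optima exist -- the asterisk
#' convention); WAAA is recomputed on the clade's subtree, since its
#' probability index is defined clade-internally.  A single-terminal clade
#' reports its observed range under every method.  A method whose
#' preconditions fail (e.g. DIVA on a non-binary tree) is reported as
#' failed for all clades with a warning, without aborting the others.
#'
#' @param tree rooted \code{"phylo"} tree.
#' @param ranges a \code{\link{range_assignment}} covering every terminal.
#' @param clades named list: clade name -> terminal labels.  Defaults to one
#'   row for the whole tree.
#' @param waaa_threshold rescaled-PI cutoff for the WAAA ancestral set.
#' @param maxareas,hold passed to \code{\link{diva}}.
#' @return an object of class \code{"area_report"}: list with \code{table}
#'   (data.frame: clade, fitch, waaa, diva, diva_multiple, diva_n_optima,
#'   jaccard_fitch_waaa, jaccard_fitch_diva, jaccard_waaa_diva), the three
#'   fits (\code{fitch}, \code{waaa}, \code{diva}; NULL where failed),
#'   \code{errors} (named character of per-method failures), \code{clades}.
#' @examples
#' ex <- load_liolaemid_example()
#' rep <- ancestral_areas(ex$tree, ex$ranges, ex$clades)
#' print(rep)
#' @export
ancestral_areas <- function(tree, ranges, clades = NULL,
                            waaa_threshold = 0.5, maxareas = Inf,
                            hold = 32767L) {
  ranges <- check_tree_ranges(tree, ranges)
  if (is.null(clades)) {
    clades <- list(all_terminals = tree$tip.label)
  }
  errors <- character(0)

  fitch_fit <- tryCatch(fitch_areas(tree, ranges), error = function(e) {
    warning("Fitch optimisation failed: ", conditionMessage(e))
    errors["fitch"] <<- conditionMessage(e)
    NULL
  })
  waaa_fit <- tryCatch(waaa(tree, ranges, threshold = waaa_threshold),
                       error = function(e) {
    warning("WAAA failed: ", conditionMessage(e))
    errors["waaa"] <<- conditionMessage(e)
    NULL
  })
  diva_fit <- tryCatch(diva(tree, ranges, maxareas = maxareas, hold = hold),
                       error = function(e) {
    warning("DIVA failed: ", conditionMessage(e))
    errors["diva"] <<- conditionMessage(e)
    NULL
  })

  nm <- node_names(tree)
  rows <- lapply(names(clades), function(cl) {
    tips <- clades[[cl]]
    bad <- setdiff(tips, tree$tip.label)
    if (length(bad)) {
      stop("clade '", cl, "' names unknown terminal(s): ",
           paste(bad, collapse = ", "))
    }
    single <- length(tips) == 1L
    node <- if (single) NA_integer_ else ape::getMRCA(tree, tips)
    if (!single && !setequal(tips_under(tree, node), tips)) {
      stop("clade '", cl, "' is not monophyletic in the tree")
    }
    f_set <- if (single) ranges[[tips]] else if (!is.null(fitch_fit)) {
      fitch_fit$mpr$states[[nm[node]]]
    }
    w_set <- if (single) ranges[[tips]] else if (!is.null(waaa_fit)) {
      waaa_clade(tree, ranges, tips, threshold = waaa_threshold)
    }
    if (single) {
      d_sets <- list(ranges[[tips]])
    } else if (!is.null(diva_fit)) {
      d_sets <- diva_fit$node_optima[[nm[node]]]
    } else {
      d_sets <- NULL
    }
    d_union <- if (!is.null(d_sets)) {
      ord <- as.character(attr(ranges, "areas"))
      ord[ord %in% unlist(d_sets, use.names = FALSE)]
    }
    list(clade = cl, fitch = f_set, waaa = w_set, diva = d_union,
         diva_multiple = if (is.null(d_sets)) NA else length(d_sets) > 1L,
         diva_n_optima = if (is.null(d_sets)) NA_integer_ else length(d_sets),
         jaccard_fitch_waaa = if (is.null(f_set) || is.null(w_set)) NA_real_
                              else jaccard(f_set, w_set),
         jaccard_fitch_diva = if (is.null(f_set) || is.null(d_union)) NA_real_
                              else jaccard(f_set, d_union),
         jaccard_waaa_diva = if (is.null(w_set) || is.null(d_union)) NA_real_
                             else jaccard(w_set, d_union))
  })

  fmt <- function(x) if (is.null(x)) NA_character_ else paste(x, collapse = "")
  tab <- data.frame(
    clade = vapply(rows, `[[`, "", "clade"),
    fitch = vapply(rows, function(r) fmt(r$fitch), ""),
    waaa = vapply(rows, function(r) fmt(r$waaa), ""),
    diva = vapply(rows, function(r) fmt(r$diva), ""),
    diva_multiple = vapply(rows, function(r) as.logical(r$diva_multiple), TRUE),
    diva_n_optima = vapply(rows, function(r) as.integer(r$diva_n_optima), 1L),
    jaccard_fitch_waaa = vapply(rows, `[[`, 0, "jaccard_fitch_waaa"),
    jaccard_fitch_diva = vapply(rows, `[[`, 0, "jaccard_fitch_diva"),
    jaccard_waaa_diva = vapply(rows, `[[`, 0, "jaccard_waaa_diva"),
    stringsAsFactors = FALSE)

  structure(list(table = tab, fitch = fitch_fit, waaa = waaa_fit,
                 diva = diva_fit, errors = errors, clades = clades,
                 sets = rows),
            class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("Ancestral-area comparison report\n\n")
  tab <- x$table
  star <- ifelse(!is.na(tab$diva_multiple) & tab$diva_multiple, "*", "")
  disp <- data.frame(Clade = paste0(tab$clade, star),
                     Fitch = tab$fitch, WAAA = tab$waaa, DIVA = tab$diva,
                     stringsAsFactors = FALSE)
  print.data.frame(disp, row.names = FALSE)
  if (any(star == "*")) {
    cat("\n* clade has multiple optimal DIVA reconstructions\n")
  }
  if (length(x$errors)) {
    cat("\nFailed methods:\n")
    for (m in names(x$errors)) cat("  ", m, ": ", x$errors[m], "\n", sep = "")
  }
  invisible(x)
}

#' Write a comparison report to JSON
#'
#' @param x an \code{"area_report"}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(x, file) {
  stopifnot(inherits(x, "area_report"))
  payload <- list(
    table = x$table,
    diva_cost = if (!is.null(x$diva)) x$diva$cost else NULL,
    diva_n_optimal = if (!is.null(x$diva)) x$diva$n_optimal else NULL,
    diva_truncated = if (!is.null(x$diva)) x$diva$truncated else NULL,
    waaa_pi = if (!is.null(x$waaa)) as.data.frame(x$waaa$pi) else NULL,
    errors = as.list(x$errors))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
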