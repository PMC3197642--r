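#' Bundled Liolaemidae metatree example
#'
#' A small worked example for the family Liolaemidae (South American
#' liolaemid lizards): a six-terminal composite (metatree) topology --
#' \emph{Ctenoblepharys} sister to (\emph{Liolaemus} + \emph{Phymaturus}),
#' with \emph{Liolaemus} split into the \emph{chiliensis} group and
#' \emph{Eulaemus} (\emph{lineomaculatus} sister to \emph{montanus} +
#' \emph{boulengeri}) -- together with named clades and a taxon-area table.
#'
#' Species-level area assignments for the full family are not publicly
#' available, so the bundled terminal ranges are \strong{synthetic
#' stand-ins} (file \code{liolaemidae_ranges_synthetic.tsv}): the
#' \emph{Ctenoblepharys} range \{W\} (Coastal Central Peru) is fixed by the
#' genus' actual distribution, and each group terminal carries a compact
#' range consistent with its documented distribution.  They make the
#' example runnable end to end; they are not species-level data.
#'
#' Also bundled: the full area codification (33 areas of endemism,
#' \code{liolaemid_area_names()}) and an area-merge coding of the kind DIVA
#' analyses use to stay within their area-count limit
#' (\code{liolaemid_merge_table()}).  The merge table is recorded verbatim
#' from its source material; rows flagged \code{ambiguous} contain tokens
#' that conflict with the area codification as printed (a "10" token
#' matching no area code, and areas I and C appearing in two groups), so
#' the table is reference data and cannot be used as a validated merge map
#' without editorial decisions.
#'
#' @return \code{load_liolaemid_example()}: list with \code{tree} (a
#'   \code{"phylo"}), \code{ranges} (a \code{\link{range_assignment}}),
#'   \code{clades} (named list of terminal vectors), \code{areas}
#'   (an \code{\link{area_set}} of the codes used by the ranges).
#' @examples
#' ex <- load_liolaemid_example()
#' ex$tree$tip.label
#' @export
load_liolaemid_example <- function() {
  path <- function(f) system.file("extdata", f, package = "ancarea",
                                  mustWork = TRUE)
  tree <- read_newick(path("liolaemidae_metatree.nwk"))
  tab <- utils::read.table(path("liolaemidae_ranges_synthetic.tsv"),
                           header = TRUE, sep = "\t",
                           colClasses = "character")
  codes <- sort(unique(unlist(strsplit(tab$areas, ""))))
  areas <- area_set(codes)
  ranges <- read_taxon_areas(tab, areas)
  clades <- jsonlite::read_json(path("liolaemidae_clades.json"),
                                simplifyVector = TRUE)
  list(tree = tree, ranges = ranges, clades = clades, areas = areas)
}

#' @rdname load_liolaemid_example
#' @return \code{liolaemid_area_names()}: data.frame with columns
#'   \code{code}, \code{name} for all 33 areas of endemism.
#' @export
liolaemid_area_names <- function() {
  utils::read.table(system.file("extdata", "liolaemidae_area_names.tsv",
                                package = "ancarea", mustWork = TRUE),
                    header = TRUE, sep = "\t", colClasses = "character",
                    quote = "", comment.char = "")
}

#' @rdname load_liolaemid_example
#' @return \code{liolaemid_merge_table()}: data.frame with columns
#'   \code{original_group}, \code{merged}, \code{ambiguous}, \code{note} --
#'   the published DIVA area-merge coding, verbatim.
#' @export
liolaemid_merge_table <- function() {
  tab <- utils::read.table(system.file("extdata",
                                       "liolaemidae_diva_merge.tsv",
                                       package = "ancarea", mustWork = TRUE),
                           header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           comment.char = "", na.strings = NULL)
  tab$ambiguous <- as.logical(tab$ambiguous)
  tab
}
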