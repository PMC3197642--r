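#' Declare an ordered set of area codes
#'
#' An area set is the fixed, ordered list of short codes (e.g. \code{"0"}--"9",
#' \code{"A"}--"W") naming the operational areas of an analysis.  The order is
#' fixed for the lifetime of the analysis: it defines the bit position of each
#' area in the internal bit-mask encoding of ranges, so every method in the
#' package refers ranges back to one \code{area_set}.
#'
#' Codes must be unique single tokens (no whitespace, no commas or dashes,
#' which are reserved as separators in input files).  At most 28 areas are
#' accepted (mask-width safety); above 14 a warning recalls that classical
#' DIVA software accepted no more than 15 area units.
#'
#' @param codes character vector of area codes.
#' @return an object of class \code{"area_set"} (a character vector).
#' @examples
#' area_set(c("a", "b", "c"))
#' @export
area_set <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) == 0L) stop("an area set needs at least one area code")
  if (anyNA(codes) || any(!nzchar(codes))) {
    stop("area codes must be non-empty strings")
  }
  if (any(grepl("[[:space:],-]", codes))) {
    stop("area codes must be single tokens without whitespace, ',' or '-'")
  }
  dup <- unique(codes[duplicated(codes)])
  if (length(dup)) {
    stop("duplicated area code(s): ", paste(dup, collapse = ", "))
  }
  if (length(codes) > 28L) {
    stop("at most 28 areas are supported (bit-mask width); got ",
         length(codes))
  }
  if (length(codes) > 14L) {
    warning("more than 14 areas declared; classical DIVA software supported ",
            "at most 15 area units, and exact DIVA optimisation grows ",
            "exponentially in the number of areas")
  }
  structure(codes, class = "area_set")
}

#' @export
print.area_set <- function(x, ...) {
  cat("Area set with", length(x), "areas:", paste(unclass(x), collapse = " "),
      "\n")
  invisible(x)
}

# encode a character vector of areas as a bit mask against `areas`
encode_areas <- function(x, areas) {
  if (length(x) == 0L) return(0L)
  idx <- match(x, areas)
  if (anyNA(idx)) {
    stop("unknown area code(s): ", paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  as.integer(sum(bitwShiftL(1L, unique(idx) - 1L)))
}

# decode a bit mask back to area codes (in area-set order)
decode_mask <- function(mask, areas) {
  idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(areas) - 1L)) != 0L)
  as.character(areas)[idx]
}

# split a range cell such as "49FKW" or "a,b,c" into individual codes
parse_range_string <- function(s, areas) {
  s <- trimws(s)
  if (!nzchar(s)) return(character(0))
  if (grepl("[,-]", s)) {
    parts <- trimws(strsplit(s, "[,-]")[[1L]])
    return(parts[nzchar(parts)])
  }
  if (s %in% areas) return(s)
  if (all(nchar(areas) == 1L)) {
    return(strsplit(s, "")[[1L]])
  }
  s
}

#' Construct a validated taxon-to-range assignment
#'
#' A range assignment maps every terminal of a tree to a non-empty subset of
#' a fixed \code{\link{area_set}}.  Validation enforces: no empty range, no
#' unknown area code, no duplicated taxon.
#'
#' @param x named list of character vectors (taxon -> area codes).
#' @param areas an \code{\link{area_set}}; if missing, built from the codes
#'   present in \code{x} (sorted).
#' @return an object of class \code{"range_assignment"}: a named list of
#'   character vectors with the \code{area_set} attached as attribute
#'   \code{"areas"}.
#' @examples
#' range_assignment(list(t1 = "a", t2 = c("a", "b")))
#' @export
range_assignment <- function(x, areas = NULL) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("ranges must be a named list (taxon -> area codes)")
  }
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup)) stop("duplicated taxon/taxa: ", paste(dup, collapse = ", "))
  if (is.null(areas)) {
    areas <- area_set(sort(unique(unlist(x, use.names = FALSE))))
  } else if (!inherits(areas, "area_set")) {
    areas <- area_set(areas)
  }
  x <- lapply(x, function(r) unique(as.character(r)))
  empty <- names(x)[vapply(x, length, 1L) == 0L]
  if (length(empty)) {
    stop("empty range for taxon/taxa: ", paste(empty, collapse = ", "))
  }
  bad <- setdiff(unique(unlist(x, use.names = FALSE)), areas)
  if (length(bad)) {
    stop("unknown area code(s): ", paste(bad, collapse = ", "))
  }
  structure(x, areas = areas, class = "range_assignment")
}

#' @export
print.range_assignment <- function(x, ...) {
  cat("Range assignment for", length(x), "terminals over",
      length(attr(x, "areas")), "areas\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = max(nchar(names(x)))), " ",
        paste(x[[nm]], collapse = ""), "\n", sep = "")
  }
  invisible(x)
}

#' Read a taxon-area table
#'
#' Reads a delimited text file (TSV or CSV, chosen by extension or sniffed
#' from the header line) with columns \code{taxon} and \code{areas}, where a
#' multi-area range is written either as concatenated single-letter codes
#' ("49FKW") or separated by commas/dashes ("4,9,F").
#'
#' @param file path to the table, or a data.frame with the two columns.
#' @param areas an \code{\link{area_set}} declaring the admissible codes.
#' @return a \code{\link{range_assignment}}.
#' @export
read_taxon_areas <- function(file, areas) {
  if (is.data.frame(file)) {
    tab <- file
  } else {
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             colClasses = "character", strip.white = TRUE,
                             comment.char = "")
  }
  if (ncol(tab) < 2L) stop("taxon-area table needs columns: taxon, areas")
  if (!inherits(areas, "area_set")) areas <- area_set(areas)
  taxa <- as.character(tab[[1L]])
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup)) stop("duplicated taxon/taxa: ", paste(dup, collapse = ", "))
  ranges <- lapply(as.character(tab[[2L]]), parse_range_string, areas = areas)
  names(ranges) <- taxa
  range_assignment(ranges, areas)
}

#' Read an area merge map
#'
#' Reads a two-column table (\code{original}, \code{merged}) giving, for each
#' original area code, the merged code it is pooled into (the coding step
#' classical DIVA analyses need to stay within their area-count limit).
#' Every original code must map to exactly one merged code.
#'
#' @param file path to a TSV/CSV file, or a data.frame.
#' @return a named character vector (names: original codes, values: merged).
#' @export
read_merge_map <- function(file) {
  if (is.data.frame(file)) {
    tab <- file
  } else {
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(file, header = TRUE, sep = sep,
                             colClasses = "character", strip.white = TRUE,
                             comment.char = "")
  }
  if (ncol(tab) < 2L) stop("merge map needs columns: original, merged")
  orig <- as.character(tab[[1L]])
  dup <- unique(orig[duplicated(orig)])
  if (length(dup)) {
    stop("original area(s) mapped more than once: ",
         paste(dup, collapse = ", "))
  }
  stats::setNames(as.character(tab[[2L]]), orig)
}

#' Apply a merge map to a range assignment
#'
#' Replaces every area of every range by its merged code.  The image of a
#' non-empty range is non-empty and never larger than the original range.
#'
#' @param ranges a \code{\link{range_assignment}}.
#' @param map named character vector (original code -> merged code), e.g.
#'   from \code{\link{read_merge_map}}.
#' @param max_merged optional cap on the number of distinct merged areas;
#'   exceeding it is an error.
#' @return a \code{\link{range_assignment}} over the merged area set (ordered
#'   by first appearance in \code{map}).
#' @export
apply_merge_map <- function(ranges, map, max_merged = NULL) {
  if (!inherits(ranges, "range_assignment")) ranges <- range_assignment(ranges)
  used <- unique(unlist(ranges, use.names = FALSE))
  unmapped <- setdiff(used, names(map))
  if (length(unmapped)) {
    stop("area code(s) without a merge-map entry: ",
         paste(unmapped, collapse = ", "))
  }
  merged_codes <- unique(unname(map))
  if (!is.null(max_merged) && length(merged_codes) > max_merged) {
    stop("merge map produces ", length(merged_codes),
         " areas, above the configured cap of ", max_merged)
  }
  out <- lapply(ranges, function(r) unique(unname(map[r])))
  range_assignment(out, area_set(merged_codes))
}

# masks for every terminal, in tip order of `tree` when given
encode_ranges <- function(ranges, areas = attr(ranges, "areas")) {
  vapply(ranges, encode_areas, integer(1L), areas = areas)
}
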