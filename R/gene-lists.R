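#' Read a gene list from a plain-text file
#'
#' One gene identifier per line; lines beginning `#` and blank lines are
#' ignored. Duplicates are collapsed with a warning. Typical lists are the
#' curated limb patterning genes and the transcription-factor atlas the
#' digit analyses are restricted to.
#'
#' @param path file path.
#' @param name label for the list (default: file base name without extension).
#' @return A `GeneList`: list with `name` and unique `members`.
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("gene list file is empty: ", path)
  if (anyDuplicated(lines)) {
    dups <- unique(lines[duplicated(lines)])
    warning("collapsing duplicated gene identifier(s): ",
            paste(utils::head(dups, 5), collapse = ", "))
  }
  gene_list(unique(lines),
            name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a GeneList
#' @param members character vector of gene identifiers (deduplicated).
#' @param name label.
#' @export
gene_list <- function(members, name = "genes") {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene list must be non-empty")
  structure(list(name = name, members = members), class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
  cat(sprintf("GeneList '%s': %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Write a GeneList to a plain-text file
#' @param x GeneList. @param path output path.
#' @export
write_gene_list <- function(x, path) {
  writeLines(c(paste0("# ", x$name), x$members), path)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cross-species ortholog map
#'
#' TSV with a `group_id` column plus one column per species holding that
#' species' gene identifier for the ortholog group (blank = no ortholog).
#' A row is flagged one-to-one for the requested `species_set` when every
#' one of those species has exactly one (non-blank) gene in the row, and no
#' gene of a species recurs across flagged rows. Cross-species gene
#' comparison throughout the pipeline goes only through this map.
#'
#' @param path TSV path.
#' @param species_set character vector of species column names to evaluate
#'   the one-to-one flag over (default: all species columns).
#' @return An `OrthologMap`: data frame of the map with attribute columns
#'   `group_id`, species columns, and logical `one_to_one`.
#' @export
read_ortholog_map <- function(path, species_set = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"group_id" %in% names(tab)) stop("ortholog map needs a group_id column")
  ortholog_map(tab, species_set)
}

#' Construct an OrthologMap from a data frame
#' @param tab data frame with `group_id` plus one column per species.
#' @param species_set species over which the one-to-one flag is computed.
#' @export
ortholog_map <- function(tab, species_set = NULL) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  species <- setdiff(names(tab), c("group_id", "one_to_one"))
  if (length(species) < 2) stop("ortholog map needs >= 2 species columns")
  if (is.null(species_set)) species_set <- species
  unknown <- setdiff(species_set, species)
  if (length(unknown) > 0)
    stop("species absent from map: ", paste(unknown, collapse = ", "))
  for (s in species) {
    tab[[s]] <- as.character(tab[[s]])
    tab[[s]][is.na(tab[[s]]) | !nzchar(trimws(tab[[s]]))] <- NA_character_
  }
  present <- !is.na(as.matrix(tab[species_set]))
  tab$one_to_one <- rowSums(present) == length(species_set)
  for (s in species_set) {
    g <- tab[[s]][tab$one_to_one]
    if (anyDuplicated(g))
      stop("gene(s) of species '", s, "' appear in multiple one-to-one rows: ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  attr(tab, "species_set") <- species_set
  class(tab) <- c("OrthologMap", "data.frame")
  tab
}

#' One-to-one ortholog universe over a species set
#'
#' @param map OrthologMap.
#' @return data frame of the one-to-one rows only (the "N" universe of the
#'   conservation statistics), keyed by `group_id`.
#' @export
one_to_one_universe <- function(map) {
  stopifnot(inherits(map, "OrthologMap"))
  out <- map[map$one_to_one, , drop = FALSE]
  rownames(out) <- out$group_id
  out
}

#' Re-express an ExpressionMatrix in another species' gene identifiers
#'
#' Restricts `x` to genes with a one-to-one ortholog in both species and
#' renames its rows from `from`-species to `to`-species identifiers, so
#' held-out samples can be projected into another species' PCA model.
#'
#' @param x ExpressionMatrix whose rows are `from`-species genes.
#' @param map OrthologMap covering both species.
#' @param from,to species column names in the map.
#' @param groups optional ortholog-group ids restricting the mapping.
#' @return ExpressionMatrix with `to`-species row names.
#' @export
map_expression_to_species <- function(x, map, from, to, groups = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(map, "OrthologMap"))
  uni <- one_to_one_universe(map)
  if (!is.null(groups)) uni <- uni[uni$group_id %in% groups, , drop = FALSE]
  keep <- uni[[from]] %in% rownames(x$values)
  uni <- uni[keep, , drop = FALSE]
  if (nrow(uni) == 0) stop("no mappable one-to-one genes")
  out <- subset_expression(x, genes = uni[[from]])
  rownames(out$values) <- uni[[to]]
  out$universe <- uni[[to]]
  out
}

#' Write an OrthologMap to TSV
#' @param map OrthologMap. @param path output path.
#' @export
write_ortholog_map <- function(map, path) {
  tab <- as.data.frame(map)
  tab$one_to_one <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(map)
}
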