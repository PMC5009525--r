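#' @title Pathway membership collections and per-sample expressed sets
#' @description Core containers for the pathway side of the analysis: a
#'   pathway collection (family of ortholog-group sets, with a reverse index
#'   from group to pathways) and a per-sample binary expressed-group set.
#' @name pathway_data
NULL

# Normalize an ortholog-group identifier: KO ids to uppercase "K" form,
# EC ids kept in dotted form. Comparison downstream is exact string equality;
# KO and EC namespaces are never translated into one another.
normalize_group_id <- function(ids) {
  ids <- trimws(ids)
  if (any(!nzchar(ids))) {
    stop("ortholog-group identifiers must be non-empty strings", call. = FALSE)
  }
  ko <- grepl("^[Kk]\\d+$", ids)
  ids[ko] <- toupper(ids[ko])
  ids
}

#' Construct a pathway collection
#'
#' A pathway collection is a family of pathways, each a set of ortholog-group
#' identifiers (KEGG KO numbers such as `"K00001"`, or EC numbers such as
#' `"1.1.1.1"`). The constructor deduplicates members, drops pathways with no
#' members, and builds the reverse `group_index` mapping each group to the
#' pathways that contain it.
#'
#' @param pathways named list; names are pathway ids (e.g. `"ko00062"`),
#'   elements are character vectors of ortholog-group ids.
#' @param names optional named character vector of human-readable pathway
#'   names, keyed by pathway id.
#' @return an object of class `pathway_collection` with elements `pathways`
#'   (named list of sorted member vectors), `group_index` (named list mapping
#'   group id to the sorted pathway ids containing it) and `pathway_names`.
#' @export
#' @examples
#' pc <- pathway_collection(list(ko00010 = c("K00001", "K00002"),
#'                               ko00020 = c("K00002", "K00003")))
#' pc$group_index[["K00002"]]
pathway_collection <- function(pathways, names = character()) {
  if (length(pathways) == 0L) {
    out <- structure(
      list(pathways = stats::setNames(list(), character()),
           group_index = stats::setNames(list(), character()),
           pathway_names = names),
      class = "pathway_collection")
    return(out)
  }
  ids <- base::names(pathways)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("pathways must be a uniquely named list of member vectors",
         call. = FALSE)
  }
  members <- lapply(pathways, function(m) sort(unique(normalize_group_id(as.character(m)))))
  keep <- vapply(members, length, integer(1)) > 0L
  members <- members[keep]
  gi <- build_group_index(members)
  structure(list(pathways = members, group_index = gi, pathway_names = names),
            class = "pathway_collection")
}

build_group_index <- function(members) {
  if (length(members) == 0L) {
    return(stats::setNames(list(), character()))
  }
  pw <- rep(base::names(members), lengths(members))
  grp <- unlist(members, use.names = FALSE)
  idx <- split(pw, grp)
  lapply(idx, function(x) sort(unique(x)))
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d distinct ortholog groups\n",
              length(x$pathways), length(x$group_index)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' Construct a per-sample expressed ortholog-group set
#'
#' The binary expression model records, for one RNA-Seq sample, the set of
#' ortholog groups with any expression evidence. The set may be empty
#' (a degenerate sample).
#'
#' @param expressed character vector of ortholog-group ids (deduplicated).
#' @param sample_id sample label.
#' @return an object of class `sample_expression` with elements `sample_id`
#'   and `expressed` (sorted character vector).
#' @export
sample_expression <- function(expressed, sample_id = "sample") {
  expressed <- as.character(expressed)
  expressed <- expressed[nzchar(trimws(expressed))]
  if (length(expressed)) expressed <- sort(unique(normalize_group_id(expressed)))
  structure(list(sample_id = sample_id, expressed = expressed),
            class = "sample_expression")
}

#' @export
print.sample_expression <- function(x, ...) {
  cat(sprintf("sample_expression '%s': %d expressed ortholog groups\n",
              x$sample_id, length(x$expressed)))
  invisible(x)
}

#' Read a pathway membership table
#'
#' Reads a two-column TSV (`pathway_id <TAB> ortholog_group_id`, one pair per
#' line, `#` comment lines and blank lines skipped) into a
#' [pathway_collection()]. Duplicate pairs are collapsed.
#'
#' @param path path to the TSV file.
#' @return a `pathway_collection`.
#' @export
read_pathway_membership <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty membership file: ", path, call. = FALSE)
    return(pathway_collection(list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 2L || !nzchar(trimws(p[1])) ||
                  !nzchar(trimws(p[2])), logical(1))
  if (any(bad)) {
    stop(sprintf("malformed membership line %d in %s: expected 'pathway<TAB>group'",
                 lineno[which(bad)[1]], path), call. = FALSE)
  }
  pw <- trimws(vapply(parts, `[`, character(1), 1L))
  grp <- trimws(vapply(parts, `[`, character(1), 2L))
  pathway_collection(split(grp, factor(pw, levels = unique(pw))))
}

#' Write a pathway membership table
#'
#' Inverse of [read_pathway_membership()]: one `pathway_id <TAB> group_id`
#' line per membership pair.
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_membership <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  pw <- rep(base::names(collection$pathways), lengths(collection$pathways))
  grp <- unlist(collection$pathways, use.names = FALSE)
  writeLines(if (length(pw)) paste(pw, grp, sep = "\t") else character(), path)
  invisible(path)
}

#' Read a per-sample expressed ortholog-group set
#'
#' Accepts either one group id per line, or a two-column TSV
#' (`contig_id <TAB> group_id`) from an upstream annotation step, in which
#' case the second column is collected. `#` comments and blank lines are
#' skipped; the result is deduplicated.
#'
#' @param path input file.
#' @param sample_id sample label; defaults to the file basename without
#'   extension.
#' @return a `sample_expression`.
#' @export
read_expressed_set <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(lines) == 0L) return(sample_expression(character(), sample_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) trimws(p[min(length(p), 2L)]), character(1))
  sample_expression(ids, sample_id)
}

#' Restrict a collection to a sample's expressed groups
#'
#' Intersects every pathway's member set with the sample's expressed set and
#' drops pathways left with no expressed member. This produces the working
#' family for the activity model: only pathways with at least one expressed
#' ortholog group enter the iteration.
#'
#' @param collection a `pathway_collection`.
#' @param sample a `sample_expression`.
#' @return a restricted `pathway_collection` (group index rebuilt).
#' @export
restrict_to_sample <- function(collection, sample) {
  stopifnot(inherits(collection, "pathway_collection"),
            inherits(sample, "sample_expression"))
  members <- lapply(collection$pathways, intersect, sample$expressed)
  pathway_collection(members[lengths(members) > 0L],
                     names = collection$pathway_names)
}

#' Drop pathways with too few mapped ortholog groups
#'
#' Pathways whose (restricted) member set is smaller than `min_groups` carry
#' too little mapping to support a meaningful topology statistic; the
#' graph-based significance branch excludes pathways with fewer than 3 mapped
#' ortholog groups by default.
#'
#' @param collection a `pathway_collection`.
#' @param min_groups minimum member count to retain (default 3).
#' @return the filtered `pathway_collection`.
#' @export
filter_min_mapped <- function(collection, min_groups = 3L) {
  stopifnot(inherits(collection, "pathway_collection"), min_groups >= 0)
  keep <- lengths(collection$pathways) >= min_groups
  pathway_collection(collection$pathways[keep], names = collection$pathway_names)
}
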