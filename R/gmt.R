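#' Read a GMT pathway-annotation file
#'
#' GMT: one pathway per line, tab-separated fields `pathway_id`,
#' `description`, then one or more member feature ids.
#'
#' @param path GMT file path.
#' @return An object of class `pathway_annotation`: a named list of character
#'   member vectors, with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate pathway_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("validation error: pathway with no members: ", paste(ids[bad], collapse = ", "))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(members) <- ids
  names(desc) <- ids
  structure(members, descriptions = desc, class = "pathway_annotation")
}

#' Write a pathway annotation to a GMT file
#'
#' @param annotation A `pathway_annotation` (or plain named list of member id
#'   vectors).
#' @param path Output file path.
#' @param descriptions Optional named character vector of descriptions;
#'   defaults to the annotation's own, or `"na"`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(annotation, "descriptions") %||%
    stats::setNames(rep("na", length(annotation)), names(annotation))
  lines <- vapply(names(annotation), function(id) {
    paste(c(id, descriptions[[id]] %||% "na", annotation[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_annotation <- function(x, ...) {
  cat(sprintf("pathway_annotation: %d pathways, member counts %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}
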