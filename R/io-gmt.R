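#' Read a GMT gene-set collection
#'
#' Standard MSigDB carrier format: one set per line,
#' `term<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a line are deduplicated with a warning giving the total duplicate count.
#'
#' @param path file path or connection.
#' @return A named list of character vectors (members per term), with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop_cd8(sprintf("GMT line %d has fewer than 3 fields", which(short)[1L]),
             "bad_format")
  }
  terms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(terms)) {
    stop_cd8(paste0("duplicate term ids: ",
                    paste(unique(terms[duplicated(terms)]), collapse = ", ")),
             "bad_format")
  }
  descriptions <- stats::setNames(vapply(fields, `[[`, "", 2L), terms)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, function(m) length(m) - length(unique(m)), 0L))
  if (n_dup > 0L) {
    rlang::warn(sprintf("%d duplicate member(s) within gene sets were dropped", n_dup))
  }
  sets <- lapply(members, unique)
  names(sets) <- terms
  attr(sets, "descriptions") <- descriptions
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of term descriptions;
#'   defaults to the term id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(t) {
    paste(c(t, descriptions[[t]], sets[[t]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
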