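#' Read a lineage table
#'
#' Format: one candidate tip per line, \code{tip_id<TAB>Name1|Name2|...},
#' root-most name first, pipe-separated; \code{#} starts a comment; UTF-8.
#'
#' @param path file path
#' @return a named list of character vectors suitable for
#'   \code{\link{pinTips}}.
#' @export
readLineages <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) .stopf("malformed lineage line: '%s'", ln)
    out[[parts[[1L]]]] <- strsplit(parts[[2L]], "|", fixed = TRUE)[[1L]]
  }
  out
}

#' Read a community table
#'
#' Format: one community per line, \code{community_id<TAB>tip1,tip2,...};
#' \code{#} starts a comment; UTF-8. Communities may not share members.
#'
#' @param path file path
#' @return a named list of character vectors of tip ids.
#' @export
readCommunities <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) .stopf("malformed community line: '%s'", ln)
    out[[parts[[1L]]]] <- strsplit(parts[[2L]], ",", fixed = TRUE)[[1L]]
  }
  all <- unlist(out)
  if (anyDuplicated(all)) {
    .stopf("communities share member '%s'", all[duplicated(all)][[1L]])
  }
  out
}

#' Write a distance matrix as TSV
#'
#' Ids as header row and first column, tab-separated, values at 9 decimal
#' places.
#'
#' @param mtrx a matrix as returned by \code{\link{calcDstMtrx}}
#' @param path output file path (\code{NULL} for stdout)
#' @export
writeDistMatrix <- function(mtrx, path = NULL) {
  ids <- rownames(mtrx)
  header <- paste(c("id", ids), collapse = "\t")
  rows <- vapply(seq_along(ids), function(i) {
    paste(c(ids[[i]], sprintf("%.9f", mtrx[i, ])), collapse = "\t")
  }, character(1))
  if (is.null(path)) writeLines(c(header, rows)) else
    writeLines(c(header, rows), path)
}
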