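#' Pathway coverage percentage
#'
#' `100 * assigned / total`, rounded half-up to two decimals — the
#' fraction of a pathway's member formulas matched by detected features.
#'
#' @param assigned Count of pathway members hit, `0 <= assigned <= total`.
#' @param total Total pathway members, `>= 1`.
#' @return Numeric percentage in `[0, 100]` with two decimals.
#' @examples
#' coveragePercent(4, 7)   # 57.14
#' coveragePercent(7, 21)  # 33.33
#' @export
coveragePercent <- function(assigned, total) {
  if (any(total < 1))
    stop("coveragePercent: total must be >= 1")
  if (any(assigned < 0) || any(assigned > total))
    stop("coveragePercent: assigned must lie in [0, total]")
  roundHalfUp(100 * assigned / total, 2)
}

#' Pathway coverage table
#'
#' Intersects a set of detected feature identifiers with externally
#' supplied pathway membership lists and reports per-pathway coverage,
#' sorted by coverage descending (name ascending on ties). Membership
#' lists are plain inputs — nothing is fetched — so the computation is
#' deterministic and offline.
#'
#' @param hits Character vector of detected feature/formula identifiers.
#' @param memberships Named list of non-empty character vectors (pathway
#'   name -> member identifiers), e.g. from [readGMT()].
#' @param pathwayIds Optional character vector of pathway ids aligned with
#'   `memberships` (defaults to the names).
#' @return A `data.frame` with columns `pathway_name`, `pathway_id`,
#'   `assigned`, `total`, `coverage_percent`.
#' @export
coverageTable <- function(hits, memberships, pathwayIds = NULL) {
  if (is.null(names(memberships)) || any(names(memberships) == ""))
    stop("coverageTable: memberships must be a named list")
  if (any(lengths(memberships) == 0L))
    stop("coverageTable: membership sets must be non-empty")
  if (is.null(pathwayIds))
    pathwayIds <- attr(memberships, "ids") %||% names(memberships)
  hits <- unique(as.character(hits))
  assigned <- vapply(memberships,
                     function(m) length(intersect(hits, m)), integer(1))
  total <- lengths(memberships)
  out <- data.frame(pathway_name = names(memberships),
                    pathway_id = as.character(pathwayIds),
                    assigned = unname(assigned), total = unname(total),
                    coverage_percent = coveragePercent(unname(assigned),
                                                       unname(total)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$coverage_percent, out$pathway_name), ]
  rownames(out) <- NULL
  out
}

#' Read / write pathway membership and coverage files
#'
#' `readGMT()` parses a GMT-style tab-separated file (pathway name,
#' pathway id, then member identifiers) into the named list expected by
#' [coverageTable()]; `writeCoverageTable()` writes the coverage result as
#' TSV with the columns pathway name, id, assigned, total and coverage
#' percent.
#'
#' @param path File path.
#' @return `readGMT()`: named list of member-id vectors, with pathway ids
#'   in the `"ids"` attribute.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop("readGMT: each line needs a name, an id and at least one member")
  memberships <- lapply(parts, function(p) p[-(1:2)])
  names(memberships) <- vapply(parts, `[[`, character(1), 1L)
  attr(memberships, "ids") <- vapply(parts, `[[`, character(1), 2L)
  memberships
}

#' @param coverage Result of [coverageTable()].
#' @rdname readGMT
#' @export
writeCoverageTable <- function(coverage, path) {
  writeTSV(coverage, path)
  invisible(path)
}
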