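#' Genomic intervals (0-based, half-open)
#'
#' All coordinates inside the package use a single convention: 0-based,
#' half-open `[start, end)` on a named contig. VCF input/output converts
#' to/from 1-based at the file boundary; BED is consumed natively.
#'
#' @param contig Character vector of contig names (non-empty).
#' @param start Integer vector, 0-based inclusive.
#' @param end Integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @return A `data.frame` with class `genomic_interval` and columns
#'   `contig`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 0L, 100L)
#' @export
genomic_interval <- function(contig, start, end, strand = ".") {
  n <- max(length(contig), length(start), length(end))
  gi <- data.frame(
    contig = rep_len(as.character(contig), n),
    start  = rep_len(as.integer(start), n),
    end    = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_genomic_interval(gi)
  class(gi) <- c("genomic_interval", class(gi))
  gi
}

validate_genomic_interval <- function(gi) {
  stopifnot(is.data.frame(gi), all(c("contig", "start", "end") %in% names(gi)))
  if (any(is.na(gi$contig)) || any(!nzchar(gi$contig)))
    stop("genomic_interval: contig must be non-empty")
  if (any(gi$start < 0L)) stop("genomic_interval: start must be >= 0")
  if (any(gi$start >= gi$end)) stop("genomic_interval: require start < end")
  if ("strand" %in% names(gi) && !all(gi$strand %in% c("+", "-", ".")))
    stop("genomic_interval: strand must be one of +, -, .")
  invisible(gi)
}

#' Build an overlap index over (possibly unsorted, overlapping) features
#'
#' The index answers half-open interval overlap queries. Backed by
#' [IRanges::IRanges] per contig; the contract is purely "return exactly the
#' payloads whose `[start, end)` intersects the query", verified elsewhere
#' against a brute-force all-pairs scan.
#'
#' @param features A `data.frame` with columns `contig`, `start`, `end`
#'   (0-based half-open) plus arbitrary payload columns. A `label` column is
#'   used as the final ordering tie-break if present.
#' @return An object of class `feature_index`.
#' @seealso [query_overlaps()]
#' @export
build_interval_index <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("contig", "start", "end") %in% names(features)))
  if (nrow(features) > 0) validate_genomic_interval(features)
  by_contig <- split(seq_len(nrow(features)), features$contig)
  trees <- lapply(by_contig, function(idx) {
    # IRanges is 1-based closed: [start+1, end]
    list(idx = idx,
         ir = IRanges::IRanges(start = features$start[idx] + 1L,
                               end = features$end[idx]))
  })
  structure(list(features = features, trees = trees), class = "feature_index")
}

#' Query a feature index for overlaps with a half-open interval
#'
#' @param index A `feature_index` from [build_interval_index()].
#' @param contig Contig name; an absent contig yields an empty result.
#' @param start,end Query interval, 0-based half-open.
#' @return The overlapping payload rows of the original feature table,
#'   deterministically ordered by `start`, then `end`, then `label`
#'   (if present).
#' @export
query_overlaps <- function(index, contig, start, end) {
  stopifnot(inherits(index, "feature_index"), start < end)
  tree <- index$trees[[as.character(contig)]]
  empty <- index$features[0, , drop = FALSE]
  if (is.null(tree)) return(empty)
  q <- IRanges::IRanges(start = start + 1L, end = as.integer(end))
  hit <- IRanges::overlapsAny(tree$ir, q)
  rows <- index$features[tree$idx[hit], , drop = FALSE]
  if (nrow(rows) == 0) return(rows)
  ord <- if ("label" %in% names(rows)) {
    order(rows$start, rows$end, rows$label)
  } else {
    order(rows$start, rows$end)
  }
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Brute-force overlap scan (reference oracle)
#'
#' Literal all-pairs definition of half-open overlap, kept deliberately
#' independent of [build_interval_index()] so the two can check each other.
#'
#' @inheritParams query_overlaps
#' @param features Feature table as in [build_interval_index()].
#' @return Same row subset and ordering as [query_overlaps()].
#' @export
overlap_scan <- function(features, contig, start, end) {
  keep <- features$contig == contig & features$start < end & start < features$end
  rows <- features[keep, , drop = FALSE]
  ord <- if ("label" %in% names(rows)) {
    order(rows$start, rows$end, rows$label)
  } else {
    order(rows$start, rows$end)
  }
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
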