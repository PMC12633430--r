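#' Summarize a read group
#'
#' Aggregate evidence used by the confidence score: group size, mean MAPQ,
#' mean soft-clip fraction, and the fraction of primary alignments.
#'
#' @param reads A read table (see [read_alignments()]); may have zero rows.
#' @return A list of class `read_group_metrics` (`n_reads = 0` groups carry
#'   `NA` metrics).
#' @export
read_group_metrics <- function(reads) {
  n <- nrow(reads)
  structure(list(
    n_reads = n,
    mean_mapq = if (n > 0) mean(reads$mapq) else NA_real_,
    softclip_fraction_mean = if (n > 0) mean(reads$softclip_fraction) else NA_real_,
    primary_fraction = if (n > 0) mean(reads$category == "primary") else NA_real_
  ), class = "read_group_metrics")
}

#' Partition reads at a call site into supporting and non-supporting groups
#'
#' Every read overlapping the locus is assigned to exactly one group by
#' membership of its name in the call's support set; metrics are computed
#' per group. A candidate whose support names are absent from the fetched
#' reads is flagged `NO_SUPPORT_AT_LOCUS`.
#'
#' @param reads Read table of alignments overlapping the locus (pre-fetch
#'   with [read_alignments()] and subset, or pass all reads plus `contig`
#'   and `pos` to fetch here).
#' @param support_names Character vector of supporting read names.
#' @param contig,pos Optional locus; when given, `reads` is first subset to
#'   alignments whose reference span contains `pos`.
#' @return A list: `supporting`, `nonsupporting` (both
#'   [read_group_metrics()]), `supporting_reads` (the rows),
#'   `flag` (`NA` or `"NO_SUPPORT_AT_LOCUS"`).
#' @export
partition_reads <- function(reads, support_names, contig = NULL, pos = NULL) {
  if (!is.null(contig)) {
    reads <- reads[reads$contig == contig & reads$start <= pos & reads$end > pos, ,
                   drop = FALSE]
  }
  if (nrow(reads) == 0) stop("no reads at locus")
  is_sup <- reads$name %in% support_names
  sup <- reads[is_sup, , drop = FALSE]
  non <- reads[!is_sup, , drop = FALSE]
  list(supporting = read_group_metrics(sup),
       nonsupporting = read_group_metrics(non),
       supporting_reads = sup,
       flag = if (nrow(sup) == 0) "NO_SUPPORT_AT_LOCUS" else NA_character_)
}

#' Read-evidence confidence score
#'
#' A base score of 1 is adjusted multiplicatively by quality factors
#' comparing the supporting group against the non-supporting baseline:
#' `f_mapq = min(1, mapq_sup / max(mapq_nonsup, 1))` and
#' `f_clip = max(0, 1 - max(0, clip_sup - clip_nonsup - c))` with clip
#' tolerance `c` (default 0.05). The score is forced to 0 when no
#' supporting alignment is primary. With an empty baseline group the
#' factors default to 1 (no evidence against). The score is monotonically
#' non-decreasing in supporting MAPQ and non-increasing in supporting
#' soft-clip excess, and always lies in `[0, 1]`.
#'
#' @param supporting,nonsupporting [read_group_metrics()] for the two
#'   groups; `supporting$n_reads` must be >= 1.
#' @param clip_tolerance Soft-clip excess tolerated before penalty.
#' @return A list of class `confidence_score`: `value` in `[0, 1]` and
#'   `components` (named numeric vector of the factors).
#' @export
confidence_score <- function(supporting, nonsupporting, clip_tolerance = 0.05) {
  if (supporting$n_reads < 1) stop("supporting group is empty")
  if (supporting$primary_fraction == 0) {
    return(structure(list(value = 0,
                          components = c(f_mapq = NA_real_, f_clip = NA_real_,
                                         primary = 0)),
                     class = "confidence_score"))
  }
  base_mapq <- if (nonsupporting$n_reads > 0) nonsupporting$mean_mapq else
    supporting$mean_mapq
  base_clip <- if (nonsupporting$n_reads > 0)
    nonsupporting$softclip_fraction_mean else supporting$softclip_fraction_mean
  f_mapq <- min(1, supporting$mean_mapq / max(base_mapq, 1))
  f_clip <- max(0, 1 - max(0, supporting$softclip_fraction_mean - base_clip -
                                clip_tolerance))
  structure(list(value = f_mapq * f_clip,
                 components = c(f_mapq = f_mapq, f_clip = f_clip, primary = 1)),
            class = "confidence_score")
}

#' Normalize a contig name to its chromosome label
#'
#' Accepts `"chr1"`, `"1"` and haplotype-suffixed assembly names
#' (`"chr1_hap1"` maps to `"1"`). Returns `NA` for anything that does not
#' normalize to 1-22, X or Y.
#'
#' @param contig Character vector of contig names.
#' @return Character vector of normalized labels (or `NA`).
#' @export
normalize_chrom <- function(contig) {
  x <- sub("^chr", "", contig)
  x <- sub("_.*$", "", x)
  ok <- x %in% c(as.character(1:22), "X", "Y")
  ifelse(ok, x, NA_character_)
}

#' Score candidates against read evidence
#'
#' For each candidate, fetches the reads overlapping its position from the
#' alignment table, partitions them by support-name membership, and writes
#' `VESPER_CONF` (the confidence score) and `PRIMARY_SUPPORT` tags.
#' Candidates without read names or without support at the locus get score
#' 0 and a flag tag.
#'
#' @param candidates List of [insertion_candidate()] objects.
#' @param alignments Read table from [read_alignments()].
#' @param clip_tolerance Passed to [confidence_score()].
#' @return Candidates with confidence tags added.
#' @export
refine_candidates <- function(candidates, alignments, clip_tolerance = 0.05) {
  lapply(candidates, function(cd) {
    if (length(cd$support_read_names) == 0) {
      cd$info_tags["VESPER_CONF"] <- "0"
      cd$info_tags["REFINE_FLAG"] <- "NO_RNAMES"
      return(cd)
    }
    part <- tryCatch(
      partition_reads(alignments, cd$support_read_names, cd$contig, cd$pos),
      error = function(e) NULL)
    if (is.null(part) || !is.na(part$flag)) {
      cd$info_tags["VESPER_CONF"] <- "0"
      cd$info_tags["REFINE_FLAG"] <- "NO_SUPPORT_AT_LOCUS"
      return(cd)
    }
    sc <- confidence_score(part$supporting, part$nonsupporting, clip_tolerance)
    cd$info_tags["VESPER_CONF"] <- sprintf("%.4f", sc$value)
    cd$info_tags["PRIMARY_SUPPORT"] <-
      if (part$supporting$primary_fraction > 0) "1" else "0"
    cd
  })
}

#' Ordered filter cascade for de novo Alu candidates
#'
#' Applies the detection filters in a fixed order, labeling each failing
#' candidate with the *first* violated rule: (1) `SVLEN` <= `max_svlen`;
#' (2) contig normalizes to chromosome 1-22, X or Y (`CONTIG`); (3) call
#' site depth within `[min_cov, max_cov]` (`COVERAGE`); (4) Alu-class
#' annotation with length >= `min_len` (`NOT_ALU`; candidates missing
#' repeat annotation fail here as `UNANNOTATED`); (5) consensus divergence
#' <= `max_div` percent (`DIVERGENCE`); (6) confidence > `min_conf` with
#' primary read support (`NO_PRIMARY`); (7) outside centromere intervals
#' (`CENTROMERE`). The cascade is order-stable: permuting the input
#' permutes the outputs identically.
#'
#' @param candidates Annotated and scored candidates (tags `RM_FAMILY`,
#'   `RM_CLASS`, `RM_DIV`, `VESPER_CONF`, `PRIMARY_SUPPORT`).
#' @param site_coverage Named numeric vector of depths keyed
#'   `"contig:pos"`, or a single number applied to all sites, or a
#'   `function(contig, pos)`.
#' @param centromeres Feature table of centromeric intervals (or `NULL`).
#' @param params List of thresholds; defaults
#'   `list(max_svlen = 10000, min_cov = 40, max_cov = 80, min_len = 300,
#'   max_div = 3.0, min_conf = 0)`.
#' @return A list with `pass` (candidates, `filter_status` set to `PASS`)
#'   and `fail` (candidates with `filter_status` set to the reason) plus
#'   `reasons`, a character vector aligned with the input.
#' @export
apply_filters <- function(candidates, site_coverage, centromeres = NULL,
                          params = list()) {
  p <- utils::modifyList(list(max_svlen = 10000, min_cov = 40, max_cov = 80,
                              min_len = 300, max_div = 3.0, min_conf = 0),
                         params)
  cen_index <- if (!is.null(centromeres) && nrow(centromeres) > 0)
    build_interval_index(centromeres) else NULL
  depth_at <- function(cd) {
    if (is.function(site_coverage)) return(site_coverage(cd$contig, cd$pos))
    if (length(site_coverage) == 1 && is.null(names(site_coverage)))
      return(as.numeric(site_coverage))
    key <- sprintf("%s:%d", cd$contig, cd$pos)
    unname(site_coverage[key])
  }
  reason_for <- function(cd) {
    if (cd$sv_len > p$max_svlen) return("SVLEN")
    if (is.na(normalize_chrom(cd$contig))) return("CONTIG")
    depth <- depth_at(cd)
    if (is.na(depth) || depth < p$min_cov || depth > p$max_cov)
      return("COVERAGE")
    fam <- unname(cd$info_tags["RM_FAMILY"])
    div <- suppressWarnings(as.numeric(cd$info_tags["RM_DIV"]))
    if (is.na(fam) || is.na(div)) return("UNANNOTATED")
    is_alu <- startsWith(fam, "Alu") &&
      identical(unname(cd$info_tags["RM_CLASS"]), "SINE")
    if (!is_alu || cd$sv_len < p$min_len) return("NOT_ALU")
    if (div > p$max_div) return("DIVERGENCE")
    conf <- suppressWarnings(as.numeric(cd$info_tags["VESPER_CONF"]))
    primary <- identical(unname(cd$info_tags["PRIMARY_SUPPORT"]), "1")
    if (is.na(conf) || conf <= p$min_conf || !primary) return("NO_PRIMARY")
    if (!is.null(cen_index) &&
        nrow(query_overlaps(cen_index, cd$contig, cd$pos, cd$pos + 1L)) > 0)
      return("CENTROMERE")
    NA_character_
  }
  reasons <- vapply(candidates, reason_for, "")
  pass <- fail <- list()
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    if (is.na(reasons[i])) {
      cd$filter_status <- "PASS"
      pass[[length(pass) + 1L]] <- cd
    } else {
      cd$filter_status <- reasons[i]
      fail[[length(fail) + 1L]] <- cd
    }
  }
  list(pass = pass, fail = fail, reasons = reasons)
}
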