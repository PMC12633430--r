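#' Turn a truth table into a truth-preserving callset (aligner stub)
#'
#' Builds one single-read insertion call per truth row, placed exactly
#' where the origin read maps (junction = `read_start + insert_offset`).
#' This stands in for the align-then-call step when benchmarking the
#' classifier itself: with error rate 0 and truth-preserving placement,
#' downstream precision and recall are 1 by construction.
#'
#' @param truth Truth `data.frame` (see [read_truth_table()]).
#' @param spike_aux Optional `spike_aux` list from [simulate_dataset()]; if
#'   supplied, calls carry the full inserted block (TSD copy + element) as
#'   their sequence, else an `N` placeholder of the right length.
#' @return List of [insertion_candidate()] objects.
#' @export
truth_to_calls <- function(truth, spike_aux = NULL) {
  lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    blk <- tr$tsd_len + tr$insert_len
    seq <- if (!is.null(spike_aux) && !is.null(spike_aux[[tr$read_name]])) {
      aux <- spike_aux[[tr$read_name]]
      paste0(aux$tsd_seq, aux$element_seq)
    } else {
      strrep("N", blk)
    }
    insertion_candidate(
      contig = tr$contig, pos = tr$read_start + tr$insert_offset,
      inserted_seq = seq, sv_len = blk, allele_fraction = 0.02,
      support_read_names = tr$read_name, filter_status = "PASS")
  })
}

#' Classify a callset against a spike-in truth table
#'
#' Implements the single-read benchmark definitions: a call is a true
#' positive when its support set is exactly one spiked (truth) read *and*
#' the call position agrees with that read's origin placement; a call
#' containing at least one spiked read that violates either condition is a
#' false positive (a single mismapped spiked read, more than one spiked
#' read, or spiked reads mixed with non-spiked reads). Calls containing no
#' spiked reads belong to the baseline callset and are ignored. FILTER
#' status plays no role. False negatives are truth reads not credited as
#' the single support of a TP call, so `tp + fn` always equals the number
#' of truth records.
#'
#' @param calls List of [insertion_candidate()] objects (must carry read
#'   names).
#' @param truth Truth `data.frame`; read names must be unique.
#' @param tolerance Position tolerance mode: the default `"span"` accepts a
#'   call whose position falls within the origin read's aligned span; a
#'   number gives a fixed +/- bp window around the origin junction.
#' @return A list of class `bench_result`: counts `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fp_categories` (named integer vector over
#'   `mapping_error`, `multiread_nova_majority`, `multiread_nova_minority`),
#'   and `labels`, a per-call `data.frame` (`call_idx`, `label`,
#'   `fp_category`).
#' @export
classify_calls <- function(calls, truth, tolerance = "span") {
  if (anyDuplicated(truth$read_name))
    stop("duplicate truth read names")
  truth_idx <- stats::setNames(seq_len(nrow(truth)), truth$read_name)
  cats <- c("mapping_error", "multiread_nova_majority", "multiread_nova_minority")
  fp_categories <- stats::setNames(integer(3), cats)
  labels <- data.frame(call_idx = seq_along(calls),
                       label = NA_character_,
                       fp_category = NA_character_,
                       stringsAsFactors = FALSE)
  tp_reads <- character(0)
  for (ci in seq_along(calls)) {
    cd <- calls[[ci]]
    nova <- intersect(cd$support_read_names, truth$read_name)
    if (length(nova) == 0) next  # baseline call, ignored
    lab <- .classify_one(cd, nova, truth, truth_idx, tolerance)
    labels$label[ci] <- lab$label
    if (lab$label == "TP") {
      tp_reads <- c(tp_reads, nova)
    } else {
      labels$fp_category[ci] <- lab$category
      fp_categories[lab$category] <- fp_categories[lab$category] + 1L
    }
  }
  tp <- length(unique(tp_reads))
  fp <- sum(fp_categories)
  fn <- nrow(truth) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fp_categories = fp_categories,
    labels = labels), class = "bench_result")
}

.position_ok <- function(cd, tr, tolerance) {
  if (identical(tolerance, "span")) {
    # span-level agreement: POS inside the origin read's aligned span
    cd$contig == tr$contig &&
      cd$pos >= tr$read_start &&
      cd$pos < tr$read_start + tr$read_len
  } else {
    cd$contig == tr$contig &&
      abs(cd$pos - (tr$read_start + tr$insert_offset)) <= tolerance
  }
}

.classify_one <- function(cd, nova, truth, truth_idx, tolerance) {
  support <- cd$support_read_names
  if (length(nova) == 1 && length(support) == 1) {
    tr <- truth[truth_idx[[nova]], ]
    if (.position_ok(cd, tr, tolerance)) return(list(label = "TP"))
    return(list(label = "FP", category = "mapping_error"))
  }
  # multi-read: majority/minority by whether nova reads are > half of support
  cat <- if (length(nova) > length(support) / 2) {
    "multiread_nova_majority"
  } else {
    "multiread_nova_minority"
  }
  list(label = "FP", category = cat)
}

#' Categorize a false-positive call
#'
#' `mapping_error`: a single mismapped spiked read; `multiread_nova_majority`:
#' spiked reads form more than half of the support set;
#' `multiread_nova_minority`: a chimeric call where spiked reads are mixed
#' with (at least as many) non-spiked reads.
#'
#' @param call An [insertion_candidate()] already labeled FP by
#'   [classify_calls()].
#' @param truth Truth `data.frame`.
#' @param tolerance As in [classify_calls()].
#' @return One of the three category strings.
#' @export
categorize_false_positive <- function(call, truth, tolerance = "span") {
  nova <- intersect(call$support_read_names, truth$read_name)
  if (length(nova) == 0) stop("call contains no spiked reads; not an FP")
  truth_idx <- stats::setNames(seq_len(nrow(truth)), truth$read_name)
  lab <- .classify_one(call, nova, truth, truth_idx, tolerance)
  if (lab$label != "FP") stop("call is not a false positive")
  lab$category
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("<bench_result> TP=%d FP=%d FN=%d precision=%.4f recall=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall))
  cat("  FP categories:",
      paste(names(x$fp_categories), x$fp_categories, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Stratify false positives by region class
#'
#' For each region class, counts the FP calls whose position overlaps the
#' class intervals (priority-ordered: the first matching class wins;
#' unmatched calls fall into `other`), and reports the enrichment ratio of
#' the FP fraction over the genomic bp fraction of that class.
#'
#' @param fp_calls List of [insertion_candidate()] objects labeled FP.
#' @param region_sets Named list of feature tables (`contig`,`start`,`end`),
#'   in priority order (e.g. segdup before centromere).
#' @param genome_size Total genome size in bp.
#' @return A `data.frame` with `region_class`, `fp_count`, `fp_fraction`,
#'   `bp_fraction`, `enrichment` (`fp_fraction / bp_fraction`).
#' @export
stratify_by_region <- function(fp_calls, region_sets, genome_size) {
  if (genome_size <= 0) stop("empty genome: enrichment undefined")
  classes <- names(region_sets)
  indexes <- lapply(region_sets, build_interval_index)
  assign_class <- function(cd) {
    for (cl in classes) {
      if (nrow(query_overlaps(indexes[[cl]], cd$contig, cd$pos, cd$pos + 1L)) > 0)
        return(cl)
    }
    "other"
  }
  got <- vapply(fp_calls, assign_class, "")
  all_classes <- c(classes, "other")
  n <- length(fp_calls)
  bp <- vapply(region_sets, function(rs) sum(rs$end - rs$start), numeric(1))
  bp <- c(bp, other = max(0, genome_size - sum(bp)))
  counts <- vapply(all_classes, function(cl) sum(got == cl), integer(1))
  data.frame(
    region_class = all_classes,
    fp_count = counts,
    fp_fraction = if (n > 0) counts / n else rep(0, length(all_classes)),
    bp_fraction = bp[all_classes] / genome_size,
    enrichment = if (n > 0) {
      ifelse(bp[all_classes] > 0, (counts / n) / (bp[all_classes] / genome_size), NA)
    } else {
      rep(0, length(all_classes))
    },
    row.names = NULL, stringsAsFactors = FALSE)
}
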