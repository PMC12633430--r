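#' Extract resolved insertion sequences as FASTA records
#'
#' One record per candidate with a resolved sequence; record ids are
#' `contig_pos_len` (deterministic ordering follows the input). Symbolic
#' candidates are skipped with a warning.
#'
#' @param candidates List of [insertion_candidate()] objects.
#' @return A [Biostrings::DNAStringSet].
#' @export
extract_insertion_sequences <- function(candidates) {
  resolved <- vapply(candidates, function(cd) !is.na(cd$inserted_seq), logical(1))
  if (any(!resolved))
    warning(sprintf("%d candidate(s) with unresolved (symbolic) sequence skipped",
                    sum(!resolved)))
  kept <- candidates[resolved]
  ss <- Biostrings::DNAStringSet(vapply(kept, `[[`, "", "inserted_seq"))
  names(ss) <- vapply(kept, function(cd)
    sprintf("%s_%d_%d", cd$contig, cd$pos, cd$sv_len), "")
  ss
}

.sub_matrix <- function(match, mismatch) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = TRUE)
}

# One batched local alignment of all library consensi against one query
# strand; returns per-entry score, divergence and 0-based spans.
.align_library <- function(consensi, query, mat, gap_open, gap_ext) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(consensi), subject = query,
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  ni <- Biostrings::nindel(aln)
  indel_bases <- methods::slot(ni, "insertion")[, "WidthSum"] +
    methods::slot(ni, "deletion")[, "WidthSum"]
  mism <- Biostrings::nmismatch(aln)
  # alignment columns = matches + mismatches + gap columns
  ncol_aln <- Biostrings::nmatch(aln) + mism + indel_bases
  data.frame(
    score = Biostrings::score(aln),
    divergence_pct = ifelse(ncol_aln > 0,
                            100 * (mism + indel_bases) / ncol_aln, NA_real_),
    q_start = Biostrings::start(methods::slot(aln, "subject")) - 1L,
    q_end = Biostrings::end(methods::slot(aln, "subject")),
    c_start = Biostrings::start(methods::slot(aln, "pattern")) - 1L,
    c_end = Biostrings::end(methods::slot(aln, "pattern")))
}

#' Annotate a sequence against a repeat consensus library
#'
#' Local alignment of the query (both strands) against every library
#' consensus, the internal replacement for an external RepeatMasker run at
#' desk scale. Scoring: match +2, mismatch -3, gap open -5, gap extend -2;
#' hits with score below `min_score` (default 150) are dropped, a margin
#' that cleanly separates real SINE-body hits from shuffled-sequence nulls
#' at the ~300 bp scale. Divergence counts mismatches plus indel bases over
#' aligned columns (no CpG adjustment, matching raw RepeatMasker-style
#' divergence). Hits are ordered best-first: highest score, then lowest
#' divergence, then alphabetical family.
#'
#' @param seq Query DNA string (length >= 50).
#' @param library A `consensus_library`.
#' @param min_score Minimum alignment score to report.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @return A `data.frame` with columns `family`, `repeat_class`, `strand`,
#'   `score`, `divergence_pct`, `query_start`, `query_end`,
#'   `consensus_start`, `consensus_end` (0-based half-open, query
#'   coordinates always on the input strand).
#' @export
annotate_repeats <- function(seq, library, min_score = 150,
                             match = 2, mismatch = -3,
                             gap_open = 5, gap_ext = 2) {
  if (length(library$entries) == 0) stop("empty consensus library")
  seq <- toupper(seq)
  qlen <- nchar(seq)
  mat <- .sub_matrix(match, mismatch)
  rc <- .revcomp(seq)
  fams <- names(library$entries)
  consensi <- vapply(library$entries, `[[`, "", "seq")
  classes <- vapply(library$entries, `[[`, "", "class")
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") seq else rc
    a <- .align_library(consensi, q, mat, gap_open, gap_ext)
    keep <- which(a$score >= min_score)
    if (length(keep) == 0) next
    qs <- a$q_start[keep]; qe <- a$q_end[keep]
    if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
    rows[[length(rows) + 1L]] <- data.frame(
      family = fams[keep], repeat_class = classes[keep], strand = strand,
      score = a$score[keep], divergence_pct = a$divergence_pct[keep],
      query_start = qs, query_end = qe,
      consensus_start = a$c_start[keep], consensus_end = a$c_end[keep],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(family = character(), repeat_class = character(),
                      strand = character(), score = numeric(),
                      divergence_pct = numeric(), query_start = integer(),
                      query_end = integer(), consensus_start = integer(),
                      consensus_end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$divergence_pct, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect a candidate with genomic features and repeat annotations
#'
#' Adds INFO tags describing the insertion locus: `GENE_IDS` (comma-joined
#' ids of overlapping genes), `FEATURE` (`exon`, `intron` inferred as
#' gene-minus-exon, or `None`), and `REPEAT_CONTEXT` (repeat class of an
#' overlapping annotated repeat, or `None`) for nesting analyses.
#'
#' @param candidate An [insertion_candidate()].
#' @param feature_index `feature_index` over a GFF-style table with a
#'   `type` column containing `gene`/`exon` rows, or `NULL`.
#' @param repeat_index `feature_index` over a repeat table with a
#'   `repeat_class` column, or `NULL`.
#' @return The candidate with tags added to `info_tags`.
#' @export
intersect_features <- function(candidate, feature_index = NULL,
                               repeat_index = NULL) {
  pos <- candidate$pos
  tags <- candidate$info_tags
  if (!is.null(feature_index)) {
    hits <- query_overlaps(feature_index, candidate$contig, pos, pos + 1L)
    genes <- hits[hits$type == "gene", , drop = FALSE]
    exons <- hits[hits$type == "exon", , drop = FALSE]
    feature <- if (nrow(exons) > 0) "exon"
               else if (nrow(genes) > 0) "intron"
               else "None"
    tags["FEATURE"] <- feature
    tags["GENE_IDS"] <- if (nrow(genes) > 0)
      paste(sort(unique(genes$gene_id)), collapse = ",") else "None"
  }
  if (!is.null(repeat_index)) {
    rhits <- query_overlaps(repeat_index, candidate$contig, pos, pos + 1L)
    tags["REPEAT_CONTEXT"] <- if (nrow(rhits) > 0) rhits$repeat_class[1] else "None"
  }
  candidate$info_tags <- tags
  candidate
}

#' GC fraction of the window around a locus
#'
#' `(G + C) / (A + C + G + T)` over a `window`-bp window centered on `pos`,
#' clipped at contig ends; `N` bases are excluded from the denominator. An
#' all-N window yields `NA`.
#'
#' @param contigs Named character vector (or `synthetic_genome`) of contig
#'   sequences.
#' @param contig,pos Locus (0-based).
#' @param window Window size in bp (default 10000).
#' @return GC fraction in `[0, 1]`, or `NA`.
#' @export
gc_window <- function(contigs, contig, pos, window = 10000L) {
  if (inherits(contigs, "synthetic_genome")) contigs <- contigs$contigs
  seq <- contigs[[contig]]
  n <- nchar(seq)
  s <- max(0L, pos - window %/% 2L)
  e <- min(n, pos + window %/% 2L)
  win <- substr(seq, s + 1L, e)
  counts <- table(strsplit(win, "")[[1]])
  acgt <- sum(counts[c("A", "C", "G", "T")], na.rm = TRUE)
  if (acgt == 0) return(NA_real_)
  sum(counts[c("G", "C")], na.rm = TRUE) / acgt
}

#' Annotate a set of candidates (repeat + feature pass)
#'
#' Convenience wrapper applying [annotate_repeats()] to each resolved
#' candidate sequence and [intersect_features()] to each locus; the best
#' repeat hit is written into `RM_FAMILY`, `RM_CLASS`, `RM_DIV`,
#' `RM_CONS_START` tags, and `GC10K` when contig sequences are given.
#'
#' @param candidates List of [insertion_candidate()] objects.
#' @param library `consensus_library` for the internal aligner, or `NULL`
#'   to skip repeat annotation (e.g. when importing RepeatMasker output).
#' @param feature_index,repeat_index As in [intersect_features()].
#' @param contigs Optional contig sequences for `GC10K`.
#' @param min_score Passed to [annotate_repeats()].
#' @return The candidates, with `info_tags` populated.
#' @export
annotate_candidates <- function(candidates, library = NULL,
                                feature_index = NULL, repeat_index = NULL,
                                contigs = NULL, min_score = 150) {
  lapply(candidates, function(cd) {
    if (!is.null(library) && !is.na(cd$inserted_seq)) {
      hits <- annotate_repeats(cd$inserted_seq, library, min_score = min_score)
      if (nrow(hits) > 0) {
        cd$info_tags["RM_FAMILY"] <- hits$family[1]
        cd$info_tags["RM_CLASS"] <- hits$repeat_class[1]
        cd$info_tags["RM_DIV"] <- sprintf("%.3f", hits$divergence_pct[1])
        cd$info_tags["RM_CONS_START"] <- as.character(hits$consensus_start[1])
        cd$info_tags["RM_STRAND"] <- hits$strand[1]
      }
    }
    cd <- intersect_features(cd, feature_index, repeat_index)
    if (!is.null(contigs)) {
      gc <- gc_window(contigs, cd$contig, cd$pos)
      cd$info_tags["GC10K"] <- sprintf("%.4f", gc)
    }
    cd
  })
}
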