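#' Classify insertion orientation against a consensus library
#'
#' Sense iff the best-scoring consensus alignment lies on the `+` strand of
#' the inserted sequence.
#'
#' @param insertion_seq Inserted DNA string.
#' @param library `consensus_library`.
#' @param min_score Passed to [annotate_repeats()].
#' @return `"sense"` or `"antisense"`.
#' @export
classify_orientation <- function(insertion_seq, library, min_score = 150) {
  hits <- annotate_repeats(insertion_seq, library, min_score = min_score)
  if (nrow(hits) == 0) stop("no consensus hit: orientation undetermined")
  if (hits$strand[1] == "+") "sense" else "antisense"
}

#' Detect the poly(A) tail of an oriented insertion sequence
#'
#' The tail is the maximal-scoring 3' segment found by score-based
#' extension from the 3' end of the element in sense orientation
#' (antisense input is reverse-complemented first): A scores +1, non-A -2,
#' and extension terminates when the running score falls more than `xdrop`
#' below its running maximum. Among suffixes of equal score the shortest
#' (closest to the 3' end) is taken, then both ends are trimmed back to an
#' A, so a pure-homopolymer tail has impurity exactly 0. Score-based
#' extension tolerates the single-base interior impurities seen in real
#' tails without fragmenting them.
#'
#' @param insertion_seq Element sequence (body + tail, read orientation).
#' @param orientation `"sense"` or `"antisense"`.
#' @param xdrop Termination threshold (default 6: three consecutive non-A
#'   bases still extend, four stop).
#' @param min_len Tails shorter than this are flagged low-confidence.
#' @return A list: `polya_len`, `polya_impurity` (non-A fraction),
#'   `tail_seq`, `low_confidence`.
#' @export
detect_polya_tail <- function(insertion_seq, orientation = "sense",
                              xdrop = 6, min_len = 5) {
  seq <- toupper(insertion_seq)
  if (orientation == "antisense") seq <- .revcomp(seq)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  running <- 0
  best <- -Inf
  best_len <- 0L
  for (i in seq_len(n)) {           # i bases back from the 3' end
    running <- running + if (b[n - i + 1L] == "A") 1 else -2
    if (running > best) { best <- running; best_len <- i }
    if (best - running > xdrop) break
  }
  tail <- b[seq.int(n - best_len + 1L, length.out = best_len)]
  # trim both ends back to the nearest A
  while (length(tail) > 0 && tail[1] != "A") tail <- tail[-1]
  while (length(tail) > 0 && tail[length(tail)] != "A")
    tail <- tail[-length(tail)]
  len <- length(tail)
  list(polya_len = len,
       polya_impurity = if (len > 0) sum(tail != "A") / len else NA_real_,
       tail_seq = paste(tail, collapse = ""),
       low_confidence = len < min_len)
}

#' Exhaustive poly(A) boundary oracle
#'
#' Brute force over all suffix segmentations of the oriented sequence:
#' every suffix is scored (+1/-2) and the shortest maximal-scoring suffix
#' is taken, then trimmed to A at both ends — independent of the x-drop
#' extension path in [detect_polya_tail()].
#'
#' @inheritParams detect_polya_tail
#' @return As [detect_polya_tail()] (without the flag).
#' @export
polya_tail_oracle <- function(insertion_seq, orientation = "sense") {
  seq <- toupper(insertion_seq)
  if (orientation == "antisense") seq <- .revcomp(seq)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  scores <- rev(cumsum(rev(ifelse(b == "A", 1, -2))))  # score of suffix i..n
  best_i <- max(which(scores == max(scores)))          # shortest suffix
  tail <- b[best_i:n]
  while (length(tail) > 0 && tail[1] != "A") tail <- tail[-1]
  while (length(tail) > 0 && tail[length(tail)] != "A")
    tail <- tail[-length(tail)]
  len <- length(tail)
  list(polya_len = len,
       polya_impurity = if (len > 0) sum(tail != "A") / len else NA_real_,
       tail_seq = paste(tail, collapse = ""))
}

#' Detect the target site duplication around an element span
#'
#' Returns the longest exact string (up to `max_len`) that both ends at
#' the 5' insertion junction and begins at the 3' junction of the element
#' span `[insert_start, insert_end)` on the read — i.e. the duplicated
#' copy immediately left of the element equals the original immediately
#' right of it. Identity is exact (no mismatches), matching the observed
#' base-perfect duplications. `NULL` when the longest such string is
#' shorter than `min_len` or the flanks are shorter than `min_len`.
#'
#' @param read_seq Read sequence.
#' @param insert_start,insert_end Element span on the read, 0-based
#'   half-open, TSD-exclusive.
#' @param max_len,min_len Length bounds on the duplication (defaults 30/5).
#' @return `list(tsd_seq, tsd_len)` or `NULL`.
#' @export
detect_tsd <- function(read_seq, insert_start, insert_end,
                       max_len = 30L, min_len = 5L) {
  n <- nchar(read_seq)
  lim <- min(max_len, insert_start, n - insert_end)
  if (lim < min_len) return(NULL)
  for (L in seq.int(lim, min_len)) {
    left <- substr(read_seq, insert_start - L + 1L, insert_start)
    right <- substr(read_seq, insert_end + 1L, insert_end + L)
    if (left == right) return(list(tsd_seq = left, tsd_len = L))
  }
  NULL
}

#' Resolve the TSD and element span inside a raw VCF insertion block
#'
#' A caller reports one inserted block (TSD copy + element) at a junction.
#' The duplication is the longest exact prefix of the block that recurs
#' immediately after it on the read; removing that prefix yields the
#' TSD-exclusive element span used by the downstream feature calls.
#'
#' @param read_seq Read sequence.
#' @param block_start 0-based start of the inserted block on the read.
#' @param block_len Block length (VCF `SVLEN`).
#' @param max_len Cap on the duplication length.
#' @return A list: `tsd_len`, `tsd_seq` (`""` when no duplication),
#'   `element_start`, `element_end` (0-based half-open).
#' @export
refine_insertion_block <- function(read_seq, block_start, block_len,
                                   max_len = 30L) {
  e <- block_start + block_len
  L <- 0L
  n <- nchar(read_seq)
  while (L < max_len && block_start + L < e && e + L < n &&
         substr(read_seq, block_start + L + 1L, block_start + L + 1L) ==
         substr(read_seq, e + L + 1L, e + L + 1L)) {
    L <- L + 1L
  }
  list(tsd_len = L,
       tsd_seq = substr(read_seq, block_start + 1L, block_start + L),
       element_start = block_start + L, element_end = e)
}

#' 5' truncation of an element from its best consensus hit
#'
#' The truncation is the 0-based offset of the first aligned consensus
#' base: a full-length element starts at consensus base 0. Strand-aware in
#' the sense that consensus coordinates from [annotate_repeats()] always
#' refer to the consensus itself regardless of query strand.
#'
#' @param repeat_hit One row of an [annotate_repeats()] result.
#' @return Truncation in bp (>= 0).
#' @export
measure_truncation <- function(repeat_hit) {
  as.integer(repeat_hit$consensus_start[1])
}

#' Extract breakpoint context windows from the native support read
#'
#' Reconstructs the pre-insertion junction (8 nt) and the two extended
#' 20-nt flanks. For sense elements the 8-mer concatenates the 4 bases
#' upstream of the left TSD copy with the 4 bases following the poly(A)
#' tail end (the start of the original target site); for antisense, the 4
#' bases upstream of the poly(A) tail end on the read (the tail appears as
#' a 5' poly(T) run) with the 4 bases following the right TSD copy. The
#' 20-nt windows are taken upstream of the left TSD and downstream of the
#' right TSD for both orientations.
#'
#' @param read_seq Read sequence.
#' @param block_start 0-based start of the inserted block (left TSD copy).
#' @param block_len Block length (TSD + element).
#' @param tsd_len Duplication length.
#' @param orientation `"sense"` or `"antisense"`.
#' @return A list: `context_4bp` (8 nt), `context_20bp_left`,
#'   `context_20bp_right`; `NA` fields with a `reason` attribute when the
#'   read ends inside a required window.
#' @export
extract_breakpoint_context <- function(read_seq, block_start, block_len,
                                       tsd_len, orientation = "sense") {
  n <- nchar(read_seq)
  bs <- block_start
  be <- block_start + block_len        # end of block = start of right TSD
  right_end <- be + tsd_len            # end of right TSD copy
  if (bs < 20L || right_end + 20L > n) {
    out <- list(context_4bp = NA_character_,
                context_20bp_left = NA_character_,
                context_20bp_right = NA_character_)
    attr(out, "reason") <- "read ends inside a required context window"
    return(out)
  }
  sub0 <- function(s, e) substr(read_seq, s + 1L, e)  # 0-based half-open
  context_4bp <- if (orientation == "sense") {
    paste0(sub0(bs - 4L, bs), sub0(be, be + 4L))
  } else {
    # tail end on the read = right edge of the poly(T) run = bs + tsd_len
    paste0(sub0(bs + tsd_len - 4L, bs + tsd_len), sub0(right_end, right_end + 4L))
  }
  list(context_4bp = context_4bp,
       context_20bp_left = sub0(bs - 20L, bs),
       context_20bp_right = sub0(right_end, right_end + 20L))
}

#' Positional adenosine profile of TSD sequences
#'
#' Per-position nucleotide counts over a set of TSDs, indexed both from
#' the proximal junction (position 1 = first base of each TSD) and from
#' the distal end, stratifiable by TSD length, plus the count of TSDs
#' extending to each position (the length histogram).
#'
#' @param tsd_seqs Character vector of TSD sequences.
#' @return A list of class `tsd_profile`: `counts_proximal`,
#'   `counts_distal` (4 x max-length matrices of A/C/G/T counts),
#'   `a_freq_proximal`, `a_freq_distal`, `extends_to` (number of TSDs with
#'   length >= position), `lengths`, `n`. Empty input gives an empty
#'   profile.
#' @export
adenosine_profile <- function(tsd_seqs) {
  tsd_seqs <- toupper(tsd_seqs[!is.na(tsd_seqs) & nzchar(tsd_seqs)])
  n <- length(tsd_seqs)
  if (n == 0) {
    return(structure(list(counts_proximal = matrix(0L, 4, 0,
                                                   dimnames = list(c("A", "C", "G", "T"), NULL)),
                          counts_distal = matrix(0L, 4, 0,
                                                 dimnames = list(c("A", "C", "G", "T"), NULL)),
                          a_freq_proximal = numeric(0),
                          a_freq_distal = numeric(0),
                          extends_to = integer(0), lengths = integer(0), n = 0L),
                     class = "tsd_profile"))
  }
  lens <- nchar(tsd_seqs)
  m <- max(lens)
  count_mat <- function(get_base) {
    out <- matrix(0L, 4, m, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (s in tsd_seqs) {
      b <- strsplit(s, "")[[1]]
      for (p in seq_along(b)) {
        nt <- get_base(b, p)
        if (nt %in% rownames(out)) out[nt, p] <- out[nt, p] + 1L
      }
    }
    out
  }
  cp <- count_mat(function(b, p) b[p])
  cdist <- count_mat(function(b, p) b[length(b) - p + 1L])
  tot_p <- colSums(cp)
  tot_d <- colSums(cdist)
  structure(list(counts_proximal = cp, counts_distal = cdist,
                 a_freq_proximal = ifelse(tot_p > 0, cp["A", ] / tot_p, NA),
                 a_freq_distal = ifelse(tot_d > 0, cdist["A", ] / tot_d, NA),
                 extends_to = vapply(seq_len(m), function(p) sum(lens >= p),
                                     integer(1)),
                 lengths = lens, n = n),
            class = "tsd_profile")
}

#' Full TPRT feature extraction for one candidate on its support read
#'
#' Pipeline wiring: resolve the TSD and element span inside the inserted
#' block, classify orientation and subfamily against the library, call the
#' poly(A) tail, measure 5' truncation, and extract breakpoint contexts.
#'
#' @param candidate An [insertion_candidate()] whose `inserted_seq` is the
#'   raw inserted block.
#' @param read_seq Sequence of the (single) support read.
#' @param read_start 0-based origin of the read's placement, used to map
#'   the call position onto the read.
#' @param library `consensus_library`.
#' @param min_score Alignment score threshold for the repeat hit.
#' @return A list of class `alu_call`: `candidate`, `subfamily`,
#'   `orientation`, `divergence_pct`, `tsd_seq`, `tsd_len`, `polya_len`,
#'   `polya_impurity`, `truncation_5p`, `context_4bp`,
#'   `context_20bp_left`, `context_20bp_right`.
#' @export
alu_features <- function(candidate, read_seq, read_start, library,
                         min_score = 150) {
  block_start <- candidate$pos - read_start
  blk <- refine_insertion_block(read_seq, block_start, candidate$sv_len)
  element <- substr(read_seq, blk$element_start + 1L, blk$element_end)
  hits <- annotate_repeats(element, library, min_score = min_score)
  if (nrow(hits) == 0) stop("no consensus hit for candidate element")
  orientation <- if (hits$strand[1] == "+") "sense" else "antisense"
  tail <- detect_polya_tail(element, orientation)
  ctx <- extract_breakpoint_context(read_seq, block_start, candidate$sv_len,
                                    blk$tsd_len, orientation)
  structure(list(candidate = candidate,
                 subfamily = hits$family[1],
                 orientation = orientation,
                 divergence_pct = hits$divergence_pct[1],
                 tsd_seq = blk$tsd_seq, tsd_len = blk$tsd_len,
                 polya_len = tail$polya_len,
                 polya_impurity = tail$polya_impurity,
                 truncation_5p = measure_truncation(hits[1, ]),
                 context_4bp = ctx$context_4bp,
                 context_20bp_left = ctx$context_20bp_left,
                 context_20bp_right = ctx$context_20bp_right),
            class = "alu_call")
}

#' @export
print.alu_call <- function(x, ...) {
  cat(sprintf("<alu_call> %s:%d %s %s TSD=%dnt polyA=%dnt (impurity %.2f) trunc5p=%d\n",
              x$candidate$contig, x$candidate$pos, x$subfamily, x$orientation,
              x$tsd_len, x$polya_len, x$polya_impurity, x$truncation_5p))
  invisible(x)
}
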