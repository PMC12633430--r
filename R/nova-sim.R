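#' Simulation configuration for read-level insertion spike-ins
#'
#' Defaults describe the sequencing regime the package targets: HiFi-like
#' reads of mean 18 kb (SD 2.5 kb), poly(A) tails drawn uniformly from the
#' observed 18-147 nt range, target site duplications from the observed
#' 8-18 nt range, antisense orientation with probability 0.5, and a
#' substitution-only error process (HiFi error profiles are
#' substitution-dominated; indels are out of scope by default).
#'
#' @param seed Integer seed; all randomness in a simulation flows from it.
#' @param n_reads Number of reads to simulate.
#' @param read_len_mean,read_len_sd Read length distribution (bp; normal,
#'   truncated below at 1 kb).
#' @param n_spiked Number of reads that receive exactly one insertion.
#' @param insert_library A `consensus_library`; SINE entries are used as
#'   insertion bodies.
#' @param polya_len_range Length-2 integer vector, inclusive uniform range
#'   for poly(A) tail lengths.
#' @param tsd_len_range Length-2 integer vector within `[0, 30]`, inclusive
#'   uniform range for TSD lengths.
#' @param target_region `"whole_genome"` or `"segdup_only"` (spike
#'   junctions are then placed inside segmental-duplication intervals).
#' @param base_error_rate Per-base substitution probability applied to every
#'   read after spiking.
#' @param antisense_prob Probability a spiked element is inserted in
#'   antisense orientation.
#' @param polya_impurity_rate Per-base probability that a tail position
#'   carries a non-A impurity; when drawn, all impurities within one tail
#'   use the same nucleotide (matching the single-base, same-nucleotide
#'   impurity structure seen in real tails). Off by default.
#' @param edge_margin Minimum distance (bp) of the insertion junction from
#'   either read end, so both breakpoints and full flank context lie inside
#'   the read. Default 2 kb.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reads = 2000L, read_len_mean = 18000L,
                       read_len_sd = 2500L, n_spiked = 50L,
                       insert_library = synthetic_consensus_library(),
                       polya_len_range = c(18L, 147L),
                       tsd_len_range = c(8L, 18L),
                       target_region = c("whole_genome", "segdup_only"),
                       base_error_rate = 0.001,
                       antisense_prob = 0.5,
                       polya_impurity_rate = 0,
                       edge_margin = 2000L) {
  target_region <- match.arg(target_region)
  stopifnot(n_spiked <= n_reads,
            tsd_len_range[1] >= 0L, tsd_len_range[2] <= 30L,
            tsd_len_range[1] <= tsd_len_range[2],
            polya_len_range[1] <= polya_len_range[2],
            base_error_rate >= 0, base_error_rate < 1)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 n_spiked = as.integer(n_spiked),
                 insert_library = insert_library,
                 polya_len_range = as.integer(polya_len_range),
                 tsd_len_range = as.integer(tsd_len_range),
                 target_region = target_region,
                 base_error_rate = base_error_rate,
                 antisense_prob = antisense_prob,
                 polya_impurity_rate = polya_impurity_rate,
                 edge_margin = as.integer(edge_margin)),
            class = "sim_config")
}

# sample() treats a length-1 numeric as 1:n; every range draw goes through
# this guard instead
.sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

.rand_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Generate a synthetic mini-genome with repeat and segdup ground truth
#'
#' A desk-scale stand-in for a real assembly: random background at ~41% GC
#' (the genome-wide average), interspersed "dead" (heavily diverged) SINE
#' and LINE copies at the requested density, and segmental-duplication
#' pairs built by copy-then-mutate at a stated identity. Full ground-truth
#' annotations are returned alongside the sequence.
#'
#' @param seed Integer seed.
#' @param n_contigs Number of contigs.
#' @param contig_len Contig length (bp, >= 50 kb).
#' @param repeat_density Target fraction of each contig covered by dead
#'   repeat copies.
#' @param n_segdup_pairs Number of duplicated segment pairs.
#' @param segdup_len Segment length (bp, < `contig_len`).
#' @param segdup_identity Pairwise identity of each segdup pair, in
#'   `[0.90, 1.0]`.
#' @param library `consensus_library` providing repeat bodies.
#' @return A list of class `synthetic_genome`: `contigs` (named character),
#'   `repeat_truth` (feature table with `family`, `repeat_class`,
#'   `divergence_pct`), `segdup_truth` (feature table, one row per placed
#'   copy, with a `pair_id` column linking the two copies of a pair).
#' @export
generate_mini_genome <- function(seed = 1L, n_contigs = 5L,
                                 contig_len = 100000L,
                                 repeat_density = 0.05,
                                 n_segdup_pairs = 2L, segdup_len = 10000L,
                                 segdup_identity = 0.98,
                                 library = synthetic_consensus_library()) {
  stopifnot(contig_len >= 50000L,
            segdup_identity >= 0.90, segdup_identity <= 1.0)
  if (segdup_len > contig_len) stop("segdup_len exceeds contig_len")
  .with_seed(seed, {
    contig_names <- paste0("ctg", seq_len(n_contigs))
    contigs <- stats::setNames(
      vapply(seq_len(n_contigs), function(i) .rand_dna(contig_len), ""),
      contig_names)

    rep_rows <- list()
    if (repeat_density > 0) {
      fams <- names(library$entries)
      for (cn in contig_names) {
        covered <- 0L
        occupied <- integer(0)
        tries <- 0L
        while (covered < repeat_density * contig_len && tries < 1000L) {
          tries <- tries + 1L
          fam <- sample(fams, 1)
          body <- .mutate_seq(library$entries[[fam]]$seq, 0.15)  # dead copy
          w <- nchar(body)
          s <- sample.int(contig_len - w, 1) - 1L
          if (any(seq(s, s + w - 1L) %in% occupied)) next
          strand <- sample(c("+", "-"), 1)
          placed <- if (strand == "-") .revcomp(body) else body
          substr(contigs[[cn]], s + 1L, s + w) <- placed
          occupied <- c(occupied, seq(s, s + w - 1L))
          covered <- covered + w
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            contig = cn, start = s, end = s + w, strand = strand,
            label = fam, family = fam,
            repeat_class = library$entries[[fam]]$class,
            divergence_pct = 15, stringsAsFactors = FALSE)
        }
      }
    }
    repeat_truth <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 strand = character(), label = character(),
                 family = character(), repeat_class = character(),
                 divergence_pct = numeric(), stringsAsFactors = FALSE)

    sd_rows <- list()
    for (k in seq_len(n_segdup_pairs)) {
      donor_ctg <- sample(contig_names, 1)
      acceptor_ctg <- sample(contig_names, 1)
      ds <- sample.int(contig_len - segdup_len, 1) - 1L
      as_ <- sample.int(contig_len - segdup_len, 1) - 1L
      seg <- substr(contigs[[donor_ctg]], ds + 1L, ds + segdup_len)
      seg2 <- .mutate_seq(seg, 1 - segdup_identity)
      substr(contigs[[acceptor_ctg]], as_ + 1L, as_ + segdup_len) <- seg2
      sd_rows[[length(sd_rows) + 1L]] <- data.frame(
        contig = c(donor_ctg, acceptor_ctg), start = c(ds, as_),
        end = c(ds + segdup_len, as_ + segdup_len), strand = "+",
        label = sprintf("segdup%d_%s", k, c("a", "b")),
        pair_id = k, stringsAsFactors = FALSE)
    }
    segdup_truth <- if (length(sd_rows)) do.call(rbind, sd_rows) else
      data.frame(contig = character(), start = integer(), end = integer(),
                 strand = character(), label = character(),
                 pair_id = integer(), stringsAsFactors = FALSE)
    rownames(repeat_truth) <- rownames(segdup_truth) <- NULL
    structure(list(contigs = contigs, repeat_truth = repeat_truth,
                   segdup_truth = segdup_truth),
              class = "synthetic_genome")
  })
}

.draw_polya <- function(len, impurity_rate) {
  tail <- rep("A", len)
  if (impurity_rate > 0 && len > 2) {
    # interior single-base impurities, one nucleotide per tail
    nt <- sample(c("C", "G", "T"), 1)
    hit <- which(stats::runif(len) < impurity_rate)
    hit <- hit[hit > 1 & hit < len]  # keep tail ends A so length stays defined
    tail[hit] <- nt
  }
  paste(tail, collapse = "")
}

# Effective (maximal) exact duplication length for an insertion block
# [s, e) on a read, 0-based half-open: largest L with
# read[s, s+L) == read[e, e+L).
.effective_tsd_len <- function(read, s, e) {
  n <- nchar(read)
  L <- 0L
  while (s + L < e && e + L < n &&
         substr(read, s + L + 1L, s + L + 1L) ==
         substr(read, e + L + 1L, e + L + 1L)) {
    L <- L + 1L
  }
  L
}

#' Spike one Alu insertion with TPRT hallmarks into a read
#'
#' At a uniform junction offset within `[edge_margin, len - edge_margin]`
#' the read receives, in order: a copy of the `tsd_len` bases immediately
#' downstream of the junction (the 5' TSD copy), the consensus body
#' (reverse-complemented for antisense draws), and a poly(A) tail (which
#' for antisense appears as a poly(T) run 5' of the reverse-complemented
#' body). Sequencing errors are the caller's responsibility and are applied
#' after spiking by [simulate_dataset()].
#'
#' The junction offset is rejection-sampled so the drawn TSD is exactly
#' the maximal duplication present in the constructed read (chance flank
#' identity could otherwise extend it and make truth ambiguous).
#'
#' @param read_seq Read sequence (character).
#' @param origin_contig,origin_start Origin placement of the unmodified
#'   read (0-based start).
#' @param config A [sim_config()]. Randomness uses the current RNG state;
#'   seed at the dataset level.
#' @param read_name Name recorded in the truth row.
#' @param offset_hint Optional junction offset on the read. When given, the
#'   junction is placed at the hint (jittered by at most a few bp if needed
#'   to keep the drawn TSD maximal); used for region-targeted spiking.
#' @return `NULL` if the read is too short (the reason is logged via
#'   `message()`), else `list(seq, truth)` where `truth` is a one-row truth
#'   `data.frame`, plus auxiliary fields (`element_seq`, `tsd_seq`,
#'   `block_len`).
#' @export
spike_alu_insertion <- function(read_seq, origin_contig, origin_start,
                                config, read_name = "read",
                                offset_hint = NULL) {
  sine <- names(config$insert_library$entries)[
    vapply(config$insert_library$entries, `[[`, "", "class") == "SINE"]
  subfam <- .sample1(sine)
  body <- config$insert_library$entries[[subfam]]$seq
  polya_len <- .sample1(seq(config$polya_len_range[1], config$polya_len_range[2]))
  tsd_len <- .sample1(seq(config$tsd_len_range[1], config$tsd_len_range[2]))
  rl <- nchar(read_seq)
  elen <- nchar(body) + polya_len
  if (rl <= elen + 2L * config$edge_margin) {
    message("spike skipped for ", read_name, ": read too short for insertion")
    return(NULL)
  }
  antisense <- stats::runif(1) < config$antisense_prob
  tail <- .draw_polya(polya_len, config$polya_impurity_rate)
  element <- if (antisense) .revcomp(paste0(body, tail)) else paste0(body, tail)
  block_len <- tsd_len + elen
  # The junction must leave the drawn TSD as the *maximal* duplication in
  # the constructed read (chance flank identity can extend it, which would
  # make truth ambiguous): rejection-sample the offset, or jitter outward
  # around the hint; P(extend) ~ 1/4 per candidate offset.
  lo <- config$edge_margin
  hi <- rl - config$edge_margin
  candidates <- if (is.null(offset_hint)) {
    NULL
  } else {
    h <- min(max(as.integer(offset_hint), lo), hi)
    unique(pmin(pmax(h + c(0L, as.vector(rbind(1:60, -(1:60)))), lo), hi))
  }
  k <- 0L
  repeat {
    k <- k + 1L
    offset <- if (is.null(candidates)) .sample1(seq(lo, hi)) else candidates[k]
    tsd_seq <- substr(read_seq, offset + 1L, offset + tsd_len)
    modified <- paste0(substr(read_seq, 1L, offset), tsd_seq, element,
                       substr(read_seq, offset + 1L, rl))
    if (.effective_tsd_len(modified, offset, offset + block_len) == tsd_len)
      break
    if (!is.null(candidates) && k >= length(candidates))
      stop("could not place a maximal TSD near the requested junction")
  }
  truth <- data.frame(
    read_name = read_name, contig = origin_contig,
    read_start = as.integer(origin_start), read_len = as.integer(rl),
    insert_offset = as.integer(offset),
    insert_len = as.integer(elen), subfamily = subfam,
    tsd_len = as.integer(tsd_len), polya_len = as.integer(polya_len),
    orientation = if (antisense) "antisense" else "sense",
    stringsAsFactors = FALSE)
  list(seq = modified, truth = truth, element_seq = element,
       tsd_seq = tsd_seq, block_len = as.integer(block_len))
}

#' Simulate a read dataset with spiked single-read insertions
#'
#' Samples `n_reads` uniformly over the genome (position and strand),
#' spikes exactly `n_spiked` of them with one insertion each via
#' [spike_alu_insertion()], applies the substitution error process, and
#' returns reads, truth table and the pristine (un-spiked, error-free)
#' read set. Read names carry no information about spike status.
#'
#' @param genome A `synthetic_genome` from [generate_mini_genome()].
#' @param config A [sim_config()].
#' @return A list: `reads` (named character vector), `truth` (truth
#'   `data.frame`, `n_spiked` rows), `pristine` (named character vector of
#'   the original reads), `spike_aux` (list keyed by read name with
#'   `element_seq` and `block_len` for fixture-building).
#' @export
simulate_dataset <- function(genome, config) {
  .with_seed(config$seed, {
    contig_names <- names(genome$contigs)
    clens <- nchar(unlist(genome$contigs))
    if (config$read_len_mean >= max(clens))
      stop("requested read length unattainable from contig sizes")
    max_elen <- max(vapply(config$insert_library$entries, function(e)
      nchar(e$seq), numeric(1))) + config$polya_len_range[2]
    min_spike_len <- max_elen + 2L * config$edge_margin + 1L

    n <- config$n_reads
    rl <- pmax(1000L, pmin(round(stats::rnorm(n, config$read_len_mean,
                                              config$read_len_sd)),
                           max(clens) - 1L))
    ctg <- sample(contig_names, n, replace = TRUE, prob = clens)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      L <- clens[match(ctg[i], contig_names)]
      if (rl[i] >= L) rl[i] <<- L - 1L
      sample.int(L - rl[i], 1) - 1L
    }, integer(1))

    eligible <- which(rl >= min_spike_len)
    if (length(eligible) < config$n_spiked)
      stop("too few reads long enough to host the requested spikes")
    spiked_idx <- eligible[sample.int(length(eligible), config$n_spiked)]

    hints <- rep(NA_integer_, n)
    if (config$target_region == "segdup_only") {
      sd <- genome$segdup_truth
      if (nrow(sd) == 0) stop("segdup_only requested but genome has no segdups")
      margin <- 700L  # room for the maximal-TSD jitter around the junction
      for (i in spiked_idx) {
        tries <- 0L
        repeat {
          tries <- tries + 1L
          if (tries > 200L) stop("cannot place segdup-targeted reads")
          row <- sd[sample.int(nrow(sd), 1L), ]
          if (row$end - row$start <= 2L * margin) next
          q <- .sample1(seq(row$start + margin, row$end - margin))
          off <- .sample1(seq(config$edge_margin, rl[i] - config$edge_margin))
          s <- q - off
          L <- clens[match(row$contig, contig_names)]
          if (s >= 0L && s + rl[i] <= L) {
            ctg[i] <- row$contig
            start[i] <- s
            hints[i] <- off
            break
          }
        }
      }
    }

    names_v <- sprintf("read_%06d", seq_len(n))
    pristine <- character(n)
    for (i in seq_len(n)) {
      slice <- substr(genome$contigs[[ctg[i]]], start[i] + 1L, start[i] + rl[i])
      pristine[i] <- if (strand[i] == "-") .revcomp(slice) else slice
    }
    names(pristine) <- names_v

    reads <- pristine
    truth_rows <- list()
    aux <- list()
    for (i in spiked_idx) {
      sp <- spike_alu_insertion(reads[[i]], ctg[i], start[i], config,
                                read_name = names_v[i],
                                offset_hint = if (is.na(hints[i])) NULL else hints[i])
      if (is.null(sp)) next  # cannot happen for eligible reads
      reads[[i]] <- sp$seq
      truth_rows[[length(truth_rows) + 1L]] <- sp$truth
      aux[[names_v[i]]] <- list(element_seq = sp$element_seq,
                                block_len = sp$block_len,
                                tsd_seq = sp$tsd_seq)
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      utils::read.table(text = paste(.TRUTH_COLS, collapse = "\t"),
                        header = TRUE, sep = "\t")
    rownames(truth) <- NULL

    if (config$base_error_rate > 0) {
      for (i in seq_len(n)) reads[[i]] <- .mutate_seq(reads[[i]],
                                                      config$base_error_rate)
    }
    list(reads = reads, truth = truth, pristine = pristine, spike_aux = aux)
  })
}

#' Write simulated reads to FASTQ
#'
#' Constant quality (`~`, Q93) is used: the substitution process already
#' encodes the error model, and downstream stages do not consume qualities.
#' Records are emitted directly (4 lines each); the Biostrings FASTQ writer
#' is avoided because its fixed line buffer overflows on reads beyond
#' ~20 kb, which HiFi-scale simulated reads routinely exceed.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- unname(unlist(reads))
  recs <- rbind(paste0("@", names(reads)), seqs, "+",
                vapply(nchar(seqs), function(w) strrep("~", w), ""))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.vector(recs), con)
  invisible(path)
}

#' Write a genome to FASTA
#' @param genome A `synthetic_genome` or named character vector of contigs.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  contigs <- if (inherits(genome, "synthetic_genome")) genome$contigs else genome
  ss <- Biostrings::DNAStringSet(unname(unlist(contigs)))
  names(ss) <- names(contigs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
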