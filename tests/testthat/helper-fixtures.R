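# Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fixture_library <- function() fx("lib", synthetic_consensus_library)

# small 2-contig genome for unit tests (the acceptance suite builds the
# full 5 x 100 kb genome itself)
fixture_genome <- function() {
  fx("genome", function() generate_mini_genome(seed = 101L, n_contigs = 2L))
}

fixture_sim <- function() {
  fx("sim", function() {
    simulate_dataset(fixture_genome(),
                     sim_config(seed = 202L, n_reads = 150L, n_spiked = 25L,
                                base_error_rate = 0))
  })
}

# one alignment-table row; refine-stage tests compose these
read_row <- function(name, contig = "ctg1", start = 0L, end = 18000L,
                     mapq = 60L, category = "primary", clip = 0, seq = "") {
  data.frame(name = name, contig = contig, start = start, end = end,
             mapq = mapq, category = category, softclip_fraction = clip,
             seq = seq, stringsAsFactors = FALSE)
}

# minimal sniffles2-dialect VCF body line
vcf_line <- function(contig, pos1, alt, info, filter = "PASS") {
  paste(contig, pos1, ".", "N", alt, ".", filter, info, sep = "\t")
}

write_vcf_fixture <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", lines), path)
  path
}

rand_dna_str <- function(n, probs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# independent brute-force TSD oracle: ascending scan over all admissible
# lengths with character-vector comparison, keeping the last (longest) match
tsd_oracle <- function(read_seq, s, e, max_len = 30L, min_len = 5L) {
  b <- strsplit(read_seq, "")[[1]]
  lim <- min(max_len, s, length(b) - e)
  if (lim < min_len) return(NULL)
  best <- NULL
  for (L in min_len:lim) {
    if (all(b[(s - L + 1):s] == b[(e + 1):(e + L)])) best <- L
  }
  if (is.null(best)) return(NULL)
  list(tsd_seq = paste(b[(s - best + 1):s], collapse = ""), tsd_len = best)
}

# independent confusion-matrix oracle for the benchmark definitions
bench_oracle <- function(calls, truth) {
  cats <- c(mapping_error = 0L, multiread_nova_majority = 0L,
            multiread_nova_minority = 0L)
  tp_reads <- character(0)
  for (cd in calls) {
    sup <- cd$support_read_names
    nova <- sup[sup %in% truth$read_name]
    if (length(nova) == 0) next
    if (length(sup) == 1 && length(nova) == 1) {
      tr <- truth[truth$read_name == nova, ]
      in_span <- cd$contig == tr$contig && cd$pos >= tr$read_start &&
        cd$pos < tr$read_start + tr$read_len
      if (in_span) {
        tp_reads <- c(tp_reads, nova)
      } else {
        cats["mapping_error"] <- cats["mapping_error"] + 1L
      }
    } else if (length(nova) > length(sup) / 2) {
      cats["multiread_nova_majority"] <- cats["multiread_nova_majority"] + 1L
    } else {
      cats["multiread_nova_minority"] <- cats["multiread_nova_minority"] + 1L
    }
  }
  tp <- length(unique(tp_reads))
  list(tp = tp, fp = sum(cats), fn = nrow(truth) - tp, fp_categories = cats)
}
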