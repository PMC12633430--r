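#' Construct an insertion candidate
#'
#' One insertion call as emitted by a mosaic-mode SV caller: point locus,
#' resolved insertion sequence (or `NA` for symbolic ALTs), allele fraction,
#' the names of the supporting reads, FILTER status, and any further INFO
#' tags kept verbatim.
#'
#' @param contig Contig name.
#' @param pos Insertion point, 0-based (the base immediately left of the
#'   insertion junction is `pos - 1`).
#' @param inserted_seq Uppercase DNA string, or `NA_character_` when the call
#'   is symbolic and the sequence is unresolved.
#' @param sv_len Insertion length in bp. Must equal `nchar(inserted_seq)`
#'   when the sequence is resolved.
#' @param allele_fraction Allele fraction in `[0, 1]` (`NA` allowed).
#' @param support_read_names Character vector of supporting read names
#'   (empty when the caller did not emit read names; such candidates can be
#'   annotated but not refined).
#' @param filter_status VCF FILTER string.
#' @param info_tags Named character vector of additional INFO tags.
#' @return A list of class `insertion_candidate`.
#' @export
insertion_candidate <- function(contig, pos, inserted_seq, sv_len = NULL,
                                allele_fraction = NA_real_,
                                support_read_names = character(),
                                filter_status = "PASS",
                                info_tags = c()) {
  if (is.null(sv_len)) {
    if (is.na(inserted_seq)) stop("sv_len required for unresolved sequences")
    sv_len <- nchar(inserted_seq)
  }
  if (!is.na(inserted_seq) && nchar(inserted_seq) != sv_len)
    stop("sv_len must equal length(inserted_seq) when the sequence is resolved")
  structure(list(
    contig = as.character(contig),
    pos = as.integer(pos),
    inserted_seq = toupper(as.character(inserted_seq)),
    sv_len = as.integer(sv_len),
    allele_fraction = as.numeric(allele_fraction),
    support_read_names = as.character(support_read_names),
    filter_status = as.character(filter_status),
    info_tags = if (length(info_tags)) {
      stats::setNames(as.character(info_tags), names(info_tags))
    } else {
      stats::setNames(character(0), character(0))
    }
  ), class = "insertion_candidate")
}

#' @export
print.insertion_candidate <- function(x, ...) {
  cat(sprintf("<insertion_candidate> %s:%d len=%d AF=%s support=%d filter=%s\n",
              x$contig, x$pos, x$sv_len,
              format(x$allele_fraction), length(x$support_read_names),
              x$filter_status))
  invisible(x)
}

.parse_info <- function(info) {
  if (info == "." || !nzchar(info)) return(stats::setNames(character(0), character(0)))
  kv <- strsplit(info, ";", fixed = TRUE)[[1]]
  keys <- sub("=.*$", "", kv)
  vals <- ifelse(grepl("=", kv, fixed = TRUE), sub("^[^=]*=", "", kv), "")
  stats::setNames(vals, keys)
}

#' Read insertion calls from a mosaic-caller VCF
#'
#' Parses a VCF 4.2 file in the dialect emitted by sniffles2-style callers
#' (INFO keys `SVTYPE`, `SVLEN`, `AF`, `SUPPORT`, `RNAMES`; missing keys are
#' tolerated and recorded as absent). Only `SVTYPE=INS` records within the
#' requested length bounds are returned; other SV types are skipped
#' silently. VCF 1-based `POS` is converted to the package's 0-based
#' convention.
#'
#' @param path Path to an uncompressed VCF file.
#' @param min_svlen,max_svlen Inclusive bounds on `|SVLEN|`.
#' @return A list of [insertion_candidate()] objects.
#' @export
read_insertion_vcf <- function(path, min_svlen = 0L, max_svlen = Inf) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  out <- list()
  for (i in body_idx) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop(sprintf("malformed VCF line %d: expected >= 8 fields, got %d", i, length(f)))
    pos1 <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos1)) stop(sprintf("malformed VCF line %d: non-integer POS", i))
    info <- .parse_info(f[8])
    svtype <- unname(info["SVTYPE"])
    if (is.na(svtype) || svtype != "INS") next
    svlen <- suppressWarnings(as.integer(info["SVLEN"]))
    alt <- f[5]
    symbolic <- startsWith(alt, "<")
    seq <- if (symbolic) NA_character_ else toupper(alt)
    if (is.na(svlen)) {
      if (symbolic) stop(sprintf("malformed VCF line %d: symbolic ALT without SVLEN", i))
      svlen <- nchar(seq)
    }
    if (abs(svlen) < min_svlen || abs(svlen) > max_svlen) next
    rnames <- if (!is.na(info["RNAMES"])) {
      strsplit(unname(info["RNAMES"]), ",", fixed = TRUE)[[1]]
    } else {
      character(0)
    }
    af <- suppressWarnings(as.numeric(info["AF"]))
    extra <- info[setdiff(names(info), c("SVTYPE", "SVLEN", "AF", "SUPPORT", "RNAMES"))]
    out[[length(out) + 1L]] <- insertion_candidate(
      contig = f[1], pos = pos1 - 1L, inserted_seq = seq, sv_len = abs(svlen),
      allele_fraction = af, support_read_names = rnames,
      filter_status = f[7], info_tags = extra)
  }
  out
}

.escape_info_value <- function(x) gsub("[;[:space:]]", "_", x)

#' Write insertion candidates to a VCF file
#'
#' Inverse of [read_insertion_vcf()]: re-reading the written file recovers
#' the candidate fields exactly (identity at the domain-type level).
#' Additional `info_tags` are emitted verbatim after the core keys;
#' whitespace and semicolons in tag values are replaced by underscores.
#'
#' @param candidates List of [insertion_candidate()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(candidates, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=gameteMEI",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##INFO=<ID=RNAMES,Number=.,Type=String,Description=\"Supporting read names\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- vapply(candidates, function(cd) {
    info <- c(sprintf("SVTYPE=INS"), sprintf("SVLEN=%d", cd$sv_len))
    if (!is.na(cd$allele_fraction))
      info <- c(info, sprintf("AF=%s", format(cd$allele_fraction, digits = 15)))
    if (length(cd$support_read_names) > 0) {
      info <- c(info, sprintf("SUPPORT=%d", length(cd$support_read_names)),
                sprintf("RNAMES=%s", paste(cd$support_read_names, collapse = ",")))
    }
    if (length(cd$info_tags) > 0)
      info <- c(info, paste0(names(cd$info_tags), "=",
                             .escape_info_value(unname(cd$info_tags))))
    alt <- if (is.na(cd$inserted_seq)) "<INS>" else cd$inserted_seq
    paste(cd$contig, cd$pos + 1L, ".", "N", alt, ".", cd$filter_status,
          paste(info, collapse = ";"), sep = "\t")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

.RM_CLASS_MAP <- c(SINE = "SINE", LINE = "LINE", LTR = "LTR", DNA = "DNA")

.normalize_repeat_class <- function(x) {
  top <- toupper(sub("/.*$", "", x))
  out <- unname(.RM_CLASS_MAP[top])
  out[is.na(out)] <- "other"
  out
}

#' Read RepeatMasker .out annotations
#'
#' Parses the whitespace-delimited RepeatMasker `.out` dialect (3-line
#' header). Query coordinates (1-based inclusive in the file) are converted
#' to 0-based half-open; a complement-strand hit (`C`) is mapped to strand
#' `"-"` and its consensus coordinates (printed as `(left) end begin`) are
#' normalized to `begin/end`.
#'
#' @param path Path to a `.out` file.
#' @return A `data.frame` with one row per hit: `query_id`, `family`,
#'   `repeat_class`, `query_start`, `query_end`, `consensus_start`,
#'   `consensus_end` (all 0-based half-open), `divergence_pct`, `strand`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0) lines <- lines[-seq_len(min(3L, length(lines)))]
  lines_idx <- which(nzchar(trimws(lines)))
  rows <- lapply(lines_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) < 14)
      stop(sprintf("truncated RepeatMasker line %d: %d fields", i + 3L, length(f)))
    strand <- if (f[9] == "C") "-" else "+"
    strip <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cb <- strip(f[12]); ce <- strip(f[13])
    } else {
      cb <- strip(f[14]); ce <- strip(f[13])
    }
    data.frame(
      query_id = f[5], family = f[10],
      repeat_class = .normalize_repeat_class(f[11]),
      query_start = as.integer(f[6]) - 1L, query_end = as.integer(f[7]),
      consensus_start = cb - 1L, consensus_end = ce,
      divergence_pct = as.numeric(f[2]), strand = strand,
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(query_id = character(), family = character(),
                      repeat_class = character(), query_start = integer(),
                      query_end = integer(), consensus_start = integer(),
                      consensus_end = integer(), divergence_pct = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.TRUTH_COLS <- c("read_name", "contig", "read_start", "read_len",
                 "insert_offset", "insert_len", "subfamily", "tsd_len",
                 "polya_len", "orientation")

#' Read / write a spike-in truth table
#'
#' Tab-separated with header; columns `read_name`, `contig`, `read_start`,
#' `read_len`, `insert_offset`, `insert_len`, `subfamily`, `tsd_len`,
#' `polya_len`, `orientation`. `read_start`/`read_len` give the 0-based
#' origin placement of the unmodified read; `insert_offset` the 0-based
#' offset of the insertion junction within the read.
#'
#' @param path File path.
#' @return `read_truth_table`: a `data.frame`; `write_truth_table`: `path`,
#'   invisibly.
#' @export
read_truth_table <- function(path) {
  tt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(.TRUTH_COLS, names(tt))
  if (length(missing))
    stop("truth table missing columns: ", paste(missing, collapse = ", "))
  tt
}

#' @rdname read_truth_table
#' @param truth A truth `data.frame` as produced by [simulate_dataset()].
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth[, .TRUTH_COLS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.cigar_softclip_fraction <- function(cigar, seqlen) {
  ifelse(is.na(cigar) | cigar == "*", 0,
         vapply(seq_along(cigar), function(i) {
           ops <- gregexpr("[0-9]+S", cigar[i])[[1]]
           if (ops[1] == -1) return(0)
           m <- regmatches(cigar[i], gregexpr("[0-9]+(?=S)", cigar[i], perl = TRUE))[[1]]
           sum(as.integer(m)) / seqlen[i]
         }, numeric(1)))
}

#' Load an aligned-read view from a SAM/BAM file
#'
#' Uses [Rsamtools::scanBam()] (SAM files are converted with
#' [Rsamtools::asBam()] first). Each read is summarized into the fields the
#' refinement stage needs: name, placement, MAPQ, alignment category
#' (exactly one of primary/secondary/supplementary) and soft-clip fraction.
#'
#' @param path SAM or BAM path.
#' @return A `data.frame` with columns `name`, `contig`, `start`, `end`
#'   (0-based half-open span on the reference), `mapq`, `category`
#'   (`primary`/`secondary`/`supplementary`), `softclip_fraction`, `seq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "flag", "cigar", "seq"))
  res <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- res$flag
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  category <- ifelse(supplementary, "supplementary",
                     ifelse(secondary, "secondary", "primary"))
  seqs <- as.character(res$seq)
  width <- nchar(seqs)
  ref_width <- .cigar_ref_width(res$cigar, width)
  data.frame(
    name = res$qname, contig = as.character(res$rname),
    start = res$pos - 1L, end = res$pos - 1L + ref_width,
    mapq = res$mapq, category = category,
    softclip_fraction = .cigar_softclip_fraction(res$cigar, width),
    seq = seqs, stringsAsFactors = FALSE)
}

# Reference-consuming CIGAR width (M/=/X/D/N), without requiring
# GenomicAlignments: small dialect, computed directly.
.cigar_ref_width <- function(cigar, fallback_width) {
  vapply(seq_along(cigar), function(i) {
    cg <- cigar[i]
    if (is.na(cg) || cg == "*") return(fallback_width[i])
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(lens[ops %in% c("M", "=", "X", "D", "N")])
  }, numeric(1))
}

#' Read genomic features from BED or GFF3 into the internal feature table
#'
#' Thin wrapper over [rtracklayer::import()]; coordinates are converted to
#' the package's 0-based half-open convention. For GFF3 the `type` column
#' and a best-effort gene identifier (`gene_id`, `ID` or `Name`) are kept.
#'
#' @param path BED or GFF3 path (format inferred from the extension).
#' @return A `data.frame` with columns `contig`, `start`, `end`, `strand`,
#'   `label` and, for GFF3, `type`.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  label <- if (!is.null(md$Name) && any(!is.na(md$Name))) as.character(md$Name)
           else if (!is.null(md$ID)) as.character(md$ID)
           else if (!is.null(md$name)) as.character(md$name)
           else paste0("feat", seq_along(gr))
  gene_id <- if (!is.null(md$gene_id)) as.character(md$gene_id) else label
  out <- data.frame(
    contig = as.character(md$seqnames),
    start = md$start - 1L, end = md$end,
    strand = as.character(md$strand), label = label,
    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "."
  if (!is.null(md$type)) out$type <- as.character(md$type)
  out$gene_id <- gene_id
  out
}
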