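test_that("read_insertion_vcf applies the SVLEN boundary filter and skips non-INS", {
  path <- write_vcf_fixture(c(
    vcf_line("chr1", 100, strrep("A", 250), "SVTYPE=INS;SVLEN=250;AF=0.02;SUPPORT=1;RNAMES=r1"),
    vcf_line("chr1", 200, strrep("C", 320), "SVTYPE=INS;SVLEN=320;AF=0.02;SUPPORT=1;RNAMES=r2"),
    vcf_line("chr2", 300, "<INS>", "SVTYPE=INS;SVLEN=12000;SUPPORT=1;RNAMES=r3"),
    vcf_line("chr2", 400, "N", "SVTYPE=DEL;SVLEN=-500")))
  got <- read_insertion_vcf(path, min_svlen = 300, max_svlen = 10000)
  expect_length(got, 1)
  expect_equal(got[[1]]$sv_len, 320L)
  expect_equal(got[[1]]$pos, 199L)  # 1-based POS -> 0-based
  expect_equal(got[[1]]$support_read_names, "r2")
  # unfiltered: symbolic ALT kept with NA sequence, DEL still skipped
  all3 <- read_insertion_vcf(path)
  expect_length(all3, 3)
  expect_true(is.na(all3[[3]]$inserted_seq))
})

test_that("read_insertion_vcf handles empty bodies and names bad lines", {
  empty <- write_vcf_fixture(character(0))
  expect_length(read_insertion_vcf(empty), 0)
  bad <- write_vcf_fixture("chr1\tnot_a_number\tonly_three")
  expect_error(read_insertion_vcf(bad), "line 3")
})

test_that("VCF write -> read is an identity on the domain type", {
  cands <- list(
    insertion_candidate("chr1", 41L, strrep("ACGT", 90), allele_fraction = 0.05,
                        support_read_names = c("a", "b"),
                        info_tags = c(VESPER_CONF = "0.93", RM_FAMILY = "AluYa5")),
    insertion_candidate("chr2_hap1", 0L, NA, sv_len = 500L,
                        filter_status = "COVERAGE"),
    insertion_candidate("chr3", 7L, strrep("G", 320),
                        support_read_names = "solo"))
  path <- tempfile(fileext = ".vcf")
  write_annotated_vcf(cands, path)
  back <- read_insertion_vcf(path)
  expect_length(back, length(cands))
  for (i in seq_along(cands)) {
    for (f in c("contig", "pos", "inserted_seq", "sv_len", "support_read_names",
                "filter_status", "info_tags")) {
      expect_equal(back[[i]][[f]], cands[[i]][[f]], info = sprintf("cand %d field %s", i, f))
    }
  }
  body <- grep("^[^#]", readLines(path), value = TRUE)
  expect_match(body[1], "VESPER_CONF=0.93")
  # empty candidate list -> header-only VCF
  p2 <- write_annotated_vcf(list(), tempfile(fileext = ".vcf"))
  expect_length(read_insertion_vcf(p2), 0)
  expect_true(all(startsWith(readLines(p2), "#")))
})

test_that("RepeatMasker .out parsing handles both strands and errors", {
  hdr <- c("   SW   perc perc perc  query     position in query    matching repeat",
           "score   div. del. ins.  sequence  begin end (left)     repeat class/family",
           "")
  plus <- " 2269   1.5  0.2  0.0  ins_1      1   312  (10) +  AluYa5  SINE/Alu   1 281  (0)  1"
  comp <- " 1500  12.3  1.0  0.5  ins_2     10   200   (5) C  L1HS    LINE/L1  (20) 600 150   2"
  path <- tempfile(fileext = ".out")
  writeLines(c(hdr, plus, comp), path)
  got <- read_repeatmasker_out(path)
  expect_equal(nrow(got), 2)
  expect_equal(got$family, c("AluYa5", "L1HS"))
  expect_equal(got$repeat_class, c("SINE", "LINE"))
  expect_equal(got$strand, c("+", "-"))
  expect_equal(got$divergence_pct, c(1.5, 12.3))
  expect_equal(got$query_start, c(0L, 9L))     # 1-based -> 0-based
  expect_equal(got$query_end, c(312L, 200L))
  expect_equal(got$consensus_start[2], 149L)   # C strand: begin is last field

  writeLines(hdr, path)
  expect_equal(nrow(read_repeatmasker_out(path)), 0)
  writeLines(c(hdr, " 100 1.0 0.0 0.0 truncated"), path)
  expect_error(read_repeatmasker_out(path), "line 4")
})

test_that("interval index obeys half-open conventions", {
  feats <- data.frame(contig = "c", start = c(0L, 5L), end = c(10L, 15L),
                      label = c("a", "b"), stringsAsFactors = FALSE)
  idx <- build_interval_index(feats)
  expect_equal(query_overlaps(idx, "c", 9L, 10L)$label, c("a", "b"))
  expect_equal(nrow(query_overlaps(idx, "c", 10L, 11L)), 1)  # [0,10) excluded
  expect_equal(query_overlaps(idx, "c", 10L, 11L)$label, "b")
  expect_equal(nrow(query_overlaps(idx, "absent", 0L, 1L)), 0)
})

test_that("interval index equals the brute-force all-pairs oracle", {
  set.seed(31)
  n <- 1000L
  feats <- data.frame(
    contig = sample(c("c1", "c2"), n, replace = TRUE),
    start = sample.int(5000L, n, replace = TRUE) - 1L,
    label = sprintf("f%04d", seq_len(n)), stringsAsFactors = FALSE)
  feats$end <- feats$start + sample.int(300L, n, replace = TRUE)
  idx <- build_interval_index(feats)
  for (k in 1:60) {
    ctg <- sample(c("c1", "c2", "c3"), 1)
    s <- sample.int(5200L, 1) - 1L
    e <- s + sample.int(400L, 1)
    expect_identical(query_overlaps(idx, ctg, s, e),
                     overlap_scan(feats, ctg, s, e))
  }
})

test_that("truth table round-trips through TSV", {
  sim <- fixture_sim()
  path <- tempfile(fileext = ".tsv")
  write_truth_table(sim$truth, path)
  back <- read_truth_table(path)
  expect_equal(back, sim$truth[, names(back)])
  writeLines("read_name\tcontig", path)
  expect_error(read_truth_table(path), "missing columns")
})

test_that("read_alignments summarizes SAM flags, spans and soft-clips", {
  sam <- tempfile(fileext = ".sam")
  seq100 <- strrep("ACGT", 25)
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ctg1\tLN:100000",
    paste("r1", 0, "ctg1", 101, 60, "100M", "*", 0, 0, seq100, "*", sep = "\t"),
    paste("r2", 256, "ctg1", 201, 0, "100M", "*", 0, 0, seq100, "*", sep = "\t"),
    paste("r3", 2048, "ctg1", 301, 30, "10S80M10S", "*", 0, 0, seq100, "*", sep = "\t")),
    sam)
  got <- read_alignments(sam)
  expect_equal(got$category, c("primary", "secondary", "supplementary"))
  expect_equal(got$start, c(100L, 200L, 300L))
  expect_equal(got$end[1], 200L)        # 100M consumes 100 ref bases
  expect_equal(got$end[3], 380L)        # only the 80M consumes reference
  expect_equal(got$softclip_fraction, c(0, 0, 0.2))
  expect_equal(got$mapq, c(60L, 0L, 30L))
})

test_that("genomic_interval validates its invariants", {
  expect_silent(genomic_interval("chr1", 0L, 1L))
  expect_error(genomic_interval("chr1", 5L, 5L), "start < end")
  expect_error(genomic_interval("", 0L, 1L), "non-empty")
  expect_error(genomic_interval("c", -1L, 1L), ">= 0")
})
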