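test_that("partition_reads splits by name membership and flags missing support", {
  reads <- rbind(
    read_row("sup1", mapq = 60L),
    do.call(rbind, lapply(1:49, function(i)
      read_row(sprintf("bg%02d", i), mapq = 58L, clip = 0.01))))
  part <- partition_reads(reads, "sup1")
  expect_equal(part$supporting$n_reads, 1)
  expect_equal(part$nonsupporting$n_reads, 49)
  expect_equal(part$supporting$mean_mapq, 60)
  expect_equal(part$nonsupporting$mean_mapq, 58)
  expect_true(is.na(part$flag))

  part2 <- partition_reads(reads, "absent_read")
  expect_equal(part2$flag, "NO_SUPPORT_AT_LOCUS")
  # locus subsetting: only reads whose span contains pos are fetched
  part3 <- partition_reads(reads, "sup1", contig = "ctg1", pos = 5000L)
  expect_equal(part3$supporting$n_reads + part3$nonsupporting$n_reads, 50)
  expect_error(partition_reads(reads, "sup1", contig = "ctg1", pos = 99999L),
               "no reads")
})

test_that("confidence score reproduces the stated behaviors", {
  m <- function(n, mapq, clip, prim = 1) {
    structure(list(n_reads = n, mean_mapq = mapq,
                   softclip_fraction_mean = clip, primary_fraction = prim),
              class = "read_group_metrics")
  }
  # supporting metrics equal to baseline -> 1.0
  expect_equal(confidence_score(m(1, 60, 0.02), m(49, 60, 0.02))$value, 1.0)
  # sole support is supplementary -> 0
  expect_equal(confidence_score(m(1, 60, 0, prim = 0), m(49, 60, 0))$value, 0)
  # MAPQ 30 vs baseline 60, equal clipping -> 0.5
  expect_equal(confidence_score(m(1, 30, 0), m(49, 60, 0))$value, 0.5)
  # clip excess within tolerance is free; beyond it, linear penalty
  expect_equal(confidence_score(m(1, 60, 0.06), m(49, 60, 0.02))$value, 1.0)
  expect_equal(confidence_score(m(1, 60, 0.27), m(49, 60, 0.02))$value, 0.8)
  expect_error(confidence_score(m(0, NA, NA), m(49, 60, 0)), "empty")
})

test_that("confidence score is bounded and monotone", {
  m <- function(n, mapq, clip, prim = 1) {
    structure(list(n_reads = n, mean_mapq = mapq,
                   softclip_fraction_mean = clip, primary_fraction = prim),
              class = "read_group_metrics")
  }
  base <- m(40, 55, 0.03)
  set.seed(12)
  prev_by_mapq <- -1
  for (mapq in seq(0, 60, by = 10)) {
    v <- confidence_score(m(1, mapq, 0.03), base)$value
    expect_gte(v, 0); expect_lte(v, 1)
    expect_gte(v, prev_by_mapq)        # non-decreasing in supporting MAPQ
    prev_by_mapq <- v
  }
  prev_by_clip <- 2
  for (clip in seq(0, 1, by = 0.1)) {
    v <- confidence_score(m(1, 55, clip), base)$value
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lte(v, prev_by_clip)        # non-increasing in soft-clip excess
    prev_by_clip <- v
  }
})

test_that("chromosome names normalize across naming schemes", {
  expect_equal(normalize_chrom(c("chr1", "1", "chr1_hap1", "chrX", "Y")),
               c("1", "1", "1", "X", "Y"))
  expect_true(is.na(normalize_chrom("ctg7")))
  expect_true(is.na(normalize_chrom("chrM")))
})

make_filter_candidate <- function(contig = "chr5_hap1", pos = 1000L,
                                  sv_len = 320L, fam = "AluYa5", div = "1.1",
                                  conf = "0.9", primary = "1",
                                  annotated = TRUE) {
  tags <- if (annotated) {
    c(RM_FAMILY = fam, RM_CLASS = if (startsWith(fam, "Alu")) "SINE" else "LINE",
      RM_DIV = div, VESPER_CONF = conf, PRIMARY_SUPPORT = primary)
  } else {
    c(VESPER_CONF = conf, PRIMARY_SUPPORT = primary)
  }
  insertion_candidate(contig, pos, strrep("A", sv_len), sv_len = sv_len,
                      support_read_names = "r1", info_tags = tags)
}

test_that("a clean candidate passes the cascade; depth 85 fails COVERAGE", {
  clean <- make_filter_candidate()
  res <- apply_filters(list(clean), site_coverage = 55, centromeres = NULL)
  expect_length(res$pass, 1)
  expect_equal(res$pass[[1]]$filter_status, "PASS")
  res85 <- apply_filters(list(clean), site_coverage = 85, centromeres = NULL)
  expect_equal(res85$reasons, "COVERAGE")
})

test_that("each cascade rule fires with its own label, in order", {
  cen <- data.frame(contig = "chr5_hap1", start = 5000L, end = 6000L,
                    stringsAsFactors = FALSE)
  cands <- list(
    make_filter_candidate(sv_len = 10500L),                      # SVLEN
    make_filter_candidate(contig = "ctg_un"),                    # CONTIG
    make_filter_candidate(pos = 2000L),                          # COVERAGE (depth 20 below)
    make_filter_candidate(fam = "L1"),                           # NOT_ALU
    make_filter_candidate(div = "4.5"),                          # DIVERGENCE
    make_filter_candidate(conf = "0", primary = "0"),            # NO_PRIMARY
    make_filter_candidate(pos = 5500L),                          # CENTROMERE
    make_filter_candidate(annotated = FALSE))                    # UNANNOTATED
  depth <- function(contig, pos) if (pos == 2000L) 20 else 55
  res <- apply_filters(cands, depth, cen)
  expect_length(res$pass, 0)
  expect_equal(res$reasons,
               c("SVLEN", "CONTIG", "COVERAGE", "NOT_ALU", "DIVERGENCE",
                 "NO_PRIMARY", "CENTROMERE", "UNANNOTATED"))
  expect_equal(length(unique(res$reasons)), 8)
  # order stability: permuting input permutes reasons identically
  perm <- c(5L, 2L, 8L, 1L, 7L, 3L, 6L, 4L)
  res_p <- apply_filters(cands[perm], depth, cen)
  expect_equal(res_p$reasons, res$reasons[perm])
  # short Alu fails the length arm of rule 4
  short <- make_filter_candidate(sv_len = 250L)
  expect_equal(apply_filters(list(short), 55, NULL)$reasons, "NOT_ALU")
})

test_that("refinement on simulated data isolates the spiked read", {
  sim <- fixture_sim()
  g <- fixture_genome()
  tr <- sim$truth[1, ]
  # alignment table: spiked read at its origin plus background reads there
  reads <- rbind(
    read_row(tr$read_name, contig = tr$contig, start = tr$read_start,
             end = tr$read_start + tr$read_len, mapq = 60L,
             seq = sim$reads[[tr$read_name]]),
    do.call(rbind, lapply(1:10, function(i)
      read_row(sprintf("bg%02d", i), contig = tr$contig,
               start = tr$read_start - 1000L,
               end = tr$read_start + tr$read_len, mapq = 60L))))
  cd <- truth_to_calls(tr, sim$spike_aux)[[1]]
  out <- refine_candidates(list(cd), reads)[[1]]
  expect_equal(unname(out$info_tags["VESPER_CONF"]), "1.0000")
  expect_equal(unname(out$info_tags["PRIMARY_SUPPORT"]), "1")
  # forcing the spiked read supplementary zeroes the score
  reads$category[1] <- "supplementary"
  out2 <- refine_candidates(list(cd), reads)[[1]]
  expect_equal(unname(out2$info_tags["VESPER_CONF"]), "0.0000")
  # support name absent entirely
  cd2 <- cd; cd2$support_read_names <- "not_in_bam"
  out3 <- refine_candidates(list(cd2), reads)[[1]]
  expect_equal(unname(out3$info_tags["REFINE_FLAG"]), "NO_SUPPORT_AT_LOCUS")
})
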