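test_that("orientation classification follows the best-hit strand", {
  lib <- fixture_library()
  elem <- paste0(lib$entries$AluYc$seq, strrep("A", 30))
  expect_equal(classify_orientation(elem, lib), "sense")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(elem)))
  expect_equal(classify_orientation(rc, lib), "antisense")
  expect_error(classify_orientation(rand_dna_str(350), lib), "no consensus hit")
})

test_that("poly(A) detection reproduces the reference behaviors", {
  lib <- fixture_library()
  body <- lib$entries$AluY$seq
  # pure 42-nt tail
  got <- detect_polya_tail(paste0(body, strrep("A", 42)))
  expect_equal(got$polya_len, 42)
  expect_equal(got$polya_impurity, 0)
  expect_false(got$low_confidence)
  # 24-nt tail with a single interior G: impurity 1/24
  tail24 <- paste0(strrep("A", 11), "G", strrep("A", 12))
  got2 <- detect_polya_tail(paste0(body, tail24))
  expect_equal(got2$polya_len, 24)
  expect_equal(got2$polya_impurity, 1 / 24, tolerance = 1e-12)
  # antisense element: tail recovered after reverse complement
  elem_as <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(body, strrep("A", 33)))))
  got3 <- detect_polya_tail(elem_as, "antisense")
  expect_equal(got3$polya_len, 33)
  # impurity 0 iff perfect homopolymer
  expect_equal(detect_polya_tail(paste0(body, tail24))$polya_impurity > 0, TRUE)
  # x-drop stops at a 4-nt non-A run: AAAA TTTT AAAA keeps the final AAAA
  blocky <- paste0(body, "AAAA", "TTTT", "AAAA")
  got4 <- detect_polya_tail(blocky)
  orc4 <- polya_tail_oracle(blocky)
  expect_equal(got4$polya_len, orc4$polya_len)
  expect_equal(got4$polya_len, 4)
})

test_that("poly(A) boundary matches the exhaustive suffix oracle on adversarial tails", {
  lib <- fixture_library()
  set.seed(321)
  bodies <- vapply(lib$entries[1:4], `[[`, "", "seq")
  for (i in 1:300) {
    body <- bodies[[sample.int(length(bodies), 1)]]
    # tails with interior impurity runs up to 3 non-A, separated by enough
    # adenosines to recover the extension score (the impurity structure seen
    # in real tails: short, interspersed, never long contiguous tracts)
    len <- sample(10:120, 1)
    tail <- rep("A", len)
    n_imp <- sample(0:4, 1)
    if (n_imp > 0 && len > 20) {
      nt <- sample(c("C", "G", "T"), 1)
      pos <- 2L
      for (k in seq_len(n_imp)) {
        run <- sample(1:3, 1)
        pos <- pos + sample(7:12, 1)
        if (pos + run > len - 7L) break
        tail[pos:(pos + run - 1)] <- nt
        pos <- pos + run
      }
    }
    seq <- paste0(body, paste(tail, collapse = ""))
    got <- detect_polya_tail(seq)
    orc <- polya_tail_oracle(seq)
    expect_equal(got$polya_len, orc$polya_len, info = paste("case", i))
    expect_equal(got$tail_seq, orc$tail_seq, info = paste("case", i))
    expect_gte(got$polya_impurity, 0)
    expect_lte(got$polya_impurity, 1)
  }
})

test_that("TSD detection returns the longest exact junction-anchored match", {
  set.seed(63)
  flank5 <- rand_dna_str(100)
  tsd <- rand_dna_str(12)
  elem <- rand_dna_str(60)
  flank3 <- rand_dna_str(100)
  read <- paste0(flank5, tsd, elem, tsd, flank3)
  s <- 100L + 12L
  e <- s + 60L
  got <- detect_tsd(read, s, e)
  orc <- tsd_oracle(read, s, e)
  expect_equal(got, orc)
  expect_gte(got$tsd_len, 12)  # >= planted (chance extension possible)
  # flanks with no shared >= 5-mer at the junctions -> NULL
  read2 <- paste0(strrep("C", 50), strrep("G", 50))
  expect_null(detect_tsd(read2, 50L, 50L + 0L, min_len = 5L))
  # flanks shorter than min_len -> undetectable
  expect_null(detect_tsd("ACGTACGTAC", 2L, 6L))
})

test_that("TSD detection equals the brute-force oracle on random planted cases", {
  set.seed(64)
  for (i in 1:500) {
    f5 <- rand_dna_str(sample(30:80, 1))
    L <- sample(5:20, 1)
    tsd <- rand_dna_str(L)
    elem <- rand_dna_str(sample(40:90, 1))
    f3 <- rand_dna_str(sample(30:80, 1))
    read <- paste0(f5, tsd, elem, tsd, f3)
    s <- nchar(f5) + L
    e <- s + nchar(elem)
    got <- detect_tsd(read, s, e)
    orc <- tsd_oracle(read, s, e)
    expect_equal(got, orc, info = paste("case", i))
  }
})

test_that("block refinement recovers the TSD/element decomposition", {
  sim <- fixture_sim()
  for (i in seq_len(min(10, nrow(sim$truth)))) {
    tr <- sim$truth[i, ]
    aux <- sim$spike_aux[[tr$read_name]]
    blk <- refine_insertion_block(sim$reads[[tr$read_name]], tr$insert_offset,
                                  aux$block_len)
    expect_equal(blk$tsd_len, tr$tsd_len)
    expect_equal(blk$tsd_seq, aux$tsd_seq)
    expect_equal(blk$element_end - blk$element_start, tr$insert_len)
  }
})

test_that("truncation is the consensus-space start offset of the hit", {
  lib <- fixture_library()
  full <- paste0(lib$entries$AluYb8$seq, strrep("A", 40))
  hit <- annotate_repeats(full, lib)[1, ]
  expect_equal(measure_truncation(hit), 0L)
  for (cut in c(5L, 20L, 35L)) {
    trunc <- paste0(substr(lib$entries$AluYb8$seq, cut + 1L, 281L), strrep("A", 40))
    h <- annotate_repeats(trunc, lib)
    h <- h[h$family == "AluYb8", ][1, ]
    expect_lte(abs(measure_truncation(h) - cut), 1)  # +/- 1 bp at the edge
  }
})

test_that("breakpoint context reconstructs the pre-insertion junction", {
  lib <- fixture_library()
  body <- lib$entries$AluYa5$seq
  set.seed(71)
  # genome site engineered as ...NNTT | AAAAGC... : TS begins with AAAA
  left <- paste0(rand_dna_str(40), "TT")
  ts <- "AAAAGCTTGGCA"                      # 12-nt target site
  right <- rand_dna_str(40)
  polya <- strrep("A", 30)
  # sense insertion: left | TS(copy) | body polyA | TS | right
  read_s <- paste0(left, ts, body, polya, ts, right)
  bs <- nchar(left)
  blklen <- nchar(ts) + nchar(body) + nchar(polya)
  ctx <- extract_breakpoint_context(read_s, bs, blklen, nchar(ts), "sense")
  expect_equal(ctx$context_4bp,
               paste0(substr(left, nchar(left) - 3, nchar(left)),
                      substr(ts, 1, 4)))
  expect_match(ctx$context_4bp, "TTAAAA")
  expect_equal(ctx$context_20bp_left, substr(read_s, bs - 19, bs))
  expect_equal(ctx$context_20bp_right,
               substr(read_s, bs + blklen + nchar(ts) + 1,
                      bs + blklen + nchar(ts) + 20))
  # antisense at the same site: windows come from the opposite junctions
  elem_as <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0(body, polya))))
  read_a <- paste0(left, ts, elem_as, ts, right)
  ctx_a <- extract_breakpoint_context(read_a, bs, blklen, nchar(ts), "antisense")
  expect_equal(ctx_a$context_4bp,
               paste0(substr(ts, 9, 12), substr(right, 1, 4)))
  expect_false(identical(ctx$context_4bp, ctx_a$context_4bp))
  # read ending inside a window -> missing with reason
  shortr <- substr(read_s, 1, bs + blklen + nchar(ts) + 5)
  ctx_s <- extract_breakpoint_context(shortr, bs, blklen, nchar(ts), "sense")
  expect_true(is.na(ctx_s$context_4bp))
  expect_match(attr(ctx_s, "reason"), "window")
})

test_that("adenosine profile counts positions from both ends", {
  prof <- adenosine_profile(c("AAAA", "AAAA", "AAAA"))
  expect_true(all(prof$a_freq_proximal == 1))
  expect_equal(prof$extends_to, rep(3L, 4))

  tab <- load_insertion_table()
  prof_t <- adenosine_profile(tab$tsd_sequence)
  hand_pos1 <- mean(substr(tab$tsd_sequence, 1, 1) == "A")
  expect_equal(prof_t$a_freq_proximal[1], hand_pos1)
  hand_last <- mean(substr(tab$tsd_sequence, nchar(tab$tsd_sequence),
                           nchar(tab$tsd_sequence)) == "A")
  expect_equal(prof_t$a_freq_distal[1], hand_last)
  expect_equal(sum(prof_t$counts_proximal[, 1]), nrow(tab))
  expect_equal(prof_t$extends_to[1], nrow(tab))

  empty <- adenosine_profile(character(0))
  expect_equal(empty$n, 0)
  expect_length(empty$a_freq_proximal, 0)
})

test_that("full feature extraction inverts the simulator (error rate 0)", {
  lib <- fixture_library()
  sim <- fixture_sim()
  calls <- truth_to_calls(sim$truth, sim$spike_aux)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ft <- alu_features(calls[[i]], sim$reads[[tr$read_name]], tr$read_start, lib)
    expect_equal(ft$subfamily, tr$subfamily, info = tr$read_name)
    expect_equal(ft$orientation, tr$orientation, info = tr$read_name)
    expect_equal(ft$tsd_len, tr$tsd_len, info = tr$read_name)
    expect_equal(ft$polya_len, tr$polya_len, info = tr$read_name)
    expect_equal(ft$polya_impurity, 0, info = tr$read_name)
    expect_equal(ft$truncation_5p, 0L, info = tr$read_name)
  }
})
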