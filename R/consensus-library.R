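#' Synthetic repeat consensus library
#'
#' A small bundled stand-in for a Repbase/Dfam-style consensus library,
#' generated deterministically in code (no third-party consensus sequences
#' are shipped). One 281-bp GC-rich SINE-like ancestral body is drawn once
#' from a fixed generator, and each Alu-family subfamily entry is derived
#' from it by a fixed set of diagnostic substitutions, mirroring how real
#' AluY subfamilies differ from AluY by a handful of positions. A diverged
#' 600-bp LINE fragment is included for repeat-context tests.
#'
#' Construction rules that make simulator truth well defined downstream:
#' the final 6 bases of every SINE body are non-A (so a spiked poly(A)
#' tail's 5' boundary is unambiguous) and no body contains an adenosine run
#' of 4 or more.
#'
#' @param subfamilies Character vector of subfamily names to generate.
#' @param body_len Body length in bp for SINE entries (consensus bodies of
#'   the Alu families targeted here are ~280 bp).
#' @return A list of class `consensus_library` with elements `entries`
#'   (named list of `list(seq, class)`) and `provenance`.
#' @export
synthetic_consensus_library <- function(
    subfamilies = c("AluY", "AluYa5", "AluYb8", "AluYb9", "AluYc", "AluYe5",
                    "AluYg6", "AluYh7", "AluYk2", "AluYk12"),
    body_len = 281L) {
  .with_seed(990331L, .build_synthetic_library(subfamilies, body_len))
}

.build_synthetic_library <- function(subfamilies, body_len) {
  bases <- c("A", "C", "G", "T")
  # GC-rich body (Alu bodies are ~60% GC), A depleted to keep tails clean
  probs <- c(A = 0.12, C = 0.31, G = 0.32, T = 0.25)
  draw_body <- function(n) {
    b <- sample(bases, n, replace = TRUE, prob = probs)
    # forbid A in the last 6 positions and any A-run >= 4
    tailidx <- (n - 5L):n
    b[tailidx][b[tailidx] == "A"] <- sample(c("C", "G", "T"), sum(b[tailidx] == "A"),
                                            replace = TRUE)
    r <- rle(b)
    while (any(r$values == "A" & r$lengths >= 4L)) {
      pos <- cumsum(r$lengths)
      k <- which(r$values == "A" & r$lengths >= 4L)[1]
      b[pos[k]] <- sample(c("C", "G", "T"), 1)
      r <- rle(b)
    }
    b
  }
  ancestor <- draw_body(body_len)
  entries <- list()
  for (i in seq_along(subfamilies)) {
    fam <- subfamilies[i]
    b <- ancestor
    if (fam != subfamilies[1]) {
      # 5-12 diagnostic substitutions per derived subfamily, positions fixed
      # by the seeded generator, avoiding the protected 3' window
      k <- 4L + i
      pos <- sample(seq_len(body_len - 6L), k)
      for (p in pos) {
        b[p] <- sample(setdiff(bases, c(b[p], if (p > body_len - 12L) "A")), 1)
      }
    }
    entries[[fam]] <- list(seq = paste(b, collapse = ""), class = "SINE")
  }
  l1 <- sample(bases, 600L, replace = TRUE,
               prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  entries[["L1"]] <- list(seq = paste(l1, collapse = ""), class = "LINE")
  structure(list(entries = entries,
                 provenance = "synthetic (generated in code, seed 990331)"),
            class = "consensus_library")
}

#' Build a consensus library from a FASTA file
#'
#' Entry names become subfamily labels; repeat class is `SINE` for names
#' starting with `Alu`, `LINE` for names starting with `L1`, else `other`.
#'
#' @param path FASTA path.
#' @return A `consensus_library`.
#' @export
read_consensus_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  entries <- lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    cls <- if (startsWith(nm, "Alu")) "SINE"
           else if (startsWith(nm, "L1")) "LINE" else "other"
    list(seq = toupper(as.character(seqs[[i]])), class = cls)
  })
  names(entries) <- names(seqs)
  structure(list(entries = entries, provenance = path),
            class = "consensus_library")
}

#' @export
print.consensus_library <- function(x, ...) {
  cat(sprintf("<consensus_library> %d entries (%s)\n",
              length(x$entries), x$provenance))
  invisible(x)
}

#' Write a consensus library to FASTA
#'
#' @param library A `consensus_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_library <- function(library, path) {
  ss <- Biostrings::DNAStringSet(vapply(library$entries, `[[`, "", "seq"))
  names(ss) <- names(library$entries)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards, so library construction never perturbs user-level randomness.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
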