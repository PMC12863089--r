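# Independent oracles used by the tests. The local-alignment oracle is a
# plain dynamic-programming (Gotoh) implementation written directly from
# the recurrences, kept independent of the package's alignment path.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa_string <- function(n) paste(sample(AA20, n, replace = TRUE),
                                      collapse = "")

blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Exhaustive affine-gap Smith-Waterman score: a gap of length k costs
# gap_open + k * gap_extend. Returns the best local alignment score
# (0 when no alignment scores positive).
sw_oracle_score <- function(q, s, mat = blosum62_matrix,
                            gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  open1 <- gap_open + gap_extend  # cost of the first gapped position
  M <- matrix(0, n + 1, m + 1)    # alignments ending in a residue pair
  X <- matrix(-Inf, n + 1, m + 1) # ending in a gap in the subject
  Y <- matrix(-Inf, n + 1, m + 1) # ending in a gap in the query
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- mat[qa[i], sa[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + sub,
                             X[i, j] + sub,
                             Y[i, j] + sub)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open1,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open1,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Brute-force nearest-partner: enumerate all candidate distances and
# return the minimum |start(candidate) - end(phaE)|.
coloc_oracle_distance <- function(phaE_end, candidate_starts) {
  if (length(candidate_starts) == 0L) return(NA_real_)
  min(abs(candidate_starts - phaE_end))
}

random_hit_frame <- function(n) {
  data.frame(qacc = "Q",
             sacc = sample(sprintf("S%02d", 1:6), n, replace = TRUE),
             pident = round(stats::runif(n, 25, 100), 3),
             length = sample(50:500, n, replace = TRUE),
             mismatch = sample(0:50, n, replace = TRUE),
             gapopen = sample(0:5, n, replace = TRUE),
             qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
             evalue = 10^stats::runif(n, -100, -2),
             bitscore = round(stats::runif(n, 50, 900), 1),
             stitle = "subject title",
             stringsAsFactors = FALSE)
}

# minimal organism_call constructor for tally tests (bypasses alignment)
fake_call <- function(organism, strong_classes, weak_classes = character()) {
  classes <- c(strong_classes, weak_classes)
  pc <- data.frame(class = classes,
                   sacc = paste0(organism, "_", classes),
                   pident = c(rep(80, length(strong_classes)),
                              rep(40, length(weak_classes))),
                   length = 400L, bitscore = 500, evalue = 1e-50,
                   strong = c(rep(TRUE, length(strong_classes)),
                              rep(FALSE, length(weak_classes))),
                   query_coverage = 95, stringsAsFactors = FALSE)
  structure(list(organism = organism, per_class = pc,
                 best_class = classes[1L], best_pident = pc$pident[1L],
                 strength = if (pc$strong[1L]) "strong" else "weak",
                 query_coverage = 95),
            class = "organism_call")
}
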