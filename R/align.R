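# Local protein alignment in the style of BLASTp tabular output.
# Smith-Waterman with affine gaps is delegated to
# Biostrings::pairwiseAlignment; this module derives the tabular hit
# statistics (pident over alignment columns including gaps, mismatch,
# gapopen, coordinates, bitscore, evalue) from the optimal alignment.

# Karlin-Altschul gapped parameters for BLOSUM62 with gap open 11 /
# extend 1 (the BLASTp protein defaults). Bitscores for other scoring
# schemes reuse these constants; they feed only the reported
# bitscore/evalue, never classification, and bitscore stays a strictly
# increasing function of the raw score either way.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Survey configuration
#'
#' Bundles the tunable parameters of the paralog survey: the weak/strong
#' percent-identity threshold, the per-organism hit cap, the scoring
#' scheme, and the minimum reportable identity.
#'
#' @param weak_threshold Percent identity at or above which a call is
#'   "strong" (default 65; calls strictly below are "weak").
#' @param max_targets Maximum hits retained per reference per species
#'   (default 4).
#' @param matrix Substitution matrix name available in Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length k
#'   costs `gap_open + k * gap_extend` (defaults 11 and 1, the BLASTp
#'   protein defaults).
#' @param min_pident Minimum percent identity for a reportable hit
#'   (default 25).
#' @param db_size Effective database size (residues) for e-value
#'   computation; `NULL` means use the subject collection's total length.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(weak_threshold = 65, max_targets = 4L,
                          matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, min_pident = 25,
                          db_size = NULL) {
  stopifnot(weak_threshold > 0, weak_threshold <= 100, max_targets >= 1,
            gap_open >= 0, gap_extend >= 0, min_pident >= 0)
  structure(list(weak_threshold = weak_threshold,
                 max_targets = as.integer(max_targets),
                 matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, min_pident = min_pident,
                 db_size = db_size),
            class = "survey_config")
}

load_substitution_matrix <- function(name) {
  available <- utils::data(package = "Biostrings")$results[, "Item"]
  if (!name %in% available) {
    stop("unknown substitution matrix '", name, "'; available: ",
         paste(sort(available), collapse = ", "), call. = FALSE)
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Best local alignment between two proteins
#'
#' Computes the optimal Smith-Waterman local alignment under affine gap
#' penalties and the configured substitution matrix, and reports it as one
#' row of the 13-column hit dialect. `pident` is computed over alignment
#' columns including gaps (`100 * identities / alignment length`),
#' `mismatch` counts aligned non-identical residue pairs, `gapopen` counts
#' gap runs in either sequence. The bitscore is derived from the raw score
#' with Karlin-Altschul scale constants and the e-value from the bitscore
#' and the query/database lengths.
#'
#' @param query,subject Single protein records (one-row `data.frame` or
#'   list with `id`, `sequence`, optionally `description`).
#' @param config A [survey_config()].
#' @param db_size Effective database size in residues for the e-value;
#'   defaults to `config$db_size`, falling back to the subject length.
#' @return A one-row hit `data.frame`, or `NULL` when no local alignment
#'   has positive score or the best alignment falls below
#'   `config$min_pident`.
#' @export
local_align <- function(query, subject, config = survey_config(),
                        db_size = NULL) {
  qseq <- query$sequence[1L]
  sseq <- subject$sequence[1L]
  if (is.null(qseq) || is.null(sseq) || !nzchar(qseq) || !nzchar(sseq)) {
    stop("local_align requires non-empty query and subject sequences",
         call. = FALSE)
  }
  mat <- load_substitution_matrix(config$matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qseq), Biostrings::AAString(sseq),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  raw <- Biostrings::score(aln)
  ap <- as.character(Biostrings::alignedPattern(aln))
  if (raw <= 0 || nchar(ap) == 0L) return(NULL)
  as_ <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(ap)
  qa <- strsplit(ap, "")[[1L]]
  sa <- strsplit(as_, "")[[1L]]
  ident <- sum(qa == sa & qa != "-")
  mism <- sum(qa != sa & qa != "-" & sa != "-")
  gapopen <- count_gap_runs(qa) + count_gap_runs(sa)
  pident <- 100 * ident / len
  if (pident < config$min_pident) return(NULL)
  if (is.null(db_size)) db_size <- config$db_size
  if (is.null(db_size)) db_size <- nchar(sseq)
  bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  evalue <- nchar(qseq) * db_size * 2^(-bits)
  data.frame(qacc = query$id[1L], sacc = subject$id[1L],
             pident = pident, length = len, mismatch = mism,
             gapopen = gapopen,
             qstart = Biostrings::start(Biostrings::pattern(aln)),
             qend = Biostrings::end(Biostrings::pattern(aln)),
             sstart = Biostrings::start(Biostrings::subject(aln)),
             send = Biostrings::end(Biostrings::subject(aln)),
             evalue = evalue, bitscore = bits,
             stitle = subject_title(subject),
             stringsAsFactors = FALSE)
}

count_gap_runs <- function(chars) {
  r <- rle(chars == "-")
  sum(r$values)
}

subject_title <- function(subject) {
  desc <- subject$description
  if (is.null(desc) || !nzchar(desc[1L])) return(subject$id[1L])
  paste(subject$id[1L], desc[1L])
}
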