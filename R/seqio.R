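# Readers/writers for the plain-text formats the pipeline exchanges:
# protein FASTA, 13-column alignment hit tables, and gene-locus TSV.
# All coordinates are 1-based inclusive (GenBank convention).

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# letters mapped to X on input: ambiguity codes B/Z, rare letters U/O/J,
# and the stop symbol '*' (all occur in real RefSeq proteomes)
AA_MAPPED_TO_X <- c("B", "Z", "U", "O", "J", "*")

HIT_COLUMNS <- c("qacc", "sacc", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore",
                 "stitle")
HIT_NUMERIC <- c("pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")

LOCI_COLUMNS <- c("genome_id", "gene_id", "start", "end", "strand", "label")

#' Construct a protein record table
#'
#' A protein record table is a plain `data.frame` with one row per protein
#' and columns `id`, `description`, `organism` and `sequence`. Sequences are
#' uppercase strings over the 20 standard amino-acid letters plus `X`.
#'
#' @param id Character vector of accessions; must be non-empty and unique.
#' @param sequence Character vector of amino-acid sequences.
#' @param description Free-text descriptions (default empty).
#' @param organism Scientific names (default empty).
#' @return A `data.frame` with columns `id`, `description`, `organism`,
#'   `sequence`.
#' @export
protein_records <- function(id, sequence, description = "", organism = "") {
  if (length(id) == 0L) {
    return(data.frame(id = character(), description = character(),
                      organism = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    organism = rep_len(as.character(organism), length(id)),
                    sequence = toupper(as.character(sequence)),
                    stringsAsFactors = FALSE)
  validate_protein_records(rec)
  rec
}

validate_protein_records <- function(rec) {
  if (any(is.na(rec$id) | rec$id == "")) {
    stop("protein record with empty id", call. = FALSE)
  }
  if (anyDuplicated(rec$id)) {
    stop("duplicate protein ids within one collection: ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(rec$sequence) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(rec$id[nchar(rec$sequence) == 0L], collapse = ", "),
         call. = FALSE)
  }
  bad <- !grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "X]+$"),
                rec$sequence)
  if (any(bad)) {
    stop("sequence characters outside the amino-acid alphabet in record(s): ",
         paste(rec$id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(rec)
}

# map ambiguity/rare letters to X, warn once per file
sanitize_sequences <- function(seqs, ids) {
  pat <- paste0("[", gsub("\\*", "\\\\*", paste(AA_MAPPED_TO_X, collapse = "")), "]")
  hits <- grepl(pat, seqs)
  if (any(hits)) {
    warning("ambiguity letters (", paste(AA_MAPPED_TO_X, collapse = ""),
            ") mapped to X in record(s): ",
            paste(ids[hits], collapse = ", "), call. = FALSE)
    for (ch in AA_MAPPED_TO_X) {
      seqs <- gsub(ch, "X", seqs, fixed = TRUE)
    }
  }
  seqs
}

#' Read a protein FASTA file
#'
#' Parses FASTA into a protein record table. The record id is the first
#' whitespace-delimited token of the header; the remainder is the
#' description. When the description ends in a bracketed scientific name
#' (`[Genus species]`, the NCBI convention) that name is extracted as the
#' organism. Sequences are uppercased; ambiguity letters `B/Z/U/O/J/*` are
#' mapped to `X` with a warning; any other non-amino-acid character is an
#' error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A protein record table (see [protein_records()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    # Biostrings errors on files with no '>' header
                    if (sum(file.size(path), na.rm = TRUE) == 0L ||
                        !any(grepl("^>", readLines(path, warn = FALSE)))) {
                      return(NULL)
                    }
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(raw) || length(raw) == 0L) {
    warning("no FASTA records in ", path, call. = FALSE)
    return(protein_records(character(), character()))
  }
  headers <- names(raw)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  organism <- ifelse(grepl("\\[[^]]+\\]\\s*$", description),
                     sub("^.*\\[([^]]+)\\]\\s*$", "\\1", description), "")
  seqs <- toupper(as.character(raw))
  seqs <- gsub("[ \t]", "", seqs)
  seqs <- sanitize_sequences(seqs, id)
  rec <- data.frame(id = id, description = description, organism = organism,
                    sequence = seqs, stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  validate_protein_records(rec)
  rec
}

#' Write a protein record table as FASTA
#'
#' Headers are `>id description`; sequences wrapped at `width` columns.
#'
#' @param records Protein record table.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_protein_records(records)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(records$description == "", records$id,
                       paste(records$id, records$description))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read an alignment hit table
#'
#' Reads the 13-column tab-separated local-alignment hit dialect with the
#' fixed column order `qacc sacc pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore stitle` (the extended tabular output of
#' protein-protein search tools). There is no header row; comment lines
#' starting with `#` are skipped; `evalue` accepts scientific notation.
#'
#' @param path Path to a hit table.
#' @return A `data.frame` with the 13 hit columns, numeric where numeric.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 13L)) {
    bad <- which(nf != 13L)[1L]
    stop("hit table row with ", nf[bad], " columns (expected 13) at line ",
         lineno[bad], " of ", path, call. = FALSE)
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(m, stringsAsFactors = FALSE)
  names(hits) <- HIT_COLUMNS
  for (col in HIT_NUMERIC) {
    val <- suppressWarnings(as.numeric(hits[[col]]))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1L]
      stop("non-numeric value '", hits[[col]][bad], "' in column ", col,
           " at line ", lineno[bad], " of ", path, call. = FALSE)
    }
    hits[[col]] <- val
  }
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")) {
    hits[[col]] <- as.integer(hits[[col]])
  }
  hits
}

empty_hits <- function() {
  hits <- data.frame(qacc = character(), sacc = character(),
                     pident = numeric(), length = integer(),
                     mismatch = integer(), gapopen = integer(),
                     qstart = integer(), qend = integer(),
                     sstart = integer(), send = integer(),
                     evalue = numeric(), bitscore = numeric(),
                     stitle = character(), stringsAsFactors = FALSE)
  hits
}

#' Write an alignment hit table
#'
#' Serializes hits in the fixed 13-column dialect: `pident` with 3 decimal
#' places, `bitscore` with 1, `evalue` in scientific notation — so written
#' files are byte-stable and round-trip through [read_hit_table()].
#'
#' @param hits Hit `data.frame` as produced by [local_align()] or
#'   [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  lines <- character(nrow(hits))
  if (nrow(hits) > 0L) {
    lines <- paste(hits$qacc, hits$sacc,
                   sprintf("%.3f", hits$pident),
                   hits$length, hits$mismatch, hits$gapopen,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   format_evalue(hits$evalue),
                   sprintf("%.1f", hits$bitscore),
                   hits$stitle, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

format_evalue <- function(e) {
  out <- sprintf("%.2e", e)
  out[e == 0] <- "0.0"
  out
}

#' Read a gene-locus table
#'
#' TSV with header `genome_id, gene_id, start, end, strand, label`.
#' Coordinates are 1-based inclusive and kept verbatim. Rows violating
#' `start <= end`, `start >= 1`, strand in `{+,-}`, or with duplicate
#' `(genome_id, gene_id)` keys are rejected with an informative error.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of loci.
#' @export
read_loci_table <- function(path) {
  loci <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!identical(names(loci), LOCI_COLUMNS)) {
    stop("loci table must have header: ",
         paste(LOCI_COLUMNS, collapse = ", "), call. = FALSE)
  }
  for (col in c("start", "end")) {
    val <- suppressWarnings(as.integer(loci[[col]]))
    if (anyNA(val) && nrow(loci) > 0L) {
      stop("non-integer ", col, " coordinate in loci table", call. = FALSE)
    }
    loci[[col]] <- val
  }
  validate_loci(loci)
  loci
}

validate_loci <- function(loci) {
  bad <- !loci$strand %in% c("+", "-")
  if (any(bad)) {
    stop("unknown strand symbol '", loci$strand[which(bad)[1L]],
         "' (allowed: +, -)", call. = FALSE)
  }
  if (any(loci$start < 1L)) stop("locus start < 1", call. = FALSE)
  if (any(loci$start > loci$end)) {
    stop("locus with start > end: ",
         paste(loci$gene_id[loci$start > loci$end], collapse = ", "),
         call. = FALSE)
  }
  key <- paste(loci$genome_id, loci$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (genome_id, gene_id) in loci table: ",
         paste(unique(loci$gene_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  invisible(loci)
}

#' Write a gene-locus table
#'
#' @param loci Locus `data.frame` (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_table <- function(loci, path) {
  stopifnot(identical(names(loci)[seq_along(LOCI_COLUMNS)], LOCI_COLUMNS))
  validate_loci(loci)
  utils::write.table(loci[, LOCI_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
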