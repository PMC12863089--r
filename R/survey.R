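# The comparative-genomics survey: search reference PhaC/PhaE proteins
# against proteome collections, deduplicate hits, retain the best hit per
# organism per reference class, classify organisms by highest percent
# identity with the strong/weak threshold, measure query coverage, and
# tally paralog occurrence across species.

PHAC_CLASSES <- c("PhaC_Hme", "PhaC1", "PhaC2", "PhaC3")
REFERENCE_CLASSES <- c(PHAC_CLASSES, "PhaE")

#' Build a reference protein set
#'
#' Attaches a class label (`PhaC_Hme`, `PhaC1`, `PhaC2`, `PhaC3`, `PhaE`)
#' to each reference protein record. Exactly one reference per class is
#' allowed.
#'
#' @param records Protein record table with one row per reference.
#' @param class_label Character vector of class labels, parallel to
#'   `records`.
#' @return The record table with an extra `class_label` column.
#' @export
reference_set <- function(records, class_label) {
  stopifnot(nrow(records) == length(class_label))
  if (!all(class_label %in% REFERENCE_CLASSES)) {
    stop("unknown reference class: ",
         paste(setdiff(class_label, REFERENCE_CLASSES), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(class_label)) {
    stop("exactly one reference per class is allowed", call. = FALSE)
  }
  records$class_label <- class_label
  records
}

#' Search a reference against a proteome collection
#'
#' Aligns the reference against every subject and keeps, per species (the
#' `organism` field of the subjects; subjects with no organism are treated
#' as a single group), at most `config$max_targets` hits ordered by
#' descending bitscore, ties broken by ascending subject accession.
#'
#' @param reference One-row reference record (with or without class
#'   label).
#' @param proteome Protein record table of subjects.
#' @param config A [survey_config()].
#' @param db_size E-value database size; defaults to the total residue
#'   count of `proteome`.
#' @return Hit `data.frame` (possibly empty) with an `organism` column.
#' @export
search_homologs <- function(reference, proteome, config = survey_config(),
                            db_size = NULL) {
  if (nrow(proteome) == 0L) {
    stop("search_homologs requires a non-empty proteome", call. = FALSE)
  }
  if (is.null(db_size)) db_size <- sum(nchar(proteome$sequence))
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    hit <- local_align(reference, proteome[i, ], config, db_size = db_size)
    if (is.null(hit)) return(NULL)
    hit$organism <- proteome$organism[i]
    hit
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- empty_hits()
    hits$organism <- character()
    return(hits)
  }
  parts <- split(hits, ifelse(nzchar(hits$organism), hits$organism, "."))
  parts <- lapply(parts, function(h) {
    h <- h[order(-h$bitscore, h$sacc), , drop = FALSE]
    utils::head(h, config$max_targets)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(-out$bitscore, out$sacc), , drop = FALSE]
}

#' Remove duplicate hits
#'
#' Collapses hits identical on the key `(sacc, pident, length, mismatch,
#' gapopen, evalue, bitscore)` to their first occurrence, preserving
#' order otherwise. Idempotent; intended to be applied within one
#' reference class.
#'
#' @param hits Hit `data.frame`.
#' @return The deduplicated subset of `hits`.
#' @export
deduplicate_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  key <- paste(hits$sacc, hits$pident, hits$length, hits$mismatch,
               hits$gapopen, hits$evalue, hits$bitscore, sep = "\r")
  out <- hits[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one organism from its per-class hits
#'
#' For each reference class, retains the single highest-scoring unique hit
#' for the organism (descending bitscore, ties by higher pident, then
#' ascending subject accession). The organism's best class is the class
#' whose retained hit has maximal percent identity (ties by higher
#' bitscore, then the fixed class order `PhaC_Hme`, `PhaC1`, `PhaC2`,
#' `PhaC3`). The call is "strong" iff the best percent identity is at
#' least `config$weak_threshold`, otherwise "weak" — strictly below the
#' threshold means weak.
#'
#' @param hits_by_class Named list mapping reference class to a hit
#'   `data.frame` for this organism (classes with no hits may be absent
#'   or empty).
#' @param organism Organism name.
#' @param config A [survey_config()].
#' @param ref_lengths Optional named vector of reference sequence lengths
#'   used to annotate per-class query coverage.
#' @return A list of class `organism_call` with elements `organism`,
#'   `per_class` (one row per class with a retained hit: class, sacc,
#'   pident, bitscore, evalue, strong, and coverage when available),
#'   `best_class`, `best_pident`, `strength`, `query_coverage`.
#' @export
classify_organism <- function(hits_by_class, organism,
                              config = survey_config(),
                              ref_lengths = NULL) {
  hits_by_class <- hits_by_class[vapply(hits_by_class,
                                        function(h) !is.null(h) && nrow(h) > 0L,
                                        logical(1))]
  if (length(hits_by_class) == 0L) {
    stop("no hits for organism '", organism, "'", call. = FALSE)
  }
  retained <- lapply(names(hits_by_class), function(cl) {
    h <- hits_by_class[[cl]]
    h <- h[order(-h$bitscore, -h$pident, h$sacc), , drop = FALSE]
    top <- h[1L, , drop = FALSE]
    cov <- NA_real_
    if (!is.null(ref_lengths) && cl %in% names(ref_lengths)) {
      cov <- min(100, 100 * top$length / ref_lengths[[cl]])
    }
    data.frame(class = cl, sacc = top$sacc, pident = top$pident,
               length = top$length, bitscore = top$bitscore,
               evalue = top$evalue,
               strong = top$pident >= config$weak_threshold,
               query_coverage = cov, stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, retained)
  ord <- match(per_class$class, REFERENCE_CLASSES)
  per_class <- per_class[order(ord), , drop = FALSE]
  rownames(per_class) <- NULL
  # PhaE hits feed colocalization, not the paralog classification: the
  # best class is chosen among PhaC classes whenever any are present
  cand <- per_class[per_class$class %in% PHAC_CLASSES, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- per_class
  pick <- order(-cand$pident, -cand$bitscore,
                match(cand$class, REFERENCE_CLASSES))[1L]
  best <- cand[pick, ]
  structure(list(organism = organism, per_class = per_class,
                 best_class = best$class, best_pident = best$pident,
                 strength = if (best$pident >= config$weak_threshold)
                   "strong" else "weak",
                 query_coverage = best$query_coverage),
            class = "organism_call")
}

#' @export
print.organism_call <- function(x, ...) {
  cat("Organism call:", x$organism, "\n")
  cat("  best class:", x$best_class,
      sprintf("(%.1f%% identity, %s)", x$best_pident, x$strength), "\n")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Query coverage of a hit
#'
#' The alignment length expressed as a percentage of the full reference
#' (query) length, capped at 100. Coverage substantially below 100 flags
#' truncated homologs.
#'
#' @param hit One-row hit `data.frame` whose `qacc` is the reference id.
#' @param reference One-row reference record.
#' @return Coverage percent.
#' @export
query_coverage <- function(hit, reference) {
  if (!identical(hit$qacc[1L], reference$id[1L])) {
    stop("hit qacc does not match the reference id", call. = FALSE)
  }
  L <- nchar(reference$sequence[1L])
  if (L == 0L) stop("zero-length reference sequence", call. = FALSE)
  min(100, 100 * hit$length[1L] / L)
}

#' Tally paralog profiles across organisms
#'
#' Builds one paralog profile per organism — which PhaC classes have a
#' strong call (percent identity at or above the threshold), how many
#' strong classes in total — and summary statistics: the histogram of
#' paralog counts, the most prevalent count (ties resolved to the
#' smallest), per-class occurrence, and the number of species with a
#' confidently colocalized phaE-phaC pair. Weak calls are retained in the
#' calls but excluded from the tallies; PhaE hits never count as
#' paralogs.
#'
#' @param calls List of `organism_call` objects.
#' @param coloc Optional colocalization pair `data.frame` (from
#'   [infer_pairs()]) with a `genome_id` column matching organism names
#'   (spaces and underscores are treated as equivalent).
#' @return A list with `profiles` (data.frame: organism, one logical
#'   column per PhaC class, n_paralogs, coloc_established) and `summary`
#'   (list: n_species, histogram, most_prevalent, class_counts,
#'   n_colocalized).
#' @export
tally_profiles <- function(calls, coloc = NULL) {
  if (length(calls) == 0L) stop("no organism calls to tally", call. = FALSE)
  profiles <- do.call(rbind, lapply(calls, function(call) {
    pc <- call$per_class
    strong <- vapply(PHAC_CLASSES, function(cl) {
      any(pc$class == cl & pc$strong)
    }, logical(1))
    out <- data.frame(organism = call$organism, t(strong),
                      n_paralogs = sum(strong), stringsAsFactors = FALSE)
    names(out)[2:5] <- PHAC_CLASSES
    out
  }))
  rownames(profiles) <- NULL
  profiles$coloc_established <- FALSE
  if (!is.null(coloc) && nrow(coloc) > 0L) {
    est <- unique(coloc$genome_id[coloc$colocalized %in% TRUE])
    norm <- function(x) tolower(gsub("[ _]", "", x))
    profiles$coloc_established <- norm(profiles$organism) %in% norm(est)
  }
  hist_tab <- table(factor(profiles$n_paralogs, levels = 0:4))
  counts <- as.integer(hist_tab)
  names(counts) <- names(hist_tab)
  most <- as.integer(names(hist_tab)[which.max(counts)])
  class_counts <- vapply(PHAC_CLASSES, function(cl) sum(profiles[[cl]]),
                         integer(1))
  list(profiles = profiles,
       summary = list(n_species = nrow(profiles),
                      histogram = counts,
                      most_prevalent = most,
                      class_counts = class_counts,
                      n_colocalized = sum(profiles$coloc_established)))
}

#' Run the full paralog survey
#'
#' Orchestrates the survey chain — per-species homolog search for every
#' reference class, deduplication, per-organism classification with query
#' coverage, phaE-phaC colocalization (when a loci table is supplied),
#' and paralog tallying — and optionally writes `hits.tsv` (13-column
#' dialect), `calls.tsv`, `profiles.tsv` and `summary.json` to `out_dir`.
#' The run is deterministic: identical inputs produce byte-identical
#' outputs.
#'
#' @param references Reference set from [reference_set()].
#' @param proteome_paths Character vector of per-species FASTA paths.
#' @param loci_path Optional path to a gene-locus TSV for colocalization.
#' @param config A [survey_config()].
#' @param out_dir Optional output directory.
#' @param coloc_cfg A [coloc_config()] for the colocalization stage.
#' @return A list with `hits`, `calls` (list of `organism_call`),
#'   `calls_table`, `pairs`, `profiles`, `summary`.
#' @export
run_survey <- function(references, proteome_paths, loci_path = NULL,
                       config = survey_config(), out_dir = NULL,
                       coloc_cfg = coloc_config()) {
  if (length(proteome_paths) == 0L) {
    stop("no proteomes found", call. = FALSE)
  }
  if (!"PhaE" %in% references$class_label ||
      !all(PHAC_CLASSES %in% references$class_label)) {
    message("survey: reference set covers classes ",
            paste(sort(references$class_label), collapse = ", "))
  }
  proteomes <- lapply(proteome_paths, read_fasta)
  db_size <- sum(vapply(proteomes, function(p) sum(nchar(p$sequence)),
                        numeric(1)))
  ref_lengths <- stats::setNames(nchar(references$sequence),
                                 references$class_label)
  # stage 1-2: search + dedup, per reference class and species
  all_hits <- list()
  for (k in seq_len(nrow(references))) {
    cl <- references$class_label[k]
    for (p in proteomes) {
      if (nrow(p) == 0L) next
      h <- search_homologs(references[k, ], p, config, db_size = db_size)
      h <- deduplicate_hits(h)
      if (nrow(h) > 0L) {
        h$class <- cl
        all_hits[[length(all_hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else {
    h <- empty_hits(); h$organism <- character(); h$class <- character(); h
  }
  rownames(hits) <- NULL
  message("survey: ", nrow(hits), " hits after search + dedup")
  # stage 3: per-organism classification
  organisms <- sort(unique(hits$organism[nzchar(hits$organism)]))
  calls <- lapply(organisms, function(org) {
    oh <- hits[hits$organism == org, , drop = FALSE]
    by_class <- split(oh, oh$class)
    classify_organism(by_class, org, config, ref_lengths = ref_lengths)
  })
  names(calls) <- organisms
  message("survey: ", length(calls), " organisms classified")
  calls_table <- do.call(rbind, lapply(calls, function(x) {
    pc <- x$per_class
    pc$organism <- x$organism
    pc$best_class <- x$best_class
    pc$is_best <- pc$class == x$best_class
    pc$strength <- x$strength
    pc[, c("organism", "class", "sacc", "pident", "length", "bitscore",
           "evalue", "query_coverage", "strong", "is_best", "best_class",
           "strength")]
  }))
  rownames(calls_table) <- NULL
  # stage 4: colocalization
  pairs <- NULL
  if (!is.null(loci_path)) {
    loci <- read_loci_table(loci_path)
    classes <- stats::setNames(calls_table$class, calls_table$sacc)
    pairs <- infer_pairs(loci, classes = classes, config = coloc_cfg)
    message("survey: ", sum(pairs$colocalized %in% TRUE),
            " colocalized phaE-phaC pairs")
  }
  # stage 5: tally
  tally <- tally_profiles(calls, coloc = pairs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hit_table(hits, file.path(out_dir, "hits.tsv"))
    utils::write.table(calls_table, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tally$profiles, file.path(out_dir, "profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(pairs)) {
      utils::write.table(pairs, file.path(out_dir, "pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(tally$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(hits = hits, calls = calls, calls_table = calls_table,
       pairs = pairs, profiles = tally$profiles, summary = tally$summary)
}
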