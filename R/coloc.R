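# phaE-phaC colocalization: pair each phaE gene with the nearest
# phaC-encoding gene in the same genome by the coordinate distance
# |start(phaC) - end(phaE)|, and flag likely phaEC operon organization.

#' Colocalization configuration
#'
#' @param max_distance Maximum base-pair distance for a pair to be called
#'   colocalized (default 1000 bp). The raw distance is always reported so
#'   results can be re-thresholded.
#' @param require_same_replicon Require the partner on the same replicon
#'   (default `TRUE`). Replicon identity is taken from an optional
#'   `replicon` column of the loci table; without one, loci grouped under
#'   one `genome_id` are assumed co-replicon.
#' @param strand_aware If `TRUE`, distance is measured between the
#'   downstream end of phaE and the strand-corrected start of the
#'   candidate. Off by default: the plain `|start - end|` formula is the
#'   primary definition.
#' @return A list of class `coloc_config`.
#' @export
coloc_config <- function(max_distance = 1000, require_same_replicon = TRUE,
                         strand_aware = FALSE) {
  stopifnot(max_distance > 0)
  structure(list(max_distance = max_distance,
                 require_same_replicon = require_same_replicon,
                 strand_aware = strand_aware),
            class = "coloc_config")
}

locus_replicon <- function(loci) {
  if ("replicon" %in% names(loci)) loci$replicon else loci$genome_id
}

candidate_start <- function(cand, strand_aware) {
  if (strand_aware) ifelse(cand$strand == "+", cand$start, cand$end)
  else cand$start
}

#' Nearest phaC partner of one phaE locus
#'
#' Among candidate loci of the same genome, returns the one minimizing
#' `|start(candidate) - end(phaE)|`; ties are broken by smaller start
#' coordinate, then lexicographic gene id. The pair is colocalized when
#' the partner lies within `max_distance` (and on the same replicon, if
#' required). With no candidates the pair has an absent partner and is not
#' colocalized.
#'
#' @param phaE One-row locus `data.frame` for the phaE gene.
#' @param candidates Locus `data.frame` of phaC candidates in the same
#'   genome (may be empty).
#' @param config A [coloc_config()].
#' @return One-row `data.frame`: `genome_id`, `phaE_gene`, `phaC_gene`,
#'   `distance`, `same_replicon`, `colocalized`.
#' @export
nearest_partner <- function(phaE, candidates, config = coloc_config()) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(data.frame(genome_id = phaE$genome_id, phaE_gene = phaE$gene_id,
                      phaC_gene = NA_character_, distance = NA_real_,
                      same_replicon = NA, colocalized = FALSE,
                      stringsAsFactors = FALSE))
  }
  d <- abs(candidate_start(candidates, config$strand_aware) - phaE$end)
  pick <- order(d, candidates$start, candidates$gene_id)[1L]
  best <- candidates[pick, ]
  same_rep <- identical(locus_replicon(best), locus_replicon(phaE))
  coloc <- d[pick] <= config$max_distance &&
    (!config$require_same_replicon || same_rep)
  data.frame(genome_id = phaE$genome_id, phaE_gene = phaE$gene_id,
             phaC_gene = best$gene_id, distance = as.numeric(d[pick]),
             same_replicon = same_rep, colocalized = coloc,
             stringsAsFactors = FALSE)
}

#' Infer phaE-phaC pairs across a loci table
#'
#' For every locus labeled `phaE`, finds the nearest phaC-labeled locus
#' within the same genome and annotates the partner's paralog class when
#' a gene-to-class mapping is available. Output is sorted by genome and
#' phaE gene id and is therefore invariant to the input row order. Rare
#' multi-phaE genomes yield one pair per phaE gene.
#'
#' @param loci Locus `data.frame` in the [read_loci_table()] layout; phaE
#'   loci have label `phaE`, candidates any label starting with `phaC`.
#' @param classes Optional named character vector mapping gene ids (as
#'   used in the loci table) to paralog classes.
#' @param config A [coloc_config()].
#' @return A pair `data.frame`, one row per phaE locus, with an extra
#'   `phaC_class` column.
#' @export
infer_pairs <- function(loci, classes = NULL, config = coloc_config()) {
  validate_loci(loci)
  is_e <- loci$label == "phaE"
  is_c <- grepl("^phaC", loci$label)
  phaE_loci <- loci[is_e, , drop = FALSE]
  pairs <- lapply(seq_len(nrow(phaE_loci)), function(i) {
    e <- phaE_loci[i, ]
    cand <- loci[is_c & loci$genome_id == e$genome_id, , drop = FALSE]
    nearest_partner(e, cand, config)
  })
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(genome_id = character(), phaE_gene = character(),
               phaC_gene = character(), distance = numeric(),
               same_replicon = logical(), colocalized = logical(),
               stringsAsFactors = FALSE)
  out$phaC_class <- NA_character_
  if (!is.null(classes) && nrow(out) > 0L) {
    known <- out$phaC_gene %in% names(classes)
    out$phaC_class[known] <- unname(classes[out$phaC_gene[known]])
  }
  out <- out[order(out$genome_id, out$phaE_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
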