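# Deterministic synthetic-data generators. They produce every input the
# analysis modules consume -- proteomes with homologs planted at
# controlled percent identity, loci tables with planted phaE-phaC
# distances, Ct tables with planted fold changes and amplification
# efficiencies, and NMR methine peak lists with planted 3HV fractions --
# together with ground-truth sidecar tables, so that every downstream
# module can be validated by planted-truth recovery. Each generator takes
# one integer seed; all draws flow from it and the caller's RNG state is
# left untouched.

#' Random protein sequence
#'
#' Uniform draw over the 20 standard amino acids.
#'
#' @param length Sequence length.
#' @param id,description,organism Record metadata.
#' @return A one-row protein record table.
#' @export
random_protein <- function(length, id = "RND_1", description = "",
                           organism = "") {
  protein_records(id, paste(sample(AA_STANDARD, length, replace = TRUE),
                            collapse = ""),
                  description = description, organism = organism)
}

#' Synthetic reference protein set
#'
#' A fixed, seeded set of five synthetic reference proteins standing in
#' for the PhaC_Hme/PhaC1/PhaC2/PhaC3 synthase subunits and the PhaE
#' subunit, with lengths in the range of real class III PHA synthase
#' subunits (PhaC around 300-520 aa, PhaE short). The sequences are
#' random, hence mutually unrelated: cross-class identities stay near the
#' random-alignment background, which is what the planted-identity
#' recovery tests require. Ids carry a `SYNREF_` prefix to mark them as
#' synthetic.
#'
#' @param seed Integer seed.
#' @return A reference set (see [reference_set()]).
#' @export
example_reference_set <- function(seed = 101L) {
  local_rng(seed)
  lens <- c(PhaC_Hme = 490L, PhaC1 = 470L, PhaC2 = 304L, PhaC3 = 520L,
            PhaE = 190L)
  recs <- do.call(rbind, lapply(names(lens), function(cl) {
    random_protein(lens[[cl]], id = paste0("SYNREF_", toupper(cl)),
                   description = sprintf("synthetic %s reference", cl))
  }))
  reference_set(recs, names(lens))
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes residues of the reference so that the percent identity of
#' the mutant to the reference, re-measured with [local_align()] under
#' the given scoring configuration, lands within 3 percentage points of
#' the target. Substitution positions are stratified along the sequence
#' (so no long native run survives and the local alignment keeps covering
#' the full sequence) and replacement residues are drawn biased toward
#' high-scoring substitution pairs, which preserves local alignability.
#' No indels are introduced. Deterministic for a fixed seed.
#'
#' @param reference One-row protein record.
#' @param target_identity Target percent identity in (25, 100]; values
#'   below 25 are refused because alignability of the mutant can no
#'   longer be guaranteed.
#' @param seed Integer seed.
#' @param config Scoring configuration used for the re-measurement.
#' @return A one-row protein record with id `<ref id>_m<target>`.
#' @export
mutate_to_identity <- function(reference, target_identity, seed,
                               config = survey_config()) {
  if (target_identity <= 0 || target_identity > 100) {
    stop("target identity must lie in (0, 100]", call. = FALSE)
  }
  if (target_identity < 25) {
    stop("target identity below 25% refused: local alignability of the ",
         "mutant cannot be guaranteed at that divergence", call. = FALSE)
  }
  local_rng(seed)
  seq <- strsplit(reference$sequence[1L], "")[[1L]]
  L <- length(seq)
  mat <- load_substitution_matrix(config$matrix)
  n_sub <- round(L * (1 - target_identity / 100))
  mutated <- mutate_positions(seq, stratified_positions(L, n_sub), mat)
  out <- protein_records(paste0(reference$id[1L], "_m",
                                round(target_identity)),
                         paste(mutated, collapse = ""),
                         description = reference$description[1L],
                         organism = reference$organism[1L])
  # adjust until the aligner-measured identity is within +/- 3 points
  meas_cfg <- survey_config(matrix = config$matrix,
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend,
                            min_pident = 0)
  for (iter in seq_len(25L)) {
    hit <- local_align(reference, out, meas_cfg)
    pid <- if (is.null(hit)) 0 else hit$pident
    if (abs(pid - target_identity) <= 3) break
    if (pid > target_identity) {
      intact <- which(mutated == seq)
      k <- max(1L, round(L * (pid - target_identity) / 200))
      mutated <- mutate_positions(mutated,
                                  resample(intact, min(k, length(intact))),
                                  mat, original = seq)
    } else {
      changed <- which(mutated != seq)
      k <- max(1L, round(L * (target_identity - pid) / 200))
      revert <- resample(changed, min(k, length(changed)))
      mutated[revert] <- seq[revert]
    }
    out$sequence <- paste(mutated, collapse = "")
  }
  out
}

# size-safe sample (sample() on a length-1 vector samples 1:x)
resample <- function(x, n) x[sample.int(length(x), n)]

stratified_positions <- function(L, n_sub) {
  if (n_sub <= 0L) return(integer())
  bounds <- as.integer(round(seq(0L, L, length.out = n_sub + 1L)))
  vapply(seq_len(n_sub), function(i) {
    lo <- bounds[i] + 1L
    hi <- max(lo, bounds[i + 1L])
    if (hi > lo) resample(lo:hi, 1L) else lo
  }, integer(1))
}

# replace residues at the given positions, drawing each replacement among
# the 19 non-identical residues with probability proportional to
# exp(score/2) under the substitution matrix
mutate_positions <- function(seq, positions, mat, original = seq) {
  for (p in positions) {
    a <- original[p]
    others <- setdiff(AA_STANDARD, a)
    w <- exp(mat[a, others] / 2)
    seq[p] <- sample(others, 1L, prob = w / sum(w))
  }
  seq
}

#' Truncate a protein from both termini
#'
#' Keeps the central `round(fraction * length)` residues, removing the
#' rest split as evenly as possible between the N- and C-termini (the
#' truncation pattern of naturally shortened synthase paralogs).
#'
#' @param record One-row protein record.
#' @param fraction Retained length fraction in (0, 1].
#' @return The truncated record.
#' @export
truncate_record <- function(record, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  L <- nchar(record$sequence[1L])
  keep <- round(fraction * L)
  drop_n <- floor((L - keep) / 2)
  record$sequence <- substr(record$sequence[1L], drop_n + 1L, drop_n + keep)
  record
}

#' Planted truth for one surveyed species
#'
#' @param species Species name (unique within a dataset).
#' @param hits `data.frame` with columns `class` (reference class),
#'   `identity` (target percent identity in (25, 100]) and optionally
#'   `truncation` (retained fraction in (0, 1], default 1).
#' @param phaE_present Plant a PhaE homolog?
#' @param phaE_identity Target identity of the planted PhaE homolog.
#' @param phaE_to_phaC_distance Signed planted distance (bp) between the
#'   phaE gene end and the nearest planted phaC gene start; `NA` places
#'   the genes far apart.
#' @return A list of class `survey_truth`.
#' @export
survey_truth <- function(species, hits, phaE_present = FALSE,
                         phaE_identity = 85,
                         phaE_to_phaC_distance = NA_real_) {
  stopifnot(is.data.frame(hits), nrow(hits) >= 1L,
            all(c("class", "identity") %in% names(hits)))
  if (!"truncation" %in% names(hits)) hits$truncation <- 1
  if (!all(hits$class %in% PHAC_CLASSES)) {
    stop("planted hit classes must be PhaC classes", call. = FALSE)
  }
  stopifnot(all(hits$identity > 0 & hits$identity <= 100),
            all(hits$truncation > 0 & hits$truncation <= 1))
  structure(list(species = species, hits = hits,
                 phaE_present = phaE_present,
                 phaE_identity = phaE_identity,
                 phaE_to_phaC_distance = phaE_to_phaC_distance),
            class = "survey_truth")
}

#' Generate a synthetic survey dataset
#'
#' Writes, for each planted truth, a species proteome FASTA containing
#' one mutated (and possibly truncated) homolog per planted hit, a PhaE
#' homolog when requested, and `n_decoys` unrelated decoy proteins;
#' a combined gene-locus TSV in which each phaE gene sits at the planted
#' signed distance from its nearest phaC gene; and a ground-truth sidecar
#' TSV. Decoys are random-composition sequences of unrelated length,
#' rejection-sampled at generation time so that none aligns to any
#' reference at 40% identity or more. Byte-identical outputs for a fixed
#' seed.
#'
#' @param truths List of [survey_truth()] objects (unique species).
#' @param references Reference set covering the planted classes (and
#'   PhaE, when any truth plants one).
#' @param dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param n_decoys Decoy proteins per species (default 20).
#' @param config Scoring configuration for identity targeting and the
#'   decoy-safety check.
#' @return A list: `proteome_paths`, `loci_path`, `truth_path`, `truth`
#'   (the sidecar `data.frame`), `loci`.
#' @export
generate_survey_dataset <- function(truths, references, dir, seed,
                                    n_decoys = 20L,
                                    config = survey_config()) {
  species <- vapply(truths, function(x) x$species, character(1))
  if (anyDuplicated(species)) {
    stop("duplicate species names: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  need_phaE <- any(vapply(truths, function(x) x$phaE_present, logical(1)))
  planted_classes <- unique(unlist(lapply(truths, function(x) x$hits$class)))
  missing_cls <- setdiff(c(planted_classes, if (need_phaE) "PhaE"),
                         references$class_label)
  if (length(missing_cls)) {
    stop("reference set lacks classes: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  local_rng(seed)
  meas_cfg <- survey_config(matrix = config$matrix,
                            gap_open = config$gap_open,
                            gap_extend = config$gap_extend, min_pident = 0)
  proteome_paths <- character(length(truths))
  loci_rows <- list()
  truth_rows <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    genome <- gsub(" ", "_", tr$species)
    sp_seed <- sample.int(.Machine$integer.max, 1L)
    planted <- list()
    for (j in seq_len(nrow(tr$hits))) {
      cl <- tr$hits$class[j]
      ref <- references[references$class_label == cl, ]
      mut <- mutate_to_identity(ref, tr$hits$identity[j],
                                seed = sp_seed + j, config = config)
      mut <- truncate_record(mut, tr$hits$truncation[j])
      mut$id <- sprintf("%s_%s", genome, cl)
      mut$description <- sprintf("%s-like PHA synthase [%s]", cl, tr$species)
      mut$organism <- tr$species
      planted[[length(planted) + 1L]] <- mut
    }
    if (tr$phaE_present) {
      ref <- references[references$class_label == "PhaE", ]
      mut <- mutate_to_identity(ref, tr$phaE_identity,
                                seed = sp_seed + nrow(tr$hits) + 1L,
                                config = config)
      mut$id <- sprintf("%s_PhaE", genome)
      mut$description <- sprintf("PhaE subunit [%s]", tr$species)
      mut$organism <- tr$species
      planted[[length(planted) + 1L]] <- mut
    }
    decoys <- make_decoys(n_decoys, references, meas_cfg, genome, tr$species)
    proteome <- do.call(rbind, c(planted, list(decoys)))
    path <- file.path(dir, paste0(genome, ".fasta"))
    write_fasta(proteome, path)
    proteome_paths[i] <- path
    loci_rows[[i]] <- plant_loci(tr, genome)
    truth_rows[[i]] <- data.frame(
      species = tr$species, class = tr$hits$class,
      target_identity = tr$hits$identity,
      truncation = tr$hits$truncation,
      gene_id = sprintf("%s_%s", genome, tr$hits$class),
      phaE_present = tr$phaE_present,
      phaE_to_phaC_distance = tr$phaE_to_phaC_distance,
      stringsAsFactors = FALSE)
  }
  loci <- do.call(rbind, loci_rows)
  truth <- do.call(rbind, truth_rows)
  loci_path <- file.path(dir, "loci.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  write_loci_table(loci, loci_path)
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(proteome_paths = proteome_paths, loci_path = loci_path,
       truth_path = truth_path, truth = truth, loci = loci)
}

# rejection-sample decoys until none aligns to any reference at >= 40%
# identity
make_decoys <- function(n_decoys, references, meas_cfg, genome, organism) {
  recs <- list()
  for (k in seq_len(n_decoys)) {
    for (try in seq_len(200L)) {
      len <- sample(100:400, 1L)
      cand <- random_protein(len, id = sprintf("%s_DECOY%02d", genome, k),
                             description = sprintf("hypothetical protein [%s]",
                                                   organism),
                             organism = organism)
      pid <- vapply(seq_len(nrow(references)), function(r) {
        hit <- local_align(references[r, ], cand, meas_cfg)
        if (is.null(hit)) 0 else hit$pident
      }, numeric(1))
      if (all(pid < 40)) break
      if (try == 200L) stop("could not generate a safe decoy", call. = FALSE)
    }
    recs[[k]] <- cand
  }
  do.call(rbind, recs)
}

# gene coordinates: the phaE gene (when present) is paired with the first
# planted phaC gene at the requested signed start-minus-end distance; all
# other genes are spaced >= 40 kb apart so the planted partner is the
# nearest by construction
plant_loci <- function(tr, genome) {
  rows <- list()
  base <- 50000L
  aa_bp <- function(aa_len) 3L * aa_len
  gene_len <- 1500L
  if (tr$phaE_present && !is.na(tr$phaE_to_phaC_distance)) {
    e_start <- 10000L
    e_end <- e_start + gene_len - 1L
    rows[[1]] <- data.frame(genome_id = genome,
                            gene_id = sprintf("%s_PhaE", genome),
                            start = e_start, end = e_end, strand = "+",
                            label = "phaE", stringsAsFactors = FALSE)
    c_start <- as.integer(e_end + tr$phaE_to_phaC_distance)
    if (c_start < 1L) stop("planted distance places phaC before position 1",
                           call. = FALSE)
    rows[[2]] <- data.frame(genome_id = genome,
                            gene_id = sprintf("%s_%s", genome,
                                              tr$hits$class[1L]),
                            start = c_start, end = c_start + gene_len - 1L,
                            strand = "+", label = "phaC-like",
                            stringsAsFactors = FALSE)
    rest <- tr$hits$class[-1L]
  } else {
    if (tr$phaE_present) {
      rows[[1]] <- data.frame(genome_id = genome,
                              gene_id = sprintf("%s_PhaE", genome),
                              start = 10000L, end = 10000L + gene_len - 1L,
                              strand = "+", label = "phaE",
                              stringsAsFactors = FALSE)
    }
    rest <- tr$hits$class
  }
  for (k in seq_along(rest)) {
    s <- base + (k - 1L) * 40000L
    rows[[length(rows) + 1L]] <-
      data.frame(genome_id = genome,
                 gene_id = sprintf("%s_%s", genome, rest[k]),
                 start = s, end = s + gene_len - 1L, strand = "+",
                 label = "phaC-like", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' qPCR simulation specification
#'
#' Defines the measurement process the Ct generator emulates: per-gene
#' amplification efficiencies, planted fold changes of each non-calibrator
#' condition relative to the first (calibrator) condition, stably
#' expressed reference genes, replicate structure, Gaussian Ct noise on
#' the cycle scale, and the 10-fold dilution series behind each standard
#' curve.
#'
#' @param genes Target gene names.
#' @param reference_genes Reference gene names (planted unchanged across
#'   conditions).
#' @param conditions Condition labels; the first is the calibrator.
#' @param fold_changes Named list: for each target gene, a named numeric
#'   vector of fold changes (> 0) per non-calibrator condition.
#' @param efficiencies Named amplification efficiencies in (1, 2.2]
#'   (default 2 for every gene).
#' @param baseline_ct Calibrator-condition Ct (scalar or named per gene;
#'   default 22 cycles).
#' @param n_bio,n_tech Biological / technical replicates (>= 1).
#' @param ct_noise_sd Gaussian Ct noise standard deviation in cycles
#'   (>= 0).
#' @param dilution_points Points in each 10-fold dilution series
#'   (>= 3).
#' @return A list of class `qpcr_sim_spec`.
#' @export
qpcr_sim_spec <- function(genes, reference_genes, conditions, fold_changes,
                          efficiencies = NULL, baseline_ct = 22,
                          n_bio = 3L, n_tech = 2L, ct_noise_sd = 0,
                          dilution_points = 5L) {
  all_genes <- c(genes, reference_genes)
  stopifnot(length(conditions) >= 2L, n_bio >= 1L, n_tech >= 1L,
            ct_noise_sd >= 0, dilution_points >= 3L)
  if (is.null(efficiencies)) {
    efficiencies <- stats::setNames(rep(2, length(all_genes)), all_genes)
  }
  if (!all(all_genes %in% names(efficiencies))) {
    stop("efficiencies missing for some genes", call. = FALSE)
  }
  if (any(efficiencies <= 1 | efficiencies > 2.2)) {
    stop("amplification efficiencies must lie in (1, 2.2]", call. = FALSE)
  }
  if (!all(genes %in% names(fold_changes))) {
    stop("fold_changes missing for some target genes", call. = FALSE)
  }
  other <- conditions[-1L]
  for (g in genes) {
    fc <- fold_changes[[g]]
    if (!all(other %in% names(fc))) {
      stop("fold change for gene '", g, "' missing conditions", call. = FALSE)
    }
    if (any(fc <= 0)) stop("fold changes must be > 0", call. = FALSE)
  }
  if (length(baseline_ct) == 1L && is.null(names(baseline_ct))) {
    baseline_ct <- stats::setNames(rep(baseline_ct, length(all_genes)),
                                   all_genes)
  }
  structure(list(genes = genes, reference_genes = reference_genes,
                 conditions = conditions, fold_changes = fold_changes,
                 efficiencies = efficiencies, baseline_ct = baseline_ct,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 ct_noise_sd = ct_noise_sd,
                 dilution_points = as.integer(dilution_points)),
            class = "qpcr_sim_spec")
}

#' Generate a synthetic RT-qPCR dataset
#'
#' Simulates Ct values for every (gene, condition, biological replicate,
#' technical replicate): `Ct = baseline - log_E(template) + N(0, sd)`,
#' where the relative template is 1 in the calibrator condition and the
#' planted fold change elsewhere (reference genes stay at 1 everywhere).
#' Also emits a 10-fold dilution series per gene consistent with the
#' planted efficiency (successive dilutions differ by `log_E(10)` cycles)
#' and a ground-truth sidecar. Deterministic for a fixed seed.
#'
#' @param spec A [qpcr_sim_spec()].
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes `ct.csv`,
#'   `dilutions.csv` and `qpcr_truth.tsv`.
#' @return A list: `ct` (long-format Ct table), `dilutions`
#'   (gene, log10_quantity, ct), `truth`.
#' @export
generate_qpcr_dataset <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "qpcr_sim_spec"))
  local_rng(seed)
  all_genes <- c(spec$genes, spec$reference_genes)
  template <- function(g, cond) {
    if (cond == spec$conditions[1L] || g %in% spec$reference_genes) 1
    else spec$fold_changes[[g]][[cond]]
  }
  grid <- expand.grid(tech_rep = seq_len(spec$n_tech),
                      bio_rep = seq_len(spec$n_bio),
                      condition = spec$conditions, gene = all_genes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("gene", "condition", "bio_rep", "tech_rep")]
  e <- spec$efficiencies
  ct0 <- mapply(function(g, cond) {
    spec$baseline_ct[[g]] - log(template(g, cond)) / log(e[[g]])
  }, grid$gene, grid$condition)
  grid$ct <- ct0 + stats::rnorm(nrow(grid), 0, spec$ct_noise_sd)
  dil <- expand.grid(log10_quantity = seq(spec$dilution_points - 1L, 0L),
                     gene = all_genes, stringsAsFactors = FALSE)
  dil <- dil[, c("gene", "log10_quantity")]
  slope <- -1 / log10(e[dil$gene])
  dil$ct <- spec$baseline_ct[dil$gene] + slope * dil$log10_quantity +
    stats::rnorm(nrow(dil), 0, spec$ct_noise_sd)
  rownames(grid) <- rownames(dil) <- NULL
  truth <- do.call(rbind, lapply(all_genes, function(g) {
    data.frame(gene = g, condition = spec$conditions,
               relative_template = vapply(spec$conditions, template,
                                          numeric(1), g = g),
               efficiency = e[[g]], baseline_ct = spec$baseline_ct[[g]],
               is_reference = g %in% spec$reference_genes,
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(grid, file.path(dir, "ct.csv"), row.names = FALSE)
    utils::write.csv(dil, file.path(dir, "dilutions.csv"),
                     row.names = FALSE)
    utils::write.table(truth, file.path(dir, "qpcr_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(ct = grid, dilutions = dil, truth = truth)
}

#' NMR simulation specification
#'
#' @param hv_mole_fraction Planted 3HV mole fraction in [0, 1].
#' @param total_methine_integral Total methine area (arbitrary units).
#' @param shift_3HB,shift_3HV Peak positions in ppm (must be distinct and
#'   fall in the default assignment windows unless custom windows are
#'   used downstream).
#' @param integral_noise_sd Multiplicative integral noise (fraction,
#'   >= 0).
#' @param extra_peaks Optional `data.frame` with `shift_ppm`, `integral`
#'   rows appended as-is (e.g. residual solvent).
#' @return A list of class `nmr_sim_spec`.
#' @export
nmr_sim_spec <- function(hv_mole_fraction, total_methine_integral = 100,
                         shift_3HB = 5.25, shift_3HV = 5.16,
                         integral_noise_sd = 0, extra_peaks = NULL) {
  stopifnot(hv_mole_fraction >= 0, hv_mole_fraction <= 1,
            total_methine_integral > 0, integral_noise_sd >= 0,
            shift_3HB != shift_3HV)
  structure(list(hv_mole_fraction = hv_mole_fraction,
                 total_methine_integral = total_methine_integral,
                 shift_3HB = shift_3HB, shift_3HV = shift_3HV,
                 integral_noise_sd = integral_noise_sd,
                 extra_peaks = extra_peaks),
            class = "nmr_sim_spec")
}

#' Generate a synthetic NMR methine peak list
#'
#' Emits a 3HB methine peak with integral proportional to
#' `1 - hv_mole_fraction` and a 3HV methine peak proportional to
#' `hv_mole_fraction`, each multiplied by `(1 + N(0, noise))` (clamped at
#' zero), plus any extra peaks, with the planted fraction recorded in the
#' truth sidecar. Deterministic for a fixed seed.
#'
#' @param spec An [nmr_sim_spec()].
#' @param seed Integer seed.
#' @param dir Optional output directory; writes `peaks.csv` and
#'   `nmr_truth.tsv` when given.
#' @return A list: `peaks` (`shift_ppm`, `integral`), `truth`.
#' @export
generate_nmr_peaklist <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "nmr_sim_spec"))
  local_rng(seed)
  noise <- stats::rnorm(2L, 0, spec$integral_noise_sd)
  I_B <- max(0, spec$total_methine_integral * (1 - spec$hv_mole_fraction) *
               (1 + noise[1L]))
  I_V <- max(0, spec$total_methine_integral * spec$hv_mole_fraction *
               (1 + noise[2L]))
  peaks <- data.frame(shift_ppm = c(spec$shift_3HB, spec$shift_3HV),
                      integral = c(I_B, I_V))
  if (!is.null(spec$extra_peaks)) {
    peaks <- rbind(peaks,
                   spec$extra_peaks[, c("shift_ppm", "integral")])
  }
  truth <- data.frame(hv_mole_fraction = spec$hv_mole_fraction,
                      total_methine_integral = spec$total_methine_integral)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(peaks, file.path(dir, "peaks.csv"), row.names = FALSE)
    utils::write.table(truth, file.path(dir, "nmr_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(peaks = peaks, truth = truth)
}

# seed the RNG for the enclosing function call, restoring the caller's
# RNG state on exit
local_rng <- function(seed, env = parent.frame()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_preserve_seed(.local_envir = env)
  set.seed(as.integer(seed))
}
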