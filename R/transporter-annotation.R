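#' Identification and classification of transporter protein encoding genes
#'
#' Genes with at least one predicted transmembrane helix are transporter
#' protein encoding gene candidates (TPGC).  Each candidate is aligned
#' against every entry of a TC-numbered reference database with an in-house
#' affine-gap Smith-Waterman aligner; entries whose alignment similarity
#' reaches a helix-dependent threshold are kept, their TC family numbers
#' and substrates are scored with the same frequency/taxonomy scorer used
#' for EC numbers, and the best family is rolled up to its superfamily
#' (TCS, three-component) number.  The reference database's organism span
#' is too narrow for a meaningful taxonomy term, so the taxonomy score of a
#' TC label is set equal to its frequency score (the convex combination is
#' then the frequency itself, whatever the alpha).
#'
#' @name transporter-annotation
NULL

#' Smith-Waterman alignment parameters
#'
#' @param matrix_name substitution matrix for ordinary queries
#'   (`"BLOSUM62"`); short queries switch to `"PAM30"`, which is better
#'   suited to short, highly similar segments.
#' @param short_sequence_cutoff queries shorter than this many residues use
#'   PAM30.
#' @param gap_open,gap_extend affine gap penalties: a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return an `sw_params` list.
#' @export
sw_params <- function(matrix_name = "BLOSUM62", short_sequence_cutoff = 35L,
                      gap_open = 10, gap_extend = 0.5) {
  stopifnot(matrix_name %in% c("BLOSUM62", "PAM30"),
            gap_open >= gap_extend, gap_extend > 0)
  structure(list(matrix_name = matrix_name,
                 short_sequence_cutoff = as.integer(short_sequence_cutoff),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "sw_params")
}

# substitution matrices shipped with Biostrings, fetched once per session
.matrix_cache <- new.env(parent = emptyenv())
.get_sub_matrix <- function(name) {
  if (!exists(name, envir = .matrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache)
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman with full traceback.  Positives are aligned
#' residue pairs with a positive substitution score; the alignment length
#' counts gap columns.  The similarity fraction is
#' `positives / alignment_length` (0 for an empty alignment).
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param params an [sw_params()]; `matrix` overrides the matrix choice.
#' @param matrix optional explicit matrix name (`"BLOSUM62"` or `"PAM30"`).
#' @return an `sw_alignment` list: `score`, `alignment_length`,
#'   `identities`, `positives`, `similarity_fraction`,
#'   `identity_fraction`, `aligned_a`, `aligned_b`, `matrix`.
#' @export
smith_waterman <- function(seq_a, seq_b, params = sw_params(), matrix = NULL) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  mat_name <- if (is.null(matrix)) params$matrix_name else matrix
  sub <- .get_sub_matrix(mat_name)
  res <- sw_align_cpp(seq_a, seq_b, sub, rownames(sub),
                      params$gap_open, params$gap_extend)
  len <- res$alignment_length
  structure(list(
    score = res$score, alignment_length = len,
    identities = res$identities, positives = res$positives,
    similarity_fraction = if (len > 0) res$positives / len else 0,
    identity_fraction = if (len > 0) res$identities / len else 0,
    aligned_a = res$aligned_a, aligned_b = res$aligned_b,
    matrix = mat_name
  ), class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %.1f (%s), length %d, %d id / %d pos (sim %.3f)\n",
              x$score, x$matrix, x$alignment_length, x$identities,
              x$positives, x$similarity_fraction))
  if (x$alignment_length > 0) cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Transporter classification configuration
#'
#' @param base_threshold alignment similarity required of a single-helix
#'   candidate (default 10%, suited to a small reference database).
#' @param threshold_floor lower clamp of the helix-scaled threshold, so
#'   many-helix candidates cannot be matched on single-residue junk
#'   alignments.
#' @param min_helices minimum predicted transmembrane helices for a gene to
#'   be a TPGC.
#' @param similarity_measure `"positives"` (default) scores similarity as
#'   positives per alignment column; `"identities"` uses exact identities
#'   instead (for sensitivity analysis).
#' @return a `transporter_config` list.
#' @export
transporter_config <- function(base_threshold = 0.10, threshold_floor = 0.02,
                               min_helices = 1L,
                               similarity_measure = c("positives", "identities")) {
  stopifnot(threshold_floor <= base_threshold,
            base_threshold >= 0, base_threshold <= 1, threshold_floor >= 0)
  structure(list(base_threshold = base_threshold,
                 threshold_floor = threshold_floor,
                 min_helices = as.integer(min_helices),
                 similarity_measure = match.arg(similarity_measure)),
            class = "transporter_config")
}

#' Select transporter protein encoding gene candidates
#'
#' @param tm_predictions data.frame from [read_tm()].
#' @param config a [transporter_config()].
#' @return character vector of TPGC locus tags.
#' @export
filter_tpgc <- function(tm_predictions, config = transporter_config()) {
  tm_predictions$locus_tag[tm_predictions$helices >= config$min_helices]
}

#' Helix-dependent similarity threshold
#'
#' The base threshold is divided by the helix count ("inversely to the
#' number of transmembrane helices") and clamped below at the floor:
#' `max(base / helix_count, floor)`.  Candidates with many transmembrane
#' helices are structurally constrained, so weaker global similarity to a
#' reference transporter is still informative.
#'
#' @param base,floor thresholds in `[0,1]`, `floor <= base`.
#' @param helix_count predicted helix count, at least 1.
#' @return the effective threshold.
#' @export
effective_threshold <- function(base, floor, helix_count) {
  if (helix_count < 1L) stop("helix_count must be >= 1")
  max(base / helix_count, floor)
}

# frequency scoring of label sets over the kept reference entries; the
# taxonomy term is set equal to the frequency term (see module docs), so the
# combined score is the frequency
.score_tc_labels <- function(labels_per_entry) {
  n <- length(labels_per_entry)
  labels <- sort(unique(unlist(labels_per_entry)))
  if (!length(labels)) {
    return(data.frame(label = character(0), score_frequency = numeric(0),
                      score_annotation = numeric(0), supporting_hits = integer(0),
                      stringsAsFactors = FALSE))
  }
  supp <- vapply(labels, function(lab) {
    sum(vapply(labels_per_entry, function(ls) lab %in% ls, logical(1)))
  }, integer(1))
  f <- supp / n
  out <- data.frame(label = labels, score_frequency = f,
                    score_annotation = f, supporting_hits = supp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score_annotation, -out$supporting_hits, out$label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one transporter candidate against the TC database
#'
#' Aligns the candidate sequence to every reference entry (PAM30 for
#' queries shorter than the cutoff, BLOSUM62 otherwise), keeps entries
#' whose similarity reaches the helix-scaled threshold, scores the distinct
#' four-component TC family prefixes and the substrates over the kept
#' entries, and rolls the winning family up to its three-component
#' superfamily (TCS) number.  A candidate with no kept entry is discarded.
#'
#' @param locus locus tag of the candidate.
#' @param sequence candidate protein sequence.
#' @param helix_count predicted transmembrane helices (>= 1).
#' @param tcdb reference database from [read_tcdb()].
#' @param params an [sw_params()].
#' @param config a [transporter_config()].
#' @return a `transporter_call` list: `locus`, `status` (`annotated` /
#'   `discarded`), `tcs_number`, `best_family`, `substrates`,
#'   `family_scores`, `substrate_scores`, `kept` (per-entry similarity
#'   table), `threshold`.
#' @export
classify_tc <- function(locus, sequence, helix_count, tcdb,
                        params = sw_params(), config = transporter_config()) {
  if (is.null(tcdb) || !nrow(tcdb)) stop("empty TC reference database")
  matrix <- if (nchar(sequence) < params$short_sequence_cutoff) "PAM30"
            else params$matrix_name
  thr <- effective_threshold(config$base_threshold, config$threshold_floor,
                             helix_count)
  sims <- numeric(nrow(tcdb))
  for (i in seq_len(nrow(tcdb))) {
    aln <- smith_waterman(sequence, tcdb$sequence[i], params, matrix = matrix)
    sims[i] <- if (config$similarity_measure == "positives")
      aln$similarity_fraction else aln$identity_fraction
  }
  keep <- sims >= thr
  kept <- data.frame(accession = tcdb$accession[keep],
                     tc_number = tcdb$tc_number[keep],
                     similarity = sims[keep], stringsAsFactors = FALSE)
  if (!nrow(kept)) {
    return(structure(list(
      locus = locus, status = "discarded", tcs_number = NA_character_,
      best_family = NA_character_, substrates = character(0),
      family_scores = .score_tc_labels(list()),
      substrate_scores = .score_tc_labels(list()),
      kept = kept, threshold = thr
    ), class = "transporter_call"))
  }
  fam_scores <- .score_tc_labels(as.list(tc_prefix(kept$tc_number, 4L)))
  sub_scores <- .score_tc_labels(tcdb$substrates[keep])
  best_family <- fam_scores$label[1]
  top_subs <- if (nrow(sub_scores)) {
    sub_scores$label[sub_scores$score_annotation ==
                     max(sub_scores$score_annotation)]
  } else character(0)
  structure(list(
    locus = locus, status = "annotated",
    tcs_number = tc_prefix(best_family, 3L), best_family = best_family,
    substrates = top_subs, family_scores = fam_scores,
    substrate_scores = sub_scores, kept = kept, threshold = thr
  ), class = "transporter_call")
}

#' @export
print.transporter_call <- function(x, ...) {
  cat("<transporter_call>", x$locus, "-", x$status, "\n")
  if (x$status == "annotated") {
    cat("  TCS:", x$tcs_number, " family:", x$best_family,
        " substrates:", paste(x$substrates, collapse = ", "), "\n")
  }
  cat(sprintf("  kept %d reference entr%s at threshold %.3f\n",
              nrow(x$kept), if (nrow(x$kept) == 1) "y" else "ies", x$threshold))
  invisible(x)
}

#' Annotate all transporter candidates of a genome
#'
#' Runs [filter_tpgc()] and [classify_tc()] over the genome.
#'
#' @param genome gene table from [read_genome()].
#' @param tm_predictions data.frame from [read_tm()].
#' @param tcdb reference database from [read_tcdb()].
#' @param params an [sw_params()].
#' @param config a [transporter_config()].
#' @return named list of `transporter_call` objects, keyed by locus, in
#'   sorted locus order (one per TPGC).
#' @export
annotate_transporters <- function(genome, tm_predictions, tcdb,
                                  params = sw_params(),
                                  config = transporter_config()) {
  tpgc <- sort(intersect(filter_tpgc(tm_predictions, config),
                         genome$locus_tag))
  helix <- tm_predictions$helices[match(tpgc, tm_predictions$locus_tag)]
  seqs <- genome$protein_sequence[match(tpgc, genome$locus_tag)]
  calls <- vector("list", length(tpgc))
  for (i in seq_along(tpgc)) {
    calls[[i]] <- classify_tc(tpgc[i], seqs[i], helix[i], tcdb, params, config)
  }
  names(calls) <- tpgc
  calls
}
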