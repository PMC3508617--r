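#' Confidence-scored homology transfer of gene functions
#'
#' Per-gene candidate functions (EC numbers and product names carried by the
#' retained homologues) are ranked by a convex combination of two scores in
#' `[0,1]`:
#'
#' \deqn{score_{annotation} = \alpha \, score_{frequency} +
#'       (1-\alpha) \, score_{taxonomy}}
#'
#' The frequency score of a candidate is the fraction of retained homologues
#' carrying it; the taxonomy score is the mean, over those homologues, of
#' the shared-lineage-prefix fraction between the query organism and the
#' homologue's organism.  Small `alpha` therefore favours functions reported
#' in taxonomically close organisms even when they are in the minority
#' among the hits.
#'
#' @name homology-scoring
NULL

#' Scoring configuration
#'
#' @param alpha weight of the frequency score in the convex combination,
#'   in `[0,1]`.  The default 0.2 weights taxonomic proximity 4:1 over raw
#'   frequency, so that closely related organisms' annotations dominate.
#' @param max_hits homologues retained per query after e-value filtering.
#' @param evalue_ceiling maximum e-value for a hit to be retained.
#' @param query_lineage ordered taxonomic lineage of the annotated organism,
#'   root to leaf (character vector).
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(alpha = 0.2, max_hits = 100L,
                           evalue_ceiling = 1e-30,
                           query_lineage = character(0)) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            max_hits >= 1L, evalue_ceiling >= 0)
  structure(list(alpha = alpha, max_hits = as.integer(max_hits),
                 evalue_ceiling = evalue_ceiling,
                 query_lineage = as.character(query_lineage)),
            class = "scoring_config")
}

#' Filter and rank a query's hits
#'
#' Keeps hits with `evalue <= evalue_ceiling`, sorts them ascending by
#' `(evalue, -bit_score, subject_accession)` and truncates to `max_hits`.
#' A tighter ceiling yields a shorter, higher-quality list.
#'
#' @param hits hit data.frame (rows for a single query locus).
#' @param config a [scoring_config()].
#' @return the retained hits, possibly zero rows.
#' @export
filter_hits <- function(hits, config) {
  if (nrow(hits) && length(unique(hits$query_locus)) > 1L) {
    stop("filter_hits expects hits of a single query locus")
  }
  keep <- hits[hits$evalue <= config$evalue_ceiling, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  ord <- order(keep$evalue, -keep$bit_score, keep$subject_accession)
  keep <- keep[ord, , drop = FALSE]
  utils::head(keep, config$max_hits)
}

# which retained hits carry a label?  EC labels match the normalized EC set;
# product labels match case-insensitively after whitespace collapse.
.canon_product <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

.hits_carrying <- function(label, hits, type = c("ec", "product")) {
  type <- match.arg(type)
  if (type == "ec") {
    lab <- normalize_ec(label)
    vapply(hits$ec_numbers, function(e) lab %in% normalize_ec(e), logical(1))
  } else {
    .canon_product(hits$product) == .canon_product(label)
  }
}

#' Frequency score of a candidate function
#'
#' Fraction of the retained homologues whose EC set (or product name)
#' contains the candidate label.
#'
#' @param function_label EC string or product string.
#' @param retained_hits non-empty hit data.frame from [filter_hits()].
#' @param type `"ec"` or `"product"`.
#' @return a number in `[0,1]`.
#' @export
score_frequency <- function(function_label, retained_hits, type = c("ec", "product")) {
  if (!nrow(retained_hits)) stop("empty hit set")
  mean(.hits_carrying(function_label, retained_hits, match.arg(type)))
}

# shared-prefix fraction between two lineages: |longest common prefix| /
# max(lengths); an empty hit lineage scores 0
.lineage_share <- function(query_lineage, hit_lineage) {
  if (!length(hit_lineage)) return(0)
  n <- min(length(query_lineage), length(hit_lineage))
  shared <- 0L
  while (shared < n && query_lineage[shared + 1L] == hit_lineage[shared + 1L]) {
    shared <- shared + 1L
  }
  shared / max(length(query_lineage), length(hit_lineage))
}

#' Taxonomy score of a candidate function
#'
#' Mean, over the retained homologues carrying the label, of the
#' shared-lineage-prefix fraction with the query lineage: the length of the
#' longest common root-to-leaf prefix divided by the longer of the two
#' lineages.  Homologues with unknown (empty) lineage contribute 0; a label
#' carried by no hit scores 0.
#'
#' @inheritParams score_frequency
#' @param query_lineage ordered lineage of the annotated organism.
#' @return a number in `[0,1]`.
#' @export
score_taxonomy <- function(function_label, retained_hits, query_lineage,
                           type = c("ec", "product")) {
  if (!nrow(retained_hits)) stop("empty hit set")
  if (!length(query_lineage)) stop("empty query lineage")
  carriers <- .hits_carrying(function_label, retained_hits, match.arg(type))
  if (!any(carriers)) return(0)
  shares <- vapply(retained_hits$lineage[carriers], function(hl) {
    .lineage_share(query_lineage, hl)
  }, numeric(1))
  mean(shares)
}

#' Rank all candidate functions of a query
#'
#' Every distinct EC number and every distinct product name among the
#' retained hits becomes a candidate; each is given its frequency, taxonomy
#' and combined scores.  Candidates are sorted by descending combined score;
#' ties are broken by complete-EC-before-partial, then more supporting hits,
#' then lexicographic label (a total order, so the ranking is deterministic).
#'
#' @param retained_hits non-empty hit data.frame from [filter_hits()].
#' @param config a [scoring_config()].
#' @return data.frame with columns `label`, `type` (`ec`/`product`),
#'   `score_frequency`, `score_taxonomy`, `score_annotation`,
#'   `supporting_hits`, `partial`.
#' @export
rank_candidates <- function(retained_hits, config) {
  if (!nrow(retained_hits)) stop("rank_candidates needs at least one hit")
  ecs <- unique(normalize_ec(unlist(retained_hits$ec_numbers)))
  prods <- unique(retained_hits$product[nzchar(retained_hits$product)])
  # products identical after canonicalization collapse onto the first spelling
  prods <- prods[!duplicated(.canon_product(prods))]
  labels <- c(ecs, prods)
  types <- c(rep("ec", length(ecs)), rep("product", length(prods)))
  if (!length(labels)) {
    return(data.frame(label = character(0), type = character(0),
                      score_frequency = numeric(0), score_taxonomy = numeric(0),
                      score_annotation = numeric(0), supporting_hits = integer(0),
                      partial = logical(0), stringsAsFactors = FALSE))
  }
  f <- t <- numeric(length(labels))
  supp <- integer(length(labels))
  for (i in seq_along(labels)) {
    carriers <- .hits_carrying(labels[i], retained_hits, types[i])
    supp[i] <- sum(carriers)
    f[i] <- supp[i] / nrow(retained_hits)
    t[i] <- if (supp[i] == 0L) 0 else {
      mean(vapply(retained_hits$lineage[carriers], function(hl) {
        .lineage_share(config$query_lineage, hl)
      }, numeric(1)))
    }
  }
  combined <- config$alpha * f + (1 - config$alpha) * t
  partial <- types == "ec" & is_partial_ec(labels)
  out <- data.frame(label = labels, type = types,
                    score_frequency = f, score_taxonomy = t,
                    score_annotation = combined, supporting_hits = supp,
                    partial = partial, stringsAsFactors = FALSE)
  ord <- order(-out$score_annotation, out$partial, -out$supporting_hits, out$label)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the automatic annotation from a ranked candidate list
#'
#' The top-scoring EC candidate (if any) is selected together with the
#' top-scoring product among the hits that support that EC; when no EC
#' candidate exists, the top product alone is selected; an empty candidate
#' list selects nothing.
#'
#' @param candidates ranked data.frame from [rank_candidates()].
#' @param retained_hits the hits the candidates were computed from (used to
#'   tie products to the supporting EC).
#' @return `NULL`, or a list with elements `product` (string, possibly
#'   empty) and `ecs` (character vector, possibly empty).
#' @export
select_annotation <- function(candidates, retained_hits = NULL) {
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  ec_rows <- candidates[candidates$type == "ec", , drop = FALSE]
  prod_rows <- candidates[candidates$type == "product", , drop = FALSE]
  if (!nrow(ec_rows)) {
    if (!nrow(prod_rows)) return(NULL)
    return(list(product = prod_rows$label[1], ecs = character(0)))
  }
  top_ec <- ec_rows$label[1]
  product <- ""
  if (nrow(prod_rows)) {
    if (!is.null(retained_hits) && nrow(retained_hits)) {
      carriers <- .hits_carrying(top_ec, retained_hits, "ec")
      supp_prods <- .canon_product(retained_hits$product[carriers])
      cand <- prod_rows[.canon_product(prod_rows$label) %in% supp_prods, , drop = FALSE]
      if (nrow(cand)) product <- cand$label[1]
    }
    if (!nzchar(product)) product <- prod_rows$label[1]
  }
  list(product = product, ecs = top_ec)
}

#' Annotate one project's loci automatically
#'
#' Runs [filter_hits()], [rank_candidates()] and [select_annotation()] for
#' every locus of a project hit table and marks enzyme encoding gene
#' candidates (EEGC): a locus is an EEGC iff its selected annotation
#' contains at least one EC number.
#'
#' @param hits hit data.frame for the whole project (many query loci).
#' @param config a [scoring_config()].
#' @param project_id label for the project (e.g. `"nr"` or `"yeast"`).
#' @return a `project_annotation` list: `project_id`, `selected` (named list
#'   of selections), `candidates` (named list of ranked tables),
#'   `retained` (named list of retained-hit tables), `eegc` (character
#'   vector of EEGC locus tags).
#' @export
annotate_project <- function(hits, config, project_id = "nr") {
  loci <- unique(hits$query_locus)
  rows_of <- split(seq_len(nrow(hits)),
                   factor(hits$query_locus, levels = loci))
  selected <- list(); cands <- list(); retained <- list()
  for (locus in loci) {
    h <- filter_hits(hits[rows_of[[locus]], , drop = FALSE], config)
    if (!nrow(h)) next
    rc <- rank_candidates(h, config)
    sel <- select_annotation(rc, h)
    retained[[locus]] <- h
    cands[[locus]] <- rc
    if (!is.null(sel)) selected[[locus]] <- sel
  }
  eegc <- names(selected)[vapply(selected, function(s) length(s$ecs) > 0L, logical(1))]
  structure(list(project_id = project_id, selected = selected,
                 candidates = cands, retained = retained, eegc = eegc),
            class = "project_annotation")
}

#' @export
print.project_annotation <- function(x, ...) {
  cat("<project_annotation> project:", x$project_id, "\n")
  cat("  loci with hits:     ", length(x$retained), "\n")
  cat("  loci with selection:", length(x$selected), "\n")
  cat("  EEGC loci:          ", length(x$eegc), "\n")
  invisible(x)
}
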