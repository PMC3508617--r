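#' Merging, classification and reporting of final annotations
#'
#' Combines the curated enzymatic decisions and the transporter calls into
#' one annotation per metabolic gene, classifies genes by functional
#' category (monofunctional / multifunctional / multiclass / with TC(S)
#' number), completeness (any partial EC number makes the gene partial) and
#' enzyme class (leading digit of the first-annotated EC number, taken as
#' the main function), and reproduces the summary, cross-tabulation and
#' external-comparison tables.
#'
#' @name reporting-integration
NULL

#' Round half away from zero
#'
#' Plain decimal rounding where `.005` rounds up, as used for all percentage
#' cells of the reports (base R `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Merge enzymatic decisions and transporter calls
#'
#' A locus appears in the output iff at least one source annotated it.
#' Dual loci carry both payloads and keep the enzymatic product (a
#' conflicting transporter-derived product is logged in `flags`);
#' transporter-only loci default their product to the best TC family.
#'
#' @param decisions named list of `curation_decision` objects.
#' @param transporter_calls named list of `transporter_call` objects.
#' @return data.frame with columns `locus_tag`, `product`, `ecs` (list
#'   column, annotation order), `tcs`, `tc_family`, `substrates` (list
#'   column), `provenance_code`, `category`, `ec_class`, `completeness`.
#' @export
merge_annotations <- function(decisions, transporter_calls = list()) {
  dec_ok <- Filter(function(d) d$status == "annotated", decisions)
  tc_ok <- Filter(function(tc) tc$status == "annotated", transporter_calls)
  loci <- sort(unique(c(names(dec_ok), names(tc_ok))))
  n <- length(loci)
  out <- data.frame(locus_tag = loci, product = character(n),
                    tcs = NA_character_, tc_family = NA_character_,
                    provenance_code = character(n),
                    stringsAsFactors = FALSE)
  out$ecs <- I(vector("list", n))
  out$substrates <- I(vector("list", n))
  for (i in seq_len(n)) {
    locus <- loci[i]
    d <- dec_ok[[locus]]
    tc <- tc_ok[[locus]]
    if (!is.null(d)) {
      out$product[i] <- d$product
      out$ecs[[i]] <- d$ec_set
      out$provenance_code[i] <- d$provenance_code
    }
    if (!is.null(tc)) {
      out$tcs[i] <- tc$tcs_number
      out$tc_family[i] <- tc$best_family
      out$substrates[[i]] <- tc$substrates
      if (is.null(d)) {
        out$product[i] <- sprintf("%s family transporter", tc$best_family)
        out$provenance_code[i] <- assign_code("T", character(0))
      }
    }
    if (length(out$ecs[[i]]) == 0L) out$ecs[[i]] <- character(0)
    if (length(out$substrates[[i]]) == 0L) out$substrates[[i]] <- character(0)
  }
  cls <- classify_function(out)
  out$category <- cls$category
  out$ec_class <- cls$ec_class
  out$completeness <- cls$completeness
  out
}

#' Classify merged annotations by functional category
#'
#' Category: `with_tc` when the gene has both an EC number and a TC(S)
#' number (this row takes precedence); otherwise `monofunctional` (one EC),
#' `multifunctional` (two or more ECs of a single leading class),
#' `multiclass` (two or more leading classes); `transporter_only` for genes
#' with a TC(S) number and no EC.  The enzyme class is derived from the
#' first-annotated EC number (the main function); completeness is `partial`
#' iff any EC number carries a `-` placeholder.
#'
#' @param annotations merged data.frame (needs `ecs` list column and `tcs`).
#' @return data.frame with `category`, `ec_class`, `completeness`.
#' @export
classify_function <- function(annotations) {
  n <- nrow(annotations)
  category <- character(n)
  klass <- rep(NA_character_, n)
  completeness <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ecs <- normalize_ec(annotations$ecs[[i]])
    has_tc <- !is.na(annotations$tcs[i])
    if (!length(ecs)) {
      category[i] <- if (has_tc) "transporter_only" else "none"
      next
    }
    klass[i] <- ec_class(ecs[1])
    completeness[i] <- if (any(is_partial_ec(ecs))) "partial" else "complete"
    leading <- unique(sub("\\..*$", "", ecs))
    category[i] <- if (has_tc) "with_tc"
      else if (length(ecs) == 1L) "monofunctional"
      else if (length(leading) == 1L) "multifunctional"
      else "multiclass"
  }
  data.frame(category = category, ec_class = klass,
             completeness = completeness, stringsAsFactors = FALSE)
}

.EC_CLASSES <- c("oxidoreductase", "transferase", "hydrolase",
                 "lyase", "isomerase", "ligase")
.EC_CATEGORIES <- c("monofunctional", "multifunctional", "multiclass", "with_tc")

#' Cross-tabulate EC-bearing genes
#'
#' Counts of EC-bearing annotations by completeness (complete / partial),
#' functional category and enzyme class, with subtotal rows per
#' completeness block, class totals and the grand total.  The grand total
#' equals the number of EC-bearing annotations.
#'
#' @param annotations merged data.frame from [merge_annotations()].
#' @return list with `cells` (8 x 6 integer matrix, rows
#'   `<completeness>.<category>`), `subtotal_complete`, `subtotal_partial`,
#'   `class_totals` (length-6), and `grand_total`.
#' @export
cross_tabulate <- function(annotations) {
  ec_rows <- annotations[annotations$category %in% .EC_CATEGORIES, , drop = FALSE]
  cells <- matrix(0L, nrow = 8L, ncol = 6L,
                  dimnames = list(
                    paste(rep(c("complete", "partial"), each = 4L),
                          rep(.EC_CATEGORIES, 2L), sep = "."),
                    .EC_CLASSES))
  for (i in seq_len(nrow(ec_rows))) {
    if (is.na(ec_rows$ec_class[i])) next
    r <- paste(ec_rows$completeness[i], ec_rows$category[i], sep = ".")
    cells[r, ec_rows$ec_class[i]] <- cells[r, ec_rows$ec_class[i]] + 1L
  }
  list(cells = cells,
       subtotal_complete = colSums(cells[1:4, , drop = FALSE]),
       subtotal_partial = colSums(cells[5:8, , drop = FALSE]),
       class_totals = colSums(cells),
       grand_total = sum(cells))
}

# does `ours` cover `ext`: exact match, or ours is a complete EC refining an
# external partial one
.ec_covered_by <- function(ext, ours) {
  any(vapply(ours, function(o) {
    o == ext || (is_partial_ec(ext) && !is_partial_ec(o) && ec_refines(o, ext))
  }, logical(1)))
}

#' Compare the final annotation with an external one
#'
#' TC components are ignored (the external annotation carries none); the
#' comparison is on normalized EC sets.  Per-locus categories: `match`
#' (equal sets), `superset` (every external EC matched exactly or refined by
#' one of ours, and the sets differ), `subset` (the converse), `conflict`
#' (neither direction covers), `new_in_ours` (locus absent externally),
#' `ruled_out` (externally metabolic but discarded by the curation
#' pipeline), `absent_in_ours` (externally annotated, never seen by us).
#' The `new_in_ours` loci are additionally bucketed by payload: complete or
#' partial EC numbers, with or without a TC(S) number, or TC-only.
#'
#' @param annotations merged data.frame from [merge_annotations()].
#' @param external named list from [read_external()].
#' @param discarded character vector of loci the curation pipeline ruled
#'   out.
#' @return a `comparison_report` list: `detail` (locus/category
#'   data.frame), `counts` (named integer vector over the seven
#'   categories) and `buckets` (named integer vector over the five
#'   new-in-ours payload buckets; sums to `counts["new_in_ours"]`).
#' @export
compare_external <- function(annotations, external, discarded = character(0)) {
  our_loci <- annotations$locus_tag
  ext_loci <- names(external)
  universe <- sort(unique(c(our_loci, ext_loci)))
  category <- character(length(universe))
  for (i in seq_along(universe)) {
    locus <- universe[i]
    in_ours <- locus %in% our_loci
    in_ext <- locus %in% ext_loci
    if (in_ours && !in_ext) {
      category[i] <- "new_in_ours"
    } else if (!in_ours) {
      category[i] <- if (locus %in% discarded) "ruled_out" else "absent_in_ours"
    } else {
      ours <- normalize_ec(annotations$ecs[[match(locus, our_loci)]])
      ext <- normalize_ec(external[[locus]])
      if (ec_sets_equal(ours, ext)) {
        category[i] <- "match"
      } else {
        ext_covered <- all(vapply(ext, .ec_covered_by, logical(1), ours = ours))
        ours_covered <- all(vapply(ours, .ec_covered_by, logical(1), ours = ext))
        category[i] <- if (ext_covered && !ours_covered) "superset"
          else if (ours_covered && !ext_covered) "subset"
          else if (ext_covered && ours_covered) "match"  # mutual refinement
          else "conflict"
      }
    }
  }
  cats <- c("match", "superset", "subset", "conflict", "new_in_ours",
            "ruled_out", "absent_in_ours")
  counts <- vapply(cats, function(ct) sum(category == ct), integer(1))
  new_loci <- universe[category == "new_in_ours"]
  idx <- match(new_loci, our_loci)
  buckets <- c(complete_ec_only = 0L, complete_ec_tc = 0L,
               partial_ec_only = 0L, partial_ec_tc = 0L, tc_only = 0L)
  for (j in idx) {
    ecs <- annotations$ecs[[j]]
    has_tc <- !is.na(annotations$tcs[j])
    b <- if (!length(ecs)) "tc_only"
      else if (any(is_partial_ec(ecs))) {
        if (has_tc) "partial_ec_tc" else "partial_ec_only"
      } else {
        if (has_tc) "complete_ec_tc" else "complete_ec_only"
      }
    buckets[b] <- buckets[b] + 1L
  }
  structure(list(
    detail = data.frame(locus_tag = universe, category = category,
                        stringsAsFactors = FALSE),
    counts = counts, buckets = buckets
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-15s %5d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Percentage shares of a count vector
#'
#' Each count as a percentage of the total, rounded half-up to two
#' decimals.  A zero total yields an empty report rather than an error.
#'
#' @param counts named numeric vector.
#' @return data.frame with `group`, `count`, `share_percent`.
#' @export
share_table <- function(counts) {
  total <- sum(counts)
  if (total == 0) {
    return(data.frame(group = character(0), count = numeric(0),
                      share_percent = numeric(0), stringsAsFactors = FALSE))
  }
  data.frame(group = names(counts), count = as.numeric(counts),
             share_percent = round_half_up(100 * counts / total, 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Provenance shares of the final annotation
#'
#' Groups the metabolic genes by annotation provenance — EC-bearing genes
#' annotated from a *S. cerevisiae* homologue versus from another
#' organism's homologue (source letter `H` in the provenance code), and
#' transporter-only genes — and reports each group's percentage share.
#'
#' @param annotations merged data.frame from [merge_annotations()].
#' @return data.frame from [share_table()].
#' @export
provenance_summary <- function(annotations) {
  has_ec <- vapply(annotations$ecs, length, integer(1)) > 0L
  other <- has_ec & grepl("H", sub("^.*-", "", annotations$provenance_code))
  counts <- c(
    sc_homologue = sum(has_ec & !other),
    other_homologue = sum(other),
    transporter_only = sum(!has_ec)
  )
  share_table(counts)
}

#' Distribution of transporter classes
#'
#' Percentage of transporter-annotated genes per TC class (first TC
#' component), over genes with a TC(S) number and no EC number.
#'
#' @param annotations merged data.frame from [merge_annotations()].
#' @param exclusively_transporter restrict to transporter-only genes
#'   (default `TRUE`).
#' @return data.frame from [share_table()], one row per TC class.
#' @export
tc_distribution <- function(annotations, exclusively_transporter = TRUE) {
  rows <- !is.na(annotations$tcs)
  if (exclusively_transporter) {
    rows <- rows & vapply(annotations$ecs, length, integer(1)) == 0L
  }
  classes <- tc_class(annotations$tcs[rows])
  if (!length(classes)) return(share_table(numeric(0)))
  counts <- table(classes)
  share_table(stats::setNames(as.integer(counts), names(counts)))
}

#' Headline counts of an annotation run
#'
#' The funnel from genome to final annotation: genes, revised candidates,
#' EEGCs, TPGCs, discarded counts, and the exclusively-enzymatic /
#' exclusively-transporter / dual split (which always sums to the total
#' metabolic count).
#'
#' @param genome gene table.
#' @param comparison `project_comparison` (EEGC universe).
#' @param decisions curation decisions.
#' @param transporter_calls transporter calls.
#' @param annotations merged annotations.
#' @return named integer vector of counts.
#' @export
summary_report <- function(genome, comparison, decisions, transporter_calls,
                           annotations) {
  eegc <- comparison$detail$locus_tag
  tpgc <- names(transporter_calls)
  has_ec <- vapply(annotations$ecs, length, integer(1)) > 0L
  has_tc <- !is.na(annotations$tcs)
  c(
    genes = nrow(genome),
    revised = length(unique(c(eegc, tpgc))),
    eegc = length(eegc),
    tpgc = length(tpgc),
    eegc_discarded = sum(vapply(decisions, function(d) d$status == "discarded",
                                logical(1))),
    eegc_confirmed = sum(vapply(decisions, function(d) d$status == "annotated",
                                logical(1))),
    tpgc_discarded = sum(vapply(transporter_calls,
                                function(x) x$status == "discarded", logical(1))),
    exclusively_enzymatic = sum(has_ec & !has_tc),
    exclusively_transporter = sum(!has_ec & has_tc),
    dual = sum(has_ec & has_tc),
    total_metabolic = nrow(annotations)
  )
}
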