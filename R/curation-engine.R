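#' Evidence-driven curation of enzyme encoding gene candidates
#'
#' Deterministic implementation of the manual-curation decision tree over
#' offline evidence bundles.  For each EEGC, in order:
#'
#' 1. **L** — a literature override, when present, wins outright (it encodes
#'    author knowledge of the organism); a contradicting reviewed record is
#'    flagged, not silently dropped.
#' 2. **A** — a reviewed database record for the locus itself is accepted.
#' 3. **B1** — otherwise the best *S. cerevisiae* homologue among the
#'    retained hits (minimum e-value at or below the homologue ceiling,
#'    ties by bit score) is taken and the UniProt and SGD entries for its
#'    systematic Y-identifier reconciled; when the two curated databases
#'    disagree, the organism-specific SGD entry is favoured.
#' 4. **B2** — failing that, a reviewed-restricted similarity search result
#'    under the lowered e-value ceiling is accepted (best hit), then an
#'    organism-unrestricted search (first hit); with no such hit the locus
#'    is discarded as non-metabolic.
#' 5. **C** — accepted EC sets are verified against the EC registry:
#'    deprecated numbers are replaced by their transfer targets and partial
#'    numbers upgraded when a unique active entry matches both the prefix
#'    and the product name.
#' 6. **D** — the decision is emitted with an alphanumeric provenance code.
#'
#' @name curation-engine
NULL

#' Curation pipeline configuration
#'
#' @param sc_taxon_pattern regular expression recognizing *S. cerevisiae*
#'   systematic identifiers among hit accessions (Y + two characters +
#'   three digits + one character).
#' @param restricted_evalue_ceiling e-value bound for the fallback
#'   (restricted and unrestricted) searches; hits must be strictly below it.
#' @param homologue_evalue_ceiling e-value bound for accepting a
#'   *S. cerevisiae* homologue from the retained hits.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sc_taxon_pattern = "^Y.{2}[0-9]{3}.$",
                            restricted_evalue_ceiling = 1e-10,
                            homologue_evalue_ceiling = 1e-30) {
  stopifnot(restricted_evalue_ceiling > 0)
  structure(list(sc_taxon_pattern = sc_taxon_pattern,
                 restricted_evalue_ceiling = restricted_evalue_ceiling,
                 homologue_evalue_ceiling = homologue_evalue_ceiling),
            class = "pipeline_config")
}

#' Reconcile the UniProt and SGD entries of a yeast homologue
#'
#' Identical EC sets are accepted as they stand; on any disagreement the
#' SGD entry is favoured (its curators are specific to the organism).
#'
#' @param u_entry,s_entry lists with `product` and `ecs`, or `NULL`.
#' @return list with `product`, `ecs` and `agreed` (logical), or `NULL`
#'   when both entries are absent (fall through to the next step).
#' @export
reconcile_uniprot_sgd <- function(u_entry, s_entry) {
  if (is.null(u_entry) && is.null(s_entry)) return(NULL)
  if (is.null(s_entry)) {
    return(list(product = u_entry$product, ecs = normalize_ec(u_entry$ecs),
                agreed = TRUE))
  }
  if (is.null(u_entry)) {
    return(list(product = s_entry$product, ecs = normalize_ec(s_entry$ecs),
                agreed = TRUE))
  }
  if (ec_sets_equal(u_entry$ecs, s_entry$ecs)) {
    list(product = s_entry$product, ecs = normalize_ec(s_entry$ecs),
         agreed = TRUE)
  } else {
    list(product = s_entry$product, ecs = normalize_ec(s_entry$ecs),
         agreed = FALSE)
  }
}

#' Verify an EC set against the registry
#'
#' Deprecated EC numbers are replaced by all their transfer targets (a
#' terminal deletion, with no targets, removes the number); partial EC
#' numbers are upgraded to a complete one when *exactly one* active registry
#' entry both refines the partial prefix and lists the product among its
#' accepted names; EC numbers absent from the registry are kept and flagged
#' unknown.
#'
#' @param ec_set character vector of EC numbers.
#' @param product product name used for partial-number upgrading.
#' @param registry data.frame from [read_ec_registry()].
#' @return list with `ecs` (revised, order-preserving, de-duplicated),
#'   `flags` (character vector of `transferred`, `split`, `deleted`,
#'   `upgraded`, `unknown` events) and `revised` (logical: any change).
#' @export
verify_ec <- function(ec_set, product, registry) {
  ec_set <- normalize_ec(ec_set)
  out <- character(0)
  flags <- character(0)
  if (is.null(registry$partial)) registry$partial <- is_partial_ec(registry$ec)
  comp <- attr(registry, "ec_components")
  if (is.null(comp)) {
    comp <- do.call(rbind, strsplit(registry$ec, ".", fixed = TRUE))
  }
  canon_prod <- .canon_product(product)
  active_i <- which(registry$status == "active" & !registry$partial)
  for (ec in ec_set) {
    i <- match(ec, registry$ec)
    if (!is.na(i) && registry$status[i] == "deprecated") {
      targets <- registry$transfers[[i]]
      if (!length(targets)) {
        flags <- c(flags, "deleted")
      } else {
        out <- c(out, targets)
        flags <- c(flags, if (length(targets) > 1L) "split" else "transferred")
        if (any(!targets %in% registry$ec)) flags <- c(flags, "unknown")
      }
      next
    }
    if (is_partial_ec(ec) && length(active_i)) {
      # upgrade attempted whether or not the partial number is itself a
      # registry row: the search is over active complete entries
      pc <- strsplit(ec, ".", fixed = TRUE)[[1]]
      refines <- rep(TRUE, length(active_i))
      for (j in seq_along(pc)) {
        if (pc[j] != "-") refines <- refines & comp[active_i, j] == pc[j]
      }
      name_ok <- vapply(registry$names[active_i], function(nm) {
        canon_prod %in% nm
      }, logical(1))
      match_i <- active_i[refines & name_ok]
      if (length(match_i) == 1L) {
        out <- c(out, registry$ec[match_i])
        flags <- c(flags, "upgraded")
        next
      }
    }
    if (is.na(i)) flags <- c(flags, "unknown")
    out <- c(out, ec)
  }
  out <- out[!duplicated(out)]
  list(ecs = out, flags = flags,
       revised = !identical(out, ec_set[!duplicated(ec_set)]))
}

#' Build the alphanumeric provenance code
#'
#' `"<origin>-<sources>"`, where origin is one of `M` (match set), `D`
#' (distinct), `N` (nr-only), `Y` (yeast-only), `T` (transporter-only) and
#' sources is the sorted subset of `U` (UniProt), `S` (SGD), `B` (registry
#' revision applied), `H` (non-cerevisiae homologue), `L` (literature)
#' actually consulted.  A discarded gene has no sources and keeps the bare
#' origin letter.
#'
#' @param origin single letter in `M`, `D`, `N`, `Y`, `T`.
#' @param sources character vector, subset of `U`, `S`, `B`, `H`, `L`.
#' @return the code string.
#' @export
assign_code <- function(origin, sources) {
  stopifnot(origin %in% c("M", "D", "N", "Y", "T"))
  bad <- setdiff(sources, c("U", "S", "B", "H", "L"))
  if (length(bad)) stop("unknown evidence source(s): ", paste(bad, collapse = ","))
  if (!length(sources)) return(origin)
  paste0(origin, "-", paste(sort(unique(sources)), collapse = ""))
}

#' Curate one enzyme encoding gene candidate
#'
#' Runs the decision tree described in [curation-engine] for a single
#' locus.
#'
#' @param locus locus tag (EEGC in at least one project).
#' @param retained_hits retained hit data.frame for the locus (union over
#'   projects; may have zero rows).
#' @param evidence the locus's evidence bundle (list with `reviewed`,
#'   `sc_entries`, `restricted`, `unrestricted`, `literature`), or `NULL`.
#' @param registry EC registry from [read_ec_registry()].
#' @param config a [pipeline_config()].
#' @param origin origin-set letter for the provenance code (see
#'   [assign_code()]).
#' @return a `curation_decision` list: `locus`, `status` (`annotated` /
#'   `discarded`), `product`, `ec_set`, `provenance_code`,
#'   `deciding_sources`, `path_trace`, `flags`.
#' @export
decide <- function(locus, retained_hits, evidence, registry, config,
                   origin = "M") {
  if (is.null(evidence)) {
    evidence <- list(reviewed = NULL, sc_entries = list(),
                     restricted = NULL, unrestricted = NULL, literature = NULL)
  }
  trace <- character(0)
  sources <- character(0)
  flags <- character(0)
  accepted <- NULL

  # L: literature override wins outright
  if (!is.null(evidence$literature)) {
    trace <- c(trace, "L")
    sources <- c(sources, "L")
    accepted <- list(product = evidence$literature$product,
                     ecs = normalize_ec(evidence$literature$ecs))
    if (!is.null(evidence$reviewed) &&
        !ec_sets_equal(evidence$reviewed$ecs, accepted$ecs)) {
      flags <- c(flags, "literature_overrides_reviewed")
    }
  }

  # A: reviewed record for the locus itself
  if (is.null(accepted) && !is.null(evidence$reviewed)) {
    trace <- c(trace, "A")
    sources <- c(sources, "U")
    accepted <- list(product = evidence$reviewed$product,
                     ecs = normalize_ec(evidence$reviewed$ecs))
  }

  # B1: best S. cerevisiae homologue among the retained hits
  if (is.null(accepted)) {
    trace <- c(trace, "B")
    sc <- if (!is.null(retained_hits) && nrow(retained_hits)) {
      retained_hits[grepl(config$sc_taxon_pattern, retained_hits$subject_accession) &
                    retained_hits$evalue <= config$homologue_evalue_ceiling, ,
                    drop = FALSE]
    }
    if (!is.null(sc) && nrow(sc)) {
      sc <- sc[order(sc$evalue, -sc$bit_score, sc$subject_accession), , drop = FALSE]
      y_id <- sc$subject_accession[1]
      trace <- c(trace, "B1")
      entries <- evidence$sc_entries[[y_id]]
      if (!is.null(entries)) {
        if (is.null(entries$uniprot) && is.null(entries$sgd)) {
          stop("evidence for ", locus, " references Y-identifier ", y_id,
               " with no UniProt or SGD entry")
        }
        rec <- reconcile_uniprot_sgd(entries$uniprot, entries$sgd)
        sources <- c(sources,
                     if (!is.null(entries$uniprot)) "U",
                     if (!is.null(entries$sgd)) "S")
        if (!rec$agreed) flags <- c(flags, "sgd_favoured")
        accepted <- list(product = rec$product, ecs = rec$ecs)
      }
      # Y-identifier absent from the evidence maps entirely: fall through
    }
  }

  # B2: restricted then unrestricted fallback searches
  if (is.null(accepted)) {
    trace <- c(trace, "B2")
    take <- function(df, first_only) {
      if (is.null(df) || !nrow(df)) return(NULL)
      ok <- df[df$evalue < config$restricted_evalue_ceiling, , drop = FALSE]
      if (!nrow(ok)) return(NULL)
      # hit lists come in sorted by ascending e-value; best == first
      list(product = ok$product[1], ecs = normalize_ec(ok$ecs[[1]]))
    }
    hit <- take(evidence$restricted, FALSE)
    if (!is.null(hit)) {
      trace <- c(trace, "B2-restricted")
    } else {
      hit <- take(evidence$unrestricted, TRUE)
      if (!is.null(hit)) trace <- c(trace, "B2-unrestricted")
    }
    if (!is.null(hit)) {
      sources <- c(sources, "H")
      accepted <- hit
    }
  }

  if (is.null(accepted)) {
    trace <- c(trace, "D")
    return(structure(list(
      locus = locus, status = "discarded", product = "",
      ec_set = character(0),
      provenance_code = assign_code(origin, character(0)),
      deciding_sources = character(0), path_trace = trace, flags = flags
    ), class = "curation_decision"))
  }

  # C: registry verification of the accepted EC set
  trace <- c(trace, "C")
  ver <- verify_ec(accepted$ecs, accepted$product, registry)
  if (ver$revised) sources <- c(sources, "B")
  flags <- c(flags, ver$flags)
  trace <- c(trace, "D")
  sources <- sort(unique(sources))
  structure(list(
    locus = locus, status = "annotated", product = accepted$product,
    ec_set = ver$ecs,
    provenance_code = assign_code(origin, sources),
    deciding_sources = sources, path_trace = trace, flags = flags
  ), class = "curation_decision")
}

#' @export
print.curation_decision <- function(x, ...) {
  cat("<curation_decision>", x$locus, "-", x$status, "\n")
  if (x$status == "annotated") {
    cat("  product:", x$product, "\n  ECs:",
        paste(x$ec_set, collapse = ", "), "\n")
  }
  cat("  code:", x$provenance_code, " path:",
      paste(x$path_trace, collapse = ">"), "\n")
  invisible(x)
}

#' Curate every EEGC of a project comparison
#'
#' Applies [decide()] to each locus of the four comparison sets, feeding it
#' the union of both projects' retained hits and the locus's evidence
#' bundle; the comparison set supplies the origin letter of the provenance
#' code.
#'
#' @param comparison a `project_comparison` from [partition_genes()].
#' @param project_nr,project_yeast the two `project_annotation` objects.
#' @param evidence named list of evidence bundles from [read_evidence()].
#' @param registry EC registry.
#' @param config a [pipeline_config()].
#' @return named list of `curation_decision` objects, keyed by locus, in
#'   sorted locus order.
#' @export
curate_all <- function(comparison, project_nr, project_yeast, evidence,
                       registry, config = pipeline_config()) {
  origin_of <- c(matches = "M", distinct = "D", nr_only = "N", yeast_only = "Y")
  loci <- comparison$detail$locus_tag
  origins <- origin_of[comparison$detail$set]
  decisions <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    locus <- loci[i]
    h <- rbind(project_nr$retained[[locus]], project_yeast$retained[[locus]])
    decisions[[i]] <- decide(locus, h, evidence[[locus]], registry, config,
                             origin = origins[[i]])
  }
  names(decisions) <- loci
  decisions[order(loci)]
}
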