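#' Comparison of the two parallel annotation projects
#'
#' The same genome is annotated twice: once against a broad protein database
#' (`nr`) and once against a yeast-restricted one (`yeast`).  The enzyme
#' encoding gene candidates (EEGC) of the two projects are partitioned into
#' four disjoint sets: loci whose selected EC sets agree (*matches*), loci
#' where both projects select but the EC sets differ (*distinct*), and loci
#' selected by only one project (*nr_only* / *yeast_only*).
#'
#' The match decision is taken on normalized EC sets only; product-name
#' disagreements are logged in the per-locus table, not partitioned.
#' Partial-versus-complete pairs (e.g. `3.2.2.-` against `3.2.2.27`) are
#' classified *distinct* but flagged revisable, since a registry lookup may
#' reconcile them later.
#'
#' @name dual-projects
NULL

#' Partition the EEGCs of two projects into the four comparison sets
#'
#' @param project_nr,project_yeast `project_annotation` objects from
#'   [annotate_project()], computed over the same locus universe.
#' @return a `project_comparison` list: character vectors `matches`,
#'   `distinct`, `nr_only`, `yeast_only` (disjoint; their union is the union
#'   of both EEGC sets), and `detail`, a data.frame with both projects'
#'   selections, a `set` column and a `revisable` flag.
#' @export
partition_genes <- function(project_nr, project_yeast) {
  eegc_nr <- project_nr$eegc
  eegc_yeast <- project_yeast$eegc
  universe <- sort(unique(c(eegc_nr, eegc_yeast)))
  set <- character(length(universe))
  revisable <- logical(length(universe))
  nr_ecs <- yeast_ecs <- nr_prod <- yeast_prod <- character(length(universe))
  for (i in seq_along(universe)) {
    locus <- universe[i]
    in_nr <- locus %in% eegc_nr
    in_yeast <- locus %in% eegc_yeast
    a <- if (in_nr) normalize_ec(project_nr$selected[[locus]]$ecs) else character(0)
    b <- if (in_yeast) normalize_ec(project_yeast$selected[[locus]]$ecs) else character(0)
    nr_ecs[i] <- paste(sort(a), collapse = ",")
    yeast_ecs[i] <- paste(sort(b), collapse = ",")
    nr_prod[i] <- if (in_nr) project_nr$selected[[locus]]$product else ""
    yeast_prod[i] <- if (in_yeast) project_yeast$selected[[locus]]$product else ""
    if (in_nr && in_yeast) {
      if (ec_sets_equal(a, b)) {
        set[i] <- "matches"
      } else {
        set[i] <- "distinct"
        # one side's partial refined by the other's complete -> revisable
        revisable[i] <- any(vapply(a, function(x) {
          any(vapply(b, function(y) ec_refines(x, y) || ec_refines(y, x),
                     logical(1)))
        }, logical(1)))
      }
    } else if (in_nr) {
      set[i] <- "nr_only"
    } else {
      set[i] <- "yeast_only"
    }
  }
  detail <- data.frame(
    locus_tag = universe, set = set,
    nr_ecs = nr_ecs, yeast_ecs = yeast_ecs,
    nr_product = nr_prod, yeast_product = yeast_prod,
    product_disagrees = nzchar(nr_prod) & nzchar(yeast_prod) &
      .canon_product(nr_prod) != .canon_product(yeast_prod),
    revisable = revisable,
    stringsAsFactors = FALSE
  )
  structure(list(
    matches = universe[set == "matches"],
    distinct = universe[set == "distinct"],
    nr_only = universe[set == "nr_only"],
    yeast_only = universe[set == "yeast_only"],
    detail = detail
  ), class = "project_comparison")
}

#' @export
print.project_comparison <- function(x, ...) {
  cat("<project_comparison>\n")
  cat(sprintf("  matches:    %5d\n", length(x$matches)))
  cat(sprintf("  distinct:   %5d (%d revisable)\n", length(x$distinct),
              sum(x$detail$revisable)))
  cat(sprintf("  nr_only:    %5d\n", length(x$nr_only)))
  cat(sprintf("  yeast_only: %5d\n", length(x$yeast_only)))
  invisible(x)
}

#' Export the four comparison sets as a TSV
#'
#' @param comparison a `project_comparison` from [partition_genes()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  write_tsv_strict(comparison$detail, path)
}
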