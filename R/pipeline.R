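#' End-to-end annotation pipeline
#'
#' [run_pipeline()] chains every stage — automatic scoring of both
#' projects, the four-set comparison, evidence-driven curation, transporter
#' classification, merging and reporting — over a directory of input files
#' in the layout produced by [generate_fixtures()] (or assembled by hand
#' from real exports):
#'
#' ```
#' genome.fasta          query_lineage.txt
#' hits_nr.tsv           hits_nr_sidecar.tsv
#' hits_yeast.tsv        hits_yeast_sidecar.tsv
#' tm.tsv                tcdb.fasta   tcdb_substrates.tsv
#' ec_registry.tsv       external.tsv (optional)
#' evidence/
#' ```
#'
#' @name pipeline
NULL

#' Run the full annotation pipeline over an input directory
#'
#' @param input_dir directory containing the input files (see [pipeline]).
#' @param out_dir optional output directory; when given, the annotation
#'   table, comparison tables, summary counts, cross-tabulation, JSON twins
#'   of every table and per-chromosome GenBank files are written there.
#' @param scoring a [scoring_config()]; its `query_lineage` is filled from
#'   `query_lineage.txt` when empty.
#' @param curation a [pipeline_config()].
#' @param sw an [sw_params()].
#' @param transporter a [transporter_config()].
#' @param verbose log per-stage counts to stderr.
#' @return a `metannot_run` list: `genome`, `projects`, `comparison`,
#'   `decisions`, `transporter_calls`, `annotations`, `cross_tab`,
#'   `external_comparison` (or `NULL`), `provenance`, `tc_distribution`,
#'   `summary`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         scoring = scoring_config(),
                         curation = pipeline_config(),
                         sw = sw_params(),
                         transporter = transporter_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  p <- function(f) file.path(input_dir, f)

  genome <- read_genome(p("genome.fasta"))
  say("genome: %d genes", nrow(genome))
  if (!length(scoring$query_lineage) && file.exists(p("query_lineage.txt"))) {
    scoring$query_lineage <- readLines(p("query_lineage.txt"))
  }
  hits_nr <- read_hits(p("hits_nr.tsv"), p("hits_nr_sidecar.tsv"))
  hits_yeast <- read_hits(p("hits_yeast.tsv"), p("hits_yeast_sidecar.tsv"))
  proj_nr <- annotate_project(hits_nr, scoring, "nr")
  proj_yeast <- annotate_project(hits_yeast, scoring, "yeast")
  say("EEGC: %d (nr) / %d (yeast)", length(proj_nr$eegc), length(proj_yeast$eegc))

  comparison <- partition_genes(proj_nr, proj_yeast)
  say("sets: %d matches, %d distinct, %d nr_only, %d yeast_only",
      length(comparison$matches), length(comparison$distinct),
      length(comparison$nr_only), length(comparison$yeast_only))

  evidence <- read_evidence(p("evidence"))
  registry <- read_ec_registry(p("ec_registry.tsv"))
  decisions <- curate_all(comparison, proj_nr, proj_yeast, evidence,
                          registry, curation)
  n_disc <- sum(vapply(decisions, function(d) d$status == "discarded", logical(1)))
  say("curation: %d annotated, %d discarded", length(decisions) - n_disc, n_disc)

  tm <- read_tm(p("tm.tsv"))
  tcdb <- read_tcdb(p("tcdb.fasta"), p("tcdb_substrates.tsv"))
  calls <- annotate_transporters(genome, tm, tcdb, sw, transporter)
  say("transporters: %d TPGC, %d annotated", length(calls),
      sum(vapply(calls, function(x) x$status == "annotated", logical(1))))

  annotations <- merge_annotations(decisions, calls)
  xtab <- cross_tabulate(annotations)
  discarded <- names(decisions)[vapply(decisions, function(d)
    d$status == "discarded", logical(1))]
  ext_cmp <- NULL
  if (file.exists(p("external.tsv"))) {
    external <- read_external(p("external.tsv"))
    ext_cmp <- compare_external(annotations, external, discarded)
  }
  prov <- provenance_summary(annotations)
  tcd <- tc_distribution(annotations)
  summ <- summary_report(genome, comparison, decisions, calls, annotations)
  say("metabolic genes: %d", summ[["total_metabolic"]])

  run <- structure(list(
    genome = genome, projects = list(nr = proj_nr, yeast = proj_yeast),
    comparison = comparison, decisions = decisions,
    transporter_calls = calls, annotations = annotations,
    cross_tab = xtab, external_comparison = ext_cmp,
    provenance = prov, tc_distribution = tcd, summary = summ
  ), class = "metannot_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.metannot_run <- function(x, ...) {
  cat("<metannot_run>\n")
  s <- x$summary
  cat(sprintf("  genes %d | revised %d | EEGC %d | TPGC %d\n",
              s[["genes"]], s[["revised"]], s[["eegc"]], s[["tpgc"]]))
  cat(sprintf("  metabolic %d = %d enzymatic + %d transporter + %d dual\n",
              s[["total_metabolic"]], s[["exclusively_enzymatic"]],
              s[["exclusively_transporter"]], s[["dual"]]))
  cat(sprintf("  discarded: %d EEGC, %d TPGC\n",
              s[["eegc_discarded"]], s[["tpgc_discarded"]]))
  invisible(x)
}

# flatten the merged annotation table for TSV export
.flatten_annotations <- function(annotations) {
  data.frame(
    locus_tag = annotations$locus_tag,
    product = annotations$product,
    ecs = vapply(annotations$ecs, paste, character(1), collapse = ","),
    tcs = ifelse(is.na(annotations$tcs), "", annotations$tcs),
    tc_family = ifelse(is.na(annotations$tc_family), "", annotations$tc_family),
    substrates = vapply(annotations$substrates, paste, character(1),
                        collapse = ","),
    category = annotations$category,
    ec_class = ifelse(is.na(annotations$ec_class), "", annotations$ec_class),
    completeness = ifelse(is.na(annotations$completeness), "",
                          annotations$completeness),
    provenance_code = annotations$provenance_code,
    stringsAsFactors = FALSE
  )
}

#' Write every report of a pipeline run
#'
#' Deterministic exports: `annotations.tsv`, `comparison_sets.tsv`,
#' `external_comparison.tsv`, `summary.tsv`, `cross_tab.tsv`,
#' `provenance.tsv`, `tc_distribution.tsv`, a JSON twin of each table
#' (`reports.json`) and per-chromosome GenBank files under `genbank/`.
#'
#' @param run a `metannot_run` from [run_pipeline()].
#' @param out_dir output directory (created).
#' @return invisibly, `out_dir`.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- .flatten_annotations(run$annotations)
  write_tsv_strict(flat, file.path(out_dir, "annotations.tsv"))
  write_comparison(run$comparison, file.path(out_dir, "comparison_sets.tsv"))
  if (!is.null(run$external_comparison)) {
    write_tsv_strict(run$external_comparison$detail,
                     file.path(out_dir, "external_comparison.tsv"))
  }
  summ <- data.frame(quantity = names(run$summary),
                     count = as.integer(run$summary))
  write_tsv_strict(summ, file.path(out_dir, "summary.tsv"))
  xt <- as.data.frame(run$cross_tab$cells)
  xt <- cbind(row = rownames(run$cross_tab$cells), xt)
  write_tsv_strict(xt, file.path(out_dir, "cross_tab.tsv"))
  write_tsv_strict(run$provenance, file.path(out_dir, "provenance.tsv"))
  write_tsv_strict(run$tc_distribution,
                   file.path(out_dir, "tc_distribution.tsv"))
  reports <- list(
    summary = as.list(run$summary),
    cross_tab = list(cells = run$cross_tab$cells,
                     grand_total = run$cross_tab$grand_total),
    provenance = run$provenance,
    tc_distribution = run$tc_distribution
  )
  if (!is.null(run$external_comparison)) {
    reports$external_comparison <- list(
      counts = as.list(run$external_comparison$counts),
      buckets = as.list(run$external_comparison$buckets))
  }
  jsonlite::write_json(reports, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ann <- run$annotations
  gb <- data.frame(locus_tag = ann$locus_tag, product = ann$product,
                   stringsAsFactors = FALSE)
  gb$ecs <- ann$ecs
  gb$tc <- ifelse(is.na(ann$tcs), NA_character_, ann$tcs)
  gb$substrates <- ann$substrates
  write_genbank(run$genome, gb, file.path(out_dir, "genbank"))
  invisible(out_dir)
}
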