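mk_decision <- function(locus, status = "annotated", product = "p",
                        ecs = character(0), code = "M-U") {
  structure(list(locus = locus, status = status, product = product,
                 ec_set = ecs, provenance_code = code,
                 deciding_sources = character(0), path_trace = character(0),
                 flags = character(0)), class = "curation_decision")
}

mk_call <- function(locus, status = "annotated", tcs = "3.A.3",
                    family = "3.A.3.1", substrates = "sodium") {
  structure(list(locus = locus, status = status,
                 tcs_number = if (status == "annotated") tcs else NA_character_,
                 best_family = if (status == "annotated") family else NA_character_,
                 substrates = substrates, family_scores = NULL,
                 substrate_scores = NULL, kept = NULL, threshold = 0.1),
            class = "transporter_call")
}

# build a one-row annotation table directly
ann_row <- function(locus, ecs, tcs = NA_character_, product = "p",
                    code = "M-U") {
  out <- data.frame(locus_tag = locus, product = product, tcs = tcs,
                    tc_family = tcs, provenance_code = code,
                    stringsAsFactors = FALSE)
  out$ecs <- list(ecs)
  out$substrates <- list(character(0))
  cls <- classify_function(out)
  cbind(out, cls)
}

test_that("merging keeps dual payloads and defaults transporter products", {
  decisions <- list(
    ENZ = mk_decision("ENZ", ecs = "1.1.1.1", product = "dehydrogenase"),
    DUAL = mk_decision("DUAL", ecs = "3.6.3.7",
                       product = "sodium-exporting ATPase"),
    GONE = mk_decision("GONE", status = "discarded", product = "")
  )
  calls <- list(
    DUAL = mk_call("DUAL"),
    TONLY = mk_call("TONLY", tcs = "2.A.1", family = "2.A.1.1",
                    substrates = "glucose"),
    TGONE = mk_call("TGONE", status = "discarded")
  )
  ann <- merge_annotations(decisions, calls)
  expect_setequal(ann$locus_tag, c("ENZ", "DUAL", "TONLY"))
  dual <- ann[ann$locus_tag == "DUAL", ]
  expect_equal(dual$category, "with_tc")
  expect_equal(dual$ecs[[1]], "3.6.3.7")
  expect_equal(dual$tcs, "3.A.3")
  expect_equal(dual$product, "sodium-exporting ATPase")  # enzymatic wins
  tonly <- ann[ann$locus_tag == "TONLY", ]
  expect_equal(tonly$category, "transporter_only")
  expect_equal(tonly$product, "2.A.1.1 family transporter")
  expect_equal(tonly$provenance_code, "T")
})

test_that("functional classification follows the category and main-function rules", {
  a <- ann_row("A", c("2.3.1.23", "2.3.1.51"))
  expect_equal(a$category, "multifunctional")
  expect_equal(a$ec_class, "transferase")
  expect_equal(a$completeness, "complete")

  b <- ann_row("B", c("6.3.5.5", "2.1.3.2"))
  expect_equal(b$category, "multiclass")
  expect_equal(b$ec_class, "ligase")  # first-annotated EC is the main function

  c_ <- ann_row("C", "1.-.-.-")
  expect_equal(c_$category, "monofunctional")
  expect_equal(c_$ec_class, "oxidoreductase")
  expect_equal(c_$completeness, "partial")

  d <- ann_row("D", c("3.6.3.7"), tcs = "3.A.3")
  expect_equal(d$category, "with_tc")  # TC presence takes precedence

  # any partial EC makes the whole gene partial, even with a TC number
  e <- ann_row("E", c("2.3.1.23", "2.-.-.-"), tcs = "2.A.1")
  expect_equal(e$completeness, "partial")
  expect_equal(e$category, "with_tc")
})

test_that("the cross-tabulation conserves its marginals", {
  rows <- rbind(ann_row("H1", "3.1.3.2"), ann_row("H2", "3.1.3.2"),
                ann_row("H3", "3.2.1.21"))
  xt <- cross_tabulate(rows)
  expect_equal(xt$cells["complete.monofunctional", "hydrolase"], 3L)
  expect_equal(xt$grand_total, 3L)
  expect_equal(sum(xt$class_totals), xt$grand_total)

  empty <- cross_tabulate(rows[0, ])
  expect_true(all(empty$cells == 0L))
  expect_equal(empty$grand_total, 0L)

  set.seed(77)
  pool <- c("1.1.1.1", "2.3.1.23", "2.3.1.51", "3.2.1.21", "4.2.1.51",
            "5.4.99.5", "6.3.5.7", "1.-.-.-", "3.2.2.-")
  rnd <- do.call(rbind, lapply(1:60, function(i) {
    ann_row(sprintf("L%02d", i), sample(pool, sample(1:3, 1)),
            tcs = if (i %% 5 == 0) "2.A.1" else NA_character_)
  }))
  xt2 <- cross_tabulate(rnd)
  expect_equal(sum(xt2$cells), nrow(rnd))  # every EC-bearing gene lands once
  expect_equal(unname(xt2$subtotal_complete + xt2$subtotal_partial),
               unname(xt2$class_totals))
  expect_equal(xt2$grand_total, sum(xt2$class_totals))
})

test_that("external comparison categorizes loci and buckets the new ones", {
  ann <- rbind(
    ann_row("SAME", "2.7.1.1"),
    ann_row("MORE", c("2.3.1.86", "4.2.1.61", "1.3.1.9", "2.3.1.38",
                      "2.3.1.39", "3.1.2.14")),
    ann_row("REFINED", "3.2.2.27"),
    ann_row("FEWER", "6.3.5.7"),
    ann_row("CLASH", "1.1.1.307"),
    ann_row("NEWC", "5.4.99.5"),
    ann_row("NEWP", "1.13.-.-"),
    ann_row("NEWD", "3.6.3.7", tcs = "3.A.3"),
    ann_row("NEWT", character(0), tcs = "2.A.1")
  )
  external <- list(
    SAME = "2.7.1.1",
    MORE = "2.3.1.86",                 # ours strictly extends the external set
    REFINED = "3.2.2.-",               # ours completes an external partial
    FEWER = c("6.3.5.6", "6.3.5.7"),
    CLASH = "1.1.1.306",
    RULED = "2.7.7.7",                 # externally metabolic, discarded by us
    GHOST = "9.9.9.1"
  )
  rep_ <- compare_external(ann, external, discarded = "RULED")
  d <- rep_$detail
  cat_of <- function(l) d$category[d$locus_tag == l]
  expect_equal(cat_of("SAME"), "match")
  expect_equal(cat_of("MORE"), "superset")
  expect_equal(cat_of("REFINED"), "superset")
  expect_equal(cat_of("FEWER"), "subset")
  expect_equal(cat_of("CLASH"), "conflict")
  expect_equal(cat_of("RULED"), "ruled_out")
  expect_equal(cat_of("GHOST"), "absent_in_ours")
  expect_equal(unname(rep_$counts["new_in_ours"]), 4L)
  expect_equal(unname(rep_$buckets),
               c(1L, 1L, 1L, 0L, 1L))  # complete/complete+tc/partial/partial+tc/tc-only
  expect_equal(sum(rep_$buckets), unname(rep_$counts["new_in_ours"]))
  # the categories partition the union of loci
  expect_equal(sum(rep_$counts), length(union(ann$locus_tag, names(external))))
})

test_that("percentage shares reproduce worked-example arithmetic", {
  expect_equal(round_half_up(c(81.975, 2.444, 0.005, -0.005), 2),
               c(81.98, 2.44, 0.01, -0.01))
  shares <- share_table(c(sc = 1442, other = 43, tcs = 270, tc = 4))
  expect_equal(shares$share_percent, c(81.98, 2.44, 15.35, 0.23))
  expect_equal(nrow(share_table(numeric(0))), 0L)  # zero total: empty report
})

test_that("TC-class distribution covers transporter-only genes", {
  ann <- rbind(ann_row("T1", character(0), tcs = "2.A.1"),
               ann_row("T2", character(0), tcs = "2.A.50"),
               ann_row("T3", character(0), tcs = "3.A.3"),
               ann_row("D1", "1.1.1.1", tcs = "3.A.3"))
  tcd <- tc_distribution(ann)
  expect_equal(tcd$share_percent[tcd$group == "2"], 66.67)
  expect_equal(sum(tcd$count), 3)  # the dual gene is excluded
  single <- tc_distribution(ann_row("T1", character(0), tcs = "2.A.1"))
  expect_equal(single$share_percent, 100.00)
})

test_that("provenance shares split yeast homologues from other organisms", {
  ann <- rbind(ann_row("A", "1.1.1.1", code = "M-SU"),
               ann_row("B", "2.2.2.2", code = "N-H"),
               ann_row("C", character(0), tcs = "2.A.1", code = "T"))
  prov <- provenance_summary(ann)
  expect_equal(prov$count[prov$group == "sc_homologue"], 1)
  expect_equal(prov$count[prov$group == "other_homologue"], 1)
  expect_equal(prov$count[prov$group == "transporter_only"], 1)
  expect_equal(sum(prov$share_percent), 100, tolerance = 0.02)
})
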