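cfg <- scoring_config(alpha = 0.2, query_lineage = QUERY_LIN)

test_that("hit filtering applies ceiling, ordering and truncation", {
  hits <- make_hits(accessions = sprintf("A%03d", 1:150),
                    evalues = 10^-seq(60, 31.2, length.out = 150))
  kept <- filter_hits(hits, cfg)
  expect_equal(nrow(kept), 100L)  # top 100 most similar homologues
  expect_true(all(diff(kept$evalue) >= 0))

  none <- make_hits(accessions = c("A", "B"), evalues = c(1e-20, 1e-5))
  expect_equal(nrow(filter_hits(none, cfg)), 0L)

  tied <- make_hits(accessions = c("A", "B"), evalues = c(1e-40, 1e-40),
                    bits = c(100, 300))
  expect_equal(filter_hits(tied, cfg)$subject_accession, c("B", "A"))
  expect_error(filter_hits(rbind(hits, make_hits("OTHER", "Z", 1e-40)), cfg),
               "single query")
})

test_that("frequency score is the carrier fraction", {
  all_carry <- make_hits(accessions = sprintf("A%d", 1:100),
                         evalues = rep(1e-40, 100),
                         ecs = rep(list("1.1.1.1"), 100))
  expect_equal(score_frequency("1.1.1.1", all_carry), 1.0)

  some <- make_hits(accessions = sprintf("A%d", 1:10), evalues = rep(1e-40, 10),
                    ecs = c(rep(list("2.3.1.23"), 4), rep(list("9.9.9.9"), 6)))
  expect_equal(score_frequency("2.3.1.23", some), 0.4)
  expect_equal(score_frequency("5.5.5.5", some), 0.0)
  expect_error(score_frequency("1.1.1.1", some[0, ]), "empty hit set")
})

test_that("taxonomy score is the mean shared-prefix fraction", {
  h <- make_hits(accessions = c("A", "B", "C"), evalues = rep(1e-40, 3),
                 ecs = rep(list("1.1.1.1"), 3),
                 lineages = list(QUERY_LIN, SC_LIN, character(0)))
  expect_equal(score_taxonomy("1.1.1.1", h[1, ], QUERY_LIN), 1.0)
  expect_equal(score_taxonomy("1.1.1.1", h[2, ], QUERY_LIN), 6 / 7)
  expect_equal(score_taxonomy("1.1.1.1", h[3, ], QUERY_LIN), 0.0)
  expect_equal(score_taxonomy("1.1.1.1", h, QUERY_LIN), mean(c(1, 6 / 7, 0)))
  expect_error(score_taxonomy("1.1.1.1", h, character(0)), "empty query lineage")
})

test_that("combined score is the stated convex combination", {
  # f = 0.5, t = 1.0, alpha = 0.2 -> 0.2*0.5 + 0.8*1.0 = 0.9
  h <- make_hits(accessions = c("A", "B"), evalues = c(1e-40, 1e-40),
                 ecs = list("1.1.1.1", character(0)),
                 lineages = list(QUERY_LIN, QUERY_LIN))
  rc <- rank_candidates(h, cfg)
  row <- rc[rc$label == "1.1.1.1", ]
  expect_equal(row$score_frequency, 0.5)
  expect_equal(row$score_taxonomy, 1.0)
  expect_equal(row$score_annotation, 0.9)
})

test_that("a minority function on close homologues outranks a distant majority", {
  # candidate A on 60/100 distant-lineage hits, candidate B on 30/100
  # same-family hits: at alpha = 0.2 taxonomy dominates and B wins
  h <- make_hits(
    accessions = sprintf("A%03d", 1:100), evalues = rep(1e-40, 100),
    ecs = c(rep(list("1.1.1.1"), 60), rep(list("2.2.2.2"), 30),
            rep(list(character(0)), 10)),
    lineages = c(rep(list(FAR_LIN), 60), rep(list(SC_LIN), 30),
                 rep(list(SC_LIN), 10))
  )
  rc <- rank_candidates(h, cfg)
  ec_rank <- rc$label[rc$type == "ec"]
  expect_equal(ec_rank[1], "2.2.2.2")
  # independently recomputed by the brute-force oracle
  orc <- oracle_scores(h, 0.2, QUERY_LIN)
  expect_gt(orc$s[orc$label == "2.2.2.2"], orc$s[orc$label == "1.1.1.1"])
})

test_that("alpha limits reduce to frequency-only and taxonomy-only rankings", {
  h <- random_hit_table(15, seed = 11)
  rc1 <- rank_candidates(h, scoring_config(alpha = 1, query_lineage = QUERY_LIN))
  expect_equal(rc1$score_annotation, rc1$score_frequency)
  rc0 <- rank_candidates(h, scoring_config(alpha = 0, query_lineage = QUERY_LIN))
  expect_equal(rc0$score_annotation, rc0$score_taxonomy)
})

test_that("ranking matches the brute-force oracle on random tables", {
  for (seed in 1:12) {
    n <- 4 + (seed %% 17)
    h <- random_hit_table(n, seed = seed)
    rc <- rank_candidates(h, cfg)
    orc <- oracle_scores(h, 0.2, QUERY_LIN)
    expect_equal(nrow(rc), nrow(orc))
    idx <- match(rc$label, orc$label)
    expect_false(anyNA(idx))
    expect_equal(rc$score_frequency, orc$f[idx], tolerance = 1e-12)
    expect_equal(rc$score_taxonomy, orc$t[idx], tolerance = 1e-12)
    expect_equal(rc$score_annotation, orc$s[idx], tolerance = 1e-12)
    expect_equal(rc$supporting_hits, orc$supp[idx])
    # convexity: min(f, t) <= combined <= max(f, t)
    expect_true(all(rc$score_annotation >= pmin(rc$score_frequency,
                                                rc$score_taxonomy) - 1e-12))
    expect_true(all(rc$score_annotation <= pmax(rc$score_frequency,
                                                rc$score_taxonomy) + 1e-12))
    # every emitted frequency lies in (0, 1]; 1 iff all hits carry the label
    expect_true(all(rc$score_frequency > 0 & rc$score_frequency <= 1))
    expect_equal(rc$score_frequency == 1, rc$supporting_hits == nrow(h))
    # ranking is the total order (-score, partial, -support, label)
    key <- order(-rc$score_annotation, rc$partial, -rc$supporting_hits, rc$label)
    expect_equal(key, seq_len(nrow(rc)))
    # determinism: identical input, identical output
    expect_identical(rc, rank_candidates(h, cfg))
  }
})

test_that("annotation selection picks the top EC and its supporting product", {
  expect_null(select_annotation(NULL))
  h <- make_hits(accessions = c("A", "B"), evalues = c(1e-40, 1e-40),
                 ecs = list("1.1.1.1", "1.1.1.1"),
                 products = c("alcohol dehydrogenase", "alcohol dehydrogenase"),
                 lineages = list(SC_LIN, SC_LIN))
  sel <- select_annotation(rank_candidates(h, cfg), h)
  expect_equal(sel$ecs, "1.1.1.1")
  expect_equal(sel$product, "alcohol dehydrogenase")

  # complete EC and its partial prefix tied on score: the complete one wins
  h2 <- make_hits(accessions = c("A", "B"), evalues = c(1e-40, 1e-40),
                  ecs = list(c("3.2.2.27", "3.2.2.-"), c("3.2.2.27", "3.2.2.-")),
                  lineages = list(SC_LIN, SC_LIN))
  rc2 <- rank_candidates(h2, cfg)
  expect_equal(rc2$score_annotation[1], rc2$score_annotation[2])
  expect_equal(select_annotation(rc2, h2)$ecs, "3.2.2.27")

  # no EC candidates: product-only selection, which is not an EEGC
  h3 <- make_hits(accessions = "A", evalues = 1e-40,
                  products = "structural protein", lineages = list(SC_LIN))
  sel3 <- select_annotation(rank_candidates(h3, cfg), h3)
  expect_equal(sel3$ecs, character(0))
  expect_equal(sel3$product, "structural protein")
})

test_that("project annotation marks EEGCs as loci whose selection carries an EC", {
  hits <- rbind(
    make_hits("ENZ1", accessions = c("A", "B"), evalues = c(1e-40, 1e-35),
              ecs = list("1.1.1.1", "1.1.1.1"), lineages = list(SC_LIN, SC_LIN)),
    make_hits("PROD1", accessions = "C", evalues = 1e-40,
              products = "ribosomal protein", lineages = list(SC_LIN)),
    make_hits("WEAK1", accessions = "D", evalues = 1e-10)
  )
  proj <- annotate_project(hits, cfg, "nr")
  expect_equal(proj$eegc, "ENZ1")
  expect_named(proj$selected, c("ENZ1", "PROD1"))
  expect_false("WEAK1" %in% names(proj$retained))  # over the e-value ceiling
})
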