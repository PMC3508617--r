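cfgc <- pipeline_config()
REG <- make_registry(
  ec = c("1.1.1.306", "2.7.1.2", "3.2.2.27", "1.1.1.109", "6.3.5.6",
         "3.1.3.2"),
  status = c("active", "active", "active", "deprecated", "deprecated",
             "active"),
  transfers = list(character(0), character(0), character(0),
                   c("1.3.1.28", "1.3.1.29"), "6.3.5.7", character(0)),
  names = list("aldose reductase", "glucokinase",
               "dna-3-methyladenine glycosylase", character(0), character(0),
               "acid phosphatase")
)

entry <- function(product, ecs) list(product = product, ecs = ecs)

test_that("UniProt/SGD reconciliation favours SGD on disagreement", {
  same <- reconcile_uniprot_sgd(entry("aldose reductase", "1.1.1.306"),
                                entry("aldose reductase", "1.1.1.306"))
  expect_equal(same$ecs, "1.1.1.306")
  expect_true(same$agreed)
  diff <- reconcile_uniprot_sgd(entry("hexokinase", "2.7.1.1"),
                                entry("glucokinase", "2.7.1.2"))
  expect_equal(diff$ecs, "2.7.1.2")
  expect_equal(diff$product, "glucokinase")
  expect_false(diff$agreed)
  expect_null(reconcile_uniprot_sgd(NULL, NULL))
  # a single present entry stands on its own
  expect_equal(reconcile_uniprot_sgd(entry("x", "1.1.1.306"), NULL)$ecs,
               "1.1.1.306")
})

test_that("registry verification upgrades, transfers and flags EC numbers", {
  up <- verify_ec("3.2.2.-", "DNA-3-methyladenine glycosylase", REG)
  expect_equal(up$ecs, "3.2.2.27")
  expect_true("upgraded" %in% up$flags)
  expect_true(up$revised)

  keep <- verify_ec("1.1.1.306", "aldose reductase", REG)
  expect_equal(keep$ecs, "1.1.1.306")
  expect_false(keep$revised)

  split <- verify_ec("1.1.1.109", "old oxidoreductase", REG)
  expect_equal(split$ecs, c("1.3.1.28", "1.3.1.29"))
  expect_true("split" %in% split$flags)

  transf <- verify_ec("6.3.5.6", "amidotransferase", REG)
  expect_equal(transf$ecs, "6.3.5.7")
  expect_true("transferred" %in% transf$flags)

  unk <- verify_ec("9.9.9.9", "mystery", REG)
  expect_equal(unk$ecs, "9.9.9.9")
  expect_true("unknown" %in% unk$flags)

  # no upgrade without a unique product-name match among active entries
  noname <- verify_ec("3.2.2.-", "some other protein", REG)
  expect_equal(noname$ecs, "3.2.2.-")
  expect_false("upgraded" %in% noname$flags)
})

test_that("provenance codes combine origin and sorted source letters", {
  expect_equal(assign_code("M", c("U", "B")), "M-BU")
  expect_equal(assign_code("N", "H"), "N-H")
  expect_equal(assign_code("Y", c("S", "U")), "Y-SU")
  expect_equal(assign_code("T", character(0)), "T")
  expect_error(assign_code("X", "U"))
  expect_error(assign_code("M", "Q"), "unknown evidence source")
})

sc_hit <- make_hits(accessions = c("YHR104W", "P00001"),
                    evalues = c(1e-60, 1e-45), bits = c(300, 200),
                    ecs = list("1.1.1.306", "1.1.1.306"),
                    lineages = list(SC_LIN, SC_LIN))

test_that("a reviewed record wins at step A with source U", {
  ev <- make_evidence(reviewed = entry("aldose reductase", "1.1.1.306"))
  d <- decide("L1", sc_hit, ev, REG, cfgc, origin = "M")
  expect_equal(d$status, "annotated")
  expect_equal(d$ec_set, "1.1.1.306")
  expect_equal(d$provenance_code, "M-U")
  expect_true("A" %in% d$path_trace)
})

test_that("step B1 reconciles the best yeast homologue's entries", {
  ev <- make_evidence(sc_entries = list(YHR104W = list(
    uniprot = entry("aldose reductase", "1.1.1.306"),
    sgd = entry("aldose reductase", "1.1.1.306"))))
  d <- decide("L2", sc_hit, ev, REG, cfgc, origin = "M")
  expect_equal(d$ec_set, "1.1.1.306")
  expect_setequal(d$deciding_sources, c("U", "S"))
  expect_equal(d$provenance_code, "M-SU")

  # disagreement: SGD favoured and flagged
  ev2 <- make_evidence(sc_entries = list(YHR104W = list(
    uniprot = entry("hexokinase", "2.7.1.1"),
    sgd = entry("glucokinase", "2.7.1.2"))))
  d2 <- decide("L2", sc_hit, ev2, REG, cfgc, origin = "D")
  expect_equal(d2$ec_set, "2.7.1.2")
  expect_true("sgd_favoured" %in% d2$flags)

  # a Y-identifier present in the map with no entry at all is a hard error
  ev3 <- make_evidence(sc_entries = list(YHR104W = list(uniprot = NULL,
                                                        sgd = NULL)))
  expect_error(decide("L2", sc_hit, ev3, REG, cfgc), "YHR104W")
})

test_that("step B2 falls back to restricted then unrestricted searches", {
  far_hits <- make_hits(accessions = c("Q1", "Q2"), evalues = c(1e-40, 1e-35),
                        ecs = list("3.1.3.2", "3.1.3.2"),
                        lineages = list(FAR_LIN, FAR_LIN))
  evr <- make_evidence(restricted = make_ev_hits(
    c("SP2", "SP1"), c(1e-15, 1e-22), "acid phosphatase",
    list("3.1.3.2", "3.1.3.2")))
  d <- decide("L3", far_hits, evr, REG, cfgc, origin = "N")
  expect_equal(d$status, "annotated")
  expect_equal(d$provenance_code, "N-H")
  expect_true("B2-restricted" %in% d$path_trace)
  # the best (lowest e-value) restricted hit decides
  expect_equal(d$product, "acid phosphatase")

  evu <- make_evidence(unrestricted = make_ev_hits(
    "TR1", 1e-12, "acid phosphatase", list("3.1.3.2")))
  d2 <- decide("L3", far_hits, evu, REG, cfgc, origin = "N")
  expect_true("B2-unrestricted" %in% d2$path_trace)
  expect_equal(d2$provenance_code, "N-H")

  # restricted hits above the lowered ceiling do not qualify
  ev_weak <- make_evidence(restricted = make_ev_hits(
    "SP1", 1e-8, "acid phosphatase", list("3.1.3.2")))
  d3 <- decide("L3", far_hits, ev_weak, REG, cfgc, origin = "N")
  expect_equal(d3$status, "discarded")
  expect_equal(d3$ec_set, character(0))
  expect_equal(d3$provenance_code, "N")
})

test_that("a literature override wins outright and conflicts are flagged", {
  ev <- make_evidence(
    reviewed = entry("aldose reductase", "1.1.1.306"),
    literature = c(entry("D-xylose reductase", "1.1.1.307"),
                   list(citation = "ref:XYL1")))
  d <- decide("L4", sc_hit, ev, REG, cfgc, origin = "M")
  expect_equal(d$ec_set, "1.1.1.307")
  expect_true("L" %in% d$deciding_sources)
  expect_true("literature_overrides_reviewed" %in% d$flags)
  expect_true(grepl("L", d$provenance_code))
})

test_that("registry revision during curation adds the B source letter", {
  ev <- make_evidence(reviewed = entry("DNA-3-methyladenine glycosylase",
                                       "3.2.2.-"))
  d <- decide("L5", sc_hit[0, ], ev, REG, cfgc, origin = "M")
  expect_equal(d$ec_set, "3.2.2.27")
  expect_equal(d$provenance_code, "M-BU")
})

test_that("decisions are deterministic and evidence is monotone", {
  ev_none <- make_evidence()
  d1 <- decide("L6", sc_hit[0, ], ev_none, REG, cfgc, origin = "N")
  expect_equal(d1$status, "discarded")
  expect_identical(d1, decide("L6", sc_hit[0, ], ev_none, REG, cfgc,
                              origin = "N"))
  # adding a reviewed record to a discarded gene's bundle annotates it
  ev_rev <- make_evidence(reviewed = entry("acid phosphatase", "3.1.3.2"))
  d2 <- decide("L6", sc_hit[0, ], ev_rev, REG, cfgc, origin = "N")
  expect_equal(d2$status, "annotated")
})

test_that("annotated decisions carry only active or flagged-unknown ECs", {
  evs <- list(
    make_evidence(reviewed = entry("aldose reductase", "1.1.1.306")),
    make_evidence(reviewed = entry("old oxidoreductase", "1.1.1.109")),
    make_evidence(reviewed = entry("amidotransferase", "6.3.5.6")),
    make_evidence(reviewed = entry("mystery", "9.9.9.9"))
  )
  for (ev in evs) {
    d <- decide("LX", sc_hit[0, ], ev, REG, cfgc)
    deprecated <- d$ec_set %in% REG$ec[REG$status == "deprecated"]
    expect_false(any(deprecated))
    unknown <- !d$ec_set %in% REG$ec
    if (any(unknown)) expect_true("unknown" %in% d$flags)
  }
})
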