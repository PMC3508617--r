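B62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("self-alignment scores the diagonal sum with similarity one", {
  s <- "MKVLWAAC"
  aln <- smith_waterman(s, s)
  expect_equal(aln$score,
               sum(diag(B62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  expect_equal(aln$similarity_fraction, 1.0)
  expect_equal(aln$identities, nchar(s))
  expect_equal(aln$identity_fraction, 1.0)
})

test_that("sequences with no positive-scoring pair align to nothing", {
  # hydrophobic versus charged residues: every cross pair scores negative
  aln <- smith_waterman("LLIVML", "DDEKRD")
  expect_equal(aln$score, 0)
  expect_equal(aln$alignment_length, 0L)
  expect_equal(aln$similarity_fraction, 0)
  expect_error(smith_waterman("", "MK"), "empty sequence")
})

test_that("alignment counts are internally consistent", {
  set.seed(5)
  alpha <- c("A", "C", "D", "E", "K", "L", "S", "W", "Y")
  for (k in 1:20) {
    a <- paste(sample(alpha, sample(5:30, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(5:30, 1), TRUE), collapse = "")
    aln <- smith_waterman(a, b)
    expect_lte(aln$identities, aln$positives)
    expect_lte(aln$positives, aln$alignment_length)
    if (aln$alignment_length > 0) {
      expect_equal(aln$similarity_fraction,
                   aln$positives / aln$alignment_length)
      expect_equal(nchar(aln$aligned_a), aln$alignment_length)
      # traceback spells subsequences of the inputs
      expect_true(grepl(gsub("-", "", aln$aligned_a), a, fixed = TRUE))
      expect_true(grepl(gsub("-", "", aln$aligned_b), b, fixed = TRUE))
    }
    # symmetry under a symmetric matrix, and self-dominance
    expect_equal(aln$score, smith_waterman(b, a)$score)
    expect_gte(smith_waterman(a, a)$score, aln$score)
  }
})

test_that("scores match the exhaustive enumeration oracle on short pairs", {
  seqs <- all_seqs(c("A", "D"), 3)
  for (a in seqs) for (b in seqs) {
    expect_equal(smith_waterman(a, b)$score, oracle_sw(a, b, B62, 10, 0.5))
  }
  set.seed(9)
  alpha4 <- c("A", "C", "D", "W")
  for (k in 1:25) {
    a <- paste(sample(alpha4, sample(2:5, 1), TRUE), collapse = "")
    b <- paste(sample(alpha4, sample(2:5, 1), TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, oracle_sw(a, b, B62, 10, 0.5))
  }
})

test_that("scores match an independent reference and Biostrings on long pairs", {
  set.seed(13)
  alpha <- rownames(B62)[1:20]
  for (k in 1:15) {
    a <- paste(sample(alpha, sample(15:60, 1), TRUE), collapse = "")
    b <- paste(sample(alpha, sample(15:60, 1), TRUE), collapse = "")
    s <- smith_waterman(a, b)$score
    expect_equal(s, oracle_sw_ref(a, b, B62, 10, 0.5))
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(s, Biostrings::score(pw))
  }
})

test_that("the helix-scaled threshold divides and clamps", {
  expect_equal(effective_threshold(0.10, 0.02, 1), 0.10)
  expect_equal(effective_threshold(0.10, 0.02, 5), 0.02)
  expect_equal(effective_threshold(0.10, 0.02, 20), 0.02)  # floor clamp
  expect_equal(effective_threshold(0.10, 0.02, 2), 0.05)
  expect_error(effective_threshold(0.10, 0.02, 0), "helix_count")
  # non-increasing in the helix count
  thr <- vapply(1:20, function(h) effective_threshold(0.10, 0.02, h), 0)
  expect_true(all(diff(thr) <= 0))
})

test_that("TPGC selection keeps genes with at least one helix", {
  tm <- data.frame(locus_tag = c("L0", "L1", "L12"),
                   helices = c(0L, 1L, 12L), stringsAsFactors = FALSE)
  expect_setequal(filter_tpgc(tm), c("L1", "L12"))
  expect_equal(filter_tpgc(tm, transporter_config(min_helices = 2)), "L12")
})

# toy TC reference built in code: two porter families plus an ATPase
# superfamily split over two subfamilies, on mutually non-positive residue
# groups so cross-family similarity is exactly zero
make_toy_tcdb <- function() {
  set.seed(101)
  sugar_seed <- paste(sample(c("L", "I", "V", "M"), 80, TRUE), collapse = "")
  atpase_seed <- paste(sample(c("F", "Y", "W"), 80, TRUE), collapse = "")
  mut <- function(seed, alpha) {
    ch <- strsplit(seed, "")[[1]]
    idx <- sample(length(ch), 6)
    ch[idx] <- sample(alpha, 6, TRUE)
    paste(ch, collapse = "")
  }
  df <- data.frame(
    accession = sprintf("T%03d", 1:6),
    tc_number = c("2.A.1.1.1", "2.A.1.1.2", "2.A.1.1.3",
                  "3.A.3.1.1", "3.A.3.2.1", "3.A.3.2.2"),
    sequence = c(mut(sugar_seed, c("L", "I", "V", "M")),
                 mut(sugar_seed, c("L", "I", "V", "M")),
                 mut(sugar_seed, c("L", "I", "V", "M")),
                 mut(atpase_seed, c("F", "Y", "W")),
                 mut(atpase_seed, c("F", "Y", "W")),
                 mut(atpase_seed, c("F", "Y", "W"))),
    stringsAsFactors = FALSE
  )
  df$substrates <- list(c("glucose"), c("glucose"), c("glucose"),
                        c("sodium"), c("sodium"), c("sodium"))
  attr(df, "seeds") <- c(sugar = sugar_seed, atpase = atpase_seed)
  df
}

test_that("a sugar-porter-like candidate rolls up to its superfamily number", {
  tcdb <- make_toy_tcdb()
  query <- attr(tcdb, "seeds")[["sugar"]]
  call <- classify_tc("LOC1", query, 12L, tcdb)
  expect_equal(call$status, "annotated")
  expect_equal(call$best_family, "2.A.1.1")
  expect_equal(call$tcs_number, "2.A.1")
  expect_equal(call$substrates, "glucose")
  # only the own family is kept: cross-group alignments score zero
  expect_true(all(tc_prefix(call$kept$tc_number, 4) == "2.A.1.1"))
})

test_that("kept hits across subfamilies of one superfamily still agree on TCS", {
  tcdb <- make_toy_tcdb()
  query <- attr(tcdb, "seeds")[["atpase"]]
  call <- classify_tc("LOC2", query, 8L, tcdb)
  expect_equal(call$status, "annotated")
  # hits span families 3.A.3.1 and 3.A.3.2; the winner's rolled-up TCS is 3.A.3
  expect_setequal(unique(tc_prefix(call$kept$tc_number, 3)), "3.A.3")
  expect_equal(call$tcs_number, "3.A.3")
  expect_true("sodium" %in% call$substrates)
})

test_that("candidates without reference similarity are discarded", {
  tcdb <- make_toy_tcdb()
  call <- classify_tc("LOC3", strrep("GP", 40), 3L, tcdb)
  expect_equal(call$status, "discarded")
  expect_true(is.na(call$tcs_number))
  expect_error(classify_tc("L", "MK", 1L, tcdb[0, ]), "empty TC reference")
})

test_that("the kept-hit set grows (weakly) with the helix count", {
  tcdb <- make_toy_tcdb()
  query <- attr(tcdb, "seeds")[["sugar"]]
  kept_sizes <- vapply(1:12, function(h) {
    nrow(classify_tc("L", query, h, tcdb)$kept)
  }, integer(1))
  expect_true(all(diff(kept_sizes) >= 0))
})

test_that("every TPGC is classified exactly once as annotated or discarded", {
  tcdb <- make_toy_tcdb()
  genome <- data.frame(
    locus_tag = c("T1", "T2", "N1", "E1"),
    protein_sequence = c(attr(tcdb, "seeds")[["sugar"]],
                         attr(tcdb, "seeds")[["atpase"]],
                         strrep("GP", 30), "MKVL"),
    chromosome_id = "c", start = 1L, end = 10L, strand = "+",
    description = "", coords_known = FALSE, stringsAsFactors = FALSE
  )
  tm <- data.frame(locus_tag = c("T1", "T2", "N1", "E1"),
                   helices = c(10L, 6L, 2L, 0L), stringsAsFactors = FALSE)
  calls <- annotate_transporters(genome, tm, tcdb)
  expect_setequal(names(calls), c("T1", "T2", "N1"))  # E1 has no helices
  status <- vapply(calls, function(x) x$status, character(1))
  expect_true(all(status %in% c("annotated", "discarded")))
  expect_equal(unname(status[c("T1", "T2", "N1")]),
               c("annotated", "annotated", "discarded"))
})
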