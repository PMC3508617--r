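#' Synthetic fixture generation with planted ground truth
#'
#' Generates, under a fixed seed, every input the annotation pipeline
#' consumes — proteome FASTA, two projects' homology hit tables with
#' annotation sidecars, transmembrane-helix summaries, a toy TC-numbered
#' reference database with substrates, an EC registry, evidence bundles and
#' an external annotation — together with a ground-truth table recording
#' each locus's intended product, EC set, TCS number, curation path and
#' external-comparison category.  On noiseless settings the pipeline
#' recovers the planted annotation exactly, by construction.
#'
#' Homologue tables are built so that the convex-combination scorer's
#' winner at the configured alpha is the planted function: the planted EC
#' rides on homologues of a taxonomically close lineage (6 of 7 shared
#' ranks) while distractor ECs ride on distant-lineage homologues, so a
#' taxonomy-weighted alpha selects the planted EC even when the distractor
#' is more frequent.
#'
#' Reference-database sequences are drawn from residue groups whose
#' BLOSUM62 cross-scores are all non-positive (e.g. hydrophobic versus
#' charged residues), so a candidate built by mutating one family's seed
#' aligns with high similarity to its own family and with exactly zero
#' Smith-Waterman score to every other family.  This makes planted
#' transporter calls exact at any helix-scaled threshold; it is a testing
#' device, not a model of sequence evolution.
#'
#' @name fixtures
NULL

.QUERY_LINEAGE <- c("Eukaryota", "Fungi", "Ascomycota", "Saccharomycotina",
                    "Saccharomycetales", "Saccharomycetaceae",
                    "Kluyveromyces lactis")
.SC_LINEAGE <- c(.QUERY_LINEAGE[1:6], "Saccharomyces cerevisiae")
.BACT_LINEAGE <- c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                   "Enterobacterales", "Enterobacteriaceae", "Escherichia",
                   "Escherichia coli")

# TC families of the toy reference database: residue groups are mutually
# non-positive under BLOSUM62, so cross-family local alignments score zero
.TC_FAMILIES <- list(
  list(family = "2.A.1.1", alphabet = c("L", "I", "V", "M"),
       substrates = c("glucose", "fructose")),
  list(family = "2.A.50.1", alphabet = c("D", "E", "K", "R"),
       substrates = c("glycerol")),
  list(family = "3.A.3.1", alphabet = c("F", "Y", "W"),
       substrates = c("sodium", "potassium")),
  list(family = "1.A.8.5", alphabet = c("S", "T"),
       substrates = c("water", "glycerol")),
  list(family = "4.A.1.1", alphabet = c("C"),
       substrates = c("glucose"))
)
# reserved for non-transporter TPGCs: non-positive against every family group
.NON_TRANSPORTER_ALPHABET <- c("G", "P")

#' Fixture specification
#'
#' Counts of each planted gene role, noise levels and the seed.  Every
#' random draw of the generator is fixed by `seed`.
#'
#' @param n_genes total genes in the genome.
#' @param n_enzymatic exclusively enzymatic genes (EC, no TC).
#' @param n_transporter exclusively transporter genes (TC, no EC).
#' @param n_dual genes with both EC and TC(S) numbers.
#' @param n_false_eegc planted false-positive EEGCs: automatically assigned
#'   an enzymatic function but backed by no evidence, so the curation
#'   pipeline must discard exactly these.
#' @param n_false_tpgc genes with transmembrane helices but no reference
#'   transporter similarity (discarded by the transporter classifier).
#' @param hits_per_gene homologues generated per EEGC per project.
#' @param wrong_ec_prob per-hit probability that the hit's EC annotation is
#'   corrupted (half the corruptions erase the EC set, half swap in a
#'   distractor EC).
#' @param missing_evidence_prob per-locus probability that a true gene's
#'   evidence bundle is dropped (the gene is then discarded, costing
#'   recall).
#' @param path_weights relative frequencies of the planted curation paths
#'   `A`, `B1`, `B1S`, `B2r`, `B2u`, `L`.  The default echoes a curated
#'   yeast re-annotation: the vast majority of genes resolve through
#'   reviewed records or *S. cerevisiae* homologues, ~2.5% through other
#'   organisms' homologues, a handful by literature.
#' @param seed integer seed fixing all draws.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 30L, n_enzymatic = 12L, n_transporter = 6L,
                         n_dual = 2L, n_false_eegc = 3L, n_false_tpgc = 2L,
                         hits_per_gene = 12L, wrong_ec_prob = 0,
                         missing_evidence_prob = 0,
                         path_weights = c(0.30, 0.50, 0.15, 0.015, 0.010, 0.005),
                         seed = 1L) {
  n_meta <- n_enzymatic + n_transporter + n_dual + n_false_eegc + n_false_tpgc
  if (n_meta > n_genes) stop("role counts exceed n_genes")
  if (n_dual > 0L && n_transporter + n_dual == 0L) {
    stop("dual genes require transporter machinery")
  }
  stopifnot(wrong_ec_prob >= 0, wrong_ec_prob <= 1,
            missing_evidence_prob >= 0, missing_evidence_prob <= 1,
            hits_per_gene >= 4L)
  structure(list(
    n_genes = as.integer(n_genes), n_enzymatic = as.integer(n_enzymatic),
    n_transporter = as.integer(n_transporter), n_dual = as.integer(n_dual),
    n_false_eegc = as.integer(n_false_eegc),
    n_false_tpgc = as.integer(n_false_tpgc),
    hits_per_gene = as.integer(hits_per_gene),
    wrong_ec_prob = wrong_ec_prob,
    missing_evidence_prob = missing_evidence_prob,
    path_weights = path_weights,
    seed = as.integer(seed)
  ), class = "fixture_spec")
}

#' Named fixture scenarios
#'
#' * `"tiny"` — 30 loci; runs in seconds, exercises every curation path.
#' * `"paper-shaped"` — 5085 loci with 2000 revised candidates: 1699 EEGCs
#'   (1410 exclusively enzymatic + 48 dual + 241 planted false positives)
#'   and 301 exclusively transporter genes, echoing the funnel of a
#'   genome-scale yeast re-annotation.
#' * `"noisy"` — the tiny scenario with EC corruption and evidence dropout.
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @return a [fixture_spec()].
#' @export
scenario <- function(name, seed = 1L) {
  # the small scenarios flatten the path mix so every curation branch runs
  tiny_paths <- c(0.25, 0.25, 0.15, 0.15, 0.10, 0.10)
  switch(name,
    "tiny" = fixture_spec(path_weights = tiny_paths, seed = seed),
    "paper-shaped" = fixture_spec(
      n_genes = 5085L, n_enzymatic = 1410L, n_transporter = 301L,
      n_dual = 48L, n_false_eegc = 241L, n_false_tpgc = 0L,
      hits_per_gene = 12L, seed = seed),
    "noisy" = fixture_spec(wrong_ec_prob = 0.15,
                           missing_evidence_prob = 0.2,
                           path_weights = tiny_paths, seed = seed),
    stop("unknown scenario '", name,
         "'; known scenarios: tiny, paper-shaped, noisy")
  )
}

.rand_seq <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate, alphabet) {
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

.y_id <- function(i) {
  sprintf("Y%s%s%03d%s", LETTERS[(i %% 26L) + 1L],
          LETTERS[((i %/% 26L) %% 26L) + 1L], i %% 1000L, "C")
}

# deterministic proportional schedule: at every position the label furthest
# below its weight quota is emitted, so any prefix carries near-target
# proportions and rare labels appear as early as their quota allows
.cycle_labels <- function(labels, weights, n) {
  w <- weights / sum(weights)
  counts <- numeric(length(labels))
  out <- character(n)
  for (i in seq_len(n)) {
    j <- which.max(w * i - counts)
    out[i] <- labels[j]
    counts[j] <- counts[j] + 1
  }
  out
}

#' Generate all fixture inputs and the ground truth
#'
#' Writes, under `out_dir`: `genome.fasta`, `query_lineage.txt`,
#' `hits_nr.tsv` / `hits_nr_sidecar.tsv`, `hits_yeast.tsv` /
#' `hits_yeast_sidecar.tsv`, `tm.tsv`, `tcdb.fasta`,
#' `tcdb_substrates.tsv`, `ec_registry.tsv`, `external.tsv`, an
#' `evidence/` directory, and `ground_truth.tsv`.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `dir`, `truth` (ground-truth data.frame)
#'   and `spec`.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "evidence"), showWarnings = FALSE)

  n <- spec$n_genes
  roles <- c(rep("enzymatic", spec$n_enzymatic), rep("dual", spec$n_dual),
             rep("transporter", spec$n_transporter),
             rep("false_eegc", spec$n_false_eegc),
             rep("false_tpgc", spec$n_false_tpgc))
  roles <- c(roles, rep("non_metabolic", n - length(roles)))
  chrom <- LETTERS[((seq_len(n) - 1L) %% 6L) + 1L]
  locus <- sprintf("KLFX0%s%05dg", chrom, seq_len(n) * 11L)

  # --- planted enzymatic functions -----------------------------------------
  ec_bearing <- which(roles %in% c("enzymatic", "dual"))
  n_ec <- length(ec_bearing)
  # cross-tabulation structure: mono / multifunctional / multiclass, and the
  # EC-verification path: plain, partial-upgrade, deprecated-transfer,
  # partial-stay
  shape <- .cycle_labels(c("mono", "multi", "multiclass"), c(0.75, 0.15, 0.10), n_ec)
  verify <- .cycle_labels(c("plain", "upgrade", "transfer", "partial"),
                          c(0.70, 0.10, 0.10, 0.10), n_ec)
  path <- .cycle_labels(c("A", "B1", "B1S", "B2r", "B2u", "L"),
                        spec$path_weights, n_ec)
  origin <- .cycle_labels(c("matches", "distinct", "nr_only", "yeast_only"),
                          c(0.70, 0.10, 0.10, 0.10), n_ec)

  classes <- ((seq_len(n_ec) - 1L) %% 6L) + 1L
  base_ec <- sprintf("%d.%d.%d.%d", classes, (seq_len(n_ec) %% 9L) + 1L,
                     (seq_len(n_ec) %% 7L) + 1L, seq_len(n_ec))
  ec_final <- vector("list", n_ec)      # planted post-verification EC set
  ec_evidence <- vector("list", n_ec)   # EC set carried by the evidence
  for (k in seq_len(n_ec)) {
    e1 <- base_ec[k]
    fin <- e1
    evi <- e1
    if (verify[k] == "upgrade") {
      evi <- sub("[0-9]+$", "-", e1)            # partial in the evidence
    } else if (verify[k] == "transfer") {
      evi <- sprintf("%d.9.9.%d", classes[k], k)  # deprecated, transfers to e1
    } else if (verify[k] == "partial") {
      fin <- evi <- sub("[0-9]+$", "-", e1)     # stays partial
    }
    if (shape[k] == "multi") {
      e2 <- sprintf("%d.%d.%d.%d", classes[k], (k %% 9L) + 1L, (k %% 7L) + 1L,
                    k + n_ec)
      fin <- c(fin, e2); evi <- c(evi, e2)
    } else if (shape[k] == "multiclass") {
      e2 <- sprintf("%d.%d.%d.%d", (classes[k] %% 6L) + 1L, (k %% 9L) + 1L,
                    (k %% 7L) + 1L, k + 2L * n_ec)
      fin <- c(fin, e2); evi <- c(evi, e2)
    }
    ec_final[[k]] <- fin
    ec_evidence[[k]] <- evi
  }
  product_of <- function(k) paste("enzyme", ec_final[[k]][1])
  distractor_ec <- sprintf("5.5.5.%d", seq_len(n_ec))   # losing nr candidates
  junk_ec <- sprintf("9.9.9.%d", seq_len(n))            # false-positive ECs

  # --- planted transporter functions ---------------------------------------
  fam_seed <- lapply(.TC_FAMILIES, function(f) .rand_seq(150L, f$alphabet))
  tc_rows <- which(roles %in% c("transporter", "dual"))
  # ~70% of transporters fall in class 2 families (porter-dominated genome)
  fam_idx_of <- as.integer(.cycle_labels(seq_along(.TC_FAMILIES),
                                         c(0.40, 0.30, 0.12, 0.10, 0.08),
                                         length(tc_rows)))

  # --- genome sequences and TM helix counts --------------------------------
  sequences <- character(n)
  helices <- integer(n)
  full_alpha <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  for (i in seq_len(n)) {
    r <- roles[i]
    if (r %in% c("transporter", "dual")) {
      fi <- fam_idx_of[match(i, tc_rows)]
      sequences[i] <- .mutate_seq(fam_seed[[fi]], 0.10,
                                  .TC_FAMILIES[[fi]]$alphabet)
      helices[i] <- 2L + (i %% 11L)           # 2..12 transmembrane helices
    } else if (r == "false_tpgc") {
      sequences[i] <- .rand_seq(120L, .NON_TRANSPORTER_ALPHABET)
      helices[i] <- 1L + (i %% 3L)
    } else {
      sequences[i] <- .rand_seq(60L + (i %% 80L), full_alpha)
      helices[i] <- 0L
    }
  }

  # --- homology hit tables -------------------------------------------------
  k_hits <- spec$hits_per_gene
  n_close <- max(3L, round(2 * k_hits / 3))
  n_far <- k_hits - n_close
  hit_acc <- 0L
  nr_rows <- list()
  yeast_rows <- list()
  corrupt <- function(ecs, i) {
    if (spec$wrong_ec_prob > 0 && stats::runif(1) < spec$wrong_ec_prob) {
      if (stats::runif(1) < 0.5) "" else junk_ec[i]
    } else paste(ecs, collapse = ",")
  }
  mk_hits <- function(locus_tag, i, accs, lineage, organism, ecs, product,
                      evalues, source_db) {
    m <- length(accs)
    data.frame(
      query = locus_tag, subject = accs,
      evalue = evalues, bit = 200 - seq_len(m),
      pident = 80, organism = organism,
      lineage = paste(lineage, collapse = ";"),
      ecs = vapply(seq_len(m), function(j) corrupt(ecs, i), character(1)),
      product = product, reviewed = 1L, source_db = source_db,
      stringsAsFactors = FALSE
    )
  }
  for (k in seq_len(n_ec)) {
    i <- ec_bearing[k]
    lt <- locus[i]
    win_ec <- ec_evidence[[k]][1]
    prod <- product_of(k)
    close_accs <- sprintf("P%05d", hit_acc + seq_len(n_close))
    far_accs <- sprintf("Q%05d", hit_acc + seq_len(n_far))
    hit_acc <- hit_acc + k_hits
    if (path[k] %in% c("B1", "B1S")) close_accs[1] <- .y_id(k)
    close_ev <- 1e-50 * seq_len(n_close)
    far_ev <- rep(1e-40, n_far)
    close_part <- mk_hits(lt, i, close_accs, .SC_LINEAGE,
                          "Saccharomyces cerevisiae", win_ec, prod,
                          close_ev, "nr")
    far_part <- mk_hits(lt, i, far_accs, .BACT_LINEAGE, "Escherichia coli",
                        distractor_ec[k], "distractor protein", far_ev, "nr")
    if (origin[k] != "yeast_only") {
      nr <- rbind(close_part, far_part)
      if (origin[k] == "distinct") {
        # the broad project selects the distractor: its close hits carry it
        nr$ecs[seq_len(n_close)] <- distractor_ec[k]
        nr$product[seq_len(n_close)] <- "distractor protein"
      }
      nr_rows[[length(nr_rows) + 1L]] <- nr
    } else {
      # automatically annotated only against the yeast database: the broad
      # search is swamped by homologues carrying no enzymatic annotation
      nr <- mk_hits(lt, i, sprintf("R%05d", hit_acc + seq_len(n_close)),
                    .BACT_LINEAGE, "Escherichia coli", character(0),
                    "uncharacterized protein", close_ev, "nr")
      nr$ecs <- ""
      nr_rows[[length(nr_rows) + 1L]] <- nr
      hit_acc <- hit_acc + n_close
    }
    if (origin[k] != "nr_only") {
      ye <- rbind(close_part, far_part)
      ye$source_db <- "yeast"
      yeast_rows[[length(yeast_rows) + 1L]] <- ye
    }
  }
  for (i in which(roles == "false_eegc")) {
    # confidently scored by the broad project, but backed by no evidence:
    # the curation tree must discard these
    accs <- sprintf("Q%05d", hit_acc + seq_len(k_hits))
    hit_acc <- hit_acc + k_hits
    nr_rows[[length(nr_rows) + 1L]] <- mk_hits(
      locus[i], i, accs, .BACT_LINEAGE, "Escherichia coli", junk_ec[i],
      "spurious enzyme", rep(1e-35, k_hits), "nr")
  }
  nr_hits <- do.call(rbind, nr_rows)
  yeast_hits <- do.call(rbind, yeast_rows)

  write_hit_files <- function(h, stem) {
    tab_path <- file.path(out_dir, paste0(stem, ".tsv"))
    side_path <- file.path(out_dir, paste0(stem, "_sidecar.tsv"))
    m <- nrow(h)
    tab <- cbind(h$query, h$subject, format(h$pident), rep("0", m), rep("0", m),
                 rep("0", m), rep("1", m), rep("100", m), rep("1", m),
                 rep("100", m), format(h$evalue, trim = TRUE, digits = 6),
                 format(h$bit, trim = TRUE, digits = 6))
    writeLines(apply(tab, 1, paste, collapse = "\t"), tab_path)
    side <- h[, c("query", "subject", "organism", "lineage", "ecs", "product",
                  "reviewed", "source_db")]
    write_tsv_strict(side, side_path)
  }
  write_hit_files(nr_hits, "hits_nr")
  write_hit_files(yeast_hits, "hits_yeast")

  # --- evidence bundles ----------------------------------------------------
  reviewed <- list(); sc_entries <- list(); restricted <- list()
  unrestricted <- list(); literature <- list()
  dropped_evidence <- character(0)
  for (k in seq_len(n_ec)) {
    i <- ec_bearing[k]
    lt <- locus[i]
    if (spec$missing_evidence_prob > 0 &&
        stats::runif(1) < spec$missing_evidence_prob) {
      dropped_evidence <- c(dropped_evidence, lt)
      next
    }
    prod <- product_of(k)
    ecs <- paste(ec_evidence[[k]], collapse = ",")
    if (path[k] == "A") {
      reviewed[[length(reviewed) + 1L]] <- data.frame(
        locus = lt, product = prod, ecs = ecs, stringsAsFactors = FALSE)
    } else if (path[k] == "B1") {
      y <- .y_id(k)
      sc_entries[[length(sc_entries) + 1L]] <- data.frame(
        locus = lt, y_id = y, source = c("uniprot", "sgd"),
        product = prod, ecs = ecs, stringsAsFactors = FALSE)
    } else if (path[k] == "B1S") {
      y <- .y_id(k)
      sc_entries[[length(sc_entries) + 1L]] <- data.frame(
        locus = lt, y_id = y, source = c("uniprot", "sgd"),
        product = c("misannotated protein", prod),
        ecs = c(sprintf("%d.8.8.8", classes[k]), ecs),
        stringsAsFactors = FALSE)
    } else if (path[k] == "B2r") {
      restricted[[length(restricted) + 1L]] <- data.frame(
        locus = lt, accession = sprintf("SP%05d", k), evalue = "1e-20",
        product = prod, ecs = ecs, stringsAsFactors = FALSE)
    } else if (path[k] == "B2u") {
      unrestricted[[length(unrestricted) + 1L]] <- data.frame(
        locus = lt, accession = sprintf("TR%05d", k), evalue = "1e-15",
        product = prod, ecs = ecs, stringsAsFactors = FALSE)
    } else {  # L
      literature[[length(literature) + 1L]] <- data.frame(
        locus = lt, product = prod, ecs = ecs,
        citation = sprintf("ref:%d", k), stringsAsFactors = FALSE)
    }
  }
  write_ev <- function(rows, file, cols) {
    df <- if (length(rows)) do.call(rbind, rows) else
      as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                    stringsAsFactors = FALSE)
    write_tsv_strict(df, file.path(out_dir, "evidence", file))
  }
  write_ev(reviewed, "reviewed.tsv", c("locus", "product", "ecs"))
  write_ev(sc_entries, "sc_entries.tsv", c("locus", "y_id", "source", "product", "ecs"))
  write_ev(restricted, "restricted.tsv", c("locus", "accession", "evalue", "product", "ecs"))
  write_ev(unrestricted, "unrestricted.tsv", c("locus", "accession", "evalue", "product", "ecs"))
  write_ev(literature, "literature.tsv", c("locus", "product", "ecs", "citation"))

  # --- EC registry ---------------------------------------------------------
  reg <- list()
  add_reg <- function(ec, status, transfers, names) {
    reg[[length(reg) + 1L]] <<- data.frame(
      ec = ec, status = status, transfers = transfers, names = names,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_ec)) {
    for (ec in ec_final[[k]]) add_reg(ec, "active", "", paste("enzyme", ec))
    if (verify[k] == "transfer") {
      add_reg(ec_evidence[[k]][1], "deprecated", ec_final[[k]][1], "")
    }
  }
  for (ec in unique(distractor_ec)) add_reg(ec, "active", "", "")
  reg <- do.call(rbind, reg)
  reg <- reg[!duplicated(reg$ec), , drop = FALSE]
  write_tsv_strict(reg, file.path(out_dir, "ec_registry.tsv"))

  # --- external annotation -------------------------------------------------
  cmp <- .cycle_labels(c("match", "superset", "subset", "conflict", "new_in_ours"),
                       c(0.60, 0.10, 0.05, 0.05, 0.20), n_ec)
  ext_rows <- list()
  add_ext <- function(lt, ecs) {
    ext_rows[[length(ext_rows) + 1L]] <<- data.frame(
      locus_tag = lt, ecs = paste(ecs, collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n_ec)) {
    lt <- locus[ec_bearing[k]]
    fin <- ec_final[[k]]
    if (cmp[k] == "match") {
      add_ext(lt, fin)
    } else if (cmp[k] == "superset") {
      ext <- if (length(fin) > 1L) fin[1] else if (!is_partial_ec(fin[1]))
        sub("[0-9]+$", "-", fin[1]) else NULL
      if (is.null(ext)) { cmp[k] <- "match"; add_ext(lt, fin) } else add_ext(lt, ext)
    } else if (cmp[k] == "subset") {
      add_ext(lt, c(fin, sprintf("6.6.6.%d", k)))
    } else if (cmp[k] == "conflict") {
      add_ext(lt, sprintf("4.4.9.%d", k))
    }
  }
  false_rows <- which(roles == "false_eegc")
  ruled <- false_rows[seq_len(ceiling(length(false_rows) * 2 / 3))]
  for (i in ruled) add_ext(locus[i], junk_ec[i])
  nonmet <- which(roles == "non_metabolic")
  ext_only <- utils::head(nonmet, min(2L, length(nonmet)))
  for (i in ext_only) add_ext(locus[i], "4.4.4.4")
  ext_df <- if (length(ext_rows)) do.call(rbind, ext_rows) else
    data.frame(locus_tag = character(0), ecs = character(0))
  write_tsv_strict(ext_df, file.path(out_dir, "external.tsv"))

  # --- transporter reference database --------------------------------------
  tcdb_fa <- character(0)
  tcdb_sub <- list()
  acc_n <- 0L
  for (fi in seq_along(.TC_FAMILIES)) {
    fam <- .TC_FAMILIES[[fi]]
    for (serial in 1:3) {
      acc_n <- acc_n + 1L
      acc <- sprintf("TCP%04d", acc_n)
      seqn <- .mutate_seq(fam_seed[[fi]], 0.05, fam$alphabet)
      tcdb_fa <- c(tcdb_fa,
                   sprintf(">gnl|TC-DB|%s|%s.%d synthetic %s family entry",
                           acc, fam$family, serial, fam$family), seqn)
      tcdb_sub[[acc_n]] <- data.frame(
        accession = acc, substrates = paste(fam$substrates, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  writeLines(tcdb_fa, file.path(out_dir, "tcdb.fasta"))
  write_tsv_strict(do.call(rbind, tcdb_sub),
                   file.path(out_dir, "tcdb_substrates.tsv"))

  # --- genome, lineage, TM table -------------------------------------------
  fa <- character(2L * n)
  fa[seq(1, 2L * n, by = 2L)] <- sprintf(">%s chromosome %s synthetic gene",
                                         locus, chrom)
  fa[seq(2, 2L * n, by = 2L)] <- sequences
  writeLines(fa, file.path(out_dir, "genome.fasta"))
  writeLines(.QUERY_LINEAGE, file.path(out_dir, "query_lineage.txt"))
  write_tsv_strict(data.frame(locus_tag = locus, helices = helices),
                   file.path(out_dir, "tm.tsv"))

  # --- ground truth --------------------------------------------------------
  truth <- data.frame(
    locus_tag = locus, role = roles, product = "", ecs = "", tcs = "",
    tc_family = "", substrates = "", path = "", origin_set = "",
    comparison = "", evidence_dropped = locus %in% dropped_evidence,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(n_ec)) {
    i <- ec_bearing[k]
    truth$product[i] <- product_of(k)
    truth$ecs[i] <- paste(ec_final[[k]], collapse = ",")
    truth$path[i] <- path[k]
    truth$origin_set[i] <- origin[k]
    truth$comparison[i] <- cmp[k]
  }
  for (j in seq_along(tc_rows)) {
    i <- tc_rows[j]
    fam <- .TC_FAMILIES[[fam_idx_of[j]]]
    truth$tc_family[i] <- fam$family
    truth$tcs[i] <- tc_prefix(fam$family, 3L)
    truth$substrates[i] <- paste(fam$substrates, collapse = ",")
    if (roles[i] == "transporter") {
      truth$product[i] <- sprintf("%s family transporter", fam$family)
      truth$comparison[i] <- "new_in_ours"
    }
  }
  truth$comparison[ruled] <- "ruled_out"
  truth$comparison[ext_only] <- "absent_in_ours"
  write_tsv_strict(truth, file.path(out_dir, "ground_truth.tsv"))

  invisible(list(dir = out_dir, truth = truth, spec = spec))
}

#' Score a pipeline run against planted ground truth
#'
#' Precision and recall of the final annotation versus the planted one.  A
#' true metabolic locus counts as recovered when its final EC set, TCS
#' number and product all equal the planted values (evidence-dropped loci
#' are excluded from the denominator of neither metric: losing them costs
#' recall).  Precision counts annotated loci that are planted metabolic
#' genes with an exact match.
#'
#' @param annotations merged data.frame from [merge_annotations()].
#' @param truth ground-truth data.frame from [generate_fixtures()].
#' @return list with `precision`, `recall`, `n_true`, `n_annotated`,
#'   `n_recovered`.
#' @export
evaluate_recovery <- function(annotations, truth) {
  true_rows <- truth[truth$role %in% c("enzymatic", "dual", "transporter"), ,
                     drop = FALSE]
  exact <- logical(nrow(true_rows))
  for (j in seq_len(nrow(true_rows))) {
    i <- match(true_rows$locus_tag[j], annotations$locus_tag)
    if (is.na(i)) next
    ecs_ok <- ec_sets_equal(annotations$ecs[[i]],
                            split_ec_field(true_rows$ecs[j], validate = FALSE))
    tcs_ok <- identical(
      if (is.na(annotations$tcs[i])) "" else annotations$tcs[i],
      true_rows$tcs[j])
    prod_ok <- .canon_product(annotations$product[i]) ==
      .canon_product(true_rows$product[j])
    exact[j] <- ecs_ok && tcs_ok && prod_ok
  }
  n_rec <- sum(exact)
  n_ann <- nrow(annotations)
  list(precision = if (n_ann) n_rec / n_ann else 1,
       recall = if (nrow(true_rows)) n_rec / nrow(true_rows) else 1,
       n_true = nrow(true_rows), n_annotated = n_ann, n_recovered = n_rec)
}
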