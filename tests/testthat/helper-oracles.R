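# In-code builders and independent brute-force oracles used across tests.

# build a hit data.frame row by row (the shape read_hits() returns)
make_hits <- function(query = "LOC1", accessions, evalues, bits = NULL,
                      ecs = NULL, lineages = NULL, products = NULL,
                      organisms = NULL, source_db = "nr") {
  n <- length(accessions)
  if (is.null(bits)) bits <- rep(100, n)
  if (is.null(ecs)) ecs <- rep(list(character(0)), n)
  if (is.null(lineages)) lineages <- rep(list(character(0)), n)
  if (is.null(products)) products <- rep("protein", n)
  if (is.null(organisms)) organisms <- rep("org", n)
  data.frame(
    query_locus = query, subject_accession = accessions,
    evalue = evalues, bit_score = bits, identity_fraction = 0.8,
    source_db = source_db, organism = organisms,
    product = products, reviewed = TRUE,
    lineage = I(lineages), ec_numbers = I(ecs),
    stringsAsFactors = FALSE
  )
}

QUERY_LIN <- c("Eukaryota", "Fungi", "Ascomycota", "Saccharomycotina",
               "Saccharomycetales", "Saccharomycetaceae", "Kluyveromyces lactis")
SC_LIN <- c(QUERY_LIN[1:6], "Saccharomyces cerevisiae")
FAR_LIN <- c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
             "Enterobacterales", "Enterobacteriaceae", "Escherichia",
             "Escherichia coli")

# small EC registry built in code (shape of read_ec_registry())
make_registry <- function(ec, status, transfers = NULL, names = NULL) {
  n <- length(ec)
  if (is.null(transfers)) transfers <- rep(list(character(0)), n)
  if (is.null(names)) names <- rep(list(character(0)), n)
  df <- data.frame(ec = ec, status = status, stringsAsFactors = FALSE)
  df$transfers <- I(transfers)
  df$names <- I(lapply(names, tolower))
  df$partial <- is_partial_ec(df$ec)
  attr(df, "ec_components") <- do.call(rbind, strsplit(df$ec, ".", fixed = TRUE))
  df
}

make_evidence <- function(reviewed = NULL, sc_entries = list(),
                          restricted = NULL, unrestricted = NULL,
                          literature = NULL) {
  list(reviewed = reviewed, sc_entries = sc_entries,
       restricted = restricted, unrestricted = unrestricted,
       literature = literature)
}

make_ev_hits <- function(accession, evalue, product, ecs) {
  df <- data.frame(accession = accession, evalue = evalue, product = product,
                   stringsAsFactors = FALSE)
  df$ecs <- I(ecs)
  df[order(df$evalue, df$accession), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# brute-force scorer oracle: plain loops, no shared code with the package

oracle_scores <- function(hits, alpha, query_lineage) {
  n <- nrow(hits)
  ec_labels <- unique(unlist(lapply(hits$ec_numbers, function(e) gsub("–", "-", e))))
  prods <- unique(hits$product[nzchar(hits$product)])
  prods <- prods[!duplicated(tolower(gsub("\\s+", " ", trimws(prods))))]
  rows <- list()
  share <- function(hl) {
    if (!length(hl)) return(0)
    k <- 0
    while (k < min(length(hl), length(query_lineage)) &&
           hl[k + 1] == query_lineage[k + 1]) k <- k + 1
    k / max(length(hl), length(query_lineage))
  }
  for (lab in ec_labels) {
    carrier <- vapply(hits$ec_numbers, function(e) lab %in% e, logical(1))
    f <- sum(carrier) / n
    t <- if (!any(carrier)) 0 else mean(vapply(hits$lineage[carrier], share, 0))
    rows[[length(rows) + 1]] <- data.frame(
      label = lab, type = "ec", f = f, t = t, s = alpha * f + (1 - alpha) * t,
      supp = sum(carrier), stringsAsFactors = FALSE)
  }
  for (lab in prods) {
    canon <- tolower(gsub("\\s+", " ", trimws(hits$product)))
    carrier <- canon == tolower(gsub("\\s+", " ", trimws(lab)))
    f <- sum(carrier) / n
    t <- if (!any(carrier)) 0 else mean(vapply(hits$lineage[carrier], share, 0))
    rows[[length(rows) + 1]] <- data.frame(
      label = lab, type = "product", f = f, t = t,
      s = alpha * f + (1 - alpha) * t, supp = sum(carrier),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# random hit table for property tests
random_hit_table <- function(n_hits, seed) {
  set.seed(seed)
  ec_pool <- c("1.1.1.1", "2.3.1.23", "3.2.2.-", "6.3.5.5", "2.3.1.51")
  lin_pool <- list(SC_LIN, FAR_LIN, QUERY_LIN[1:4], character(0))
  make_hits(
    accessions = sprintf("P%03d", seq_len(n_hits)),
    evalues = 10^-stats::runif(n_hits, 31, 60),
    bits = round(stats::runif(n_hits, 50, 300)),
    ecs = lapply(seq_len(n_hits), function(i)
      sample(ec_pool, sample(0:2, 1))),
    lineages = lapply(seq_len(n_hits), function(i)
      lin_pool[[sample(length(lin_pool), 1)]]),
    products = sample(c("kinase", "dehydrogenase", "transferase"),
                      n_hits, replace = TRUE)
  )
}

# ---------------------------------------------------------------------------
# exhaustive local-alignment oracle: enumerates every alignment path
# explicitly (no dynamic programming, no memoization); gap of length L costs
# open + L * ext

oracle_sw <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- 0
  rec <- function(i, j, score, state) {
    best <<- max(best, score)
    if (i > n || j > m) return(invisible(NULL))
    # diagonal column
    rec(i + 1, j + 1, score + sub[av[i], bv[j]], "d")
    # gap in a (consume b)
    rec(i, j + 1, score - if (state == "ga") ext else open + ext, "ga")
    # gap in b (consume a)
    rec(i + 1, j, score - if (state == "gb") ext else open + ext, "gb")
    invisible(NULL)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, 0, "d0")
  best
}

all_seqs <- function(alphabet, max_len) {
  out <- character(0)
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# plain-R affine-gap local alignment reference (score only).  Independent
# implementation of the recurrence used to cross-check the compiled aligner
# on exhaustive pair sets where pure enumeration is intractable; it is
# itself validated against oracle_sw() on short pairs.
oracle_sw_ref <- function(a, b, sub, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  Fm <- matrix(-Inf, n + 1, m + 1)
  for (i in 1 + seq_len(n)) {
    for (j in 1 + seq_len(m)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      Fm[i, j] <- max(H[i - 1, j] - (open + ext), Fm[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]],
                     E[i, j], Fm[i, j])
    }
  }
  max(H)
}
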