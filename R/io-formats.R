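#' Readers and writers for the toolkit's on-disk formats
#'
#' Every format the annotation pipeline touches has a strict, validating
#' reader here, and a writer where round trips are needed: amino-acid FASTA
#' and GenBank flat files for genomes, 12-column BLAST tabular hit tables
#' with a tab-separated annotation sidecar, a TC-numbered FASTA plus
#' substrate table, an EC registry, transmembrane-helix summaries, evidence
#' bundles and external annotations.  All loaders are pure: no network, no
#' caching.
#'
#' All TSV dialects are UTF-8, tab-delimited, with `#` comment lines and a
#' header row.
#'
#' @name io-formats
NULL

# amino-acid alphabet accepted in protein sequences: 20 standard residues + X
.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

.check_protein <- function(seqs, where) {
  bad <- grepl(sprintf("[^%s]", .AA_ALPHABET), seqs)
  if (any(bad)) {
    stop("illegal amino-acid residue(s) in ", where, ": ",
         paste(utils::head(names(seqs)[bad], 3), collapse = ", "),
         " (alphabet is the 20 standard residues plus X)")
  }
  invisible(TRUE)
}

# strict TSV reader shared by all loaders
read_tsv_strict <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  df
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# genomes

#' Read a proteome into a gene table
#'
#' Accepts amino-acid FASTA (the locus tag is the first whitespace-delimited
#' header token) or a GenBank flat file whose CDS features carry
#' `/locus_tag` and `/translation` qualifiers.  FASTA-only inputs carry no
#' coordinates; they receive placeholder coordinates (`start = 1`,
#' `end = 3*len + 3`) and `coords_known = FALSE`.
#'
#' @param path path to a `.fasta`/`.fa`/`.faa` or `.gb`/`.gbk`/`.genbank`
#'   file; `format` overrides extension sniffing.
#' @param format `"auto"`, `"fasta"` or `"genbank"`.
#' @return a data.frame with one row per gene, in file order: `locus_tag`,
#'   `protein_sequence`, `chromosome_id`, `start`, `end`, `strand`,
#'   `description`, `coords_known`.
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gb", "gbk", "gbff", "genbank")) "genbank" else "fasta"
  }
  genome <- if (format == "fasta") .read_genome_fasta(path)
            else .read_genome_genbank(path)
  if (nrow(genome) == 0L) stop("no gene records in ", path)
  dup <- genome$locus_tag[duplicated(genome$locus_tag)]
  if (length(dup)) stop("duplicate locus tag(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(genome$protein_sequence))) stop("empty protein sequence in ", path)
  if (any(genome$end < genome$start)) stop("end < start for locus ",
      genome$locus_tag[which(genome$end < genome$start)[1]])
  seqs <- genome$protein_sequence
  names(seqs) <- genome$locus_tag
  .check_protein(seqs, path)
  genome
}

.read_genome_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  locus <- sub("\\s.*$", "", headers)
  desc <- trimws(sub("^\\S+\\s*", "", headers))
  seqs <- as.character(aa)
  data.frame(
    locus_tag = locus,
    protein_sequence = unname(seqs),
    chromosome_id = "unplaced",
    start = 1L,
    end = 3L * nchar(seqs) + 3L,  # placeholder CDS span incl. stop codon
    strand = "+",
    description = desc,
    coords_known = FALSE,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# GenBank flat files.  No installed R package both reads and writes GenBank
# feature tables, so a minimal, strict parser/emitter for the subset we use
# (LOCUS, CDS features with qualifiers) lives here.

.parse_genbank_qualifiers <- function(lines) {
  # lines: feature block lines already stripped of the 21-column indent
  quals <- list()
  current_key <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^/([A-Za-z_]+)(=(.*))?$", ln))[[1]]
    if (length(m)) {
      current_key <- m[2]
      val <- if (nzchar(m[3])) m[4] else "TRUE"
      quals[[length(quals) + 1L]] <- list(key = current_key, value = val)
    } else if (!is.null(current_key)) {
      # continuation of a wrapped qualifier value
      last <- quals[[length(quals)]]
      sep <- if (last$key == "translation") "" else " "
      quals[[length(quals)]]$value <- paste0(last$value, sep, ln)
    }
  }
  for (i in seq_along(quals)) {
    quals[[i]]$value <- gsub("^\"|\"$", "", quals[[i]]$value)
  }
  quals
}

.read_genome_genbank <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty GenBank file: ", path)
  records <- list()
  chrom <- NA_character_
  in_features <- FALSE
  feature_buf <- character(0)
  flush_feature <- function() {
    if (!length(feature_buf)) return(invisible(NULL))
    loc_line <- feature_buf[1]
    qual_lines <- feature_buf[-1]
    strand <- if (grepl("complement", loc_line)) "-" else "+"
    nums <- regmatches(loc_line, gregexpr("[0-9]+", loc_line))[[1]]
    if (length(nums) < 2L) stop("unparseable CDS location: ", loc_line)
    quals <- .parse_genbank_qualifiers(trimws(qual_lines))
    getq <- function(key) {
      vals <- vapply(quals, function(q) if (q$key == key) q$value else NA_character_,
                     character(1))
      vals[!is.na(vals)]
    }
    lt <- getq("locus_tag")
    tr <- getq("translation")
    if (!length(lt)) stop("CDS feature without /locus_tag in GenBank input")
    if (!length(tr)) stop("CDS for ", lt[1], " lacks /translation")
    records[[length(records) + 1L]] <<- data.frame(
      locus_tag = lt[1],
      protein_sequence = gsub("\\s", "", tr[1]),
      chromosome_id = chrom,
      start = as.integer(nums[1]),
      end = as.integer(nums[length(nums)]),
      strand = strand,
      description = if (length(getq("product"))) getq("product")[1] else "",
      coords_known = TRUE,
      stringsAsFactors = FALSE
    )
    feature_buf <<- character(0)
    invisible(NULL)
  }
  for (ln in lines) {
    if (grepl("^LOCUS", ln)) {
      chrom <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
    } else if (grepl("^(ORIGIN|//|CONTIG)", ln)) {
      flush_feature()
      in_features <- FALSE
    } else if (in_features) {
      if (grepl("^ {5}\\S", ln)) {       # new feature key
        flush_feature()
        key <- trimws(substr(ln, 1, 20))
        if (key == "CDS") feature_buf <- trimws(substr(ln, 21, nchar(ln)))
      } else if (length(feature_buf) && grepl("^ {21}", ln)) {
        feature_buf <- c(feature_buf, substr(ln, 22, nchar(ln)))
      }
    }
  }
  flush_feature()
  if (!length(records)) stop("no CDS features in ", path)
  do.call(rbind, records)
}

.wrap_qualifier <- function(key, value, quote = TRUE, width = 79L) {
  body <- if (quote) sprintf("/%s=\"%s\"", key, value) else sprintf("/%s=%s", key, value)
  indent <- strrep(" ", 21)
  out <- character(0)
  line <- paste0(indent, body)
  while (nchar(line) > width) {
    # break at the last space inside width, or hard-break (translations)
    cut <- max(gregexpr(" ", substr(line, 22, width))[[1]])
    cut <- if (cut > 0) cut + 21L else width
    out <- c(out, substr(line, 1, cut))
    line <- paste0(indent, trimws(substr(line, cut + 1L, nchar(line))))
  }
  c(out, line)
}

#' Write annotated genomes as GenBank flat files, one per chromosome
#'
#' Each annotated CDS carries a single `/product` qualifier and one
#' `/EC_number` qualifier per EC number.  Transporter classifications, which
#' have no standard INSDC qualifier, are written as
#' `/note="TC:<number>; substrates:<comma list>"`.  Unannotated genes are
#' written unchanged (locus tag and translation only).
#'
#' @param genome gene table from [read_genome()].
#' @param annotations data.frame with columns `locus_tag`, `product`, `ecs`
#'   (comma-delimited string or list column), and optionally `tc`
#'   and `substrates`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written (one per chromosome).
#' @export
write_genbank <- function(genome, annotations, out_dir) {
  unknown <- setdiff(annotations$locus_tag, genome$locus_tag)
  if (length(unknown)) {
    stop("annotation(s) for unknown locus tag(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann_idx <- match(genome$locus_tag, annotations$locus_tag)
  paths <- character(0)
  for (chrom in unique(genome$chromosome_id)) {
    rows <- which(genome$chromosome_id == chrom)
    path <- file.path(out_dir, paste0(chrom, ".gbk"))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    span <- max(genome$end[rows])
    writeLines(sprintf("LOCUS       %-16s %11d bp    DNA     linear   UNA",
                       chrom, span), con)
    writeLines(sprintf("DEFINITION  %s re-annotated chromosome.", chrom), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    for (i in rows) {
      loc <- if (genome$strand[i] == "-") {
        sprintf("complement(%d..%d)", genome$start[i], genome$end[i])
      } else sprintf("%d..%d", genome$start[i], genome$end[i])
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(.wrap_qualifier("locus_tag", genome$locus_tag[i]), con)
      ai <- ann_idx[i]
      if (!is.na(ai)) {
        prod <- annotations$product[ai]
        if (!is.na(prod) && nzchar(prod)) {
          writeLines(.wrap_qualifier("product", prod), con)
        }
        ecs <- annotations$ecs[[ai]]
        if (is.character(ecs) && length(ecs) == 1L && grepl(",", ecs)) {
          ecs <- split_ec_field(ecs)
        }
        for (ec in ecs[nzchar(ecs)]) {
          writeLines(.wrap_qualifier("EC_number", normalize_ec(ec)), con)
        }
        tc <- if ("tc" %in% names(annotations)) annotations$tc[ai] else NA_character_
        if (!is.na(tc) && nzchar(tc)) {
          subs <- if ("substrates" %in% names(annotations))
            annotations$substrates[[ai]] else character(0)
          note <- sprintf("TC:%s; substrates:%s", tc,
                          paste(subs, collapse = ","))
          writeLines(.wrap_qualifier("note", note), con)
        }
      }
      writeLines(.wrap_qualifier("translation", genome$protein_sequence[i]), con)
    }
    writeLines("ORIGIN", con)
    writeLines("//", con)
    close(con)
    on.exit()
    paths <- c(paths, path)
  }
  invisible(paths)
}

# ---------------------------------------------------------------------------
# homology hit tables

#' Read a homology hit table (BLAST tabular + annotation sidecar)
#'
#' The tabular file is the standard 12-column BLAST dialect (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`,
#' no header).  The sidecar TSV, keyed by `(query, subject)`, supplies the
#' annotation payload the upstream retrieval step collected for each
#' homologue: organism, semicolon-delimited lineage (root to leaf),
#' comma-delimited EC numbers, product, reviewed flag, and the source
#' database.  Hits missing from the sidecar are kept with empty annotation
#' and a warning.
#'
#' @param tabular_path 12-column BLAST tabular file.
#' @param sidecar_path sidecar TSV with columns `query`, `subject`,
#'   `organism`, `lineage`, `ecs`, `product`, `reviewed`, `source_db`.
#' @return data.frame of hits in tabular-file order with columns
#'   `query_locus`, `subject_accession`, `evalue`, `bit_score`,
#'   `identity_fraction`, `source_db`, `organism`, `product`, `reviewed`,
#'   plus list columns `lineage` and `ec_numbers`.
#' @export
read_hits <- function(tabular_path, sidecar_path) {
  lines <- readLines(tabular_path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(.empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_bad <- which(lengths(fields) != 12L)
  if (length(ncol_bad)) {
    stop("line ", ncol_bad[1], " of ", basename(tabular_path),
         " has ", lengths(fields)[ncol_bad[1]], " columns; expected 12")
  }
  m <- do.call(rbind, fields)
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  if (anyNA(evalue)) {
    stop("malformed e-value '", m[which(is.na(evalue))[1], 11],
         "' on line ", which(is.na(evalue))[1], " of ", basename(tabular_path))
  }
  if (any(evalue < 0)) stop("negative e-value on line ", which(evalue < 0)[1])
  hits <- data.frame(
    query_locus = m[, 1],
    subject_accession = m[, 2],
    evalue = evalue,
    bit_score = as.numeric(m[, 12]),
    identity_fraction = as.numeric(m[, 3]) / 100,
    stringsAsFactors = FALSE
  )
  side <- read_tsv_strict(sidecar_path,
    c("query", "subject", "organism", "lineage", "ecs", "product",
      "reviewed", "source_db"))
  key <- paste(hits$query_locus, hits$subject_accession, sep = "\r")
  skey <- paste(side$query, side$subject, sep = "\r")
  idx <- match(key, skey)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " hit(s) missing from sidecar ",
            basename(sidecar_path), "; kept with empty annotation")
  }
  pick <- function(col, default = "") {
    out <- ifelse(is.na(idx), default, side[[col]][idx])
    out[is.na(out)] <- default
    out
  }
  hits$source_db <- pick("source_db", "nr")
  hits$organism <- pick("organism")
  hits$product <- pick("product")
  hits$reviewed <- pick("reviewed", "0") %in% c("1", "TRUE", "true")
  lineage_str <- pick("lineage")
  hits$lineage <- I(lapply(lineage_str, function(s) {
    if (!nzchar(s)) character(0) else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  }))
  ec_str <- pick("ecs")
  hits$ec_numbers <- I(lapply(ec_str, split_ec_field))
  hits
}

.empty_hits <- function() {
  data.frame(
    query_locus = character(0), subject_accession = character(0),
    evalue = numeric(0), bit_score = numeric(0),
    identity_fraction = numeric(0), source_db = character(0),
    organism = character(0), product = character(0),
    reviewed = logical(0),
    lineage = I(list()), ec_numbers = I(list()),
    stringsAsFactors = FALSE
  )
}

#' Write a hit table back to the tabular + sidecar dialect
#'
#' Inverse of [read_hits()]; `read_hits(write_hits(h)) == h` on the typed
#' collection.
#'
#' @param hits hit data.frame as returned by [read_hits()].
#' @param tabular_path,sidecar_path output paths.
#' @return invisibly, `c(tabular_path, sidecar_path)`.
#' @export
write_hits <- function(hits, tabular_path, sidecar_path) {
  n <- nrow(hits)
  tab <- cbind(hits$query_locus, hits$subject_accession,
               format(hits$identity_fraction * 100, trim = TRUE, digits = 6),
               rep("0", n), rep("0", n), rep("0", n),
               rep("1", n), rep("1", n), rep("1", n), rep("1", n),
               format(hits$evalue, trim = TRUE, digits = 6),
               format(hits$bit_score, trim = TRUE, digits = 6))
  writeLines(apply(tab, 1, paste, collapse = "\t"), tabular_path)
  side <- data.frame(
    query = hits$query_locus,
    subject = hits$subject_accession,
    organism = hits$organism,
    lineage = vapply(hits$lineage, paste, character(1), collapse = ";"),
    ecs = vapply(hits$ec_numbers, paste, character(1), collapse = ","),
    product = hits$product,
    reviewed = as.integer(hits$reviewed),
    source_db = hits$source_db,
    stringsAsFactors = FALSE
  )
  write_tsv_strict(side, sidecar_path)
  invisible(c(tabular_path, sidecar_path))
}

# ---------------------------------------------------------------------------
# TC-numbered reference database

#' Read a TC-numbered FASTA plus substrate table
#'
#' Headers follow the `>gnl|TC-DB|<accession>|<TC number> <description>`
#' convention; the substrate TSV (columns `accession`, `substrates`) lists
#' the transported metabolites per entry, comma-delimited.
#'
#' @param fasta_path TC-numbered protein FASTA.
#' @param substrate_tsv substrate table path.
#' @return data.frame with columns `accession`, `tc_number`, `sequence` and
#'   list column `substrates`.
#' @export
read_tcdb <- function(fasta_path, substrate_tsv) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  if (length(aa) == 0L) stop("empty TC database FASTA: ", fasta_path)
  headers <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad)) stop("unparseable TC FASTA header: ", headers[bad[1]])
  accession <- vapply(parts, function(p) p[3], character(1))
  tc <- vapply(parts, function(p) p[4], character(1))
  if (any(!is_valid_tc(tc))) {
    stop("invalid TC number(s) in FASTA headers: ",
         paste(tc[!is_valid_tc(tc)], collapse = ", "))
  }
  seqs <- as.character(aa)
  names(seqs) <- accession
  .check_protein(seqs, fasta_path)
  sub_df <- read_tsv_strict(substrate_tsv, c("accession", "substrates"))
  idx <- match(accession, sub_df$accession)
  substrates <- lapply(idx, function(i) {
    if (is.na(i) || !nzchar(sub_df$substrates[i])) character(0)
    else trimws(strsplit(sub_df$substrates[i], ",", fixed = TRUE)[[1]])
  })
  data.frame(
    accession = accession, tc_number = tc, sequence = unname(seqs),
    substrates = I(substrates), stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# EC registry

#' Read an EC registry table
#'
#' One row per EC number with its status, transfer targets (for deprecated
#' entries that were transferred) and accepted product names.  Columns:
#' `ec`, `status` (`active`/`deprecated`), `transfers` (comma-delimited EC
#' numbers, may be empty), `names` (semicolon-delimited, matched
#' case-insensitively).
#'
#' @param path registry TSV path.
#' @return data.frame with list columns `transfers` and `names` (names are
#'   lower-cased for matching).
#' @export
read_ec_registry <- function(path) {
  df <- read_tsv_strict(path, c("ec", "status", "transfers", "names"))
  df$ec <- normalize_ec(df$ec)
  if (any(!is_valid_ec(df$ec))) {
    stop("malformed EC in registry: ",
         paste(df$ec[!is_valid_ec(df$ec)], collapse = ", "))
  }
  if (any(!df$status %in% c("active", "deprecated"))) {
    stop("registry status must be 'active' or 'deprecated'")
  }
  if (anyDuplicated(df$ec)) stop("duplicate EC in registry: ",
                                 df$ec[duplicated(df$ec)][1])
  df$transfers <- I(lapply(df$transfers, split_ec_field))
  df$names <- I(lapply(df$names, function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else tolower(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  }))
  df$partial <- is_partial_ec(df$ec)
  # pre-split components: registry lookups are on the curation hot path
  attr(df, "ec_components") <- do.call(rbind, strsplit(df$ec, ".", fixed = TRUE))
  df
}

# ---------------------------------------------------------------------------
# transmembrane predictions

#' Read transmembrane-helix count summaries
#'
#' One row per locus, TMHMM-short style: columns `locus_tag`, `helices`
#' (predicted transmembrane helix count, integer >= 0).
#'
#' @param path TSV path.
#' @return data.frame `locus_tag`, `helices`.
#' @export
read_tm <- function(path) {
  df <- read_tsv_strict(path, c("locus_tag", "helices"))
  if (anyDuplicated(df$locus_tag)) {
    stop("duplicate locus in TM predictions: ",
         df$locus_tag[duplicated(df$locus_tag)][1])
  }
  helices <- suppressWarnings(as.integer(df$helices))
  if (anyNA(helices) || any(helices < 0)) {
    stop("helix counts must be non-negative integers")
  }
  data.frame(locus_tag = df$locus_tag, helices = helices,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# evidence bundles

.Y_ID_REGEX <- "^Y.{2}[0-9]{3}.$"

#' Read an evidence directory into per-locus evidence bundles
#'
#' The directory emulates curated-database lookups with five optional TSV
#' files: `reviewed.tsv` (locus, product, ecs) for reviewed records keyed by
#' the locus itself; `sc_entries.tsv` (locus, y_id, source, product, ecs)
#' carrying the UniProt and SGD entries for a locus's *S. cerevisiae*
#' homologue; `restricted.tsv` and `unrestricted.tsv` (locus, accession,
#' evalue, product, ecs) for the fallback similarity searches; and
#' `literature.tsv` (locus, product, ecs, citation) for author-knowledge
#' overrides.
#'
#' @param dir evidence directory.
#' @return named list of evidence bundles (one per locus that has any
#'   evidence); each bundle is a list with elements `reviewed`,
#'   `sc_entries`, `restricted`, `unrestricted`, `literature`.
#' @export
read_evidence <- function(dir) {
  if (!dir.exists(dir)) stop("evidence directory not found: ", dir)
  opt <- function(file, cols) {
    p <- file.path(dir, file)
    if (!file.exists(p)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                          stringsAsFactors = FALSE)
      return(df)
    }
    read_tsv_strict(p, cols)
  }
  reviewed <- opt("reviewed.tsv", c("locus", "product", "ecs"))
  sc <- opt("sc_entries.tsv", c("locus", "y_id", "source", "product", "ecs"))
  restricted <- opt("restricted.tsv", c("locus", "accession", "evalue", "product", "ecs"))
  unrestricted <- opt("unrestricted.tsv", c("locus", "accession", "evalue", "product", "ecs"))
  literature <- opt("literature.tsv", c("locus", "product", "ecs", "citation"))
  if (nrow(sc) && any(!grepl(.Y_ID_REGEX, sc$y_id))) {
    stop("malformed S. cerevisiae identifier in sc_entries.tsv: ",
         sc$y_id[!grepl(.Y_ID_REGEX, sc$y_id)][1])
  }
  if (nrow(sc) && any(!sc$source %in% c("uniprot", "sgd"))) {
    stop("sc_entries source must be 'uniprot' or 'sgd'")
  }
  loci <- unique(c(reviewed$locus, sc$locus, restricted$locus,
                   unrestricted$locus, literature$locus))
  entry <- function(product, ecs) list(product = product, ecs = split_ec_field(ecs))
  hits_of <- function(df, locus) {
    rows <- df[df$locus == locus, , drop = FALSE]
    if (!nrow(rows)) {
      return(data.frame(accession = character(0), evalue = numeric(0),
                        product = character(0), stringsAsFactors = FALSE))
    }
    ev <- suppressWarnings(as.numeric(rows$evalue))
    if (anyNA(ev)) stop("malformed e-value in evidence for ", locus)
    out <- data.frame(accession = rows$accession, evalue = ev,
                      product = rows$product, stringsAsFactors = FALSE)
    out$ecs <- I(lapply(rows$ecs, split_ec_field))
    out[order(out$evalue, out$accession), , drop = FALSE]
  }
  bundles <- lapply(loci, function(locus) {
    b <- list(reviewed = NULL, sc_entries = list(),
              restricted = hits_of(restricted, locus),
              unrestricted = hits_of(unrestricted, locus),
              literature = NULL)
    r <- reviewed[reviewed$locus == locus, , drop = FALSE]
    if (nrow(r)) b$reviewed <- entry(r$product[1], r$ecs[1])
    s <- sc[sc$locus == locus, , drop = FALSE]
    if (nrow(s)) {
      for (y in unique(s$y_id)) {
        ys <- s[s$y_id == y, , drop = FALSE]
        b$sc_entries[[y]] <- list(
          uniprot = if (any(ys$source == "uniprot")) {
            i <- which(ys$source == "uniprot")[1]; entry(ys$product[i], ys$ecs[i])
          },
          sgd = if (any(ys$source == "sgd")) {
            i <- which(ys$source == "sgd")[1]; entry(ys$product[i], ys$ecs[i])
          })
      }
    }
    l <- literature[literature$locus == locus, , drop = FALSE]
    if (nrow(l)) {
      b$literature <- c(entry(l$product[1], l$ecs[1]),
                        list(citation = l$citation[1]))
    }
    b
  })
  names(bundles) <- loci
  bundles
}

# ---------------------------------------------------------------------------
# external annotations

#' Read an external annotation table
#'
#' A KEGG-dump style TSV: columns `locus_tag`, `ecs` (comma-delimited; a
#' locus may also appear on several rows, whose EC sets are unioned).
#'
#' @param path TSV path.
#' @return named list mapping locus tag to a character vector of normalized
#'   EC numbers.
#' @export
read_external <- function(path) {
  df <- read_tsv_strict(path, c("locus_tag", "ecs"))
  out <- list()
  for (i in seq_len(nrow(df))) {
    lt <- df$locus_tag[i]
    out[[lt]] <- unique(c(out[[lt]], split_ec_field(df$ecs[i])))
  }
  out
}
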