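# Synonym table mapping common GenBank mitochondrial gene labels to the
# canonical names used throughout the package. Deposited records vary
# wildly in their labels; unknown labels are skipped with a warning
# rather than failing the whole read.
gene_synonyms <- function() {
  syn <- c(
    COX1 = "cox1", COI = "cox1", CO1 = "cox1", COXI = "cox1",
    COX2 = "cox2", COII = "cox2", CO2 = "cox2", COXII = "cox2",
    COX3 = "cox3", COIII = "cox3", CO3 = "cox3", COXIII = "cox3",
    ND1 = "nad1", ND2 = "nad2", ND3 = "nad3", ND4 = "nad4",
    ND4L = "nad4L", ND5 = "nad5", ND6 = "nad6",
    NAD1 = "nad1", NAD2 = "nad2", NAD3 = "nad3", NAD4 = "nad4",
    NAD4L = "nad4L", NAD5 = "nad5", NAD6 = "nad6",
    CYTB = "cytb", COB = "cytb", CYB = "cytb",
    ATP6 = "atp6", ATPASE6 = "atp6", ATP8 = "atp8", ATPASE8 = "atp8",
    `12S` = "rrnS", `12SRRNA` = "rrnS", RRNS = "rrnS", SRRNA = "rrnS",
    `S-RRNA` = "rrnS", `12SRIBOSOMALRNA` = "rrnS",
    `16S` = "rrnL", `16SRRNA` = "rrnL", RRNL = "rrnL", LRRNA = "rrnL",
    `L-RRNA` = "rrnL", `16SRIBOSOMALRNA` = "rrnL",
    `D-LOOP` = "NCR", DLOOP = "NCR", `CONTROLREGION` = "NCR",
    `A+T-RICHREGION` = "NCR", `ATRICHREGION` = "NCR", NCR = "NCR")
  trn <- c(ALA = "trnA", ARG = "trnR", ASN = "trnN", ASP = "trnD",
           CYS = "trnC", GLN = "trnQ", GLU = "trnE", GLY = "trnG",
           HIS = "trnH", ILE = "trnI", LYS = "trnK", MET = "trnM",
           PHE = "trnF", PRO = "trnP", THR = "trnT", TRP = "trnW",
           TYR = "trnY", VAL = "trnV")
  for (a in names(trn)) syn[[paste0("TRNA-", a)]] <- trn[[a]]
  syn[["TRNA-LEU(CUN)"]] <- "trnL1"; syn[["TRNA-LEU(UUR)"]] <- "trnL2"
  syn[["TRNA-SER(AGN)"]] <- "trnS1"; syn[["TRNA-SER(UCN)"]] <- "trnS2"
  syn
}

#' Map a GenBank gene label to its canonical name
#'
#' @param label Gene label as found in a `/gene=`, `/product=` or
#'   `/note=` qualifier.
#' @return Canonical name, or `NA` if the label is not recognized.
#' @export
canonical_gene_name <- function(label) {
  if (is.na(label) || !nzchar(label)) return(NA_character_)
  if (label %in% canonical_gene_order()) return(label)
  key <- toupper(gsub("[ _]", "", label))
  syn <- gene_synonyms()
  if (key %in% names(syn)) return(unname(syn[[key]]))
  NA_character_
}

class_to_feature_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                          NCR = "misc_feature")

#' Write a minimal GenBank flatfile
#'
#' Emits a minimal but valid record: LOCUS line, FEATURES table with one
#' feature per annotated region (CDS / tRNA / rRNA / misc_feature,
#' N-strand features as `complement(a..b)`) and the ORIGIN sequence
#' block.
#'
#' @param genome A [mito_genome].
#' @param annotation A [mito_annotation].
#' @param path Output path.
#' @export
write_genbank <- function(genome, annotation, path) {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     %s INV",
                     genome$id, genome$length, genome$topology),
             sprintf("DEFINITION  %s mitochondrion.", genome$id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", genome$length))
  for (i in seq_len(nrow(annotation))) {
    f <- annotation[i, ]
    loc <- sprintf("%d..%d", f$from, f$to)
    if (f$strand == "N") loc <- sprintf("complement(%s)", loc)
    key <- class_to_feature_key[[f$class]]
    lines <- c(lines, sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", f$gene))
    if (f$class == "NCR")
      lines <- c(lines, "                     /note=\"A+T-rich region\"")
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read a GenBank flatfile
#'
#' Parses a well-formed flatfile with an ORIGIN sequence block and
#' CDS/tRNA/rRNA/misc_feature (or D-loop) features. Feature labels are
#' mapped to canonical names through a built-in synonym table (e.g.
#' `ND4L` -> `nad4L`, `COI` -> `cox1`, `D-loop` -> `NCR`);
#' `complement(a..b)` locations become strand N. Features whose label
#' cannot be mapped are skipped with a warning. Start/stop codons of
#' protein-coding genes are classified from the sequence.
#'
#' @param path Path to a GenBank flatfile.
#' @return List with elements `genome` ([mito_genome]) and `annotation`
#'   ([mito_annotation]).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
        else "genome"
  topology <- if (length(locus) && grepl("circular", locus[1L])) "circular" else "linear"

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank parse error: no ORIGIN block in ", path, call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^a-zA-Z]", "", paste0(seq_lines, collapse = "")))

  # features section
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    cur <- NULL
    flush <- function(cur) {
      if (is.null(cur)) return()
      feats[[length(feats) + 1L]] <<- cur
    }
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        flush(cur)
        key <- trimws(substr(ln, 1L, 20L))
        loc <- trimws(substr(ln, 21L, nchar(ln)))
        cur <- list(key = key, loc = loc, quals = character())
      } else if (!is.null(cur)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) cur$quals <- c(cur$quals, txt)
        else if (length(cur$quals)) # continuation line
          cur$quals[length(cur$quals)] <- paste0(cur$quals[length(cur$quals)], txt)
        else cur$loc <- paste0(cur$loc, txt)
      }
    }
    flush(cur)
  }

  key_to_class <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                    misc_feature = "NCR", `D-loop` = "NCR")
  rows <- list()
  for (f in feats) {
    if (!f$key %in% names(key_to_class)) next
    strand <- if (grepl("complement", f$loc)) "N" else "J"
    m <- regmatches(f$loc, regexec("(\\d+)\\.\\.(\\d+)", f$loc))[[1L]]
    if (length(m) < 3L) {
      warning("skipping feature with unparseable location: ", f$loc)
      next
    }
    qual_value <- function(q) {
      hit <- grep(paste0("^/", q, "="), f$quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub("\"", "", sub(paste0("^/", q, "="), "", hit[1L]))
    }
    label <- qual_value("gene")
    name <- canonical_gene_name(label)
    if (is.na(name)) name <- canonical_gene_name(qual_value("product"))
    if (is.na(name) && f$key %in% c("misc_feature", "D-loop")) {
      note <- qual_value("note")
      if (!is.na(note) && grepl("A\\+?T.rich|control region", note, ignore.case = TRUE))
        name <- "NCR"
    }
    if (is.na(name)) {
      warning("skipping feature with unmappable label: ",
              if (is.na(label)) f$key else label)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = name, class = key_to_class[[f$key]],
      from = as.integer(m[2L]), to = as.integer(m[3L]), strand = strand,
      start_codon = NA_character_, stop_codon = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no mappable features found in ", path, call. = FALSE)
  features <- do.call(rbind, rows)
  genome <- mito_genome(sequence, id = id, topology = topology)
  ann <- mito_annotation(features, genome_id = id, genome_length = genome$length)
  for (i in which(ann$class == "PCG")) {
    cls <- classify_codons(sense_sequence(genome, ann[i, ]))
    ann$start_codon[i] <- cls$start_codon
    ann$stop_codon[i] <- cls$stop_codon
  }
  list(genome = genome, annotation = ann)
}
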