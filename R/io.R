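#' Read a feature table into a mitogenome record
#'
#' Reads a Table-1-style gene organization table (comma- or tab-separated)
#' with columns `name`, `strand`, `start`, `end` and optional
#' `feature_class`, `length`, `start_codon`, `stop_codon`, `anticodon`
#' columns, or an NCBI 5-column `.tbl` file (see `format`). Digit-grouping
#' commas and stray spaces inside numbers (frequent typesetting artifacts in
#' printed tables, e.g. `"1, 141"`) are tolerated and stripped.
#'
#' Lengths are always recomputed from the coordinates; when a printed length
#' column is present and disagrees, a warning is emitted and the computed
#' value wins.
#'
#' @param path file path.
#' @param genome_length optional genome length (otherwise the maximum feature
#'   end is used).
#' @param format `"auto"` (default: `.tbl` extension selects tbl), `"table"`
#'   or `"tbl"`.
#' @param record_id identifier for the resulting record.
#' @param circular logical, default `TRUE`.
#' @return a table-only [mitogenome_record()] (no sequence).
#' @export
read_feature_table <- function(path, genome_length = NULL, format = "auto",
                               record_id = basename(path), circular = TRUE) {
  format <- match.arg(format, c("auto", "table", "tbl"))
  if (format == "auto")
    format <- if (grepl("\\.tbl$", path, ignore.case = TRUE)) "tbl" else "table"
  if (format == "tbl")
    return(read_tbl(path, genome_length, record_id, circular))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !nzchar(trimws(first)))
    stop("empty feature table: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          strip.white = TRUE, comment.char = "#",
                          colClasses = "character")
  names(df) <- tolower(names(df))
  need <- c("name", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("empty feature table: ", path)
  df$start_i <- clean_int(df$start)
  df$end_i <- clean_int(df$end)
  orig <- if ("origin_spanning" %in% names(df))
    as.logical(df$origin_spanning) else rep(FALSE, nrow(df))
  orig[is.na(orig)] <- FALSE
  cls <- if ("feature_class" %in% names(df)) df$feature_class
         else infer_class(df$name)
  if (anyDuplicated(df$name))
    stop("duplicated feature name(s) in table: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  feats <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    gene_feature(df$name[i], cls[i], df$strand[i], df$start_i[i], df$end_i[i],
                 origin_spanning = orig[i],
                 anticodon = na_if_blank(df$anticodon[i], cls[i] == "tRNA"),
                 start_codon = na_if_blank(df$start_codon[i], cls[i] == "PCG"),
                 stop_codon = na_if_blank(df$stop_codon[i], cls[i] == "PCG"))
  }))
  gl <- genome_length %||% max(feats$end)
  if ("length" %in% names(df)) {
    printed <- clean_int(df$length)
    computed <- feature_lengths(feats, gl)[match(df$name, feats$name)]
    bad <- which(!is.na(printed) & printed != computed)
    if (length(bad))
      warning("printed length differs from coordinates for: ",
              paste0(df$name[bad], " (", printed[bad], " vs ",
                     computed[bad], ")", collapse = ", "),
              "; computed values win")
  }
  rec <- mitogenome_record(record_id, feats, length = gl, circular = circular)
  extra <- setdiff(names(df), c(need, "start_i", "end_i", "feature_class",
                                "length", "start_codon", "stop_codon",
                                "anticodon", "origin_spanning"))
  if (length(extra))
    attr(rec, "extra_columns") <- df[c("name", extra)]
  rec
}

na_if_blank <- function(x, keep = TRUE) {
  if (is.null(x) || length(x) == 0 || is_blank(x) || !keep) NA_character_
  else trimws(x)
}

# infer feature class from conventional mitochondrial gene names
infer_class <- function(name) {
  ifelse(grepl("^trn", name, ignore.case = TRUE), "tRNA",
  ifelse(grepl("^rrn", name, ignore.case = TRUE), "rRNA",
  ifelse(grepl("^(OH|OL|CR|D-?loop)", name, ignore.case = TRUE),
         "control_region", "PCG")))
}

#' Write a mitogenome record as an NCBI 5-column feature table
#'
#' Emits the `.tbl` dialect used for GenBank submissions: a `>Feature`
#' header, then per feature a coordinate line (start, end, feature key) and
#' qualifier lines. Strand is encoded by coordinate order: J-strand
#' (complement) features are written with `start > end`.
#'
#' @param record a `mitogenome_record` with at least one feature.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(record, path) {
  f <- record$features
  if (is.null(f) || nrow(f) == 0) stop("record has no features to write")
  key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           control_region = "D-loop")[f$feature_class]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf(">Feature %s", record$record_id), con)
  for (i in seq_len(nrow(f))) {
    a <- f$start[i]; b <- f$end[i]
    if (f$strand[i] == "J") { tmp <- a; a <- b; b <- tmp }
    writeLines(sprintf("%d\t%d\t%s", a, b, key[i]), con)
    writeLines(sprintf("\t\t\tgene\t%s", f$name[i]), con)
    if (!is.na(f$anticodon[i]))
      writeLines(sprintf("\t\t\tanticodon\t%s", f$anticodon[i]), con)
    if (!is.na(f$start_codon[i]))
      writeLines(sprintf("\t\t\tstart_codon\t%s", f$start_codon[i]), con)
    if (!is.na(f$stop_codon[i]))
      writeLines(sprintf("\t\t\tstop_codon\t%s", f$stop_codon[i]), con)
  }
  invisible(path)
}

read_tbl <- function(path, genome_length, record_id, circular) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty feature table: ", path)
  hdr <- grepl("^>Feature", lines)
  if (any(hdr)) {
    id <- sub("^>Feature\\s+", "", lines[which(hdr)[1]])
    if (nzchar(id)) record_id <- id
  }
  lines <- lines[!hdr]
  feats <- list(); cur <- NULL
  flush <- function(cur, feats) { if (!is.null(cur)) c(feats, list(cur)) else feats }
  for (ln in lines) {
    if (!grepl("^\t", ln)) {
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) < 3) stop("malformed .tbl coordinate line: ", ln)
      feats <- flush(cur, feats)
      cur <- list(a = clean_int(parts[1]), b = clean_int(parts[2]),
                  key = parts[3], quals = list())
    } else {
      parts <- strsplit(sub("^\t+", "", ln), "\t")[[1]]
      if (length(parts) >= 2 && !is.null(cur))
        cur$quals[[parts[1]]] <- parts[2]
    }
  }
  feats <- flush(cur, feats)
  cls_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
               `D-loop` = "control_region")
  rows <- do.call(rbind, lapply(feats, function(x) {
    strand <- if (x$a > x$b) "J" else "N"
    a <- min(x$a, x$b); b <- max(x$a, x$b)
    cls <- cls_map[[x$key]] %||% "PCG"
    gene_feature(x$quals$gene %||% x$key, cls, strand, a, b,
                 anticodon = x$quals$anticodon %||% NA_character_,
                 start_codon = x$quals$start_codon %||% NA_character_,
                 stop_codon = x$quals$stop_codon %||% NA_character_)
  }))
  mitogenome_record(record_id, rows, length = genome_length %||% max(rows$end),
                    circular = circular)
}

#' Read a GenBank flat file
#'
#' Minimal parser for annotated mitogenome flat files: LOCUS line, FEATURES
#' table with `CDS`, `tRNA`, `rRNA` and `D-loop` keys (plain and
#' `complement(a..b)` locations), and the ORIGIN sequence block. A
#' `complement(...)` location is assigned the J strand under the package's
#' default convention (deposited orientation = N reading orientation).
#' A file without an ORIGIN block yields a table-only record with a warning.
#'
#' @param path file path.
#' @return a [mitogenome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^LOCUS", lines[1]))
    stop("malformed GenBank record (", path, "): missing LOCUS at line 1")
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- locus[2]
  circular <- any(grepl("circular", lines[1], ignore.case = TRUE))
  fi <- grep("^FEATURES", lines)
  oi <- grep("^ORIGIN", lines)
  feats <- list()
  if (length(fi)) {
    stop_at <- if (length(oi)) oi[1] else length(lines) + 1L
    block <- lines[(fi[1] + 1L):(stop_at - 1L)]
    cur <- NULL
    for (k in seq_along(block)) {
      ln <- block[k]
      if (grepl("^ {5}\\S", ln)) {
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        if (!is.null(cur)) feats <- c(feats, list(cur))
        cur <- list(key = key, loc = loc, quals = list())
      } else if (grepl("^ {21}/", ln) && !is.null(cur)) {
        q <- sub("^\\s*/", "", trimws(ln))
        kv <- strsplit(q, "=", fixed = TRUE)[[1]]
        val <- if (length(kv) > 1) gsub("\"", "", kv[2]) else TRUE
        cur$quals[[kv[1]]] <- val
      } else if (!is.null(cur) && grepl("^ {21}\\S", ln) &&
                 !grepl("^ {21}/", ln)) {
        cur$loc <- paste0(cur$loc, trimws(ln))  # continuation of location
      }
    }
    if (!is.null(cur)) feats <- c(feats, list(cur))
  }
  sequence <- NULL
  if (length(oi)) {
    body <- lines[(oi[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(body, collapse = "")))
  }
  cls_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
               `D-loop` = "control_region")
  keep <- vapply(feats, function(x) x$key %in% names(cls_map), logical(1))
  rows <- do.call(rbind, lapply(feats[keep], function(x) {
    comp <- grepl("^complement", x$loc)
    m <- regmatches(x$loc, regexec("(\\d+)\\.\\.[<>]?(\\d+)", x$loc))[[1]]
    if (length(m) < 3)
      stop("malformed GenBank location '", x$loc, "' in ", path)
    nm <- x$quals$gene %||% x$quals$product %||% x$key
    gene_feature(nm, cls_map[[x$key]], if (comp) "J" else "N",
                 as.integer(m[2]), as.integer(m[3]),
                 anticodon = if (cls_map[[x$key]] == "tRNA")
                   x$quals$anticodon %||% NA_character_ else NA_character_,
                 start_codon = if (cls_map[[x$key]] == "PCG")
                   x$quals$start_codon %||% NA_character_ else NA_character_,
                 stop_codon = if (cls_map[[x$key]] == "PCG")
                   x$quals$stop_codon %||% NA_character_ else NA_character_)
  }))
  if (is.null(rows)) rows <- gene_feature("dummy", "PCG", "N", 1, 3)[0, ]
  if (is.null(sequence)) {
    warning("no ORIGIN block in ", path, "; returning table-only record")
    gl <- suppressWarnings(clean_int(locus[3]))
    if (is.na(gl)) gl <- max(rows$end)
    return(mitogenome_record(record_id, rows, length = gl,
                             circular = circular))
  }
  mitogenome_record(record_id, rows, sequence = sequence, circular = circular)
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Companion writer to [read_genbank()]: LOCUS, FEATURES (J-strand features
#' as `complement(a..b)`), ORIGIN with 60-column sequence blocks.
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stop_if_no_sequence(record)
  key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
           control_region = "D-loop")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s MIT",
                     record$record_id, record$length,
                     if (record$circular) "circular" else "linear"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     %-16s1..%d", "source", record$length), con)
  f <- record$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "J") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key[[f$feature_class[i]]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name[i]), con)
    if (!is.na(f$anticodon[i]))
      writeLines(sprintf("                     /anticodon=\"%s\"",
                         f$anticodon[i]), con)
    if (!is.na(f$start_codon[i]))
      writeLines(sprintf("                     /start_codon=\"%s\"",
                         f$start_codon[i]), con)
    if (!is.na(f$stop_codon[i]))
      writeLines(sprintf("                     /stop_codon=\"%s\"",
                         f$stop_codon[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(record$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write a record's sequence as FASTA
#'
#' @param record a `mitogenome_record` carrying sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path) {
  stop_if_no_sequence(record)
  x <- Biostrings::DNAStringSet(stats::setNames(record$sequence,
                                                record$record_id))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read an aligned FASTA file as a character matrix
#'
#' Rows are taxa, columns aligned sites; all sequences must have equal
#' length. Used as input to [concatenate_alignments()].
#'
#' @param path aligned FASTA file.
#' @return character matrix with taxon rownames, class `mito_alignment`.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(x))) != 1)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  m <- do.call(rbind, strsplit(toupper(as.character(x)), "", fixed = TRUE))
  rownames(m) <- names(x)
  as_alignment(m)
}

#' Write an alignment matrix as aligned FASTA
#'
#' @param aln character matrix (rows = taxa).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}
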