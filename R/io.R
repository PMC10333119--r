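#' Read a FASTA file as a character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' upper-case character sequences named by their full headers.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file
#'
#' Parses a (plain-text, uncompressed) FASTQ file. Malformed records —
#' truncated blocks, missing `@`/`+` markers, or a quality string whose
#' length differs from its sequence — raise an error naming the offending
#' line, never a silent skip.
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ: line ", (bad[1L] - 1L) * 4L + 1L,
         " does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ: line ", (bad[1L] - 1L) * 4L + 3L,
         " does not start with '+'")
  }
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ: record at line ", (bad[1L] - 1L) * 4L + 1L,
         " has sequence/quality length mismatch")
  }
  data.frame(id = sub("^@", "", hdr), sequence = toupper(seq),
             quality = qual, stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `sequence` and optionally `quality`
#'   (a constant placeholder quality is used when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else
    vapply(nchar(reads$sequence), function(n) strrep("I", n), "")
  if (any(nchar(qual) != nchar(reads$sequence))) {
    stop("quality strings must match sequence lengths")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' TSV (tab-separated, UTF-8, header row) is the canonical tabular dialect
#' for all pipeline artifacts.
#'
#' @param path file path.
#' @return for `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA", showProgress = FALSE))
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Split `|`-delimited FASTA headers into fields
#'
#' Barcode FASTA headers follow `specimenID|trapID|family[|speciesID]`.
#'
#' @param headers character vector of headers.
#' @param fields field names to assign.
#' @return data.frame with one column per field.
#' @export
parse_barcode_headers <- function(headers,
                                  fields = c("specimen", "trap", "family",
                                             "species")) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  npart <- lengths(parts)
  if (length(unique(npart)) > 1L) {
    stop("inconsistent header field counts: ", paste(unique(npart),
         collapse = ", "))
  }
  k <- npart[1L]
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- fields[seq_len(k)]
  out
}

# reverse complement preserving IUPAC codes
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-position sets of plain bases matched by an IUPAC string
iupac_sets <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% names(map))) {
    stop("invalid IUPAC characters: ",
         paste(unique(chars[!chars %in% names(map)]), collapse = ", "))
  }
  lapply(chars, function(c) strsplit(map[[c]], "")[[1]])
}
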