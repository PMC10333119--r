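# Demultiplexing and per-specimen barcode calling.
#
# Rules: a read is assigned to a specimen iff both tags match exactly (in
# either read orientation) and both primers match with at most
# `max_primer_mismatch` substitutions under IUPAC semantics; a dominant
# unique sequence is called as the specimen's barcode iff the specimen has
# >= 50 assigned reads, the dominant count exceeds 10 and is at least five
# times the second-most-common count. This module is fully deterministic.

#' Validate a demultiplexing sheet
#'
#' @param sheet data.frame with columns `specimen`, `fwd_tag`, `rev_tag`
#'   and optionally `trap`. Tag pairs must be unique across specimens and
#'   all tags the same length.
#' @return the sheet, invisibly, or an error.
#' @export
validate_demux_sheet <- function(sheet) {
  stopifnot(all(c("specimen", "fwd_tag", "rev_tag") %in% names(sheet)))
  if (anyDuplicated(sheet$specimen)) {
    stop("duplicate specimen ids in demux sheet")
  }
  key <- paste(toupper(sheet$fwd_tag), toupper(sheet$rev_tag), sep = "\r")
  if (anyDuplicated(key)) {
    dup <- sheet$specimen[duplicated(key) | duplicated(key, fromLast = TRUE)]
    stop("duplicate tag pairs in demux sheet (specimens: ",
         paste(head(dup, 5), collapse = ", "), ")")
  }
  lens <- unique(c(nchar(sheet$fwd_tag), nchar(sheet$rev_tag)))
  if (length(lens) != 1L) stop("all tags must have the same length")
  invisible(sheet)
}

# per-position IUPAC mismatch counts of fixed-length strings vs a pattern
iupac_mismatches <- function(strings, pattern) {
  sets <- iupac_sets(pattern)
  mm <- integer(length(strings))
  for (j in seq_along(sets)) {
    mm <- mm + !(substr(strings, j, j) %in% sets[[j]])
  }
  mm
}

# one orientation: specimen index (NA = no tag-pair match or primer fail)
match_orientation <- function(seqs, sheet, primer_fwd, primer_rev,
                              max_primer_mismatch) {
  tag_len <- nchar(sheet$fwd_tag[1L])
  lpf <- nchar(primer_fwd)
  lpr <- nchar(primer_rev)
  len <- nchar(seqs)
  long_enough <- len >= 2L * tag_len + lpf + lpr + 1L
  fwd_obs <- substr(seqs, 1L, tag_len)
  rev_obs <- revcomp(substr(seqs, len - tag_len + 1L, len))
  key <- paste(fwd_obs, rev_obs, sep = "\r")
  sheet_key <- paste(toupper(sheet$fwd_tag), toupper(sheet$rev_tag),
                     sep = "\r")
  idx <- match(key, sheet_key)
  idx[!long_enough] <- NA_integer_
  hit <- which(!is.na(idx))
  if (length(hit)) {
    fwd_region <- substr(seqs[hit], tag_len + 1L, tag_len + lpf)
    rev_region <- substr(seqs[hit], len[hit] - tag_len - lpr + 1L,
                         len[hit] - tag_len)
    mm_f <- iupac_mismatches(fwd_region, primer_fwd)
    mm_r <- iupac_mismatches(rev_region, revcomp(primer_rev))
    bad <- mm_f > max_primer_mismatch | mm_r > max_primer_mismatch
    idx[hit[bad]] <- NA_integer_
  }
  idx
}

#' Demultiplex tagged reads to specimens
#'
#' Both read orientations are tested. A read matching a specimen in both
#' orientations is treated as ambiguous and left unassigned. Assigned reads
#' are trimmed of tags and primers, and the per-specimen tally of unique
#' trimmed sequences is returned.
#'
#' @param reads data.frame with `id` and `sequence` (from [read_fastq()] or
#'   [simulate_reads()]).
#' @param sheet demux sheet (see [validate_demux_sheet()]).
#' @param primer_fwd,primer_rev shared IUPAC primer strings.
#' @param max_primer_mismatch maximum substitutions tolerated in each
#'   primer (default 2).
#' @param max_tag_mismatch maximum tag substitutions; only the exact-match
#'   rule (`0`) is supported, matching the no-tag-mismatch convention of
#'   tag-based demultiplexing.
#' @return object of class `specimen_amplicons`: list with `tally`
#'   (data.frame `specimen`, `sequence`, `count`), `totals` (named reads
#'   per specimen), `assignments` (data.frame `id`, `specimen`),
#'   `n_assigned`, `n_unassigned`, `n_total`.
#' @export
demultiplex <- function(reads, sheet,
                        primer_fwd = "GGWACWGGWTGAACWGTWTAYCCYCC",
                        primer_rev = "TANACYTCNGGRTGNCCRAARAAYCA",
                        max_primer_mismatch = 2L,
                        max_tag_mismatch = 0L) {
  validate_demux_sheet(sheet)
  if (max_tag_mismatch != 0L) {
    stop("only exact tag matching (max_tag_mismatch = 0) is supported")
  }
  seqs <- toupper(reads$sequence)
  tag_len <- nchar(sheet$fwd_tag[1L])
  lpf <- nchar(primer_fwd)
  lpr <- nchar(primer_rev)

  idx_f <- match_orientation(seqs, sheet, primer_fwd, primer_rev,
                             max_primer_mismatch)
  rc <- revcomp(seqs)
  idx_r <- match_orientation(rc, sheet, primer_fwd, primer_rev,
                             max_primer_mismatch)
  ambiguous <- !is.na(idx_f) & !is.na(idx_r)
  idx <- ifelse(ambiguous, NA_integer_, ifelse(is.na(idx_f), idx_r, idx_f))
  use_rc <- is.na(idx_f) & !is.na(idx_r) & !ambiguous

  assigned <- which(!is.na(idx))
  oriented <- ifelse(use_rc, rc, seqs)
  len <- nchar(oriented)
  template <- substr(oriented, tag_len + lpf + 1L, len - tag_len - lpr)

  tally <- data.frame(specimen = character(0), sequence = character(0),
                      count = integer(0))
  totals <- integer(0)
  assignments <- data.frame(id = character(0), specimen = character(0))
  if (length(assigned)) {
    dt <- data.table::data.table(
      specimen = sheet$specimen[idx[assigned]],
      sequence = template[assigned])
    agg <- dt[, list(count = .N), by = c("specimen", "sequence")]
    data.table::setorder(agg, specimen, -count, sequence)
    tally <- as.data.frame(agg)
    tot <- dt[, list(total = .N), by = "specimen"]
    totals <- setNames(tot$total, tot$specimen)
    assignments <- data.frame(id = reads$id[assigned],
                              specimen = sheet$specimen[idx[assigned]],
                              stringsAsFactors = FALSE)
  }
  structure(list(tally = tally, totals = totals, assignments = assignments,
                 n_assigned = length(assigned),
                 n_unassigned = length(seqs) - length(assigned),
                 n_total = length(seqs)),
            class = "specimen_amplicons")
}

#' @export
print.specimen_amplicons <- function(x, ...) {
  cat("<specimen_amplicons> ", x$n_assigned, "/", x$n_total,
      " reads assigned to ", length(x$totals), " specimens\n", sep = "")
  invisible(x)
}

#' Call the barcode for one specimen
#'
#' Implements the dominant-sequence rule: no call unless the specimen has
#' at least `min_total` reads; the dominant unique sequence is called iff
#' its count strictly exceeds `min_support` and is at least
#' `dominance` times the second-most-common count. A tie for the top count
#' yields no call (no unique dominant sequence).
#'
#' @param tally named integer vector (unique sequence -> read count) for
#'   one specimen.
#' @param min_total minimum assigned reads per specimen (default 50).
#' @param min_support dominant count must strictly exceed this (default 10).
#' @param dominance dominant count must be at least this multiple of the
#'   second count (default 5).
#' @return the called sequence (with attribute `support`) or `NULL`.
#' @export
call_barcode <- function(tally, min_total = 50L, min_support = 10L,
                         dominance = 5) {
  stopifnot(length(tally) > 0, !is.null(names(tally)), all(tally >= 0))
  if (sum(tally) < min_total) return(NULL)
  ord <- order(-tally)
  c1 <- tally[ord[1L]]
  c2 <- if (length(tally) > 1L) tally[ord[2L]] else 0L
  if (c1 == c2) return(NULL)           # tie: no unique dominant sequence
  if (c1 <= min_support) return(NULL)
  if (c1 < dominance * c2) return(NULL)
  structure(names(tally)[ord[1L]], support = as.integer(c1))
}

#' Call barcodes for all specimens in a demultiplexed set
#'
#' @param amplicons a `specimen_amplicons` object from [demultiplex()].
#' @param sheet demux sheet providing `trap` per specimen (optional).
#' @param family_map optional named vector specimen -> family; specimens
#'   absent from the map get family `"unassigned"`.
#' @inheritParams call_barcode
#' @return data.frame of barcode records: `specimen`, `sequence`, `length`,
#'   `trap`, `family`, `support`.
#' @export
call_barcodes <- function(amplicons, sheet = NULL, family_map = NULL,
                          min_total = 50L, min_support = 10L,
                          dominance = 5) {
  stopifnot(inherits(amplicons, "specimen_amplicons"))
  tal <- amplicons$tally
  out <- lapply(split(tal, tal$specimen), function(g) {
    bc <- call_barcode(setNames(g$count, g$sequence), min_total,
                       min_support, dominance)
    if (is.null(bc)) return(NULL)
    data.frame(specimen = g$specimen[1L], sequence = as.character(bc),
               length = nchar(as.character(bc)),
               support = attr(bc, "support"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(specimen = character(0), sequence = character(0),
                      length = integer(0), support = integer(0))
  }
  rownames(out) <- NULL
  out$trap <- if (!is.null(sheet)) {
    sheet$trap[match(out$specimen, sheet$specimen)]
  } else rep(NA_character_, nrow(out))
  out$family <- if (!is.null(family_map)) {
    fam <- unname(family_map[out$specimen])
    ifelse(is.na(fam), "unassigned", fam)
  } else rep("unassigned", nrow(out))
  out[, c("specimen", "sequence", "length", "trap", "family", "support")]
}

# stop codons of a genetic code (default: invertebrate mitochondrial)
stop_codons <- function(code = Biostrings::getGeneticCode("5")) {
  names(code)[code == "*"]
}

#' Does a sequence contain an in-frame stop codon?
#'
#' @param sequence nucleotide string.
#' @param frame reading frame on the forward strand (1, 2 or 3); the
#'   default frame 2 is the reading frame of the 313 bp COI mini-barcode.
#' @param code genetic code (codon -> amino acid); defaults to the
#'   invertebrate mitochondrial code (translation table 5).
#' @return logical.
#' @export
has_stop_codon <- function(sequence, frame = 2L,
                           code = Biostrings::getGeneticCode("5")) {
  stopifnot(frame %in% 1:3)
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < frame + 2L) return(FALSE)
  starts <- seq(frame, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  any(codons %in% stop_codons(code))
}

#' Apply length and stop-codon quality filters to barcodes
#'
#' Drops barcodes shorter than the length cut-off (300 bp for 313 bp
#' datasets, 500 bp for 658 bp datasets) and barcodes whose translation in
#' the configured reading frame under the invertebrate mitochondrial code
#' contains a stop codon. Every rejection is logged with a reason code.
#'
#' @param records barcode data.frame from [call_barcodes()] (needs
#'   `specimen` and `sequence`).
#' @param expected_length amplicon length of the dataset: 313 or 658.
#' @param frame reading frame for the stop-codon screen (default 2).
#' @return list with `retained` (data.frame) and `rejected` (data.frame
#'   `specimen`, `reason` in `"length"`/`"stop_codon"`).
#' @export
filter_barcodes <- function(records, expected_length = 313L, frame = 2L) {
  if (!expected_length %in% c(313L, 658L)) {
    stop("expected_length must be 313 or 658, got ", expected_length)
  }
  cutoff <- if (expected_length == 313L) 300L else 500L
  len_ok <- nchar(records$sequence) >= cutoff
  stop_hit <- vapply(records$sequence, has_stop_codon, TRUE, frame = frame,
                     USE.NAMES = FALSE)
  reason <- rep(NA_character_, nrow(records))
  reason[!len_ok] <- "length"
  reason[len_ok & stop_hit] <- "stop_codon"
  keep <- is.na(reason)
  list(retained = records[keep, , drop = FALSE],
       rejected = data.frame(specimen = records$specimen[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Drop traps/samples with too few barcodes
#'
#' @param records barcode data.frame with a grouping column.
#' @param group_col grouping column name (default `"trap"`).
#' @param min_barcodes minimum barcodes per group (default 100; groups with
#'   fewer are excluded).
#' @return list with `retained` (data.frame) and `removed_groups`
#'   (data.frame `group`, `n_barcodes`).
#' @export
filter_samples <- function(records, group_col = "trap",
                           min_barcodes = 100L) {
  if (!group_col %in% names(records)) {
    stop("grouping column '", group_col, "' not present")
  }
  if (nrow(records) == 0L) {
    return(list(retained = records,
                removed_groups = data.frame(group = character(0),
                                            n_barcodes = integer(0))))
  }
  n_by <- table(records[[group_col]])
  drop <- names(n_by)[n_by < min_barcodes]
  list(retained = records[!records[[group_col]] %in% drop, , drop = FALSE],
       removed_groups = data.frame(group = drop,
                                   n_barcodes = as.integer(n_by[drop]),
                                   stringsAsFactors = FALSE))
}
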