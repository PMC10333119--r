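# End-to-end driver: simulate -> demultiplex/call -> cluster -> community
# -> neglect, with every threshold explicit in the echoed configuration,
# all randomness derived from one top-level seed, and per-stage count
# reconciliation in the run report.

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("dt_config_error", "error")))
}

#' Build a pipeline run configuration
#'
#' All thresholds are explicit so the echoed config fully documents a run.
#' Stage toggles: `simulate` (community + bibliography), `reads` (tagged
#' read simulation + demultiplexing/barcode calling; implies `simulate`),
#' `cluster`, `community`, `neglect`. When `reads` is off, clustering runs
#' directly on the simulated (or supplied) barcodes.
#'
#' @param out_dir output directory for artifacts.
#' @param seed top-level integer seed; per-stage streams are derived from
#'   it.
#' @param stages named logical list; see description.
#' @param scenario a [community_scenario()] (its seed is overridden by the
#'   derived stream).
#' @param read_spec a [read_sim_spec()] (seed likewise overridden).
#' @param biblio a [biblio_scenario()] (seed likewise overridden).
#' @param max_primer_mismatch,max_tag_mismatch demultiplexing thresholds.
#' @param min_total,min_support,dominance barcode-calling thresholds
#'   (50 reads / >10 support / 5x dominance).
#' @param expected_length,frame length cut-off set (313 or 658) and
#'   reading frame for the stop-codon screen.
#' @param min_barcodes_per_sample sample floor (default 100).
#' @param cluster_threshold,min_overlap objective-clustering parameters.
#' @param proportion_offset offset inside `log(proportion + offset)`.
#' @param top_n dominance ranking size.
#' @param s_threshold author-dedication threshold.
#' @param nsp10_offset offset for zero per-decade description counts.
#' @param decades decade labels for the neglect stage.
#' @param barcodes_fasta,reads_fastq,sheet_tsv,dossiers_tsv,descriptions_tsv
#'   optional input files used when the corresponding simulation stage is
#'   disabled.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = list(simulate = TRUE, reads = FALSE,
                                     cluster = TRUE, community = TRUE,
                                     neglect = FALSE),
                       scenario = community_scenario(),
                       read_spec = read_sim_spec(),
                       biblio = biblio_scenario(),
                       max_primer_mismatch = 2L,
                       max_tag_mismatch = 0L,
                       min_total = 50L,
                       min_support = 10L,
                       dominance = 5,
                       expected_length = 313L,
                       frame = 2L,
                       min_barcodes_per_sample = 100L,
                       cluster_threshold = 0.03,
                       min_overlap = 100L,
                       proportion_offset = 0.01,
                       top_n = 20L,
                       s_threshold = 50,
                       nsp10_offset = 1,
                       decades = DECADES_DEFAULT,
                       barcodes_fasta = NULL,
                       reads_fastq = NULL,
                       sheet_tsv = NULL,
                       dossiers_tsv = NULL,
                       descriptions_tsv = NULL) {
  defaults <- list(simulate = TRUE, reads = FALSE, cluster = TRUE,
                   community = TRUE, neglect = FALSE)
  defaults[names(stages)] <- stages
  stages <- lapply(defaults, isTRUE)
  if (stages$reads) stages$simulate <- TRUE
  if (stages$community && !stages$cluster) {
    config_error("community stage requires the cluster stage")
  }
  if (stages$cluster && !stages$simulate && is.null(barcodes_fasta) &&
      is.null(reads_fastq)) {
    config_error("cluster stage needs simulated data or a barcodes_fasta")
  }
  if (stages$neglect && !stages$simulate &&
      (is.null(dossiers_tsv) || is.null(descriptions_tsv))) {
    config_error("neglect stage needs simulation or dossier/description",
                 " input files")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, scenario = scenario,
                 read_spec = read_spec, biblio = biblio,
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 max_tag_mismatch = as.integer(max_tag_mismatch),
                 min_total = as.integer(min_total),
                 min_support = as.integer(min_support),
                 dominance = dominance,
                 expected_length = as.integer(expected_length),
                 frame = as.integer(frame),
                 min_barcodes_per_sample =
                   as.integer(min_barcodes_per_sample),
                 cluster_threshold = cluster_threshold,
                 min_overlap = as.integer(min_overlap),
                 proportion_offset = proportion_offset,
                 top_n = as.integer(top_n),
                 s_threshold = s_threshold,
                 nsp10_offset = nsp10_offset,
                 decades = decades,
                 barcodes_fasta = barcodes_fasta,
                 reads_fastq = reads_fastq,
                 sheet_tsv = sheet_tsv,
                 dossiers_tsv = dossiers_tsv,
                 descriptions_tsv = descriptions_tsv),
            class = "run_config")
}

# per-stage derived seeds, kept well below 2^31
derive_seed <- function(seed, k) {
  (as.integer(seed) * 97L + k * 131L) %% 2000000011L
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, reads/barcode-calling,
#' cluster, community, neglect), writes all artifacts plus the echoed
#' config under `config$out_dir`, and returns a run report whose counts
#' reconcile at every stage boundary. Idempotent for a fixed seed.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `stages` (per-stage in/out/rejected
#'   counts), `stats` (headline statistics) and `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(stages = list(), stats = list())
  truth <- NULL
  barcodes <- NULL          # named character, specimen|trap|family[|species]
  meta <- NULL              # label/trap/family per barcode

  if (config$stages$simulate) {
    sc <- config$scenario
    sc$seed <- derive_seed(config$seed, 1L)
    sim <- simulate_community(sc)
    truth <- sim$specimens
    write_tsv(truth, file.path(config$out_dir, "truth_specimens.tsv"))
    write_fasta(sim$barcodes, file.path(config$out_dir,
                                        "true_barcodes.fasta"))
    report$stages$simulate <- list(n_specimens = nrow(truth),
                                   n_species = length(sim$species_seqs),
                                   n_traps = sc$n_traps,
                                   n_families = sc$n_families)
    barcodes <- sim$barcodes
  }

  if (config$stages$reads) {
    rs <- config$read_spec
    rs$seed <- derive_seed(config$seed, 2L)
    sheet <- make_demux_sheet(truth, tag_length = rs$tag_length,
                              seed = derive_seed(config$seed, 3L))
    rsim <- simulate_reads(barcodes, sheet, rs)
    write_fastq(rsim$reads, file.path(config$out_dir, "reads.fastq"))
    write_tsv(sheet, file.path(config$out_dir, "demux_sheet.tsv"))
    write_tsv(rsim$truth, file.path(config$out_dir, "truth_reads.tsv"))

    amp <- demultiplex(rsim$reads, sheet,
                       primer_fwd = rs$primer_fwd,
                       primer_rev = rs$primer_rev,
                       max_primer_mismatch = config$max_primer_mismatch,
                       max_tag_mismatch = config$max_tag_mismatch)
    stopifnot(amp$n_assigned + amp$n_unassigned == amp$n_total)
    family_map <- setNames(truth$family, truth$specimen)
    called <- call_barcodes(amp, sheet = sheet, family_map = family_map,
                            min_total = config$min_total,
                            min_support = config$min_support,
                            dominance = config$dominance)
    filt <- filter_barcodes(called, config$expected_length, config$frame)
    samp <- filter_samples(filt$retained, "trap",
                           config$min_barcodes_per_sample)
    kept <- samp$retained
    write_tsv(filt$rejected, file.path(config$out_dir,
                                       "barcode_rejections.tsv"))
    report$stages$callbarcodes <- list(
      n_reads = amp$n_total, n_assigned = amp$n_assigned,
      n_unassigned = amp$n_unassigned,
      n_specimens_with_reads = length(amp$totals),
      n_called = nrow(called),
      n_rejected_quality = nrow(filt$rejected),
      n_removed_samples = nrow(samp$removed_groups),
      n_barcodes = nrow(kept))
    sp <- truth$species[match(kept$specimen, truth$specimen)]
    barcodes <- setNames(kept$sequence,
                         paste(kept$specimen, kept$trap, kept$family, sp,
                               sep = "|"))
    write_fasta(barcodes, file.path(config$out_dir, "barcodes.fasta"))
  } else if (!config$stages$simulate && !is.null(config$barcodes_fasta)) {
    barcodes <- read_fasta(config$barcodes_fasta)
  }

  partition <- NULL
  if (config$stages$cluster) {
    if (is.null(barcodes)) config_error("no barcodes available to cluster")
    hdr <- parse_barcode_headers(names(barcodes))
    meta <- data.frame(label = names(barcodes), trap = hdr$trap,
                       family = hdr$family, stringsAsFactors = FALSE)
    partition <- cluster_barcodes(barcodes,
                                  threshold = config$cluster_threshold,
                                  min_overlap = config$min_overlap)
    stopifnot(length(partition$assignment) == length(barcodes))
    write_tsv(data.frame(label = names(partition$assignment),
                         cluster = unname(partition$assignment)),
              file.path(config$out_dir, "partition.tsv"))
    per_trap <- count_motus(partition, meta, by = "trap")
    write_tsv(per_trap, file.path(config$out_dir, "motus_per_trap.tsv"))
    report$stages$cluster <- list(n_barcodes = length(barcodes),
                                  n_motus = partition$n_clusters,
                                  threshold = config$cluster_threshold)
    report$stats$motus_per_trap <- per_trap
  }

  if (config$stages$community) {
    tab <- motu_table(partition, meta)
    mat <- build_community_matrix(tab, mode = "species")
    write_tsv(cbind(data.frame(trap = rownames(mat)), as.data.frame(mat)),
              file.path(config$out_dir, "community_matrix.tsv"))
    ranking <- rank_top_families(mat, min(config$top_n, ncol(mat)))
    write_tsv(ranking, file.path(config$out_dir, "family_ranking.tsv"))
    ve <- variance_explained_by_taxon(mat, config$proportion_offset)
    pca <- pca_relative_eigenvalues(mat)

    # site x mOTU incidence (sites = traps in the synthetic world)
    cl <- partition$assignment[meta$label]
    inc <- table(meta$trap, cl) > 0
    inc <- matrix(inc, nrow(inc), ncol(inc),
                  dimnames = dimnames(table(meta$trap, cl)))
    turn <- turnover_single_site(inc)
    report$stages$community <- list(n_traps = nrow(mat),
                                    n_families = ncol(mat))
    report$stats$top_families <- ranking
    report$stats$adj_r_squared <- ve$adj_r_squared
    report$stats$relative_eigenvalues <- pca$relative_eigenvalues
    report$stats$turnover_single_site <- turn
  }

  if (config$stages$neglect) {
    if (config$stages$simulate) {
      bs <- config$biblio
      bs$seed <- derive_seed(config$seed, 4L)
      bib <- simulate_bibliography(bs)
      write_tsv(bib, file.path(config$out_dir, "bibliography.tsv"))
      n_sp <- tapply(bib$species, bib$family, length)
      fams <- if (!is.null(partition)) {
        cm <- count_motus(partition, meta, by = "family")
        setNames(cm$n_motus, cm$group)
      } else {
        setNames(rep(0L, length(n_sp)), names(n_sp))
      }
      common <- intersect(names(n_sp), names(fams))
      if (length(common) < 1L) {
        config_error("no family overlap between community and bibliography")
      }
      dossiers <- data.frame(family = common,
                             n_motu = as.integer(fams[common]),
                             n_sp = as.integer(n_sp[common]),
                             stringsAsFactors = FALSE)
      records <- bib
    } else {
      dossiers <- read_tsv(config$dossiers_tsv)
      records <- read_tsv(config$descriptions_tsv)
    }
    dossiers$ni <- neglect_index(dossiers$n_motu, dossiers$n_sp)
    write_tsv(dossiers, file.path(config$out_dir, "ni_table.tsv"))
    dpd <- descriptions_per_decade(records, config$decades)
    ni <- setNames(dossiers$ni, dossiers$family)
    ni_pos <- ni[ni > 0]
    stats_neglect <- list()
    common_f <- intersect(rownames(dpd$table), names(ni_pos))
    if (length(common_f) >= 3) {
      stats_neglect$activity_correlation <- neglect_activity_correlation(
        dpd$table[common_f, , drop = FALSE], ni_pos[common_f],
        offset = config$nsp10_offset)
    }
    scores <- author_scores(records, decades = config$decades)
    dedicated <- count_dedicated_authors(scores, config$s_threshold,
                                         config$decades)
    write_tsv(dedicated, file.path(config$out_dir,
                                   "dedicated_authors.tsv"))
    if (all(c("body_min_mm", "body_max_mm") %in% names(dossiers)) &&
        sum(dossiers$n_motu > 0) >= 4) {
      drv <- fit_neglect_drivers(dossiers)
      stats_neglect$drivers <- drv$final
    }
    report$stages$neglect <- list(n_families = nrow(dossiers),
                                  n_description_records = nrow(records),
                                  n_excluded_records = nrow(dpd$excluded))
    report$stats$ni_table <- dossiers
    report$stats$dedicated_authors <- dedicated
    report$stats <- c(report$stats, stats_neglect)
  }

  echo <- config
  echo$scenario <- unclass(echo$scenario)
  echo$read_spec <- unclass(echo$read_spec)
  echo$biblio <- unclass(echo$biblio)
  jsonlite::write_json(unclass(echo),
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  report$config <- config
  class(report) <- "run_report"
  jsonlite::write_json(report_to_json(report),
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  report
}

report_to_json <- function(report) {
  list(stages = report$stages,
       stats = lapply(report$stats, function(x) {
         if (is.data.frame(x)) x else unclass(x)
       }))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$stats$adj_r_squared)) {
    cat("  adjusted R2 (family model):",
        format(x$stats$adj_r_squared, digits = 4), "\n")
  }
  if (!is.null(x$stats$turnover_single_site)) {
    cat("  single-site species fraction:",
        format(x$stats$turnover_single_site, digits = 4), "\n")
  }
  invisible(x)
}

#' Check that files survive a read/write round trip
#'
#' Reads each file with the package's reader for its format, writes it back
#' to a temporary file, re-reads it, and compares. Formats are inferred
#' from the extension (`.fasta`/`.fa`, `.fastq`/`.fq`, `.tsv`, `.json`).
#'
#' @param files character vector of paths.
#' @return data.frame `file`, `format`, `ok`, `detail`.
#' @export
read_write_roundtrips <- function(files) {
  check_one <- function(path) {
    ext <- tolower(tools::file_ext(path))
    fmt <- switch(ext,
                  fasta = , fa = "fasta",
                  fastq = , fq = "fastq",
                  tsv = "tsv",
                  json = "json",
                  return(list(format = ext, ok = FALSE,
                              detail = "unknown format")))
    tmp <- tempfile(fileext = paste0(".", ext))
    on.exit(unlink(tmp))
    res <- tryCatch({
      if (fmt == "fasta") {
        x <- read_fasta(path); write_fasta(x, tmp)
        identical(x, read_fasta(tmp))
      } else if (fmt == "fastq") {
        x <- read_fastq(path); write_fastq(x, tmp)
        identical(x[c("id", "sequence")],
                  read_fastq(tmp)[c("id", "sequence")])
      } else if (fmt == "tsv") {
        x <- read_tsv(path); write_tsv(x, tmp)
        isTRUE(all.equal(x, read_tsv(tmp)))
      } else {
        x <- jsonlite::fromJSON(path)
        jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
        isTRUE(all.equal(x, jsonlite::fromJSON(tmp)))
      }
    }, error = function(e) conditionMessage(e))
    if (isTRUE(res)) list(format = fmt, ok = TRUE, detail = "")
    else list(format = fmt, ok = FALSE,
              detail = if (is.character(res)) res else "content mismatch")
  }
  out <- lapply(files, check_one)
  data.frame(file = files,
             format = vapply(out, `[[`, "", "format"),
             ok = vapply(out, `[[`, TRUE, "ok"),
             detail = vapply(out, `[[`, "", "detail"),
             stringsAsFactors = FALSE)
}
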