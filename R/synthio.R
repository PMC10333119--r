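# Synthetic-data generators. Every generator is seeded, bitwise
# reproducible, and returns ground truth alongside the data so that the
# downstream stages can be tested without any external dataset.

# run code under a fixed seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS_INVERT_MITO <- c("TAA", "TAG")

# default decreasing richness profile over n families
default_family_profile <- function(n_families) {
  w <- 0.8^(seq_len(n_families) - 1)
  w / sum(w)
}

#' Describe a synthetic multi-trap insect community
#'
#' A `community_scenario` is the complete stated world for
#' [simulate_community()]: how many Malaise traps and insect families,
#' the shared family-level relative-richness profile, how strongly each
#' trap deviates from it, how per-trap species counts are drawn, how much
#' species turnover separates traps, and how many specimens each species
#' contributes.
#'
#' @param n_traps number of Malaise traps (>= 1).
#' @param n_families number of insect families (>= 1).
#' @param family_profile simplex weights (length `n_families`, summing to 1
#'   within 1e-9): each family's expected share of per-trap species
#'   richness. Defaults to a decreasing geometric profile.
#' @param profile_noise_sd standard deviation of the per-trap, per-family
#'   log-share perturbation. 0 gives every trap the same expected profile.
#' @param richness_mean expected total species per trap (summed over
#'   families). The default keeps per-trap richness within the 69-3,426
#'   range typical of Malaise trap surveys.
#' @param richness_dispersion negative-binomial size for per-trap,
#'   per-family species counts; `Inf` uses a Poisson draw.
#' @param count_model `"nbinom"`, `"poisson"` or `"deterministic"`
#'   (rounded expectation; no sampling noise in the counts).
#' @param turnover probability, in `[0, 1]`, that a species is private to a
#'   single trap. Shared species occur in `shared_sites` traps.
#' @param shared_sites number of traps occupied by a non-private species.
#' @param abundance_shape geometric-success parameter for the number of
#'   specimens per species per trap (`1 + rgeom(abundance_shape)`); 1
#'   means exactly one specimen per species occurrence.
#' @param intra_sub_prob probability that a specimen barcode carries one
#'   private substitution relative to its species sequence (keeps
#'   intra-species divergence below 1%).
#' @param amplicon_bp barcode template length in bp.
#' @param seed integer seed.
#' @return a `community_scenario` list.
#' @export
community_scenario <- function(n_traps = 20,
                               n_families = 10,
                               family_profile = default_family_profile(n_families),
                               profile_noise_sd = 0.5,
                               richness_mean = 300,
                               richness_dispersion = 5,
                               count_model = c("nbinom", "poisson",
                                               "deterministic"),
                               turnover = 0.976,
                               shared_sites = 2,
                               abundance_shape = 0.6,
                               intra_sub_prob = 0.3,
                               amplicon_bp = 313,
                               seed = 1L) {
  count_model <- match.arg(count_model)
  stopifnot(n_traps >= 1, n_families >= 1,
            length(family_profile) == n_families,
            turnover >= 0, turnover <= 1,
            shared_sites >= 2 || n_traps == 1,
            abundance_shape > 0, abundance_shape <= 1,
            intra_sub_prob >= 0, intra_sub_prob <= 1,
            richness_mean >= 1, amplicon_bp >= 60)
  if (abs(sum(family_profile) - 1) > 1e-9) {
    stop("family_profile must sum to 1 (got ", sum(family_profile), ")")
  }
  if (any(family_profile <= 0)) {
    stop("degenerate profile: zero-weight families cannot host species")
  }
  structure(list(n_traps = as.integer(n_traps),
                 n_families = as.integer(n_families),
                 family_profile = family_profile,
                 profile_noise_sd = profile_noise_sd,
                 richness_mean = richness_mean,
                 richness_dispersion = richness_dispersion,
                 count_model = count_model,
                 turnover = turnover,
                 shared_sites = as.integer(shared_sites),
                 abundance_shape = abundance_shape,
                 intra_sub_prob = intra_sub_prob,
                 amplicon_bp = as.integer(amplicon_bp),
                 seed = as.integer(seed)),
            class = "community_scenario")
}

# replace any in-frame stop codon (frame 2 of the forward strand) by
# editing the codon's middle base; only TAA/TAG are stops in the
# invertebrate mitochondrial code, and T[CGT]A / T[CGT]G are never stops
fix_frame2_stops <- function(chars) {
  len <- length(chars)
  starts <- seq(2L, len - 2L, by = 3L)
  repeat {
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- starts[codons %in% STOP_CODONS_INVERT_MITO]
    if (!length(bad)) return(chars)
    chars[bad + 1L] <- sample(c("C", "G", "T"), length(bad), replace = TRUE)
  }
}

# does the frame-2 codon containing position pos encode a stop?
creates_stop <- function(chars, pos) {
  start <- pos - ((pos - 2L) %% 3L)
  if (start < 2L || start + 2L > length(chars)) return(FALSE)
  paste0(chars[start], chars[start + 1L], chars[start + 2L]) %in%
    STOP_CODONS_INVERT_MITO
}

# substitute a random different base at pos, avoiding in-frame stops
mutate_base <- function(chars, pos) {
  alts <- sample(setdiff(c("A", "C", "G", "T"), chars[pos]))
  for (b in alts) {
    cand <- chars
    cand[pos] <- b
    if (!creates_stop(cand, pos)) return(cand)
  }
  chars
}

#' Simulate a multi-trap community with true species barcodes
#'
#' Draws per-trap, per-family species counts around the scenario's family
#' profile, allocates species to traps so that the realised fraction of
#' single-trap species matches `turnover`, and emits one COI-like barcode
#' per specimen. Species sequences share a template and differ at a fixed
#' set of signature positions, guaranteeing inter-species divergence above
#' 5% and intra-species divergence below 1%, so that clustering at a 3%
#' threshold recovers the true species exactly. All sequences are free of
#' in-frame stop codons under the invertebrate mitochondrial code (frame 2).
#'
#' @param scenario a [community_scenario()].
#' @return list with `specimens` (data.frame: `specimen`, `trap`, `family`,
#'   `species`), `barcodes` (named character vector; names follow
#'   `specimenID|trapID|family|speciesID`), `species_seqs` (one true
#'   sequence per species) and `scenario` (the echoed scenario).
#' @export
simulate_community <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  with_seed(scenario$seed, simulate_community_impl(scenario))
}

simulate_community_impl <- function(sc) {
  traps <- sprintf("trap%02d", seq_len(sc$n_traps))
  families <- sprintf("family%02d", seq_len(sc$n_families))

  # expected count matrix with per-trap log-normal perturbation
  eps <- matrix(0, sc$n_traps, sc$n_families)
  if (sc$profile_noise_sd > 0) {
    eps <- matrix(rnorm(sc$n_traps * sc$n_families, 0, sc$profile_noise_sd),
                  sc$n_traps, sc$n_families)
  }
  mu <- outer(rep(sc$richness_mean, sc$n_traps), sc$family_profile) *
    exp(eps - sc$profile_noise_sd^2 / 2)
  counts <- switch(sc$count_model,
    deterministic = round(mu),
    poisson = matrix(rpois(length(mu), mu), nrow(mu), ncol(mu)),
    nbinom = matrix(rnbinom(length(mu), mu = mu,
                            size = sc$richness_dispersion),
                    nrow(mu), ncol(mu)))
  storage.mode(counts) <- "integer"

  # per family: create species with occupancy 1 (private) or shared_sites,
  # then fill the per-trap count capacities greedily
  occ <- list()   # per species: vector of trap indices
  fam_of <- integer(0)
  for (f in seq_len(sc$n_families)) {
    cap <- counts[, f]
    total <- sum(cap)
    if (total == 0L) next
    d <- integer(0)
    while (sum(d) < total) {
      private <- runif(1) < sc$turnover
      d <- c(d, if (private) 1L else min(sc$shared_sites, sc$n_traps))
    }
    excess <- sum(d) - total
    if (excess > 0L) d[length(d)] <- d[length(d)] - excess
    d <- d[d > 0L]
    for (di in sort(d, decreasing = TRUE)) {
      open <- which(cap > 0L)
      k <- min(di, length(open))
      pick <- open[order(-cap[open])][seq_len(k)]
      cap[pick] <- cap[pick] - 1L
      occ[[length(occ) + 1L]] <- pick
      fam_of <- c(fam_of, f)
    }
  }
  n_species <- length(occ)
  if (n_species == 0L) stop("scenario produced an empty community")
  species <- sprintf("sp%05d", seq_len(n_species))

  # species sequences: shared stop-free template + signature positions
  bp <- sc$amplicon_bp
  n_sig <- max(20L, ceiling(0.13 * bp))
  template <- fix_frame2_stops(sample(c("A", "C", "G", "T"), bp,
                                      replace = TRUE))
  sig_pos <- sort(sample(seq_len(bp), n_sig))
  min_sep <- floor(0.05 * bp) + 1L  # > 5% of positions must differ
  sig_mat <- matrix(sample(c("A", "C", "G", "T"), n_species * n_sig,
                           replace = TRUE), n_species, n_sig)
  if (n_species > 1L) {
    repeat {
      sig_str <- apply(sig_mat, 1L, paste, collapse = "")
      hd <- .pdist_matrix_cpp(sig_str, 1L) * n_sig
      diag(hd) <- Inf
      clash <- which(apply(hd, 1L, min) < min_sep)
      if (!length(clash)) break
      for (i in clash[-1L]) {  # keep the first of each clashing set
        sig_mat[i, ] <- sample(c("A", "C", "G", "T"), n_sig, replace = TRUE)
      }
    }
  }
  species_chars <- lapply(seq_len(n_species), function(i) {
    chars <- template
    chars[sig_pos] <- sig_mat[i, ]
    fix_frame2_stops(chars)
  })
  species_seqs <- vapply(species_chars, paste, "", collapse = "")
  names(species_seqs) <- species

  # specimens: per species occurrence, 1 + geometric count of specimens
  rows <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    tr <- occ[[i]]
    nspec <- 1L + rgeom(length(tr), sc$abundance_shape)
    rows[[i]] <- data.frame(trap = rep(traps[tr], nspec),
                            family = families[fam_of[i]],
                            species = species[i],
                            stringsAsFactors = FALSE)
  }
  specimens <- do.call(rbind, rows)
  specimens$specimen <- sprintf("spec%06d", seq_len(nrow(specimens)))
  specimens <- specimens[, c("specimen", "trap", "family", "species")]
  rownames(specimens) <- NULL

  # barcodes: species sequence, with at most one private substitution at a
  # non-signature position (keeps intra-species pairwise divergence < 1%)
  editable <- setdiff(seq_len(bp), sig_pos)
  sp_idx <- match(specimens$species, species)
  mutate_flag <- runif(nrow(specimens)) < sc$intra_sub_prob
  barcodes <- character(nrow(specimens))
  for (r in seq_len(nrow(specimens))) {
    if (mutate_flag[r]) {
      chars <- mutate_base(species_chars[[sp_idx[r]]],
                           sample(editable, 1L))
      barcodes[r] <- paste(chars, collapse = "")
    } else {
      barcodes[r] <- species_seqs[sp_idx[r]]
    }
  }
  names(barcodes) <- paste(specimens$specimen, specimens$trap,
                           specimens$family, specimens$species, sep = "|")

  list(specimens = specimens, barcodes = barcodes,
       species_seqs = species_seqs, scenario = sc)
}

#' Describe the tagged-read simulator
#'
#' @param tag_length tag length in bp (13 for MinION-style tags, 9 for
#'   Illumina-style).
#' @param primer_fwd,primer_rev IUPAC primer strings; defaults are the
#'   degenerate COI mini-barcode primer pair used for 313 bp amplicons.
#' @param depth_mean expected reads per specimen.
#' @param depth_dispersion negative-binomial size for per-specimen depth;
#'   `Inf` gives every specimen exactly `depth_mean` reads.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a `read_sim_spec` list.
#' @export
read_sim_spec <- function(tag_length = 13,
                          primer_fwd = "GGWACWGGWTGAACWGTWTAYCCYCC",
                          primer_rev = "TANACYTCNGGRTGNCCRAARAAYCA",
                          depth_mean = 200,
                          depth_dispersion = 5,
                          error_rate = 0.01,
                          seed = 1L) {
  stopifnot(tag_length > 0, error_rate >= 0, error_rate < 1,
            depth_mean >= 0)
  iupac_sets(primer_fwd)  # validates
  iupac_sets(primer_rev)
  structure(list(tag_length = as.integer(tag_length),
                 primer_fwd = toupper(primer_fwd),
                 primer_rev = toupper(primer_rev),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_spec")
}

#' Build a demultiplexing sheet with unique random tag pairs
#'
#' @param specimens data.frame with at least `specimen` and `trap` columns.
#' @param tag_length tag length in bp.
#' @param seed integer seed.
#' @return data.frame `specimen`, `fwd_tag`, `rev_tag`, `trap`.
#' @export
make_demux_sheet <- function(specimens, tag_length = 13, seed = 1L) {
  stopifnot(all(c("specimen", "trap") %in% names(specimens)))
  n <- nrow(specimens)
  with_seed(seed, {
    random_tags <- function(k) {
      repeat {
        tags <- vapply(seq_len(k), function(i) {
          paste(sample(c("A", "C", "G", "T"), tag_length, replace = TRUE),
                collapse = "")
        }, "")
        if (!anyDuplicated(tags)) return(tags)
      }
    }
    data.frame(specimen = specimens$specimen,
               fwd_tag = random_tags(n),
               rev_tag = random_tags(n),
               trap = specimens$trap,
               stringsAsFactors = FALSE)
  })
}

#' Simulate tagged amplicon reads
#'
#' Each read is `fwd_tag + fwd_primer + template + revcomp(rev_primer) +
#' revcomp(rev_tag)`. Degenerate primer positions are realised uniformly at
#' random per read (as in a degenerate oligo pool); substitution errors are
#' then applied across the whole read at `error_rate`. Roughly half the
#' reads are emitted in reverse-complement orientation, as for merged
#' paired-end reads. Read provenance (`truth`) is recorded for every read.
#'
#' @param barcodes named character vector of per-specimen template
#'   sequences; names must start with the specimen id (`|`-delimited).
#' @param sheet demux sheet from [make_demux_sheet()] covering every
#'   specimen in `barcodes`.
#' @param spec a [read_sim_spec()].
#' @return list with `reads` (data.frame `id`, `sequence`, `quality`) and
#'   `truth` (data.frame `id`, `specimen`).
#' @export
simulate_reads <- function(barcodes, sheet, spec) {
  stopifnot(inherits(spec, "read_sim_spec"))
  specimen_of <- parse_barcode_headers(names(barcodes),
                                       fields = c("specimen", "trap",
                                                  "family", "species"))$specimen
  missing <- setdiff(specimen_of, sheet$specimen)
  if (length(missing)) {
    stop("specimens missing from demux sheet: ",
         paste(head(missing, 5), collapse = ", "))
  }
  with_seed(spec$seed, {
    idx <- match(specimen_of, sheet$specimen)
    n_spec <- length(barcodes)
    depth <- if (is.infinite(spec$depth_dispersion)) {
      rep(as.integer(round(spec$depth_mean)), n_spec)
    } else {
      rnbinom(n_spec, mu = spec$depth_mean, size = spec$depth_dispersion)
    }
    which_spec <- rep(seq_len(n_spec), depth)
    n_reads <- length(which_spec)
    if (n_reads == 0L) {
      return(list(reads = data.frame(id = character(0),
                                     sequence = character(0),
                                     quality = character(0)),
                  truth = data.frame(id = character(0),
                                     specimen = character(0))))
    }
    realize <- function(pattern, n) {
      sets <- iupac_sets(pattern)
      cols <- lapply(sets, function(s) {
        if (length(s) == 1L) rep(s, n) else sample(s, n, replace = TRUE)
      })
      do.call(paste0, cols)
    }
    fwd_p <- realize(spec$primer_fwd, n_reads)
    rev_p <- revcomp(realize(spec$primer_rev, n_reads))
    seqs <- paste0(sheet$fwd_tag[idx][which_spec], fwd_p,
                   unname(barcodes)[which_spec], rev_p,
                   revcomp(sheet$rev_tag[idx][which_spec]))
    if (spec$error_rate > 0) {
      lens <- nchar(seqs)
      n_err <- rbinom(n_reads, lens, spec$error_rate)
      for (r in which(n_err > 0L)) {
        chars <- strsplit(seqs[r], "")[[1]]
        pos <- sample.int(lens[r], n_err[r])
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, "")
        seqs[r] <- paste(chars, collapse = "")
      }
    }
    flip <- runif(n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    ids <- sprintf("read%07d", seq_len(n_reads))
    list(reads = data.frame(id = ids, sequence = seqs,
                            quality = vapply(nchar(seqs),
                                             function(n) strrep("I", n), ""),
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids,
                            specimen = sheet$specimen[idx][which_spec],
                            stringsAsFactors = FALSE))
  })
}

#' Describe a synthetic species-description bibliography
#'
#' @param n_families number of families.
#' @param decades ordered decade labels; the default matches the four
#'   decades 1980-2019 used in neglect analyses.
#' @param intensity expected number of species described per family per
#'   decade: a single number, a per-decade vector, or an
#'   `n_families x length(decades)` matrix.
#' @param author_pool number of candidate authors per family.
#' @param study_size_p geometric-success parameter for species per study
#'   (`1 + rgeom(study_size_p)`).
#' @param coauthor_probs probabilities for 1, 2, ... authors per study.
#' @param seed integer seed.
#' @return a `biblio_scenario` list.
#' @export
biblio_scenario <- function(n_families = 20,
                            decades = c("1980-1989", "1990-1999",
                                        "2000-2009", "2010-2019"),
                            intensity = 25,
                            author_pool = 10,
                            study_size_p = 0.15,
                            coauthor_probs = c(0.45, 0.35, 0.15, 0.05),
                            seed = 1L) {
  stopifnot(n_families >= 1, length(decades) >= 1, all(intensity >= 0),
            author_pool >= 1, study_size_p > 0, study_size_p <= 1,
            all(coauthor_probs >= 0), sum(coauthor_probs) > 0)
  if (is.matrix(intensity)) {
    stopifnot(nrow(intensity) == n_families,
              ncol(intensity) == length(decades))
  } else if (length(intensity) == length(decades)) {
    intensity <- matrix(intensity, n_families, length(decades), byrow = TRUE)
  } else if (length(intensity) == 1L) {
    intensity <- matrix(intensity, n_families, length(decades))
  } else {
    stop("intensity must be scalar, per-decade, or a family x decade matrix")
  }
  structure(list(n_families = as.integer(n_families),
                 decades = decades,
                 intensity = intensity,
                 author_pool = as.integer(author_pool),
                 study_size_p = study_size_p,
                 coauthor_probs = coauthor_probs / sum(coauthor_probs),
                 seed = as.integer(seed)),
            class = "biblio_scenario")
}

decade_bounds <- function(label) {
  as.integer(strsplit(label, "-", fixed = TRUE)[[1]])
}

#' Simulate a species-description bibliography
#'
#' Draws Poisson numbers of described species per family per decade around
#' the scenario intensities, groups species into studies of geometric size,
#' and assigns each study an author team sampled from the family's author
#' pool. One record per described species.
#'
#' @param scenario a [biblio_scenario()].
#' @return data.frame with columns `species`, `family`, `year`, `decade`,
#'   `authors` (semicolon-separated), `study`, `n_species_in_study`.
#' @export
simulate_bibliography <- function(scenario) {
  stopifnot(inherits(scenario, "biblio_scenario"))
  with_seed(scenario$seed, {
    sc <- scenario
    families <- sprintf("family%02d", seq_len(sc$n_families))
    out <- list()
    study_counter <- 0L
    sp_counter <- 0L
    for (f in seq_len(sc$n_families)) {
      pool <- sprintf("author_%s_%02d", families[f], seq_len(sc$author_pool))
      for (d in seq_along(sc$decades)) {
        n_sp <- rpois(1L, sc$intensity[f, d])
        if (n_sp == 0L) next
        yr <- decade_bounds(sc$decades[d])
        remaining <- n_sp
        while (remaining > 0L) {
          study_counter <- study_counter + 1L
          size <- min(remaining, 1L + rgeom(1L, sc$study_size_p))
          n_auth <- min(sample(seq_along(sc$coauthor_probs), 1L,
                               prob = sc$coauthor_probs), length(pool))
          auth <- paste(sort(sample(pool, n_auth)), collapse = ";")
          year <- sample(seq(yr[1], yr[2]), 1L)
          sp_ids <- sprintf("%s_sp%05d", families[f],
                            sp_counter + seq_len(size))
          sp_counter <- sp_counter + size
          out[[length(out) + 1L]] <- data.frame(
            species = sp_ids, family = families[f], year = year,
            decade = sc$decades[d], authors = auth,
            study = sprintf("study%06d", study_counter),
            n_species_in_study = size, stringsAsFactors = FALSE)
          remaining <- remaining - size
        }
      }
    }
    if (!length(out)) {
      return(data.frame(species = character(0), family = character(0),
                        year = integer(0), decade = character(0),
                        authors = character(0), study = character(0),
                        n_species_in_study = integer(0)))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
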