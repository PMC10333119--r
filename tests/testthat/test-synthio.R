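test_that("scenario validation rejects degenerate inputs", {
  expect_error(community_scenario(n_families = 3,
                                  family_profile = c(0.5, 0.5, 0)),
               "degenerate profile")
  expect_error(community_scenario(n_families = 2,
                                  family_profile = c(0.6, 0.3)),
               "sum to 1")
  expect_error(community_scenario(turnover = 1.2))
  expect_error(read_sim_spec(error_rate = 1))
  expect_error(read_sim_spec(primer_fwd = "ACGTX"), "IUPAC")
})

test_that("turnover = 1 makes every species private to one trap", {
  sim <- simulate_community(tiny_scenario(turnover = 1, seed = 3))
  per_sp <- tapply(sim$specimens$trap, sim$specimens$species,
                   function(x) length(unique(x)))
  expect_true(all(per_sp == 1L))
})

test_that("noise-free deterministic counts give identical trap profiles", {
  sim <- simulate_community(tiny_scenario(profile_noise_sd = 0,
                                          count_model = "deterministic",
                                          seed = 5))
  sp <- unique(sim$specimens[c("trap", "family", "species")])
  cnt <- table(sp$trap, sp$family)
  shares <- sweep(cnt, 1, rowSums(cnt), "/")
  for (j in seq_len(ncol(shares))) {
    expect_equal(max(shares[, j]) - min(shares[, j]), 0)
  }
})

test_that("empirical mean per-trap shares track the generating weights", {
  w <- c(0.4, 0.3, 0.2, 0.05, 0.05)
  sim <- simulate_community(community_scenario(
    n_traps = 20, n_families = 5, family_profile = w,
    profile_noise_sd = 0.2, richness_mean = 80, count_model = "poisson",
    seed = 31))
  sp <- unique(sim$specimens[c("trap", "family", "species")])
  cnt <- table(sp$trap, sp$family)
  shares <- sweep(cnt, 1, rowSums(cnt), "/")
  mshare <- colMeans(shares)
  se <- apply(shares, 2, sd) / sqrt(nrow(shares))
  expect_true(all(abs(mshare - w) <= 3 * se))
})

test_that("species sequences respect the divergence separation", {
  sim <- simulate_community(tiny_scenario(seed = 17))
  d <- pdistance_matrix(sim$species_seqs)
  diag(d) <- NA
  expect_gt(min(d, na.rm = TRUE), 0.05)
  # intra-specimen divergence within a species stays below 1%
  sp <- parse_barcode_headers(names(sim$barcodes))$species
  multi <- names(which(table(sp) >= 2))
  expect_gt(length(multi), 0)
  for (one in head(multi, 5)) {
    db <- pdistance_matrix(sim$barcodes[sp == one])
    expect_lt(max(db), 0.01)
  }
  # no in-frame stop codons anywhere
  expect_false(any(vapply(sim$barcodes, has_stop_codon, TRUE)))
})

test_that("generators are bitwise reproducible given a seed", {
  s1 <- simulate_community(tiny_scenario(seed = 23))
  s2 <- simulate_community(tiny_scenario(seed = 23))
  expect_identical(s1, s2)
  sheet <- make_demux_sheet(s1$specimens, seed = 4)
  expect_identical(sheet, make_demux_sheet(s1$specimens, seed = 4))
  spec <- read_sim_spec(error_rate = 0.01, depth_mean = 30, seed = 8)
  expect_identical(simulate_reads(s1$barcodes[1:10], sheet, spec),
                   simulate_reads(s1$barcodes[1:10], sheet, spec))
  bsc <- biblio_scenario(n_families = 3, intensity = 10, seed = 6)
  expect_identical(simulate_bibliography(bsc), simulate_bibliography(bsc))
})

test_that("reads have the tag-primer-template-primer-tag structure", {
  sim <- simulate_community(tiny_scenario(seed = 2))
  sub <- sim$specimens[1:5, ]
  sheet <- make_demux_sheet(sub, tag_length = 13, seed = 1)
  spec <- read_sim_spec(error_rate = 0, depth_mean = 3,
                        depth_dispersion = Inf, seed = 9)
  rr <- simulate_reads(sim$barcodes[1:5], sheet, spec)
  truth1 <- rr$truth$specimen[1]
  i <- match(truth1, sheet$specimen)
  s <- rr$reads$sequence[1]
  # orient the read forward if it was emitted reverse-complemented
  if (substr(s, 1, 13) != sheet$fwd_tag[i]) {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  expect_identical(substr(s, 1, 13), sheet$fwd_tag[i])
  expect_identical(substr(s, nchar(s) - 12, nchar(s)),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(sheet$rev_tag[i]))))
  template <- substr(s, 13 + 26 + 1, nchar(s) - 13 - 26)
  expect_identical(template,
                   unname(sim$barcodes[match(truth1,
                                             sim$specimens$specimen)]))
})

test_that("noiseless round trip recovers every true barcode", {
  sim <- simulate_community(tiny_scenario(seed = 13))
  sub_idx <- 1:40
  sub <- sim$specimens[sub_idx, ]
  sheet <- make_demux_sheet(sub, seed = 2)
  spec <- read_sim_spec(error_rate = 0, depth_mean = 55,
                        depth_dispersion = Inf, seed = 3)
  rr <- simulate_reads(sim$barcodes[sub_idx], sheet, spec)
  amp <- demultiplex(rr$reads, sheet)
  called <- call_barcodes(amp, sheet = sheet)
  expect_equal(nrow(called), length(sub_idx))
  truth <- setNames(unname(sim$barcodes[sub_idx]), sub$specimen)
  expect_identical(called$sequence, unname(truth[called$specimen]))
})

test_that("depth fixed at 49 reads yields zero called barcodes", {
  sim <- simulate_community(tiny_scenario(seed = 13))
  sub <- sim$specimens[1:10, ]
  sheet <- make_demux_sheet(sub, seed = 2)
  spec <- read_sim_spec(error_rate = 0, depth_mean = 49,
                        depth_dispersion = Inf, seed = 3)
  rr <- simulate_reads(sim$barcodes[1:10], sheet, spec)
  called <- call_barcodes(demultiplex(rr$reads, sheet), sheet = sheet)
  expect_equal(nrow(called), 0L)
})

test_that("at 1% error and depth 200 the dominant sequence is the truth", {
  sim <- simulate_community(community_scenario(
    n_traps = 2, n_families = 2, family_profile = c(0.6, 0.4),
    richness_mean = 25, count_model = "deterministic",
    abundance_shape = 1, seed = 42))
  sheet <- make_demux_sheet(sim$specimens, seed = 9)
  spec <- read_sim_spec(error_rate = 0.01, depth_mean = 200,
                        depth_dispersion = Inf, seed = 13)
  rr <- simulate_reads(sim$barcodes, sheet, spec)
  amp <- demultiplex(rr$reads, sheet)
  dom <- vapply(split(amp$tally, amp$tally$specimen),
                function(g) g$sequence[which.max(g$count)], "")
  truth <- setNames(unname(sim$barcodes), sim$specimens$specimen)
  expect_gte(mean(dom == truth[names(dom)]), 0.95)
})

test_that("bibliography totals and author credits behave as constructed", {
  # sole author: credit equals the number of species generated
  sole <- simulate_bibliography(biblio_scenario(
    n_families = 1, decades = "2000-2009", intensity = 60,
    author_pool = 1, seed = 21))
  sc <- author_scores(sole, decades = "2000-2009")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$score, nrow(sole))
  # all 2-author studies: every score is a multiple of 0.5
  duo <- simulate_bibliography(biblio_scenario(
    n_families = 2, intensity = 15, author_pool = 4,
    coauthor_probs = c(0, 1), seed = 22))
  expect_true(all(lengths(strsplit(duo$authors, ";")) == 2L))
  sc2 <- author_scores(duo)
  expect_true(all(abs(sc2$score * 2 - round(sc2$score * 2)) < 1e-9))
  # per-decade totals match the description table truth
  bib <- simulate_bibliography(biblio_scenario(
    n_families = 3, intensity = 10, seed = 23))
  dpd <- descriptions_per_decade(bib)
  expect_equal(sum(dpd$table), nrow(bib))
  expect_equal(nrow(dpd$excluded), 0L)
  truth_tab <- table(bib$family, bib$decade)
  expect_equal(as.integer(dpd$table[rownames(truth_tab),
                                    colnames(truth_tab)]),
               as.integer(truth_tab))
})

test_that("realised single-trap fraction matches the turnover setting", {
  tau <- 0.9
  sim <- simulate_community(community_scenario(
    n_traps = 15, n_families = 4, family_profile = c(0.4, 0.3, 0.2, 0.1),
    richness_mean = 100, count_model = "poisson", turnover = tau,
    seed = 37))
  per_sp <- tapply(sim$specimens$trap, sim$specimens$species,
                   function(x) length(unique(x)))
  n <- length(per_sp)
  ci <- tau + c(-1, 1) * qnorm(0.995) * sqrt(tau * (1 - tau) / n)
  expect_gte(mean(per_sp == 1), ci[1])
  expect_lte(mean(per_sp == 1), ci[2])
})
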