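counts_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

test_that("community matrix rows are normalised proportions", {
  cnt <- counts_df(trap = c("t1", "t1", "t2"),
                   family = c("F1", "F2", "F1"),
                   n_motus = c(5L, 5L, 7L))
  m <- build_community_matrix(cnt)
  expect_equal(m["t1", ], c(F1 = 0.5, F2 = 0.5))
  expect_equal(m["t2", ], c(F1 = 1, F2 = 0))
  expect_equal(unname(rowSums(m)), c(1, 1))
  # unidentified families are excluded before normalisation
  cnt2 <- counts_df(trap = "t1", family = c("F1", "unassigned"),
                    n_motus = c(3L, 9L))
  m2 <- build_community_matrix(cnt2)
  expect_equal(unname(m2["t1", "F1"]), 1)
  expect_false("unassigned" %in% colnames(m2))
  # empty traps are dropped with a warning
  cnt3 <- counts_df(trap = c("t1", "t2"), family = c("F1", "unassigned"),
                    n_motus = c(3L, 5L))
  expect_warning(m3 <- build_community_matrix(cnt3), "empty traps")
  expect_equal(rownames(m3), "t1")
})

test_that("family exclusions follow the specimen and sample rules", {
  m <- matrix(0.25, 2, 4,
              dimnames = list(c("t1", "t2"), c("F1", "F2", "F3", "F4")))
  meta <- data.frame(family = c("F1", "F2", "F3", "F4"),
                     total_specimens = c(10L, 11L, 500L, 11L),
                     n_samples_present = c(2L, 1L, 2L, 2L))
  out <- apply_family_exclusions(m, meta)
  # F1 (10 specimens) and F2 (single sample) drop; F4 (11 in 2) stays
  expect_equal(colnames(out), c("F3", "F4"))
  # proportions keep their original denominator (no re-normalisation)
  expect_equal(unname(rowSums(out)), c(0.5, 0.5))
  expect_error(apply_family_exclusions(m, meta[1:3, ]),
               "without metadata")
})

test_that("ranking orders by mean proportion with stable ties", {
  m <- rbind(t1 = c(F1 = 0.3, F2 = 0.1, F3 = 0.6),
             t2 = c(F1 = 0.3, F2 = 0.1, F3 = 0.6))
  r <- rank_top_families(m, 2)
  expect_equal(r$family, c("F3", "F1"))
  expect_equal(r$mean_proportion, c(0.6, 0.3))
  expect_equal(nrow(rank_top_families(m, 0)), 0L)
  expect_warning(all_r <- rank_top_families(m, 10), "available families")
  expect_equal(nrow(all_r), 3L)
  # noise-free scenario: ranking equals the generating profile order
  sim <- simulate_community(tiny_scenario(profile_noise_sd = 0,
                                          count_model = "deterministic",
                                          seed = 61))
  sp <- unique(sim$specimens[c("trap", "family", "species")])
  cnt <- as.data.frame(table(trap = sp$trap, family = sp$family),
                       responseName = "n_motus", stringsAsFactors = FALSE)
  rk <- rank_top_families(build_community_matrix(cnt), 3)
  expect_equal(rk$family, c("family01", "family02", "family03"))
})

test_that("adjusted R2 of the family model matches closed-form algebra", {
  # constant proportions within family -> zero residual variance
  m <- rbind(t1 = c(F1 = 0.7, F2 = 0.3), t2 = c(F1 = 0.7, F2 = 0.3),
             t3 = c(F1 = 0.7, F2 = 0.3))
  expect_equal(variance_explained_by_taxon(m)$adj_r_squared, 1)
  # 2 families x 2 traps against a normal-equations oracle
  m2 <- rbind(t1 = c(F1 = 0.6, F2 = 0.4), t2 = c(F1 = 0.8, F2 = 0.2))
  y <- log(c(0.6, 0.8, 0.4, 0.2) + 0.01)
  X <- cbind(1, c(0, 0, 1, 1))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (4 - 1) / (4 - 1 - 1)
  expect_equal(variance_explained_by_taxon(m2)$adj_r_squared, adj)
  # shuffled labels: adjusted R2 near zero on average
  set.seed(90)
  null_adj <- replicate(100, {
    long <- data.frame(family = sample(rep(sprintf("F%d", 1:5), 20)),
                       proportion = runif(100))
    variance_explained_by_taxon(long)$adj_r_squared
  })
  expect_lt(abs(mean(null_adj)), 0.05)
  expect_error(variance_explained_by_taxon(
    rbind(t1 = c(F1 = 0.5, F2 = 0.5))), "nrow")
})

test_that("variance explained is invariant to reordering and relabelling", {
  set.seed(91)
  m <- matrix(runif(24), 6, 4,
              dimnames = list(sprintf("t%d", 1:6), sprintf("F%d", 1:4)))
  m <- sweep(m, 1, rowSums(m), "/")
  base <- variance_explained_by_taxon(m)$adj_r_squared
  perm <- m[sample(6), sample(4)]
  expect_equal(variance_explained_by_taxon(perm)$adj_r_squared, base)
  relab <- m
  colnames(relab) <- sprintf("Zz%d", 1:4)
  expect_equal(variance_explained_by_taxon(relab)$adj_r_squared, base)
})

test_that("adjusted R2 grows as family structure strengthens", {
  adj_at <- function(sd, seed) {
    sim <- simulate_community(community_scenario(
      n_traps = 12, n_families = 5,
      family_profile = c(0.4, 0.25, 0.15, 0.12, 0.08),
      profile_noise_sd = sd, richness_mean = 80, count_model = "poisson",
      seed = seed))
    sp <- unique(sim$specimens[c("trap", "family", "species")])
    cnt <- as.data.frame(table(trap = sp$trap, family = sp$family),
                         responseName = "n_motus",
                         stringsAsFactors = FALSE)
    variance_explained_by_taxon(build_community_matrix(cnt))$adj_r_squared
  }
  lo <- adj_at(0.1, 101)
  hi <- adj_at(1.5, 101)
  expect_gt(lo, 0.8)
  expect_gt(lo, hi)
})

test_that("PCA relative eigenvalues match a covariance eigen oracle", {
  set.seed(92)
  m <- matrix(runif(20), 5, 4)
  out <- pca_relative_eigenvalues(m)
  expect_equal(sum(out$relative_eigenvalues), 1)
  expect_true(all(diff(out$relative_eigenvalues) <= 1e-12))
  expect_true(all(out$relative_eigenvalues >= 0))
  centred <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(centred) / (nrow(m) - 1), symmetric = TRUE)$values
  expect_equal(out$eigenvalues, ev, tolerance = 1e-10)
  # rank-1 matrix: first axis absorbs everything
  r1 <- outer(c(1, 2, 3), c(0.2, 0.3, 0.5))
  out1 <- pca_relative_eigenvalues(r1)
  expect_equal(out1$relative_eigenvalues[1], 1)
  expect_warning(pca_relative_eigenvalues(matrix(0.5, 3, 3)), "constant")
})

test_that("single-site turnover counts private species", {
  inc <- rbind(site1 = c(a = 1, b = 1, c = 0),
               site2 = c(a = 1, b = 0, c = 1))
  expect_equal(turnover_single_site(inc), 2 / 3)
  expect_equal(turnover_single_site(inc, c("a", "b")), 0.5)
  all_private <- diag(3)
  dimnames(all_private) <- list(sprintf("s%d", 1:3), sprintf("sp%d", 1:3))
  expect_equal(turnover_single_site(all_private), 1)
  expect_error(turnover_single_site(inc, character(0)), "empty")
  expect_error(turnover_single_site(inc, "zz"), "not in incidence")
  # generator truth: estimate within the 99% binomial CI of the setting
  sim <- simulate_community(tiny_scenario(n_traps = 10, turnover = 0.9,
                                          richness_mean = 120, seed = 62))
  pres <- table(sim$specimens$trap, sim$specimens$species) > 0
  pres <- matrix(pres, nrow(pres), dimnames = dimnames(pres))
  est <- turnover_single_site(pres)
  n <- ncol(pres)
  half <- qnorm(0.995) * sqrt(0.9 * 0.1 / n)
  expect_gte(est, 0.9 - half)
  expect_lte(est, 0.9 + half)
})

test_that("clade-age correlation matches the textbook formula", {
  age <- c(50, 100, 200)
  prop <- 0.001 * age + 0.02
  expect_equal(clade_age_correlation(age, prop)$r, 1)
  x <- c(10, 40, 90)
  y <- c(0.3, 0.1, 0.25)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- clade_age_correlation(x, y)
  expect_equal(out$r, r_hand)
  expect_equal(out$n, 3L)
  # permutation null: |r| small at n = 10,000
  set.seed(93)
  big_age <- runif(10000, 10, 300)
  big_prop <- sample(runif(10000))
  expect_lt(abs(clade_age_correlation(big_age, big_prop)$r), 0.05)
  expect_error(clade_age_correlation(c(1, 1, 1), c(0.1, 0.2, 0.3)),
               "zero variance")
})

test_that("sister-clade merging sums columns and re-ranks", {
  m <- rbind(t1 = c(A = 0.5, B = 0.04, C = 0.03, D = 0.43),
             t2 = c(A = 0.5, B = 0.04, C = 0.03, D = 0.43))
  ident <- merge_and_rerank(m, c(A = "A", B = "B", C = "C", D = "D"), 4)
  expect_equal(ident$ranking$family, rank_top_families(m, 4)$family)
  merged <- merge_and_rerank(m, c(B = "BC", C = "BC"), 4)
  expect_equal(unname(merged$matrix[, "BC"]), c(0.07, 0.07))
  # a merge can lift a clade into the top n
  top2 <- merge_and_rerank(m, c(B = "BC", C = "BC"), 2)$ranking$family
  expect_false("BC" %in% rank_top_families(m, 2)$family)
  expect_false("B" %in% rank_top_families(m, 2)$family)
  expect_true(all(c("A", "D") %in% rank_top_families(m, 2)$family))
  expect_equal(top2, c("A", "D"))  # 0.07 still below D
  lifted <- merge_and_rerank(
    rbind(t1 = c(A = 0.5, B = 0.2, C = 0.18, D = 0.12)),
    c(B = "BC", C = "BC"), 2)
  expect_equal(lifted$ranking$family, c("A", "BC"))
  expect_error(merge_and_rerank(m, c(B = "A")), "duplicate")
  expect_error(merge_and_rerank(m, c(Z = "Y")), "not in matrix")
})
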