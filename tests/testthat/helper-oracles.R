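# Independent oracles and small fixture builders used across test files.

# O(n^3) transitive-closure clustering oracle: connected components of the
# threshold graph via repeated boolean matrix multiplication
closure_cluster <- function(d, threshold) {
  n <- nrow(d)
  adj <- !is.na(d) & d <= threshold
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # canonical membership: each row's reachable set defines its cluster
  match(apply(adj, 1, paste, collapse = ""),
        unique(apply(adj, 1, paste, collapse = "")))
}

# adjusted Rand index between two labellings
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# partitions equal up to cluster relabelling?
same_partition <- function(a, b) {
  isTRUE(all.equal(adjusted_rand_index(a, b), 1))
}

# random symmetric distance matrix with zero diagonal
random_dist_matrix <- function(n, scale = 0.06) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, scale)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("s%02d", seq_len(n))
  d
}

# brute-force demultiplexer: scans every (specimen, orientation) pair with
# plain string operations; exact tags, <= max_mm IUPAC primer mismatches
brute_force_demux <- function(reads, sheet, primer_fwd, primer_rev,
                              max_mm = 2L) {
  rc1 <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N", W = "W",
              S = "S", Y = "R", R = "Y", K = "M", M = "K", B = "V",
              V = "B", D = "H", H = "D")
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }
  mm_count <- function(obs, pat) {
    sets <- lapply(strsplit(Biostrings::IUPAC_CODE_MAP[
      strsplit(toupper(pat), "")[[1]]], ""), identity)
    o <- strsplit(obs, "")[[1]]
    sum(vapply(seq_along(sets),
               function(j) !(o[j] %in% sets[[j]]), TRUE))
  }
  tag_len <- nchar(sheet$fwd_tag[1])
  lpf <- nchar(primer_fwd)
  lpr <- nchar(primer_rev)
  out <- character(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    hits <- character(0)
    for (ori in 1:2) {
      s <- if (ori == 1) toupper(reads$sequence[r]) else
        rc1(reads$sequence[r])
      len <- nchar(s)
      if (len < 2 * tag_len + lpf + lpr + 1) next
      ft <- substr(s, 1, tag_len)
      rt <- rc1(substr(s, len - tag_len + 1, len))
      pf <- substr(s, tag_len + 1, tag_len + lpf)
      pr <- rc1(substr(s, len - tag_len - lpr + 1, len - tag_len))
      for (i in seq_len(nrow(sheet))) {
        if (ft == toupper(sheet$fwd_tag[i]) &&
            rt == toupper(sheet$rev_tag[i]) &&
            mm_count(pf, primer_fwd) <= max_mm &&
            mm_count(pr, primer_rev) <= max_mm) {
          hits <- c(hits, sheet$specimen[i])
        }
      }
    }
    hits <- unique(hits)
    out[r] <- if (length(hits) == 1L) hits else NA_character_
  }
  out
}

# tiny community scenario used by several files
tiny_scenario <- function(...) {
  defaults <- list(n_traps = 4, n_families = 3,
                   family_profile = c(0.5, 0.3, 0.2), richness_mean = 30,
                   count_model = "poisson", turnover = 0.8,
                   abundance_shape = 1, seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(community_scenario, args)
}

# dossiers drawn from ln(NI) = b1 ln(N_mOTU) + b2 mean_log_body + eps;
# n_sp is left continuous so the linear-model error stays exactly Gaussian
make_dossiers <- function(n = 20, b1 = 0.7, b2 = -1.2, sigma = 0.3) {
  n_motu <- round(exp(runif(n, 2, 8)))
  mlb <- runif(n, -1, 3)
  log_ni <- b1 * log(n_motu) + b2 * mlb + rnorm(n, 0, sigma)
  data.frame(family = sprintf("f%02d", seq_len(n)), n_motu = n_motu,
             n_sp = n_motu / exp(log_ni), mean_log_body = mlb,
             stringsAsFactors = FALSE)
}

# family x decade N_sp10 matrix simulated around log-linear activity
make_nsp10 <- function(ni, slopes, sigma = 0.5,
                       decades = c("1980-1989", "1990-1999", "2000-2009",
                                   "2010-2019")) {
  tab <- sapply(seq_along(decades), function(d) {
    exp(1.5 + slopes[d] * log(ni) + rnorm(length(ni), 0, sigma))
  })
  dimnames(tab) <- list(names(ni), decades)
  tab
}
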