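# Family-level community-composition statistics: proportion matrices,
# dominance rankings, variance explained by family identity, PCA structure,
# single-site species turnover, and clade-age correlation.

#' Build a trap x family community matrix of proportions
#'
#' Rows are traps/samples, columns families, cells the proportion of mOTUs
#' (or specimens) per family within the trap. mOTUs that could not be
#' identified to family (`"unassigned"` or `NA`) are excluded before row
#' normalisation, so each row sums to 1 over the included families.
#'
#' @param counts data.frame `trap`, `family`, and a count column:
#'   `n_motus` (mode `"species"`) or `n_specimens` (mode `"specimens"`).
#' @param mode `"species"` or `"specimens"`.
#' @param unassigned labels treated as unidentified families.
#' @return numeric matrix of row-normalised proportions, traps as rows.
#' @export
build_community_matrix <- function(counts, mode = c("species", "specimens"),
                                   unassigned = "unassigned") {
  mode <- match.arg(mode)
  col <- if (mode == "species") "n_motus" else "n_specimens"
  stopifnot(all(c("trap", "family", col) %in% names(counts)))
  all_traps <- sort(unique(counts$trap))
  counts <- counts[!is.na(counts$family) &
                     !counts$family %in% unassigned, , drop = FALSE]
  if (any(counts[[col]] < 0)) stop("negative counts")
  traps <- sort(unique(counts$trap))
  gone <- setdiff(all_traps, traps)
  if (length(gone)) {
    warning("dropping empty traps: ", paste(gone, collapse = ", "))
  }
  fams <- sort(unique(counts$family))
  m <- matrix(0, length(traps), length(fams),
              dimnames = list(traps, fams))
  m[cbind(match(counts$trap, traps), match(counts$family, fams))] <-
    counts[[col]]
  rs <- rowSums(m)
  empty <- rs == 0
  if (any(empty)) {
    warning("dropping empty traps: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
    rs <- rs[!empty]
  }
  sweep(m, 1, rs, "/")
}

#' Exclude rare and single-sample families
#'
#' Removes families with 10 or fewer specimens across all samples, or
#' present in one sample only, ahead of the statistical analyses. Rows are
#' deliberately NOT re-normalised: the remaining proportions keep their
#' original denominators.
#'
#' @param matrix community matrix from [build_community_matrix()].
#' @param meta data.frame `family`, `total_specimens`, `n_samples_present`
#'   covering every column.
#' @param min_specimens exclusion threshold on total specimens (families
#'   with `<= min_specimens` are dropped; default 10).
#' @return filtered matrix (same rows, fewer columns).
#' @export
apply_family_exclusions <- function(matrix, meta, min_specimens = 10L) {
  stopifnot(all(c("family", "total_specimens", "n_samples_present")
                %in% names(meta)))
  idx <- match(colnames(matrix), meta$family)
  if (anyNA(idx)) {
    stop("families without metadata: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  }
  keep <- meta$total_specimens[idx] > min_specimens &
    meta$n_samples_present[idx] > 1L
  matrix[, keep, drop = FALSE]
}

#' Rank families by average per-trap proportion
#'
#' Families are sorted by the unweighted mean of their per-trap
#' proportions, descending; ties are broken by total proportion mass, then
#' by family name.
#'
#' @param matrix community matrix (traps x families).
#' @param n number of top families to return (default 20).
#' @return data.frame `rank`, `family`, `mean_proportion`.
#' @export
rank_top_families <- function(matrix, n = 20L) {
  stopifnot(nrow(matrix) >= 1)
  if (n > ncol(matrix)) {
    warning("n = ", n, " exceeds the ", ncol(matrix),
            " available families; returning all")
    n <- ncol(matrix)
  }
  means <- colMeans(matrix)
  totals <- colSums(matrix)
  ord <- order(-means, -totals, colnames(matrix))
  top <- head(ord, n)
  data.frame(rank = seq_along(top), family = colnames(matrix)[top],
             mean_proportion = unname(means[top]),
             stringsAsFactors = FALSE)
}

#' Variance in composition explained by family identity
#'
#' Fits the one-factor linear model `log(proportion + offset) ~ family` to
#' the long-form community matrix and returns its adjusted R-squared,
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p` = number of family levels
#' minus 1. The natural-log offset (default 0.01) is added to all
#' proportions so zero cells stay defined.
#'
#' @param matrix community matrix (traps x families), or a long-form
#'   data.frame with columns `family` and `proportion`.
#' @param offset value added to every proportion before the log.
#' @return list with `adj_r_squared`, `r_squared` and `fit` (the `lm`).
#' @export
variance_explained_by_taxon <- function(matrix, offset = 0.01) {
  if (is.matrix(matrix)) {
    stopifnot(nrow(matrix) >= 2, ncol(matrix) >= 2)
    long <- data.frame(
      family = rep(colnames(matrix), each = nrow(matrix)),
      proportion = as.vector(matrix))
  } else {
    stopifnot(all(c("family", "proportion") %in% names(matrix)))
    long <- matrix
  }
  if (length(unique(long$family)) < 2) stop("need >= 2 families")
  n_per <- table(long$family)
  if (all(n_per == 1)) {
    stop("singular fit: one observation per family leaves no residual df")
  }
  fit <- lm(log(proportion + offset) ~ family, data = long)
  s <- summary(fit)
  list(adj_r_squared = s$adj.r.squared, r_squared = s$r.squared, fit = fit)
}

#' PCA of the community matrix with relative eigenvalues
#'
#' Columns are centred, not scaled; eigenvalues come from the covariance of
#' the rows. Returns relative eigenvalues (each eigenvalue over their sum),
#' descending, plus the row scores.
#'
#' @param matrix community matrix (traps x families), >= 2 rows.
#' @return list with `relative_eigenvalues`, `eigenvalues`, `scores` and
#'   `constant` (TRUE when the matrix has no variance at all, in which case
#'   relative eigenvalues are all zero).
#' @export
pca_relative_eigenvalues <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2)
  pc <- prcomp(matrix, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot < .Machine$double.eps) {
    warning("constant matrix: all eigenvalues are zero")
    return(list(relative_eigenvalues = rep(0, length(ev)),
                eigenvalues = ev, scores = pc$x, constant = TRUE))
  }
  list(relative_eigenvalues = ev / tot, eigenvalues = ev, scores = pc$x,
       constant = FALSE)
}

#' Fraction of species found at a single site
#'
#' @param incidence logical or 0/1 matrix, sites as rows, species as
#'   columns (presence/absence). Sites are coarse units (one per
#'   country/region), not individual traps.
#' @param species subset of column names to restrict to (e.g. species of
#'   the top-20 families); `NULL` uses all columns.
#' @return fraction of the subset's species present in exactly one site.
#' @export
turnover_single_site <- function(incidence, species = NULL) {
  stopifnot(is.matrix(incidence))
  if (!is.null(species)) {
    missing <- setdiff(species, colnames(incidence))
    if (length(missing)) {
      stop("species not in incidence matrix: ",
           paste(head(missing, 5), collapse = ", "))
    }
    incidence <- incidence[, species, drop = FALSE]
  }
  if (ncol(incidence) == 0L) stop("empty species subset")
  n_sites <- colSums(incidence > 0)
  if (any(n_sites == 0)) stop("species present at no site")
  mean(n_sites == 1L)
}

#' Correlation between family clade age and richness proportion
#'
#' @param age clade ages (million years), positive.
#' @param proportion matching richness proportions.
#' @return list `r`, `n`, `p_value` from a two-sided Pearson test.
#' @export
clade_age_correlation <- function(age, proportion) {
  stopifnot(length(age) == length(proportion), length(age) >= 3,
            all(age > 0))
  if (var(age) == 0 || var(proportion) == 0) {
    stop("zero variance in age or proportion")
  }
  ct <- cor.test(age, proportion, method = "pearson")
  list(r = unname(ct$estimate), n = length(age), p_value = ct$p.value)
}

#' Merge families into coarser clades and re-rank
#'
#' Sums the proportion columns of families mapped to the same merged clade
#' (e.g. a family plus its sister clade) and recomputes the dominance
#' ranking, to test the sensitivity of the top-n list to rank subjectivity.
#'
#' @param matrix community matrix (traps x families).
#' @param merge_map named character vector `family -> merged clade name`;
#'   unmapped families keep their own name.
#' @param n top-n size for the new ranking.
#' @return list with `matrix` (merged columns) and `ranking` (from
#'   [rank_top_families()]).
#' @export
merge_and_rerank <- function(matrix, merge_map, n = 20L) {
  unknown <- setdiff(names(merge_map), colnames(matrix))
  if (length(unknown)) {
    stop("merge_map keys not in matrix: ", paste(unknown, collapse = ", "))
  }
  new_names <- colnames(matrix)
  mapped <- match(new_names, names(merge_map))
  new_names[!is.na(mapped)] <- merge_map[mapped[!is.na(mapped)]]
  clash <- intersect(unique(merge_map),
                     setdiff(colnames(matrix), names(merge_map)))
  if (length(clash)) {
    stop("merge would duplicate existing family names: ",
         paste(clash, collapse = ", "))
  }
  merged <- t(rowsum(t(matrix), group = new_names))
  merged <- merged[, order(colnames(merged)), drop = FALSE]
  list(matrix = merged, ranking = rank_top_families(merged, n))
}
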