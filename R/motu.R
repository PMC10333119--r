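# Species delimitation by objective clustering: mOTUs are the connected
# components of the graph joining sequence pairs whose uncorrected
# p-distance is at or below the threshold (single linkage). Deterministic
# and parameter-free apart from the threshold.

#' Uncorrected p-distance between two aligned sequences
#'
#' Mismatches divided by compared positions, under pairwise deletion:
#' positions with a gap (`-`) or ambiguous base (anything outside ACGT) in
#' either sequence are excluded from the comparison.
#'
#' @param a,b aligned sequences of equal length.
#' @param min_overlap minimum compared positions; below it the pair is
#'   flagged as unclusterable and `NA` is returned. The default 100 bp is a
#'   safety net: upstream length filters guarantee >= 300 bp.
#' @return distance in `[0, 1]`, or `NA` on insufficient overlap.
#' @export
p_distance <- function(a, b, min_overlap = 100L) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences must have equal aligned length (", length(a), " vs ",
         length(b), ")")
  }
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  compared <- sum(ok)
  if (compared < min_overlap) return(NA_real_)
  sum(a[ok] != b[ok]) / compared
}

#' Pairwise p-distance matrix
#'
#' C++ implementation of [p_distance()] over all pairs.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @inheritParams p_distance
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names; `NA` marks pairs with insufficient overlap.
#' @export
pdistance_matrix <- function(seqs, min_overlap = 100L) {
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) {
    return(matrix(numeric(0), 0, 0))
  }
  d <- .pdist_matrix_cpp(toupper(seqs), as.integer(min_overlap))
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Objective clustering at a distance threshold
#'
#' Clusters are the connected components of the graph whose edges join
#' pairs with distance at or below the threshold (single linkage). `NA`
#' distances (insufficient overlap) never create an edge. Cluster ids are
#' contiguous integers from 0, numbered by first appearance in label order,
#' so relabelling the input order permutes ids but never the partition.
#'
#' @param d symmetric distance matrix (from [pdistance_matrix()]).
#' @param threshold distance threshold in (0, 1); 0.03 is the conventional
#'   species-level threshold, 0.01 the within-species sorting threshold.
#' @return object of class `motu_partition`: list with `threshold`,
#'   `assignment` (named integer vector label -> cluster id) and
#'   `n_clusters`.
#' @export
objective_cluster <- function(d, threshold = 0.03) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            threshold > 0, threshold < 1)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 0L) {
    return(structure(list(threshold = threshold,
                          assignment = setNames(integer(0), character(0)),
                          n_clusters = 0L),
                     class = "motu_partition"))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(upper.tri(d) & !is.na(d) & d <= threshold, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1L])
    rj <- find(edges[e, 2L])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, 1L)
  ids <- match(roots, unique(roots)) - 1L
  structure(list(threshold = threshold,
                 assignment = setNames(ids, labels),
                 n_clusters = length(unique(ids))),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("<motu_partition> ", length(x$assignment), " sequences -> ",
      x$n_clusters, " mOTUs at threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Cluster aligned barcodes into mOTUs
#'
#' Convenience wrapper: [pdistance_matrix()] then [objective_cluster()].
#'
#' @inheritParams pdistance_matrix
#' @inheritParams objective_cluster
#' @return a `motu_partition`.
#' @export
cluster_barcodes <- function(seqs, threshold = 0.03, min_overlap = 100L) {
  objective_cluster(pdistance_matrix(seqs, min_overlap), threshold)
}

#' Count mOTUs per group
#'
#' Number of distinct clusters with at least one member in each group
#' (trap, family, site, ...), or the global cluster count.
#'
#' @param partition a `motu_partition`.
#' @param metadata data.frame with a `label` column matching the partition
#'   labels plus grouping columns; not needed for `by = "global"`.
#' @param by name of the grouping column in `metadata`, or `"global"`.
#' @return data.frame `group`, `n_motus` (single row `"global"` when
#'   ungrouped).
#' @export
count_motus <- function(partition, metadata = NULL, by = "global") {
  stopifnot(inherits(partition, "motu_partition"))
  labels <- names(partition$assignment)
  if (identical(by, "global")) {
    return(data.frame(group = "global", n_motus = partition$n_clusters,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(metadata), "label" %in% names(metadata),
            by %in% names(metadata))
  idx <- match(labels, metadata$label)
  if (anyNA(idx)) {
    stop("labels without metadata: ",
         paste(head(labels[is.na(idx)], 5), collapse = ", "))
  }
  grp <- metadata[[by]][idx]
  tab <- tapply(partition$assignment, grp,
                function(x) length(unique(x)))
  data.frame(group = names(tab), n_motus = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate mOTU counts by trap and family
#'
#' Distinct clusters per (trap, family) cell — the input to
#' [build_community_matrix()] in species mode.
#'
#' @param partition a `motu_partition`.
#' @param metadata data.frame with `label`, `trap`, `family`.
#' @return data.frame `trap`, `family`, `n_motus`.
#' @export
motu_table <- function(partition, metadata) {
  stopifnot(inherits(partition, "motu_partition"),
            all(c("label", "trap", "family") %in% names(metadata)))
  labels <- names(partition$assignment)
  idx <- match(labels, metadata$label)
  if (anyNA(idx)) {
    stop("labels without metadata: ",
         paste(head(labels[is.na(idx)], 5), collapse = ", "))
  }
  dt <- data.table::data.table(trap = metadata$trap[idx],
                               family = metadata$family[idx],
                               cluster = unname(partition$assignment))
  agg <- dt[, list(n_motus = length(unique(cluster))),
            by = c("trap", "family")]
  data.table::setorder(agg, trap, family)
  as.data.frame(agg)
}
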