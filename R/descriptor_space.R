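#' Pairwise descriptor similarity matrix
#'
#' Computes a percentage similarity between descriptor columns,
#' similarity(i, j) = 100 * (1 + r_ij) / 2, where r_ij is the Pearson
#' correlation. Identical columns score 100, exactly anti-correlated
#' columns score 0, and uncorrelated columns 50. This is the
#' correlation-to-similarity convention used by variable-clustering
#' dendrograms in common statistical packages.
#'
#' @param table A `descriptor_table` (or data frame).
#' @param columns Descriptor column names to compare (>= 2, non-constant).
#' @return An object of class `similarity_matrix`: a symmetric numeric
#'   matrix in \[0, 100\] with the descriptor names as dimnames.
#' @export
pairwise_similarity <- function(table, columns) {
  if (length(columns) < 2L)
    stop("need at least 2 columns")
  missing <- setdiff(columns, names(table))
  if (length(missing))
    stop("column(s) not in table: ", paste(missing, collapse = ", "))
  x <- as.matrix(as.data.frame(table)[columns])
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: constant column(s): ",
         paste(columns[sds == 0], collapse = ", "))
  sim <- 100 * (1 + stats::cor(x)) / 2
  diag(sim) <- 100
  structure(sim, class = c("similarity_matrix", "matrix"))
}

#' Group descriptors by hierarchical clustering of similarities
#'
#' Agglomerative clustering on the dissimilarity 100 - similarity, cut at
#' `k` clusters. On the packaged 65-compound dataset the descriptors
#' \{TPSA, HBA, MW, alpha, parachor, NRB\} split into a polar group
#' (TPSA, HBA), a molecular-size group (MW, alpha, parachor) and a
#' singleton flexibility group (NRB). Group labels are Roman numerals in
#' order of first appearance among the supplied columns; the attained
#' similarity of a group is 100 minus the height at which its members are
#' fully merged (100 for singletons).
#'
#' @param sim A [pairwise_similarity()] matrix.
#' @param linkage Agglomeration method: `"average"` (default), `"single"`
#'   or `"complete"`.
#' @param k Number of groups (default 3).
#' @return An object of class `descriptor_grouping`: a list with `groups`
#'   (data frame: descriptor, group), `group_similarity` (named numeric,
#'   % attained within each group), `linkage`, and `hclust` (the tree).
#' @export
cluster_variables <- function(sim, linkage = c("average", "single", "complete"),
                              k = 3) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(sim, "similarity_matrix"))
  labels <- colnames(sim)
  if (length(labels) < k)
    stop("parameter error: fewer descriptors (", length(labels),
         ") than requested clusters (", k, ")")
  hc <- stats::hclust(stats::as.dist(100 - sim), method = linkage)
  membership <- stats::cutree(hc, k = k)   # numbered by first appearance
  roman <- as.character(utils::as.roman(membership))
  groups <- data.frame(descriptor = labels, group = roman,
                       stringsAsFactors = FALSE)
  attained <- vapply(sort(unique(membership)), function(g) {
    members <- labels[membership == g]
    if (length(members) == 1L) return(100)
    # height at which the group is fully merged under this linkage
    sub <- sim[members, members]
    heights <- hc$height[vapply(seq_along(hc$height), function(i) {
      in_cut <- labels[stats::cutree(hc, h = hc$height[i])[members[1]] ==
                         stats::cutree(hc, h = hc$height[i])]
      all(members %in% in_cut)
    }, logical(1))]
    100 - min(heights)
  }, numeric(1))
  names(attained) <- as.character(utils::as.roman(sort(unique(membership))))
  structure(list(groups = groups, group_similarity = attained,
                 linkage = linkage, hclust = hc),
            class = "descriptor_grouping")
}

#' @export
print.descriptor_grouping <- function(x, ...) {
  cat("Descriptor grouping (", x$linkage, " linkage)\n", sep = "")
  for (g in unique(x$groups$group)) {
    members <- x$groups$descriptor[x$groups$group == g]
    cat(sprintf("  %-4s %s  (similarity %.2f%%)\n", g,
                paste(members, collapse = ", "), x$group_similarity[[g]]))
  }
  invisible(x)
}

#' Members of a grouping
#'
#' @param grouping A `descriptor_grouping`.
#' @param group Group label, e.g. `"I"`.
#' @return Character vector of descriptor names in that group.
#' @export
group_members <- function(grouping, group) {
  stopifnot(inherits(grouping, "descriptor_grouping"))
  grouping$groups$descriptor[grouping$groups$group == group]
}
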