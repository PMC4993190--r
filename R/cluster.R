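#' Ward hierarchical classification into functional germination groups
#'
#' Agglomerative clustering of species on their germination profile
#' (`t0`, `topt`, `tmax`, `psi_b` by default): at each step the pair of
#' clusters whose merge least increases the total within-cluster variance is
#' merged (Ward criterion, squared Euclidean distances), and the tree is cut
#' at `k` groups. `t0` is used rather than `tb` because the minimum
#' temperature is generally the more precisely estimated of the two.
#'
#' Merge heights are reported as the increase in total within-cluster sum of
#' squares at each merge, so they are non-decreasing along the sequence. By
#' default features enter on their raw scales (degrees C and MPa), matching
#' the convention of the reference group summaries; `standardize = TRUE`
#' z-scores each feature first, which is statistically safer when mixing
#' units.
#'
#' @param profiles Data frame with one row per species, a `species_id`
#'   column and the feature columns.
#' @param k Number of groups to cut at (default 5), `1 <= k <= n`.
#' @param standardize Z-score the features before clustering? Default
#'   `FALSE`.
#' @param features Character vector of feature column names (default
#'   `c("t0", "topt", "tmax", "psi_b")`).
#' @return An object of class `germ_grouping`: list with `k`, `labels`
#'   (tibble `species_id`, `group`), `merges` (tibble with merged pair and
#'   `height` = within-variance increase), `feature_names`, `standardized`
#'   and the underlying `hclust` object.
#' @examples
#' profiles <- tibble::tibble(
#'   species_id = letters[1:5],
#'   t0 = c(0, 1, 8, 9, 2), topt = c(25, 26, 33, 34, 28),
#'   tmax = c(35, 36, 42, 42, 37), psi_b = c(-1, -1.1, -0.8, -0.9, -2.3))
#' ward_cluster(profiles, k = 3)
#' @export
ward_cluster <- function(profiles, k = 5, standardize = FALSE,
                         features = c("t0", "topt", "tmax", "psi_b")) {
  profiles <- tibble::as_tibble(profiles)
  missing <- setdiff(features, names(profiles))
  if (length(missing) > 0) {
    abort(sprintf("Missing feature column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "germresp_feature_error")
  }
  X <- as.matrix(profiles[features])
  if (any(!is.finite(X))) {
    bad <- features[colSums(!is.finite(X)) > 0]
    abort(sprintf("Non-finite values in feature(s): %s",
                  paste(bad, collapse = ", ")),
          class = "germresp_feature_error")
  }
  n <- nrow(X)
  if (!is.numeric(k) || k < 1 || k > n) {
    abort(sprintf("`k` must lie in [1, %d].", n),
          class = "germresp_argument_error")
  }
  if (standardize) X <- scale(X)
  rownames(X) <- profiles$species_id

  h <- hclust(dist(X)^2, method = "ward.D")
  # ward.D heights on squared Euclidean distances equal twice the increase in
  # total within-cluster SS at each merge
  heights <- h$height / 2
  labels <- cutree(h, k = k)
  merges <- tibble::tibble(
    step = seq_len(nrow(h$merge)),
    member_a = h$merge[, 1],
    member_b = h$merge[, 2],
    height = heights
  )
  structure(
    list(k = as.integer(k),
         labels = tibble::tibble(species_id = profiles$species_id,
                                 group = unname(labels)),
         merges = merges,
         feature_names = features,
         standardized = standardize,
         hclust = h),
    class = "germ_grouping"
  )
}

#' @export
print.germ_grouping <- function(x, ...) {
  cat(sprintf("<germ_grouping> %d species in %d groups on (%s)%s\n",
              nrow(x$labels), x$k, paste(x$feature_names, collapse = ", "),
              if (x$standardized) ", standardized" else ""))
  print(table(group = x$labels$group))
  invisible(x)
}

#' @export
tidy.germ_grouping <- function(x, ...) x$labels

#' @export
glance.germ_grouping <- function(x, ...) {
  tibble::tibble(k = x$k, n_species = nrow(x$labels),
                 standardized = x$standardized,
                 total_merge_height = sum(x$merges$height))
}

#' @export
autoplot.germ_grouping <- function(object, ...) {
  h <- object$hclust
  heights <- object$merges$height
  n <- length(h$order)
  leaf_x <- match(seq_len(n), h$order)
  node_x <- node_y <- numeric(nrow(h$merge))
  segs <- vector("list", nrow(h$merge))
  child_xy <- function(id, row) {
    if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  }
  for (m in seq_len(nrow(h$merge))) {
    a <- child_xy(h$merge[m, 1])
    b <- child_xy(h$merge[m, 2])
    y <- heights[m]
    node_x[m] <- mean(c(a[1], b[1]))
    node_y[m] <- y
    segs[[m]] <- data.frame(
      x = c(a[1], b[1], a[1]), y = c(a[2], b[2], y),
      xend = c(a[1], b[1], b[1]), yend = c(y, y, y))
  }
  seg <- do.call(rbind, segs)
  lab <- data.frame(x = seq_len(n), label = h$labels[h$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y,
                               xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(
      data = lab, ggplot2::aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1.05, size = 2.8) +
    ggplot2::labs(x = NULL, y = "Within-cluster variance increase") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Export a grouping's dendrogram as a Newick string
#'
#' Serializes the merge tree with the within-variance merge heights as node
#' heights, via [ape::as.phylo()].
#'
#' @param grouping A `germ_grouping`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
grouping_newick <- function(grouping, path = NULL) {
  h <- grouping$hclust
  h$height <- grouping$merges$height
  phy <- ape::as.phylo(h)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
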