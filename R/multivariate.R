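#' PCA of ear-photometry traits
#'
#' Principal component analysis of a hybrids x traits matrix. Missing values
#' are mean-imputed per trait (reported), constant traits are dropped with a
#' warning, and every column is standardised to unit variance before the
#' decomposition, so the percent variance of the components sums to 100.
#'
#' @param data Data frame or matrix of trait values (rows = hybrids). A
#'   column named `hybrid` is carried through as row identifier.
#' @return An object of class `trait_pca` wrapping `prcomp`: `scores`,
#'   `loadings`, `pct_var`, `dropped`, `n_imputed`.
#' @export
trait_pca <- function(data) {
  ids <- NULL
  if (is.data.frame(data) && "hybrid" %in% names(data)) {
    ids <- as.character(data$hybrid)
    data <- data[setdiff(names(data), "hybrid")]
  }
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  n_imputed <- 0L
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) {
      x[nas, j] <- mean(x[, j], na.rm = TRUE)
      n_imputed <- n_imputed + sum(nas)
    }
  }
  if (n_imputed > 0) {
    inform(sprintf("Mean-imputed %d missing value(s) before PCA.", n_imputed))
  }
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warn(paste0("Dropping constant trait(s): ",
                paste(dropped, collapse = ", ")))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x)
  if (!is.null(ids)) scores <- mutate(scores, hybrid = ids, .before = 1)
  structure(list(prcomp = pc, scores = scores,
                 loadings = pc$rotation, pct_var = pct,
                 dropped = dropped, n_imputed = n_imputed),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  k <- min(5L, length(x$pct_var))
  cat("<trait_pca>", ncol(x$loadings), "components;",
      "PC1..", k, ": ", paste0(round(x$pct_var[seq_len(k)], 1), "%",
                               collapse = " "), "\n")
  invisible(x)
}

#' @rdname trait_pca
#' @param x A `trait_pca` object.
#' @param ... Unused.
#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, ...) {
  ld <- x$loadings
  tibble(trait = rep(rownames(ld), times = ncol(ld)),
         component = rep(colnames(ld), each = nrow(ld)),
         loading = as.vector(ld))
}

#' @rdname trait_pca
#' @method glance trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  tibble(component = colnames(x$loadings),
         pct_var = x$pct_var,
         cum_pct_var = cumsum(x$pct_var))
}

#' Ball-Hall index of a partition
#'
#' Mean, over clusters, of the mean squared Euclidean distance of cluster
#' members to their cluster centroid:
#' \deqn{BH(k) = \frac{1}{k} \sum_{c=1}^{k} \frac{1}{n_c}
#'   \sum_{i \in c} \lVert x_i - \bar{x}_c \rVert^2}
#'
#' @param x Numeric matrix (rows = observations).
#' @param membership Integer/factor cluster membership, one per row.
#' @return The index value (scalar).
#' @export
ball_hall_index <- function(x, membership) {
  x <- as.matrix(x)
  membership <- as.integer(factor(membership))
  per_cluster <- vapply(split(seq_len(nrow(x)), membership), function(idx) {
    xm <- x[idx, , drop = FALSE]
    ctr <- colMeans(xm)
    mean(rowSums((xm - matrix(ctr, nrow(xm), ncol(xm), byrow = TRUE))^2))
  }, numeric(1))
  mean(per_cluster)
}

#' Ward clustering of traits with Ball-Hall selection of k
#'
#' Hierarchical clustering of the traits of a hybrids x traits matrix:
#' observations are the traits, features are the per-hybrid values after
#' each trait is standardised to unit variance; Euclidean distance with
#' Ward's minimum-variance linkage (`ward.D2`). The Ball-Hall index is
#' evaluated on the nested partitions for `k = 1..k_max` and the number of
#' clusters is chosen at the elbow of the index curve: the `k >= 2`
#' maximising the second difference `BH(k-1) - 2 BH(k) + BH(k+1)` (the drop
#' into `k` minus the drop out of it). Degenerate input whose index curve
#' never drops (e.g. all traits identical) returns `k = 1`.
#'
#' @param data Hybrids x traits data frame or matrix (a `hybrid` column is
#'   ignored for clustering). At least 3 trait columns.
#' @param k_max Largest k examined; clamped to the number of traits.
#'   Default 10.
#' @return A list of class `trait_clusters`: `hclust` tree, `bh` tibble
#'   (`k`, `index`), `k`, `membership` (named integer vector).
#' @export
cluster_traits <- function(data, k_max = 10) {
  if (is.data.frame(data) && "hybrid" %in% names(data)) {
    data <- data[setdiff(names(data), "hybrid")]
  }
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (ncol(x) < 3) abort("Need at least 3 traits to cluster.")
  sds <- apply(x, 2, sd)
  scl <- ifelse(sds > 0, sds, 1)
  xs <- scale(x, center = TRUE, scale = scl)
  tmat <- t(xs)                       # observations = traits
  k_max <- as.integer(min(k_max, nrow(tmat)))
  tree <- hclust(dist(tmat), method = "ward.D2")
  ks <- seq_len(k_max)
  bh <- vapply(ks, function(k) {
    ball_hall_index(tmat, cutree(tree, k = k))
  }, numeric(1))
  k_sel <- select_k_elbow(bh)
  membership <- cutree(tree, k = k_sel)
  structure(list(hclust = tree, bh = tibble(k = ks, index = bh),
                 k = k_sel, membership = membership, k_max = k_max),
            class = "trait_clusters")
}

# elbow of a non-increasing index curve; zero-drop guard returns 1
#' @noRd
select_k_elbow <- function(bh, tol = 1e-10) {
  k_max <- length(bh)
  if (k_max < 2 || max(bh[1] - bh) <= tol * max(bh[1], 1)) return(1L)
  if (k_max == 2) return(2L)
  drops <- -diff(bh)                          # drops[k-1] = BH(k-1) - BH(k)
  curv <- drops[-length(drops)] - drops[-1]   # curv[k-1], k = 2..k_max-1
  k <- which.max(curv) + 1L
  if (drops[k - 1L] <= tol * max(bh[1], 1)) return(1L)
  k
}

#' @export
print.trait_clusters <- function(x, ...) {
  cat(sprintf("<trait_clusters> Ward (ward.D2), Ball-Hall k = %d (of %d examined)\n",
              x$k, x$k_max))
  print(split(names(x$membership), x$membership))
  invisible(x)
}

#' @rdname cluster_traits
#' @param x A `trait_clusters` object.
#' @param ... Unused.
#' @method tidy trait_clusters
#' @export
tidy.trait_clusters <- function(x, ...) {
  tibble(trait = names(x$membership),
         cluster = unname(x$membership))
}
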