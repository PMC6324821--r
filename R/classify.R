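# Per-segment feature assembly, PCA compartment classification and
# compartment-state profiles.

#' Pairwise DS / ES matrices for one homolog
#'
#' Symmetric matrices of distance scores (diagonal 0) and entanglement
#' scores (diagonal 1) over the homolog's segment maps, in segment order.
#'
#' @param maps named list of thresholded `density_map`s, one per segment.
#' @return a list with `ds` and `es` (k x k matrices, segment names on the
#'   dimnames).
#' @export
pairwise_scores <- function(maps) {
  k <- length(maps)
  nm <- names(maps) %||% paste0("CS", seq_len(k))
  ds <- matrix(0, k, k, dimnames = list(nm, nm))
  es <- diag(1, k)
  dimnames(es) <- list(nm, nm)
  if (k > 1) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    ds[i, j] <- ds[j, i] <- distance_score(maps[[i]], maps[[j]])
    es[i, j] <- es[j, i] <- entanglement_score(maps[[i]], maps[[j]])
  }
  list(ds = ds, es = es)
}

#' Structural feature table for a set of homologs
#'
#' For each homolog (a named list of segment maps), computes the 8 distance
#' scores and 8 entanglement scores to the other segments plus the shape
#' triplet (convex-hull area, body volume, sphericity), one row per
#' segment.
#'
#' @param homologs a list of homolog entries; each entry is a list with
#'   `maps` (named list of 9 thresholded maps), `nucleus` and `homolog`
#'   identifiers.
#' @return a data frame with columns `nucleus, homolog, segment,
#'   ds_1..ds_<k-1>, es_1..es_<k-1>, area, volume, sphericity`.
#' @export
feature_table <- function(homologs) {
  rows <- lapply(homologs, function(h) {
    ps <- pairwise_scores(h$maps)
    k <- length(h$maps)
    nm <- rownames(ps$ds)
    do.call(rbind, lapply(seq_len(k), function(i) {
      vol <- body_volume(h$maps[[i]])
      area <- surface_area(h$maps[[i]])
      row <- data.frame(nucleus = h$nucleus, homolog = h$homolog,
                        segment = nm[i])
      ds <- ps$ds[i, -i]; es <- ps$es[i, -i]
      for (t in seq_len(k - 1)) row[[paste0("ds_", t)]] <- ds[[t]]
      for (t in seq_len(k - 1)) row[[paste0("es_", t)]] <- es[[t]]
      row$area <- area
      row$volume <- vol
      row$sphericity <- sphericity(vol, area)
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size-corrected z-score columns for a feature table
#'
#' DS entries are corrected for the genomic separation between segment
#' midpoints, ES entries likewise; area, volume and sphericity are
#' corrected for segment genomic length. Each correction is a pooled
#' power-law fit over the whole table ([size_corrected_zscore()]).
#'
#' @param features output of [feature_table()].
#' @param segments segment BED data frame (`chrom, start, end, name`) in
#'   segment order; `name` must match `features$segment`.
#' @return `features` with `_z` columns appended.
#' @export
zscore_features <- function(features, segments) {
  k <- nrow(segments)
  mid <- (segments$start + segments$end) / 2
  len <- segments$end - segments$start
  names(mid) <- names(len) <- segments$name
  seg_i <- match(features$segment, segments$name)
  if (any(is.na(seg_i))) stop_ct("feature segments not found in BED")

  # per row, the genomic separation to each "other" segment, in table order
  sep <- t(vapply(seg_i, function(i) abs(mid[-i] - mid[i]),
                  numeric(k - 1)))
  ds_cols <- paste0("ds_", seq_len(k - 1))
  es_cols <- paste0("es_", seq_len(k - 1))
  ds_z <- size_corrected_zscore(unlist(features[ds_cols], use.names = FALSE),
                                as.numeric(sep))
  es_z <- size_corrected_zscore(unlist(features[es_cols], use.names = FALSE),
                                as.numeric(sep))
  n <- nrow(features)
  for (t in seq_len(k - 1)) {
    features[[paste0("ds_", t, "_z")]] <- ds_z[(t - 1) * n + seq_len(n)]
    features[[paste0("es_", t, "_z")]] <- es_z[(t - 1) * n + seq_len(n)]
  }
  sz <- len[seg_i]
  features$area_z <- size_corrected_zscore(features$area, sz)
  features$volume_z <- size_corrected_zscore(features$volume, sz)
  features$sphericity_z <- size_corrected_zscore(features$sphericity, sz)
  features
}

# Deterministic k-means++ style initial centres.
kmeanspp_centers <- function(X, k, seed) {
  with_seed(seed, {
    n <- nrow(X)
    centers <- X[sample.int(n, 1), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(X, 1, function(p)
        min(colSums((t(centers) - p)^2)))
      p <- d2 / sum(d2)
      centers <- rbind(centers, X[sample.int(n, 1, prob = p), , drop = FALSE])
    }
    centers
  })
}

#' PCA classification of segment features into two compartment clusters
#'
#' Column-standardizes the feature matrix (constant columns are dropped
#' with a warning), runs PCA, and partitions the segments by 2-means on the
#' first two principal-component scores with deterministic k-means++
#' initialization. Cluster 1 is relabelled as the group with the larger
#' mean volume (the active-like, larger/less-spherical cluster).
#'
#' @param features numeric matrix or data frame of feature columns (one row
#'   per imaged segment; typically the 19 `_z` columns: 8 DS-z, 8 ES-z,
#'   area-z, volume-z, sphericity-z).
#' @param volume raw volumes used for the cluster-1 relabelling; defaults
#'   to the `volume_z` / `volume` column of `features` when present.
#' @param seed seed for the k-means initialization (default 1).
#' @return a list with `scores` (PC score matrix), `explained_variance`
#'   (proportions), `labels` (1/2 per row) and `pca` (the `prcomp` fit).
#' @export
pca_classify <- function(features, volume = NULL, seed = 1) {
  X <- as.matrix(as.data.frame(features))
  if (!is.numeric(X)) stop_ct("features must be numeric")
  if (anyNA(X)) stop_ct("features contain missing values")
  if (is.null(volume)) {
    vc <- intersect(c("volume_z", "volume"), colnames(X))
    volume <- if (length(vc)) X[, vc[1]] else NULL
  }
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  S <- pca$x[, 1:min(2, ncol(pca$x)), drop = FALSE]
  centers <- kmeanspp_centers(S, 2, seed)
  km <- kmeans(S, centers = centers, iter.max = 100, algorithm = "Lloyd")
  labels <- km$cluster
  if (!is.null(volume)) {
    mv <- tapply(volume, labels, mean)
    if (length(mv) == 2L && mv[["2"]] > mv[["1"]])
      labels <- 3L - labels
  }
  list(scores = pca$x, explained_variance = expl, labels = labels, pca = pca)
}

#' Compartment-state profile of a nucleus
#'
#' Element-wise comparison of the two homologs' cluster labels per segment
#' position: 1 when both segments are in cluster 1, -1 when both are in
#' cluster 2, 0 when they differ.
#'
#' @param labelsH1,labelsH2 integer vectors of length 9 with values in
#'   `{1, 2}`.
#' @return integer vector of length 9 with values in `{1, 0, -1}`.
#' @export
compartment_profile <- function(labelsH1, labelsH2) {
  if (length(labelsH1) != 9L || length(labelsH2) != 9L)
    stop_ct("label vectors must have length 9")
  if (!all(c(labelsH1, labelsH2) %in% 1:2))
    stop_ct("labels must be 1 or 2")
  ifelse(labelsH1 == 1L & labelsH2 == 1L, 1L,
         ifelse(labelsH1 == 2L & labelsH2 == 2L, -1L, 0L))
}

#' Hierarchical clustering of profile or score matrices
#'
#' Average-linkage clustering on Euclidean row distances; convenience
#' wrapper used for compartment-state profiles and for the 9 x 9 mean DS /
#' ES matrices.
#'
#' @param m numeric matrix (rows are clustered).
#' @param k number of groups to cut (optional).
#' @return the `hclust` tree, or (when `k` given) a list with `tree` and
#'   `groups`.
#' @export
profile_cluster <- function(m, k = NULL) {
  tree <- hclust(dist(m, method = "euclidean"), method = "average")
  if (is.null(k)) return(tree)
  list(tree = tree, groups = cutree(tree, k = k))
}
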