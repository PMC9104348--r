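#' Construct an MSI dataset
#'
#' In-memory model of a mass spectrometry imaging dataset: integer pixel
#' coordinates with one centroid spectrum (ascending m/z, non-negative
#' intensity) per pixel.
#'
#' @param coords data.frame with integer columns `x`, `y` (unique pairs).
#' @param mz list of numeric vectors, strictly ascending m/z per pixel.
#' @param intensity list of numeric vectors matching `mz` in length.
#' @param mz_range overall m/z interval (default c(150, 1200)).
#' @param polarity "+" or "-" (default "-", the lipid discovery mode).
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensity, mz_range = c(150, 1200),
                        polarity = "-") {
  if (nrow(coords) == 0) stop("empty pixel list")
  if (anyDuplicated(coords[, c("x", "y")])) stop("pixel coordinates must be unique")
  if (length(mz) != nrow(coords) || length(intensity) != nrow(coords)) {
    stop("mz/intensity lists must match the pixel count")
  }
  for (i in seq_along(mz)) {
    if (length(mz[[i]]) != length(intensity[[i]])) {
      stop("mz/intensity length mismatch at pixel ", i)
    }
    if (is.unsorted(mz[[i]], strictly = TRUE)) {
      stop("m/z must be strictly ascending at pixel ", i)
    }
    if (any(intensity[[i]] < 0)) stop("negative intensity at pixel ", i)
  }
  structure(list(coords = coords, mz = mz, intensity = intensity,
                 mz_range = mz_range, polarity = polarity),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels, m/z [%g, %g], polarity %s\n",
              nrow(x$coords), x$mz_range[1], x$mz_range[2], x$polarity))
  invisible(x)
}

#' Total-ion-current normalisation
#'
#' Divides each pixel's intensities by that pixel's summed intensity, so
#' every pixel's spectrum sums to 1 and between-pixel comparisons are
#' insensitive to per-pixel signal yield. Pixels with zero total intensity
#' cannot be normalised; they are excluded and reported.
#'
#' @param dataset an [msi_dataset()].
#' @return list with `dataset` (normalised) and `excluded` (row indices of
#'   zero-TIC pixels removed).
#' @export
tic_normalize <- function(dataset) {
  tic <- vapply(dataset$intensity, sum, numeric(1))
  excluded <- which(tic == 0)
  keep <- which(tic > 0)
  out <- msi_dataset(
    dataset$coords[keep, , drop = FALSE],
    dataset$mz[keep],
    lapply(keep, function(i) dataset$intensity[[i]] / tic[i]),
    mz_range = dataset$mz_range, polarity = dataset$polarity
  )
  list(dataset = out, excluded = excluded)
}

#' Extract an ion image
#'
#' Per pixel, sums the intensities of all centroids whose m/z lies within
#' `target_mz +- window_da` (an absolute Da window). Pixels with no peak in
#' the window get 0.
#'
#' @param dataset an [msi_dataset()].
#' @param target_mz centre of the extraction window (Da).
#' @param window_da half-width of the window (default 0.001 Da).
#' @return data.frame `x`, `y`, `intensity`.
#' @export
ion_image <- function(dataset, target_mz, window_da = 0.001) {
  if (window_da <= 0) stop("window_da must be positive")
  v <- vapply(seq_along(dataset$mz), function(i) {
    mz <- dataset$mz[[i]]
    inside <- mz >= target_mz - window_da & mz <= target_mz + window_da
    sum(dataset$intensity[[i]][inside])
  }, numeric(1))
  data.frame(x = dataset$coords$x, y = dataset$coords$y, intensity = v)
}

#' Build a pixels x features matrix from reference m/z values
#'
#' Each column is the ion image of one reference m/z at tolerance `tol_da`,
#' flattened over pixels — the binned representation that spatial
#' segmentation clusters.
#'
#' @param dataset an [msi_dataset()].
#' @param reference_mzs numeric vector of reference m/z values (non-empty).
#' @param tol_da extraction half-window (Da).
#' @return numeric matrix pixels x references, with all-zero columns
#'   flagged in attribute `"empty_columns"`.
#' @export
build_pixel_matrix <- function(dataset, reference_mzs, tol_da = 0.001) {
  if (length(reference_mzs) == 0) stop("reference m/z list is empty")
  cols <- vapply(reference_mzs, function(mz) {
    ion_image(dataset, mz, tol_da)$intensity
  }, numeric(nrow(dataset$coords)))
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = nrow(dataset$coords))
  colnames(cols) <- sprintf("mz_%.4f", reference_mzs)
  attr(cols, "empty_columns") <- unname(which(colSums(cols) == 0))
  cols
}

# squared distances of rows to a center
row_sq_dist <- function(m, center) {
  rowSums(sweep(m, 2, center)^2)
}

#' Bisecting k-means spatial segmentation
#'
#' Divisive clustering of pixel spectra: starting from a single cluster of
#' all pixels, the cluster with the largest within-cluster sum of squares is
#' repeatedly split by 2-means until `k` clusters exist. Rows are TIC
#' (sum-to-one) normalised and, for the default cosine metric, L2-normalised
#' before each split, making the 2-means objective equivalent to cosine
#' dissimilarity; `metric = "euclidean"` skips the L2 step. Each split keeps
#' the best of `n_restarts` seeded starts. The split tree (which cluster was
#' bisected, with SSE before/after) is recorded.
#'
#' @param pixel_matrix pixels x features matrix (e.g. from
#'   [build_pixel_matrix()]).
#' @param k number of clusters (1 <= k <= pixels).
#' @param n_restarts 2-means restarts per split (default 10).
#' @param seed RNG seed (splits are deterministic given it).
#' @param metric "cosine" (default) or "euclidean".
#' @return list with `cluster` (id per pixel, 0-based contiguous),
#'   `split_tree` (data.frame: step, cluster split, SSE before/after), `k`.
#' @export
bisecting_kmeans_segment <- function(pixel_matrix, k, n_restarts = 10,
                                     seed = 1, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  m <- as.matrix(pixel_matrix)
  n <- nrow(m)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds number of pixels")
  rs <- rowSums(m)
  mn <- m / ifelse(rs > 0, rs, 1)  # TIC normalisation of rows
  if (metric == "cosine") {
    l2 <- sqrt(rowSums(mn^2))
    mn <- mn / ifelse(l2 > 0, l2, 1)
  }
  cluster <- rep(1L, n)
  sse_of <- function(idx) {
    if (length(idx) < 2) return(0)
    sub <- mn[idx, , drop = FALSE]
    sum(row_sq_dist(sub, colMeans(sub)))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  tree <- data.frame(step = integer(0), split_cluster = integer(0),
                     sse_before = numeric(0), sse_after = numeric(0))
  n_clusters <- 1L
  while (n_clusters < k) {
    sses <- vapply(seq_len(n_clusters), function(c) sse_of(which(cluster == c)),
                   numeric(1))
    splittable <- which(vapply(seq_len(n_clusters), function(c) {
      idx <- which(cluster == c)
      length(idx) >= 2 && nrow(unique(mn[idx, , drop = FALSE])) >= 2
    }, logical(1)))
    if (length(splittable) == 0) {
      stop("cannot reach k clusters: no cluster with >= 2 distinct spectra left")
    }
    target <- splittable[which.max(sses[splittable])]
    idx <- which(cluster == target)
    km <- stats::kmeans(mn[idx, , drop = FALSE], centers = 2,
                        nstart = n_restarts)
    n_clusters <- n_clusters + 1L
    cluster[idx[km$cluster == 2]] <- n_clusters
    tree <- rbind(tree, data.frame(
      step = n_clusters - 1L, split_cluster = target,
      sse_before = sses[target], sse_after = sum(km$withinss)
    ))
  }
  list(cluster = cluster - 1L, split_tree = tree, k = k)
}

#' Region-versus-region log2 fold changes
#'
#' Per feature of a pixel matrix, `log2(mean intensity in region_a / mean
#' intensity in region_b)` over the pixels carrying each label. Features
#' with a zero denominator mean are flagged with `NA`.
#'
#' @param pixel_matrix pixels x features matrix.
#' @param labels region label per pixel.
#' @param region_a,region_b labels to compare (a over b).
#' @return Named numeric vector of per-feature log2 fold changes.
#' @export
region_log2fc <- function(pixel_matrix, labels, region_a, region_b) {
  ia <- which(labels == region_a)
  ib <- which(labels == region_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty region")
  ma <- colMeans(pixel_matrix[ia, , drop = FALSE])
  mb <- colMeans(pixel_matrix[ib, , drop = FALSE])
  out <- ifelse(mb > 0, log2(ma / mb), NA_real_)
  names(out) <- colnames(pixel_matrix)
  out
}
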