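# local RNG scope: run code with a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

field_matrix <- function(x) {
  if (inherits(x, "transparency_field")) {
    d <- dim(x$values)
    list(X = matrix(x$values, d[1] * d[2], d[3]),
         valid = as.vector(x$valid), dims = d[1:2])
  } else if (inherits(x, "channel_image")) {
    d <- dim(x$values)
    list(X = matrix(normalized_intensities(x), d[1] * d[2], d[3]),
         valid = as.vector(!x$saturated), dims = d[1:2])
  } else {
    X <- as.matrix(x)
    list(X = X, valid = rep(TRUE, nrow(X)), dims = NULL)
  }
}

#' Spherical (cosine) k-means clustering of spectra
#'
#' k-means under the cosine metric: vectors are L2-normalized, assignment is
#' by maximal cosine similarity to the centroids, and each centroid is the
#' normalized mean of its members.  Initialization is k-means++ (adapted to
#' cosine distance); `restarts` independent runs are performed and the best
#' objective kept.  The cosine metric is the natural choice for spectra: it
#' compares shapes and ignores overall magnitude (e.g. sample thickness).
#'
#' @param x a [transparency_field()], [channel_image()], or numeric matrix
#'   of row vectors.
#' @param k number of clusters (>= 1).
#' @param seed integer seed (clustering is deterministic given the seed).
#' @param restarts independent restarts; the run with the lowest total
#'   within-cluster cosine distance wins.
#' @param max_iter Lloyd iteration cap per run.
#' @return An object of class `cluster_result`: list with `labels`
#'   (vector, `NA` for zero-norm or invalid pixels; also as a matrix
#'   `label_map` when the input carries image geometry), `centroids`
#'   (`k x w`, unit rows), `objective`, `sizes`, `k`, `metric`, `seed`.
#' @export
cluster_spectra <- function(x, k, seed = 1L, restarts = 5L, max_iter = 100L) {
  fm <- field_matrix(x)
  X <- fm$X
  norms <- sqrt(rowSums(X^2))
  usable <- fm$valid & norms > 0
  if (sum(usable) < k) stop("fewer usable vectors than clusters")
  U <- X[usable, , drop = FALSE] / norms[usable]
  best <- NULL
  for (r in seq_len(restarts)) {
    run <- with_seed(seed + r - 1L, skmeans_once(U, k, max_iter))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  labels <- rep(NA_integer_, nrow(X))
  labels[usable] <- best$labels
  out <- list(labels = labels, centroids = best$centroids,
              objective = best$objective,
              sizes = tabulate(best$labels, k), k = k,
              metric = "cosine", seed = seed)
  if (!is.null(fm$dims)) out$label_map <- matrix(labels, fm$dims[1], fm$dims[2])
  structure(out, class = "cluster_result")
}

skmeans_once <- function(U, k, max_iter) {
  n <- nrow(U)
  if (k == 1) {
    ctr <- colMeans(U)
    ctr <- ctr / max(sqrt(sum(ctr^2)), 1e-300)
    sim <- drop(U %*% ctr)
    return(list(labels = rep(1L, n), centroids = matrix(ctr, 1),
                objective = sum(1 - sim)))
  }
  # k-means++ seeding with cosine distance
  centers <- matrix(0, k, ncol(U))
  centers[1, ] <- U[sample.int(n, 1), ]
  d2 <- pmax(1 - drop(U %*% centers[1, ]), 0)
  for (j in 2:k) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- U[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, pmax(1 - drop(U %*% centers[j, ]), 0))
  }
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    sims <- U %*% t(centers)
    new_labels <- max.col(sims, ties.method = "first")
    for (j in seq_len(k)) {
      members <- new_labels == j
      if (!any(members)) { # re-seed an empty cluster at the worst-fit point
        worst <- which.min(sims[cbind(seq_len(n), new_labels)])
        new_labels[worst] <- j
        members <- new_labels == j
      }
      ctr <- colMeans(U[members, , drop = FALSE])
      nrm <- sqrt(sum(ctr^2))
      centers[j, ] <- if (nrm > 0) ctr / nrm else U[which(members)[1], ]
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  obj <- sum(1 - (U %*% t(centers))[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = centers, objective = obj)
}

cosine_within_dispersion <- function(U, labels, k) {
  # sum over clusters of (1/(2 n_r)) * sum of pairwise cosine distances;
  # pairwise sums reduce to n_r^2 - ||sum of unit vectors||^2
  W <- 0
  for (j in seq_len(k)) {
    members <- which(labels == j)
    nr <- length(members)
    if (nr == 0) next
    s <- colSums(U[members, , drop = FALSE])
    W <- W + (nr^2 - sum(s^2)) / (2 * nr)
  }
  W
}

#' Gap statistic for the cluster count
#'
#' Compares the log within-cluster dispersion of the data, under the cosine
#' metric, against its expectation under `B` reference datasets drawn
#' uniformly over the feature-wise bounding box of the data:
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)`, with standard error
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`.  The first local maximum (the
#' smallest `k` with `Gap(k) >= Gap(k+1) - s_{k+1}`) estimates the cluster
#' count.
#'
#' @inheritParams cluster_spectra
#' @param k_range integer vector of candidate cluster counts.
#' @param B number of reference datasets.
#' @return An object of class `gap_curve`: data frame with columns `k`,
#'   `gap`, `se`, `logW`, `logW_ref`, plus attributes `B`, `seed`, and
#'   `k_hat` (first-max rule).
#' @export
gap_statistic <- function(x, k_range = 1:10, B = 20L, seed = 1L,
                          restarts = 3L) {
  fm <- field_matrix(x)
  X <- fm$X
  norms <- sqrt(rowSums(X^2))
  usable <- fm$valid & norms > 0
  Xu <- X[usable, , drop = FALSE]
  n <- nrow(Xu)
  lo <- apply(Xu, 2, min); hi <- apply(Xu, 2, max)
  logW <- numeric(length(k_range))
  logWref <- matrix(0, B, length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    cl <- cluster_spectra(Xu, k, seed = seed, restarts = restarts)
    U <- Xu / pmax(sqrt(rowSums(Xu^2)), 1e-300)
    logW[ki] <- log(max(cosine_within_dispersion(U, cl$labels, k), 1e-300))
  }
  for (b in seq_len(B)) {
    ref <- with_seed(seed * 1000L + b, {
      matrix(runif(n * ncol(Xu), rep(lo, each = n), rep(hi, each = n)),
             n, ncol(Xu))
    })
    rn <- sqrt(rowSums(ref^2))
    ok <- rn > 0
    refU <- ref[ok, , drop = FALSE] / rn[ok]
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      cl <- cluster_spectra(ref[ok, , drop = FALSE], k,
                            seed = seed + 7L * b, restarts = restarts)
      logWref[b, ki] <-
        log(max(cosine_within_dispersion(refU, cl$labels, k), 1e-300))
    }
  }
  gap <- colMeans(logWref) - logW
  se <- apply(logWref, 2, sd) * sqrt(1 + 1 / B)
  out <- data.frame(k = k_range, gap = gap, se = se, logW = logW,
                    logW_ref = colMeans(logWref))
  k_hat <- NA_integer_
  for (ki in seq_along(k_range)[-length(k_range)]) {
    if (gap[ki] >= gap[ki + 1] - se[ki + 1]) { k_hat <- k_range[ki]; break }
  }
  structure(out, B = B, seed = seed, k_hat = k_hat,
            class = c("gap_curve", "data.frame"))
}

#' Per-class mean spectra
#'
#' Arithmetic mean of the member spectra of every cluster, on the working
#' grid.  Empty classes are omitted (with a warning).
#'
#' @param result a [cluster_spectra()] result.
#' @param cube the [transparency_field()] (or matrix) that was clustered.
#' @return Named list of [spectrum()] objects (or plain numeric vectors for
#'   matrix input), one per non-empty class.
#' @export
class_mean_spectra <- function(result, cube) {
  fm <- field_matrix(cube)
  grid <- if (inherits(cube, "transparency_field")) cube$grid else NULL
  out <- list()
  for (j in seq_len(result$k)) {
    members <- which(!is.na(result$labels) & result$labels == j)
    if (length(members) == 0) {
      warning("class ", j, " is empty and was omitted")
      next
    }
    mv <- colMeans(fm$X[members, , drop = FALSE])
    out[[paste0("class_", j)]] <- if (is.null(grid)) mv else spectrum(grid, mv)
  }
  out
}

#' Digital staining by dimensionality reduction
#'
#' Projects the per-pixel spectra onto a few components (PCA, factor
#' analysis, or non-negative matrix factorization), min-max scales each
#' component to `[0, 1]`, and maps the components to display channels --
#' a false-colour image that highlights spectrally distinct structures.
#'
#' @param cube a [transparency_field()].
#' @param method `"pca"`, `"factor_analysis"`, or `"nmf"`.
#' @param n_components number of components (display channels), default 3.
#' @param seed seed for the NMF initialization.
#' @return List with `rgb` (`h x w x n_components` array in `[0, 1]`) and
#'   `scores` (pixel x component matrix).
#' @export
digital_stain <- function(cube, method = c("pca", "factor_analysis", "nmf"),
                          n_components = 3, seed = 1L) {
  method <- match.arg(method)
  fm <- field_matrix(cube)
  X <- fm$X
  if (any(X < 0) && method == "nmf") stop("NMF requires non-negative data")
  scores <- switch(method,
    pca = {
      p <- prcomp(X, center = TRUE, scale. = FALSE)
      p$x[, seq_len(min(n_components, ncol(p$x))), drop = FALSE]
    },
    factor_analysis = {
      fa <- factanal(X, factors = n_components, scores = "regression")
      fa$scores
    },
    nmf = nmf_scores(X, n_components, seed))
  nc <- ncol(scores)
  for (j in seq_len(nc)) {
    rng <- range(scores[, j])
    scores[, j] <- (scores[, j] - rng[1]) / max(rng[2] - rng[1], 1e-300)
  }
  d <- fm$dims
  rgb <- if (!is.null(d)) array(scores, c(d[1], d[2], nc)) else NULL
  list(rgb = rgb, scores = scores, method = method)
}

# plain multiplicative-update NMF (Lee & Seung), seeded, for staining only
nmf_scores <- function(X, k, seed, n_iter = 200) {
  with_seed(seed, {
    n <- nrow(X); p <- ncol(X)
    W <- matrix(runif(n * k, 0.1, 1), n, k)
    H <- matrix(runif(k * p, 0.1, 1), k, p)
    eps <- 1e-12
    for (it in seq_len(n_iter)) {
      H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
      W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
    }
    W
  })
}
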