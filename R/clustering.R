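# Clustering of modelled trajectories (fitted curves or their
# derivatives), with the Dunn index as the single criterion to pick both
# the algorithm and the number of clusters.

#' Dunn index of a clustering
#'
#' Ratio of the smallest inter-cluster distance to the largest
#' intra-cluster distance; larger values indicate better-separated,
#' tighter clusters. An all-singleton clustering (zero maximal
#' intra-cluster distance) returns `Inf` by convention.
#'
#' @param distances symmetric distance matrix (or a `dist`), zero
#'   diagonal, non-negative.
#' @param assignments cluster label per object.
#' @return non-negative real (possibly `Inf`).
#' @export
dunn_index <- function(distances, assignments) {
  D <- as.matrix(distances)
  cl <- as.character(assignments)
  lv <- unique(cl)
  if (length(lv) < 2) stop("need at least 2 non-empty clusters")
  idx <- lapply(lv, function(l) which(cl == l))
  max_intra <- max(vapply(idx, function(i)
    if (length(i) < 2) 0 else max(D[i, i]), numeric(1)))
  min_inter <- min(vapply(seq_along(lv)[-1], function(a)
    min(vapply(seq_len(a - 1), function(b)
      min(D[idx[[a]], idx[[b]]]), numeric(1))), numeric(1)))
  if (max_intra == 0) return(Inf)
  min_inter / max_intra
}

# distance between curve rows
curve_dist <- function(curves, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") stats::dist(curves)
  else stats::as.dist(1 - stats::cor(t(curves)))
}

# Minimal 1-D self-organizing map: k nodes on a line, sequential training
# with shrinking neighbourhood and learning rate. Nodes map to clusters.
som_1d <- function(x, k, epochs = 100, alpha0 = 0.05) {
  n <- nrow(x)
  nodes <- x[sample.int(n, k), , drop = FALSE]
  radius0 <- max(k / 2, 1)
  step <- 0
  total <- epochs * n
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      step <- step + 1
      frac <- step / total
      alpha <- alpha0 * (1 - frac)
      radius <- radius0 * (1 - frac)
      d2 <- rowSums(sweep(nodes, 2, x[i, ])^2)
      win <- which.min(d2)
      infl <- exp(-((seq_len(k) - win)^2) / (2 * max(radius, 0.5)^2))
      nodes <- nodes + (alpha * infl) *
        matrix(rep(x[i, ], each = k), k) - (alpha * infl) * nodes
    }
  }
  assign <- apply(x, 1, function(r)
    which.min(rowSums(sweep(nodes, 2, r)^2)))
  assign
}

#' Cluster modelled trajectories
#'
#' @param curves molecules x grid numeric matrix (no missing values;
#'   modelled curves are complete by construction).
#' @param algorithm one of `"hierarchical"` (complete linkage),
#'   `"kmeans"`, `"pam"`, `"som"` (1-dimensional map with k nodes),
#'   `"model_based"` (Gaussian mixture via \pkg{mclust}).
#' @param k number of clusters, between 2 and the number of molecules.
#' @param metric distance for the distance-based algorithms:
#'   `"euclidean"` (default) or `"correlation"`.
#' @param seed seed for the stochastic algorithms (kmeans and SOM use the
#'   best of `nstart` restarts).
#' @param nstart restarts for kmeans/SOM.
#' @param scale z-scale each curve before clustering.
#' @return integer cluster assignment per molecule (named by rownames).
#' @export
cluster_profiles <- function(curves,
                             algorithm = c("hierarchical", "kmeans", "pam",
                                           "som", "model_based"),
                             k, metric = "euclidean", seed = 1L,
                             nstart = 10, scale = FALSE) {
  algorithm <- match.arg(algorithm)
  if (k > nrow(curves)) stop("k exceeds the number of molecules")
  if (scale) curves <- t(scale(t(curves)))
  cl <- withr_seed(seed, switch(algorithm,
    hierarchical = stats::cutree(
      stats::hclust(curve_dist(curves, metric), method = "complete"), k),
    kmeans = stats::kmeans(curves, centers = k, nstart = nstart,
                           iter.max = 50)$cluster,
    pam = cluster::pam(curve_dist(curves, metric), k = k,
                       cluster.only = TRUE),
    som = {
      best <- NULL; best_ss <- Inf
      for (r in seq_len(nstart)) {
        a <- som_1d(curves, k)
        ss <- sum(vapply(unique(a), function(l) {
          rows <- curves[a == l, , drop = FALSE]
          sum(sweep(rows, 2, colMeans(rows))^2)
        }, numeric(1)))
        if (ss < best_ss) { best_ss <- ss; best <- a }
      }
      best
    },
    model_based = {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(curves, G = k, verbose = FALSE)),
        error = function(e) NULL)
      # near-singular covariances (e.g. almost-duplicate curves): retry
      # with spherical equal-volume components
      if (is.null(fit)) fit <- tryCatch(
        suppressWarnings(mclust::Mclust(curves, G = k,
                                        modelNames = "EII",
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) stop("model-based clustering failed for k = ", k)
      fit$classification
    }))
  cl <- as.integer(factor(cl))
  names(cl) <- rownames(curves)
  cl
}

#' Select clustering algorithm and cluster count by the Dunn index
#'
#' Evaluates every combination of algorithm and `k` and returns the one
#' maximizing the Dunn index (ties broken towards smaller `k`, then the
#' order algorithms are listed). Degenerate all-singleton solutions (Dunn
#' `Inf`) are excluded from the argmax unless `allow_singletons`.
#'
#' @param curves molecules x grid matrix.
#' @param algorithms character vector of algorithms (see
#'   [cluster_profiles()]).
#' @param k_range candidate cluster counts (default 2 to 9).
#' @param metric,seed,scale passed to [cluster_profiles()].
#' @param allow_singletons keep `Inf` Dunn solutions in the argmax.
#' @return list with `best` (list: algorithm, k, assignments, dunn) and
#'   `grid` (data.frame of all evaluated combinations with their Dunn
#'   index; failed evaluations carry `NA`).
#' @export
select_clustering <- function(curves,
                              algorithms = c("hierarchical", "kmeans",
                                             "pam", "som", "model_based"),
                              k_range = 2:9, metric = "euclidean",
                              seed = 1L, scale = FALSE,
                              allow_singletons = FALSE) {
  D <- curve_dist(curves, metric)
  grid <- expand.grid(k = k_range, algorithm = algorithms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("algorithm", "k")]
  grid$dunn <- NA_real_
  assigns <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- tryCatch(
      cluster_profiles(curves, grid$algorithm[i], grid$k[i],
                       metric = metric, seed = seed, scale = scale),
      error = function(e) NULL)
    if (is.null(a) || length(unique(a)) < 2) next
    assigns[[i]] <- a
    grid$dunn[i] <- dunn_index(D, a)
  }
  cand <- which(!is.na(grid$dunn) &
                  (allow_singletons | is.finite(grid$dunn)))
  if (!length(cand)) stop("every clustering evaluation failed")
  # ties: larger dunn, then smaller k, then listed algorithm order
  ord <- cand[order(-grid$dunn[cand], grid$k[cand],
                    match(grid$algorithm[cand], algorithms))]
  best_i <- ord[1]
  list(best = list(algorithm = grid$algorithm[best_i], k = grid$k[best_i],
                   assignments = assigns[[best_i]],
                   dunn = grid$dunn[best_i]),
       grid = grid)
}

#' Hypergeometric set enrichment of clusters
#'
#' For each (cluster, annotation term) pair tests over-representation of
#' the term's molecules in the cluster with the hypergeometric upper tail
#' `P(X >= x)`, where `x` is the overlap, out of a universe of `N`
#' molecules with `K` annotated and a cluster of size `n`. The log odds
#' ratio comes from the 2x2 table (0.5 added to every cell when any cell
#' is zero). Benjamini-Hochberg adjustment is applied across terms within
#' each cluster. Terms with at most one annotated molecule in a cluster
#' are dropped.
#'
#' @param assignments named cluster labels (molecule -> cluster).
#' @param annotation named list: term -> character vector of molecule ids.
#' @param universe molecule universe; defaults to the assigned molecules.
#' @return data.frame: `cluster`, `term`, `overlap`, `cluster_size`,
#'   `term_size`, `universe_size`, `p`, `adj_p`, `log_odds`.
#' @export
cluster_enrichment <- function(assignments, annotation,
                               universe = names(assignments)) {
  if (length(universe) == 0) stop("empty universe")
  annotation <- lapply(annotation, intersect, universe)
  N <- length(universe)
  out <- NULL
  for (cl in unique(assignments)) {
    members <- names(assignments)[assignments == cl]
    n <- length(members)
    rows <- lapply(names(annotation), function(tm) {
      ann <- annotation[[tm]]
      K <- length(ann)
      x <- length(intersect(members, ann))
      if (x <= 1) return(NULL)
      p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      tab <- c(x, K - x, n - x, N - K - n + x)
      if (any(tab == 0)) tab <- tab + 0.5
      lor <- log(tab[1] * tab[4] / (tab[2] * tab[3]))
      data.frame(cluster = cl, term = tm, overlap = x, cluster_size = n,
                 term_size = K, universe_size = N, p = p,
                 log_odds = lor, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    if (!is.null(block)) {
      block$adj_p <- adjust_bh(block$p)
      out <- rbind(out, block)
    }
  }
  if (is.null(out))
    out <- data.frame(cluster = character(), term = character(),
                      overlap = integer(), cluster_size = integer(),
                      term_size = integer(), universe_size = integer(),
                      p = numeric(), log_odds = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE)
  out[, c("cluster", "term", "overlap", "cluster_size", "term_size",
          "universe_size", "p", "adj_p", "log_odds")]
}
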