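#' Two-dimensional fuzzy-neighbor embedding of binary symptom profiles
#'
#' Embeds a binary feature matrix into two dimensions with the standard
#' manifold-approximation recipe: a fuzzy simplicial set is built from the
#' Euclidean k-nearest-neighbor graph (per-point bandwidths calibrated so the
#' effective neighbor count is `log2(n_neighbors)`, connectivity distance
#' equal to the nearest-neighbor distance), symmetrized by probabilistic
#' t-conorm, and the low-dimensional layout minimizes the fuzzy-set
#' cross-entropy with the rational kernel `1 / (1 + a d^(2b))` whose `a`, `b`
#' are least-squares matched to the `min_dist` target curve. Layout is
#' initialized from classical metric scaling of the input distances and
#' refined by gradient epochs with uniform negative sampling. Defaults are 15
#' neighbors, minimum distance 0.1, and 2 components.
#'
#' The result is deterministic for a fixed seed.
#'
#' @param x Numeric matrix (rows = patients, columns = the 12 binary symptom
#'   indicators). At least `n_neighbors + 1` rows are required.
#' @param n_neighbors Neighborhood size (default 15).
#' @param min_dist Minimum separation in the layout (default 0.1).
#' @param n_epochs Optimization epochs (default 200).
#' @param seed Integer seed.
#' @return Numeric matrix `n x 2` with the input rownames.
#' @export
umap_embed <- function(x, n_neighbors = 15, min_dist = 0.1, n_epochs = 200,
                       seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " rows, got ", n)
  D <- as.matrix(stats::dist(x))
  k <- n_neighbors

  # per-point fuzzy membership over the k nearest neighbors
  target <- log2(k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    ord <- order(d)[seq_len(k)]
    dk <- d[ord]
    # local connectivity: with coincident rows (frequent in a binary feature
    # space) the connectivity radius is the nearest *distinct* neighbor, so
    # low-multiplicity patterns stay firmly attached to their neighborhood
    rho <- if (any(dk > 0)) min(dk[dk > 0]) else 0
    excess <- pmax(dk - rho, 0)
    if (all(excess == 0)) {
      w <- rep(1, k)
    } else {
      lo <- 1e-6; hi <- max(excess) * 10
      for (it in 1:64) {
        mid <- (lo + hi) / 2
        s <- sum(exp(-excess / mid))
        if (s > target) hi <- mid else lo <- mid
      }
      w <- exp(-excess / ((lo + hi) / 2))
    }
    cols <- setdiff(seq_len(n), i)[ord]
    W[i, cols] <- w
  }
  P <- W + t(W) - W * t(W)

  ed <- which(upper.tri(P) & P > 1e-8, arr.ind = TRUE)
  ei <- ed[, 1]; ej <- ed[, 2]
  ew <- P[ed]

  ab <- .fit_ab(min_dist)
  a <- ab[1]; b <- ab[2]

  # connected components of the fuzzy graph; disconnected components are
  # laid out separately and placed apart, as is standard for this embedding
  comp <- .graph_components(P > 1e-8)

  with_seed(seed, {
    # classical-scaling initialization per component, jittered
    Y <- matrix(0, n, 2)
    k_comp <- max(comp)
    for (cid in seq_len(k_comp)) {
      idx <- which(comp == cid)
      if (length(idx) >= 3) {
        Yc <- suppressWarnings(stats::cmdscale(D[idx, idx, drop = FALSE],
                                               k = 2))
        if (is.null(dim(Yc)) || ncol(Yc) < 2)
          Yc <- matrix(0, length(idx), 2)
        sc <- max(abs(Yc), 1e-12)
        Yc <- Yc / sc * 2
      } else {
        Yc <- matrix(0, length(idx), 2)
      }
      center <- if (k_comp == 1) c(0, 0)
        else 8 * c(cos(2 * pi * cid / k_comp), sin(2 * pi * cid / k_comp))
      Y[idx, ] <- sweep(Yc, 2, center, "+")
    }
    Y <- Y + matrix(stats::rnorm(2 * n, 0, 1e-2), n, 2)

    for (epoch in seq_len(n_epochs)) {
      alpha <- 1 - (epoch - 1) / n_epochs
      # edges fire in proportion to their fuzzy weight, with unit gradients,
      # so weakly attached points receive correspondingly few updates
      fire <- stats::runif(length(ew)) < ew
      ai <- ei[fire]; aj <- ej[fire]
      if (length(ai)) {
        diff <- Y[ai, , drop = FALSE] - Y[aj, , drop = FALSE]
        d2 <- rowSums(diff^2)
        co <- (-2 * a * b * d2^pmax(b - 1, 0)) / (a * d2^b + 1)
        g <- clip(co, -4, 4) * diff
        upd <- rowsum(rbind(g, -g), c(ai, aj))
        ids <- as.integer(rownames(upd))
        Y[ids, ] <- Y[ids, ] + alpha * 0.2 * upd
        # five negative samples per fired edge head
        ni <- rep(ai, 5L)
        nj <- sample.int(n, length(ni), replace = TRUE)
        keep <- ni != nj
        ni <- ni[keep]; nj <- nj[keep]
        diff <- Y[ni, , drop = FALSE] - Y[nj, , drop = FALSE]
        d2 <- rowSums(diff^2)
        co <- (2 * b) / ((0.001 + d2) * (a * d2^b + 1))
        g <- clip(co, -4, 4) * diff
        upd <- rowsum(g, ni)
        ids <- as.integer(rownames(upd))
        Y[ids, ] <- Y[ids, ] + alpha * 0.2 * upd
      }
    }
    rownames(Y) <- rownames(x)
    colnames(Y) <- c("dim1", "dim2")
    Y
  })
}

# least-squares fit of 1/(1 + a x^(2b)) to the min_dist target curve
# (1 for x <= min_dist, exp(-(x - min_dist)) beyond), over x in (0, 3]
.fit_ab <- function(min_dist, spread = 1) {
  xs <- seq(0.05, 3, by = 0.05)
  ys <- ifelse(xs <= min_dist, 1, exp(-(xs - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * xs^(2 * b)) - ys)^2)
  }
  p <- stats::optim(c(log(1.5), log(1)), obj)$par
  exp(p)
}

# connected-component labels of an undirected adjacency matrix (BFS)
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Density-based cluster detection on a 2-D embedding
#'
#' Density-peak clustering over the embedding. Each point's local density is
#' the number of points within radius `3 h`, where the bandwidth `h` is the
#' median of the `min_cluster_size`-th nearest-neighbor distances; its
#' separation is the distance to the nearest point of higher density.
#' Cluster centers are the points with density at least `min_cluster_size`
#' and separation greater than both `3 h` and 5% of the embedding diameter
#' -- high-density modes far from any denser point -- and every remaining point joins the cluster of its
#' nearest higher-density neighbor, in decreasing density order. The
#' single-scale rule is robust to the mixed densities a discrete feature
#' space produces (tight stacks of duplicated symptom profiles surrounded by
#' sparse satellite patterns): sparse satellites can never found a cluster
#' and instead drain into their parent mode. Low-density points (fewer than
#' a third of `min_cluster_size` neighbors) are flagged as noise but still
#' carry their basin's label for downstream supervision.
#'
#' @param embedding Numeric matrix `n x 2` from [umap_embed()].
#' @param min_cluster_size Minimum local density (neighbor count within the
#'   density radius) for a cluster center (default 15).
#' @param h Bandwidth; `NULL` for the automatic heuristic.
#' @return List of class `psp_clusters`: `embedding`, `labels` (integer
#'   cluster ids 1..n_clusters for every row), `noise` (logical),
#'   `n_clusters`, `h`.
#' @export
detect_clusters <- function(embedding, min_cluster_size = 15, h = NULL) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) == 0) stop("empty embedding")
  n <- nrow(embedding)
  D <- as.matrix(stats::dist(embedding))
  k <- min(min_cluster_size, n)
  if (is.null(h)) {
    dk <- apply(D, 1, function(r) sort(r)[k])  # includes self at distance 0
    h <- max(stats::median(dk), 1e-8)
  }
  rho <- rowSums(D <= 3 * h)  # ball count, self included
  ord <- order(-rho, seq_len(n))  # density rank, ties broken by index
  delta <- numeric(n)
  uphill <- integer(n)
  for (r in seq_along(ord)) {
    i <- ord[r]
    if (r == 1L) {
      delta[i] <- max(D[i, ])
      uphill[i] <- i
      next
    }
    higher <- ord[seq_len(r - 1L)]
    j <- higher[which.min(D[i, higher])]
    delta[i] <- D[i, j]
    uphill[i] <- j
  }
  # modes must be separated by at least 3 bandwidths and 5% of the
  # embedding diameter, so a diffuse stack cannot fragment into micro-modes
  sep <- max(3 * h, max(D) / 20)
  centers <- which(rho >= min_cluster_size & delta > sep)
  if (!length(centers)) centers <- ord[1]  # degenerate: a single mode
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  for (i in ord) {
    if (labels[i] == 0L) labels[i] <- labels[uphill[i]]
  }
  structure(list(embedding = embedding, labels = labels,
                 noise = rho < min_cluster_size / 3,
                 n_clusters = length(centers), h = unname(h)),
            class = "psp_clusters")
}

#' @export
print.psp_clusters <- function(x, ...) {
  cat("psp_clusters:", x$n_clusters, "cluster(s) over",
      length(x$labels), "points;", sum(x$noise), "low-density point(s)",
      sprintf("(bandwidth = %.3g)\n", x$h))
  print(table(cluster = x$labels))
  invisible(x)
}
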