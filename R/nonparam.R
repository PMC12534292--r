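#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference on k - 1
#' degrees of freedom, via [stats::kruskal.test()]. The degenerate case where
#' every value in every group is identical returns `H = 0, p = 1` with a
#' message.
#'
#' @param groups List of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return List `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) > 0))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L) {
    message("all values identical across groups; returning p = 1")
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(vals, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

# tie-corrected standardized pairwise rank statistic for one pair of groups
.sd_pair_stat <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  E <- na * (N + 1) / 2
  V <- na * nb / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric post hoc test
#'
#' For every pair of groups, the tie-corrected standardized pairwise rank-sum
#' statistic is referred to the studentized range distribution with `k`
#' groups and infinite degrees of freedom (statistic times sqrt(2)), giving
#' family-wise adjusted p values; the raw per-pair p is the two-sided normal
#' tail. When any group has fewer than `min_asymptotic` observations the
#' adjusted p values come instead from a seeded single-step max-T permutation
#' reference (all pairwise statistics recomputed under pooled-label
#' permutations), with a logged notice; `method = "permutation"` forces that
#' path.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each; the studentized-range reference is intended for >= 3 groups).
#' @param method `"asymptotic"`, `"permutation"`, or `"auto"` (default).
#' @param n_perm Permutation draws for the fallback (default 10000).
#' @param min_asymptotic Smallest group size trusted to the asymptotic
#'   reference under `"auto"` (default 5).
#' @param seed Integer seed for the permutation reference.
#' @return data.frame `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `method`.
#' @export
steel_dwass <- function(groups, method = c("auto", "asymptotic",
                                           "permutation"),
                        n_perm = 10000, min_asymptotic = 5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 2))
  k <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(k))
  pairs <- utils::combn(k, 2)
  tstat <- apply(pairs, 2, function(pq)
    .sd_pair_stat(groups[[pq[1]]], groups[[pq[2]]]))
  p_raw <- 2 * stats::pnorm(-abs(tstat))
  if (method == "auto") {
    method <- if (min(lengths(groups)) < min_asymptotic) "permutation"
              else "asymptotic"
    if (method == "permutation")
      message("small group(s); using the seeded permutation reference")
  }
  if (method == "asymptotic") {
    p_adj <- stats::ptukey(sqrt(2) * abs(tstat), nmeans = k, df = Inf,
                           lower.tail = FALSE)
  } else {
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    idx_end <- cumsum(sizes)
    idx_start <- idx_end - sizes + 1L
    p_adj <- with_seed(seed, {
      maxT <- vapply(seq_len(n_perm), function(i) {
        perm <- sample(pooled)
        max(abs(apply(pairs, 2, function(pq)
          .sd_pair_stat(perm[idx_start[pq[1]]:idx_end[pq[1]]],
                        perm[idx_start[pq[2]]:idx_end[pq[2]]]))))
      }, 0)
      vapply(abs(tstat), function(t0) mean(maxT >= t0 - 1e-12), 0)
    })
  }
  # a family-wise adjusted p can never undercut the per-pair raw p
  p_adj <- pmax(p_adj, p_raw)
  data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
             statistic = tstat, p_raw = p_raw, p_adjusted = pmin(p_adj, 1),
             method = paste0("steel_dwass_", method),
             stringsAsFactors = FALSE)
}

#' Pairwise chi-square tests with Holm correction
#'
#' For every pair of groups (rows), a chi-square test on the corresponding
#' 2 x c sub-table, without continuity correction, followed by Holm's
#' step-down family-wise adjustment across all pairs. Sub-tables with a zero
#' margin (an all-zero row or column) are excluded with a notice.
#'
#' @param counts Integer matrix of group-by-category counts with row names.
#' @return data.frame `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted`, `method`.
#' @export
#' @examples
#' m <- rbind(A = c(5, 21), B = c(5, 152))
#' pairwise_chisq_holm(m)
pairwise_chisq_holm <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2, ncol(counts) >= 2,
            all(counts >= 0), all(counts == round(counts)))
  nm <- rownames(counts) %||% paste0("g", seq_len(nrow(counts)))
  pairs <- utils::combn(nrow(counts), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    pq <- pairs[, i]
    sub <- counts[pq, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (ncol(sub) < 2 || any(rowSums(sub) == 0)) {
      message("excluding pair ", nm[pq[1]], " vs ", nm[pq[2]],
              ": zero-margin sub-table")
      return(NULL)
    }
    ct <- suppressWarnings(stats::chisq.test(sub, correct = FALSE))
    data.frame(group_a = nm[pq[1]], group_b = nm[pq[2]],
               statistic = unname(ct$statistic), p_raw = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable pairs")
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "holm")
  out$method <- "chisq_holm"
  rownames(out) <- NULL
  out
}
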