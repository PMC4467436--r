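# GSVA-style single-sample scoring: per-gene empirical-cdf transform, a
# symmetric rank statistic per sample, and a weighted Kolmogorov-Smirnov
# random walk over each gene set.

#' Per-gene empirical cdf transform
#'
#' For each gene, `z_gj = #{samples j' : x_gj' <= x_gj} / n_samples`; ties
#' share the value, so a constant gene maps to all 1 (it carries no ranking
#' information; such genes are listed in the `constant_genes` attribute).
#' Missing values map to 0, placing them below every observed value in the
#' subsequent per-sample ranking.
#'
#' @param x Numeric gene x sample matrix.
#' @return Matrix of the same shape with values in (0, 1] (0 for missing).
#' @export
ecdf_transform <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  n <- ncol(x)
  z <- t(apply(x, 1L, function(v) {
    nv <- sum(!is.na(v))
    out <- rep(0, n)
    if (nv) out[!is.na(v)] <- rank(v[!is.na(v)], ties.method = "max") / nv
    out
  }))
  dimnames(z) <- dimnames(x)
  const <- apply(x, 1L, function(v) length(unique(v[!is.na(v)])) <= 1L)
  attr(z, "constant_genes") <- rownames(x)[const]
  z
}

#' Per-sample gene ordering and symmetric rank weights
#'
#' Genes are ordered by decreasing transformed expression within the sample
#' (ties broken by input row order, which is deterministic); a gene at rank
#' `rho` in a list of `N` genes gets walk weight `|N/2 - rho|`, so genes at
#' either expression extreme weigh most and mid-ranked genes least.
#'
#' @param z Transformed matrix from [ecdf_transform()].
#' @param sample Sample id or column index.
#' @return List with `order` (row indices, best rank first), `genes`
#'   (ids in walk order) and `weights` (`|N/2 - rho|` for rho = 1..N).
#' @export
sample_rank_statistic <- function(z, sample) {
  v <- z[, sample]
  ord <- order(v, decreasing = TRUE)
  n <- length(v)
  list(order = ord, genes = rownames(z)[ord],
       weights = abs(n / 2 - seq_len(n)))
}

#' Weighted KS random-walk enrichment score
#'
#' Walking down an ordered gene list, member genes add
#' `s^tau / sum(member s^tau)` and non-members subtract `1/(N - m)`. With
#' `D+ = max(0, max deviation)` and `D- = min(0, min deviation)`, the
#' default score is the signed magnitude difference `ES = D+ + D-`, which
#' rewards sets activated concordantly in one direction; `es_mode = "max"`
#' instead returns the deviation of largest absolute magnitude.
#'
#' @param weights Nonnegative walk weights, in list order (rank 1 first).
#' @param member Logical vector, same length: is the gene at this position
#'   a set member?
#' @param tau Weight exponent (default 1, linear weighting).
#' @param es_mode `"diff"` (D+ + D-) or `"max"`.
#' @return The enrichment score.
#' @export
random_walk_es <- function(weights, member, tau = 1,
                           es_mode = c("diff", "max")) {
  es_mode <- match.arg(es_mode)
  stopifnot(length(weights) == length(member))
  m <- sum(member); n <- length(member)
  if (m < 2 || m >= n)
    stop("need 2 <= matched set size < number of genes")
  w <- weights^tau
  wm <- sum(w[member])
  step <- ifelse(member,
                 if (wm > 0) w / wm else 1 / m,
                 -1 / (n - m))
  dev <- cumsum(step)
  if (es_mode == "diff") {
    max(0, max(dev)) + min(0, min(dev))
  } else {
    dev[which.max(abs(dev))]
  }
}

#' Score every sample against every gene set (GSVA-style)
#'
#' Composes [ecdf_transform()], [sample_rank_statistic()] and
#' [random_walk_es()] per (set, sample). Sets matching fewer than 2 genes of
#' the matrix (or all of them) are skipped with a warning; set genes absent
#' from the matrix are reported via the `unmatched` attribute.
#'
#' @param x Numeric gene x sample expression matrix (log scale).
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()], or
#'   `coexpression_module` objects).
#' @param tau Weight exponent.
#' @param es_mode `"diff"` or `"max"`; see [random_walk_es()].
#' @return Numeric set x sample matrix of enrichment scores, with
#'   attributes `scoring_params` and `unmatched`.
#' @export
score_samples <- function(x, sets, tau = 1, es_mode = c("diff", "max")) {
  es_mode <- match.arg(es_mode)
  sets <- lapply(sets, function(s)
    if (inherits(s, "coexpression_module")) s$genes else s)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("'sets' must be named")
  matched <- lapply(sets, function(s) unique(s[s %in% rownames(x)]))
  unmatched <- mapply(function(s, m) setdiff(unique(s), m), sets, matched,
                      SIMPLIFY = FALSE)
  usable <- vapply(matched, function(m)
    length(m) >= 2 && length(m) < nrow(x), logical(1))
  if (!any(usable)) stop("no gene set matches >= 2 genes of the matrix")
  if (any(!usable))
    warning("skipping set(s) with < 2 matched genes: ",
            paste(names(sets)[!usable], collapse = ", "))
  matched <- matched[usable]
  z <- ecdf_transform(x)
  member_rows <- lapply(matched, function(m) rownames(x) %in% m)
  es <- matrix(NA_real_, length(matched), ncol(x),
               dimnames = list(names(matched), colnames(x)))
  for (j in seq_len(ncol(x))) {
    rk <- sample_rank_statistic(z, j)
    for (i in seq_along(matched)) {
      es[i, j] <- random_walk_es(rk$weights, member_rows[[i]][rk$order],
                                 tau = tau, es_mode = es_mode)
    }
  }
  attr(es, "scoring_params") <- list(transform = "ecdf", tau = tau,
                                     es_mode = es_mode)
  attr(es, "unmatched") <- unmatched[usable]
  es
}

#' Assign each sample to the candidate module with the greater score
#'
#' The dichotomous subtype call: label = argmax of the enrichment scores
#' over the candidate modules, with the winning margin (winner minus
#' runner-up). Exact ties go to the first candidate in the given order, with
#' a warning.
#'
#' @param scores Set x sample enrichment-score matrix from
#'   [score_samples()].
#' @param candidates Ordered character vector of module names to compare
#'   (default: all rows of `scores`).
#' @return data.frame of class `subtype_call`: one row per sample with the
#'   candidate scores, `label` and `margin`.
#' @export
classify <- function(scores, candidates = rownames(scores)) {
  missing_c <- setdiff(candidates, rownames(scores))
  if (length(missing_c))
    stop("missing score for candidate(s): ",
         paste(missing_c, collapse = ", "))
  if (length(candidates) < 2) stop("need at least 2 candidate modules")
  s <- scores[candidates, , drop = FALSE]
  if (anyNA(s)) stop("candidate scores contain missing values")
  lab <- character(ncol(s)); margin <- numeric(ncol(s)); tied <- FALSE
  for (j in seq_len(ncol(s))) {
    v <- s[, j]
    best <- which.max(v)       # first maximum in candidate order
    srt <- sort(v, decreasing = TRUE)
    if (sum(v == srt[1]) > 1) tied <- TRUE
    lab[j] <- candidates[best]
    margin[j] <- srt[1] - srt[2]
  }
  if (tied) warning("exact score tie(s) resolved to the first-listed candidate")
  out <- data.frame(sample = colnames(s), t(s), label = lab, margin = margin,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("subtype_call", "data.frame")
  out
}
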