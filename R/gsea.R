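# Preranked gene-set enrichment with a gene-set permutation null,
# normalized enrichment scores and the pooled null-ratio FDR of the
# canonical GSEA procedure.

#' Build a ranked gene list
#'
#' Sorts scores in strictly descending order with ties broken
#' deterministically by gene id, e.g. correlation coefficients of every gene
#' with a marker ready for preranked enrichment.
#'
#' @param scores Named numeric vector (names are unique gene ids); `NA`
#'   scores are dropped.
#' @param source Free-text provenance label (e.g. "Pearson r with PROM1").
#' @return Named numeric vector sorted descending, class `ranked_list`,
#'   with a `source` attribute.
#' @export
ranked_list <- function(scores, source = "") {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("'scores' must have unique gene-id names")
  scores <- scores[!is.na(scores)]
  ord <- order(-scores, names(scores), method = "radix")
  structure(scores[ord], source = source,
            class = c("ranked_list", "numeric"))
}

#' Preranked enrichment score
#'
#' Classic weighted KS walk down a ranked list: member genes ("hits") add
#' `|score|^w / sum(hit |score|^w)`, non-members subtract `1/(N - n_hits)`;
#' the ES is the walk deviation of maximum absolute magnitude, signed.
#' If every hit score is zero the hit increments fall back to uniform.
#'
#' @param ranked A [ranked_list()] (or named numeric vector already sorted
#'   descending).
#' @param set Character vector of gene ids.
#' @param weight_exponent Score weighting exponent (default 1, the classic
#'   weighted statistic).
#' @return The enrichment score, with attribute `n_matched`; `NA` (with a
#'   warning) when fewer than 2 set genes match the list.
#' @examples
#' rl <- ranked_list(c(a = 5, b = 4, c = 3, d = 2, e = 1))
#' preranked_es(rl, c("a", "c"))  # 2/3
#' @export
preranked_es <- function(ranked, set, weight_exponent = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% set
  nh <- sum(hit)
  if (nh < 2 || nh >= n) {
    warning("set matches ", nh, " genes; need 2 <= matched < list size")
    return(structure(NA_real_, n_matched = nh))
  }
  w <- abs(ranked)^weight_exponent
  wh <- sum(w[hit])
  step <- ifelse(hit, if (wh > 0) w / wh else 1 / nh, -1 / (n - nh))
  dev <- cumsum(step)
  structure(dev[which.max(abs(dev))], n_matched = nh)
}

#' Gene-set permutation null for the preranked ES
#'
#' ES values of `n_perm` uniformly random gene sets of size `set_size` drawn
#' from the ranked list. Seeded and reproducible.
#'
#' @param ranked A ranked list.
#' @param set_size Size of the random sets (must be smaller than the list).
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @param weight_exponent Passed to [preranked_es()].
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm, seed,
                             weight_exponent = 1) {
  n <- length(ranked)
  if (set_size >= n) stop("'set_size' must be smaller than the list")
  if (set_size < 2) stop("'set_size' must be at least 2")
  set.seed(seed)
  genes <- names(ranked)
  vapply(seq_len(n_perm), function(i)
    as.numeric(preranked_es(ranked, sample(genes, set_size),
                            weight_exponent)),
    numeric(1))
}

#' Normalize enrichment scores and attach permutation p-values and FDR
#'
#' For each set, `NES = ES / mean(|null ES| of the matching sign)` and the
#' nominal p-value is the add-one tail fraction among same-sign nulls
#' (never exactly zero). The FDR q-value follows the pooled null-ratio
#' method of the canonical GSEA procedure: all null ES are normalized the
#' same way and pooled, and `q` is the ratio of the null tail fraction to
#' the observed tail fraction at the set's NES (per sign), clipped to
#' `[0, 1]` and monotonized from the most extreme NES inward.
#'
#' @param es Named numeric vector of observed enrichment scores per set.
#' @param nulls Named list (same names) of null ES vectors, one per set.
#' @return data.frame with columns `name`, `es`, `nes`, `nominal_p`,
#'   `fdr_q`.
#' @export
nes_fdr <- function(es, nulls) {
  stopifnot(identical(names(es), names(nulls)))
  norm_one <- function(e, null) {
    same <- null[sign(null) == sign(e) & null != 0]
    if (!length(same)) return(NA_real_)
    e / mean(abs(same))
  }
  nes <- mapply(norm_one, es, nulls)
  nominal_p <- mapply(function(e, null) {
    same <- null[sign(null) == sign(e) & null != 0]
    (1 + sum(abs(same) >= abs(e))) / (1 + length(same))
  }, es, nulls)
  # pooled normalized null NES
  null_nes <- unlist(lapply(nulls, function(null) {
    pos <- null[null > 0]; neg <- null[null < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }), use.names = FALSE)
  fdr_q <- rep(NA_real_, length(es))
  for (sgn in c(1, -1)) {
    obs_side <- which(sign(nes) == sgn & is.finite(nes))
    null_side <- null_nes[sign(null_nes) == sgn]
    if (!length(obs_side) || !length(null_side)) next
    for (i in obs_side) {
      frac_null <- mean(abs(null_side) >= abs(nes[i]))
      frac_obs <- mean(abs(nes[obs_side]) >= abs(nes[i]))
      fdr_q[i] <- min(1, frac_null / max(frac_obs, .Machine$double.eps))
    }
    # monotonize: a more extreme NES never has a larger q
    o <- obs_side[order(abs(nes[obs_side]))]
    fdr_q[o] <- cummin(fdr_q[o])
  }
  data.frame(name = names(es), es = as.numeric(es), nes = as.numeric(nes),
             nominal_p = as.numeric(nominal_p), fdr_q = fdr_q,
             stringsAsFactors = FALSE)
}

#' Preranked gene-set enrichment analysis
#'
#' Runs [preranked_es()] for every set passing the size filter, builds a
#' gene-set permutation null per distinct matched size (shared across sets
#' of equal size), and reports NES, nominal p and FDR q via [nes_fdr()].
#'
#' @param ranked A [ranked_list()].
#' @param sets Named list of gene-id vectors.
#' @param n_perm Permutations per set size (default 1000).
#' @param seed Integer RNG seed.
#' @param weight_exponent Walk weight exponent (default 1).
#' @param min_size,max_size Matched set-size filter (defaults 15 and 500,
#'   the conventional preranked defaults).
#' @return data.frame (class `gsea_result`) with one row per analyzed set:
#'   `name`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`, sorted by `nes`
#'   descending.
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, seed = 1,
                           weight_exponent = 1, min_size = 15,
                           max_size = 500) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  matched <- lapply(sets, function(s) unique(s[s %in% names(ranked)]))
  sizes <- lengths(matched)
  keep <- sizes >= max(2, min_size) & sizes <= min(max_size,
                                                   length(ranked) - 1L)
  if (!any(keep)) stop("no gene set passes the size filter")
  matched <- matched[keep]; sizes <- sizes[keep]
  es <- vapply(matched, function(s)
    as.numeric(preranked_es(ranked, s, weight_exponent)), numeric(1))
  null_by_size <- lapply(unique(sizes), function(sz)
    permutation_null(ranked, sz, n_perm,
                     seed = substream_seed(seed, paste0("gsea", sz)),
                     weight_exponent = weight_exponent))
  names(null_by_size) <- as.character(unique(sizes))
  nulls <- null_by_size[as.character(sizes)]
  names(nulls) <- names(matched)
  res <- nes_fdr(es, nulls)
  res$size <- as.integer(sizes)
  res <- res[order(-res$nes), c("name", "size", "es", "nes", "nominal_p",
                                "fdr_q")]
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  res
}

#' Write a GSEA result table (GSEA-report-style columns)
#'
#' @param res A `gsea_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gsea_result <- function(res, path) {
  out <- data.frame(NAME = res$name, SIZE = res$size, ES = res$es,
                    NES = res$nes, `NOM p-val` = res$nominal_p,
                    `FDR q-val` = res$fdr_q, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
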