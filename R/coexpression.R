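#' Correlate every gene with a seed (marker) gene
#'
#' Pearson (or Spearman, i.e. Pearson on average ranks) correlation of each
#' gene with the seed across samples, using pairwise-complete observations.
#' Two-sided p-values come from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom; q-values are Benjamini-Hochberg over all
#' finite p. Genes with fewer than 3 complete pairs or zero variance on the
#' complete pairs get `NA` entries and are excluded downstream. The seed is
#' excluded from the profile.
#'
#' @param x Numeric gene x sample matrix with gene-id rownames.
#' @param seed Seed gene id (must be a row of `x`).
#' @param method `"pearson"` or `"spearman"`.
#' @return A data.frame of class `correlation_profile` with columns `gene`,
#'   `r`, `n_used`, `p`, `q` and attributes `seed` and `method`.
#' @export
correlate_with_seed <- function(x, seed, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (!seed %in% rownames(x)) stop("seed gene '", seed, "' not in matrix")
  if (method == "spearman") {
    x <- t(apply(x, 1L, rank, ties.method = "average", na.last = "keep"))
  }
  s <- x[seed, ]
  g <- x[setdiff(rownames(x), seed), , drop = FALSE]
  n_used <- as.integer((!is.na(g)) %*% (!is.na(s)))
  r <- suppressWarnings(as.vector(stats::cor(s, t(g),
                                             use = "pairwise.complete.obs")))
  r[n_used < 3] <- NA_real_
  tt <- r * sqrt((n_used - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tt), n_used - 2)
  p[is.finite(r) & abs(r) == 1] <- 0
  p[!is.finite(r)] <- NA_real_
  out <- data.frame(gene = rownames(g), r = r, n_used = n_used, p = p,
                    q = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Select a coexpression module from a correlation profile
#'
#' Members are the genes whose finite correlation exceeds
#' `mean(r) + sd_mult * sd(r)` (mean and SD over all finite signed
#' correlations of the profile, seed excluded), with BH q-value below
#' `fdr_max`, and positive correlation when `positive_only` is set. An empty
#' selection is legal and produces a warning, not an error.
#'
#' @param profile A [correlate_with_seed()] result with at least 10 finite
#'   correlations.
#' @param sd_mult SD multiplier for the correlation cutoff (default 2).
#' @param fdr_max Maximum BH q-value (default 0.05).
#' @param positive_only Keep positively correlated genes only (default
#'   `TRUE`; positively correlated genes are detectable in the
#'   marker-expressing population, negatively correlated ones are not).
#' @return An object of class `coexpression_module`: list with `marker`,
#'   `genes`, `cutoff_params`, `threshold`, `percentile` (empirical
#'   percentile of the threshold among finite correlations) and
#'   `n_candidates`.
#' @export
select_module <- function(profile, sd_mult = 2, fdr_max = 0.05,
                          positive_only = TRUE) {
  stopifnot(inherits(profile, "correlation_profile"))
  fin <- is.finite(profile$r)
  if (sum(fin) < 10)
    stop("profile has fewer than 10 finite correlations")
  mu <- mean(profile$r[fin]); sdv <- stats::sd(profile$r[fin])
  thr <- mu + sd_mult * sdv
  keep <- fin & profile$r > thr & !is.na(profile$q) & profile$q < fdr_max
  if (positive_only) keep <- keep & profile$r > 0
  genes <- profile$gene[keep]
  if (!length(genes))
    warning("empty module for seed '", attr(profile, "seed"), "'")
  structure(list(marker = attr(profile, "seed"),
                 genes = genes,
                 cutoff_params = list(sd_mult = sd_mult, fdr_max = fdr_max,
                                      positive_only = positive_only),
                 threshold = thr,
                 percentile = mean(profile$r[fin] <= thr),
                 n_candidates = sum(fin)),
            class = "coexpression_module")
}

#' @export
print.coexpression_module <- function(x, ...) {
  cat("Coexpression module for seed '", x$marker, "': ", length(x$genes),
      " genes\n", sep = "")
  cat(sprintf("  cutoff: mean + %g SD (r > %.4f, %.1f percentile), q < %g%s\n",
              x$cutoff_params$sd_mult, x$threshold, 100 * x$percentile,
              x$cutoff_params$fdr_max,
              if (x$cutoff_params$positive_only) ", positive only" else ""))
  invisible(x)
}

#' Overlap of a module with a reference gene set
#'
#' Intersection size plus the upper-tail hypergeometric p-value against a
#' universe of `universe` genes.
#'
#' @param a A `coexpression_module` or character vector of gene ids.
#' @param b Character vector of gene ids (e.g. an established signature).
#' @param universe Universe size (number of genes both sets were drawn
#'   from); must be at least as large as either set.
#' @return List with `k` (overlap) and `p`.
#' @export
module_overlap <- function(a, b, universe) {
  ga <- if (inherits(a, "coexpression_module")) a$genes else a
  ga <- unique(ga); gb <- unique(b)
  if (universe < length(ga) || universe < length(gb))
    stop("universe smaller than one of the sets")
  k <- length(intersect(ga, gb))
  list(k = k, p = hypergeom_overlap_test(k, length(ga), length(gb), universe))
}

#' Write / read a discovered module and its correlation profile
#'
#' Modules are written as a two-column TSV (`module`, `gene`) with a JSON
#' sidecar (`<path>.json`) holding the cutoff parameters and threshold
#' percentile; profiles as a five-column TSV (`gene`, `r`, `n`, `p`, `q`).
#'
#' @param module A `coexpression_module`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_module <- function(module, path) {
  stopifnot(inherits(module, "coexpression_module"))
  d <- data.frame(module = rep(paste0(module$marker, "-M"),
                               length(module$genes)),
                  gene = module$genes, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(marker = module$marker,
               cutoff_params = module$cutoff_params,
               threshold = module$threshold,
               percentile = module$percentile,
               n_candidates = module$n_candidates,
               n_genes = length(module$genes))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_module
#' @param profile A `correlation_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "correlation_profile"))
  d <- profile
  names(d) <- c("gene", "r", "n", "p", "q")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
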