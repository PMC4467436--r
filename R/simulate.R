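#' Define a planted coexpression module for simulation
#'
#' A planted module is a block of genes tied to one latent expression program.
#' Every member gene (including the seed) is generated as
#' `sqrt(latent_corr) * f + sqrt(1 - latent_corr) * e`, where `f` is the
#' module's unit-variance latent factor and `e` is independent gene-level
#' noise, so any two members (and in particular any member and the seed)
#' have Pearson correlation exactly `latent_corr` in expectation.
#'
#' @param name Module name (e.g. `"CD133-M"`).
#' @param seed_gene Gene identifier of the seed/marker gene; always a member.
#' @param n_members Total number of member genes including the seed (>= 2).
#' @param latent_corr Target member-member Pearson correlation, strictly in
#'   (0, 1).
#' @param subtype_activation Named numeric vector: mean shift of the latent
#'   factor (in latent SD units) in each subtype. Missing subtypes get 0.
#' @return An object of class `planted_module`.
#' @seealso [sim_config()], [simulate_expression()]
#' @export
planted_module <- function(name, seed_gene, n_members, latent_corr,
                           subtype_activation = numeric()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(seed_gene), length(seed_gene) == 1L)
  if (n_members < 2) stop("a planted module needs at least 2 members")
  if (!is.numeric(latent_corr) || latent_corr <= 0 || latent_corr >= 1)
    stop("'latent_corr' must lie strictly between 0 and 1")
  structure(list(name = name, seed_gene = seed_gene,
                 n_members = as.integer(n_members),
                 latent_corr = latent_corr,
                 subtype_activation = subtype_activation),
            class = "planted_module")
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: expression structure,
#' subtype mixture, clinical/survival generation and mutation rates.
#' Survival times are in days. Defaults emulate a glioblastoma-like cohort:
#' baseline hazard `log(2)/450` per day (median survival ~15 months),
#' light exponential censoring, administrative censoring at 10 years,
#' age ~ Normal(58, 10), treatments assigned Bernoulli(0.5).
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (tumors).
#' @param modules List of [planted_module()] objects. Background genes are
#'   pure noise.
#' @param subtype_proportions Named probability vector over subtype labels;
#'   must sum to 1.
#' @param noise_sd Marginal SD of every gene's expression (log2 scale).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression levels
#'   are drawn Normal(`baseline_mean`, `baseline_sd`).
#' @param survival List with components `baseline_hazard` (events/day),
#'   `treatment_log_hr` (data.frame with columns `subtype`, `treatment`,
#'   `log_hr`; `treatment` is `"radiotherapy"` or `"temozolomide"`),
#'   `censoring_rate` (events/day; 0 disables random censoring) and
#'   `accrual_horizon` (days; administrative censoring, may be `Inf`).
#' @param mutation Named list: gene id -> named vector of per-subtype
#'   Bernoulli mutation probabilities.
#' @param gcimp_prob Named per-subtype probability of the G-CIMP flag; by
#'   default 0.30 in the first subtype and 0.05 elsewhere (the flag is
#'   enriched in one designated subtype).
#' @param rng_seed Integer seed; all generators derive named substreams from
#'   it, so outputs are byte-identical across runs and adding one generator
#'   does not perturb the others.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes, n_samples, modules = list(),
                       subtype_proportions = c(A = 0.5, B = 0.5),
                       noise_sd = 1, baseline_mean = 7, baseline_sd = 1.5,
                       survival = list(), mutation = list(),
                       gcimp_prob = NULL, rng_seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 2)
  if (is.null(names(subtype_proportions)) ||
      any(!nzchar(names(subtype_proportions))))
    stop("'subtype_proportions' must be a named vector")
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stop("'subtype_proportions' must sum to 1")
  if (any(subtype_proportions < 0 | subtype_proportions > 1))
    stop("subtype proportions must be probabilities in [0,1]")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  for (m in modules)
    if (!inherits(m, "planted_module")) stop("'modules' must be planted_module objects")
  sizes <- vapply(modules, function(m) m$n_members, integer(1))
  if (sum(sizes) > n_genes)
    stop("module gene counts exceed 'n_genes'")
  mod_names <- vapply(modules, function(m) m$name, character(1))
  if (anyDuplicated(mod_names)) stop("module names must be unique")

  surv_default <- list(baseline_hazard = log(2) / 450,
                       treatment_log_hr = data.frame(subtype = character(),
                                                     treatment = character(),
                                                     log_hr = numeric()),
                       censoring_rate = 2e-4, accrual_horizon = 3650)
  unknown <- setdiff(names(survival), names(surv_default))
  if (length(unknown))
    stop("unknown survival setting(s): ", paste(unknown, collapse = ", "))
  survival <- c(survival,
                surv_default[setdiff(names(surv_default), names(survival))])
  if (survival$baseline_hazard <= 0) stop("'baseline_hazard' must be positive")
  if (survival$censoring_rate < 0) stop("'censoring_rate' must be >= 0")
  lhr <- survival$treatment_log_hr
  if (!all(c("subtype", "treatment", "log_hr") %in% names(lhr)))
    stop("'treatment_log_hr' needs columns subtype, treatment, log_hr")

  labels <- names(subtype_proportions)
  if (is.null(gcimp_prob)) {
    gcimp_prob <- stats::setNames(rep(0.05, length(labels)), labels)
    gcimp_prob[1L] <- 0.30
  }
  if (!all(labels %in% names(gcimp_prob)))
    stop("'gcimp_prob' must cover every subtype label")
  for (g in names(mutation)) {
    pr <- mutation[[g]]
    if (any(pr < 0 | pr > 1)) stop("mutation probabilities must be in [0,1]")
  }
  if (any(gcimp_prob < 0 | gcimp_prob > 1))
    stop("'gcimp_prob' values must be in [0,1]")

  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 modules = modules,
                 subtype_proportions = subtype_proportions,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 survival = survival, mutation = mutation,
                 gcimp_prob = gcimp_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Deterministic per-generator substream seed: order-sensitive string hash
# folded with the master seed, kept below 2^31.
substream_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) %% 1000003
  as.integer((as.numeric(seed) %% 1000003L * 7919 + h * 104729) %%
               (.Machine$integer.max - 1L))
}

sim_sample_subtypes <- function(config) {
  set.seed(substream_seed(config$rng_seed, "subtype"))
  labels <- names(config$subtype_proportions)
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  stats::setNames(sample(labels, config$n_samples, replace = TRUE,
                         prob = config$subtype_proportions), samples)
}

#' Simulate a log-scale expression matrix with planted coexpression modules
#'
#' Member genes of a planted module m are generated as
#' `x = baseline + noise_sd * (sqrt(rho) * f_m + sqrt(1 - rho) * e)`, with
#' `f_m` a standard-normal latent factor shifted by the module's
#' `subtype_activation` for each sample's subtype, and `e` iid standard
#' normal; background genes are pure noise. The mixing is chosen so the
#' pairwise member-member correlation is analytically `rho = latent_corr`
#' (in the absence of activation shifts).
#'
#' @param config A [sim_config()].
#' @return A list with components `expression` (numeric genes x samples
#'   matrix with gene/sample dimnames) and `truth`, a list with
#'   `sample_subtype` (named character vector over all samples) and
#'   `module_membership` (named character vector over all genes; `NA` for
#'   background genes).
#' @examples
#' cfg <- sim_config(100, 40, modules = list(
#'   planted_module("M1", "SEED1", 10, 0.8)), rng_seed = 7)
#' sim <- simulate_expression(cfg)
#' dim(sim$expression)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  subtype <- sim_sample_subtypes(config)
  set.seed(substream_seed(config$rng_seed, "expression"))
  ng <- config$n_genes; ns <- config$n_samples
  samples <- names(subtype)
  genes <- sprintf("G%05d", seq_len(ng))
  membership <- stats::setNames(rep(NA_character_, ng), genes)

  x <- matrix(stats::rnorm(ng * ns, sd = config$noise_sd), ng, ns)
  pos <- 1L
  for (m in config$modules) {
    idx <- pos:(pos + m$n_members - 1L)
    ids <- c(m$seed_gene,
             sprintf("%s_m%03d", gsub("[^A-Za-z0-9]", "", m$name),
                     seq_len(m$n_members - 1L)))
    genes[idx] <- ids
    act <- rep(0, ns)
    hit <- subtype %in% names(m$subtype_activation)
    act[hit] <- m$subtype_activation[subtype[hit]]
    f <- stats::rnorm(ns) + act
    e <- matrix(stats::rnorm(m$n_members * ns), m$n_members, ns)
    x[idx, ] <- config$noise_sd *
      (sqrt(m$latent_corr) * matrix(f, m$n_members, ns, byrow = TRUE) +
         sqrt(1 - m$latent_corr) * e)
    pos <- pos + m$n_members
  }
  if (anyDuplicated(genes)) stop("duplicate gene ids across modules")
  names(membership) <- genes
  pos <- 1L
  for (m in config$modules) {
    membership[pos:(pos + m$n_members - 1L)] <- m$name
    pos <- pos + m$n_members
  }
  x <- x + stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  dimnames(x) <- list(genes, samples)
  list(expression = x,
       truth = list(sample_subtype = subtype, module_membership = membership))
}

#' Simulate clinical/survival data with subtype-specific treatment effects
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(sum of treatment_log_hr entries matching the
#' sample's subtype and received treatments)`; random censoring is
#' exponential at `censoring_rate` and administrative at `accrual_horizon`
#' days. Radiotherapy and temozolomide are assigned independently
#' Bernoulli(0.5); age ~ Normal(58, 10); the G-CIMP flag is Bernoulli with
#' the configured per-subtype probability.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` component returned by [simulate_expression()]
#'   (must cover every sample).
#' @return A data.frame (one row per sample) with columns `sample`, `time`
#'   (days), `event` (1 = death observed), `age`, `gcimp`, `radiotherapy`,
#'   `temozolomide`, `subtype`.
#' @export
simulate_clinical <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  subtype <- truth$sample_subtype
  if (length(subtype) != config$n_samples)
    stop("'truth' does not cover every sample")
  sv <- config$survival
  lhr <- sv$treatment_log_hr
  known <- names(config$subtype_proportions)
  if (nrow(lhr) && !all(lhr$subtype %in% known))
    stop("unknown subtype label in 'treatment_log_hr': ",
         paste(setdiff(lhr$subtype, known), collapse = ", "))
  if (nrow(lhr) && !all(lhr$treatment %in% c("radiotherapy", "temozolomide")))
    stop("unknown treatment in 'treatment_log_hr'")

  set.seed(substream_seed(config$rng_seed, "clinical"))
  n <- length(subtype)
  radiotherapy <- stats::rbinom(n, 1, 0.5)
  temozolomide <- stats::rbinom(n, 1, 0.5)
  eta <- rep(0, n)
  if (nrow(lhr)) {
    trt <- cbind(radiotherapy = radiotherapy, temozolomide = temozolomide)
    for (i in seq_len(nrow(lhr))) {
      sel <- subtype == lhr$subtype[i] & trt[, lhr$treatment[i]] == 1
      eta[sel] <- eta[sel] + lhr$log_hr[i]
    }
  }
  tt <- stats::rexp(n, rate = sv$baseline_hazard * exp(eta))
  cc <- if (sv$censoring_rate > 0) stats::rexp(n, sv$censoring_rate) else
    rep(Inf, n)
  cc <- pmin(cc, sv$accrual_horizon)
  age <- stats::rnorm(n, 58, 10)
  gcimp <- stats::rbinom(n, 1, config$gcimp_prob[subtype])
  data.frame(sample = names(subtype),
             time = pmin(tt, cc),
             event = as.integer(tt <= cc),
             age = age, gcimp = gcimp,
             radiotherapy = radiotherapy, temozolomide = temozolomide,
             subtype = unname(subtype),
             stringsAsFactors = FALSE)
}

#' Simulate a binary mutation table with subtype-conditional rates
#'
#' Independent Bernoulli draws per (gene, sample) with the probability given
#' by the sample's subtype in `config$mutation`; genes without an entry for
#' a subtype use probability 0.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` component from [simulate_expression()].
#' @return Binary integer matrix, mutation genes x samples.
#' @export
simulate_mutations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  subtype <- truth$sample_subtype
  known <- names(config$subtype_proportions)
  for (g in names(config$mutation)) {
    pr <- config$mutation[[g]]
    if (!all(names(pr) %in% known))
      stop("unknown subtype label in mutation rates for gene ", g)
  }
  set.seed(substream_seed(config$rng_seed, "mutation"))
  genes <- names(config$mutation)
  n <- length(subtype)
  out <- matrix(0L, length(genes), n,
                dimnames = list(genes, names(subtype)))
  for (g in genes) {
    pr <- config$mutation[[g]]
    p <- rep(0, n)
    hit <- subtype %in% names(pr)
    p[hit] <- pr[subtype[hit]]
    out[g, ] <- stats::rbinom(n, 1, p)
  }
  out
}
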