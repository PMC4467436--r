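# End-to-end orchestration: configuration, the discovery stage, and the
# full discover -> score -> classify -> associate -> GSEA -> survival run.
# Every stage writes plain TSV/JSON artifacts plus a manifest of parameters
# and input/output checksums, so reruns are verifiably identical.

#' Pipeline configuration
#'
#' @param expression Path to the expression matrix (TSV or GCT 1.2).
#' @param gene_sets Optional GMT path with reference signatures/pathways.
#' @param clinical Optional clinical TSV path.
#' @param mutations Optional binary gene x sample mutation TSV path.
#' @param markers Named character vector of seed genes; names label the
#'   modules. Defaults to the six glioma stem-progenitor-cell markers
#'   CD133 (PROM1), CD44, CD15 (FUT4), Integrin-alpha-6 (ITGA6), L1CAM and
#'   ALDH1A3.
#' @param classify_markers The two marker names whose module scores define
#'   the dichotomous subtype (default CD133 vs CD44).
#' @param sd_mult,fdr_max,positive_only Module-selection cutoff parameters;
#'   see [select_module()].
#' @param tau,es_mode Scoring parameters; see [score_samples()].
#' @param gsea_n_perm,gsea_min_size,gsea_max_size Preranked GSEA parameters.
#' @param survival_covariates Covariates of the per-subtype Cox models.
#' @param rng_seed Integer seed for all stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, gene_sets = NULL, clinical = NULL,
                            mutations = NULL,
                            markers = c(CD133 = "PROM1", CD44 = "CD44",
                                        CD15 = "FUT4", ITGA6 = "ITGA6",
                                        L1CAM = "L1CAM",
                                        ALDH1A3 = "ALDH1A3"),
                            classify_markers = names(markers)[1:2],
                            sd_mult = 2, fdr_max = 0.05,
                            positive_only = TRUE,
                            tau = 1, es_mode = "diff",
                            gsea_n_perm = 1000, gsea_min_size = 15,
                            gsea_max_size = 500,
                            survival_covariates = c("age", "gcimp",
                                                    "radiotherapy",
                                                    "temozolomide"),
                            rng_seed = 1L, out_dir = "coexsig-out") {
  if (is.null(names(markers)) || any(!nzchar(names(markers))))
    stop("'markers' must be a named vector (module label = seed gene)")
  if (!all(classify_markers %in% names(markers)))
    stop("'classify_markers' must name entries of 'markers'")
  structure(list(expression = expression, gene_sets = gene_sets,
                 clinical = clinical, mutations = mutations,
                 markers = markers, classify_markers = classify_markers,
                 sd_mult = sd_mult, fdr_max = fdr_max,
                 positive_only = positive_only,
                 tau = tau, es_mode = es_mode,
                 gsea_n_perm = gsea_n_perm,
                 gsea_min_size = gsea_min_size,
                 gsea_max_size = gsea_max_size,
                 survival_covariates = survival_covariates,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error so every threshold in a run is auditable.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$markers)) y$markers <- unlist(y$markers)
  do.call(pipeline_config, y)
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_manifest <- function(config, files, path) {
  inputs <- Filter(Negate(is.null),
                   config[c("expression", "gene_sets", "clinical",
                            "mutations")])
  manifest <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    input_checksums = as.list(tools::md5sum(unlist(inputs))),
    output_checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

load_expression_collapsed <- function(config) {
  x <- read_expression(config$expression)
  collapse_duplicate_genes(x)
}

#' Discovery stage: one coexpression module per marker
#'
#' Reads the expression matrix (collapsing duplicate gene rows), aborts
#' naming any marker seed absent from it, then computes a correlation
#' profile and selects a module for every marker. Profiles, module files
#' (TSV + JSON sidecar) and a manifest with parameter and checksum records
#' are written to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `modules`, `profiles` and `files`.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- stage_fail("read", load_expression_collapsed(config))
  absent <- config$markers[!config$markers %in% rownames(x)]
  if (length(absent))
    stop("marker seed(s) absent from the expression matrix: ",
         paste(sprintf("%s (%s)", names(absent), absent), collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  modules <- list(); profiles <- list(); files <- character()
  for (mk in names(config$markers)) {
    prof <- correlate_with_seed(x, config$markers[[mk]])
    mod <- suppressWarnings(
      select_module(prof, sd_mult = config$sd_mult,
                    fdr_max = config$fdr_max,
                    positive_only = config$positive_only))
    profiles[[mk]] <- prof
    modules[[paste0(mk, "-M")]] <- mod
    pf <- file.path(config$out_dir, paste0("profile_", mk, ".tsv"))
    mf <- file.path(config$out_dir, paste0("module_", mk, ".tsv"))
    write_profile(prof, pf)
    write_module(mod, mf)
    files <- c(files, pf, mf, paste0(mf, ".json"))
  }
  write_manifest(config, files,
                 file.path(config$out_dir, "manifest_discover.json"))
  invisible(list(modules = modules, profiles = profiles, files = files))
}

#' Run the full analysis pipeline
#'
#' discover -> score -> classify -> associate -> GSEA -> survival. Optional
#' inputs degrade gracefully: without a clinical table the survival stage is
#' skipped with a notice, without gene sets the GSEA/overlap stages are
#' skipped, without mutations the mutation-association stage is skipped.
#' Any stage error halts the run naming the stage. All tabular outputs are
#' TSV under `out_dir`, summarized in `summary.txt`, with a JSON manifest
#' of parameters and checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's in-memory results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  notes <- character()
  x <- stage_fail("read", load_expression_collapsed(config))
  disc <- stage_fail("discover", run_discover(config))
  files <- disc$files

  # --- score & classify ---------------------------------------------------
  scorable <- disc$modules[vapply(disc$modules, function(m)
    length(m$genes) >= 2, logical(1))]
  if (!length(scorable))
    stop("stage 'score' failed: every discovered module is empty")
  es <- stage_fail("score",
                   score_samples(x, scorable, tau = config$tau,
                                 es_mode = config$es_mode))
  esf <- file.path(config$out_dir, "enrichment_scores.tsv")
  utils::write.table(data.frame(set = rownames(es), es,
                                check.names = FALSE),
                     esf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, esf)

  cand <- paste0(config$classify_markers, "-M")
  calls <- NULL
  if (all(cand %in% rownames(es))) {
    calls <- stage_fail("classify", classify(es, cand))
    cf <- file.path(config$out_dir, "subtype_calls.tsv")
    utils::write.table(calls, cf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, cf)
  } else {
    notes <- c(notes, "classify: skipped (classification modules not scored)")
  }

  # --- association --------------------------------------------------------
  assoc <- list()
  if (!is.null(config$gene_sets)) {
    sets <- stage_fail("associate", read_gmt(config$gene_sets))
    rows <- list()
    for (mn in names(disc$modules)) {
      for (sn in names(sets)) {
        ov <- module_overlap(disc$modules[[mn]], sets[[sn]], nrow(x))
        rows[[length(rows) + 1L]] <-
          data.frame(module = mn, set = sn, k = ov$k, p = ov$p)
      }
    }
    assoc$overlap <- do.call(rbind, rows)
    assoc$overlap$q <- bh_fdr(assoc$overlap$p)
    of <- file.path(config$out_dir, "module_set_overlap.tsv")
    utils::write.table(assoc$overlap, of, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, of)
  } else notes <- c(notes, "associate/overlap: skipped (no gene sets)")

  if (!is.null(config$mutations) && !is.null(calls)) {
    mut <- stage_fail("associate", read_expression(config$mutations,
                                                   format = "tsv"))
    shared <- intersect(colnames(mut), calls$sample)
    lab <- stats::setNames(calls$label, calls$sample)[shared]
    rows <- list()
    for (g in rownames(mut)) {
      tab <- table(factor(mut[g, shared] > 0, levels = c(TRUE, FALSE)),
                   factor(lab == cand[1L], levels = c(TRUE, FALSE)))
      ft <- fisher_exact(tab)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, or = ft$estimate[["sample_or"]],
                   cmle_or = ft$estimate[["cmle_or"]], p = ft$p.value)
    }
    assoc$mutations <- do.call(rbind, rows)
    assoc$mutations$q <- bh_fdr(assoc$mutations$p)
    mfile <- file.path(config$out_dir, "mutation_association.tsv")
    utils::write.table(assoc$mutations, mfile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, mfile)
  } else notes <- c(notes, "associate/mutations: skipped")

  # --- preranked GSEA -----------------------------------------------------
  gsea <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- read_gmt(config$gene_sets)
    gsea <- list()
    for (mk in names(config$markers)) {
      prof <- disc$profiles[[mk]]
      rl <- ranked_list(stats::setNames(prof$r, prof$gene),
                        source = paste("Pearson r with",
                                       config$markers[[mk]]))
      res <- tryCatch(
        preranked_gsea(rl, sets, n_perm = config$gsea_n_perm,
                       seed = config$rng_seed,
                       min_size = config$gsea_min_size,
                       max_size = config$gsea_max_size),
        error = function(e) NULL)
      if (is.null(res)) {
        notes <- c(notes, paste0("gsea/", mk,
                                 ": skipped (no set passed the size filter)"))
        next
      }
      gsea[[mk]] <- res
      gf <- file.path(config$out_dir, paste0("gsea_", mk, ".tsv"))
      write_gsea_result(res, gf)
      files <- c(files, gf)
    }
  } else notes <- c(notes, "gsea: skipped (no gene sets)")

  # --- survival -----------------------------------------------------------
  surv <- NULL
  if (!is.null(config$clinical) && !is.null(calls)) {
    surv <- stage_fail("survival", {
      cl <- read_clinical(config$clinical)
      cl <- cl[cl$sample %in% calls$sample, , drop = FALSE]
      lab <- stats::setNames(calls$label, calls$sample)
      km <- lapply(split(cl, lab[cl$sample]), function(d)
        km_estimate(d$time, d$event))
      lr <- logrank_test(cl$time, cl$event, lab[cl$sample])
      sta <- subtype_treatment_analysis(cl, calls,
                                        covariates =
                                          config$survival_covariates)
      list(km = km, logrank = lr, treatment = sta)
    })
    tf <- file.path(config$out_dir, "subtype_treatment_hr.tsv")
    utils::write.table(surv$treatment$table, tf, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, tf)
  } else notes <- c(notes,
                    "survival: skipped (no clinical table or no calls)")

  # --- summary & manifest -------------------------------------------------
  sm <- file.path(config$out_dir, "summary.txt")
  lines <- c("coexsig run summary",
             sprintf("expression: %d genes x %d samples", nrow(x), ncol(x)),
             sprintf("module %s: %d genes", names(disc$modules),
                     vapply(disc$modules, function(m) length(m$genes),
                            integer(1))))
  if (!is.null(calls))
    lines <- c(lines, sprintf("subtype calls: %s",
                              paste(sprintf("%s=%d", names(table(calls$label)),
                                            table(calls$label)),
                                    collapse = ", ")))
  if (!is.null(surv))
    lines <- c(lines, sprintf("log-rank p between subtypes: %.4g",
                              surv$logrank$p.value))
  lines <- c(lines, notes)
  writeLines(lines, sm)
  files <- c(files, sm)
  for (nt in notes) message(nt)
  write_manifest(config, files, file.path(config$out_dir, "manifest.json"))
  invisible(list(expression = x, discover = disc, scores = es,
                 calls = calls, assoc = assoc, gsea = gsea,
                 survival = surv, notes = notes))
}
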