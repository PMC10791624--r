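#' Analysis parameters for the crosstalk pipeline
#'
#' One place for every screening threshold, each with its conventional
#' default: differential screening at FDR < 0.01, |log2FC| > 2, p < 0.05;
#' miRNA attachment and risk-pathway retention at p < 0.05; single drugs at
#' DS > 0.01; combinations kept when the joint DS is `>=` the sum of the
#' single scores.
#'
#' @param fdr_threshold,lfc_threshold,p_threshold differential screening
#'   cutoffs (see [compute_differential()]).
#' @param module_alpha module-trait significance cutoff.
#' @param module_mode `"all-significant"` or `"top"` (see
#'   [extract_risk_factors()]).
#' @param min_module_size,cut_height module detection settings (see
#'   [detect_modules()]).
#' @param recon_alpha miRNA attachment threshold.
#' @param risk_alpha risk-pathway retention threshold.
#' @param ds_threshold single-drug DS cutoff.
#' @param combo_criterion `"ge"` or `"gt"`.
#' @param cascade cascade removal of orphaned pathway miRNAs.
#' @param cor_samples compute expression correlations over `"all"` samples
#'   or `"tumor"` only.
#' @param seed root seed for the stochastic stages (k-means).
#' @return list of class `PipelineParams`.
#' @export
pipeline_params <- function(fdr_threshold = 0.01, lfc_threshold = 2,
                            p_threshold = 0.05, module_alpha = 0.05,
                            module_mode = "all-significant",
                            min_module_size = 10, cut_height = 0.5,
                            recon_alpha = 0.05, risk_alpha = 0.05,
                            ds_threshold = 0.01, combo_criterion = "ge",
                            cascade = TRUE, cor_samples = "all", seed = 1) {
  p <- list(fdr_threshold = fdr_threshold, lfc_threshold = lfc_threshold,
            p_threshold = p_threshold, module_alpha = module_alpha,
            module_mode = module_mode, min_module_size = min_module_size,
            cut_height = cut_height, recon_alpha = recon_alpha,
            risk_alpha = risk_alpha, ds_threshold = ds_threshold,
            combo_criterion = combo_criterion, cascade = cascade,
            cor_samples = cor_samples, seed = seed)
  for (nm in c("fdr_threshold", "p_threshold", "module_alpha", "recon_alpha",
               "risk_alpha"))
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      stop("parameter ", nm, " must lie in (0, 1]")
  if (p$ds_threshold < 0 || p$ds_threshold > 1)
    stop("parameter ds_threshold must lie in [0, 1]")
  if (p$lfc_threshold <= 0) stop("parameter lfc_threshold must be positive")
  if (!p$combo_criterion %in% c("ge", "gt"))
    stop("combo_criterion must be 'ge' or 'gt'")
  if (!p$cor_samples %in% c("all", "tumor"))
    stop("cor_samples must be 'all' or 'tumor'")
  if (!p$module_mode %in% c("top", "all-significant"))
    stop("module_mode must be 'top' or 'all-significant'")
  structure(p, class = "PipelineParams")
}

# log2 view of a bundle's combined matrix for correlation work
.log2_matrix <- function(bundle, pseudocount = 1e-9) {
  m <- bundle_matrix(bundle)
  if (bundle$is_log2) m else log2(m + pseudocount)
}

#' Run the full crosstalk analysis on in-memory objects
#'
#' Executes the whole chain: differential screening, co-expression module
#' detection and risk-factor extraction, miRNA attachment to pathways,
#' risk-pathway identification, crosstalk network construction, single-drug
#' DS screening, drug-pair optimization, and survival stratification of the
#' top selected combination's target signature (targets restricted to the
#' pathways of the combination's affected pathway pairs).
#'
#' @param bundle an `ExpressionBundle`.
#' @param network an `InteractionNetwork`.
#' @param pathways named list of `PathwayGraph` objects.
#' @param drug_map a `DrugTargetMap`.
#' @param surv optional `SurvivalTable` (survival stage skipped when `NULL`).
#' @param params a [pipeline_params()] list.
#' @return list of class `CrosstalkAnalysis` with elements `diff`, `power`,
#'   `modules`, `risk`, `recon`, `risk_pathways`, `crosstalk`, `drugs`,
#'   `combos`, `survival` (may be `NULL`), `params` and `stage_counts`.
#' @export
analyze_cohort <- function(bundle, network, pathways, drug_map, surv = NULL,
                           params = pipeline_params()) {
  pr <- params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()

  # differential testing on the log2 scale (variance stabilization for
  # expression abundances); fold change = difference of log2 group means
  bundle_log <- if (bundle$is_log2) bundle else
    expression_bundle(log2(bundle$mrna + 1e-9), log2(bundle$mirna + 1e-9),
                      bundle$phenotype, is_log2 = TRUE)
  diff <- stage("diffexp", compute_differential(
    bundle_log, pr$fdr_threshold, pr$lfc_threshold, pr$p_threshold))
  counts$features_tested <- nrow(diff)
  counts$differential <- sum(diff$is_differential)
  message("diffexp: ", counts$differential, " / ", counts$features_tested,
          " features differential")

  kind <- bundle_feature_kind(bundle)
  log2m <- .log2_matrix(bundle)
  diff_feats <- diff$feature[diff$is_differential]
  mods <- list(); risk <- structure(list(risk_mrnas = character(0),
                                         risk_mirnas = character(0),
                                         selected_modules = character(0)),
                                    class = "RiskFactorSet")
  power <- NA_real_
  if (length(diff_feats) >= 3L) {
    expr_sub <- log2m[diff_feats, , drop = FALSE]
    sp <- stage("coexpression", suppressWarnings(pick_soft_power(expr_sub)))
    power <- sp$power
    adj <- stage("coexpression", build_adjacency(expr_sub, power))
    mods <- stage("coexpression",
                  detect_modules(adj, pr$min_module_size, pr$cut_height))
    mods <- stage("coexpression",
                  module_trait(mods, expr_sub, bundle$phenotype))
    risk <- stage("coexpression", suppressWarnings(
      extract_risk_factors(mods, kind, pr$module_alpha, pr$module_mode)))
  }
  counts$modules <- sum(vapply(mods, function(m) !identical(m$id, "grey"),
                               logical(1)))
  counts$risk_mrnas <- length(risk$risk_mrnas)
  counts$risk_mirnas <- length(risk$risk_mirnas)
  message("coexpression: ", counts$modules, " modules; ",
          counts$risk_mrnas, " risk mRNAs, ", counts$risk_mirnas,
          " risk miRNAs")

  recon <- stage("pathway_recon", attach_mirnas(
    pathways, network, rownames(bundle$mrna), alpha = pr$recon_alpha))
  counts$attached_mirnas <- sum(vapply(recon, function(p)
    length(p$mirna_nodes), integer(1)))

  riskp <- stage("risk_enrich", suppressWarnings(identify_risk_pathways(
    recon, risk, background_n = nrow(bundle$mrna) + nrow(bundle$mirna),
    alpha = pr$risk_alpha)))
  counts$risk_pathways <- length(riskp)
  message("risk_enrich: ", counts$risk_pathways, " risk pathways")

  expr_cor <- if (pr$cor_samples == "tumor")
    log2m[, bundle$phenotype == "tumor", drop = FALSE] else log2m
  ct <- stage("crosstalk", suppressWarnings(build_crosstalk_network(
    riskp, network, differential_p_lookup(diff), expr_cor)))
  counts$pathway_pairs <- nrow(ct$pairs)
  counts$total_crosstalk <- ct$total_crosstalk
  message("crosstalk: ", counts$pathway_pairs, " pathway pairs, total ",
          format(ct$total_crosstalk, digits = 6))

  drugs <- NULL; combos <- NULL; surv_split <- NULL
  if (ct$total_crosstalk > 0) {
    drugs <- stage("drug_screen", screen_single_drugs(
      drug_map, ct, pr$ds_threshold, pr$cascade))
    counts$drugs_passing <- sum(drugs$passes_single)
    message("drug_screen: ", counts$drugs_passing, " / ", nrow(drugs),
            " drugs pass DS > ", pr$ds_threshold)
    combos <- stage("combos", suppressWarnings(optimize_combinations(
      drugs, drug_map, ct, pr$combo_criterion, cascade = pr$cascade)))
    counts$combos_selected <- sum(combos$selected)
    message("combos: ", counts$combos_selected, " / ", nrow(combos),
            " combinations selected")
    sel <- combos[combos$selected, , drop = FALSE]
    if (!is.null(surv) && nrow(sel)) {
      top <- sel[1L, ]
      targets <- unique(c(drug_targets(drug_map, top$drug1),
                          drug_targets(drug_map, top$drug2)))
      aff <- attr(combos, "affected")[[paste(top$drug1, top$drug2, sep = "|")]]
      if (!is.null(aff) && nrow(aff)) {
        aff_paths <- unique(c(aff$pathway_i, aff$pathway_j))
        in_aff <- unique(unlist(lapply(ct$pathways[aff_paths],
                                       pathway_features)))
        restricted <- intersect(targets, in_aff)
        if (length(restricted)) targets <- restricted
      }
      surv_split <- stage("survival", survival_split(
        bundle, surv, targets, seed = pr$seed))
      counts$survival_p <- surv_split$p_value
      message("survival: log-rank p = ", format(surv_split$p_value, digits = 4),
              " for top combination ", top$drug1, " + ", top$drug2)
    }
  } else {
    message("drug_screen: skipped (no crosstalk)")
  }

  structure(list(diff = diff, power = power, modules = mods, risk = risk,
                 recon = recon, risk_pathways = riskp, crosstalk = ct,
                 drugs = drugs, combos = combos, survival = surv_split,
                 params = pr, stage_counts = counts),
            class = "CrosstalkAnalysis")
}

#' Pipeline configuration
#'
#' Bundles the input file paths, the output directory and the analysis
#' parameters; serializes losslessly to/from YAML.
#'
#' @param inputs named list of paths: `mrna`, `mirna`, `phenotype`,
#'   `pathways` (GMT), `ppi`, `mirna_targets`, `drug_targets` and optionally
#'   `survival`.
#' @param outdir output directory.
#' @param params a [pipeline_params()] list.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(inputs, outdir, params = pipeline_params()) {
  needed <- c("mrna", "mirna", "phenotype", "pathways", "ppi",
              "mirna_targets", "drug_targets")
  missing <- setdiff(needed, names(inputs))
  if (length(missing)) stop("missing input path(s): ",
                            paste(missing, collapse = ", "))
  structure(list(inputs = inputs, outdir = outdir, params = params),
            class = "PipelineConfig")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return for the reader, a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(y$inputs, y$outdir, do.call(pipeline_params, y$params))
}

#' @rdname read_pipeline_config
#' @param config a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(list(inputs = config$inputs, outdir = config$outdir,
                        params = unclass(config$params)), path)
}

#' Run the whole pipeline from files on disk
#'
#' Reads every input declared in the configuration, runs [analyze_cohort()],
#' and writes each stage's output plus a manifest (package version, seed,
#' parameter hash, input file checksums, per-stage counts) into the output
#' directory. Rerunning with an identical configuration and inputs is
#' byte-identical for the deterministic stages (all of them: k-means is
#' seeded from the configuration).
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return the `CrosstalkAnalysis`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  ins <- config$inputs
  bundle <- read_expression(ins$mrna, ins$mirna, ins$phenotype)
  pathways <- read_gmt(ins$pathways)
  network <- interaction_network(read_edges(ins$ppi, "ppi"),
                                 read_edges(ins$mirna_targets, "mirna_target"))
  drug_map <- read_drug_targets(ins$drug_targets)
  surv <- if (!is.null(ins$survival)) read_survival(ins$survival) else NULL
  res <- analyze_cohort(bundle, network, pathways, drug_map, surv,
                        config$params)
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  write_analysis(res, config$outdir, config)
  invisible(res)
}

#' Write every stage output of an analysis to a directory
#'
#' @param res a `CrosstalkAnalysis` from [analyze_cohort()].
#' @param outdir output directory (created if needed).
#' @param config optional `PipelineConfig` whose inputs are checksummed into
#'   the manifest.
#' @return invisibly, the manifest list.
#' @export
write_analysis <- function(res, outdir, config = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(outdir, f), auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)
  utils::write.table(res$diff, file.path(outdir, "diff.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wj(list(risk_mrnas = res$risk$risk_mrnas,
          risk_mirnas = res$risk$risk_mirnas,
          selected_modules = res$risk$selected_modules,
          modules = lapply(res$modules, function(m)
            list(id = m$id, n_members = length(m$members),
                 members = m$members, trait_r = m$trait_r,
                 trait_p = m$trait_p))),
     "risk_factors.json")
  wj(lapply(res$recon, function(p)
    list(id = p$base$id, n_mrnas = length(p$base$mrna_nodes),
         mirnas = p$mirna_nodes,
         enrichment_p = as.list(p$enrichment_p))),
     "reconstructed_pathways.json")
  wj(lapply(res$risk_pathways, function(rp)
    list(id = rp$pathway$base$id, enrichment_p = rp$enrichment_p,
         overlap = rp$overlap_features)),
     "risk_pathways.json")
  wj(list(total_crosstalk = res$crosstalk$total_crosstalk,
          pairs = res$crosstalk$pairs,
          contributions = res$crosstalk$contributions),
     "crosstalk.json")
  if (!is.null(res$drugs)) wj(res$drugs, "drugs.json")
  if (!is.null(res$combos))
    wj(list(table = res$combos, affected = attr(res$combos, "affected")),
       "combos.json")
  if (!is.null(res$survival))
    wj(list(groups = as.list(res$survival$groups),
            logrank_stat = res$survival$logrank_stat,
            p_value = res$survival$p_value,
            median_survival = as.list(res$survival$median_survival),
            km = res$survival$km),
       "survival.json")
  param_file <- file.path(outdir, "params.yaml")
  yaml::write_yaml(unclass(res$params), param_file)
  manifest <- list(
    package = "crosspath",
    version = as.character(utils::packageVersion("crosspath")),
    seed = res$params$seed,
    parameter_hash = unname(tools::md5sum(param_file)),
    input_md5 = if (!is.null(config))
      as.list(vapply(config$inputs, function(p)
        unname(tools::md5sum(p)), character(1))) else NULL,
    stages = res$stage_counts)
  wj(manifest, "manifest.json")
  invisible(manifest)
}
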