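#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a two-phenotype
#' expression cohort with planted differential features, block-correlated
#' co-expression modules, pathways overlapping the modules, PPI edges
#' enriched between designated "bridge" pathway pairs, miRNAs negatively
#' correlated with their targets, and drugs whose target sets hit the
#' bridges (including one planted superadditive pair and one exactly
#' additive pair).
#'
#' @param n_tumor,n_normal sample counts per phenotype (default 40 + 40).
#' @param n_mrna,n_mirna feature counts (default 500 mRNAs, 50 miRNAs).
#' @param n_modules planted co-expression blocks among the differential
#'   features (default 4).
#' @param n_pathways number of pathways (default 20).
#' @param pathway_size inclusive size range of pathway mRNA sets
#'   (default 15..25).
#' @param n_risk_pathways planted risk pathways whose members are drawn
#'   mostly from the differential pool (default 4).
#' @param frac_differential fraction of features given a phenotype effect
#'   (default 0.2).
#' @param effect_log2fc planted mean tumor/normal log2 fold change
#'   (default 3; miRNA effects are negative, mRNA effects positive).
#' @param within_module_rho target pairwise correlation of features within a
#'   module (default 0.8; must exceed the correlation the phenotype shift
#'   alone induces).
#' @param n_drugs number of drugs (default 8; at least 5 are reserved for
#'   the planted superadditive pair, the additive pair and a null drug).
#' @param planted_synergy_pairs number of planted cascade-superadditive drug
#'   pairs (currently 1 is supported).
#' @param noise_sd per-feature residual standard deviation on the log2 scale
#'   (default 1).
#' @param n_ppi_background random background PPI edges (default 300).
#' @param n_bridge_edges PPI edges per planted pathway pair (default 20).
#' @param survival_beta log-hazard slope on the latent risk score
#'   (default 1).
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_tumor = 40, n_normal = 40, n_mrna = 500,
                             n_mirna = 50, n_modules = 4, n_pathways = 20,
                             pathway_size = c(15, 25), n_risk_pathways = 4,
                             frac_differential = 0.2, effect_log2fc = 3,
                             within_module_rho = 0.8, n_drugs = 8,
                             planted_synergy_pairs = 1, noise_sd = 1,
                             n_ppi_background = 300, n_bridge_edges = 20,
                             survival_beta = 1, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_mrna = n_mrna,
              n_mirna = n_mirna, n_modules = n_modules,
              n_pathways = n_pathways, pathway_size = pathway_size,
              n_risk_pathways = n_risk_pathways,
              frac_differential = frac_differential,
              effect_log2fc = effect_log2fc,
              within_module_rho = within_module_rho, n_drugs = n_drugs,
              planted_synergy_pairs = planted_synergy_pairs,
              noise_sd = noise_sd, n_ppi_background = n_ppi_background,
              n_bridge_edges = n_bridge_edges,
              survival_beta = survival_beta, seed = seed)
  with(cfg, {
    stopifnot(n_tumor >= 2, n_normal >= 2, n_mrna >= 1, n_mirna >= 1,
              n_modules >= 1, n_pathways >= 1, n_drugs >= 1,
              frac_differential >= 0, frac_differential < 1,
              abs(within_module_rho) < 1, noise_sd > 0,
              planted_synergy_pairs %in% c(0, 1),
              length(pathway_size) == 2, pathway_size[1] <= pathway_size[2])
    if (pathway_size[2] > n_mrna)
      stop("pathway sizes infeasible: max size exceeds n_mrna")
    if (n_risk_pathways > n_pathways)
      stop("more planted risk pathways than pathways")
  })
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression model (log2 scale, then exponentiated to linear): a
#' differential feature in module `m` has value
#' `mu + s*(effect/2)*pheno + s*h_m + noise`, where `pheno` is +1 in tumor
#' and -1 in normal, `h_m` is the module's shared latent factor and `s` is
#' +1 for mRNAs and -1 for miRNAs (planting negative miRNA-target
#' correlations). The factor variance is solved so that within-module
#' pairwise correlation matches `within_module_rho`. Non-differential
#' features are baseline plus noise.
#'
#' Planted structure: `n_risk_pathways` pathways draw ~70% of their members
#' from the differential mRNAs; each differential miRNA gets 5 target mRNAs
#' inside a "home" planted pathway plus 1 in another planted pathway; PPI
#' bridge edges connect differential members of every planted pathway pair.
#' Drugs: `drug_synA`/`drug_synB` split the first pathway-miRNA's home
#' target set (their union orphans it, the cascade superadditivity
#' mechanism); `drug_addC`/`drug_addD` hit bridge endpoints chosen so the
#' two drugs share no interacting pair (exact additivity); remaining drugs
#' get single bridge targets; `drug_null` targets pathway-free mRNAs.
#' Survival times are exponential with log-hazard proportional to the
#' latent risk score of the combo-target signature, with uniform censoring.
#'
#' @param config a [synthetic_config()].
#' @return list of class `SyntheticCohort` with elements `bundle`
#'   (`ExpressionBundle`), `network` (`InteractionNetwork`), `pathways`
#'   (named list of `PathwayGraph`), `drug_map` (`DrugTargetMap`), `surv`
#'   (`SurvivalTable`) and `truth` (list: `differential`, `modules` (named
#'   integer vector), `risk_pathways`, `superadditive_pair`, `additive_pair`,
#'   `strong_drug`, `cascade_mirna`, `signature_features`,
#'   `planted_negative_edges`, `latent_risk`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  cf <- config
  # sample() treats a length-1 vector as 1:n; always index explicitly
  ssample <- function(x, size = length(x), replace = FALSE, prob = NULL)
    x[sample.int(length(x), size, replace = replace, prob = prob)]
  mrna_ids <- sprintf("gene%04d", seq_len(cf$n_mrna))
  mirna_ids <- sprintf("hsa-mir-%03d", seq_len(cf$n_mirna))
  samples <- c(sprintf("T%03d", seq_len(cf$n_tumor)),
               sprintf("N%03d", seq_len(cf$n_normal)))
  phenotype <- stats::setNames(rep(c("tumor", "normal"),
                                   c(cf$n_tumor, cf$n_normal)), samples)
  pm <- ifelse(phenotype == "tumor", 1, -1)

  ## planted differential features and module membership
  n_dm <- round(cf$frac_differential * cf$n_mrna)
  n_dmi <- round(cf$frac_differential * cf$n_mirna)
  diff_mrna <- sort(ssample(mrna_ids, n_dm))
  diff_mirna <- sort(ssample(mirna_ids, n_dmi))
  diff_all <- c(diff_mrna, diff_mirna)
  modules <- integer(0)
  if (length(diff_all) >= cf$n_modules)
    modules <- stats::setNames(rep_len(seq_len(cf$n_modules), length(diff_all)),
                               ssample(diff_all))

  ## latent-factor variance solved from the within-module correlation target
  q <- (cf$effect_log2fc / 2)^2
  s2 <- cf$within_module_rho * cf$noise_sd^2 / (1 - cf$within_module_rho) - q
  if (s2 < 0) {
    warning("within_module_rho below the correlation induced by the ",
            "phenotype effect alone; module factor variance floored at 0")
    s2 <- 0
  }
  h <- matrix(stats::rnorm(cf$n_modules * length(samples), 0, sqrt(s2)),
              nrow = cf$n_modules)

  sim_matrix <- function(ids, diff_ids, sgn, mu_range) {
    mu <- stats::runif(length(ids), mu_range[1], mu_range[2])
    m <- matrix(stats::rnorm(length(ids) * length(samples), 0, cf$noise_sd),
                nrow = length(ids), dimnames = list(ids, samples))
    m <- m + mu
    for (f in intersect(ids, diff_ids)) {
      mod <- modules[[f]]
      m[f, ] <- m[f, ] + sgn * (cf$effect_log2fc / 2) * pm + sgn * h[mod, ]
    }
    m
  }
  log2_mrna <- sim_matrix(mrna_ids, diff_mrna, +1, c(4, 10))
  log2_mirna <- sim_matrix(mirna_ids, diff_mirna, -1, c(2, 8))
  bundle <- expression_bundle(2^log2_mrna, 2^log2_mirna, phenotype)

  ## pathways: planted risk pathways sample ~70% from the differential pool,
  ## preferentially from one "dominant" co-expression module each (pathways
  ## and modules overlap, as in real cohorts where a dysregulated program
  ## spans a pathway)
  nondiff_mrna <- setdiff(mrna_ids, diff_mrna)
  path_ids <- sprintf("path%02d", seq_len(cf$n_pathways))
  planted <- if (n_dm > 0) path_ids[seq_len(cf$n_risk_pathways)] else character(0)
  dom_module <- stats::setNames(rep_len(seq_len(cf$n_modules),
                                        length(planted)), planted)
  sizes <- ssample(seq(cf$pathway_size[1], cf$pathway_size[2]),
                  cf$n_pathways, replace = TRUE)
  mod_mrnas <- if (length(modules)) {
    mm <- intersect(names(modules), mrna_ids)
    split(mm, modules[mm])
  } else list()
  pathways <- list()
  for (i in seq_len(cf$n_pathways)) {
    if (path_ids[i] %in% planted) {
      k_risk <- min(round(0.7 * sizes[i]), n_dm)
      dom_pool <- mod_mrnas[[as.character(dom_module[path_ids[i]])]]
      k_dom <- min(ceiling(0.6 * k_risk), length(dom_pool))
      dom_members <- ssample(dom_pool, k_dom)
      members <- c(dom_members,
                   ssample(setdiff(diff_mrna, dom_members), k_risk - k_dom),
                   ssample(nondiff_mrna, sizes[i] - k_risk))
    } else {
      members <- ssample(nondiff_mrna, min(sizes[i], length(nondiff_mrna)))
    }
    pathways[[path_ids[i]]] <- pathway_graph(path_ids[i],
                                             paste("pathway", i), members)
  }

  ## miRNA targets: each differential miRNA is homed in the planted pathway
  ## whose dominant module matches its own and targets 5 same-module mRNAs
  ## there (strong planted negative correlations), plus one away-pathway
  ## target; non-differential miRNAs get random targets
  mt_edges <- NULL
  home_targets <- list()
  home_path <- character(0)
  if (n_dmi > 0 && length(planted) >= 2) {
    for (i in seq_len(n_dmi)) {
      mi <- diff_mirna[i]
      matching <- planted[dom_module[planted] == modules[[mi]]]
      home <- if (length(matching)) matching[1L] else
        planted[(i - 1L) %% length(planted) + 1L]
      cand <- intersect(pathways[[home]]$mrna_nodes, diff_mrna)
      cand_same <- cand[modules[cand] == modules[[mi]]]
      tg_home <- ssample(cand_same, min(5L, length(cand_same)))
      if (length(tg_home) < 5L)
        tg_home <- c(tg_home, ssample(setdiff(cand, tg_home),
                                      min(5L - length(tg_home),
                                          length(setdiff(cand, tg_home)))))
      # the first (cascade) miRNA reaches into every other planted pathway,
      # so orphaning it severs several cross-pathway interactions
      aways <- if (i == 1L) setdiff(planted, home) else
        ssample(setdiff(planted, home), 1L)
      tg_away <- character(0)
      for (aw in aways) {
        # away targets must not belong to the home pathway, or they would
        # enlarge the miRNA's in-home target set beyond the planted one
        cand_away <- setdiff(intersect(pathways[[aw]]$mrna_nodes, diff_mrna),
                             c(tg_home, tg_away, pathways[[home]]$mrna_nodes))
        if (length(cand_away)) tg_away <- c(tg_away, ssample(cand_away, 1L))
      }
      home_targets[[mi]] <- tg_home
      home_path[mi] <- home
      mt_edges <- rbind(mt_edges, cbind(mi, c(tg_home, tg_away)))
    }
  }
  for (mi in setdiff(mirna_ids, diff_mirna))
    mt_edges <- rbind(mt_edges, cbind(mi, ssample(mrna_ids, 5L)))

  ## drug target design (before PPI so bridge edges can avoid the additive
  ## pair's cross edges)
  drug_list <- list()
  truth_syn <- NULL; truth_add <- NULL; cascade_mi <- NULL
  aC <- aD <- character(0)
  # cascade candidate: a pathway miRNA with >= 4 home targets from its own
  # module (a coherent signature for the survival stage)
  cascade_cand <- names(home_targets)[vapply(names(home_targets), function(mi)
    length(home_targets[[mi]]) >= 4 &&
      sum(modules[home_targets[[mi]]] == modules[[mi]]) >= 4, logical(1))]
  can_plant <- cf$planted_synergy_pairs > 0 && n_dmi > 0 &&
    length(planted) >= 4 && length(cascade_cand) > 0
  # competitor drugs draw from "quiet" members: differential mRNAs sitting
  # in exactly one planted pathway, away from the cascade miRNA's targets,
  # so their destruction scores stay clearly below the planted pair's
  planted_membership <- table(unlist(lapply(pathways[planted], `[[`,
                                            "mrna_nodes")))
  single_members <- names(planted_membership)[planted_membership == 1L]
  mi_away <- if (!is.null(mt_edges))
    setdiff(mt_edges[mt_edges[, 1L] %in% diff_mirna, 2L],
            unlist(home_targets)) else character(0)
  quiet_pool <- function(pw, exclude) {
    setdiff(intersect(intersect(pathways[[pw]]$mrna_nodes, diff_mrna),
                      single_members),
            c(exclude, mi_away))
  }
  if (can_plant) {
    cascade_mi <- cascade_cand[1L]
    tg <- home_targets[[cascade_mi]]
    k_split <- ceiling(length(tg) / 2)
    drug_list[["drug_synA"]] <- list(mrna_targets = tg[seq_len(k_split)])
    drug_list[["drug_synB"]] <- list(mrna_targets = tg[-seq_len(k_split)])
    truth_syn <- c("drug_synA", "drug_synB")
    p2 <- setdiff(planted, home_path[cascade_mi])[1:2]
    poolC <- quiet_pool(p2[1L], tg)
    poolD <- setdiff(quiet_pool(p2[2L], tg), poolC)
    aC <- ssample(poolC, min(1L, length(poolC)))
    aD <- ssample(poolD, min(1L, length(poolD)))
    if (length(aC) && length(aD)) {
      drug_list[["drug_addC"]] <- list(mrna_targets = aC)
      drug_list[["drug_addD"]] <- list(mrna_targets = aD)
      truth_add <- c("drug_addC", "drug_addD")
    }
  }
  n_extra <- cf$n_drugs - length(drug_list) - 1L
  if (n_extra > 0 && n_dm > 0 && length(planted)) {
    taken <- unique(unlist(lapply(drug_list, `[[`, "mrna_targets")))
    for (k in seq_len(n_extra)) {
      pw <- planted[(k - 1L) %% length(planted) + 1L]
      pool <- quiet_pool(pw, taken)
      id <- sprintf("drug_mod%d", k)
      if (length(pool)) {
        tgt <- ssample(pool, 1L)
        taken <- c(taken, tgt)
        drug_list[[id]] <- list(mrna_targets = tgt)
      } else {
        drug_list[[id]] <- list(mrna_targets = ssample(diff_mrna, 1L))
      }
      # one moderate drug also silences a pathway miRNA directly
      if (k == 1L && n_dmi >= 2L)
        drug_list[[id]]$mirna_targets <- setdiff(diff_mirna, cascade_mi)[1L]
    }
  }
  free_mrna <- setdiff(mrna_ids, unlist(lapply(pathways, `[[`, "mrna_nodes")))
  if (length(free_mrna) >= 2L) {
    drug_list[["drug_null"]] <- list(mrna_targets = ssample(free_mrna, 2L))
  } else {
    drug_list[["drug_null"]] <- list(mrna_targets = ssample(nondiff_mrna, 2L))
  }
  while (length(drug_list) < cf$n_drugs)
    drug_list[[sprintf("drug_fill%d", length(drug_list))]] <-
      list(mrna_targets = ssample(mrna_ids, 2L))
  drug_map <- drug_target_map(drug_list)

  ## PPI: bridges between planted pathway pairs + random background;
  ## bridge endpoints favor the cascade miRNA's home targets (making the
  ## drugs that split that set the strongest), and edges joining the
  ## additive pair's two target sets are excluded so that pair shares no
  ## interacting pair
  # no PPI edges inside the cascade target set either: such an edge would be
  # a pair destroyed by both halves of the planted combination, making the
  # split of that set sub- rather than super-additive
  tstar <- if (!is.null(cascade_mi)) home_targets[[cascade_mi]] else character(0)
  forbidden <- function(a, b)
    (a %in% aC & b %in% aD) | (a %in% aD & b %in% aC) |
    (a %in% tstar & b %in% tstar)
  ppi <- NULL
  if (length(planted) >= 2) {
    pairs <- utils::combn(planted, 2L)
    for (k in seq_len(ncol(pairs))) {
      ma <- intersect(pathways[[pairs[1L, k]]]$mrna_nodes, diff_mrna)
      mb <- intersect(pathways[[pairs[2L, k]]]$mrna_nodes, diff_mrna)
      if (!length(ma) || !length(mb)) next
      wa <- ifelse(ma %in% tstar, 4, 1)
      wb <- ifelse(mb %in% tstar, 4, 1)
      a <- ssample(ma, cf$n_bridge_edges, replace = TRUE, prob = wa)
      b <- ssample(mb, cf$n_bridge_edges, replace = TRUE, prob = wb)
      keep <- a != b & !forbidden(a, b)
      ppi <- rbind(ppi, cbind(a[keep], b[keep]))
    }
  }
  bg_a <- ssample(mrna_ids, cf$n_ppi_background, replace = TRUE)
  bg_b <- ssample(mrna_ids, cf$n_ppi_background, replace = TRUE)
  keep <- bg_a != bg_b & !forbidden(bg_a, bg_b)
  ppi <- rbind(ppi, cbind(bg_a[keep], bg_b[keep]))
  network <- suppressWarnings(interaction_network(ppi, mt_edges))

  ## survival: exponential with log-hazard on the combo-signature risk score
  tumor_samples <- samples[phenotype == "tumor"]
  signature <- unique(c(unlist(lapply(drug_list[truth_syn], `[[`,
                                      "mrna_targets")), cascade_mi))
  if (length(signature) == 0L) signature <- diff_all
  if (length(signature) == 0L) signature <- mrna_ids[1:5]
  logm <- rbind(log2_mrna, log2_mirna)[signature, tumor_samples, drop = FALSE]
  sgn <- ifelse(signature %in% mirna_ids, -1, 1)
  z <- colMeans(sgn * t(scale(t(logm))))
  z[!is.finite(z)] <- 0
  rate <- log(2) / 730 * exp(cf$survival_beta * z)
  t_true <- stats::rexp(length(tumor_samples), rate)
  cens <- stats::runif(length(tumor_samples), 200, 2500)
  surv <- survival_table(tumor_samples, pmin(t_true, cens),
                         as.integer(t_true <= cens))

  truth <- list(
    differential = diff_all,
    differential_mrna = diff_mrna,
    differential_mirna = diff_mirna,
    modules = modules,
    risk_pathways = planted,
    superadditive_pair = truth_syn,
    additive_pair = truth_add,
    strong_drug = if (!is.null(truth_syn)) "drug_synA" else NULL,
    null_drug = "drug_null",
    cascade_mirna = cascade_mi,
    signature_features = signature,
    planted_negative_edges = if (!is.null(mt_edges)) {
      sel <- mt_edges[, 1L] %in% diff_mirna & mt_edges[, 2L] %in% diff_mrna
      unname(mt_edges[sel, , drop = FALSE])
    } else NULL,
    latent_risk = stats::setNames(z, tumor_samples))
  structure(list(bundle = bundle, network = network, pathways = pathways,
                 drug_map = drug_map, surv = surv, truth = truth,
                 config = config),
            class = "SyntheticCohort")
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `mrna.tsv`, `mirna.tsv`, `phenotype.tsv`, `pathways.gmt`,
#' `ppi.tsv`, `mirna_targets.tsv`, `drug_targets.tsv`, `survival.tsv` and
#' `ground_truth.json` into `outdir` (created if absent).
#'
#' @param cohort a `SyntheticCohort` from [generate_cohort()].
#' @param outdir output directory.
#' @return invisibly, the named vector of written file paths.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(mrna = file.path(outdir, "mrna.tsv"),
             mirna = file.path(outdir, "mirna.tsv"),
             phenotype = file.path(outdir, "phenotype.tsv"),
             pathways = file.path(outdir, "pathways.gmt"),
             ppi = file.path(outdir, "ppi.tsv"),
             mirna_targets = file.path(outdir, "mirna_targets.tsv"),
             drug_targets = file.path(outdir, "drug_targets.tsv"),
             survival = file.path(outdir, "survival.tsv"),
             ground_truth = file.path(outdir, "ground_truth.json"))
  write_matrix_tsv(cohort$bundle$mrna, paths["mrna"])
  write_matrix_tsv(cohort$bundle$mirna, paths["mirna"])
  utils::write.table(data.frame(sample = names(cohort$bundle$phenotype),
                                label = cohort$bundle$phenotype),
                     paths["phenotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gmt(cohort$pathways, paths["pathways"])
  write_edges(cohort$network$ppi, paths["ppi"])
  write_edges(cohort$network$mirna_targets, paths["mirna_targets"])
  write_drug_targets(cohort$drug_map, paths["drug_targets"])
  write_survival(cohort$surv, paths["survival"])
  truth <- cohort$truth
  truth$planted_negative_edges <- if (!is.null(truth$planted_negative_edges))
    apply(truth$planted_negative_edges, 1L, paste, collapse = "|")
  jsonlite::write_json(truth, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
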