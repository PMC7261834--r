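## End-to-end analysis pipeline: diversity -> differentiation -> admixture
## -> bottleneck -> ABC -> core collection, driven by one config.

pipeline_defaults <- function() {
  list(
    diversity = list(n_perm = 100L, rarefaction = "auto"),
    differentiation = list(n_perm = 100L, bootstrap = 100L),
    structure = list(k_values = 1:6, n_runs = 3L, burn_in = 500L,
                     iterations = 2000L, thinning = 5L, q_star = 0.8,
                     model = "independent", n_orders = 20L),
    bottleneck = list(enabled = TRUE, models = c("iam", "smm", "tpm"),
                      n_iter = 200L, tpm_single = 0.95, tpm_var = 12),
    abc = list(enabled = FALSE, n_sims = 500L, accept_rate = 0.05,
               n_loci = 25L, n_per_pop = 20L, theta = 5),
    core = list(enabled = TRUE))
}

#' Validate a pipeline configuration
#'
#' A config is a named list (or a YAML file with the same structure) with
#' an `input` block (`genotypes` + `dialect`, or `preset: worldwide`), an
#' `output_dir`, a `seeds` block with one explicit integer seed per
#' stochastic stage (`diversity`, `differentiation`, `structure`,
#' `bottleneck`, `abc` when enabled), and optional per-stage parameter
#' blocks merged over the package defaults.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The completed config list (invisibly usable by
#'   [run_pipeline()]); errors before any computation when a referenced
#'   path does not exist or a required seed is missing.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$input))
    stop("config validation: missing 'input' block")
  if (is.null(config$input$preset)) {
    if (is.null(config$input$genotypes))
      stop("config validation: input needs 'genotypes' path or 'preset'")
    if (!file.exists(config$input$genotypes))
      stop("config validation: genotype file not found: ",
           config$input$genotypes)
  }
  if (is.null(config$output_dir))
    stop("config validation: missing 'output_dir'")
  defs <- pipeline_defaults()
  for (blk in names(defs)) {
    user <- if (is.null(config[[blk]])) list() else config[[blk]]
    merged <- defs[[blk]]
    merged[names(user)] <- user
    config[[blk]] <- merged
  }
  needed <- c("diversity", "differentiation", "structure", "bottleneck")
  if (isTRUE(config$abc$enabled)) needed <- c(needed, "abc")
  if (isTRUE(config$input$preset == "worldwide")) needed <- c(needed, "simulate")
  for (s in needed)
    if (is.null(config$seeds[[s]]))
      stop("config validation: missing seed for stage '", s, "'")
  config
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- diversity, differentiation, admixture
#' clustering, bottleneck tests per inferred cluster, optional ABC
#' demographic inference, and core-collection selection -- with
#' inter-stage handoff: consensus cluster assignments at the K with the
#' highest interior delta-K feed the per-cluster stages, with "admixed"
#' individuals excluded from per-cluster statistics.  Every output file
#' lands under `output_dir`; `run_info.tsv` records the config hash and
#' seeds, so a rerun with an identical config reproduces the outputs.
#'
#' @param config Path to a YAML config or a named list (see
#'   [validate_pipeline_config()]).
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## input ------------------------------------------------------------------
  inp <- stage("input", {
    if (!is.null(cfg$input$preset)) {
      if (cfg$input$preset != "worldwide")
        stop("unknown preset: ", cfg$input$preset)
      pre <- worldwide_preset(seed = cfg$seeds$simulate)
      list(g = pre$genotypes, p = pre$groups)
    } else {
      rd <- read_genotype_table(cfg$input$genotypes,
                                dialect = cfg$input$dialect %||% "csv")
      list(g = rd$genotypes, p = rd$partition)
    }
  })
  g <- inp$g; grp <- inp$p
  cfg_file <- file.path(cfg$output_dir, "config_used.yaml")
  yaml::write_yaml(cfg, cfg_file)
  write_tsv(data.frame(key = c("config_md5", names(cfg$seeds)),
                       value = c(unname(tools::md5sum(cfg_file)),
                                 unlist(cfg$seeds))),
            file.path(cfg$output_dir, "run_info.tsv"))
  res <- list()
  ## diversity ---------------------------------------------------------------
  res$diversity <- stage("diversity", {
    ls <- locus_summary(g, rarefaction_g = cfg$diversity$rarefaction,
                        n_perm = cfg$diversity$n_perm,
                        seed = cfg$seeds$diversity)
    write_tsv(ls, file.path(cfg$output_dir, "locus_summary.tsv"))
    if (!is.null(grp)) {
      gs <- group_summary(g, grp, n_perm = cfg$diversity$n_perm,
                          seed = cfg$seeds$diversity)
      write_tsv(gs, file.path(cfg$output_dir, "group_summary.tsv"))
    } else gs <- NULL
    list(locus = ls, group = gs)
  })
  ## differentiation ---------------------------------------------------------
  res$differentiation <- stage("differentiation", {
    if (is.null(grp)) return(NULL)
    fst <- pairwise_fst(g, grp, n_perm = cfg$differentiation$n_perm,
                        seed = cfg$seeds$differentiation)
    nei <- nei_distance(g, grp)
    am <- amova(g, grp, n_perm = cfg$differentiation$n_perm,
                seed = cfg$seeds$differentiation)
    write_tsv(as.data.frame(fst$fst), file.path(cfg$output_dir, "fst.tsv"))
    write_tsv(as.data.frame(nei), file.path(cfg$output_dir, "nei.tsv"))
    write_tsv(am$table, file.path(cfg$output_dir, "amova_groups.tsv"))
    tr <- NULL
    if (nlevels(grp) >= 3L) {
      tr <- nj_tree(nei,
                    boot_fun = function(idx)
                      nei_distance(gm_subset(g, loci = idx), grp),
                    n_loci_boot = n_loci(g),
                    B = cfg$differentiation$bootstrap,
                    seed = cfg$seeds$differentiation)
      writeLines(tr$newick, file.path(cfg$output_dir, "groups_nei_nj.nwk"))
    }
    list(fst = fst, nei = nei, amova = am, tree = tr)
  })
  ## admixture ---------------------------------------------------------------
  res$structure <- stage("structure", {
    sc <- cfg$structure
    ens <- admixture_ensemble(g, k_values = sc$k_values, n_runs = sc$n_runs,
                              burn_in = sc$burn_in,
                              iterations = sc$iterations,
                              thinning = sc$thinning, model = sc$model,
                              n_orders = sc$n_orders,
                              seed = cfg$seeds$structure)
    write_tsv(ens$summary, file.path(cfg$output_dir, "structure_summary.tsv"))
    dk <- ens$summary$delta_k
    best_k <- if (all(is.na(dk))) max(sc$k_values)
    else ens$summary$K[which.max(dk)]
    qbar <- ens$consensus[[as.character(best_k)]]
    write_tsv(data.frame(id = rownames(qbar), qbar),
              file.path(cfg$output_dir, sprintf("consensus_Q_K%d.tsv", best_k)))
    asg <- assign_clusters(qbar, q_star = sc$q_star, p = grp)
    write_tsv(data.frame(id = names(asg$labels), label = asg$labels),
              file.path(cfg$output_dir, "cluster_assignment.tsv"))
    list(ensemble = ens, best_k = best_k, assignment = asg)
  })
  clus_lab <- res$structure$assignment$labels
  assigned <- clus_lab != "admixed"
  clus_part <- if (sum(assigned) >= 4L && length(unique(clus_lab[assigned])) >= 2L)
    partition(clus_lab[assigned], ids = names(clus_lab)[assigned]) else NULL
  ## per-cluster diversity + bottleneck ---------------------------------------
  if (!is.null(clus_part)) {
    res$cluster_diversity <- stage("cluster_diversity", {
      ga <- gm_subset(g, names(clus_part))
      gs <- group_summary(ga, clus_part, n_perm = cfg$diversity$n_perm,
                          seed = cfg$seeds$diversity)
      write_tsv(gs, file.path(cfg$output_dir, "cluster_summary.tsv"))
      gs
    })
    if (isTRUE(cfg$bottleneck$enabled))
      res$bottleneck <- stage("bottleneck", {
        ga <- gm_subset(g, names(clus_part))
        tpm <- tpm_params(cfg$bottleneck$tpm_single, cfg$bottleneck$tpm_var)
        cache <- new.env(parent = emptyenv())
        out <- list()
        set.seed(cfg$seeds$bottleneck)
        for (cl in levels(clus_part)) {
          for (mod in cfg$bottleneck$models) {
            rep <- tryCatch(
              heterozygosity_excess_test(ga, clus_part, group = cl,
                                         model = mod, tpm = tpm,
                                         n_iter = cfg$bottleneck$n_iter,
                                         heq_cache = cache),
              error = function(e) NULL)
            if (!is.null(rep))
              out[[paste(cl, mod, sep = ".")]] <-
                data.frame(cluster = cl, model = mod,
                           wilcoxon_p = rep$wilcoxon_p,
                           n_excess = rep$n_excess,
                           n_deficit = rep$n_deficit)
          }
          ms <- mode_shift(ga, clus_part, group = cl)
          out[[paste(cl, "mode_shift", sep = ".")]] <-
            data.frame(cluster = cl, model = "mode_shift",
                       wilcoxon_p = NA_real_,
                       n_excess = NA, n_deficit = NA,
                       shape = ms$shape)
        }
        tab <- do.call(rbind, lapply(out, function(d) {
          if (is.null(d$shape)) d$shape <- NA_character_
          d
        }))
        write_tsv(tab, file.path(cfg$output_dir, "bottleneck.tsv"))
        tab
      })
  }
  ## ABC ----------------------------------------------------------------------
  if (isTRUE(cfg$abc$enabled) && !is.null(clus_part) &&
      nlevels(clus_part) == 5L)
    res$abc <- stage("abc", {
      ga <- gm_subset(g, names(clus_part))
      obs <- summary_statistics(ga, clus_part)
      tmpl <- five_cluster_scenario(n_per_pop = cfg$abc$n_per_pop,
                                    theta = cfg$abc$theta)
      fit <- abc_fit(obs, tmpl,
                     n_sims = cfg$abc$n_sims,
                     accept_rate = cfg$abc$accept_rate,
                     n_loci = cfg$abc$n_loci, seed = cfg$seeds$abc)
      rep <- posterior_r_report(fit)
      write_tsv(rep, file.path(cfg$output_dir, "abc_report.tsv"))
      list(fit = fit, report = rep)
    })
  ## core ----------------------------------------------------------------------
  if (isTRUE(cfg$core$enabled))
    res$core <- stage("core", {
      core <- build_core(g)
      parts <- list()
      if (!is.null(grp)) parts$group <- grp
      rpt <- coverage_report(g, core, partitions = parts)
      writeLines(core$selected, file.path(cfg$output_dir, "core.txt"))
      write_tsv(data.frame(metric = c("coverage", "size", "size_fraction_pct"),
                           value = c(rpt$coverage, rpt$size,
                                     rpt$size_fraction_pct)),
                file.path(cfg$output_dir, "core_coverage.tsv"))
      list(core = core, report = rpt)
    })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
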