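# End-to-end pipeline orchestration: simulate (or load) -> diversity ->
# co-occurrence network -> assembly null models -> spatial drivers, with a
# JSON manifest that makes the run reproducible bit-for-bit.

#' Phylogeny-derived pseudo-taxonomy for synthetic metacommunities
#'
#' Cuts the ultrametric tree at fixed heights to define nested pseudo-ranks
#' (phylum, class, order) and splits the deepest bifurcation into two
#' guilds, so that synthetic data can exercise the order-level network
#' stage.
#'
#' @param tree ultrametric phylogeny.
#' @param n_orders approximate number of orders (default 15).
#' @return Taxonomy data frame: taxon, phylum, class, order, guild.
#' @export
synthetic_taxonomy <- function(tree, n_orders = 15L) {
  coph <- cophenetic(tree)
  hc <- stats::hclust(stats::as.dist(coph), method = "average")
  cut_k <- function(k) stats::cutree(hc, k = min(k, length(tree$tip.label)))
  ord <- cut_k(n_orders); cls <- cut_k(max(2, n_orders %/% 3))
  phy <- cut_k(max(2, n_orders %/% 6)); gld <- cut_k(2)
  data.frame(taxon = tree$tip.label,
             phylum = sprintf("Phylum%02d", phy[tree$tip.label]),
             class = sprintf("Class%02d", cls[tree$tip.label]),
             order = sprintf("Order%02d", ord[tree$tip.label]),
             guild = c("bacteria", "microeukaryote")[gld[tree$tip.label]],
             stringsAsFactors = FALSE)
}

#' Depth strata used by the stratified analyses
#'
#' Maps each sample to the photic-and-mesopelagic stratum (nominal depth
#' <= 200 m) or the deep stratum (> 500 m).
#'
#' @param frame sample metadata frame.
#' @return Named character vector, sample -> stratum.
#' @export
depth_strata <- function(frame) {
  dpt <- .layer_depths(levels(frame$depth_layer))[as.character(frame$depth_layer)]
  setNames(ifelse(dpt <= 200, "5-200m", ">500m"), frame$sample)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (or load real inputs),
#' diversity, network, assembly, drivers -- writing each stage's tables
#' under `out_dir` and a `manifest.json` capturing the configuration,
#' per-stage seeds and output listing. Stage seeds derive from
#' `config$seed` via [stage_seed()].
#'
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param scenario a [scenario_config()] to simulate inputs, or NULL to
#'   read real inputs from `config$paths` (`counts`, `tree`, `metadata`,
#'   and optionally `taxonomy`).
#' @param stages subset of stages to run (simulate/load always runs).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = run_config(), scenario = NULL,
                         stages = c("diversity", "network", "assembly",
                                    "drivers")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_log <- character()
  note <- function(w) { warnings_log <<- c(warnings_log, conditionMessage(w))
                        invokeRestart("muffleWarning") }
  if (!is.null(scenario)) {
    sim <- simulate_metacommunity(scenario, file.path(out_dir, "simulate"))
    counts <- sim$counts; tree <- sim$tree; frame <- sim$frame
    taxonomy <- synthetic_taxonomy(tree)
    write.table(taxonomy, file.path(out_dir, "simulate", "taxonomy.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    p <- config$paths
    need <- setdiff(c("counts", "tree", "metadata"), names(p))
    if (length(need)) stop("config$paths missing: ", paste(need, collapse = ", "))
    counts <- read_count_table(p$counts)
    tree <- read_newick(p$tree)
    frame <- read_sample_frame(p$metadata)
    taxonomy <- if (!is.null(p$taxonomy)) read_taxonomy(p$taxonomy) else NULL
  }
  missing_tips <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing_tips))
    stop(length(missing_tips), " taxa absent from the phylogeny; ",
         "a total tip mapping is required (e.g. ", missing_tips[1], ")")
  outputs <- list()
  withCallingHandlers({
    depth <- min(config$rarefaction_depth, max(colSums(counts)))
    rare <- rarefy(counts, depth, seed = stage_seed(config$seed, "diversity"))
    frame <- frame[frame$sample %in% colnames(rare), , drop = FALSE]
    if ("diversity" %in% stages) {
      alpha <- alpha_diversity(rare, tree)
      hel <- hellinger(rare)
      bc <- bray_curtis(hel)
      ordn <- pcoa(bc)
      layer <- setNames(as.character(frame$depth_layer), frame$sample)
      pairs <- combn(levels(frame$depth_layer), 2)
      wtab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
        la <- pairs[1, j]; lb <- pairs[2, j]
        do.call(rbind, lapply(c("shannon", "simpson", "pielou", "richness",
                                "faith_pd"), function(ix) {
          va <- alpha[[ix]][layer[alpha$sample] == la]
          vb <- alpha[[ix]][layer[alpha$sample] == lb]
          if (!length(va) || !length(vb)) return(NULL)
          wt <- wilcoxon_rank_sum(va[!is.na(va)], vb[!is.na(vb)])
          data.frame(layer_a = la, layer_b = lb, index = ix,
                     statistic = wt$statistic, p_value = wt$p_value)
        }))
      }))
      outputs$alpha_diversity <- alpha
      outputs$bray_curtis <- as.matrix(bc)
      outputs$pcoa_axes <- data.frame(sample = rownames(ordn$points),
                                      ordn$points[, seq_len(min(4, ncol(ordn$points))),
                                                  drop = FALSE])
      outputs$alpha_wilcoxon <- wtab
    }
    if ("network" %in% stages && !is.null(taxonomy)) {
      agg <- aggregate_to_order(rare, taxonomy)
      filt <- filter_mean_relabund(agg$abundance, 0.01)
      sp <- spearman_matrix(filt)
      net <- build_network(sp, config$rho_threshold, config$alpha,
                           mean_abundance = rowMeans(filt), guild = agg$guild)
      outputs$network_edges <- net$edges
      outputs$network_nodes <- net$nodes
    }
    if ("assembly" %in% stages) {
      asm <- assembly_analysis(rare, tree, n_null = config$n_null,
                               seed = stage_seed(config$seed, "assembly"),
                               strata = depth_strata(frame))
      outputs$assembly_pairs <- asm$pairs
      outputs$process_fractions <- asm$fractions %||%
        data.frame(stratum = character(0))
    }
    if ("drivers" %in% stages) {
      hel <- hellinger(rare)
      bc <- bray_curtis(hel)
      geo <- haversine_matrix(frame)
      sd0 <- stage_seed(config$seed, "drivers")
      dd <- distance_decay(bc, geo, n_perm = config$n_null, seed = sd0)
      envm <- scale(as.matrix(frame[, .ENV_COLS]))
      rownames(envm) <- frame$sample
      env_d <- dist(envm)
      mt <- mantel_test(bc, env_d, n_perm = config$n_null, seed = sd0 + 1L)
      perm <- lapply(c(depth = "depth_layer", station = "station",
                       section = "section"),
                     function(cl) if (length(unique(frame[[cl]])) > 1)
                       permanova(bc, setNames(frame[[cl]], frame$sample),
                                 n_perm = config$n_null, seed = sd0 + 2L))
      pc <- pcnm_axes(geo, n_axes = config$n_pcnm)
      vp <- if (nrow(envm) > ncol(envm) + ncol(pc$vectors) + 2) {
        variation_partitioning(t(hel), envm, pc$vectors)
      } else {
        warning("too few samples for variation partitioning; skipped")
        list(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_)
      }
      outputs$drivers_summary <- data.frame(
        analysis = c("distance_decay_r", "distance_decay_p",
                     "mantel_env_r", "mantel_env_p",
                     paste0("permanova_", names(perm), "_r2"),
                     paste0("permanova_", names(perm), "_p"),
                     "vpa_env_pure", "vpa_shared", "vpa_spatial_pure",
                     "vpa_unexplained"),
        value = c(dd$r, dd$p_value, mt$statistic, mt$p_value,
                  vapply(perm, function(x) if (is.null(x)) NA_real_ else x$r2, 1),
                  vapply(perm, function(x) if (is.null(x)) NA_real_ else x$p_value, 1),
                  vp$a, vp$b, vp$c, vp$d))
      outputs$pcnm_vectors <- data.frame(sample = rownames(pc$vectors),
                                         pc$vectors)
      if (!is.null(taxonomy)) {
        agg <- aggregate_to_order(rare, taxonomy)
        filt <- filter_mean_relabund(agg$abundance, 0.01)
        outputs$env_taxon_correlations <- env_taxon_correlations(filt, frame)
      }
    }
  }, warning = note)
  manifest <- write_results(outputs, out_dir, config, warnings = warnings_log)
  invisible(manifest)
}

#' Run the pipeline from a YAML configuration file
#'
#' The file may contain `run:` (fields of [run_config()]), `scenario:`
#' (fields of [scenario_config()]; omit to analyse real inputs), `paths:`
#' and `out_dir`. Values given in `...` override the file.
#'
#' @param path YAML configuration file.
#' @param ... overrides (e.g. `seed`, `out_dir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline_yaml <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  if (!is.null(dots$seed)) cfg$run$seed <- dots$seed
  if (!is.null(dots$out_dir)) cfg$out_dir <- dots$out_dir
  run <- do.call(run_config, c(cfg$run, list(paths = cfg$paths %||% list())))
  scen <- if (!is.null(cfg$scenario)) {
    if (!is.null(dots$seed)) cfg$scenario$seed <- dots$seed
    do.call(scenario_config, cfg$scenario)
  }
  run_pipeline(cfg$out_dir, config = run, scenario = scen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
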