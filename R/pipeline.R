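#' Build a validated pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' bacterial analysis conventions: six equal salinity-ordered groups, taxa
#' retained only when present in all of a group's samples, CLR + Pearson
#' with a uniform |r| threshold of 0.96, abundant/rare thresholds of 0.1 %
#' and 0.01 % mean relative abundance, and 999 Mantel permutations. The
#' at-least-half prevalence mode with threshold 0.83 reproduces the fungal
#' variant.
#'
#' @param rarefaction_depth Reads per sample; `NULL` rarefies to the
#'   smallest sample total.
#' @param n_groups Number of salinity-ordered groups.
#' @param group_remainder `"fail"` or `"trim"` (see
#'   [assign_salinity_groups()]).
#' @param min_prevalence Within-group prevalence fraction in (0, 1].
#' @param threshold Uniform correlation threshold in (0, 1].
#' @param abundant_min,rare_max Biosphere thresholds (fractions).
#' @param pseudocount CLR pseudocount (`NULL` = automatic).
#' @param removal_fractions,removal_replicates Node-removal design.
#' @param mantel_permutations Permutations for the Mantel test.
#' @param mantel_variables Metadata columns defining environmental
#'   distance.
#' @param rf_iterations,rf_ntree,rf_cv_folds,rf_cv_repeats,rf_ns
#'   Random-forest biomarker settings.
#' @param colonizer_alpha Significance level for colonizer labels.
#' @param similarity_mode `"abundance"` or `"presence"` for community
#'   turnover.
#' @param stages Character vector of stages to run, a subset of
#'   `c("prep", "gradient", "biomarkers", "networks", "stability",
#'   "turnover", "roles")`.
#' @param seed Root seed; all stage seeds derive from it via
#'   [derive_seed()].
#' @param out_dir Output directory for stage reports.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(rarefaction_depth = NULL,
                            n_groups = 6,
                            group_remainder = "fail",
                            min_prevalence = 1,
                            threshold = 0.96,
                            abundant_min = 0.001,
                            rare_max = 0.0001,
                            pseudocount = NULL,
                            removal_fractions = seq(0.05, 0.5, by = 0.05),
                            removal_replicates = 100,
                            mantel_permutations = 999,
                            mantel_variables = "salinity",
                            rf_iterations = 1000,
                            rf_ntree = 500,
                            rf_cv_folds = 10,
                            rf_cv_repeats = 5,
                            rf_ns = NULL,
                            colonizer_alpha = 0.05,
                            similarity_mode = "abundance",
                            stages = c("prep", "gradient", "biomarkers",
                                       "networks", "stability", "turnover",
                                       "roles"),
                            seed = 1,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!is.null(rarefaction_depth) &&
        (rarefaction_depth <= 0 || rarefaction_depth != round(rarefaction_depth)))
      stop("rarefaction_depth must be a positive count")
    if (n_groups < 1) stop("n_groups must be >= 1")
    if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
    if (min_prevalence <= 0 || min_prevalence > 1)
      stop("min_prevalence must lie in (0, 1]")
    if (abundant_min <= rare_max || rare_max <= 0)
      stop("abundance thresholds must satisfy abundant_min > rare_max > 0")
    if (any(removal_fractions < 0 | removal_fractions >= 1))
      stop("removal_fractions must lie in [0, 1)")
    if (removal_replicates < 1) stop("removal_replicates must be >= 1")
    if (mantel_permutations < 1) stop("mantel_permutations must be >= 1")
    if (colonizer_alpha <= 0 || colonizer_alpha >= 1)
      stop("colonizer_alpha must lie in (0, 1)")
    if (!similarity_mode %in% c("abundance", "presence"))
      stop("similarity_mode must be \"abundance\" or \"presence\"")
    bad <- setdiff(stages, c("prep", "gradient", "biomarkers", "networks",
                             "stability", "turnover", "roles"))
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    if (!is.numeric(seed) || length(seed) != 1)
      stop("seed must be a single number")
  })
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [pipeline_config()] arguments and
#' merges it over the defaults; `overrides` (named values) win over the
#' file.
#'
#' @param path YAML file.
#' @param ... Named overrides.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

write_report <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  if (grepl("\\.csv$", name)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

trend_row <- function(name, tr) {
  data.frame(quantity = name, slope = tr$slope, intercept = tr$intercept,
             r_squared = tr$r_squared, p_value = tr$p_value, n = tr$n,
             stringsAsFactors = FALSE)
}

#' Run the full gradient-network analysis
#'
#' Orchestrates the stages end to end: rarefaction and biosphere
#' classification, salinity-ordered grouping, gradient statistics
#' (alpha-diversity trends and the Mantel test of community versus
#' environmental distance), random-forest biomarker discovery, per-group
#' network construction and topology, node-removal stability, network
#' community turnover, and biosphere role trends (relative degree,
#' Freeman's theta, Levins niche breadth). Stage reports are written as
#' CSV/JSON under `config$out_dir` (when set) together with a provenance
#' record; outputs are deterministic functions of the inputs and
#' `config$seed`.
#'
#' @param table Taxa-by-samples count matrix (or a path to a TSV readable
#'   by [read_abundance_tsv()]).
#' @param meta Sample metadata data frame (or a TSV path) with `sample_id`
#'   and `salinity`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(table, meta, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  if (is.character(table)) table <- read_abundance_tsv(table)
  if (is.character(meta)) meta <- read_metadata_tsv(meta)
  check_abundance(table)
  if (!all(colnames(table) %in% meta$sample_id))
    stop("metadata is missing sample(s) present in the table")
  meta <- meta[match(colnames(table), meta$sample_id), ]
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = config)

  ## --- prep -------------------------------------------------------------
  depth <- config$rarefaction_depth %||% min(colSums(table))
  rar <- rarefy(table, depth, seed = derive_seed(config$seed, "rarefy"))
  tab <- rar$table
  meta <- meta[meta$sample_id %in% colnames(tab), ]
  classes <- classify_abundance(tab, config$abundant_min, config$rare_max)
  groups <- assign_salinity_groups(meta, config$n_groups,
                                   remainder = config$group_remainder)
  out$prep <- list(depth = depth, dropped = rar$dropped,
                   class_counts = as.list(table(classes)),
                   groups = groups)
  if ("prep" %in% config$stages) {
    write_report(data.frame(class = names(table(classes)),
                            n_taxa = as.integer(table(classes))),
                 dir, "prep_classes.csv")
    write_report(groups$groups, dir, "prep_groups.csv")
    write_report(rar$dropped, dir, "prep_dropped_samples.csv")
  }

  ## --- gradient statistics ---------------------------------------------
  if ("gradient" %in% config$stages) {
    rich <- alpha_diversity(tab, "richness")
    shan <- alpha_diversity(tab, "shannon")
    sal <- meta$salinity[match(colnames(tab), meta$sample_id)]
    trends <- rbind(trend_row("richness_vs_salinity",
                              linear_trend(sal, rich)),
                    trend_row("shannon_vs_salinity",
                              linear_trend(sal, shan)))
    mt <- mantel_test(community_distance(tab),
                      environment_distance(meta, config$mantel_variables),
                      n_perm = config$mantel_permutations,
                      seed = derive_seed(config$seed, "mantel"))
    geo <- NULL
    if (all(c("latitude", "longitude", "transect") %in% names(meta))) {
      geo <- do.call(rbind, lapply(split(meta, meta$transect), function(m) {
        gc <- geo_env_correlation(m, "salinity")
        data.frame(transect = m$transect[1], r = gc$r,
                   p_value = gc$p_value, n_pairs = gc$n_pairs)
      }))
      rownames(geo) <- NULL
    }
    out$gradient <- list(alpha = data.frame(sample_id = colnames(tab),
                                            salinity = sal,
                                            richness = unname(rich),
                                            shannon = unname(shan)),
                         trends = trends, mantel = unclass(mt),
                         geo_env = geo)
    write_report(out$gradient$alpha, dir, "gradient_alpha.csv")
    write_report(trends, dir, "gradient_trends.csv")
    write_report(unclass(mt), dir, "gradient_mantel.json")
    if (!is.null(geo)) write_report(geo, dir, "gradient_geo_env.csv")
  }

  ## --- biomarkers -------------------------------------------------------
  if ("biomarkers" %in% config$stages) {
    feats <- t(rel_abundance(tab))
    sal <- meta$salinity[match(rownames(feats), meta$sample_id)]
    ranked <- rank_biomarkers(feats, sal,
                              n_iterations = config$rf_iterations,
                              ntree = config$rf_ntree,
                              seed = derive_seed(config$seed, "rf_rank"))
    sel <- select_biomarker_count(feats, sal, ranked,
                                  folds = config$rf_cv_folds,
                                  repeats = config$rf_cv_repeats,
                                  ntree = config$rf_ntree,
                                  ns = config$rf_ns,
                                  seed = derive_seed(config$seed, "rf_cv"))
    markers <- ranked$taxon[seq_len(sel$selected_n)]
    colonizers <- classify_colonizers(feats, sal, markers,
                                      alpha = config$colonizer_alpha)
    out$biomarkers <- list(ranking = ranked, cv = sel,
                           colonizers = colonizers)
    write_report(ranked, dir, "biomarker_ranking.csv")
    write_report(sel$cv_error_curve, dir, "biomarker_cv_curve.csv")
    write_report(data.frame(taxon = names(colonizers),
                            colonizer = unname(colonizers)),
                 dir, "biomarker_colonizers.csv")
  }

  ## --- networks ----------------------------------------------------------
  need_networks <- any(c("networks", "stability", "turnover", "roles") %in%
                         config$stages)
  if (need_networks) {
    nets <- list()
    communities <- list()
    for (i in seq_len(nrow(groups$groups))) {
      gid <- groups$groups$group[i]
      ids <- groups$assignment$sample_id[groups$assignment$group == gid]
      sub <- prevalence_filter(tab, ids, config$min_prevalence)
      if (nrow(sub) < 2) stop(sprintf("group %s retains < 2 taxa", gid))
      clr <- clr_transform(sub, config$pseudocount)
      nets[[gid]] <- build_network(clr, threshold = config$threshold,
                                   group_salinity =
                                     groups$groups$mean_salinity[i],
                                   group_id = gid)
      ab <- rowMeans(rel_abundance(tab[, ids, drop = FALSE]))
      communities[[gid]] <- network_community(nets[[gid]], classes, ab)
    }
    topo <- do.call(rbind, lapply(nets, topology))
    topo <- cbind(group = names(nets),
                  mean_salinity = groups$groups$mean_salinity, topo)
    rownames(topo) <- NULL
    topo_trends <- do.call(rbind, lapply(
      c("n_nodes", "n_links", "avg_degree", "avg_clustering", "density",
        "connectedness", "modularity", "n_modules"),
      function(m) trend_row(paste0(m, "_vs_salinity"),
                            linear_trend(topo$mean_salinity, topo[[m]]))))
    out$networks <- list(networks = nets, topology = topo,
                         trends = topo_trends)
    if ("networks" %in% config$stages) {
      write_report(topo, dir, "network_topology.csv")
      write_report(topo_trends, dir, "network_trends.csv")
      if (!is.null(dir))
        for (gid in names(nets))
          write_network(nets[[gid]],
                        file.path(dir, sprintf("network_%s.graphml", gid)),
                        format = "graphml")
    }
  }

  ## --- stability ----------------------------------------------------------
  if ("stability" %in% config$stages) {
    rob <- lapply(names(nets), function(gid)
      removal_simulation(nets[[gid]], fractions = config$removal_fractions,
                         n_replicates = config$removal_replicates,
                         seed = derive_seed(config$seed,
                                            paste0("removal_", gid))))
    names(rob) <- names(nets)
    sal <- groups$groups$mean_salinity
    stab_trends <- do.call(rbind, unlist(lapply(config$removal_fractions,
      function(p) lapply(c("natural_connectivity", "avg_degree"),
        function(ix) trend_row(sprintf("%s_at_p%.2f_vs_salinity", ix, p),
                               stability_trend(rob, sal, p, ix)))),
      recursive = FALSE))
    rob_summary <- do.call(rbind, Map(function(gid, r)
      cbind(group = gid, r$summary), names(rob), rob))
    rownames(rob_summary) <- NULL
    out$stability <- list(robustness = rob, summary = rob_summary,
                          trends = stab_trends)
    write_report(rob_summary, dir, "stability_summary.csv")
    write_report(stab_trends, dir, "stability_trends.csv")
  }

  ## --- turnover -----------------------------------------------------------
  if ("turnover" %in% config$stages) {
    adj <- lapply(seq_len(length(communities) - 1), function(i) {
      ov <- community_overlap(communities[[i]], communities[[i + 1]])
      data.frame(pair = sprintf("%s-%s", names(communities)[i],
                                names(communities)[i + 1]),
                 n_overlap = length(ov$overlap),
                 n_unique_1 = length(ov$unique_1),
                 n_unique_2 = length(ov$unique_2),
                 overlap_abundant = ov$proportions$overlap["abundant"] %||% NA,
                 overlap_rare = ov$proportions$overlap["rare"] %||% NA)
    })
    adj <- do.call(rbind, adj)
    rownames(adj) <- NULL
    tt <- turnover_trend(communities, mode = config$similarity_mode)
    comm_comp <- do.call(rbind, lapply(communities, function(cc)
      data.frame(group = cc$id, n_nodes = length(cc$nodes),
                 prop_abundant = mean(cc$classes == "abundant"),
                 prop_intermediate = mean(cc$classes == "intermediate"),
                 prop_rare = mean(cc$classes == "rare"))))
    rownames(comm_comp) <- NULL
    out$turnover <- list(adjacent_overlap = adj, community_classes = comm_comp,
                         pairs = tt$pairs, trend = tt$trend)
    write_report(adj, dir, "turnover_adjacent_overlap.csv")
    write_report(comm_comp, dir, "turnover_community_classes.csv")
    write_report(tt$pairs, dir, "turnover_pairs.csv")
    write_report(trend_row("similarity_vs_salinity_span", tt$trend),
                 dir, "turnover_trend.csv")
  }

  ## --- roles ----------------------------------------------------------------
  if ("roles" %in% config$stages) {
    records <- lapply(nets, relative_degree, classes = classes)
    rt <- role_trends(records)
    nb <- levins_breadth(tab, classes)
    bc <- breadth_comparison(nb)
    role_df <- do.call(rbind, records)
    rownames(role_df) <- NULL
    rt_df <- rbind(trend_row("abundant_rd_vs_salinity", rt$abundant_rd),
                   trend_row("rare_rd_vs_salinity", rt$rare_rd),
                   trend_row("class_gap_vs_salinity", rt$class_gap),
                   trend_row("theta_vs_salinity", rt$theta))
    out$roles <- list(records = role_df, trends = rt, niche_breadth = nb,
                      breadth_test = bc)
    write_report(role_df, dir, "role_records.csv")
    write_report(rt$per_network, dir, "role_per_network.csv")
    write_report(rt_df, dir, "role_trends.csv")
    write_report(nb, dir, "niche_breadth.csv")
    write_report(bc, dir, "niche_breadth_test.json")
  }

  ## --- provenance -----------------------------------------------------------
  if (!is.null(dir)) {
    cfg_echo <- unclass(config)
    cfg_echo$out_dir <- NULL   # path-independent provenance
    cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE,
                                 digits = NA, null = "null", force = TRUE)
    tf <- tempfile()
    writeLines(cfg_json, tf)
    prov <- list(config = cfg_echo,
                 config_md5 = unname(tools::md5sum(tf)),
                 seed = config$seed,
                 package_version = as.character(
                   utils::packageVersion("salinet")),
                 r_version = R.version.string)
    unlink(tf)
    write_report(prov, dir, "provenance.json")
  }
  invisible(out)
}
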