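# Orchestration: staged runs over a flat config, with manifests, and a
# one-command synthetic end-to-end demonstration.

PIPELINE_STAGES <- c("simulate", "diversity", "assembly", "seasonality",
                     "categories", "networks", "demo")

# Cheap deterministic hash of a config list (provenance stamp for
# manifests; not cryptographic).
config_hash <- function(config) {
  bytes <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(bytes) * (seq_along(bytes) %% 97)) %% .Machine$integer.max)
}

write_manifest <- function(outdir, stage, config, extra = list()) {
  man <- c(list(stage = stage, config_hash = config_hash(config),
                seed = config$seed %||% NA,
                package_version = as.character(utils::packageVersion("planktime")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           extra)
  jsonlite::write_json(man, file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}

#' Default pipeline configuration
#'
#' Flat key-value list holding every stage threshold at its standard value
#' (betaNTI 2, RCbray 0.95, PN 0.2 with p 0.01 and a 10-14 month window,
#' 10% occupancy, 50% occurrence, IndVal 0.7 / 0.01, 50% co-occurrence
#' score) plus null/permutation counts per fidelity: `"demo"` uses 199,
#' `"full"` 999.
#'
#' @param seed integer seed.
#' @param fidelity `"demo"` or `"full"`.
#' @param ... overrides for any config key.
#' @return named list.
#' @export
run_config <- function(seed, fidelity = c("demo", "full"), ...) {
  fidelity <- match.arg(fidelity)
  n_rep <- if (fidelity == "demo") 199 else 999
  cfg <- list(seed = as.integer(seed), fidelity = fidelity,
              n_null = n_rep, n_perm = n_rep,
              bnti_threshold = 2, rc_threshold = 0.95,
              pn_min = 0.2, p_max = 0.01, period_window = c(10, 14),
              occupancy_min = 0.10, occurrence_min = 0.5,
              indval_min = 0.7, indval_p = 0.01,
              cooccurrence_min = 0.5, rarefaction_depth = NA,
              scenario = list())
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Run one pipeline stage
#'
#' Thin dispatcher over the module functions: reads the stage inputs from
#' `outdir` (as written by earlier stages), writes the stage outputs as
#' tidy TSV plus a JSON manifest recording config hash and seed.
#'
#' @param stage one of `"simulate"`, `"diversity"`, `"assembly"`,
#'   `"seasonality"`, `"categories"`, `"networks"`, `"demo"`.
#' @param config list from [run_config()].
#' @param outdir output/working directory, created if needed.
#' @return the stage's main result, invisibly.
#' @export
run_stage <- function(stage, config, outdir) {
  if (!stage %in% PIPELINE_STAGES) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(PIPELINE_STAGES, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "demo") return(run_demo(config$seed, outdir, config = config))
  res <- switch(stage,
    simulate = {
      scen <- make_scenario(do.call(scenario_config,
        c(config$scenario, list(seed = config$seed))))
      for (nm in names(scen$tables)) {
        write_count_table(scen$tables[[nm]], file.path(outdir, paste0("counts_", nm, ".tsv")))
      }
      write_sample_table(scen$meta, file.path(outdir, "samples.tsv"))
      ape::write.tree(scen$tree, file.path(outdir, "tree.nwk"))
      utils::write.table(
        data.frame(asv_id = names(scen$traits), optimum = as.numeric(scen$traits)),
        file.path(outdir, "traits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      scen
    },
    stop("stage '", stage, "' requires inputs produced in R; see run_demo()"))
  write_manifest(outdir, stage, config,
                 list(n_rows = if (is.list(res) && !is.null(res$meta)) nrow(res$meta) else NA))
  invisible(res)
}

#' One-command synthetic end-to-end demonstration
#'
#' Generates the two-observatory scenario and runs every analysis stage:
#' alpha/beta diversity with PERMANOVA and time decay, assembly-process
#' quantification per site, seasonality screening per site, two-site ASV
#' categorisation, and a planted static network followed through monthly
#' subnetworks and metric-environment correlations. All outputs are tidy
#' TSV under `outdir` plus a plain-text summary juxtaposing the sites.
#'
#' @param seed integer seed; the only source of randomness.
#' @param outdir output directory.
#' @param config list from [run_config()]; defaults to demo fidelity
#'   (199 randomisations/permutations).
#' @return list with the per-site process fractions, seasonal counts,
#'   categories, network correlation table and file paths, invisibly.
#' @export
run_demo <- function(seed, outdir, config = run_config(seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scen_cfg <- do.call(scenario_config, c(config$scenario, list(seed = config$seed)))
  scen <- make_scenario(scen_cfg)
  sites <- names(scen$tables)
  write_sample_table(scen$meta, file.path(outdir, "samples.tsv"))
  ape::write.tree(scen$tree, file.path(outdir, "tree.nwk"))

  depth <- config$rarefaction_depth
  tables <- list()
  for (s in sites) {
    tab <- scen$tables[[s]]
    d <- if (is.na(depth)) min(rowSums(tab)) else depth
    tables[[s]] <- rarefy(tab, d, seed = sub_seed(config$seed, 20 + match(s, sites)))
    write_count_table(tables[[s]], file.path(outdir, paste0("counts_", s, ".tsv")))
  }

  # diversity
  merged <- do.call(rbind, tables)
  alpha <- alpha_diversity(merged, scen$tree)
  utils::write.table(alpha, file.path(outdir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- bray_curtis(merged)
  pv <- permanova(bc, scen$meta, terms = "site", n_perm = config$n_perm,
                  seed = sub_seed(config$seed, 31))
  utils::write.table(pv, file.path(outdir, "permanova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  td <- time_decay(bc, scen$meta)
  utils::write.table(td, file.path(outdir, "time_decay.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # assembly per site
  fractions <- list(); pair_rows <- list()
  for (s in sites) {
    ap <- assembly_processes(tables[[s]], scen$tree, n_null = config$n_null,
                             seed = sub_seed(config$seed, 40 + match(s, sites)))
    fractions[[s]] <- cbind(site = s, ap$fractions)
    pair_rows[[s]] <- cbind(site = s, ap$pairs)
  }
  frac_df <- do.call(rbind, c(fractions, list(make.row.names = FALSE)))
  utils::write.table(frac_df, file.path(outdir, "process_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
                     file.path(outdir, "assembly_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # seasonality per site
  seas <- list()
  for (s in sites) {
    rec <- seasonality_analysis(tables[[s]], scen$meta, n_perm = config$n_perm,
                                seed = sub_seed(config$seed, 50 + match(s, sites)),
                                min_frac = config$occupancy_min,
                                pn_min = config$pn_min, p_max = config$p_max,
                                period_window = config$period_window)
    seas[[s]] <- cbind(site = s, rec)
  }
  seas_df <- do.call(rbind, c(seas, list(make.row.names = FALSE)))
  utils::write.table(seas_df, file.path(outdir, "seasonality.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seas_counts <- vapply(sites, function(s) sum(seas[[s]]$seasonal), 0L)

  # categories across the first two site tables
  cats <- assign_categories(tables[[1]], tables[[2]], site_names = sites[1:2],
                            n_perm = config$n_perm,
                            seed = sub_seed(config$seed, 60),
                            min_occ = config$occurrence_min,
                            indval_min = config$indval_min,
                            indval_p = config$indval_p)
  utils::write.table(cats, file.path(outdir, "asv_categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # networks: planted static network on site 1, filtered and followed monthly
  s1 <- sites[1]
  net0 <- make_static_network(colnames(tables[[s1]]), edge_density = 0.03,
                              positive_fraction = 0.9,
                              seed = sub_seed(config$seed, 70))
  net <- cooccurrence_filter(net0, tables[[s1]], min_score = config$cooccurrence_min)
  write_network(net, file.path(outdir, "static_network.tsv"))
  meta1 <- scen$meta[scen$meta$sample_id %in% rownames(tables[[s1]]), ]
  subs <- monthly_subnetworks(net, tables[[s1]], meta1)
  sm <- subnetwork_metrics(subs)
  utils::write.table(sm, file.path(outdir, "subnetwork_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  env <- data.frame(month = format(meta1$date, "%Y-%m"),
                    temperature = meta1$temperature, daylength = meta1$daylength)
  corr <- metric_env_correlations(sm, env)
  utils::write.table(corr, file.path(outdir, "metric_env_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # summary report
  rpt <- c(
    "planktime synthetic two-observatory demo",
    sprintf("seed: %d  fidelity: %s (n_null = n_perm = %d)",
            config$seed, config$fidelity, config$n_null),
    "",
    "process fractions per site:",
    utils::capture.output(print(frac_df, row.names = FALSE)),
    "",
    sprintf("seasonal ASVs: %s",
            paste(sprintf("%s = %d", sites, seas_counts), collapse = ", ")),
    sprintf("ASV categories: %s",
            paste(sprintf("%s = %d", names(table(cats$category)),
                          as.integer(table(cats$category))), collapse = ", ")),
    sprintf("network metric-environment correlations with Holm p < 0.05: %d of %d tested",
            sum(corr$p_holm < 0.05, na.rm = TRUE), sum(!is.na(corr$p_holm))))
  writeLines(rpt, file.path(outdir, "summary.txt"))
  write_manifest(outdir, "demo", config,
                 list(sites = sites, n_samples = nrow(scen$meta)))
  invisible(list(fractions = frac_df, seasonal_counts = seas_counts,
                 categories = cats, correlations = corr, seasonality = seas_df,
                 permanova = pv, outdir = outdir, truth = scen$truth))
}
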