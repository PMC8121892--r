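tsv_matrix <- function(m, path, id = "site_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "clean", "alpha", "beta", "cluster"),
    simulate = list(scenario = "four_zone"),
    input = list(),
    clean = list(fraction = 0.001),
    alpha = list(accum_method = "exact", n_perm = 1000),
    beta = list(n_perm = 999, alternative = "greater"),
    cluster = list(methods = c("hierarchical", "kmeans", "pam", "diana"),
                   k_min = 2, k_max = 10, L = 10)
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      merge_config(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  defaults
}

validate_config <- function(cfg) {
  known <- names(pipeline_defaults())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  bad <- setdiff(cfg$stages, c("simulate", "clean", "alpha", "beta", "cluster"))
  if (length(bad))
    stop(sprintf("unknown stages: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("seed must be a single integer", call. = FALSE)
  if (!"simulate" %in% cfg$stages) {
    need <- c("kelly_counts", "kelly_meta", "mifish_counts", "mifish_meta",
              "network_edges", "network_nodes")
    for (f in need) {
      if (is.null(cfg$input[[f]]))
        stop(sprintf("input.%s is required when not simulating", f),
             call. = FALSE)
      if (!file.exists(cfg$input[[f]]))
        stop(sprintf("input file not found: %s", cfg$input[[f]]),
             call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Run the full catchment-analysis pipeline from a YAML config
#'
#' Orchestrates the stages `simulate` (synthetic survey generation),
#' `clean` (filters and merges to the community matrix), `alpha` (richness,
#' distance-decay GLM, accumulation curves, environmental PCA), `beta`
#' (Jaccard partition and Mantel tests against river distance) and
#' `cluster` (validation grid, optimal clustering, network projection).
#' Every stage writes plain-text outputs into `out_dir`; a `manifest.json`
#' records the fully-defaulted configuration (so unstated parameters are
#' visible in every run record), per-output MD5 checksums, timings, and —
#' if a stage fails — the failure point, with earlier outputs retained.
#' Given the same config and seed the outputs are byte-identical.
#'
#' @param config_path Path to a YAML configuration file. Recognised keys:
#'   `seed`, `stages`, `simulate` ([scenario_config()] fields), `input`
#'   (file paths when not simulating), `clean`, `alpha`, `beta`, `cluster`.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir) {
  user <- if (is.list(config_path)) config_path else yaml::read_yaml(config_path)
  cfg <- merge_config(pipeline_defaults(), user %||% list())
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages_completed = character(),
                   outputs = list(), timings = list())
  out <- function(...) file.path(out_dir, ...)
  state <- new.env()
  record <- function(stage, paths, elapsed) {
    manifest$stages_completed <<- c(manifest$stages_completed, stage)
    manifest$timings[[stage]] <<- round(elapsed, 3)
    for (p in paths)
      manifest$outputs[[basename(p)]] <- unname(tools::md5sum(p))
    manifest <<- manifest
  }

  stage_fns <- list(
    simulate = function() {
      sc <- cfg$simulate
      sc$seed <- sc$seed %||% cfg$seed
      scfg <- do.call(scenario_config, sc)
      ds <- generate_dataset(scfg)
      state$ds <- ds
      write_count_table(ds$kelly, out("kelly_counts.tsv"),
                        out("kelly_meta.tsv"))
      write_count_table(ds$mifish, out("mifish_counts.tsv"),
                        out("mifish_meta.tsv"))
      write_river_network(ds$network, out("network_edges.csv"),
                          out("network_nodes.csv"))
      tsv_matrix(ds$env, out("env.tsv"))
      truth <- list(presence = as.data.frame(ds$truth$presence),
                    zones = as.list(ds$truth$zones),
                    scenario = scfg$scenario, seed = scfg$seed)
      jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE)
      c(out("kelly_counts.tsv"), out("kelly_meta.tsv"),
        out("mifish_counts.tsv"), out("mifish_meta.tsv"),
        out("network_edges.csv"), out("network_nodes.csv"),
        out("env.tsv"), out("truth.json"))
    },
    clean = function() {
      if (is.null(state$ds)) {
        state$ds <- list(
          kelly = read_count_table(cfg$input$kelly_counts,
                                   cfg$input$kelly_meta),
          mifish = read_count_table(cfg$input$mifish_counts,
                                    cfg$input$mifish_meta),
          network = read_river_network(cfg$input$network_edges,
                                       cfg$input$network_nodes),
          env = if (!is.null(cfg$input$env)) {
            e <- utils::read.delim(cfg$input$env)
            m <- as.matrix(e[, -1]); rownames(m) <- e[[1]]; m
          })
      }
      state$counts <- clean_pipeline(state$ds$kelly, state$ds$mifish,
                                     fraction = cfg$clean$fraction)
      state$presence <- to_presence_absence(state$counts)
      message(sprintf("clean: low-frequency fraction %g, negative-control max subtraction",
                      cfg$clean$fraction))
      write_community_matrix(state$counts, out("community_counts.tsv"))
      write_community_matrix(state$presence, out("community_presence.tsv"))
      c(out("community_counts.tsv"), out("community_presence.tsv"))
    },
    alpha = function() {
      sites <- rownames(state$presence$values)
      net <- state$ds$network
      rich <- local_richness(state$presence)
      d_out <- distance_to_outlet(net, sites)
      fit <- fit_richness_glm(rich, d_out)
      groups <- if (!is.null(net$node_attrs$river))
        net$node_attrs$river[match(sites, net$node_attrs$node)]
      curve <- accumulation_curve(state$presence, groups = groups,
                                  method = cfg$alpha$accum_method,
                                  n_perm = cfg$alpha$n_perm, seed = cfg$seed)
      utils::write.table(data.frame(site_id = sites, richness = rich,
                                    dist_outlet_km = d_out),
                         out("richness.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      glm_df <- data.frame(term = c("intercept", "slope"),
                           estimate = c(fit$intercept, fit$slope),
                           se = fit$se, z = fit$z, p = fit$p)
      utils::write.table(cbind(glm_df,
                               aic = fit$aic, loglik = fit$loglik,
                               deviance = fit$deviance, n = fit$n),
                         out("glm_summary.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(curve, out("accumulation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(out("richness.tsv"), out("glm_summary.tsv"),
                 out("accumulation.tsv"))
      if (!is.null(state$ds$env)) {
        pca <- env_pca(state$ds$env[sites, , drop = FALSE])
        tsv_matrix(round(pca$scores, 6), out("env_pca_scores.tsv"))
        utils::write.table(data.frame(component = colnames(pca$loadings),
                                      explained = pca$explained),
                           out("env_pca_explained.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, out("env_pca_scores.tsv"),
                   out("env_pca_explained.tsv"))
      }
      state$fit <- fit
      paths
    },
    beta = function() {
      sites <- rownames(state$presence$values)
      dnet <- network_distance_matrix(state$ds$network, sites)
      bp <- jaccard_partition(state$presence)
      seeds <- cfg$seed
      mt <- lapply(list(jaccard = bp$jaccard, turnover = bp$turnover,
                        nestedness = bp$nestedness),
                   function(b) mantel_test(b, dnet, n_perm = cfg$beta$n_perm,
                                           alternative = cfg$beta$alternative,
                                           seed = seeds))
      tsv_matrix(round(bp$jaccard, 6), out("beta_jaccard.tsv"))
      tsv_matrix(round(bp$turnover, 6), out("beta_turnover.tsv"))
      tsv_matrix(round(bp$nestedness, 6), out("beta_nestedness.tsv"))
      tsv_matrix(round(dnet, 3), out("river_distances.tsv"))
      utils::write.table(
        data.frame(component = names(mt),
                   mantel_r = vapply(mt, `[[`, numeric(1), "statistic"),
                   p_value = vapply(mt, `[[`, numeric(1), "p_value"),
                   n_perm = cfg$beta$n_perm,
                   alternative = cfg$beta$alternative, seed = seeds),
        out("mantel.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      c(out("beta_jaccard.tsv"), out("beta_turnover.tsv"),
        out("beta_nestedness.tsv"), out("river_distances.tsv"),
        out("mantel.tsv"))
    },
    cluster = function() {
      k_range <- seq(cfg$cluster$k_min, cfg$cluster$k_max)
      vg <- validate_grid(state$counts, methods = cfg$cluster$methods,
                          k_range = k_range, L = cfg$cluster$L,
                          seed = cfg$seed)
      sc <- as.data.frame.table(vg$scores,
                                responseName = "score")
      names(sc)[1:3] <- c("measure", "method", "k")
      utils::write.table(sc, out("validation_scores.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(cbind(vg$optima, hopkins = vg$hopkins),
                         out("validation_optima.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      # majority-supported k with the winning method
      kbest <- as.integer(names(sort(table(vg$optima$k), decreasing = TRUE))[1])
      mbest <- names(sort(table(vg$optima$method), decreasing = TRUE))[1]
      cl <- cluster_sites(state$counts, mbest, kbest, seed = cfg$seed)
      paths <- character()
      if (!is.null(cl$tree)) {
        write_dendrogram_newick(cl$tree, out("dendrogram.nwk"))
        paths <- out("dendrogram.nwk")
      }
      utils::write.table(data.frame(site_id = names(cl$labels),
                                    cluster = cl$labels),
                         out("clusters.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      pr <- project_clusters(cl$labels, state$ds$network)
      utils::write.table(pr$coherence, out("cluster_coherence.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      c(out("validation_scores.tsv"), out("validation_optima.tsv"),
        out("clusters.tsv"), out("cluster_coherence.tsv"), paths)
    })

  for (stage in cfg$stages) {
    t0 <- proc.time()["elapsed"]
    res <- tryCatch(stage_fns[[stage]](), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$failed_stage <- stage
      manifest$error <- conditionMessage(res)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(res)),
           call. = FALSE)
    }
    record(stage, res, proc.time()["elapsed"] - t0)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
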