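#' Run the full embedding-and-clustering workflow
#'
#' Executes the complete pipeline described by a [run_config()]:
#' read expression -> log-normalize + min-max scale + select highly
#' variable genes -> build the cell graph (KNN / Pearson-KNN / custom) ->
#' train the variational graph autoencoder -> cluster the latent embedding
#' with HDBSCAN (optionally rescuing small clusters) -> interpretability
#' outputs (attention record, weight products, per-cluster gene report).
#'
#' Artifacts written to `config$outdir`:
#' `embeddings.csv` (cell_id + latent columns), `labels.csv`,
#' `metrics.json`, `attention.tsv`, `gene_report.tsv`, `graph.tsv`,
#' `history.csv`, `config.yaml` and `run.log`. Every text artifact carries
#' the hash of the configuration that produced it.
#'
#' @param config a `run_config`.
#' @return Invisibly, a list with the in-memory results (`fit`,
#'   `assignment`, `metrics`, `report`, `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(outdir, "run.log")
  log_lines <- c(sprintf("# config: %s", hash),
                 sprintf("started: %s", format(Sys.time())))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    if (isTRUE(config$verbose)) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  expr <- stage("read_expression", read_expression(config$input, config$input_format))
  say("input: %d cells x %d genes", nrow(expr$values), ncol(expr$values))

  # gene variability is ranked on the log-normalized values (min-max
  # scaling equalizes per-gene variance and would distort the ranking);
  # the scaled values are what the model and the graph metric consume
  prep <- stage("preprocess", {
    ln <- log_normalize(expr, target_sum = config$target_sum)
    scaled <- minmax_scale(ln)
    hvg_idx <- select_hvg(ln, min(config$n_hvg, ncol(ln$values)))
    khvg_idx <- select_hvg(ln, min(config$khvg, ncol(ln$values)))
    list(features = subset_expression(scaled, genes = hvg_idx),
         graph_features = subset_expression(scaled, genes = khvg_idx))
  })
  feat <- prep$features
  say("preprocess: log-normalize (target %g), min-max scale, %d HVGs",
      config$target_sum, ncol(feat$values))

  graph <- stage("graph_builder", {
    if (config$graph == "custom") {
      if (is.null(config$custom_graph)) stop("custom graph requires custom_graph path")
      read_edge_list(config$custom_graph, n_nodes = nrow(expr$values))
    } else {
      metric <- if (config$graph == "pknn") "pearson" else "euclidean"
      build_knn_graph(prep$graph_features, k = config$k, metric = metric,
                      use_pca = config$use_pca)
    }
  })
  say("graph: %s, %d nodes, %d edges", config$graph, graph$n_nodes,
      n_edges(graph))

  fit <- stage("trainer", {
    tc <- training_config(hidden_dims = config$hidden_dims,
                          n_heads = config$n_heads,
                          latent_dim = config$latent_dim,
                          reg_kind = config$reg_kind,
                          use_feature_recon = config$use_feature_recon,
                          epochs = config$epochs,
                          learning_rate = config$learning_rate,
                          seed = config$seed,
                          holdout_fraction = config$holdout_fraction,
                          k = config$k, khvg = config$khvg,
                          n_hvg = config$n_hvg)
    fit_vgae(feat, graph, tc)
  })
  say("training: %d epochs, final loss %.4f", config$epochs,
      fit$history$loss[nrow(fit$history)])

  assignment <- stage("cluster_metrics", {
    a <- cluster_latent(fit$embedding, min_cluster_size = config$min_cluster_size)
    if (!is.null(config$rescue_min_size)) {
      a <- rescue_small_clusters(a, fit$embedding,
                                 rescue_min_size = config$rescue_min_size)
    }
    a
  })
  say("clustering: %d clusters, %d noise cells", assignment$n_clusters,
      assignment$n_noise)

  metrics <- stage("cluster_metrics", {
    m <- list(n_clusters = assignment$n_clusters,
              n_noise = assignment$n_noise,
              final_loss = fit$history$loss[nrow(fit$history)])
    if (assignment$n_clusters >= 2) {
      m$sc <- silhouette_coefficient(fit$embedding, assignment$labels)
    }
    if (!is.null(config$reference_labels)) {
      ref <- utils::read.csv(config$reference_labels, comment.char = "#")
      ord <- match(expr$cell_ids, ref[[1]])
      if (anyNA(ord)) stop("reference labels missing some cell ids")
      m$ari <- adjusted_rand_index(assignment$labels, ref[[2]][ord])
    }
    if (any(!is.na(fit$history$holdout_auc))) {
      m$holdout_auc <- fit$history$holdout_auc[nrow(fit$history)]
    }
    m
  })

  report <- stage("interpretability", {
    wp <- model_weight_products(fit$model)
    ranked_genes(wp, fit$embedding, assignment, gene_ids = feat$gene_ids)
  })

  stage("write_artifacts", {
    stamp <- sprintf("config: %s", hash)
    emb <- data.frame(cell_id = expr$cell_ids, fit$embedding)
    colnames(emb) <- c("cell_id", paste0("latent_", seq_len(ncol(fit$embedding))))
    emb_con <- file(file.path(outdir, "embeddings.csv"), "w")
    writeLines(paste0("# ", stamp), emb_con)
    utils::write.csv(emb, emb_con, row.names = FALSE, quote = FALSE)
    close(emb_con)

    lab_con <- file(file.path(outdir, "labels.csv"), "w")
    writeLines(paste0("# ", stamp), lab_con)
    utils::write.csv(data.frame(cell_id = expr$cell_ids,
                                label = assignment$labels),
                     lab_con, row.names = FALSE, quote = FALSE)
    close(lab_con)

    jsonlite::write_json(c(list(config_hash = hash), metrics),
                         file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_attention_tsv(fit$attention, file.path(outdir, "attention.tsv"),
                        header = stamp)
    write_gene_report(report, file.path(outdir, "gene_report.tsv"),
                      header = stamp)
    write_edge_list(graph, file.path(outdir, "graph.tsv"), header = stamp)
    hist_con <- file(file.path(outdir, "history.csv"), "w")
    writeLines(paste0("# ", stamp), hist_con)
    utils::write.csv(fit$history, hist_con, row.names = FALSE, quote = FALSE)
    close(hist_con)
    write_run_config(config, file.path(outdir, "config.yaml"))
  })
  say("done: artifacts in %s", outdir)
  writeLines(log_lines, log_path)

  invisible(list(fit = fit, assignment = assignment, metrics = metrics,
                 report = report, outdir = outdir, config_hash = hash))
}
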