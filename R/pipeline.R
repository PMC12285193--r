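#' Run the full analysis pipeline, writing every intermediate artifact
#'
#' Executes train -> embed -> (optional) rotate -> trajectory -> patterns ->
#' basis -> disruption on a counts file, writing each stage's output, a
#' structured log, and the resolved configuration into \code{out_dir}. A
#' stage whose artifact already exists on disk is skipped, so a run can be
#' resumed after deleting only the artifacts to recompute.
#'
#' @param counts a \code{\link{count_matrix}}, or a path readable by
#'   \code{\link{read_counts}}.
#' @param out_dir artifact directory (created if needed).
#' @param config a \code{\link{decipher_config}}.
#' @param condition_column annotation column naming the condition of each
#'   cell; one trajectory is computed per condition.
#' @param start_markers,end_markers marker genes locating the trajectory
#'   endpoints.
#' @param rotate optional list of axis targets for
#'   \code{\link{rotate_space}}.
#' @param genes genes whose patterns are reconstructed (default: all model
#'   genes, capped at 200 by pattern-reconstruction cost).
#' @param basis_cfg a \code{\link{basis_config}}.
#' @param cond_pair two condition names scored for disruption (default: the
#'   first two).
#' @param n_neighbors,resolution clustering parameters (see
#'   \code{\link{cluster_latent}}).
#' @param spacing trajectory interpolation spacing.
#' @return Invisibly, the artifact directory path.
#' @export
run_pipeline <- function(counts, out_dir, config = decipher_config(),
                         condition_column = "condition",
                         start_markers = NULL, end_markers = NULL,
                         rotate = NULL, genes = NULL,
                         basis_cfg = basis_config(),
                         cond_pair = NULL,
                         n_neighbors = 15L, resolution = 0.7,
                         spacing = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline_log.txt")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE)
    message(line)
  }
  stage <- function(artifact, run) {
    path <- file.path(out_dir, artifact)
    if (file.exists(path)) {
      logmsg("stage %s: artifact exists, skipping", artifact)
      return(path)
    }
    t0 <- Sys.time()
    run(path)
    logmsg("stage %s: done in %.1fs (seed %d)", artifact,
           as.numeric(difftime(Sys.time(), t0, units = "secs")), config$seed)
    path
  }

  if (is.character(counts)) counts <- read_counts(counts)
  write_config(config, file.path(out_dir, "resolved_config.toml"))
  cat("decipher R package version",
      as.character(utils::packageVersion("decipher")), "\n",
      file = file.path(out_dir, "VERSION"))

  model_path <- file.path(out_dir, "model.rds.txt")
  if (!file.exists(model_path)) {
    fit <- decipher(counts, config)
    # text serialization keeps the artifact tree plain-text
    writeLines(jsonlite_free_serialize(fit), model_path)
    utils::write.csv(fit$training_log, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)
    logmsg("stage model: trained %d epochs", nrow(fit$training_log))
  } else {
    fit <- jsonlite_free_deserialize(readLines(model_path))
    logmsg("stage model: artifact exists, skipping")
  }

  emb_path <- file.path(out_dir, "embedding.tsv")
  if (!file.exists(emb_path)) {
    emb <- decipher_encode(fit, counts)
    if (!is.null(rotate)) emb <- rotate_space(emb, rotate)
    write_embedding(emb, emb_path)
    logmsg("stage embedding: %d cells", length(emb$cell_ids))
  } else {
    emb <- read_embedding(emb_path)
    logmsg("stage embedding: artifact exists, skipping")
  }

  conds <- if (!is.null(counts$annotations) &&
               condition_column %in% names(counts$annotations)) {
    as.character(counts$annotations[[condition_column]])
  } else {
    rep("all", nrow(counts$counts))
  }

  traj_path <- file.path(out_dir, "trajectories.tsv")
  patt_path <- file.path(out_dir, "patterns.csv")
  time_path <- file.path(out_dir, "decipher_time.tsv")
  if (!file.exists(traj_path) || !file.exists(patt_path) ||
      !file.exists(time_path)) {
    labels <- cluster_latent(emb$z, n_neighbors = n_neighbors,
                             resolution = resolution, seed = config$seed)
    paths <- list(); pattern_sets <- list()
    if (is.null(genes)) genes <- utils::head(fit$gene_ids, 200)
    for (cond in unique(conds)) {
      sel <- conds == cond
      sub_emb <- list(v = emb$v[sel, , drop = FALSE],
                      z = emb$z[sel, , drop = FALSE])
      sub_lab <- labels[sel]
      if (length(unique(sub_lab)) < 2) next
      graph <- build_cluster_graph(sub_emb, sub_lab)
      seqc <- find_path(graph, subset_counts(counts, cells = which(sel)),
                        start_markers = start_markers,
                        end_markers = end_markers)
      paths[[cond]] <- interpolate_path(graph, seqc, spacing = spacing,
                                        condition = cond)
      pattern_sets[[cond]] <- reconstruct_gene_patterns(
        fit, paths[[cond]], genes,
        library_size = stats::median(counts$library_sizes),
        seed = config$seed)
    }
    tdf <- do.call(rbind, lapply(names(paths), function(cond) {
      p <- paths[[cond]]
      data.frame(condition = cond, point = seq_along(p$times),
                 v1 = p$points[, 1], v2 = p$points[, 2], time = p$times)
    }))
    utils::write.table(tdf, traj_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    times <- assign_time(emb, paths, conds)
    utils::write.table(times, time_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    pdf_all <- do.call(rbind, lapply(names(pattern_sets), function(cond) {
      ps <- pattern_sets[[cond]]
      do.call(rbind, lapply(seq_along(ps$genes), function(gi) {
        data.frame(gene = ps$genes[gi], condition = cond,
                   time = ps$time_grid, value = ps$mean[gi, ])
      }))
    }))
    utils::write.csv(pdf_all, patt_path, row.names = FALSE, quote = FALSE)
    logmsg("stage trajectory/patterns: %d conditions", length(paths))
  } else {
    logmsg("stage trajectory/patterns: artifacts exist, skipping")
  }

  disr_path <- file.path(out_dir, "disruption.csv")
  basis_path <- file.path(out_dir, "bases.csv")
  if (!file.exists(disr_path)) {
    pm <- read_patterns(patt_path)
    if (length(pm$condition_ids) >= 2) {
      bfit <- fit_basis(pm, basis_cfg)
      if (is.null(cond_pair)) cond_pair <- pm$condition_ids[1:2]
      utils::write.csv(disruption_scores(bfit, cond_pair), disr_path,
                       row.names = FALSE, quote = FALSE)
      bd <- do.call(rbind, lapply(seq_len(nrow(bfit$basis_values)), function(k) {
        data.frame(k = k, time = bfit$time_grid, value = bfit$basis_values[k, ])
      }))
      utils::write.csv(bd, basis_path, row.names = FALSE, quote = FALSE)
      logmsg("stage basis/disruption: done")
    } else {
      logmsg("stage basis/disruption: fewer than 2 conditions, skipped")
    }
  } else {
    logmsg("stage basis/disruption: artifact exists, skipping")
  }
  invisible(out_dir)
}

# Plain-text serialization of a fitted model: R's dput text, exact numerics.
jsonlite_free_serialize <- function(obj) {
  paste(deparse(obj, control = "exact"), collapse = "\n")
}

jsonlite_free_deserialize <- function(lines) {
  eval(parse(text = paste(lines, collapse = "\n")))
}
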