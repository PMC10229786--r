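# Discriminative-connection interpretation: per-edge importance extracted
# from trained branch classifiers, averaged across models (e.g. CV folds),
# min-max normalized, accumulated onto ROIs, and ranked.

#' Per-edge importance weights of a trained branch classifier
#'
#' Extraction depends on the classifier kind: absolute linear coefficients
#' for the linear SVM (aggregated over the pairwise machines in multiclass
#' problems), mean-decrease-in-impurity importances for the random forest,
#' and input-layer weight magnitudes summed over hidden units for the neural
#' network. Weights are nonnegative; larger means more discriminative.
#'
#' @param model A [train_branch()] model fitted on FBN feature vectors.
#' @return Numeric nonnegative vector, one weight per edge
#'   (length m(m-1)/2).
#' @export
edge_weights <- function(model) {
  if (!inherits(model, "branch_model")) {
    abort("`model` must be a branch_model.")
  }
  w <- switch(model$kind,
    svm = {
      if (model$fit$kernel != 0) {
        abort("Edge weights require a linear-kernel SVM.")
      }
      W <- crossprod(model$fit$coefs, model$fit$SV)
      colSums(abs(W))
    },
    rf = {
      imp <- randomForest::importance(model$fit)
      as.numeric(imp[, 1])
    },
    nnet = {
      fit <- model$fit
      p <- model$n_features
      size <- fit$n[2]
      Win <- matrix(fit$wts[seq_len((p + 1) * size)], nrow = p + 1)
      rowSums(abs(Win[-1, , drop = FALSE]))
    },
    abort(sprintf("No weight extraction defined for kind '%s'.", model$kind))
  )
  as.numeric(w)
}

#' Aggregate edge weights across models and rank connections
#'
#' Averages the per-edge weight vectors of several trained models (e.g. one
#' per cross-validation fold), min-max normalizes the average to \[0, 1\],
#' accumulates edge weights onto their endpoint ROIs (each edge contributes
#' its full weight to both endpoints, so `sum(roi_weights) = 2 *
#' sum(edge_weights)` exactly), and returns the `top_k` strongest
#' connections.
#'
#' @param weight_list List of numeric edge-weight vectors of equal length
#'   (or a single vector).
#' @param geometry An [atlas_geometry()] naming the ROIs; its edge count
#'   must match the weight length.
#' @param top_k Number of top connections to report (default 20).
#' @param branch Optional tag ("spatial"/"temporal") recorded in the result.
#' @return An `edge_weight_map`: list with `edges` (tibble: edge, roi_a,
#'   roi_b, weight — all edges, normalized), `top_edges` (tibble: rank,
#'   roi_a, roi_b, weight), `roi_weights` (tibble: roi, weight) and
#'   `branch`.
#' @export
aggregate_and_rank <- function(weight_list, geometry, top_k = 20,
                               branch = NULL) {
  if (is.numeric(weight_list)) weight_list <- list(weight_list)
  lens <- unique(lengths(weight_list))
  if (length(lens) != 1) {
    abort("All weight vectors must have the same length.")
  }
  m <- geometry$m
  n_edges <- m * (m - 1) / 2
  if (lens != n_edges) {
    abort(sprintf(
      "Weight length %d does not match the atlas edge count %d.",
      lens, n_edges
    ))
  }
  if (top_k > n_edges) {
    abort(sprintf("top_k = %d exceeds the edge count %d.", top_k, n_edges))
  }
  avg <- Reduce(`+`, weight_list) / length(weight_list)
  rng <- range(avg)
  norm <- if (rng[2] == rng[1]) {
    if (rng[2] > 0) rep(1, n_edges) else rep(0, n_edges)
  } else {
    (avg - rng[1]) / (rng[2] - rng[1])
  }
  et <- edge_index_table(m)
  roi_w <- numeric(m)
  for (e in seq_len(n_edges)) {
    roi_w[et$i[e]] <- roi_w[et$i[e]] + norm[e]
    roi_w[et$j[e]] <- roi_w[et$j[e]] + norm[e]
  }
  edges <- tibble(
    edge = et$edge,
    roi_a = geometry$roi$roi_name[et$i],
    roi_b = geometry$roi$roi_name[et$j],
    weight = norm
  )
  top <- edges %>%
    arrange(dplyr::desc(.data$weight), .data$edge) %>%
    head(top_k) %>%
    mutate(rank = row_number(), .before = 1) %>%
    select("rank", "roi_a", "roi_b", "weight")
  structure(
    list(
      edges = edges,
      top_edges = top,
      roi_weights = tibble(roi = geometry$roi$roi_name, weight = roi_w),
      branch = branch,
      geometry = geometry
    ),
    class = "edge_weight_map"
  )
}

#' @export
print.edge_weight_map <- function(x, ...) {
  cat(sprintf(
    "<edge_weight_map>%s %d edges, top %d:\n",
    if (is.null(x$branch)) "" else sprintf(" branch = %s,", x$branch),
    nrow(x$edges), nrow(x$top_edges)
  ))
  print(x$top_edges)
  invisible(x)
}

#' @rdname aggregate_and_rank
#' @param x,object An `edge_weight_map`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.edge_weight_map <- function(x, ...) x$top_edges

#' @rdname aggregate_and_rank
#' @exportS3Method ggplot2::autoplot
autoplot.edge_weight_map <- function(object, ...) {
  df <- object$top_edges %>%
    mutate(pair = paste(.data$roi_a, .data$roi_b, sep = " - "))
  ggplot2::ggplot(df, ggplot2::aes(.data$weight,
                                   stats::reorder(.data$pair, .data$weight))) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Normalized weight", y = NULL,
      title = sprintf("Top %d discriminative connections%s",
                      nrow(df),
                      if (is.null(object$branch)) ""
                      else paste0(" (", object$branch, " branch)"))
    )
}

#' Export an edge-weight map for external visualization
#'
#' Writes `edges.tsv` (rank, roi_a, roi_b, weight), `rois.tsv` (roi,
#' weight), and BrainNet-Viewer-compatible `.node` (centroid coordinates
#' with ROI weight as node size) and `.edge` (top-k adjacency matrix) files.
#'
#' @param map An [aggregate_and_rank()] result.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_edge_map <- function(map, dir, prefix = "fbn") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(map$top_edges, file.path(dir, paste0(prefix, "_edges.tsv")))
  readr::write_tsv(map$roi_weights, file.path(dir, paste0(prefix, "_rois.tsv")))
  geo <- map$geometry
  node <- data.frame(
    x = geo$roi$x, y = geo$roi$y, z = geo$roi$z,
    color = 1, size = map$roi_weights$weight,
    label = gsub("\\s+", "_", geo$roi$roi_name)
  )
  utils::write.table(node, file.path(dir, paste0(prefix, ".node")),
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  adj <- matrix(0, geo$m, geo$m)
  et <- edge_index_table(geo$m)
  top_idx <- match(
    paste(map$top_edges$roi_a, map$top_edges$roi_b),
    paste(geo$roi$roi_name[et$i], geo$roi$roi_name[et$j])
  )
  for (r in seq_along(top_idx)) {
    e <- top_idx[r]
    adj[et$i[e], et$j[e]] <- adj[et$j[e], et$i[e]] <- map$top_edges$weight[r]
  }
  utils::write.table(adj, file.path(dir, paste0(prefix, ".edge")),
                     sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Edge-weight maps from a fitted STDAC model or CV fold models
#'
#' Convenience wrapper: extracts [edge_weights()] from each supplied branch
#' model and aggregates them with [aggregate_and_rank()].
#'
#' @param models A single `branch_model` or list of them (e.g. the spatial
#'   branch from each CV fold).
#' @param geometry An [atlas_geometry()].
#' @param top_k Connections to report.
#' @param branch Optional branch tag.
#' @return An `edge_weight_map`.
#' @export
rank_connections <- function(models, geometry, top_k = 20, branch = NULL) {
  if (inherits(models, "branch_model")) models <- list(models)
  aggregate_and_rank(purrr::map(models, edge_weights), geometry,
                     top_k = top_k, branch = branch)
}
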