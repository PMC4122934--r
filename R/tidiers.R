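# broom-style tidiers and ggplot2 views of the result objects.

#' @method tidy plts_cluster
#' @export
tidy.plts_cluster <- function(x, ...) {
  mutate(x$genes, genome_id = x$genome_id, status = x$status,
         .before = 1)
}

#' Tidy a cluster set into one row per member gene
#' @param x A `plts_clusters` list.
#' @param ... Unused.
#' @method tidy plts_clusters
#' @export
tidy.plts_clusters <- function(x, ...) {
  if (!length(x)) {
    return(tibble(cluster_id = character(), genome_id = character()))
  }
  bind_rows(lapply(seq_along(x), function(i) {
    mutate(tidy(x[[i]]), cluster_id = sprintf("cluster%02d", i),
           .before = 1)
  }))
}

#' One summary row per detected cluster
#' @param x A `plts_scan` result.
#' @param ... Unused.
#' @method tidy plts_scan
#' @export
tidy.plts_scan <- function(x, ...) {
  if (!length(x$clusters)) {
    return(tibble(genome_id = character(), cluster_id = character()))
  }
  bind_rows(lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    tibble(genome_id = cl$genome_id,
           cluster_id = sprintf("cluster%02d", i),
           contig_id = cl$contig_id,
           span_start = cl$span[1], span_end = cl$span[2],
           n_genes = nrow(cl$genes), core_count = cl$core_count,
           synteny_score = cl$synteny_score, status = cl$status)
  }))
}

#' @method glance plts_scan
#' @export
glance.plts_scan <- function(x, ...) {
  ret <- vapply(x$clusters, function(cl) cl$status == "retained", logical(1))
  tibble(genome_id = x$genome_id, n_hits = nrow(x$hits),
         n_assigned = nrow(x$assignments),
         n_clusters = length(x$clusters), n_retained = sum(ret),
         best_synteny = if (any(ret)) {
           max(vapply(x$clusters[ret], function(cl) cl$synteny_score,
                      numeric(1)))
         } else NA_real_)
}

#' @method tidy incongruence_report
#' @export
tidy.incongruence_report <- function(x, ...) x$displaced

#' @method glance incongruence_report
#' @export
glance.incongruence_report <- function(x, ...) {
  tibble(shared_leaf_count = x$shared_leaf_count, rf = x$rf,
         rf_normalized = x$rf_normalized,
         n_displaced = nrow(x$displaced))
}

#' Gene-map view of detected clusters
#'
#' Draws each cluster's genes as strand-aware arrows colored by family,
#' one facet row per cluster.
#'
#' @param object A `plts_scan` result (or `plts_clusters`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plts_scan
#' @export
autoplot.plts_scan <- function(object, ...) {
  autoplot(object$clusters, ...)
}

#' @rdname autoplot.plts_scan
#' @method autoplot plts_clusters
#' @export
autoplot.plts_clusters <- function(object, ...) {
  df <- tidy(object)
  if (!nrow(df)) abort("no clusters to plot")
  df <- mutate(df,
               xmin = (.data$start - .data$start[1]) / 1e3,
               xmax = (.data$end - .data$start[1]) / 1e3,
               fam = ifelse(is.na(.data$family), "(none)", .data$family))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$xmin, xmax = .data$xmax,
      ymin = ifelse(.data$strand == "+", 0.05, -0.95),
      ymax = ifelse(.data$strand == "+", 0.95, -0.05),
      fill = .data$fam)) +
    ggplot2::facet_wrap(~ cluster_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = NULL, fill = "family") +
    ggplot2::scale_y_continuous(breaks = c(-0.5, 0.5),
                                labels = c("-", "+"), limits = c(-1, 1)) +
    ggplot2::theme_minimal()
}

#' Bootstrap support histogram
#'
#' @param object A tree returned by [bootstrap_support()].
#' @return A ggplot object.
#' @export
plot_support <- function(object) {
  s <- attr(object, "support")
  if (is.null(s)) abort("tree carries no bootstrap supports")
  df <- tibble(support = s[!is.na(s)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$support)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05)) +
    ggplot2::labs(x = "bipartition support", y = "internal edges") +
    ggplot2::theme_minimal()
}
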