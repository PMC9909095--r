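# Order-level Spearman co-occurrence networks: aggregation, the 1% mean
# relative-abundance filter, the rho/p edge gate and simple summaries.

#' Aggregate a count table to order-level relative abundances
#'
#' @param counts taxa x samples count matrix.
#' @param taxonomy data frame with columns `taxon` and `order` covering all
#'   taxa in `counts` (see [read_taxonomy()]); a `guild` column, if present,
#'   is carried through as a node attribute.
#' @return List with `abundance` (orders x samples, columns sum to 1) and
#'   `guild` (named vector, or NULL).
#' @export
aggregate_to_order <- function(counts, taxonomy) {
  missing_taxa <- setdiff(rownames(counts), taxonomy$taxon)
  if (length(missing_taxa))
    stop("taxa without taxonomy: ", paste(head(missing_taxa, 5), collapse = ", "),
         if (length(missing_taxa) > 5) " ..." else "")
  rel <- relative_abundance(counts)
  ord <- taxonomy$order[match(rownames(counts), taxonomy$taxon)]
  ab <- rowsum(rel, group = ord)
  guild <- NULL
  if ("guild" %in% names(taxonomy)) {
    g <- tapply(taxonomy$guild[match(rownames(counts), taxonomy$taxon)], ord,
                function(x) names(sort(table(x), decreasing = TRUE))[1])
    guild <- setNames(as.character(g), names(g))[rownames(ab)]
    names(guild) <- rownames(ab)
  }
  list(abundance = ab, guild = guild)
}

#' Drop orders with low mean relative abundance
#'
#' Orders whose mean relative abundance across samples is strictly below
#' `threshold` are removed (a mean of exactly `threshold` is retained).
#'
#' @param abundance orders x samples relative-abundance matrix.
#' @param threshold mean relative-abundance cut-off (default 0.01).
#' @export
filter_mean_relabund <- function(abundance, threshold = 0.01) {
  keep <- rowMeans(abundance) >= threshold
  if (!any(keep)) stop("no orders pass the mean relative-abundance filter")
  abundance[keep, , drop = FALSE]
}

#' Spearman rank correlation matrix with t-distribution p-values
#'
#' Ranks each row across samples (average ranks for ties) and computes all
#' pairwise Pearson correlations of the ranks. Two-sided p-values come from
#' the t transform `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 degrees of
#' freedom. Rows with zero variance get NA against every partner.
#'
#' @param x variables x samples matrix (>= 4 samples).
#' @return List with `rho`, `p` (matrices) and `n` (number of samples).
#' @export
spearman_matrix <- function(x) {
  n <- ncol(x)
  if (n < 4) stop("need at least 4 samples")
  rk <- t(apply(x, 1, rank))
  const <- apply(rk, 1, function(r) var(r) == 0)
  rho <- suppressWarnings(cor(t(rk)))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- 1
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[is.na(rho)] <- NA
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Build a thresholded co-occurrence network
#'
#' An undirected edge connects two orders iff |rho| > `rho_threshold` and
#' p < `alpha`; the sign of rho labels the edge positive or negative.
#' Undefined correlations never produce an edge. All filtered orders remain
#' as nodes, including isolated ones.
#'
#' @param spearman result of [spearman_matrix()] (or a compatible list).
#' @param rho_threshold absolute-correlation gate in (0, 1).
#' @param alpha p-value gate.
#' @param mean_abundance optional named vector of node mean relative
#'   abundances.
#' @param guild optional named vector of node guilds.
#' @return List of class `cooccurrence_network` with `edges` (data frame:
#'   source, target, rho, p, sign) and `nodes` (data frame).
#' @export
build_network <- function(spearman, rho_threshold = 0.4, alpha = 0.05,
                          mean_abundance = NULL, guild = NULL) {
  if (rho_threshold <= 0 || rho_threshold >= 1)
    stop("rho_threshold must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  rho <- spearman$rho; p <- spearman$p
  orders <- rownames(rho)
  idx <- which(upper.tri(rho) & !is.na(rho) & abs(rho) > rho_threshold &
                 p < alpha, arr.ind = TRUE)
  edges <- data.frame(
    source = orders[idx[, 1]], target = orders[idx[, 2]],
    rho = rho[idx], p = p[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  nodes <- data.frame(order = orders, stringsAsFactors = FALSE)
  if (!is.null(mean_abundance)) nodes$mean_abundance <- unname(mean_abundance[orders])
  if (!is.null(guild)) nodes$guild <- unname(guild[orders])
  structure(list(edges = edges, nodes = nodes), class = "cooccurrence_network")
}

#' Summarise a co-occurrence network
#'
#' @param net a `cooccurrence_network`.
#' @return List with edge totals by sign, within- vs cross-guild counts
#'   (when guilds are known) and per-node degree.
#' @export
network_summary <- function(net) {
  e <- net$edges
  degree <- setNames(rep(0L, nrow(net$nodes)), net$nodes$order)
  if (nrow(e)) {
    tab <- table(c(e$source, e$target))
    degree[names(tab)] <- as.integer(tab)
  }
  out <- list(n_edges = nrow(e),
              n_positive = sum(e$sign == "positive"),
              n_negative = sum(e$sign == "negative"),
              degree = degree)
  if (!is.null(net$nodes$guild) && nrow(e)) {
    g <- setNames(net$nodes$guild, net$nodes$order)
    same <- g[e$source] == g[e$target]
    out$n_within_guild <- sum(same)
    out$n_cross_guild <- sum(!same)
  } else if (!is.null(net$nodes$guild)) {
    out$n_within_guild <- 0L; out$n_cross_guild <- 0L
  }
  out
}

#' Write a network as Cytoscape-importable TSVs
#'
#' Writes `<prefix>_edges.tsv` (source, target, rho, p, sign) and
#' `<prefix>_nodes.tsv`.
#'
#' @param net a `cooccurrence_network`.
#' @param prefix output path prefix.
#' @export
write_edge_list <- function(net, prefix) {
  write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(net$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
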