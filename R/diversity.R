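# Rarefaction, alpha diversity, community transforms, Bray-Curtis / PCoA,
# depth-group comparisons and shared-taxon summaries.

#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled uniformly without replacement to
#' exactly `depth` reads (a single draw, not an average over draws).
#' Samples with fewer than `depth` reads are dropped with a warning.
#'
#' @param counts taxa x samples count matrix.
#' @param depth target reads per sample.
#' @param seed random seed.
#' @return Rarefied count matrix; taxa rows are retained even if empty.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  counts <- validate_counts(counts, require_nonzero = FALSE)
  if (depth < 1) stop("depth must be >= 1")
  keep <- colSums(counts) >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(counts)[!keep], collapse = ", "))
  x <- t(counts[, keep, drop = FALSE])
  set.seed(seed)
  # vegan warns whenever the smallest positive count exceeds 1 (a heuristic
  # for already-normalised data); inputs here are validated integer counts
  r <- withCallingHandlers(vegan::rrarefy(x, depth),
                           warning = function(w) {
                             if (grepl("observed counts", conditionMessage(w)))
                               invokeRestart("muffleWarning")
                           })
  out <- t(r)
  storage.mode(out) <- "integer"
  out
}

#' Shannon-Wiener diversity (natural log) of one sample
#' @param x non-negative count (or abundance) vector with a positive total.
#' @return H = -sum p log p.
#' @export
shannon <- function(x) {
  .check_sample(x)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Gini-Simpson diversity of one sample
#' @param x count vector.
#' @return 1 - sum p^2, in \[0, 1\].
#' @export
simpson <- function(x) {
  .check_sample(x)
  p <- x / sum(x)
  1 - sum(p^2)
}

#' Observed richness of one sample
#' @param x count vector.
#' @return Number of taxa with count > 0.
#' @export
richness <- function(x) {
  .check_sample(x)
  sum(x > 0)
}

#' Pielou's evenness of one sample
#'
#' J = H / ln(S) with natural-log Shannon H; undefined (NA) when S = 1.
#' @param x count vector.
#' @export
pielou <- function(x) {
  s <- richness(x)
  if (s < 2) return(NA_real_)
  shannon(x) / log(s)
}

#' Good's coverage of one sample
#'
#' 1 - F1/N, where F1 is the number of taxa observed exactly once and N the
#' total reads: the estimated fraction of reads drawn from observed taxa.
#' @param x count vector.
#' @export
goods_coverage <- function(x) {
  .check_sample(x)
  1 - sum(x == 1) / sum(x)
}

.check_sample <- function(x) {
  if (length(x) == 0 || sum(x) <= 0) stop("sample has no reads")
  if (any(x < 0)) stop("negative counts")
  invisible(x)
}

#' Faith's phylogenetic diversity (rooted)
#'
#' Sum of branch lengths of the minimal rooted subtree connecting the
#' present taxa to the root (the stem to the root is included; conventions
#' differ and this choice is deliberate). The empty set has PD 0.
#'
#' @param present character vector of present taxa (must be tips of `tree`).
#' @param tree rooted phylogeny with branch lengths.
#' @export
faith_pd <- function(present, tree) {
  if (length(present) == 0) return(0)
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown)) stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  picante::pd(comm, tree, include.root = TRUE)$PD
}

#' Alpha-diversity table
#'
#' Per-sample Shannon-Wiener H, Gini-Simpson, Pielou J, observed richness,
#' Good's coverage, and (when a tree is supplied) rooted Faith PD.
#'
#' @param counts taxa x samples count matrix.
#' @param tree optional phylogeny covering the observed taxa.
#' @return Data frame with one row per sample.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  counts <- validate_counts(counts)
  out <- data.frame(
    sample = colnames(counts),
    shannon = apply(counts, 2, shannon),
    simpson = apply(counts, 2, simpson),
    pielou = apply(counts, 2, pielou),
    richness = apply(counts, 2, richness),
    goods_coverage = apply(counts, 2, goods_coverage),
    row.names = NULL)
  if (!is.null(tree))
    out$faith_pd <- apply(counts, 2, function(x)
      faith_pd(rownames(counts)[x > 0], tree))
  out
}

#' Relative-abundance transform
#' @param counts taxa x samples matrix with positive column sums.
#' @return Matrix whose columns sum to 1.
#' @export
relative_abundance <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total sample")
  sweep(counts, 2, tot, "/")
}

#' Hellinger transform
#'
#' Square root of relative abundance, so each sample's squared values sum
#' to 1; makes Euclidean-geometry ordinations appropriate for count data.
#' @param counts taxa x samples matrix with positive column sums.
#' @export
hellinger <- function(counts) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total sample")
  t(vegan::decostand(t(counts), method = "hellinger"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(u, v) = sum |u_i - v_i| / sum (u_i + v_i) over taxa; works on counts or
#' transformed abundances.
#'
#' @param x taxa x samples matrix.
#' @return A [stats::dist] over samples.
#' @export
bray_curtis <- function(x) {
  if (ncol(x) < 2) stop("need at least two samples")
  if (any(colSums(x) <= 0)) stop("all-zero sample: Bray-Curtis undefined")
  vegan::vegdist(t(x), method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centred -D^2/2 matrix. Axes are ordered
#' by eigenvalue; negative eigenvalues are reported but their axes are not
#' returned as coordinates.
#'
#' @param d a distance object or symmetric matrix.
#' @return List with `points` (samples x axes), `eig` (all eigenvalues,
#'   non-increasing), and `rel_eig` (eigenvalues over their positive sum).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(m)
  sc <- cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE)
  eig <- sort(sc$eig, decreasing = TRUE)
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0)
    pts <- matrix(0, n, 1, dimnames = list(rownames(m), "Axis1"))
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  list(points = pts, eig = eig, rel_eig = eig / sum(eig[eig > 0]))
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p by full enumeration of rank splits (with average-rank
#' ties) when nA + nB <= 12; otherwise a normal approximation with tie
#' correction and continuity correction. The two-sided exact p is
#' 2 * min(P(W <= w), P(W >= w)), capped at 1.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return List with `statistic` (rank sum W of `a`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])
  if (n <= 12) {
    splits <- combn(n, na)
    ws <- colSums(matrix(r[splits], nrow = na))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
    list(statistic = w, p_value = p, method = "exact")
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    list(statistic = w, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal")
  }
}

#' Per-layer unique and all-layer shared taxon counts
#'
#' A taxon is present in a layer if its summed count there is positive.
#' Reports the number of taxa present in every layer and the number
#' exclusive to each layer.
#'
#' @param counts taxa x samples count matrix.
#' @param grouping named vector (or factor) mapping every sample to a layer.
#' @return List with `shared_all` and named vector `unique_per_layer`.
#' @export
shared_taxon_counts <- function(counts, grouping) {
  counts <- validate_counts(counts, require_nonzero = FALSE)
  if (is.null(names(grouping))) stop("grouping must be named by sample")
  unknown <- setdiff(colnames(counts), names(grouping))
  if (length(unknown)) stop("samples missing from grouping: ",
                            paste(unknown, collapse = ", "))
  g <- factor(unname(grouping[colnames(counts)]))
  pres <- vapply(levels(g), function(l)
    rowSums(counts[, g == l, drop = FALSE]) > 0, logical(nrow(counts)))
  n_layers <- rowSums(pres)
  list(shared_all = sum(n_layers == ncol(pres)),
       unique_per_layer = colSums(pres & n_layers == 1))
}
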