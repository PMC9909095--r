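# Geographic distance, distance decay, Mantel tests, one-factor PERMANOVA,
# PCNM spatial eigenfunctions, RDA and variation partitioning: the
# environmental-versus-spatial driver suite.

#' Great-circle distance matrix between samples (km)
#'
#' Haversine distances on a sphere of radius 6,371 km from the `longitude`
#' and `latitude` columns of a sample frame.
#'
#' @param frame data frame with `sample`, `longitude`, `latitude` columns.
#' @return A [stats::dist] over samples, in kilometres.
#' @export
haversine_matrix <- function(frame) {
  m <- geosphere::distm(cbind(frame$longitude, frame$latitude),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371)) 
  dimnames(m) <- list(frame$sample, frame$sample)
  stats::as.dist(m)
}

.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' Mantel test between two distance matrices
#'
#' Correlation of the lower triangles with a permutation p-value obtained
#' by simultaneously permuting rows and columns of the second matrix;
#' one-sided (greater), `p = (1 + #{perm >= obs}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` all n! - 1 non-identity permutations are used and
#' the p-value is exact.
#'
#' @param d1,d2 distance objects or symmetric matrices with matching labels.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of random permutations (default 999).
#' @param seed random seed.
#' @param exhaustive enumerate every permutation (n <= 8 recommended).
#' @return List with `statistic`, `p_value`, `n_perm`, `method`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999L, seed = 1L, exhaustive = FALSE) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (nrow(m1) < 4) stop("need at least 4 samples")
  if (!is.null(dimnames(m1)[[1]]) && !is.null(dimnames(m2)[[1]])) {
    if (!setequal(rownames(m1), rownames(m2))) stop("label mismatch")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  if (sd(m1[lower.tri(m1)]) == 0 || sd(m2[lower.tri(m2)]) == 0)
    stop("constant distance matrix: Mantel statistic undefined")
  if (exhaustive) {
    perms <- .all_perms(nrow(m1))
    perms <- perms[rowSums(perms == matrix(seq_len(ncol(perms)),
                                           nrow(perms), ncol(perms),
                                           byrow = TRUE)) != ncol(perms), ,
                   drop = FALSE]
  } else {
    set.seed(seed)
    perms <- n_perm
  }
  fit <- vegan::mantel(stats::as.dist(m1), stats::as.dist(m2),
                       method = method, permutations = perms)
  list(statistic = unname(fit$statistic), p_value = unname(fit$signif),
       n_perm = if (is.matrix(perms)) nrow(perms) else n_perm,
       method = method)
}

#' Distance-decay relationship
#'
#' Spearman correlation between community dissimilarity and geographic
#' distance, with a Mantel row/column permutation p-value (pairwise
#' distances are not independent, so an ordinary correlation test would be
#' anticonservative).
#'
#' @param community_d community distance matrix (e.g. Bray-Curtis).
#' @param geo_d geographic distance matrix with matching labels.
#' @param n_perm permutations (default 999).
#' @param seed random seed.
#' @return List with `r`, `p_value`, `n_perm`.
#' @export
distance_decay <- function(community_d, geo_d, n_perm = 999L, seed = 1L) {
  fit <- mantel_test(community_d, geo_d, method = "spearman",
                     n_perm = n_perm, seed = seed)
  list(r = fit$statistic, p_value = fit$p_value, n_perm = n_perm)
}

#' One-factor PERMANOVA
#'
#' Partitions the sum of squared inter-point distances among and within the
#' levels of a single factor (`SS_total = sum d^2 / N`; pseudo-F on the
#' among/within decomposition) with a label-permutation p-value.
#'
#' @param d distance object or symmetric matrix over samples.
#' @param groups factor (or named vector) of group labels, >= 2 levels.
#' @param n_perm permutations (default 999).
#' @param seed random seed.
#' @param blocks optional factor of the same length as `groups`: restrict
#'   permutations to occur within its levels. Use this to test one factor
#'   while conditioning on another that structures the distances (e.g.
#'   stations within depth layers); with free permutation such a test is
#'   conservative, not exact.
#' @return List with `f`, `r2`, `p_value`, `df_among`, `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L, blocks = NULL) {
  m <- as.matrix(d)
  if (!is.null(names(groups)) && !is.null(rownames(m)))
    groups <- groups[rownames(m)]
  g <- factor(unname(groups))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (length(g) != nrow(m)) stop("groups length must match samples")
  set.seed(seed)
  df <- data.frame(group = g)
  perm <- if (is.null(blocks)) n_perm else
    permute::how(blocks = as.factor(blocks), nperm = n_perm)
  fit <- vegan::adonis2(stats::as.dist(m) ~ group, data = df,
                        permutations = perm)
  list(f = fit$F[1], r2 = fit$R2[1], p_value = fit$`Pr(>F)`[1],
       df_among = fit$Df[1], df_within = fit$Df[2])
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at the longest minimum-spanning-tree edge (larger
#' distances replaced by four times the threshold) and double-centred;
#' eigenvectors with positive eigenvalues, ordered by eigenvalue, serve as
#' spatial predictors.
#'
#' @param geo_d geographic distance object or symmetric matrix.
#' @param n_axes optional cap on the number of returned eigenfunctions
#'   (the driver analyses default to the first five).
#' @return List with `vectors` (samples x axes), `values` (positive
#'   eigenvalues) and `threshold`.
#' @export
pcnm_axes <- function(geo_d, n_axes = NULL) {
  dd <- stats::as.dist(geo_d)
  if (max(dd) == 0) stop("all points coincide")
  fit <- vegan::pcnm(dd)
  v <- fit$vectors
  vals <- fit$values[fit$values > 0]
  if (!is.null(n_axes)) {
    k <- min(n_axes, ncol(v))
    v <- v[, seq_len(k), drop = FALSE]
    vals <- vals[seq_len(k)]
  }
  rownames(v) <- attr(dd, "Labels")
  list(vectors = v, values = vals, threshold = fit$threshold)
}

.prep_predictors <- function(predictors) {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  keepc <- apply(x, 2, function(v) sd(v) > 0)
  x <- scale(x[, keepc, drop = FALSE])
  q <- qr(x)
  dropped <- character()
  if (q$rank < ncol(x)) {
    keep <- q$pivot[seq_len(q$rank)]
    dropped <- colnames(x)[-keep]
    warning("dropping collinear predictor(s): ", paste(dropped, collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  list(x = x, dropped = c(colnames(predictors)[!keepc], dropped))
}

#' Redundancy analysis R-squared
#'
#' Proportion of total response variance captured by the least-squares
#' projection onto the (column-standardised) predictors, with Ezekiel's
#' adjustment `1 - (1 - R2) (n - 1) / (n - p - 1)`. Collinear predictors
#' are dropped with a warning; the adjustment is NA when n <= p + 1.
#'
#' @param response samples x variables community matrix (e.g. the
#'   transposed Hellinger table).
#' @param predictors samples x p matrix or data frame.
#' @return List with `r2`, `adj_r2`, `n`, `p`, `dropped` and
#'   `marginal` (per-predictor marginal R2).
#' @export
rda_r2 <- function(response, predictors) {
  y <- as.matrix(response)
  pp <- .prep_predictors(predictors)
  x <- pp$x
  n <- nrow(y); p <- ncol(x)
  if (nrow(x) != n) stop("response and predictors must share samples")
  fit <- vegan::rda(y ~ x)
  r2 <- vegan::RsquareAdj(fit)$r.squared
  adj <- if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  marginal <- vapply(seq_len(p), function(j)
    vegan::RsquareAdj(vegan::rda(y ~ x[, j]))$r.squared, numeric(1))
  names(marginal) <- colnames(x)
  list(r2 = r2, adj_r2 = adj, n = n, p = p, dropped = pp$dropped,
       marginal = marginal)
}

#' Variation partitioning between environmental and spatial predictors
#'
#' Adjusted-R2 decomposition of community variation into pure
#' environmental \[a\], shared \[b\], pure spatial \[c\] and unexplained
#' \[d\] fractions: `[a+b] = adjR2(Y ~ env)`, `[b+c] = adjR2(Y ~ spat)`,
#' `[a+b+c] = adjR2(Y ~ env + spat)`, with the pure and shared fractions by
#' subtraction and `[d] = 1 - [a+b+c]`. Small negative adjusted fractions
#' are reported as computed and flagged, not clipped.
#'
#' @param response samples x variables community matrix.
#' @param env samples x p environmental predictor matrix.
#' @param spat samples x q spatial predictor matrix (e.g. PCNM vectors).
#' @return List of class `vpa_result` with `a`, `b`, `c`, `d`, the three
#'   component adjusted R2 values, and `negative_fractions`.
#' @export
variation_partitioning <- function(response, env, spat) {
  ab <- rda_r2(response, env)$adj_r2
  bc <- rda_r2(response, spat)$adj_r2
  abc <- rda_r2(response, cbind(as.matrix(env), as.matrix(spat)))$adj_r2
  if (anyNA(c(ab, bc, abc)))
    stop("adjusted R2 undefined (n <= p + 1) for a component model")
  a <- abc - bc; cc <- abc - ab; b <- ab + bc - abc; d <- 1 - abc
  neg <- c(a = a, b = b, c = cc)[c(a, b, cc) < 0]
  structure(list(a = a, b = b, c = cc, d = d,
                 adj_env = ab, adj_spat = bc, adj_full = abc,
                 negative_fractions = names(neg)),
            class = "vpa_result")
}

.ENV_FACTORS <- c("temperature", "salinity", "dissolved_oxygen",
                  "chlorophyll_a", "dip", "tin", "silicate",
                  "longitude", "latitude")

#' Order-by-environment Spearman correlation table
#'
#' Spearman rho and two-sided p for every (order, environmental factor)
#' pair, computed with the same rank machinery as [spearman_matrix()], with
#' significance flags at 0.05 / 0.01 / 0.001. Constant factors give NA.
#'
#' @param orders orders x samples relative-abundance matrix.
#' @param frame sample metadata frame covering the same samples.
#' @param factors metadata columns to correlate against (default: the
#'   seven environmental variables plus longitude and latitude).
#' @return Long data frame: order, factor, rho, p, signif.
#' @export
env_taxon_correlations <- function(orders, frame, factors = .ENV_FACTORS) {
  miss <- setdiff(factors, names(frame))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  idx <- match(colnames(orders), frame$sample)
  if (anyNA(idx)) stop("samples missing from metadata")
  envm <- t(as.matrix(frame[idx, factors, drop = FALSE]))
  colnames(envm) <- colnames(orders)
  sp <- spearman_matrix(rbind(orders, envm))
  io <- seq_len(nrow(orders)); ie <- nrow(orders) + seq_along(factors)
  rho <- sp$rho[io, ie, drop = FALSE]; p <- sp$p[io, ie, drop = FALSE]
  out <- data.frame(
    order = rep(rownames(orders), times = length(factors)),
    factor = rep(factors, each = nrow(orders)),
    rho = as.vector(rho), p = as.vector(p), stringsAsFactors = FALSE)
  out$signif <- cut(out$p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""))
  out$signif[is.na(out$p)] <- ""
  out
}
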