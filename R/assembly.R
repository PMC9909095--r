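# The three-step community assembly framework: phylogenetic turnover
# (bMNTD), its standardised effect size against a tip-shuffle null (bNTI),
# the Bray-Curtis-based Raup-Crick metric against probabilistic assembly
# nulls, and the five-process classification with per-stratum summaries.

.PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
                "dispersal_limitation", "homogenizing_dispersal", "drift")

.ab_matrix <- function(counts, tree) {
  if (!all(rownames(counts) %in% tree$tip.label))
    stop("taxa absent from tree: ",
         paste(head(setdiff(rownames(counts), tree$tip.label), 5), collapse = ", "))
  if (any(colSums(counts) <= 0)) stop("sample with no taxa")
  sweep(counts, 2, colSums(counts), "/")
}

#' Beta mean nearest taxon distance between samples
#'
#' For each taxon present in one sample, the minimum cophenetic distance to
#' any taxon present in the other sample is found; each directional mean
#' (abundance-weighted by the source sample, or unweighted) is computed and
#' bMNTD is half their sum.
#'
#' @param counts taxa x samples matrix (counts or abundances); row names
#'   must be tips of `tree`.
#' @param tree phylogeny with branch lengths.
#' @param weighted abundance-weight the nearest-taxon distances (default).
#' @return A [stats::dist] over samples.
#' @export
bmntd <- function(counts, tree, weighted = TRUE) {
  ab <- .ab_matrix(counts, tree)
  pr <- ape::keep.tip(tree, rownames(ab))
  coph <- cophenetic(pr)[rownames(ab), rownames(ab)]
  m <- cpp_bmntd_pairs(coph, ab, seq_len(nrow(ab)) - 1L, weighted)
  dimnames(m) <- list(colnames(ab), colnames(ab))
  stats::as.dist(m)
}

#' Beta nearest taxon index (bNTI)
#'
#' Standardised effect size of the observed bMNTD against a null in which
#' taxon labels are shuffled across the tips of the regional tree and bMNTD
#' recomputed: `(observed - mean(null)) / sd(null)`. The regional pool is
#' every tip of the supplied phylogeny, i.e. the metacommunity the tree
#' describes; supply a tree pruned to the analysed taxa if the pool should
#' be the observed union. Values beyond +2 indicate heterogeneous selection
#' and below -2 homogeneous selection. Pairs whose null has zero spread
#' (e.g. both samples containing identical taxon sets) are flagged NA with
#' a warning.
#'
#' @param counts taxa x samples matrix; rows must be tips of `tree`.
#' @param tree regional phylogeny (its full tip set is the shuffle pool).
#' @param n_null number of randomisations (default 999).
#' @param seed random seed.
#' @param weighted abundance-weighted bMNTD (default).
#' @return List with `bnti` (samples x samples matrix, NA diagonal),
#'   `bmntd_obs`, `null_mean`, `null_sd` and `n_undefined`.
#' @export
bnti <- function(counts, tree, n_null = 999L, seed = 1L, weighted = TRUE) {
  if (n_null < 2) stop("n_null must be >= 2")
  ab <- .ab_matrix(counts, tree)
  pool <- tree$tip.label
  coph <- cophenetic(tree)[pool, pool]
  full <- matrix(0, length(pool), ncol(ab), dimnames = list(pool, colnames(ab)))
  full[rownames(ab), ] <- ab
  nt <- length(pool); ns <- ncol(ab)
  obs <- cpp_bmntd_pairs(coph, full, seq_len(nt) - 1L, weighted)
  set.seed(seed)
  s1 <- s2 <- matrix(0, ns, ns)
  for (k in seq_len(n_null)) {
    nb <- cpp_bmntd_pairs(coph, full, sample.int(nt) - 1L, weighted)
    s1 <- s1 + nb; s2 <- s2 + nb * nb
  }
  mu <- s1 / n_null
  sdv <- sqrt(pmax((s2 - n_null * mu^2) / (n_null - 1), 0))
  z <- (obs - mu) / sdv
  undef <- sdv < 1e-12
  z[undef] <- NA
  diag(z) <- NA
  n_undef <- sum(undef[upper.tri(undef)])
  if (n_undef > 0)
    warning(n_undef, " sample pair(s) have a degenerate bNTI null (sd = 0); flagged NA")
  dimnames(z) <- dimnames(mu) <- dimnames(sdv) <- list(colnames(ab), colnames(ab))
  dimnames(obs) <- list(colnames(ab), colnames(ab))
  list(bnti = z, bmntd_obs = stats::as.dist(obs), null_mean = mu,
       null_sd = sdv, n_undefined = n_undef)
}

#' Bray-Curtis-based Raup-Crick metric (RC-bray)
#'
#' Each null iteration assembles one null community per sample: the
#' observed number of taxa is drawn without replacement with probability
#' proportional to occupancy frequency across the metacommunity, and the
#' observed number of reads is then allocated among the drawn taxa with
#' probability proportional to metacommunity relative abundance. Null
#' Bray-Curtis distances are compared with the observed ones:
#' `RC = 2 * ((#null < obs) + 0.5 * (#null = obs)) / n_null - 1`, in
#' \[-1, 1\]. The metacommunity pool is the analysed table itself.
#'
#' @param counts taxa x samples count matrix.
#' @param n_null number of null iterations (default 999).
#' @param seed random seed.
#' @return Samples x samples matrix of RC values (NA diagonal).
#' @export
rc_bray <- function(counts, n_null = 999L, seed = 1L) {
  counts <- validate_counts(counts)
  nt <- nrow(counts); ns <- ncol(counts)
  occ <- rowSums(counts > 0)
  pool_ab <- rowSums(counts) / sum(counts)
  S <- colSums(counts > 0); N <- colSums(counts)
  obs <- as.matrix(bray_curtis(counts))
  less <- eq <- matrix(0, ns, ns)
  set.seed(seed)
  for (k in seq_len(n_null)) {
    nullc <- matrix(0, nt, ns)
    for (s in seq_len(ns)) {
      idx <- sample.int(nt, S[s], prob = occ)
      nullc[idx, s] <- as.numeric(rmultinom(1, N[s], pool_ab[idx]))
    }
    nb <- as.matrix(vegan::vegdist(t(nullc), method = "bray"))
    less <- less + (nb < obs - 1e-12)
    eq <- eq + (abs(nb - obs) <= 1e-12)
  }
  rc <- 2 * (less + 0.5 * eq) / n_null - 1
  diag(rc) <- NA
  dimnames(rc) <- dimnames(obs)
  rc
}

#' Classify sample pairs into the five assembly processes
#'
#' bNTI > +2: heterogeneous selection; bNTI < -2: homogeneous selection;
#' otherwise by RC-bray: > +0.95 dispersal limitation, < -0.95 homogenizing
#' dispersal, else drift. Inequalities are strict: bNTI of exactly +/-2
#' falls through to the stochastic step, RC of exactly +/-0.95 is drift.
#'
#' @param bnti_value numeric vector of bNTI values (NA allowed; stays NA).
#' @param rc_value numeric vector of RC-bray values; required (non-NA)
#'   wherever |bNTI| < 2.
#' @return Factor with the five process levels.
#' @export
classify_pair <- function(bnti_value, rc_value = NULL) {
  n <- length(bnti_value)
  if (is.null(rc_value)) rc_value <- rep(NA_real_, n)
  if (length(rc_value) != n) stop("bnti_value and rc_value lengths differ")
  need_rc <- !is.na(bnti_value) & abs(bnti_value) <= 2
  if (any(need_rc & is.na(rc_value)))
    stop("RC-bray value required when |bNTI| <= 2")
  out <- rep(NA_character_, n)
  out[!is.na(bnti_value) & bnti_value > 2] <- "heterogeneous_selection"
  out[!is.na(bnti_value) & bnti_value < -2] <- "homogeneous_selection"
  sto <- need_rc
  out[sto & rc_value > 0.95] <- "dispersal_limitation"
  out[sto & rc_value < -0.95] <- "homogenizing_dispersal"
  out[sto & abs(rc_value) <= 0.95] <- "drift"
  factor(out, levels = .PROCESSES)
}

#' Per-stratum fractions of the five assembly processes
#'
#' @param pairs data frame with columns `sample_a`, `sample_b`, `process`
#'   (factor or character; NA = unclassified pair).
#' @param strata optional named vector mapping samples to strata; a pair is
#'   counted in a stratum when both members belong to it. An `all` stratum
#'   over every classified pair is always included.
#' @return Data frame: stratum, one column per process (fractions summing
#'   to 1 over classified pairs), `n_pairs`, `n_unclassified`.
#' @export
process_fractions <- function(pairs, strata = NULL) {
  tally <- function(sub, name) {
    cls <- factor(as.character(sub$process), levels = .PROCESSES)
    n_ok <- sum(!is.na(cls))
    if (n_ok == 0) return(NULL)
    fr <- as.list(table(cls) / n_ok)
    data.frame(stratum = name, as.data.frame(fr, check.names = FALSE),
               n_pairs = n_ok, n_unclassified = sum(is.na(cls)),
               check.names = FALSE)
  }
  out <- list(tally(pairs, "all"))
  if (!is.null(strata)) {
    for (st in unique(stats::na.omit(unname(strata)))) {
      inset <- names(strata)[!is.na(strata) & strata == st]
      sub <- pairs[pairs$sample_a %in% inset & pairs$sample_b %in% inset, ]
      row <- if (nrow(sub)) tally(sub, st) else NULL
      if (is.null(row)) warning("stratum '", st, "' has no classified pairs; omitted")
      out <- c(out, list(row))
    }
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Full assembly null-model analysis
#'
#' Runs [bnti()] and [rc_bray()] on a count table, classifies every sample
#' pair and summarises process fractions, optionally per stratum. RC-bray
#' values are reported only where the classification needed them
#' (|bNTI| <= 2), as the framework prescribes.
#'
#' @param counts taxa x samples count matrix.
#' @param tree regional phylogeny.
#' @param n_null randomisations for both null models (default 999).
#' @param seed master seed (bNTI uses `seed`, RC-bray `seed + 1`).
#' @param strata optional named vector mapping samples to strata.
#' @param weighted abundance-weighted bMNTD (default).
#' @return List with `pairs` (per-pair data frame), `fractions`,
#'   `bnti` (full result list) and `rc` (matrix).
#' @export
assembly_analysis <- function(counts, tree, n_null = 999L, seed = 1L,
                              strata = NULL, weighted = TRUE) {
  bz <- bnti(counts, tree, n_null = n_null, seed = seed, weighted = weighted)
  rc <- rc_bray(counts, n_null = n_null, seed = seed + 1L)
  sn <- colnames(bz$bnti)
  iu <- which(upper.tri(bz$bnti), arr.ind = TRUE)
  b <- bz$bnti[iu]; r <- rc[iu]
  r_used <- ifelse(!is.na(b) & abs(b) <= 2, r, NA_real_)
  pairs <- data.frame(sample_a = sn[iu[, 1]], sample_b = sn[iu[, 2]],
                      bmntd = as.matrix(bz$bmntd_obs)[iu], bnti = b,
                      rc_bray = r_used,
                      process = classify_pair(b, r),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, fractions = process_fractions(pairs, strata),
       bnti = bz, rc = rc)
}
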