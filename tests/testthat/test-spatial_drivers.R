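test_that("haversine distances match reference great-circle values", {
  fr <- toy_frame(c("p", "q", "r"), lon = c(0, 0, 0), lat = c(0, 1, 0))
  d <- as.matrix(haversine_matrix(fr))
  expect_equal(d["p", "r"], 0)
  expect_equal(d["p", "q"], 2 * pi * 6371 / 360, tolerance = 1e-4)
  anti <- toy_frame(c("a", "b"), lon = c(0, 180), lat = c(0, 0))
  expect_equal(max(haversine_matrix(anti)), pi * 6371, tolerance = 1e-4)
})

test_that("Mantel test matches the exhaustive permutation oracle at n = 5", {
  set.seed(10)
  x <- matrix(rnorm(10), 5, 2); y <- matrix(rnorm(10), 5, 2)
  d1 <- dist(x); d2 <- dist(y)
  got <- mantel_test(d1, d2, method = "pearson", exhaustive = TRUE)

  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  v1 <- m1[lower.tri(m1)]
  obs <- cor(v1, m2[lower.tri(m2)])
  perms <- oceancomm:::.all_perms(5)
  stats <- apply(perms, 1, function(p) {
    mp <- m2[p, p]; cor(v1, mp[lower.tri(mp)])
  })
  idn <- which(apply(perms, 1, function(p) all(p == 1:5)))
  exact_p <- (sum(stats[-idn] >= obs) + 1) / 120
  expect_equal(got$statistic, obs, tolerance = 1e-12)
  expect_equal(got$p_value, exact_p, tolerance = 1e-12)
  expect_equal(got$n_perm, 119)

  expect_equal(mantel_test(d1, d1, n_perm = 99)$statistic, 1)
  expect_gte(mantel_test(d1, d2, n_perm = 99)$p_value, 1 / 100)
  cst <- matrix(1, 5, 5); diag(cst) <- 0
  expect_error(mantel_test(cst, m2), "constant")
})

test_that("distance decay detects monotone structure and is rank-invariant", {
  set.seed(3)
  coords <- cbind(runif(12), runif(12))
  geo <- dist(coords)
  comm <- as.dist(log1p(as.matrix(geo)) * 2 + 0.1)  # monotone transform
  dd <- distance_decay(comm, geo, n_perm = 199, seed = 1)
  expect_equal(dd$r, 1)
  expect_lte(dd$p_value, 0.05)
  # Spearman statistic invariant to monotone transforms of either matrix
  dd2 <- distance_decay(comm, as.dist(as.matrix(geo)^3), n_perm = 99, seed = 1)
  expect_equal(dd2$r, 1)
})

test_that("PERMANOVA reproduces the direct sum-of-squares decomposition", {
  # hand-checkable 4-sample toy: groups {a1,a2} vs {b1,b2}
  m <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 2,
                5, 5, 2, 0), 4, 4,
              dimnames = list(c("a1", "a2", "b1", "b2"),
                              c("a1", "a2", "b1", "b2")))
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  got <- permanova(m, g, n_perm = 199, seed = 1)
  ss_total <- sum(m[upper.tri(m)]^2) / 4
  ss_within <- (1^2) / 2 + (2^2) / 2
  ss_among <- ss_total - ss_within
  expect_equal(got$r2, ss_among / ss_total, tolerance = 1e-12)
  expect_equal(got$f, (ss_among / 1) / (ss_within / 2), tolerance = 1e-12)

  # complete separation: within-group distances all zero
  sep <- matrix(3, 4, 4, dimnames = dimnames(m))
  sep[1:2, 1:2] <- 0; sep[3:4, 3:4] <- 0
  expect_equal(permanova(sep, g, n_perm = 99, seed = 1)$r2, 1)
  expect_error(permanova(m, setNames(rep("A", 4), rownames(m))), "two groups")
})

test_that("PCNM eigenfunctions are centred, orthogonal and track a line", {
  fr <- toy_frame(sprintf("s%02d", 1:10), lon = seq(0, 9) * 0.5, lat = rep(0, 10))
  geo <- haversine_matrix(fr)
  pc <- pcnm_axes(geo)
  v <- pc$vectors
  expect_lt(ncol(v), 10)
  expect_true(all(abs(colMeans(v)) < 1e-10))
  gram <- crossprod(v)
  expect_true(all(abs(gram[upper.tri(gram)]) < 1e-10))
  expect_true(all(pc$values > 0))
  # first eigenfunction carries the broadest spatial structure: a single
  # zero crossing along the transect and a strong linear trend
  expect_equal(sum(diff(sign(v[, 1])) != 0), 1)
  expect_gt(abs(cor(v[, 1], seq_len(10))), 0.8)
  same <- toy_frame(c("x", "y"), lon = c(5, 5), lat = c(2, 2))
  expect_error(pcnm_axes(haversine_matrix(same)), "coincide")
})

test_that("RDA R2 and the Ezekiel adjustment behave as defined", {
  set.seed(5)
  n <- 11
  x <- scale(rnorm(n), scale = FALSE)
  e <- rnorm(n); e <- e - x %*% (crossprod(x, e) / crossprod(x))
  e <- e - mean(e)
  e <- e * sqrt(sum(x^2) / sum(e^2))
  y <- x + e                      # R2 exactly 0.5 by construction
  fit <- rda_r2(matrix(y, ncol = 1), matrix(x, ncol = 1))
  expect_equal(fit$r2, 0.5, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - 0.5 * 10 / 9, tolerance = 1e-10)

  yo <- matrix(e, ncol = 1)       # orthogonal to predictor
  expect_lt(rda_r2(yo, matrix(x, ncol = 1))$r2, 1e-10)
  yl <- cbind(2 * x + 1, -x)      # exact linear map
  fit2 <- rda_r2(yl, matrix(x, ncol = 1))
  expect_equal(fit2$r2, 1, tolerance = 1e-10)
  expect_equal(fit2$adj_r2, 1, tolerance = 1e-10)

  expect_warning(rda_r2(matrix(y, ncol = 1), cbind(a = x, b = 2 * x)),
                 "collinear")
})

test_that("variation partitioning closes algebraically and finds the truth", {
  set.seed(6)
  n <- 40
  env <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("e1", "e2")))
  sp <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("s1", "s2")))
  sp <- qr.resid(qr(cbind(1, env)), sp)   # orthogonal to env
  y <- env %*% rbind(c(1, 0.5), c(-0.5, 1)) + matrix(rnorm(2 * n, sd = 0.3), n, 2)
  vp <- variation_partitioning(y, env, sp)
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-9)
  expect_lt(abs(vp$c), 0.05)
  expect_gt(vp$a, vp$c)

  # perfectly confounded predictors: all signal shared
  vp2 <- suppressWarnings(variation_partitioning(y, env, env))
  expect_lt(abs(vp2$a), 1e-8)
  expect_lt(abs(vp2$c), 1e-8)
  expect_gt(vp2$b, 0.5)

  # cross-check against vegan's varpart (vegan labels pure fractions
  # [a] = X1|X2 and [b] = X2|X1, with the shared fraction as [c])
  ref <- vegan::varpart(y, env, sp)$part$indfract$Adj.R.square
  expect_equal(c(vp$a, vp$c, vp$b, vp$d), ref, tolerance = 1e-10)
})

test_that("order-environment correlations reuse the Spearman machinery", {
  cfg <- scenario_config("drift", n_taxa = 30, n_stations = 4,
                         layers = paste0("L", 1:3), reads = 500, seed = 2)
  sim <- simulate_metacommunity(cfg)
  tax <- synthetic_taxonomy(sim$tree, n_orders = 6)
  agg <- aggregate_to_order(sim$counts, tax)
  orders <- agg$abundance
  # an order tracking a monotone transform of temperature exactly
  orders <- rbind(orders, tracker = rank(sim$frame$temperature) / 100)
  out <- env_taxon_correlations(orders, sim$frame)
  expect_equal(out$rho[out$order == "tracker" & out$factor == "temperature"], 1)
  sp <- spearman_matrix(rbind(orders[1, , drop = FALSE],
                              temp = sim$frame$temperature[
                                match(colnames(orders), sim$frame$sample)]))
  expect_equal(out$rho[out$order == rownames(orders)[1] &
                         out$factor == "temperature"],
               sp$rho[1, "temp"])
  # constant factor flagged undefined
  fr2 <- sim$frame; fr2$salinity <- 34
  out2 <- env_taxon_correlations(orders, fr2)
  expect_true(all(is.na(out2$rho[out2$factor == "salinity"])))
})

test_that("dispersal limitation produces distance decay; homogenizing dispersal does not", {
  decay <- function(regime, rep) {
    cfg <- scenario_config(regime, n_taxa = 100, n_stations = 8,
                           layers = paste0("L", 1:2), reads = 1000,
                           seed = 40000 + rep)
    sim <- simulate_metacommunity(cfg)
    bc <- bray_curtis(hellinger(sim$counts))
    dd <- distance_decay(bc, haversine_matrix(sim$frame),
                         n_perm = 199, seed = rep)
    c(r = dd$r, rej = dd$p_value <= 0.05)
  }
  dl <- vapply(1:10, function(r) decay("dispersal_limitation", r), numeric(2))
  expect_gte(mean(dl["rej", ]), 0.8)
  expect_gt(mean(dl["r", ]), 0)
  hd <- vapply(1:20, function(r) decay("homogenizing_dispersal", r), numeric(2))
  expect_lte(mean(hd["rej", ]), 0.2)   # no spurious decay beyond noise
})
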