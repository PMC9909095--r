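test_that("bMNTD matches its definition on hand-checkable trees", {
  qt <- quartet_tree()
  ab <- matrix(0, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  ab["A", "s1"] <- 10; ab["C", "s2"] <- 10
  expect_equal(as.numeric(bmntd(ab, qt)), 4)  # cophenetic A-C both directions

  same <- matrix(c(3, 1, 0, 0, 3, 1, 0, 0), 4, 2,
                 dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_equal(as.numeric(bmntd(same, qt)), 0)

  eq <- matrix(c(2, 2, 0, 0, 0, 0, 2, 2), 4, 2,
               dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_equal(as.numeric(bmntd(eq, qt, weighted = TRUE)),
               as.numeric(bmntd(eq, qt, weighted = FALSE)))
  expect_error(bmntd(rbind(eq, Z = c(1, 1)), qt), "absent from tree")
})

test_that("bMNTD agrees with a brute-force cophenetic oracle on small trees", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rcoal(6)
    tr$tip.label <- paste0("t", 1:6)
    m <- matrix(rpois(12, 3), 6, 2, dimnames = list(tr$tip.label, c("u", "v")))
    m[m == 0 & row(m) == 1] <- 1
    if (any(colSums(m) == 0)) m[1, colSums(m) == 0] <- 1
    coph <- cophenetic(tr)[rownames(m), rownames(m)]
    for (w in c(TRUE, FALSE)) {
      got <- as.numeric(bmntd(m, tr, weighted = w))
      expect_equal(got, oracle_bmntd(m[, 1], m[, 2], coph, weighted = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted bMNTD matches picante::comdistnt", {
  tr <- simulate_phylogeny(40, seed = 2)
  m <- random_counts(40, 5, seed = 3)
  rownames(m) <- tr$tip.label
  mine <- as.matrix(bmntd(m, tr, weighted = TRUE))
  ref <- as.matrix(picante::comdistnt(t(m), cophenetic(tr),
                                      abundance.weighted = TRUE))
  ref <- ref[rownames(mine), colnames(mine)]
  expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("bNTI is deterministic, centred under its own null and scale-invariant", {
  tr <- simulate_phylogeny(50, seed = 4)
  m <- random_counts(50, 6, seed = 5)
  rownames(m) <- tr$tip.label
  b1 <- bnti(m, tr, n_null = 99, seed = 7)
  b2 <- bnti(m, tr, n_null = 99, seed = 7)
  expect_identical(b1$bnti, b2$bnti)

  # uniform branch-length scaling cancels in the standardised effect
  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  b10 <- bnti(m, tr10, n_null = 99, seed = 7)
  expect_equal(b1$bnti, b10$bnti, tolerance = 1e-8)

  # identical taxon sets in both samples -> degenerate null, flagged NA
  dup <- cbind(m[, 1, drop = FALSE], S2 = m[, 1] + 1L)
  colnames(dup) <- c("S1", "S2")
  expect_warning(bd <- bnti(dup, tr, n_null = 29, seed = 1), "degenerate")
  expect_true(is.na(bd$bnti["S1", "S2"]))
  expect_equal(bd$n_undefined, 1)
})

test_that("RC-bray respects its bounds and boundary fixtures", {
  # disjoint communities: observed Bray-Curtis = 1 exceeds every null
  m <- matrix(0L, 16, 2, dimnames = list(sprintf("t%02d", 1:16), c("u", "v")))
  m[1:8, 1] <- 20L; m[9:16, 2] <- 20L
  rc <- rc_bray(m, n_null = 199, seed = 3)
  expect_equal(rc["u", "v"], 1)

  # identical communities: observed 0 below every null
  m2 <- matrix(0L, 16, 2, dimnames = dimnames(m))
  m2[1:6, 1] <- m2[1:6, 2] <- c(30L, 25L, 20L, 15L, 10L, 5L)
  rc2 <- rc_bray(m2, n_null = 199, seed = 3)
  expect_equal(rc2["u", "v"], -1)

  m3 <- random_counts(25, 8, seed = 11)
  rc3 <- rc_bray(m3, n_null = 99, seed = 4)
  expect_true(all(rc3 >= -1 & rc3 <= 1, na.rm = TRUE))
  expect_identical(rc3, rc_bray(m3, n_null = 99, seed = 4))
})

test_that("pair classification follows the threshold rules strictly", {
  expect_equal(as.character(classify_pair(3.1)), "heterogeneous_selection")
  expect_equal(as.character(classify_pair(-2.5)), "homogeneous_selection")
  expect_equal(as.character(classify_pair(0.5, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classify_pair(0.5, -0.99)), "homogenizing_dispersal")
  expect_equal(as.character(classify_pair(0.5, -0.2)), "drift")
  expect_error(classify_pair(0.5), "RC-bray value required")
  expect_true(is.na(classify_pair(NA, NA)))
})

test_that("process fractions tally pairs per stratum and warn on empty strata", {
  pairs <- data.frame(
    sample_a = c("a", "a", "b", "a"), sample_b = c("b", "c", "c", "d"),
    process = c("drift", "drift", "heterogeneous_selection", NA))
  fr <- process_fractions(pairs)
  expect_equal(fr$stratum, "all")
  expect_equal(fr$drift, 2 / 3)
  expect_equal(fr$heterogeneous_selection, 1 / 3)
  expect_equal(fr$n_unclassified, 1)
  expect_equal(sum(fr[, oceancomm:::.PROCESSES]), 1)

  strata <- c(a = "top", b = "top", c = "deep", d = "deep")
  expect_warning(fr2 <- process_fractions(pairs, strata), "no classified pairs")
  expect_setequal(fr2$stratum, c("all", "top"))
  expect_equal(fr2$drift[fr2$stratum == "top"], 1)

  only <- data.frame(sample_a = "a", sample_b = "b", process = "drift")
  fr3 <- process_fractions(only)
  expect_equal(fr3$drift, 1)
  expect_equal(sum(fr3[, oceancomm:::.PROCESSES]), 1)

  # counting oracle on a random label fixture
  set.seed(2)
  lab <- sample(oceancomm:::.PROCESSES, 60, replace = TRUE)
  prs <- data.frame(sample_a = "x", sample_b = "y", process = lab)
  fr4 <- process_fractions(prs)
  for (p in oceancomm:::.PROCESSES)
    expect_equal(fr4[[p]], mean(lab == p))
})

test_that("RC-bray is near-uniform on exchangeable null-assembled samples", {
  absrc <- unlist(lapply(1:8, function(rep) {
    set.seed(60000 + rep)
    nt <- 60
    pool <- as.numeric(rmultinom(1, 300, rep(1 / nt, nt)))
    counts <- sapply(1:10, function(s)
      as.numeric(rmultinom(1, 800, pool / sum(pool))))
    dimnames(counts) <- list(paste0("t", 1:nt), paste0("s", 1:10))
    storage.mode(counts) <- "integer"
    rc <- rc_bray(counts, n_null = 199, seed = rep)
    abs(rc[upper.tri(rc)])
  }))
  # |RC| of a uniform variate on [-1, 1] has mean 0.5
  expect_lt(abs(mean(absrc) - 0.5), 0.1)
})
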