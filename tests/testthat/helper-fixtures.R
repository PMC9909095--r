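# Shared fixtures: tiny trees and random tables built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

random_counts <- function(n_taxa, n_samples, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda = max_count / 5),
              nrow = n_taxa,
              dimnames = list(sprintf("T%03d", seq_len(n_taxa)),
                              sprintf("S%02d", seq_len(n_samples))))
  m[, colSums(m) == 0] <- 1L
  storage.mode(m) <- "integer"
  m
}

# minimal valid metadata frame for n samples at given coordinates
toy_frame <- function(samples, lon, lat) {
  n <- length(samples)
  data.frame(sample = samples, station = paste0("S", seq_len(n)),
             depth_layer = rep("5m", n), latitude = lat, longitude = lon,
             temperature = 25, salinity = 34, dissolved_oxygen = 200,
             chlorophyll_a = 0.1, tin = 1, dip = 0.1, silicate = 2)
}

# brute-force abundance-weighted bMNTD for one sample pair
oracle_bmntd <- function(a, b, coph, weighted = TRUE) {
  ia <- which(a > 0); ib <- which(b > 0)
  one_way <- function(src, dst, w) {
    mins <- vapply(src, function(i) min(coph[i, dst]), numeric(1))
    wts <- if (weighted) w[src] / sum(w[src]) else rep(1 / length(src), length(src))
    sum(wts * mins)
  }
  0.5 * (one_way(ia, ib, a / sum(a)) + one_way(ib, ia, b / sum(b)))
}
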