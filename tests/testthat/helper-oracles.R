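# Independent oracles used by the tracking tests: brute-force enumeration
# of all one-to-one matchings (tractable for <= 6 cells).

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# minimum total-distance one-to-one matching between two equal-count
# point sets, by exhaustive enumeration; returns the permutation (index
# into set 2 for each point of set 1) and its cost
brute_force_matching <- function(x1, y1, x2, y2) {
  n <- length(x1)
  d <- sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
  perms <- all_permutations(n)
  costs <- apply(perms, 1, function(p) sum(d[cbind(seq_len(n), p)]))
  best <- which.min(costs)
  list(perm = as.integer(perms[best, ]), cost = costs[best])
}

# random equal-weight detection frame within a box
random_detections <- function(n, box = 50, area = 10) {
  data.frame(label = seq_len(n),
             x_um = runif(n, 0, box), y_um = runif(n, 0, box),
             area_px = rep(area, n))
}
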