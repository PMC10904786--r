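# Independent reference implementations used to cross-check the package's
# fast paths. Deliberately naive: full pairwise matrices, exhaustive
# enumeration, textbook definitions.

# Hamming distance between two equal-length strings, character by character.
r_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

r_min_pairwise <- function(seqs) {
  n <- length(seqs)
  min(apply(utils::combn(n, 2), 2, function(ij) {
    r_hamming(seqs[ij[1]], seqs[ij[2]])
  }))
}

# Exhaustive directional UMI collapse: build the full edge set from a
# pairwise distance matrix, then cluster greedily from the highest-count
# node (lexicographic tie-break), absorbing everything reachable.
oracle_collapse_directional <- function(umi_counts) {
  n <- length(umi_counts)
  if (n == 0) return(0L)
  umis <- names(umi_counts)
  counts <- as.numeric(umi_counts)
  adj <- matrix(FALSE, n, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && r_hamming(umis[i], umis[j]) == 1 &&
            counts[i] >= 2 * counts[j] - 1) {
          adj[i, j] <- TRUE
        }
      }
    }
  }
  ord <- order(-counts, umis)
  visited <- rep(FALSE, n)
  clusters <- 0L
  for (root in ord) {
    if (visited[root]) next
    clusters <- clusters + 1L
    frontier <- root
    visited[root] <- TRUE
    while (length(frontier) > 0) {
      u <- frontier[1]
      frontier <- frontier[-1]
      for (v in which(adj[u, ] & !visited)) {
        visited[v] <- TRUE
        frontier <- c(frontier, v)
      }
    }
  }
  clusters
}

random_umi_instance <- function(n_max = 12L, umi_len = 4L) {
  n <- sample.int(n_max, 1)
  umis <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), umi_len,
                                           replace = TRUE), collapse = "")))
  counts <- sample.int(20L, length(umis), replace = TRUE)
  stats::setNames(counts, umis)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n+m, n) assignments of the observations to group x.
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(vals), n)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  lower <- mean(w_all <= w_obs)
  upper <- mean(w_all >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Textbook BH step-up: q_(i) = min over j >= i of min(1, p_(j) * m / j).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# Small planted-tropism world used by several tests: truth-level only.
make_small_world <- function(seed, n_bc = 24, planted = sprintf("BC%03d", 1:3),
                             affinity = 8, mouse_sd = 0.3,
                             molecules = 20000) {
  wl <- design_whitelist(n = n_bc, barcode_len = 8, min_dist = 3, seed = 5)
  aff <- plant_tropism(wl, planted, "lung", affinity)
  model <- biodistribution_model(wl, organ_affinity = aff,
                                 mouse_sd = mouse_sd,
                                 molecules_per_organ = molecules,
                                 seed = seed)
  list(wl = wl, model = model, planted = planted)
}
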