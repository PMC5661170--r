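# Independent brute-force oracles, deliberately written without igraph:
# Floyd-Warshall distances and explicit triangle enumeration.

# All-pairs shortest paths on a length matrix (Inf = no edge).
fw_distances <- function(L) {
  n <- nrow(L)
  d <- L
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# Brute-force weighted metrics matching the package's conventions:
# max-normalized weights, Onnela clustering via triangle loops, lengths
# 1/w, Lp over reachable pairs, efficiencies with 0 for unreachable.
brute_metrics <- function(W) {
  n <- nrow(W)
  Wn <- if (max(W) > 0) W / max(W) else W
  # clustering by explicit triangle enumeration
  cvec <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(Wn[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      if (Wn[j, h] > 0)
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    cvec[i] <- 2 * s / (k * (k - 1))
  }
  L <- ifelse(Wn > 0, 1 / Wn, Inf)
  d <- fw_distances(L)
  off <- d[upper.tri(d)]
  lp <- if (any(is.finite(off))) mean(off[is.finite(off)]) else 0
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  enodal <- rowSums(inv) / (n - 1)
  eglob <- sum(inv) / (n * (n - 1))
  eloc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(Wn[i, ] > 0)
    if (length(nb) < 2) next
    sub <- Wn[nb, nb, drop = FALSE]
    ds <- fw_distances(ifelse(sub > 0, 1 / sub, Inf))
    ivs <- 1 / ds
    ivs[!is.finite(ivs)] <- 0
    diag(ivs) <- 0
    m <- length(nb)
    eloc[i] <- sum(ivs) / (m * (m - 1))
  }
  list(Cp = mean(cvec), Lp = lp, Eglob = eglob, Eloc = mean(eloc),
       Enodal = enodal)
}

# Connected components of an undirected edge list by depth-first search.
# edges: k x 2 node indices. Returns list of sorted node vectors.
brute_components_nodes <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(setNames(nodes, nodes), function(v)
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  seen <- setNames(logical(length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[as.character(v)]) next
    stack <- v; comp <- integer(0)
    while (length(stack)) {
      u <- stack[[1]]; stack <- stack[-1]
      uu <- as.character(u)
      if (seen[uu]) next
      seen[uu] <- TRUE
      comp <- c(comp, u)
      stack <- c(stack, adj[[uu]])
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

# Random sparse symmetric test matrix.
random_weight_matrix <- function(n, density = 0.3, seed = 1) {
  set.seed(seed)
  np <- n * (n - 1) / 2
  w <- ifelse(runif(np) < density, runif(np, 0.1, 5), 0)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w
  m + t(m)
}
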