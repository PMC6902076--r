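# Shared fixtures and independent oracles, all built in code.

toyParcellation <- function(nNetworks = 2, roisPerNetwork = 3,
                            networks = NULL) {
  if (is.null(networks))
    networks <- c("DMN", "VIS", "SMN", "FPN", "SAN", "DAN")[seq_len(nNetworks)]
  lab <- rep(networks, each = roisPerNetwork)
  makeParcellation(sprintf("r%02d", seq_along(lab)), lab)
}

# independent breadth-first shortest-path oracle (no igraph)
bfsDistancesOracle <- function(adj) {
  N <- nrow(adj)
  D <- matrix(Inf, N, N)
  for (s in seq_len(N)) {
    dist <- rep(Inf, N)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] != 0)
      for (u in nb) {
        if (!is.finite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

globalEfficiencyOracle <- function(adj) {
  N <- nrow(adj)
  D <- bfsDistancesOracle(adj)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

localEfficiencyOracle <- function(adj) {
  N <- nrow(adj)
  mean(vapply(seq_len(N), function(i) {
    nb <- setdiff(which(adj[i, ] != 0), i)
    if (length(nb) < 2) return(0)
    globalEfficiencyOracle(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

randomSymmetricMatrix <- function(N) {
  M <- matrix(rnorm(N * N), N, N)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

randomAdjacency <- function(N, p = 0.5) {
  v <- rbinom(N * (N - 1) / 2, 1, p)
  vectorToMatrix(v, N, diagonal = 0)
}

# quick WindowedFC from a raw values matrix
makeWfc <- function(values, id = "s", window = 20L, step = 1L) {
  new("WindowedFC", subjectId = id, values = values,
      window = as.integer(window), step = as.integer(step),
      starts = seq_len(nrow(values)))
}

# small manifest for group tests
makeManifest <- function(n1, n2, groups = c("patient", "control"),
                         seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = rep(groups, c(n1, n2)),
    age = round(rnorm(n, 70, 6), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
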