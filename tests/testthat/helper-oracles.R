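# Independent oracles used across the suite. These deliberately re-derive
# results by brute force (plain dynamic programming, exhaustive enumeration,
# grid search) so they share no code path with the package implementation.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA_LETTERS, n, TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Plain Gotoh affine-gap DP, global mode. Convention: a gap of length L
# costs open + L * ext (matches the package's scoring contract).
oracle_global_score <- function(a, b, submat = blosum62, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(NEG, m + 1, n + 1)  # best overall
  E <- matrix(NEG, m + 1, n + 1)  # gap in a (consumes b)
  F_ <- matrix(NEG, m + 1, n + 1) # gap in b (consumes a)
  H[1, 1] <- 0
  for (j in 2:(n + 1)) { E[1, j] <- -(open + (j - 1) * ext); H[1, j] <- E[1, j] }
  for (i in 2:(m + 1)) { F_[i, 1] <- -(open + (i - 1) * ext); H[i, 1] <- F_[i, 1] }
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
    H[i, j] <- max(H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                   E[i, j], F_[i, j])
  }
  H[m + 1, n + 1]
}

# Plain Gotoh DP, local mode (empty alignment scores 0).
oracle_local_score <- function(a, b, submat = blosum62, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                   E[i, j], F_[i, j])
    best <- max(best, H[i, j])
  }
  best
}

nuc_submat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)

# BFS reachability partition of an undirected graph given as an edge tibble
oracle_components <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (r in seq_len(nrow(edges))) {
    a <- edges$gene_a[r]; b <- edges$gene_b[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# Rand index between two flat partitions (1 iff identical up to labels)
rand_index <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  tab <- table(p1, p2)
  n <- length(p1)
  a <- sum(choose(tab, 2))
  b1 <- sum(choose(rowSums(tab), 2))
  b2 <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * a - b1 - b2) / choose(n, 2)
}

# All 15 unrooted 5-taxon topologies as newick strings over given labels
five_taxon_topologies <- function(labels) {
  stopifnot(length(labels) == 5)
  out <- character(0)
  prs <- utils::combn(5, 2, simplify = FALSE)
  for (p in prs) {
    rest <- setdiff(1:5, p)
    qrs <- utils::combn(rest, 2, simplify = FALSE)
    for (q in qrs) {
      if (min(p) > min(q)) next  # unordered pair of cherries
      m <- setdiff(rest, q)
      out <- c(out, sprintf("((%s,%s),(%s,%s),%s);",
                            labels[p[1]], labels[p[2]],
                            labels[q[1]], labels[q[2]], labels[m]))
    }
  }
  unique(out)
}

# Least-squares fit of branch lengths for a fixed topology; returns SSQ
topology_ssq <- function(nwk, dmat) {
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  # design matrix: rows = taxon pairs, cols = edges on the path
  labs <- tr$tip.label
  n <- length(labs)
  pair_idx <- utils::combn(n, 2)
  paths <- ape::nodepath(tr)
  g <- igraph::graph_from_edgelist(tr$edge, directed = FALSE)
  X <- matrix(0, ncol(pair_idx), nrow(tr$edge))
  y <- numeric(ncol(pair_idx))
  for (r in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, r]; j <- pair_idx[2, r]
    vp <- as.integer(igraph::shortest_paths(g, i, j)$vpath[[1]])
    for (s in seq_len(length(vp) - 1)) {
      e <- which((tr$edge[, 1] == vp[s] & tr$edge[, 2] == vp[s + 1]) |
                 (tr$edge[, 2] == vp[s] & tr$edge[, 1] == vp[s + 1]))
      X[r, e] <- 1
    }
    y[r] <- dmat[labs[i], labs[j]]
  }
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# grid-search oracle: Heaps' law, gamma on a grid, (kappa, b) by linear LS
oracle_heaps_grid <- function(x, y, gammas = seq(0.05, 1.5, by = 0.01)) {
  best <- NULL
  for (g in gammas) {
    X <- cbind(x^g, 1)
    fit <- stats::lm.fit(X, y)
    ssq <- sum(fit$residuals^2)
    if (is.null(best) || ssq < best$ssq)
      best <- list(kappa = fit$coefficients[1], gamma = g,
                   b = fit$coefficients[2], ssq = ssq)
  }
  best
}

# grid-search oracle: exponential decay, B on a grid, (A, K) by linear LS
oracle_decay_grid <- function(x, y, Bs = seq(-1, -0.01, by = 0.005)) {
  best <- NULL
  for (B in Bs) {
    X <- cbind(exp(B * x), 1)
    fit <- stats::lm.fit(X, y)
    ssq <- sum(fit$residuals^2)
    if (is.null(best) || ssq < best$ssq)
      best <- list(A = fit$coefficients[1], B = B, K = fit$coefficients[2],
                   ssq = ssq)
  }
  best
}

# small helper: gene tibble from named protein vectors per genome
genes_tbl <- function(...) {
  gs <- list(...)
  dplyr::bind_rows(lapply(names(gs), function(g) {
    tibble::tibble(genome_id = g, gene_id = names(gs[[g]]),
                   seq = unname(gs[[g]]))
  }))
}
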