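# Shared fixtures and independent oracles used across the suite.

# balanced 4-tip tree ((t1,t2),(t3,t4)) with unit branches
balanced4 <- function() {
  ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")
}

# star tree: n tips radiating from the root with branch length len
star_tree <- function(n, len = 1) {
  txt <- paste0("(", paste(sprintf("t%d:%g", seq_len(n), len), collapse = ","),
                ");")
  ape::read.tree(text = txt)
}

# --- independent UniFrac oracle ------------------------------------------
# Edge set on the path from the root to a tip, by walking parent pointers.
root_path_edges <- function(tree, tip) {
  node <- match(tip, tree$tip.label)
  root <- length(tree$tip.label) + 1L
  edges <- integer(0)
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    edges <- c(edges, e)
    node <- tree$edge[e, 1]
  }
  edges
}

# brute-force unweighted UniFrac via root-to-tip path-edge unions
unifrac_bruteforce <- function(tree, tips_a, tips_b) {
  union_a <- unique(unlist(lapply(tips_a, root_path_edges, tree = tree)))
  union_b <- unique(unlist(lapply(tips_b, root_path_edges, tree = tree)))
  uniq <- c(setdiff(union_a, union_b), setdiff(union_b, union_a))
  either <- union(union_a, union_b)
  sum(tree$edge.length[uniq]) / sum(tree$edge.length[either])
}

# --- independent permutation enumerator -----------------------------------
# lexicographic next-permutation walk, distinct from the package's recursive
# insertion enumerator
lex_permutations <- function(n) {
  a <- seq_len(n)
  out <- list(a)
  repeat {
    i <- n - 1L
    while (i >= 1L && a[i] >= a[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (a[j] <= a[i]) j <- j - 1L
    tmp <- a[i]; a[i] <- a[j]; a[j] <- tmp
    a[(i + 1L):n] <- rev(a[(i + 1L):n])
    out[[length(out) + 1L]] <- a
  }
  do.call(rbind, out)
}

# --- independent isotonic regression (PAVA) for stress checks -------------
pava <- function(y) {
  n <- length(y)
  vals <- y
  wts <- rep(1, n)
  blocks <- as.list(seq_len(n))
  i <- 1L
  while (i < length(vals)) {
    if (vals[i] > vals[i + 1] + 1e-15) {
      new_val <- (vals[i] * wts[i] + vals[i + 1] * wts[i + 1]) /
        (wts[i] + wts[i + 1])
      vals[i] <- new_val
      wts[i] <- wts[i] + wts[i + 1]
      blocks[[i]] <- c(blocks[[i]], blocks[[i + 1]])
      vals <- vals[-(i + 1)]; wts <- wts[-(i + 1)]
      blocks[[i + 1]] <- NULL
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  out <- numeric(n)
  for (b in seq_along(vals)) out[blocks[[b]]] <- vals[b]
  out
}

# Kruskal stress-1 of a configuration, with PAVA done independently
stress_oracle <- function(dist, points) {
  dobs <- as.vector(stats::as.dist(dist))
  dcfg <- as.vector(stats::dist(points))
  ord <- order(dobs)
  dhat <- numeric(length(dobs))
  dhat[ord] <- pava(dcfg[ord])
  sqrt(sum((dcfg - dhat)^2) / sum(dcfg^2))
}

# small default truth/design helpers for end-to-end tests
tiny_truth <- function(...) {
  synthetic_truth(clones_per_library = 30, ...)
}
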