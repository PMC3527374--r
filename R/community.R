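#' Unweighted UniFrac distance between two tip sets
#'
#' Fraction of branch length leading exclusively to one community's tips
#' among the branch length leading to either community's tips
#' (presence/absence based). 0 for identical presence sets, 1 for communities
#' with no shared lineage.
#'
#' @param tree `phylo` object with branch lengths.
#' @param present_a,present_b non-empty tip-label sets.
#' @return distance in [0, 1].
#' @export
unweighted_unifrac <- function(tree, present_a, present_b) {
  present_a <- unique(present_a); present_b <- unique(present_b)
  unknown <- setdiff(c(present_a, present_b), tree$tip.label)
  if (length(unknown)) {
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(present_a) == 0L || length(present_b) == 0L) {
    stop("both tip sets must be non-empty", call. = FALSE)
  }
  tips <- unique(c(present_a, present_b))
  inc <- edge_tip_incidence(tree, tips)
  in_a <- rowSums(inc[, intersect(tips, present_a), drop = FALSE]) > 0
  in_b <- rowSums(inc[, intersect(tips, present_b), drop = FALSE]) > 0
  unique_len <- sum(tree$edge.length[xor(in_a, in_b)])
  either_len <- sum(tree$edge.length[in_a | in_b])
  if (either_len == 0) return(0)
  unique_len / either_len
}

#' Pairwise unweighted UniFrac distance matrix
#'
#' @param tree `phylo` object.
#' @param communities named list of tip-label sets, or a unit x genotype
#'   count/presence matrix with genotype column names matching tree tips.
#' @return symmetric `dist`-convertible matrix with zero diagonal, class
#'   retained as a plain matrix.
#' @export
unifrac_matrix <- function(tree, communities) {
  if (is.matrix(communities)) {
    m <- communities
    communities <- stats::setNames(
      lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] > 0]),
      rownames(m))
  }
  n <- length(communities)
  if (n < 2L) stop("need >= 2 units", call. = FALSE)
  empty <- vapply(communities, length, 1L) == 0
  if (any(empty)) {
    stop("empty unit(s): ", paste(names(communities)[empty], collapse = ", "),
         call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(names(communities), names(communities)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- unweighted_unifrac(tree, communities[[i]],
                                             communities[[j]])
  }
  d
}

# Within-group sum of squared distances (sum over groups of SS/group size),
# per the standard AMOVA sums-of-squares partition. The full matrix sum is
# used (symmetric, zero diagonal), hence the /2.
amova_ss_within <- function(d2, grouping_idx) {
  ss_within <- 0
  for (g in unique(grouping_idx)) {
    idx <- which(grouping_idx == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_within
}

#' Analysis of molecular variance (one-level AMOVA)
#'
#' Partitions squared-distance variance among and within groups, reports the
#' variance components, the percent of variation among groups and the
#' Phi_ST statistic, with a permutation p-value (group labels permuted across
#' units, +1 correction so p > 0).
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param grouping group label per unit (named or in matrix order); every
#'   group needs >= 2 units.
#' @param permutations number of label permutations (default 999).
#' @param seed integer seed.
#' @return object of class `amova_result`: sigma_among, sigma_within,
#'   percent_among, percent_within, phi_st, p_value, ss (total/within/among),
#'   df, permutations.
#' @export
amova <- function(dist, grouping, permutations = 999, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (!is.null(names(grouping)) && !is.null(rownames(d))) {
    grouping <- grouping[rownames(d)]
  }
  grouping <- as.character(grouping)
  if (length(grouping) != n) {
    stop("'grouping' must match the distance matrix units", call. = FALSE)
  }
  tab <- table(grouping)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop("need >= 2 groups with >= 2 units each", call. = FALSE)
  }
  d2 <- d^2
  gidx <- match(grouping, names(tab))
  ss_total <- sum(d2) / (2 * n)
  ss_within <- amova_ss_within(d2, gidx)
  ss <- c(total = ss_total, within = ss_within, among = ss_total - ss_within)
  g <- length(tab)
  df_among <- g - 1
  df_within <- n - g
  msd_among <- ss[["among"]] / df_among
  msd_within <- ss[["within"]] / df_within
  n0 <- (n - sum(tab^2) / n) / df_among
  sigma_within <- msd_within
  sigma_among <- (msd_among - msd_within) / n0
  sigma_total <- sigma_among + sigma_within
  phi <- if (sigma_total > 0) sigma_among / sigma_total else 0
  perm_phi <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      gi <- sample(gidx)
      w <- amova_ss_within(d2, gi)
      s_w <- w / df_within
      s_a <- ((ss_total - w) / df_among - s_w) / n0
      tot <- s_a + s_w
      if (tot > 0) s_a / tot else 0
    }, 1)
  })
  p <- (sum(perm_phi >= phi) + 1) / (permutations + 1)
  structure(list(
    sigma_among = sigma_among, sigma_within = sigma_within,
    percent_among = 100 * sigma_among / sigma_total,
    percent_within = 100 * sigma_within / sigma_total,
    phi_st = phi, p_value = p,
    ss = ss, df = c(among = df_among, within = df_within),
    permutations = permutations
  ), class = "amova_result")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS via [vegan::metaMDS()] (monoMDS engine, no
#' autotransform), using up to `n_starts` random starts and declaring
#' convergence when two configurations agree under Procrustes rotation.
#' Coordinates are centered at the origin.
#'
#' @param dist symmetric distance matrix (or `dist`).
#' @param dims ordination dimensions (default 2).
#' @param n_starts maximum random starts (default 20).
#' @param seed integer seed.
#' @return object of class `ordination_result`: `points` (unit x dims),
#'   `stress` (fraction), `stress100` (the x100 convention), `converged`,
#'   `n_starts`.
#' @export
nmds <- function(dist, dims = 2, n_starts = 20, seed = 1) {
  d <- stats::as.dist(dist)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (attr(d, "Size") < dims + 2) stop("need >= dims + 2 units", call. = FALSE)
  fit <- with_seed(seed, {
    vegan::metaMDS(d, k = dims, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  })
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  colnames(pts) <- paste0("NMDS", seq_len(dims))
  structure(list(points = pts, stress = fit$stress,
                 stress100 = 100 * fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 n_starts = n_starts),
            class = "ordination_result")
}

#' Kruskal stress-1 of a configuration against a distance matrix
#'
#' Computes stress-1 with the optimal monotone (isotonic) regression of the
#' configuration distances on the observed dissimilarity ranks. Useful as an
#' independent check of an NMDS solution.
#'
#' @param dist observed dissimilarities (matrix or `dist`).
#' @param points configuration coordinates (unit x dims).
#' @return stress-1 (fraction).
#' @export
kruskal_stress <- function(dist, points) {
  dobs <- as.vector(stats::as.dist(dist))
  dcfg <- as.vector(stats::dist(points))
  ord <- order(dobs)
  iso <- stats::isoreg(dcfg[ord])
  dhat <- numeric(length(dobs)); dhat[ord] <- iso$yf
  sqrt(sum((dcfg - dhat)^2) / sum(dcfg^2))
}

#' Fit an environmental vector to an ordination
#'
#' Least-squares regression of a variable on the (centered) ordination
#' coordinates; the normalized coefficient vector is the arrow direction and
#' the regression r-squared its strength. Significance by permuting the
#' variable across units (+1 correction), or exactly over all permutations
#' when `exact = TRUE` (n <= 8).
#'
#' @param ordination an [nmds()] result or a coordinate matrix.
#' @param variable numeric value per unit (finite, non-constant).
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return list: direction (unit vector), r_squared, p_value, permutations.
#' @export
fit_env_vector <- function(ordination, variable, permutations = 999, seed = 1,
                           exact = FALSE) {
  pts <- if (inherits(ordination, "ordination_result")) ordination$points
         else as.matrix(ordination)
  if (any(!is.finite(variable))) stop("variable must be finite", call. = FALSE)
  if (stats::var(variable) == 0) stop("constant variable", call. = FALSE)
  if (nrow(pts) != length(variable)) {
    stop("variable length must match ordination units", call. = FALSE)
  }
  x <- scale(pts, center = TRUE, scale = FALSE)
  r2_of <- function(v) {
    v <- v - mean(v)
    b <- stats::lm.fit(x, v)$coefficients
    pred <- x %*% b
    sum(pred^2) / sum(v^2)
  }
  r2 <- r2_of(variable)
  b <- stats::lm.fit(x, variable - mean(variable))$coefficients
  direction <- b / sqrt(sum(b^2))
  if (exact) {
    perms <- all_permutations(length(variable))
    r2_null <- apply(perms, 1, function(ix) r2_of(variable[ix]))
    # the identity permutation is part of the enumeration
    p <- sum(r2_null >= r2 - 1e-12) / nrow(perms)
    n_perm <- nrow(perms)
  } else {
    r2_null <- with_seed(seed, {
      vapply(seq_len(permutations), function(i) r2_of(sample(variable)), 1)
    })
    p <- (sum(r2_null >= r2) + 1) / (permutations + 1)
    n_perm <- permutations
  }
  list(direction = stats::setNames(as.numeric(direction), colnames(pts)),
       r_squared = as.numeric(r2), p_value = p, permutations = n_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the unique off-diagonal pairs, with a one-sided
#' (greater) permutation test permuting the unit labels of the second matrix
#' (+1 correction), or exact enumeration of all unit permutations when
#' `exact = TRUE` (n <= 8).
#'
#' @param d1,d2 symmetric distance matrices over the same units, same order.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param exact enumerate all permutations.
#' @return list: r, p_value, permutations.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1, exact = FALSE) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) stop("size mismatch", call. = FALSE)
  n <- nrow(m1)
  lt <- lower.tri(m1)
  r_obs <- stats::cor(m1[lt], m2[lt])
  r_of <- function(ix) stats::cor(m1[lt], m2[ix, ix][lt])
  if (exact) {
    perms <- all_permutations(n)
    r_null <- apply(perms, 1, r_of)
    p <- sum(r_null >= r_obs - 1e-12) / nrow(perms)
    n_perm <- nrow(perms)
  } else {
    r_null <- with_seed(seed, {
      vapply(seq_len(permutations), function(i) r_of(sample(n)), 1)
    })
    p <- (sum(r_null >= r_obs) + 1) / (permutations + 1)
    n_perm <- permutations
  }
  list(r = as.numeric(r_obs), p_value = p, permutations = n_perm)
}

#' Pairwise correlations among diversity metrics and model parameters
#'
#' Squared Pearson correlation and two-sided p-value (t transform) for every
#' pair of numeric columns, dropping incomplete cases per pair.
#'
#' @param metrics data.frame of numeric columns (units in rows).
#' @return data.frame: var1, var2, r, r_squared, p_value, n.
#' @export
pairwise_correlations <- function(metrics) {
  metrics <- as.data.frame(metrics)
  num <- vapply(metrics, is.numeric, TRUE)
  metrics <- metrics[, num, drop = FALSE]
  vars <- names(metrics)
  if (length(vars) < 2L) stop("need >= 2 numeric columns", call. = FALSE)
  out <- list()
  for (i in seq_len(length(vars) - 1)) for (j in seq(i + 1, length(vars))) {
    x <- metrics[[i]]; y <- metrics[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      stop(sprintf("fewer than 3 complete pairs for %s vs %s",
                   vars[i], vars[j]), call. = FALSE)
    }
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      stop(sprintf("constant column in pair %s vs %s", vars[i], vars[j]),
           call. = FALSE)
    }
    ct <- stats::cor.test(x[ok], y[ok])
    out[[length(out) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j],
      r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
      p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
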