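#' Bias-corrected Chao1 richness estimate with 95% CI
#'
#' Chao1 = S_obs + f1 (f1 - 1) / (2 (f2 + 1)), where f1 and f2 are the
#' numbers of singleton and doubleton genotypes. The confidence interval uses
#' Chao's variance with the log-normal transformation on T = Chao1 - S_obs:
#' K = exp(z sqrt(ln(1 + var/T^2))), bounds S_obs + T/K and S_obs + T K, so
#' the lower bound never falls below the observed richness.
#'
#' @param counts non-negative genotype counts (zeros ignored).
#' @param conf confidence level (default 0.95).
#' @return list: estimate, ci_low, ci_high, s_obs, f1, f2, variance.
#' @export
chao1 <- function(counts, conf = 0.95) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero count vector", call. = FALSE)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  if (f1 > 0 && f2 > 0) {
    r <- f1 / f2
    v <- f1 * (r / 4 + r^2 / 2 + r^3 / 4) # Chao (1987) variance, f2 > 0 form
  } else if (f1 > 0) {
    v <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
  } else {
    v <- 0
  }
  tt <- est - s_obs
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (tt > 0 && v > 0) {
    kk <- exp(z * sqrt(log(1 + v / tt^2)))
    lo <- s_obs + tt / kk
    hi <- s_obs + tt * kk
  } else {
    lo <- hi <- est
  }
  list(estimate = est, ci_low = lo, ci_high = hi,
       s_obs = s_obs, f1 = f1, f2 = f2, variance = v)
}

#' Shannon diversity H' with 95% CI
#'
#' H' = -sum p_i ln p_i (natural log). The CI uses the normal approximation
#' with variance (sum p_i (ln p_i)^2 - H'^2) / N + (S - 1) / (2 N^2).
#'
#' @param counts non-negative genotype counts (zeros ignored).
#' @param conf confidence level (default 0.95).
#' @return list: estimate, ci_low, ci_high, variance.
#' @export
shannon <- function(counts, conf = 0.95) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all-zero count vector", call. = FALSE)
  n <- sum(counts)
  p <- counts / n
  h <- -sum(p * log(p))
  v <- (sum(p * log(p)^2) - h^2) / n + (length(p) - 1) / (2 * n^2)
  v <- max(v, 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = h, ci_low = h - z * sqrt(v), ci_high = h + z * sqrt(v),
       variance = v)
}

# For each edge of `tree`, which of `tips` lie below it. Returns a logical
# edge x tip matrix.
edge_tip_incidence <- function(tree, tips = tree$tip.label) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  desc <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  # edges in postorder so children are resolved before parents
  post <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1]; ch <- post$edge[i, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  idx <- match(tips, tree$tip.label)
  inc <- matrix(FALSE, nrow(tree$edge), length(tips),
                dimnames = list(NULL, tips))
  for (i in seq_len(nrow(tree$edge))) {
    inc[i, ] <- idx %in% desc[[tree$edge[i, 2]]]
  }
  inc
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the subtree spanning the present tips. By
#' default the spanning subtree is rooted at the tree root (the classic
#' formulation: every branch leading to at least one present tip counts);
#' with `include_root = FALSE` only branches below the most recent common
#' ancestor of the present set are summed.
#'
#' @param tree `phylo` object with branch lengths.
#' @param present character vector of present tip labels.
#' @param include_root include the branches from the present set's MRCA up
#'   to the tree root (default TRUE).
#' @return PD in branch-length units.
#' @export
faith_pd <- function(tree, present, include_root = TRUE) {
  present <- unique(present)
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown)) {
    stop("unknown genotype id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(present) == 0L) return(0)
  inc <- edge_tip_incidence(tree, present)
  n_in <- rowSums(inc)
  on_path <- if (include_root) n_in >= 1 else n_in >= 1 & n_in < length(present)
  sum(tree$edge.length[on_path])
}

# Patristic (cophenetic) distance submatrix for a tip set.
tip_distances <- function(tree, present) {
  d <- ape::cophenetic.phylo(tree)
  d[present, present, drop = FALSE]
}

#' Mean pairwise phylogenetic distance of a tip set
#'
#' Mean patristic distance over all unordered pairs of present tips
#' (presence-based, unweighted).
#'
#' @param tree `phylo` object.
#' @param present >= 2 tip labels.
#' @param dist optional precomputed cophenetic matrix over all tips.
#' @return MPD in branch-length units.
#' @export
mpd <- function(tree, present, dist = NULL) {
  present <- unique(present)
  if (length(present) < 2L) stop("need >= 2 present tips", call. = FALSE)
  d <- if (is.null(dist)) tip_distances(tree, present) else dist[present, present]
  mean(d[lower.tri(d)])
}

#' Mean nearest-taxon distance of a tip set
#'
#' Mean over present tips of the patristic distance to the nearest other
#' present tip.
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units.
#' @export
mntd <- function(tree, present, dist = NULL) {
  present <- unique(present)
  if (length(present) < 2L) stop("need >= 2 present tips", call. = FALSE)
  d <- if (is.null(dist)) tip_distances(tree, present) else dist[present, present]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Shared engine for NRI/NTI: standardized effect size of `stat_fun` against a
# tip-pool null (random tip sets of equal richness). exhaustive = TRUE
# enumerates every subset instead of sampling (small pools only).
ses_phylo <- function(tree, present, stat_fun, null_reps = 999, seed = 1,
                      exhaustive = FALSE) {
  present <- unique(present)
  if (length(present) < 2L) stop("need >= 2 present tips", call. = FALSE)
  if (!exhaustive && null_reps < 99) stop("null_reps must be >= 99", call. = FALSE)
  pool <- tree$tip.label
  d <- ape::cophenetic.phylo(tree)
  obs <- stat_fun(tree, present, dist = d)
  if (exhaustive) {
    if (choose(length(pool), length(present)) > 1e5) {
      stop("exhaustive null too large", call. = FALSE)
    }
    sets <- utils::combn(pool, length(present), simplify = FALSE)
    null_vals <- vapply(sets, function(s) stat_fun(tree, s, dist = d), 1)
  } else {
    null_vals <- with_seed(seed, {
      vapply(seq_len(null_reps), function(i) {
        stat_fun(tree, sample(pool, length(present)), dist = d)
      }, 1)
    })
  }
  mu <- mean(null_vals)
  sdv <- stats::sd(null_vals)
  if (!is.finite(sdv) || sdv == 0) {
    return(list(z = 0, p = 1, observed = obs, null_mean = mu, null_sd = sdv,
                degenerate = TRUE))
  }
  z <- -(obs - mu) / sdv
  n_le <- sum(null_vals <= obs)
  n_ge <- sum(null_vals >= obs)
  m <- length(null_vals)
  p <- min(1, 2 * min(n_le + 1, n_ge + 1) / (m + 1))
  list(z = z, p = p, observed = obs, null_mean = mu, null_sd = sdv,
       degenerate = FALSE)
}

#' Net relatedness index
#'
#' NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null), where the null draws
#' richness-matched random tip sets from the tree's tip pool. Positive values
#' indicate phylogenetic clustering (environmental filtering), negative
#' values overdispersion. Two-sided p from the null rank. A degenerate null
#' (zero sd, e.g. the present set is the whole pool) returns z = 0 with
#' `degenerate = TRUE`.
#'
#' @param tree `phylo` object.
#' @param present >= 2 present tip labels.
#' @param null_reps null randomizations (>= 99; default 999).
#' @param seed integer seed for the null.
#' @param exhaustive enumerate all richness-matched subsets instead of
#'   sampling (small trees only).
#' @return list: z, p, observed, null_mean, null_sd, degenerate.
#' @export
nri <- function(tree, present, null_reps = 999, seed = 1, exhaustive = FALSE) {
  ses_phylo(tree, present, mpd, null_reps, seed, exhaustive)
}

#' Nearest taxon index
#'
#' NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null); the tip-level
#' counterpart of [nri()], same null model and sign convention.
#'
#' @inheritParams nri
#' @return list: z, p, observed, null_mean, null_sd, degenerate.
#' @export
nti <- function(tree, present, null_reps = 999, seed = 1, exhaustive = FALSE) {
  ses_phylo(tree, present, mntd, null_reps, seed, exhaustive)
}

#' Diversity table per replicate and per pooled community
#'
#' Computes Chao1 (with CI), Shannon H' (with CI), Faith's PD, NRI and NTI
#' for every sample (replicate library) and for every community after pooling
#' its replicates' counts.
#'
#' @param counts sample x genotype count matrix (genotype ids = tree tips).
#' @param tree genotype phylogeny.
#' @param grouping named vector sample -> community.
#' @param null_reps null randomizations for NRI/NTI.
#' @param seed integer seed.
#' @return data.frame, one row per replicate and per pooled community:
#'   unit, level, chao1, chao1_low, chao1_high, shannon, shannon_low,
#'   shannon_high, pd, nri, nri_p, nti, nti_p.
#' @export
diversity_table <- function(counts, tree, grouping, null_reps = 999, seed = 1) {
  units <- c(
    stats::setNames(rownames(counts), rownames(counts)),
    stats::setNames(unique(grouping[rownames(counts)]),
                    unique(grouping[rownames(counts)]))
  )
  level <- c(rep("replicate", nrow(counts)),
             rep("community", length(unique(grouping[rownames(counts)]))))
  rows <- lapply(seq_along(units), function(i) {
    u <- units[i]
    cnt <- if (level[i] == "replicate") {
      counts[u, ]
    } else {
      colSums(counts[grouping[rownames(counts)] == u, , drop = FALSE])
    }
    ch <- chao1(cnt)
    sh <- shannon(cnt)
    present <- colnames(counts)[cnt > 0]
    pd_val <- faith_pd(tree, present)
    nri_r <- nri(tree, present, null_reps = null_reps, seed = seed + i)
    nti_r <- nti(tree, present, null_reps = null_reps, seed = seed + i)
    data.frame(unit = unname(u), level = level[i],
               s_obs = ch$s_obs,
               chao1 = ch$estimate, chao1_low = ch$ci_low, chao1_high = ch$ci_high,
               shannon = sh$estimate, shannon_low = sh$ci_low,
               shannon_high = sh$ci_high,
               pd = pd_val,
               nri = nri_r$z, nri_p = nri_r$p,
               nti = nti_r$z, nti_p = nti_r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
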