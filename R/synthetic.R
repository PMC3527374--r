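#' Gaussian temperature-response model
#'
#' Rate at temperature `temp` under the Gaussian model
#' v = v_max * exp(-(T - t_m)^2 / (2 w^2)), the standard model for the
#' temperature dependence of soil microbial process rates.
#'
#' @param temp temperature(s), degrees C.
#' @param v_max maximum rate, attained at `t_m` (rate units).
#' @param t_m optimum temperature, degrees C.
#' @param w width parameter, degrees C; 2.355 * w is the full width at half
#'   maximum.
#' @return predicted rate(s), same units as `v_max`.
#' @export
gaussian_rate <- function(temp, v_max, t_m, w) {
  stopifnot_scalar_num(v_max, "v_max", positive = TRUE)
  stopifnot_scalar_num(w, "w", positive = TRUE)
  v_max * exp(-(temp - t_m)^2 / (2 * w^2))
}

#' Power-law salt-inhibition model
#'
#' Rate at salt concentration `conc` (% w/v) under v = k / sqrt(c) - a,
#' clamped at zero. At c = 0 the model is undefined and the uninhibited
#' rate `v0` is returned. The model predicts complete inhibition at
#' c = (k/a)^2 and onset of inhibition (rate falling below v0) at
#' c = (k/(v0 + a))^2.
#'
#' @param conc salt concentration(s), % w/v, >= 0.
#' @param k slope of the rate against c^-0.5 (rate * %^0.5).
#' @param a magnitude of the intercept of that plot (rate units).
#' @param v0 uninhibited rate at c = 0 (rate units).
#' @return predicted rate(s), floored at 0.
#' @export
power_rate <- function(conc, k, a, v0) {
  stopifnot_scalar_num(k, "k", positive = TRUE)
  stopifnot_scalar_num(a, "a", positive = TRUE)
  stopifnot_scalar_num(v0, "v0", positive = TRUE)
  out <- ifelse(conc <= 0, v0, pmax(0, k / sqrt(conc) - a))
  as.numeric(out)
}

#' Derive power-model slope and intercept from inhibition thresholds
#'
#' Inverts the threshold relations SA0 = (k/a)^2 and SAI = (k/(v0+a))^2:
#' given the concentration where inhibition starts (`sai`), where activity
#' ceases (`sa0`) and the uninhibited rate (`v0`), returns the (k, a) pair
#' that produces them.
#'
#' @param sai onset-of-inhibition concentration, % w/v.
#' @param sa0 complete-inhibition concentration, % w/v; must exceed `sai`.
#' @param v0 uninhibited rate.
#' @return list with elements `k` and `a`.
#' @export
salt_params_from_thresholds <- function(sai, sa0, v0) {
  stopifnot_scalar_num(sai, "sai", positive = TRUE)
  stopifnot_scalar_num(sa0, "sa0", positive = TRUE)
  stopifnot_scalar_num(v0, "v0", positive = TRUE)
  if (sai >= sa0) stop("'sai' must be smaller than 'sa0'", call. = FALSE)
  k <- sqrt(sai) * v0 / (1 - sqrt(sai / sa0))
  a <- k / sqrt(sa0)
  list(k = k, a = a)
}

#' Ground-truth parameter set for synthetic experiments
#'
#' Bundles the per-community response-model parameters, the clone-library
#' design and the assay noise level that the synthetic generators draw from.
#' Salt-model slope/intercept may be given directly (`k`, `a`) or via the
#' inhibition thresholds (`sai`, `sa0`), in which case they are derived with
#' [salt_params_from_thresholds()]; `v0` defaults to the Gaussian rate at the
#' salt-assay incubation temperature (30 C).
#'
#' @param communities character vector of community ids.
#' @param v_max,t_m,w per-community Gaussian parameters (recycled if scalar).
#' @param sai,sa0 per-community salt inhibition thresholds (% w/v), used when
#'   `k`/`a` are NULL.
#' @param k,a per-community salt-model parameters (optional).
#' @param v0 per-community uninhibited rate at 0% salt; default Gaussian rate
#'   at 30 C.
#' @param community_sizes genotypes per community.
#' @param pool_size genotype pool size; NULL = minimal pool for the requested
#'   overlap.
#' @param overlap fraction in [0,1] controlling shared genotype membership.
#' @param evenness_sigma lognormal sigma of genotype abundances (0 = even).
#' @param clones_per_library clones sequenced per library.
#' @param noise_sd assay noise, as a fraction of each community's `v_max`.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(communities = c("A", "B", "C", "J"),
                            v_max = c(60, 80, 100, 140),
                            t_m = c(32.7, 32.8, 33.4, 35.6),
                            w = c(11.2, 10.4, 10.8, 12.4),
                            sai = c(0.254, 0.267, 0.499, 0.425),
                            sa0 = c(2.86, 2.39, 4.24, 5.87),
                            k = NULL, a = NULL, v0 = NULL,
                            community_sizes = c(30, 34, 23, 44),
                            pool_size = NULL,
                            overlap = 0.5,
                            evenness_sigma = 1,
                            clones_per_library = 100,
                            noise_sd = 0.05) {
  nc <- length(communities)
  rec <- function(x) {
    if (length(x) == 1L) x <- rep(x, nc)
    if (length(x) != nc) stop("parameter length must be 1 or length(communities)", call. = FALSE)
    x
  }
  v_max <- rec(v_max); t_m <- rec(t_m); w <- rec(w)
  if (any(v_max <= 0) || any(w <= 0)) stop("v_max and w must be > 0", call. = FALSE)
  if (is.null(v0)) v0 <- v_max * exp(-(30 - t_m)^2 / (2 * w^2)) else v0 <- rec(v0)
  if (any(v0 <= 0)) stop("v0 must be > 0", call. = FALSE)
  if (is.null(k) || is.null(a)) {
    sai <- rec(sai); sa0 <- rec(sa0)
    ka <- mapply(function(s1, s0, v) unlist(salt_params_from_thresholds(s1, s0, v)),
                 sai, sa0, v0)
    k <- ka["k", ]; a <- ka["a", ]
  } else {
    k <- rec(k); a <- rec(a)
    if (any(k <= 0) || any(a <= 0)) stop("k and a must be > 0", call. = FALSE)
    sai <- (k / (v0 + a))^2
    sa0 <- (k / a)^2
  }
  community_sizes <- rec(community_sizes)
  if (!is.numeric(overlap) || overlap < 0 || overlap > 1) {
    stop("'overlap' must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  core <- round(overlap * min(community_sizes))
  min_pool <- core + sum(community_sizes - core)
  if (is.null(pool_size)) pool_size <- min_pool
  if (pool_size < min_pool) {
    stop(sprintf("pool_size %d too small: need >= %d for overlap %.2f",
                 pool_size, min_pool, overlap), call. = FALSE)
  }
  structure(list(
    communities = communities,
    v_max = stats::setNames(v_max, communities),
    t_m = stats::setNames(t_m, communities),
    w = stats::setNames(w, communities),
    k = stats::setNames(k, communities),
    a = stats::setNames(a, communities),
    v0 = stats::setNames(v0, communities),
    sai = stats::setNames(sai, communities),
    sa0 = stats::setNames(sa0, communities),
    community_sizes = stats::setNames(community_sizes, communities),
    pool_size = pool_size,
    overlap = overlap,
    evenness_sigma = evenness_sigma,
    clones_per_library = clones_per_library,
    noise_sd = noise_sd
  ), class = "synthetic_truth")
}

#' Gradient and microcosm design
#'
#' Describes the assay layout: the temperature and salt gradient points, the
#' gas-sampling schedule and the microcosm geometry used for the dissolved-gas
#' correction. Defaults follow the standard potential-denitrification assay:
#' incubation at 2, 10, 20, 30, 37, 45, 53 and 60 C; NaCl at 0, 0.5, 0.75, 1,
#' 1.5, 2, 3 and 4% w/v (incubated at 30 C); headspace sampled every half hour
#' for 3 h; 8 g soil with 8 ml liquid.
#'
#' @param temperatures temperature gradient points, degrees C (increasing).
#' @param salt_concentrations NaCl gradient points, % w/v (increasing).
#' @param sampling_times gas sampling times, h (increasing, >= 3 points).
#' @param soil_mass g soil per flask.
#' @param liquid_volume ml liquid per flask.
#' @param headspace_volume ml headspace per flask.
#' @param salt_incubation_temp incubation temperature of the salt series, C.
#' @return object of class `gradient_design`.
#' @export
gradient_design <- function(temperatures = c(2, 10, 20, 30, 37, 45, 53, 60),
                            salt_concentrations = c(0, 0.5, 0.75, 1, 1.5, 2, 3, 4),
                            sampling_times = seq(0, 3, by = 0.5),
                            soil_mass = 8,
                            liquid_volume = 8,
                            headspace_volume = 90,
                            salt_incubation_temp = 30) {
  chk_inc <- function(x, name) {
    if (length(x) < 1L || any(diff(x) <= 0)) {
      stop(sprintf("'%s' must be strictly increasing", name), call. = FALSE)
    }
  }
  chk_inc(temperatures, "temperatures")
  chk_inc(salt_concentrations, "salt_concentrations")
  chk_inc(sampling_times, "sampling_times")
  if (length(sampling_times) == 0L) stop("empty sampling_times", call. = FALSE)
  for (nm in c("soil_mass", "liquid_volume", "headspace_volume")) {
    stopifnot_scalar_num(get(nm), nm)
  }
  if (soil_mass <= 0 || headspace_volume <= 0 || liquid_volume < 0) {
    stop("volumes/masses must be positive (liquid_volume >= 0)", call. = FALSE)
  }
  structure(list(
    temperatures = temperatures,
    salt_concentrations = salt_concentrations,
    sampling_times = sampling_times,
    soil_mass = soil_mass,
    liquid_volume = liquid_volume,
    headspace_volume = headspace_volume,
    salt_incubation_temp = salt_incubation_temp
  ), class = "gradient_design")
}

#' Simulate N2O accumulation series for one field replicate
#'
#' For every community and gradient condition, generates a linear N2O
#' accumulation curve whose slope follows the community's Gaussian model
#' (temperature series) or power model clamped at zero (salt series), with
#' i.i.d. Gaussian noise of sd `noise_sd * v_max` added to the amounts and the
#' result floored at zero. With `headspace = TRUE` the produced amounts are
#' partitioned between headspace and liquid using the N2O Bunsen coefficient
#' at the incubation temperature, so the recorded headspace amounts require
#' the dissolved-gas correction — exactly as raw assay data do. With
#' `headspace = FALSE` total produced amounts are recorded and the noiseless
#' slope equals the model rate exactly.
#'
#' @param truth a [synthetic_truth()] object.
#' @param design a [gradient_design()] object.
#' @param replicate replicate id (integer or string).
#' @param seed integer seed; same seed reproduces the series bit for bit.
#' @param headspace logical; record headspace amounts (default TRUE).
#' @return data.frame with columns flask_id, community, replicate,
#'   gradient_type, condition_value, incubation_temp_c, time_h, n2o_amount,
#'   liquid_volume_ml, headspace_volume_ml.
#' @export
gen_gas_series <- function(truth, design, replicate = 1, seed = 1,
                           headspace = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(design, "gradient_design"))
  if (length(design$sampling_times) == 0L) stop("empty sampling_times", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (com in truth$communities) {
      conds <- rbind(
        data.frame(gradient_type = "temperature",
                   condition_value = design$temperatures,
                   incubation_temp_c = design$temperatures),
        data.frame(gradient_type = "salt",
                   condition_value = design$salt_concentrations,
                   incubation_temp_c = design$salt_incubation_temp)
      )
      for (i in seq_len(nrow(conds))) {
        gt <- conds$gradient_type[i]
        cv <- conds$condition_value[i]
        tin <- conds$incubation_temp_c[i]
        rate <- if (gt == "temperature") {
          gaussian_rate(cv, truth$v_max[com], truth$t_m[com], truth$w[com])
        } else {
          power_rate(cv, truth$k[com], truth$a[com], truth$v0[com])
        }
        tt <- design$sampling_times
        eps <- if (truth$noise_sd > 0) {
          stats::rnorm(length(tt), 0, truth$noise_sd * truth$v_max[com])
        } else 0
        total <- pmax(0, rate * tt + eps)
        amount <- if (headspace) {
          total / (1 + n2o_bunsen(tin) * design$liquid_volume / design$headspace_volume)
        } else total
        rows[[length(rows) + 1L]] <- data.frame(
          flask_id = sprintf("%s_r%s_%s_%g", com, replicate, gt, cv),
          community = com,
          replicate = as.character(replicate),
          gradient_type = gt,
          condition_value = cv,
          incubation_temp_c = tin,
          time_h = tt,
          n2o_amount = amount,
          liquid_volume_ml = design$liquid_volume,
          headspace_volume_ml = design$headspace_volume,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a genotype phylogeny
#'
#' Kingman-coalescent topology with exponential waiting times (ultrametric),
#' via [ape::rcoal()], with optional multiplicative lognormal branch-length
#' jitter to break the molecular clock.
#'
#' @param n_tips number of genotypes (>= 1).
#' @param seed integer seed.
#' @param jitter_sd sd of lognormal branch-length jitter (0 = ultrametric).
#' @param tip_prefix tip label prefix.
#' @return an [ape] `phylo` object, rooted and binary with positive branch
#'   lengths and tip labels `<tip_prefix>1..n`.
#' @export
gen_phylogeny <- function(n_tips, seed = 1, jitter_sd = 0, tip_prefix = "g") {
  if (!is.numeric(n_tips) || n_tips < 1 || n_tips != round(n_tips)) {
    stop("'n_tips' must be a positive integer", call. = FALSE)
  }
  labels <- paste0(tip_prefix, seq_len(n_tips))
  with_seed(seed, {
    if (n_tips == 1L) {
      tree <- ape::read.tree(text = sprintf("(%s:1);", labels))
      return(tree)
    }
    tree <- ape::rcoal(n_tips, tip.label = labels)
    if (jitter_sd > 0) {
      tree$edge.length <- tree$edge.length *
        stats::rlnorm(length(tree$edge.length), 0, jitter_sd)
    }
    tree
  })
}

#' Simulate community memberships and clone libraries
#'
#' Assigns each community a genotype set of the requested size built from a
#' shared core (size `round(overlap * min(sizes))`, common to all
#' communities) plus community-unique genotypes, then gives each community a
#' lognormal-shaped abundance vector (sigma = `evenness_sigma`; 0 = uniform)
#' and draws each replicate library as a multinomial sample of
#' `clones_per_library` clones.
#'
#' @param tree genotype phylogeny; its tips are the pool.
#' @param n_communities number of communities.
#' @param n_replicates libraries per community.
#' @param overlap membership overlap in [0,1]; 1 = identical memberships,
#'   0 = disjoint.
#' @param evenness_sigma lognormal sigma of abundances.
#' @param clones_per_library clones per library (>= 1).
#' @param community_sizes genotypes per community (scalar or vector);
#'   default: equal split of the pool at the requested overlap.
#' @param community_ids community labels.
#' @param seed integer seed.
#' @return list with `memberships` (list of tip-label vectors), `abundances`
#'   (list of named numeric vectors summing to 1), `counts` (sample x genotype
#'   count matrix over all pool tips), `mapping` (data.frame clone_id,
#'   sample_id, community, replicate, genotype), and `grouping` (named vector
#'   sample -> community).
#' @export
gen_communities <- function(tree, n_communities = 4, n_replicates = 3,
                            overlap = 0.5, evenness_sigma = 1,
                            clones_per_library = 100,
                            community_sizes = NULL,
                            community_ids = NULL, seed = 1) {
  pool <- tree$tip.label
  if (!is.numeric(overlap) || overlap < 0 || overlap > 1) {
    stop("'overlap' must be in [0, 1]", call. = FALSE)
  }
  if (clones_per_library < 1) stop("'clones_per_library' must be >= 1", call. = FALSE)
  if (is.null(community_ids)) community_ids <- LETTERS[seq_len(n_communities)]
  if (is.null(community_sizes)) {
    core0 <- if (n_communities > 1) {
      floor(length(pool) * overlap / (overlap + n_communities * (1 - overlap)))
    } else length(pool)
    size <- core0 + floor((length(pool) - core0) / n_communities) * (overlap < 1)
    community_sizes <- rep(max(1L, size), n_communities)
  }
  if (length(community_sizes) == 1L) community_sizes <- rep(community_sizes, n_communities)
  core_n <- round(overlap * min(community_sizes))
  need <- core_n + sum(community_sizes - core_n)
  if (need > length(pool)) {
    stop(sprintf("genotype pool too small: need %d tips, have %d",
                 need, length(pool)), call. = FALSE)
  }
  with_seed(seed, {
    shuffled <- sample(pool)
    core <- shuffled[seq_len(core_n)]
    rest <- if (core_n > 0) shuffled[-seq_len(core_n)] else shuffled
    memberships <- vector("list", n_communities)
    names(memberships) <- community_ids
    off <- 0L
    for (i in seq_len(n_communities)) {
      n_uniq <- community_sizes[i] - core_n
      uniq <- if (n_uniq > 0) rest[off + seq_len(n_uniq)] else character(0)
      off <- off + n_uniq
      memberships[[i]] <- c(core, uniq)
    }
    abundances <- lapply(memberships, function(m) {
      wgt <- if (evenness_sigma > 0) {
        stats::rlnorm(length(m), 0, evenness_sigma)
      } else rep(1, length(m))
      stats::setNames(wgt / sum(wgt), m)
    })
    sample_ids <- as.vector(t(outer(community_ids, seq_len(n_replicates),
                                    function(c, r) paste0(c, "_r", r))))
    counts <- matrix(0L, length(sample_ids), length(pool),
                     dimnames = list(sample_ids, pool))
    mapping <- list()
    grouping <- character(0)
    clone_no <- 0L
    for (i in seq_len(n_communities)) {
      ab <- abundances[[i]]
      for (r in seq_len(n_replicates)) {
        sid <- paste0(community_ids[i], "_r", r)
        grouping[sid] <- community_ids[i]
        draw <- as.integer(stats::rmultinom(1, clones_per_library, ab))
        counts[sid, names(ab)] <- draw
        genos <- rep(names(ab), draw)
        ids <- sprintf("clone%05d", clone_no + seq_along(genos))
        clone_no <- clone_no + length(genos)
        mapping[[length(mapping) + 1L]] <- data.frame(
          clone_id = ids, sample_id = sid, community = community_ids[i],
          replicate = as.character(r), genotype = genos,
          stringsAsFactors = FALSE
        )
      }
    }
    list(memberships = memberships, abundances = abundances, counts = counts,
         mapping = do.call(rbind, mapping), grouping = grouping)
  })
}

#' Simulate marker-gene sequences along a phylogeny
#'
#' Evolves a random root sequence along the tree under the Jukes-Cantor
#' single-rate substitution model (no indels), via [phangorn::simSeq()].
#' Branch lengths are multiplied by `subst_rate`, so the expected number of
#' substitutions per site between two tips is `subst_rate` times their
#' patristic distance.
#'
#' @param tree `phylo` object.
#' @param root_length sequence length, bp (>= 1).
#' @param subst_rate substitutions/site per unit branch length (>= 0).
#' @param seed integer seed.
#' @return named character vector of uppercase DNA sequences, one per tip.
#' @export
gen_sequences <- function(tree, root_length = 708, subst_rate = 0.1, seed = 1) {
  if (root_length < 1) stop("'root_length' must be >= 1", call. = FALSE)
  if (subst_rate < 0) stop("'subst_rate' must be >= 0", call. = FALSE)
  with_seed(seed, {
    sim <- phangorn::simSeq(tree, l = root_length, type = "DNA", rate = subst_rate)
    m <- toupper(as.character(sim))
    stats::setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
  })
}
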