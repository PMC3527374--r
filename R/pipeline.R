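#' Default pipeline configuration
#'
#' Nested list of all tunables for [run_pipeline()]. The defaults reproduce
#' the reference experimental design: 4 communities x 3 field replicates,
#' 8 temperatures, 8 salt concentrations, 7 sampling times over 3 h, ~100
#' clones per library, AluI digestion scored on a high-resolution gel, and
#' 999-permutation null/permutation engines at alpha = 0.1.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (NULL = no files written).
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  list(
    seed = seed,
    out_dir = out_dir,
    log_level = "info",
    stages = c("simulate", "rates", "fit", "rflp", "diversity", "compare"),
    gradients = c("temperature", "salt"),
    truth = list(n_replicates = 3, noise_sd = 0.05, overlap = 0.5,
                 evenness_sigma = 1, clones_per_library = 100),
    design = list(),  # overrides for gradient_design()
    sequence = list(root_length = 708, subst_rate = 0.15),
    enzyme = list(name = "AluI", site = "AGCT", cut_offset = 2),
    gel = list(min_detectable = 50, resolution = 0.05),
    alpha = 0.1,
    nulls = list(null_reps = 999, amova_permutations = 999,
                 mantel_permutations = 999, envfit_permutations = 999,
                 nmds_starts = 20),
    paths = list()  # input paths when not simulating
  )
}

# merge override list b into list a, recursively
merge_config <- function(a, b) {
  for (nm in names(b)) {
    if (is.list(b[[nm]]) && is.list(a[[nm]])) {
      a[[nm]] <- merge_config(a[[nm]], b[[nm]])
    } else {
      a[[nm]] <- b[[nm]]
    }
  }
  a
}

#' Read a flat key-value configuration file
#'
#' Format: optional `[section]` headers, then `key = value` lines; `#` starts
#' a comment. Values are parsed as numeric vectors (comma separated) when
#' possible, as logicals for true/false, otherwise as strings. Sections map
#' to nested entries of [default_config()].
#'
#' @param path configuration file.
#' @return configuration list (defaults merged with the file's overrides).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path)
  cfg <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("config line %d is not 'key = value': %s", i, lines[i]),
           call. = FALSE)
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    suppressWarnings(num <- as.numeric(parts))
    parsed <- if (!any(is.na(num))) {
      num
    } else if (all(tolower(parts) %in% c("true", "false"))) {
      tolower(parts) == "true"
    } else parts
    if (is.null(section)) cfg[[key]] <- parsed else cfg[[section]][[key]] <- parsed
  }
  merge_config(default_config(), cfg)
}

config_hash <- function(config) {
  # hash only the scientific configuration, not where results land or how
  # chatty the run is
  config <- config[setdiff(names(config), c("out_dir", "log_level"))]
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

pipe_log <- function(config, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [denitrange] ", ...)
}

run_stage <- function(name, config, fun) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fun(), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  pipe_log(config, sprintf("stage %s done in %.1fs", name,
                           proc.time()[["elapsed"]] - t0))
  out
}

# map RFLP groups back to a genotype-level community matrix using each
# group's representative clone
rflp_to_community <- function(rflp, mapping) {
  geno_of_clone <- stats::setNames(mapping$genotype, mapping$clone_id)
  rep_geno <- geno_of_clone[rflp$representative]
  samples <- colnames(rflp$counts)
  genos <- unique(rep_geno)
  out <- matrix(0L, length(samples), length(genos),
                dimnames = list(samples, genos))
  for (g in seq_len(nrow(rflp$counts))) {
    out[, rep_geno[g]] <- out[, rep_geno[g]] + rflp$counts[g, ]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: simulate (synthetic gas curves, phylogeny,
#' clone libraries, sequences), rates (dissolved-gas correction + linear
#' fits), fit (Gaussian and power operating-range models per community
#' replicate, ANOVA/Tukey comparison), rflp (in-silico digestion, gel
#' binning, grouping, Venn summaries), diversity (Chao1, Shannon, PD, NRI,
#' NTI per replicate and pooled community) and compare (UniFrac, AMOVA, NMDS
#' with vector fitting, Mantel, pairwise correlations). When `out_dir` is
#' set, every table is written as TSV/JSON stamped with the config hash and
#' seed. A failing stage halts the pipeline with the stage named.
#'
#' @param config configuration list from [default_config()] /
#'   [read_config()].
#' @return result bundle (named list of all stage outputs), invisibly
#'   containing `config_md5` and `seed`.
#' @export
run_pipeline <- function(config = default_config()) {
  seed <- config$seed
  md5 <- config_hash(config)
  stamp <- c(sprintf("denitrange %s", as.character(utils::packageVersion("denitrange"))),
             sprintf("seed=%s config_md5=%s", seed, md5))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_tsv <- function(x, name, extra = character(0), rownames_as = NULL) {
    if (is.null(out_dir)) return(invisible())
    write_tsv(x, file.path(out_dir, name), comments = c(stamp, extra),
              rownames_as = rownames_as)
  }
  save_json <- function(x, name) {
    if (is.null(out_dir)) return(invisible())
    jsonlite::write_json(c(list(seed = seed, config_md5 = md5), x),
                         file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  res <- list(seed = seed, config_md5 = md5, config = config)
  on <- function(st) st %in% config$stages

  if (on("simulate")) {
    res$truth <- do.call(synthetic_truth, config$truth[
      intersect(names(config$truth),
                names(formals(synthetic_truth)))])
    res$design <- do.call(gradient_design, config$design)
    n_rep <- config$truth$n_replicates %||% 3
    res$gas <- run_stage("simulate", config, function() {
      gas <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
        gen_gas_series(res$truth, res$design, replicate = r,
                       seed = seed * 1000 + r)
      }))
      gas[gas$gradient_type %in% config$gradients, ]
    })
    res$tree <- gen_phylogeny(res$truth$pool_size, seed = seed + 101)
    res$communities <- gen_communities(
      res$tree, n_communities = length(res$truth$communities),
      n_replicates = n_rep, overlap = res$truth$overlap,
      evenness_sigma = res$truth$evenness_sigma,
      clones_per_library = res$truth$clones_per_library,
      community_sizes = unname(res$truth$community_sizes),
      community_ids = res$truth$communities, seed = seed + 202)
    res$genotype_seqs <- gen_sequences(
      res$tree, root_length = config$sequence$root_length,
      subst_rate = config$sequence$subst_rate, seed = seed + 303)
    res$clone_seqs <- stats::setNames(
      res$genotype_seqs[res$communities$mapping$genotype],
      res$communities$mapping$clone_id)
    if (!is.null(out_dir)) {
      write_gas_csv(res$gas, file.path(out_dir, "gas_series.csv"))
      write_newick(res$tree, file.path(out_dir, "genotype_tree.nwk"))
      write_fasta(res$clone_seqs, file.path(out_dir, "clone_sequences.fasta"))
      save_tsv(res$communities$mapping, "clone_mapping.tsv")
    }
  } else {
    res$gas <- read_gas_csv(config$paths$gas)
    res$tree <- read_newick(config$paths$tree)
    res$clone_seqs <- read_fasta(config$paths$sequences)
    mp <- read_mapping_tsv(config$paths$mapping)
    res$communities <- list(
      mapping = mp,
      grouping = stats::setNames(mp$community[!duplicated(mp$sample_id)],
                                 mp$sample_id[!duplicated(mp$sample_id)]))
  }

  if (on("rates")) {
    res$rates <- run_stage("rates", config, function() {
      estimate_rates(res$gas)
    })
    save_tsv(res$rates, "rates.tsv",
             "columns: rate in amount/h per flask; r_squared of the linear fit")
  }

  if (on("fit")) {
    res$fits <- run_stage("fit", config, function() {
      fit_operating_range(res$rates, alpha = config$alpha,
                          gradients = config$gradients)
    })
    if ("temperature" %in% config$gradients) {
      save_tsv(res$fits$temperature, "temperature_fits.tsv",
               "Gaussian fits per community replicate: v_max, t_m (C), w (C), fwhm (C)")
    }
    if ("salt" %in% config$gradients) {
      save_tsv(res$fits$salt, "salt_fits.tsv",
               "power fits per community replicate: k, a, v0, sai (% w/v), sa0 (% w/v)")
    }
    save_tsv(res$fits$comparison_table, "parameter_comparison.tsv",
             sprintf("mean (sd) with Tukey letters at alpha=%g", config$alpha))
  }

  if (on("rflp")) {
    res$rflp <- run_stage("rflp", config, function() {
      enz <- restriction_enzyme(config$enzyme$name, config$enzyme$site,
                                config$enzyme$cut_offset)
      profiles <- digest_set(res$clone_seqs, enz)
      binned <- bin_profiles(profiles, config$gel$min_detectable,
                             config$gel$resolution)
      group_clones(binned, res$communities$mapping)
    })
    res$venn <- shared_unique(res$rflp, res$communities$grouping)
    save_tsv(res$rflp$counts, "rflp_table.tsv", rownames_as = "group")
    save_json(list(totals = as.list(res$venn$totals),
                   unique = as.list(res$venn$unique),
                   regions = as.list(res$venn$regions),
                   n_groups = res$venn$n_groups), "venn.json")
  }

  if (on("diversity")) {
    res$community_matrix <- rflp_to_community(res$rflp, res$communities$mapping)
    res$diversity <- run_stage("diversity", config, function() {
      diversity_table(res$community_matrix, res$tree,
                      res$communities$grouping,
                      null_reps = config$nulls$null_reps, seed = seed + 404)
    })
    save_tsv(res$diversity, "diversity.tsv",
             "chao1/shannon with 95% CI; pd in branch-length units; nri/nti z-scores")
  }

  if (on("compare")) {
    res$compare <- run_stage("compare", config, function() {
      compare_communities(res, config)
    })
    save_tsv(res$compare$unifrac, "unifrac.tsv", rownames_as = "unit")
    save_json(list(percent_among = res$compare$amova$percent_among,
                   phi_st = res$compare$amova$phi_st,
                   p_value = res$compare$amova$p_value), "amova.json")
    save_tsv(cbind(data.frame(unit = rownames(res$compare$ordination$points)),
                   as.data.frame(res$compare$ordination$points)),
             "ordination.tsv",
             sprintf("stress=%.4f (x100: %.1f)", res$compare$ordination$stress,
                     res$compare$ordination$stress100))
    save_tsv(res$compare$vectors, "ordination_vectors.tsv")
    save_json(list(r = res$compare$mantel$r,
                   p_value = res$compare$mantel$p_value), "mantel.json")
    save_tsv(res$compare$correlations, "pairwise_correlations.tsv")
  }
  pipe_log(config, "pipeline complete")
  invisible(res)
}

# per-replicate operating-range fits + ANOVA/Tukey comparison tables
fit_operating_range <- function(rates, alpha = 0.1,
                                gradients = c("temperature", "salt")) {
  out <- list()
  key <- unique(rates[, c("community", "replicate")])
  if ("temperature" %in% gradients) {
    rows <- lapply(seq_len(nrow(key)), function(i) {
      sel <- rates$community == key$community[i] &
        rates$replicate == key$replicate[i] &
        rates$gradient_type == "temperature"
      f <- fit_gaussian(rates$condition_value[sel], rates$rate[sel])
      data.frame(community = key$community[i], replicate = key$replicate[i],
                 v_max = f$v_max, t_m = f$t_m, w = f$w, fwhm = f$fwhm,
                 adj_r_squared = f$adj_r_squared, stringsAsFactors = FALSE)
    })
    out$temperature <- do.call(rbind, rows)
  }
  if ("salt" %in% gradients) {
    rows <- lapply(seq_len(nrow(key)), function(i) {
      sel <- rates$community == key$community[i] &
        rates$replicate == key$replicate[i] &
        rates$gradient_type == "salt"
      f <- fit_power(rates$condition_value[sel], rates$rate[sel])
      data.frame(community = key$community[i], replicate = key$replicate[i],
                 k = f$k, a = f$a, v0 = f$v0, sai = f$sai, sa0 = f$sa0,
                 r_squared = f$r_squared, flagged = f$flagged,
                 stringsAsFactors = FALSE)
    })
    out$salt <- do.call(rbind, rows)
  }
  params <- c(
    if (!is.null(out$temperature)) c("t_m", "w"),
    if (!is.null(out$salt)) c("sai", "sa0")
  )
  out$comparisons <- list()
  tab <- NULL
  for (p in params) {
    src <- if (p %in% c("t_m", "w")) out$temperature else out$salt
    cmp <- compare_parameters(src[[p]], src$community, alpha = alpha)
    out$comparisons[[p]] <- cmp
    cell <- sprintf("%.3g(%.2g)%s", cmp$summary$mean, cmp$summary$sd,
                    cmp$summary$letters)
    col <- stats::setNames(data.frame(cell, stringsAsFactors = FALSE), p)
    tab <- if (is.null(tab)) {
      cbind(data.frame(community = cmp$summary$group,
                       stringsAsFactors = FALSE), col)
    } else cbind(tab, col)
  }
  out$comparison_table <- tab
  out
}

# UniFrac + AMOVA + NMDS + vectors + Mantel + correlations
compare_communities <- function(res, config) {
  seed <- config$seed
  cm <- res$community_matrix
  uf <- unifrac_matrix(res$tree, cm)
  # clone-level haplotype-identity distances for AMOVA: 0 within an RFLP
  # group, 1 between groups
  mapping <- res$communities$mapping
  grp_of_clone <- rep(names(res$rflp$members),
                      vapply(res$rflp$members, length, 1L))
  names(grp_of_clone) <- unlist(res$rflp$members)
  clone_group <- grp_of_clone[mapping$clone_id]
  d_clone <- outer(clone_group, clone_group, FUN = "!=") * 1
  dimnames(d_clone) <- list(mapping$clone_id, mapping$clone_id)
  am <- amova(d_clone, stats::setNames(mapping$community, mapping$clone_id),
              permutations = config$nulls$amova_permutations, seed = seed + 505)
  ord <- nmds(uf, dims = 2, n_starts = config$nulls$nmds_starts,
              seed = seed + 606)
  # replicate-level metric table for vectors / Mantel
  div_rep <- res$diversity[res$diversity$level == "replicate", ]
  met <- data.frame(unit = div_rep$unit, chao1 = div_rep$chao1,
                    shannon = div_rep$shannon, pd = div_rep$pd,
                    nri = div_rep$nri, nti = div_rep$nti,
                    stringsAsFactors = FALSE)
  tf <- res$fits$temperature; sf <- res$fits$salt
  if (!is.null(tf)) {
    tf$unit <- paste0(tf$community, "_r", tf$replicate)
    met <- merge(met, tf[, c("unit", "t_m", "w")], by = "unit")
  }
  if (!is.null(sf)) {
    sf$unit <- paste0(sf$community, "_r", sf$replicate)
    met <- merge(met, sf[, c("unit", "sai", "sa0")], by = "unit")
  }
  met <- met[match(rownames(uf), met$unit), ]
  vecs <- list()
  for (v in setdiff(names(met), "unit")) {
    fv <- tryCatch(
      fit_env_vector(ord, met[[v]],
                     permutations = config$nulls$envfit_permutations,
                     seed = seed + 707),
      error = function(e) NULL)
    if (!is.null(fv)) {
      vecs[[length(vecs) + 1L]] <- data.frame(
        variable = v, nmds1 = fv$direction[1], nmds2 = fv$direction[2],
        r_squared = fv$r_squared, p_value = fv$p_value,
        stringsAsFactors = FALSE)
    }
  }
  vectors <- do.call(rbind, vecs)
  rownames(vectors) <- NULL
  mm <- scale(as.matrix(met[, setdiff(names(met), "unit")]))
  d_met <- as.matrix(stats::dist(mm))
  dimnames(d_met) <- list(met$unit, met$unit)
  mt <- mantel_test(uf, d_met,
                    permutations = config$nulls$mantel_permutations,
                    seed = seed + 808)
  # community-level means for pairwise correlations
  grouping <- res$communities$grouping
  met_comm <- stats::aggregate(met[, setdiff(names(met), "unit")],
                               by = list(community = grouping[met$unit]),
                               FUN = mean)
  cors <- pairwise_correlations(met_comm[, -1])
  list(unifrac = uf, amova = am, ordination = ord, vectors = vectors,
       mantel = mt, correlations = cors, metrics = met,
       metrics_community = met_comm)
}
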