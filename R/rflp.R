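#' Restriction enzyme specification
#'
#' @param name enzyme name.
#' @param site recognition sequence (ACGT only).
#' @param cut_offset bases 5' of the cut within the site; AluI (AG^CT) cuts
#'   bluntly between G and C, offset 2.
#' @return list of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name = "AluI", site = "AGCT", cut_offset = 2) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    stop("'site' must be an ACGT string", call. = FALSE)
  }
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("'cut_offset' must lie within the site", call. = FALSE)
  }
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' In-silico restriction digest of one sequence
#'
#' Scans the sequence left to right for the recognition site (overlapping
#' occurrences included) and cuts `cut_offset` bases into each site. Any
#' non-ACGT character breaks a site match (conservative handling of ambiguity
#' codes). Fragment lengths are returned 5' to 3' and always sum to the
#' sequence length.
#'
#' @param sequence DNA string.
#' @param enzyme a [restriction_enzyme()]; AluI by default.
#' @return integer vector of fragment lengths, 5' to 3'.
#' @export
digest <- function(sequence, enzyme = restriction_enzyme()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  subj <- Biostrings::BString(sequence)
  hits <- Biostrings::matchPattern(enzyme$site, subj, fixed = TRUE)
  starts <- Biostrings::start(hits)
  cuts <- sort(unique(starts + enzyme$cut_offset - 1L))  # cut after this base
  cuts <- cuts[cuts >= 1L & cuts < n]
  as.integer(diff(c(0L, cuts, n)))
}

#' Digest a set of clone sequences
#'
#' @param sequences named character vector of DNA sequences.
#' @param enzyme a [restriction_enzyme()].
#' @return named list of integer fragment-length vectors.
#' @export
digest_set <- function(sequences, enzyme = restriction_enzyme()) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("'sequences' must have unique names", call. = FALSE)
  }
  lapply(stats::setNames(as.character(sequences), names(sequences)),
         digest, enzyme = enzyme)
}

#' Apply gel detection and co-migration binning to fragment profiles
#'
#' Emulates scoring bands on a high-resolution agarose gel: fragments below
#' the detection limit are dropped, and fragments (pooled over all profiles)
#' whose lengths differ by at most `resolution` times their mean are merged
#' into a single band whose length is the rounded mean of the members.
#' Binning walks the pooled sorted lengths and opens a new band as soon as a
#' length differs from the band's smallest member by more than the tolerance;
#' anchoring at the smallest member keeps each band no wider than the gel
#' resolution and prevents transitive chaining from collapsing the whole
#' ladder. Binning on the pooled length set guarantees the same physical band
#' is scored identically in every profile.
#'
#' @param profiles named list of fragment-length vectors (from
#'   [digest_set()]).
#' @param min_detectable smallest detectable fragment, bp (default 50).
#' @param resolution relative co-migration tolerance (default 0.05,
#'   approximating a 3% high-resolution gel).
#' @return named list of sorted band-length vectors.
#' @export
bin_profiles <- function(profiles, min_detectable = 50, resolution = 0.05) {
  if (min_detectable < 0 || resolution < 0) {
    stop("'min_detectable' and 'resolution' must be >= 0", call. = FALSE)
  }
  kept <- lapply(profiles, function(f) f[f >= min_detectable])
  lens <- sort(unique(unlist(kept)))
  if (length(lens) == 0L) return(lapply(kept, function(f) integer(0)))
  # merge sorted lengths into bands anchored at each band's smallest member
  bin_id <- integer(length(lens))
  bin_id[1] <- 1L
  anchor <- lens[1]
  for (i in seq_along(lens)[-1]) {
    in_band <- (lens[i] - anchor) <= resolution * mean(c(anchor, lens[i]))
    if (in_band) {
      bin_id[i] <- bin_id[i - 1]
    } else {
      bin_id[i] <- bin_id[i - 1] + 1L
      anchor <- lens[i]
    }
  }
  band_len <- vapply(split(lens, bin_id), function(x) as.integer(round(mean(x))), 1L)
  lut <- stats::setNames(band_len[as.character(bin_id)], lens)
  lapply(kept, function(f) {
    if (length(f) == 0L) return(integer(0))
    sort(as.integer(lut[as.character(f)]))
  })
}

#' Group clones by identical banding profile
#'
#' Clones whose (sorted) band profiles are identical form one RFLP group.
#' Groups are numbered by first occurrence in the clone order of `mapping`,
#' which makes the numbering deterministic for a given input table.
#'
#' @param profiles named list of band-length vectors, one per clone.
#' @param mapping data.frame with columns clone_id and sample_id (every clone
#'   mapped to exactly one sample).
#' @param samples sample ids to tabulate; defaults to those present in
#'   `mapping`. Extra ids yield retained zero-count columns (empty
#'   libraries).
#' @return object of class `rflp_table`: integer matrix `counts` (group x
#'   sample), list `members` (clone ids per group), character `representative`
#'   (first clone per group), list `profiles` (band profile per group).
#' @export
group_clones <- function(profiles, mapping, samples = NULL) {
  if (anyDuplicated(mapping$clone_id)) stop("duplicate clone ids", call. = FALSE)
  miss <- setdiff(mapping$clone_id, names(profiles))
  if (length(miss)) {
    stop("profiles missing for clones: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(samples)) samples <- unique(mapping$sample_id)
  keys <- vapply(mapping$clone_id,
                 function(id) paste(profiles[[id]], collapse = "_"), "")
  group_of <- match(keys, unique(keys))
  n_groups <- max(group_of)
  group_ids <- sprintf("RFLP%03d", seq_len(n_groups))
  counts <- matrix(0L, n_groups, length(samples),
                   dimnames = list(group_ids, samples))
  tab <- table(factor(group_of, levels = seq_len(n_groups)),
               factor(mapping$sample_id, levels = samples))
  counts[, ] <- tab
  members <- split(mapping$clone_id, factor(group_of, levels = seq_len(n_groups)))
  names(members) <- group_ids
  structure(list(
    counts = counts,
    members = members,
    representative = vapply(members, `[`, "", 1),
    profiles = stats::setNames(
      lapply(group_ids, function(g) profiles[[members[[g]][1]]]), group_ids)
  ), class = "rflp_table")
}

#' Shared and unique RFLP groups across communities
#'
#' Pools each community's replicate samples to presence/absence and computes
#' per-community totals, counts unique to each community, all pairwise shared
#' counts, and the full set of Venn region counts (one per non-empty
#' community combination; regions partition the observed groups, so region
#' counts sum to the number of distinct groups).
#'
#' @param table an [group_clones()] `rflp_table` (or a group x sample count
#'   matrix).
#' @param grouping named character vector sample_id -> community.
#' @return list: `totals`, `unique`, `pairwise_shared` (matrix), `regions`
#'   (named vector keyed by "+"-joined community combos), `n_groups`.
#' @export
shared_unique <- function(table, grouping) {
  counts <- if (inherits(table, "rflp_table")) table$counts else table
  miss <- setdiff(colnames(counts), names(grouping))
  if (length(miss)) {
    stop("grouping missing for samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  comms <- unname(unique(grouping[colnames(counts)]))
  if (length(comms) < 1L) stop("need >= 1 community", call. = FALSE)
  pres <- sapply(comms, function(cm) {
    cols <- colnames(counts)[grouping[colnames(counts)] == cm]
    rowSums(counts[, cols, drop = FALSE]) > 0
  })
  pres <- matrix(pres, nrow = nrow(counts), dimnames = list(NULL, comms))
  observed <- rowSums(pres) > 0
  pres <- pres[observed, , drop = FALSE]
  totals <- colSums(pres)
  membership_key <- apply(pres, 1, function(p) paste(comms[p], collapse = "+"))
  regions_tab <- table(membership_key)
  # all non-empty combos, zero-filled
  combos <- unlist(lapply(seq_along(comms), function(k) {
    utils::combn(comms, k, paste, collapse = "+", simplify = TRUE)
  }))
  regions <- stats::setNames(integer(length(combos)), combos)
  regions[names(regions_tab)] <- as.integer(regions_tab)
  uniq <- stats::setNames(regions[comms], comms)
  pw <- matrix(0L, length(comms), length(comms), dimnames = list(comms, comms))
  for (i in seq_along(comms)) for (j in seq_along(comms)) {
    pw[i, j] <- sum(pres[, i] & pres[, j])
  }
  list(totals = totals, unique = uniq, pairwise_shared = pw,
       regions = regions, n_groups = sum(observed))
}
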