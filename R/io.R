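#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  stats::setNames(toupper(as.character(set)), names(set))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty Newick file: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick file: ", path, call. = FALSE)
  tr
}

#' Write a tree to Newick
#'
#' @param tree `phylo` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read/write the gas-series CSV dialect
#'
#' Columns: flask_id, community, replicate, gradient_type, condition_value,
#' incubation_temp_c, time_h, n2o_amount, liquid_volume_ml,
#' headspace_volume_ml.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_gas_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(replicate = "character"))
  need <- c("flask_id", "community", "replicate", "gradient_type",
            "condition_value", "time_h", "n2o_amount")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("gas CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(out) == 0) stop("empty gas CSV: ", path, call. = FALSE)
  out
}

#' @rdname read_gas_csv
#' @param gas gas-series data.frame.
#' @export
write_gas_csv <- function(gas, path) {
  utils::write.csv(gas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table as TSV with provenance header comments
#'
#' @param x data.frame or matrix.
#' @param path output file.
#' @param comments character vector written as leading `#` lines.
#' @param rownames_as column name under which to keep rownames (NULL drops).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comments = character(0), rownames_as = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  df <- as.data.frame(x)
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownames_as), df)
  }
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path TSV file, `#` comment lines skipped.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(out) == 0) stop("empty table: ", path, call. = FALSE)
  out
}

#' Read a clone-to-sample mapping TSV
#'
#' @param path TSV with at least clone_id and sample_id columns.
#' @return data.frame.
#' @export
read_mapping_tsv <- function(path) {
  out <- read_tsv(path)
  miss <- setdiff(c("clone_id", "sample_id"), names(out))
  if (length(miss)) {
    stop("mapping TSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}
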