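#' Read a tab-separated gene rate table
#'
#' Expected columns: `id`, `beta_m`, `beta_p`; optional `m`, `r`, `s`,
#' `alpha_m`, `alpha_p`, `p`.  A header row is required; `.` or an empty
#' field denotes a missing value.  Rates must be strictly positive where
#' present.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per gene.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path))
    stop("gene table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c(".", "", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_gene_table(tab)
}

validate_gene_table <- function(tab) {
  need <- c("id", "beta_m", "beta_p")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene table lacks required column(s): ", paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id))
    stop("gene table contains duplicated gene ids")
  for (col in intersect(c("beta_m", "beta_p", "m", "r", "s",
                          "alpha_m", "alpha_p", "p"), names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
    v <- tab[[col]]
    if (any(!is.na(v) & v <= 0))
      stop("gene table column '", col, "' has non-positive entries")
  }
  tab
}

#' Write a gene table as TSV
#'
#' Missing values are written as `.`.
#'
#' @param tab Gene table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(tab, path) {
  out <- validate_gene_table(tab)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a tab-separated paralog-pair table
#'
#' Expected columns: `gene1`, `gene2`, `dup_type` with `dup_type` in
#' `{WGD, SSD}` (whole-genome vs small-scale duplication).
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per pair.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path))
    stop("pair table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           na.strings = c(".", "", "NA"),
                           stringsAsFactors = FALSE)
  validate_pair_table(tab)
}

validate_pair_table <- function(tab) {
  need <- c("gene1", "gene2", "dup_type")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pair table lacks required column(s): ", paste(miss, collapse = ", "))
  tab$gene1 <- as.character(tab$gene1)
  tab$gene2 <- as.character(tab$gene2)
  if (any(tab$gene1 == tab$gene2))
    stop("pair table contains self-pairs (gene1 == gene2)")
  if (!all(tab$dup_type %in% c("WGD", "SSD")))
    stop("dup_type must be 'WGD' or 'SSD'")
  tab
}

#' @rdname read_pair_table
#' @param tab Pair table to write.
#' @param path Output path.
#' @export
write_pair_table <- function(tab, path) {
  out <- validate_pair_table(tab)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
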