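#' Construct an OTU count table
#'
#' The basic unit of the package: a samples x OTUs matrix of non-negative
#' integer read counts with unique sample and OTU identifiers.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Must be
#'   non-negative integers (within 1e-8 of whole numbers).
#' @param sample_ids,otu_ids character vectors; default to the dimnames of
#'   `counts`.
#' @return An object of class `otu_table`: the integer matrix with
#'   `sample_ids` as rownames and `otu_ids` as colnames.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("sample_ids and otu_ids are required (supply dimnames or arguments)")
  if (length(sample_ids) != nrow(counts) || length(otu_ids) != ncol(counts))
    stop("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyNA(counts) || !is.numeric(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers")
  counts <- round(counts)
  storage.mode(counts) <- "double"  # keep totals exact yet overflow-safe
  dimnames(counts) <- list(as.character(sample_ids), as.character(otu_ids))
  structure(counts, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Read an OTU count table from TSV
#'
#' Expects OTUs as rows and samples as columns (the common mothur/Qiime
#' export orientation): first column OTU id, remaining columns one per
#' sample, header row with sample ids. The returned table is transposed to
#' the package's samples x OTUs orientation.
#'
#' @param path path to a tab-separated file.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("OTU table needs an id column plus >=1 sample column")
  otu_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))) | is.na(m),
               arr.ind = TRUE)
  if (length(bad))
    stop(sprintf("non-numeric or missing cell at OTU '%s', sample '%s'",
                 otu_ids[bad[1, 1]], sample_ids[bad[1, 2]]))
  storage.mode(m) <- "double"
  neg <- which(m < 0, arr.ind = TRUE)
  if (length(neg))
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 otu_ids[neg[1, 1]], sample_ids[neg[1, 2]]))
  otu_table(t(m), sample_ids = sample_ids, otu_ids = otu_ids)
}

#' Write an OTU count table as TSV
#'
#' Writes in the same orientation [read_otu_table()] expects (OTUs as rows),
#' so `read_otu_table(write_otu_table(x, f))` round-trips.
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @param id_column header name for the OTU id column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, id_column = "otu_id") {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(colnames(x), t(unclass(x)), check.names = FALSE)
  colnames(df) <- c(id_column, rownames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total read count. Samples with zero
#' total stay all-zero and are flagged in the `zero_total` attribute rather
#' than raising an error.
#'
#' @param x an [otu_table()] or a samples x OTUs numeric matrix.
#' @return a `rel_abundance` matrix (samples x OTUs, rows summing to 1),
#'   with attribute `zero_total`: character vector of all-zero sample ids.
#' @export
relative_abundance <- function(x) {
  m <- unclass(as.matrix(x))
  if (any(m < 0)) stop("counts must be non-negative")
  totals <- rowSums(m)
  zero <- rownames(m)[totals == 0]
  p <- m / ifelse(totals == 0, 1, totals)
  structure(p, class = c("rel_abundance", "matrix", "array"),
            zero_total = zero)
}

#' Rarefy counts to an even depth
#'
#' Optional seeded subsampling of each sample's reads without replacement
#' to a common depth. Diversity comparisons in this package default to NO
#' rarefaction; this helper exists for sensitivity analyses.
#'
#' @param x an [otu_table()].
#' @param depth target reads per sample; samples below it are dropped with
#'   a warning.
#' @param seed integer seed.
#' @return a rarefied [otu_table()].
#' @export
rarefy_counts <- function(x, depth, seed) {
  m <- unclass(as.matrix(x))
  totals <- rowSums(m)
  low <- rownames(m)[totals < depth]
  if (length(low)) {
    warning("samples below depth dropped: ", paste(low, collapse = ", "))
    m <- m[totals >= depth, , drop = FALSE]
  }
  set.seed(seed)
  out <- t(apply(m, 1, function(row) {
    picked <- sample(rep.int(seq_along(row), row), depth)
    tabulate(picked, nbins = length(row))
  }))
  dimnames(out) <- dimnames(m)
  otu_table(out)
}

#' Read a taxonomy assignment table
#'
#' TSV with columns `otu_id`, any subset of the ranks domain..genus, and an
#' optional `species` column. Empty strings and "unclassified" are treated
#' as missing assignments.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame with one row per OTU; rownames are OTU ids.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"otu_id" %in% colnames(df)) stop("taxonomy file needs an 'otu_id' column")
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy file")
  rownames(df) <- df$otu_id
  df
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `subject_id`, `arm` (invitro/human),
#' `group`, `timepoint`, and optional plasma columns `frap`, `glucose`,
#' `crp`.
#'
#' @param path path to a tab-separated file.
#' @return a data.frame keyed by `sample_id` (also the rownames).
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group", "timepoint")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  rownames(df) <- df$sample_id
  df
}

#' Check that metadata covers a table's samples
#' @param x an [otu_table()] or abundance matrix.
#' @param meta metadata data.frame as from [read_sample_metadata()].
#' @return invisibly TRUE; errors naming uncovered samples otherwise.
#' @export
validate_metadata <- function(x, meta) {
  missing <- setdiff(rownames(x), meta$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' Sums OTU relative abundances sharing the same label at the requested
#' rank. OTUs with no assignment at that rank are pooled under
#' `unclassified_<parent>`, where the parent is the OTU's deepest assigned
#' rank above the requested one (or "unclassified" if none).
#'
#' @param p a `rel_abundance` matrix (samples x OTUs).
#' @param taxonomy data.frame from [read_taxonomy()]; rownames are OTU ids.
#' @param rank one of the taxonomy columns, typically "genus", "family" or
#'   "species".
#' @return a `rel_abundance` matrix, samples x taxa; per-sample totals are
#'   preserved.
#' @export
aggregate_taxa <- function(p, taxonomy, rank = c("genus", "family", "species")) {
  rank <- match.arg(rank)
  if (!rank %in% colnames(taxonomy))
    stop("taxonomy has no '", rank, "' column")
  ids <- colnames(p)
  unknown <- setdiff(ids, rownames(taxonomy))
  if (length(unknown))
    stop("OTUs missing from taxonomy: ", paste(utils::head(unknown, 5), collapse = ", "))
  tx <- taxonomy[ids, , drop = FALSE]
  lab <- as.character(tx[[rank]])
  lab[is.na(lab) | lab == "" | lab == "unclassified"] <- NA
  if (anyNA(lab)) {
    ranks <- intersect(c("domain", "phylum", "class", "order", "family", "genus",
                         "species"), colnames(taxonomy))
    above <- ranks[seq_len(max(match(rank, ranks) - 1L, 0L))]
    parent <- rep("unclassified", length(lab))
    for (r in above) {
      v <- as.character(tx[[r]])
      ok <- !is.na(v) & v != "" & v != "unclassified"
      parent[ok] <- v[ok]
    }
    lab[is.na(lab)] <- paste0("unclassified_", parent[is.na(lab)])
  }
  groups <- factor(lab, levels = unique(lab))
  agg <- t(rowsum(t(unclass(p)), group = groups))
  structure(agg, class = c("rel_abundance", "matrix", "array"),
            zero_total = attr(p, "zero_total"))
}
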