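#' Write / read an OTU count table with library metadata as TSV
#'
#' Two tab-delimited files: the count table (rows = OTUs, first column
#' \code{otu_id}, remaining columns one per library, integer counts) and a
#' metadata table with columns \code{library_id}, \code{treatment},
#' \code{isotope}, \code{fraction}, \code{replicate}, \code{marker}. An
#' optional third file records the 13C/12C treatment pairing
#' (\code{labeled}, \code{control}).
#'
#' @param x a \code{sip_experiment}.
#' @param counts_path,meta_path,design_path output paths;
#'   \code{design_path} may be \code{NULL}.
#' @return \code{write_otu_table} returns the paths invisibly;
#'   \code{read_otu_table} returns a \code{sip_experiment} (without
#'   truth).
#' @export
write_otu_table <- function(x, counts_path, meta_path, design_path = NULL) {
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$libraries, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(design_path) && !is.null(x$design))
    utils::write.table(x$design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(counts_path, meta_path, design_path))
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(counts_path, meta_path, design_path = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$otu_id
  libraries <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  libraries$isotope <- as.character(libraries$isotope)
  missing <- setdiff(libraries$library_id, colnames(counts))
  if (length(missing))
    stop("metadata lists libraries absent from the count table: ",
         paste(missing, collapse = ", "))
  design <- if (!is.null(design_path))
    utils::read.delim(design_path, stringsAsFactors = FALSE) else NULL
  structure(list(counts = counts, libraries = libraries, design = design,
                 truth = NULL),
            class = "sip_experiment")
}

#' Write / read a synthetic-truth record as TSV
#'
#' @param truth a [synthetic_truth()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- data.frame(
    field = c("true_k", "true_labeled_otus", "enrichment_factor",
              "true_mineralized_fraction", "seed"),
    value = c(truth$true_k, paste(truth$true_labeled_otus, collapse = ","),
              truth$enrichment_factor, truth$true_mineralized_fraction,
              truth$seed))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- stats::setNames(df$value, df$field)
  synthetic_truth(
    true_k = as.numeric(v[["true_k"]]),
    true_labeled_otus = strsplit(v[["true_labeled_otus"]], ",")[[1]],
    enrichment_factor = as.numeric(v[["enrichment_factor"]]),
    true_mineralized_fraction = as.numeric(v[["true_mineralized_fraction"]]),
    seed = as.integer(v[["seed"]]))
}
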