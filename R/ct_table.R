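#' Construct a cycle-threshold (Ct) table
#'
#' Container for raw qPCR cycle-threshold values together with the
#' housekeeping-gene designation, the reference-group membership used for
#' ddCt normalization, and an optional per-sample group label (e.g. Braak
#' stage).
#'
#' @param ct Numeric matrix of Ct values, samples in rows, genes in columns.
#'   Row and column names are required.
#' @param housekeeping Character vector of housekeeping gene names (columns
#'   of `ct`).
#' @param reference_samples Character vector of sample names (rows of `ct`)
#'   forming the reference group of the ddCt computation.
#' @param group Optional factor or character vector of group labels, one per
#'   sample (named or in row order).
#' @param metadata Optional data.frame of per-sample covariates, one row per
#'   sample.
#'
#' @return An object of class `ct_table`: a list with elements `ct`,
#'   `housekeeping`, `reference_samples`, `group`, `metadata`.
#'
#' @details Ct values must be finite and positive (a Ct is a PCR cycle
#'   number). Housekeeping genes and target genes are disjoint by
#'   construction: every gene not listed in `housekeeping` is a target.
#'
#' @export
ct_table <- function(ct, housekeeping, reference_samples, group = NULL,
                     metadata = NULL) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (samples x genes)")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have sample row names and gene column names")
  if (anyDuplicated(rownames(ct)) || anyDuplicated(colnames(ct)))
    stop("duplicate sample or gene names in `ct`")
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be finite and > 0")
  housekeeping <- as.character(housekeeping)
  missing_hk <- setdiff(housekeeping, colnames(ct))
  if (length(missing_hk))
    stop("housekeeping genes absent from table: ",
         paste(missing_hk, collapse = ", "))
  reference_samples <- as.character(reference_samples)
  if (!length(reference_samples))
    stop("reference group must be non-empty")
  missing_ref <- setdiff(reference_samples, rownames(ct))
  if (length(missing_ref))
    stop("reference samples absent from table: ",
         paste(missing_ref, collapse = ", "))
  if (!is.null(group)) {
    if (!is.null(names(group))) group <- group[rownames(ct)]
    if (length(group) != nrow(ct))
      stop("`group` must have one label per sample")
    group <- factor(group)
    names(group) <- rownames(ct)
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(ct))
      stop("`metadata` must have one row per sample")
    rownames(metadata) <- rownames(ct)
  }
  structure(
    list(ct = ct, housekeeping = housekeeping,
         reference_samples = reference_samples, group = group,
         metadata = metadata),
    class = "ct_table"
  )
}

#' @export
print.ct_table <- function(x, ...) {
  cat("ct_table:", nrow(x$ct), "samples x", ncol(x$ct), "genes\n")
  cat("  housekeeping:", paste(x$housekeeping, collapse = ", "), "\n")
  cat("  reference group:", length(x$reference_samples), "samples\n")
  if (!is.null(x$group))
    cat("  groups:", paste(levels(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' Target (non-housekeeping) genes of a Ct table
#' @param x A [ct_table()].
#' @return Character vector of target gene names.
#' @export
target_genes <- function(x) {
  stopifnot(inherits(x, "ct_table"))
  setdiff(colnames(x$ct), x$housekeeping)
}

#' Write / read a Ct table as TSV
#'
#' Samples are rows and genes columns; metadata columns are prefixed
#' `meta_`; the housekeeping designation, reference group and group label
#' are stored in `meta_`-prefixed columns so that one flat file round-trips
#' the object.
#'
#' @param x A [ct_table()].
#' @param path File path.
#' @return `write_ct_table` returns `path` invisibly; `read_ct_table`
#'   returns a [ct_table()].
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  df <- as.data.frame(x$ct)
  df <- cbind(sample = rownames(x$ct), df)
  df$meta_group <- if (is.null(x$group)) NA else as.character(x$group)
  df$meta_reference <- rownames(x$ct) %in% x$reference_samples
  df$meta_housekeeping <- paste(x$housekeeping, collapse = ";")
  if (!is.null(x$metadata)) {
    md <- x$metadata
    names(md) <- paste0("meta_", names(md))
    df <- cbind(df, md)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- grep("^meta_", names(df), value = TRUE)
  gene_cols <- setdiff(names(df), c("sample", meta_cols))
  ct <- as.matrix(df[, gene_cols, drop = FALSE])
  rownames(ct) <- df$sample
  hk <- strsplit(df$meta_housekeeping[1], ";", fixed = TRUE)[[1]]
  ref <- df$sample[df$meta_reference]
  grp <- if (all(is.na(df$meta_group))) NULL else df$meta_group
  extra <- setdiff(meta_cols, c("meta_group", "meta_reference",
                                "meta_housekeeping"))
  md <- if (length(extra)) {
    out <- df[, extra, drop = FALSE]
    names(out) <- sub("^meta_", "", names(out))
    out
  } else NULL
  ct_table(ct, hk, ref, group = grp, metadata = md)
}
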