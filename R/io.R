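# Readers, writers and sample alignment for the three input tables:
# total-expression (gene x sample), intron-excision ratios (intron x
# sample, LeafCutter perind-style ids) and sample covariates.

#' Load a gene x sample total-expression table
#'
#' @param path TSV with a gene-id column followed by one column per sample,
#'   or a GCT 1.2 file (\code{"#1.2"} header, dimensions line, and a
#'   Description column that is dropped on load).
#' @param dialect \code{"tsv"} or \code{"gct"}.
#' @return numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
load_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_splicecor("file not found: %s", path, class = "splicecor_io_error")
  skip <- 0L
  if (dialect == "gct") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !startsWith(hdr[[1L]], "#1.2"))
      stop_splicecor("malformed GCT header at line 1 of %s", path,
                     class = "splicecor_parse_error")
    dims <- suppressWarnings(as.integer(strsplit(hdr[[2L]], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims))
      stop_splicecor("malformed GCT dimensions at line 2 of %s", path,
                     class = "splicecor_parse_error")
    skip <- 2L
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_splicecor("malformed header at line %d of %s: need id + sample columns",
                   skip + 1L, path, class = "splicecor_parse_error")
  ids <- as.character(df[[1L]])
  drop_cols <- if (dialect == "gct") 1:2 else 1L
  vals <- as.matrix(df[, -drop_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyDuplicated(ids))
    stop_splicecor("duplicated gene id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", "),
                   class = "splicecor_validation_error")
  if (anyDuplicated(colnames(vals)))
    stop_splicecor("duplicated sample id(s) in %s", path,
                   class = "splicecor_validation_error")
  rownames(vals) <- ids
  vals
}

parse_ratio_entries <- function(x) {
  # Entries are either plain numbers or "count/total" fractions; "0/0"
  # (LeafCutter's empty cluster-sample) becomes NA.
  out <- suppressWarnings(as.numeric(x))
  frac <- grepl("/", x, fixed = TRUE)
  if (any(frac)) {
    parts <- strsplit(x[frac], "/", fixed = TRUE)
    num <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1L])), 0)
    den <- vapply(parts, function(p) suppressWarnings(as.numeric(p[2L])), 0)
    r <- num / den
    r[den == 0] <- NA_real_
    out[frac] <- r
  }
  out
}

#' Load an intron-excision-ratio (IER) table with its intron-to-gene map
#'
#' The ratio file is TSV with a first column of LeafCutter-style intron ids
#' (\code{chrom:start:end:clusterID}) and one column per sample; entries
#' are ratios in [0, 1] or \code{"count/total"} fractions (\code{0/0}
#' recorded as missing). The gene map is a 2-column TSV: intron id, gene
#' id. Introns absent from the map are dropped with a warning. Complete
#' (fully observed) cluster-sample ratio sets must sum to 1 within 1e-6;
#' clusters violating this are rejected (dropped with a warning), never
#' renormalized, since a bad sum indicates an upstream quantification bug.
#'
#' @param path ratio TSV.
#' @param gene_map_path 2-column TSV mapping intron id to gene id.
#' @return list of class \code{ier_table}: \code{values} (intron x sample
#'   numeric matrix, possibly with NAs), \code{gene_map} (named character:
#'   intron id -> gene id), \code{clusters} (named character: intron id ->
#'   cluster key).
#' @export
load_ier <- function(path, gene_map_path) {
  for (p in c(path, gene_map_path))
    if (!file.exists(p))
      stop_splicecor("file not found: %s", p, class = "splicecor_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop_splicecor("malformed header at line 1 of %s", path,
                   class = "splicecor_parse_error")
  ids <- as.character(df[[1L]])
  vals <- apply(df[, -1L, drop = FALSE], 2L, parse_ratio_entries)
  vals <- matrix(vals, nrow = length(ids),
                 dimnames = list(ids, colnames(df)[-1L]))
  bad <- !is.na(vals) & (vals < 0 | vals > 1)
  if (any(bad))
    stop_splicecor("ratio outside [0, 1] for intron(s): %s",
                   paste(utils::head(unique(ids[row(vals)[bad]]), 5),
                         collapse = ", "),
                   class = "splicecor_validation_error")

  gm <- utils::read.delim(gene_map_path, header = FALSE,
                          stringsAsFactors = FALSE)
  if (grepl(":", gm[1, 1], fixed = TRUE) == FALSE && nrow(gm) > 1) {
    # tolerate a header row in the gene map
    gm <- gm[-1L, , drop = FALSE]
  }
  gene_map <- stats::setNames(as.character(gm[[2L]]), as.character(gm[[1L]]))

  unmapped <- setdiff(ids, names(gene_map))
  if (length(unmapped)) {
    warn_splicecor("dropping %d intron(s) absent from the gene map",
                   length(unmapped))
    keep <- ids %in% names(gene_map)
    vals <- vals[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (!nrow(vals))
    stop_splicecor("no mapped introns remain", class = "splicecor_io_error")

  parts <- strsplit(ids, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L))
    stop_splicecor("intron ids must be chrom:start:end:cluster",
                   class = "splicecor_parse_error")
  clusters <- vapply(parts, `[[`, "", 4L)
  names(clusters) <- ids

  # cluster-sum validation on complete cluster-sample sets
  bad_clu <- character(0)
  for (clu in unique(clusters)) {
    block <- vals[clusters == clu, , drop = FALSE]
    complete <- colSums(is.na(block)) == 0
    if (any(complete)) {
      sums <- colSums(block[, complete, drop = FALSE])
      if (any(abs(sums - 1) > 1e-6)) bad_clu <- c(bad_clu, clu)
    }
  }
  if (length(bad_clu)) {
    warn_splicecor("rejecting %d cluster(s) with ratio sums != 1: %s",
                   length(bad_clu),
                   paste(utils::head(bad_clu, 5), collapse = ", "))
    keep <- !(clusters %in% bad_clu)
    vals <- vals[keep, , drop = FALSE]
    clusters <- clusters[keep]
    ids <- ids[keep]
    if (!nrow(vals))
      stop_splicecor("no valid clusters remain", class = "splicecor_io_error")
  }

  structure(list(values = vals,
                 gene_map = gene_map[rownames(vals)],
                 clusters = clusters),
            class = "ier_table")
}

#' Load a sample x covariate table
#'
#' Samples are rows (first column = sample id). An intercept column is
#' prepended; rank-deficient covariate sets are pruned column by column
#' with a warning until full rank.
#'
#' @param path TSV path.
#' @return numeric matrix, samples in rows, covariates in columns
#'   (including \code{"(Intercept)"}).
#' @export
load_covariates <- function(path) {
  if (!file.exists(path))
    stop_splicecor("file not found: %s", path, class = "splicecor_io_error")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  Z <- cbind(`(Intercept)` = 1, vals)
  rownames(Z) <- ids
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    drop <- setdiff(seq_len(ncol(Z)), qrZ$pivot[seq_len(qrZ$rank)])
    warn_splicecor("covariates rank-deficient; pruning column(s): %s",
                   paste(colnames(Z)[drop], collapse = ", "))
    Z <- Z[, -drop, drop = FALSE]
  }
  Z
}

#' Select analysis-ready (multi-intron) genes
#'
#' A gene is eligible when it is present in the expression table and its
#' IER block has at least \code{min_introns} introns: the intron count is
#' used as the surrogate for isoform count, since only genes with at least
#' two quantified introns carry usable splicing variation.
#'
#' @param expr expression matrix from \code{\link{load_expression}}.
#' @param ier \code{ier_table} from \code{\link{load_ier}}.
#' @param min_introns minimum introns per gene (default 2).
#' @return character vector of eligible gene ids.
#' @export
select_genes <- function(expr, ier, min_introns = 2) {
  counts <- table(ier$gene_map[rownames(ier$values)])
  eligible <- names(counts)[counts >= min_introns]
  out <- intersect(rownames(expr), eligible)
  if (!length(out))
    stop_splicecor("no eligible genes (min_introns = %d)", min_introns,
                   class = "splicecor_no_genes_error")
  out
}

#' Align samples across tables, mean-center expression, impute IERs
#'
#' Restricts all three tables to the (sorted) intersection of sample ids,
#' mean-centers every expression row, and imputes missing IER entries with
#' the intron's mean over observed samples. Mean imputation is neutral
#' after the kernel's per-intron standardization; the count of imputed
#' entries is reported via a message.
#'
#' @param expr expression matrix (genes x samples).
#' @param ier \code{ier_table}.
#' @param cov covariate matrix (samples x covariates).
#' @return list with aligned \code{expr}, \code{ier}, \code{cov} and the
#'   canonical \code{sample_ids}.
#' @export
center_and_align <- function(expr, ier, cov) {
  shared <- Reduce(intersect, list(colnames(expr), colnames(ier$values),
                                   rownames(cov)))
  if (length(shared) < 10)
    stop_splicecor("only %d shared sample(s); need at least 10",
                   length(shared), class = "splicecor_size_error")
  shared <- sort(shared)
  expr <- expr[, shared, drop = FALSE]
  expr <- expr - rowMeans(expr)
  vals <- ier$values[, shared, drop = FALSE]
  n_imputed <- sum(is.na(vals))
  if (n_imputed) {
    message(sprintf("imputing %d missing IER entr%s by intron means",
                    n_imputed, if (n_imputed == 1) "y" else "ies"))
    rm_ <- rowMeans(vals, na.rm = TRUE)
    idx <- which(is.na(vals), arr.ind = TRUE)
    vals[idx] <- rm_[idx[, 1L]]
  }
  ier$values <- vals
  list(expr = expr,
       ier = ier,
       cov = cov[shared, , drop = FALSE],
       sample_ids = shared)
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param expr genes x samples matrix with dimnames.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"gct"}.
#' @export
write_expression <- function(expr, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  if (dialect == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    df <- data.frame(Name = rownames(expr), Description = rownames(expr),
                     expr, check.names = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
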