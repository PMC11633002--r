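# Directed co-expression networks from per-pair significance calls:
# edge construction at a stratified-FDR threshold, hub (outdegree)
# summaries, pathway-size adjustment, tissue-sharing profiles, and the
# tumor-versus-normal differential-correlation test.

#' Build a directed network from a pair-result table
#'
#' Draws an edge predictor -> response for every pair passing stratified
#' FDR (strata = response gene) at level \code{q} on the chosen test's
#' p-value column (\code{p_interaction}, \code{p_joint} or
#' \code{p_correlation}).
#'
#' @param pair_table data.frame with columns \code{predictor},
#'   \code{response} and the p-value column for \code{test_label}.
#' @param test_label \code{"interaction"}, \code{"joint"} or
#'   \code{"correlation"}.
#' @param q stratified FDR level.
#' @param stratum_key column to stratify by (default \code{"response"}).
#' @return object of class \code{coexpr_network}: list with
#'   \code{graph} (igraph), \code{edges} (data.frame), \code{nodes},
#'   \code{outdegree}, \code{indegree}, \code{test_label}, \code{q}.
#' @export
build_network <- function(pair_table, test_label = c("interaction", "joint",
                                                     "correlation"),
                          q = 0.05, stratum_key = "response") {
  test_label <- match.arg(test_label)
  pcol <- paste0("p_", test_label)
  for (col in c("predictor", "response", pcol, stratum_key))
    if (!col %in% names(pair_table))
      stop_splicecor("pair table lacks column '%s'", col,
                     class = "splicecor_missing_column")
  self <- pair_table$predictor == pair_table$response
  if (any(self)) pair_table <- pair_table[!self, , drop = FALSE]
  rej <- stratified_fdr(pair_table[[pcol]], pair_table[[stratum_key]], q)
  edges <- pair_table[which(rej), c("predictor", "response", pcol),
                      drop = FALSE]
  names(edges)[3L] <- "p"
  edges$test_label <- rep(test_label, nrow(edges))
  nodes <- sort(unique(c(pair_table$predictor, pair_table$response)))
  g <- igraph::graph_from_data_frame(edges[, c("predictor", "response")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  outd <- as.integer(igraph::degree(g, mode = "out"))
  names(outd) <- nodes
  ind <- as.integer(igraph::degree(g, mode = "in"))
  names(ind) <- nodes
  structure(list(graph = g, edges = edges, nodes = nodes,
                 outdegree = outd, indegree = ind,
                 test_label = test_label, q = q),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network (%s test, %d%% FDR): %d nodes, %d edges\n",
              x$test_label, round(100 * x$q), length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Hub genes by outdegree
#'
#' Genes whose test is significant on at least \code{min_outdegree} other
#' genes, sorted by outdegree descending with ties broken by gene id.
#'
#' @param network \code{coexpr_network}.
#' @param min_outdegree hub threshold (default 5).
#' @return data.frame with columns \code{gene}, \code{outdegree}.
#' @export
detect_hubs <- function(network, min_outdegree = 5) {
  outd <- network$outdegree
  keep <- outd >= min_outdegree
  genes <- names(outd)[keep]
  outd <- unname(outd[keep])
  ord <- order(-outd, genes)
  data.frame(gene = genes[ord], outdegree = outd[ord],
             stringsAsFactors = FALSE)
}

#' Pathway-size-adjusted mean outdegree
#'
#' Sum of the outdegrees of the pathway's genes divided by the pathway
#' size, so networks from pathways of different sizes are comparable.
#' Genes absent from the network contribute outdegree 0.
#'
#' @param network \code{coexpr_network}.
#' @param pathway_genes nonempty character vector of gene ids.
#' @return mean outdegree per gene.
#' @export
size_adjusted_outdegree <- function(network, pathway_genes) {
  if (!length(pathway_genes))
    stop_splicecor("pathway is empty", class = "splicecor_domain_error")
  outd <- network$outdegree[pathway_genes]
  outd[is.na(outd)] <- 0
  sum(outd) / length(pathway_genes)
}

#' Tissue-sharing profile of significant effects
#'
#' Given per-tissue pair-result tables over the same pair keys, counts
#' for every pair the number of tissues where it is significant at the
#' stratified FDR level, tabulates per-gene per-tissue outdegrees, and
#' summarizes hub-level sharing (in how many tissues a gene reaches hub
#' outdegree).
#'
#' @param per_tissue_tables named list of pair-result data.frames with
#'   identical (predictor, response) keys.
#' @param test_label which test's p-value column to threshold.
#' @param q stratified FDR level.
#' @param min_outdegree hub threshold for the hub-level profile.
#' @return list of class \code{tissue_sharing}: \code{pair_sharing}
#'   (data.frame predictor / response / n_tissues), \code{outdegree}
#'   (gene x tissue matrix), \code{sharing_histogram} (table of pair
#'   counts by number of sharing tissues, significant pairs only),
#'   \code{hub_sharing} (data.frame gene / n_tissues_as_hub).
#' @export
tissue_sharing <- function(per_tissue_tables, test_label = "interaction",
                           q = 0.05, min_outdegree = 5) {
  stopifnot(length(per_tissue_tables) >= 2)
  keys <- lapply(per_tissue_tables, function(tb)
    paste(tb$predictor, tb$response, sep = "\r"))
  ref <- sort(keys[[1L]])
  for (i in seq_along(keys)[-1L]) {
    if (!identical(sort(keys[[i]]), ref)) {
      off <- c(setdiff(keys[[i]], keys[[1L]]), setdiff(keys[[1L]], keys[[i]]))
      stop_splicecor("pair keys differ across tissues; offending pairs: %s",
                     paste(gsub("\r", "->", utils::head(off, 5)),
                           collapse = ", "),
                     class = "splicecor_key_mismatch")
    }
  }
  nets <- lapply(per_tissue_tables, build_network, test_label = test_label,
                 q = q)
  # per-pair significance indicator matrix
  sig <- vapply(seq_along(nets), function(i) {
    tb <- per_tissue_tables[[i]]
    ek <- paste(nets[[i]]$edges$predictor, nets[[i]]$edges$response,
                sep = "\r")
    keys[[i]] %in% ek
  }, logical(length(keys[[1L]])))
  counts <- rowSums(sig)
  pair_sharing <- data.frame(
    predictor = per_tissue_tables[[1L]]$predictor,
    response = per_tissue_tables[[1L]]$response,
    n_tissues = counts, stringsAsFactors = FALSE)

  genes <- sort(unique(unlist(lapply(nets, function(n) n$nodes))))
  outdeg <- sapply(nets, function(n) {
    d <- n$outdegree[genes]; d[is.na(d)] <- 0; d
  })
  rownames(outdeg) <- genes
  colnames(outdeg) <- names(per_tissue_tables) %||%
    paste0("tissue", seq_along(per_tissue_tables))

  hub_counts <- rowSums(outdeg >= min_outdegree)
  hub_sharing <- data.frame(gene = names(hub_counts)[hub_counts > 0],
                            n_tissues_as_hub = unname(hub_counts[hub_counts > 0]),
                            stringsAsFactors = FALSE)
  structure(list(pair_sharing = pair_sharing,
                 outdegree = outdeg,
                 sharing_histogram = table(counts[counts > 0]),
                 hub_sharing = hub_sharing),
            class = "tissue_sharing")
}

#' Differential correlation between two sample groups
#'
#' Tests whether the slope of \code{y} on \code{x} (adjusting for
#' covariates) differs between two groups (e.g. tumor versus
#' tumor-adjacent normal): a stacked linear model
#' \eqn{y \sim x + g + x\!\cdot\!g + Z} with a two-sided Wald test on the
#' \eqn{x\!\cdot\!g} coefficient. A Fisher-z contrast of the two groups'
#' residual correlations is available as an alternative.
#'
#' @param y,x numeric vectors over all samples of both groups.
#' @param Z covariate matrix (intercept column tolerated).
#' @param group_labels binary vector (2 levels), both groups >= 10
#'   samples.
#' @param mode \code{"wald"} (default) or \code{"fisher_z"}.
#' @return list with \code{p_value}, \code{estimate} (interaction
#'   coefficient or correlation difference), \code{mode}.
#' @export
differential_correlation <- function(y, x, Z, group_labels,
                                     mode = c("wald", "fisher_z")) {
  mode <- match.arg(mode)
  g <- as.integer(factor(group_labels)) - 1L
  if (length(unique(g)) != 2L)
    stop_splicecor("group_labels must have exactly 2 levels",
                   class = "splicecor_domain_error")
  if (min(table(g)) < 10)
    stop_splicecor("both groups need >= 10 samples",
                   class = "splicecor_size_error")
  for (gi in 0:1)
    if (stats::sd(x[g == gi]) == 0)
      stop_splicecor("a group has zero variance in x",
                     class = "splicecor_domain_error")
  Z <- as.matrix(Z)
  # drop constant columns; a single intercept is added back
  keep <- apply(Z, 2L, function(col) stats::sd(col) > 0)
  Zc <- Z[, keep, drop = FALSE]
  if (mode == "wald") {
    M <- cbind(1, x, g, xg = x * g, Zc)
    fit <- stats::lm.fit(M, y)
    dfres <- length(y) - ncol(M)
    s2 <- sum(fit$residuals^2) / dfres
    XtXinv <- chol2inv(chol(crossprod(M)))
    j <- 4L
    se <- sqrt(s2 * XtXinv[j, j])
    tval <- fit$coefficients[j] / se
    list(p_value = unname(2 * stats::pt(abs(tval), dfres, lower.tail = FALSE)),
         estimate = unname(fit$coefficients[j]), mode = mode)
  } else {
    cors <- ns <- numeric(2)
    for (gi in 0:1) {
      idx <- g == gi
      ry <- stats::lm.fit(cbind(1, Zc[idx, , drop = FALSE]), y[idx])$residuals
      rx <- stats::lm.fit(cbind(1, Zc[idx, , drop = FALSE]), x[idx])$residuals
      cors[gi + 1L] <- stats::cor(ry, rx)
      ns[gi + 1L] <- sum(idx)
    }
    z <- atanh(cors)
    se <- sqrt(sum(1 / (ns - 3 - ncol(Zc))))
    stat <- (z[2L] - z[1L]) / se
    list(p_value = 2 * stats::pnorm(abs(stat), lower.tail = FALSE),
         estimate = cors[2L] - cors[1L], mode = mode)
  }
}

#' Serialize a network
#'
#' Edge-list TSV (predictor, response, test_label, p, q_threshold) and
#' GraphML for interactive viewers.
#'
#' @param network \code{coexpr_network}.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  df <- network$edges[, c("predictor", "response", "test_label", "p")]
  df$q_threshold <- network$q
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Read pathway membership in GMT format
#'
#' @param path GMT file (pathway, description, gene ids, tab-separated).
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, "", 1L))
}
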