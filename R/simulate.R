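# Generative simulator: expression, intron-excision-ratio and covariate
# data drawn exactly under the mixed model
#
#   y = x b1 + diag(x) b2 + Z g + u + e,
#   b2 ~ N(0, s_Int^2 Sigma),  u ~ N(0, s_u^2 Sigma),  e ~ N(0, s_e^2 I),
#
# with Sigma built from the simulated IER block exactly as build_kernel
# does. IER compositions are Dirichlet draws (one intron cluster per
# gene), so per-sample ratios sum to 1 by construction.

#' Simulation configuration
#'
#' Named scenarios fix the signal parameters consistently:
#' \code{"null"} (no predictor effect at all), \code{"fixed_only"}
#' (overall slope, no interaction), \code{"interaction_only"} (random
#' slope only: the regime where only samples enriched for certain
#' isoforms show a correlation), \code{"mixed"} (both). Defaults are a
#' desk-scale bulk-tissue-like cohort: n = 300 samples, 5 introns per
#' gene, symmetric Dirichlet concentration 1 (strong inter-sample
#' composition heterogeneity), 3 covariates, unit residual variance,
#' random-intercept variance 0.3, slope 0.3 and interaction variance 0.5
#' where active.
#'
#' @param n_samples,k_introns,n_covariates cohort dimensions.
#' @param dirichlet_concentration per-intron symmetric Dirichlet
#'   parameter; smaller means more inter-sample IER heterogeneity.
#' @param beta1 fixed expression-expression slope.
#' @param sigma_Int2 random-slope (interaction) variance.
#' @param sigma_u2 random-intercept variance.
#' @param sigma_e2 residual variance.
#' @param gamma covariate effects (length \code{n_covariates + 1}
#'   including intercept); default intercept 0, others 0.5.
#' @param seed integer seed or NULL.
#' @param scenario preset name or \code{"custom"} (use the parameters as
#'   given).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 300, k_introns = 5,
                       dirichlet_concentration = 1,
                       beta1 = 0.3, sigma_Int2 = 0.5,
                       sigma_u2 = 0.3, sigma_e2 = 1,
                       gamma = NULL, n_covariates = 3, seed = NULL,
                       scenario = c("custom", "null", "fixed_only",
                                    "interaction_only", "mixed")) {
  scenario <- match.arg(scenario)
  sig <- switch(scenario,
                custom = list(beta1 = beta1, sigma_Int2 = sigma_Int2),
                null = list(beta1 = 0, sigma_Int2 = 0),
                fixed_only = list(beta1 = beta1, sigma_Int2 = 0),
                interaction_only = list(beta1 = 0, sigma_Int2 = sigma_Int2),
                mixed = list(beta1 = beta1, sigma_Int2 = sigma_Int2))
  if (scenario == "interaction_only" && sig$sigma_Int2 <= 0)
    sig$sigma_Int2 <- 0.5
  stopifnot(sigma_u2 >= 0, sigma_e2 > 0, sig$sigma_Int2 >= 0)
  if (is.null(gamma)) gamma <- c(0, rep(0.5, n_covariates))
  stopifnot(length(gamma) == n_covariates + 1)
  structure(list(n_samples = n_samples, k_introns = k_introns,
                 dirichlet_concentration = dirichlet_concentration,
                 beta1 = sig$beta1, sigma_Int2 = sig$sigma_Int2,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 gamma = gamma, n_covariates = n_covariates,
                 seed = seed, scenario = scenario),
            class = "sim_config")
}

rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

# N(0, s2 * Sigma) draw through the kernel's eigenpairs (supported on the
# kernel's range, which is where a rank-deficient Sigma puts all mass).
rmvn_kernel <- function(kernel, s2) {
  if (s2 <= 0) return(numeric(kernel$n))
  z <- stats::rnorm(length(kernel$evalues))
  drop(kernel$evectors %*% (sqrt(s2 * kernel$evalues) * z))
}

sim_ier_block <- function(config, gene_index, samples) {
  k <- config$k_introns
  comp <- rdirichlet_mat(length(samples),
                         rep(config$dirichlet_concentration, k))
  blk <- t(comp)
  rownames(blk) <- sprintf("chr1:%d:%d:clu_%d",
                           10000L * gene_index + 100L * seq_len(k),
                           10000L * gene_index + 100L * seq_len(k) + 50L,
                           gene_index)
  colnames(blk) <- samples
  blk
}

#' Simulate one predictor-response gene pair under the generative model
#'
#' Draws the predictor gene's IER block (one intron cluster, Dirichlet
#' compositions per sample), builds its splicing kernel exactly as
#' \code{\link{build_kernel}} does, draws the random slope and intercept
#' with covariance proportional to that kernel, and assembles the
#' response. Degenerate Dirichlet draws (kernel construction fails) are
#' resampled up to 10 times with a message.
#'
#' @param config \code{sim_config}.
#' @param x_confounded_with_ier if TRUE, the predictor's expression is
#'   shifted by the first intron's (centered) IER so that predictor and
#'   splicing composition are correlated — exercises confounding-
#'   reduction analyses.
#' @return list with \code{y}, \code{x}, \code{Z}, \code{ier_block}
#'   (intron x sample, rownames chrom:start:end:cluster), \code{kernel},
#'   and \code{truth} (every latent draw plus the config).
#' @export
simulate_pair <- function(config, x_confounded_with_ier = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))

  kernel <- NULL
  for (try in 1:10) {
    ier_block <- sim_ier_block(config, 1L, samples)
    kernel <- tryCatch(build_kernel(ier_block), error = function(e) NULL)
    if (!is.null(kernel)) break
    message("degenerate Dirichlet draw; resampling (attempt ", try, ")")
  }
  if (is.null(kernel))
    stop_splicecor("could not build a valid kernel in 10 attempts",
                   class = "splicecor_kernel_error")

  x <- stats::rnorm(n)
  if (x_confounded_with_ier)
    x <- x + 2 * scale(ier_block[1L, ])[, 1L]
  Z <- cbind(1, matrix(stats::rnorm(n * config$n_covariates), n,
                       dimnames = list(NULL,
                                       paste0("C", seq_len(config$n_covariates)))))
  colnames(Z)[1L] <- "(Intercept)"
  beta2 <- rmvn_kernel(kernel, config$sigma_Int2)
  u <- rmvn_kernel(kernel, config$sigma_u2)
  eps <- stats::rnorm(n, sd = sqrt(config$sigma_e2))
  y <- x * config$beta1 + x * beta2 + drop(Z %*% config$gamma) + u + eps
  names(y) <- names(x) <- rownames(Z) <- colnames(ier_block)

  list(y = y, x = x, Z = Z, ier_block = ier_block, kernel = kernel,
       truth = list(beta2 = beta2, u = u, eps = eps, config = config))
}

# Shared cohort generator for a prescribed truth table. Signal pairs are
# constrained to predictor index < response index, so the effects form a
# DAG and can be accumulated through the *observed* predictor
# expression, exactly as the model sees it.
gen_cohort <- function(config, n_genes, truth, dir = NULL) {
  n <- config$n_samples
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n))

  ier_rows <- vector("list", n_genes)
  gene_map <- character(0)
  kernels <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    blk <- sim_ier_block(config, gi, samples)
    ier_rows[[gi]] <- blk
    gene_map <- c(gene_map,
                  stats::setNames(rep(genes[gi], nrow(blk)), rownames(blk)))
    kernels[[gi]] <- build_kernel(blk)
  }
  names(kernels) <- genes
  ier_values <- do.call(rbind, ier_rows)

  Z <- cbind(1, matrix(stats::rnorm(n * config$n_covariates), n))
  colnames(Z) <- c("(Intercept)", paste0("C", seq_len(config$n_covariates)))
  rownames(Z) <- samples
  gam <- drop(Z %*% config$gamma)

  expr <- matrix(0, n_genes, n, dimnames = list(genes, samples))
  for (gi in seq_len(n_genes)) {
    g <- genes[gi]
    y <- stats::rnorm(n, sd = sqrt(config$sigma_e2)) + gam +
      rmvn_kernel(kernels[[gi]], config$sigma_u2)
    rows <- truth[truth$response == g & truth$effect != "none", ]
    if (nrow(rows)) for (ri in seq_len(nrow(rows))) {
      p <- rows$predictor[ri]
      xg <- expr[p, ] - mean(expr[p, ])   # observed, centered predictor TE
      b2 <- rmvn_kernel(kernels[[p]], rows$sigma_Int2[ri])
      y <- y + xg * rows$beta1[ri] + xg * b2
    }
    expr[gi, ] <- y
  }

  ier <- structure(list(values = ier_values, gene_map = gene_map,
                        clusters = stats::setNames(
                          sub("^.*:", "", rownames(ier_values)),
                          rownames(ier_values))),
                   class = "ier_table")

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(expression = file.path(dir, "expression.tsv"),
               ier = file.path(dir, "ier.tsv"),
               gene_map = file.path(dir, "gene_map.tsv"),
               covariates = file.path(dir, "covariates.tsv"),
               truth = file.path(dir, "truth.tsv"),
               manifest = file.path(dir, "manifest.json"))
    write_expression(expr, paths[["expression"]])
    utils::write.table(data.frame(intron = rownames(ier_values), ier_values,
                                  check.names = FALSE),
                       paths[["ier"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(names(gene_map), gene_map),
                       paths[["gene_map"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(sample_id = samples,
                                  Z[, -1L, drop = FALSE], check.names = FALSE),
                       paths[["covariates"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, scenario = config$scenario,
           n_samples = n, n_genes = n_genes, k_introns = config$k_introns,
           package_version = as.character(utils::packageVersion("splicecor"))),
      paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  }
  list(expr = expr, ier = ier, cov = Z, truth = truth, kernels = kernels,
       paths = paths)
}

make_truth <- function(config, n_genes, active_keys) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  truth <- expand.grid(predictor = genes, response = genes,
                       stringsAsFactors = FALSE)
  truth <- truth[truth$predictor != truth$response, ]
  rownames(truth) <- NULL
  key <- paste(truth$predictor, truth$response)
  on_ <- key %in% active_keys
  use_fixed <- config$beta1 != 0
  use_int <- config$sigma_Int2 != 0
  truth$beta1 <- ifelse(on_ & use_fixed, config$beta1, 0)
  truth$sigma_Int2 <- ifelse(on_ & use_int, config$sigma_Int2, 0)
  truth$effect <- ifelse(on_,
                         if (use_fixed && use_int) "mixed"
                         else if (use_int) "interaction"
                         else if (use_fixed) "fixed" else "none",
                         "none")
  truth
}

sample_signal_pairs <- function(n_genes, n_signal) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  # forward pairs only (predictor index < response index): effects form
  # a DAG, so signal flows through observed expression
  fwd <- expand.grid(pi_ = seq_len(n_genes), ri_ = seq_len(n_genes))
  fwd <- fwd[fwd$pi_ < fwd$ri_, ]
  take <- fwd[sample(nrow(fwd), min(n_signal, nrow(fwd))), ]
  paste(genes[take$pi_], genes[take$ri_])
}

#' Simulate a multi-gene cohort and write its input file set
#'
#' Generates a gene x sample expression matrix, a stacked IER table (one
#' intron cluster per gene) with its gene map, a covariate table, and a
#' truth table of which directed pairs carry which effect (type per the
#' config's scenario). Signal pairs are drawn among forward-ordered gene
#' pairs so effects form a DAG and accumulate through the observed
#' predictor expression. Files are written in exactly the formats
#' \code{\link{load_expression}}, \code{\link{load_ier}} and
#' \code{\link{load_covariates}} read, plus a JSON manifest recording
#' seed and parameters.
#'
#' @param config \code{sim_config}.
#' @param n_genes number of genes (>= 4).
#' @param signal_fraction fraction of all directed pairs carrying signal.
#' @param dir output directory (created); NULL to skip writing.
#' @return list with in-memory \code{expr}, \code{ier} (ier_table),
#'   \code{cov}, \code{truth} (data.frame over all directed pairs),
#'   \code{kernels}, \code{paths} (named vector if written).
#' @export
simulate_cohort <- function(config, n_genes = 20, signal_fraction = 0.1,
                            dir = NULL) {
  stopifnot(n_genes >= 4)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pairs <- n_genes * (n_genes - 1)
  n_signal <- ceiling(signal_fraction * n_pairs)
  active <- sample_signal_pairs(n_genes, n_signal)
  truth <- make_truth(config, n_genes, active)
  gen_cohort(config, n_genes, truth, dir)
}

#' Simulate a multi-tissue cohort family
#'
#' Shared gene set across tissues; signal pairs are split into a shared
#' set (active in every tissue) and tissue-specific sets (active in
#' exactly one), per \code{tissue_specific_fraction}. Each tissue gets
#' its own samples, IER draws, random effects and noise.
#'
#' @param config \code{sim_config}.
#' @param n_tissues number of tissues (>= 2).
#' @param tissue_specific_fraction fraction of signal pairs specific to
#'   a single tissue (the rest are shared by all).
#' @param n_genes,signal_fraction as in \code{\link{simulate_cohort}}.
#' @param dir optional output directory; one subdirectory per tissue.
#' @return named list of per-tissue cohorts (as from
#'   \code{\link{simulate_cohort}}), with attribute \code{assignment}
#'   giving each signal pair's tissue scope.
#' @export
simulate_multitissue <- function(config, n_tissues = 3,
                                 tissue_specific_fraction = 0.7,
                                 n_genes = 20, signal_fraction = 0.1,
                                 dir = NULL) {
  stopifnot(n_tissues >= 2)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pairs <- n_genes * (n_genes - 1)
  n_signal <- ceiling(signal_fraction * n_pairs)
  active <- sample_signal_pairs(n_genes, n_signal)
  tissues <- paste0("tissue", seq_len(n_tissues))
  n_specific <- round(tissue_specific_fraction * length(active))
  scope <- rep("shared", length(active))
  if (n_specific > 0)
    scope[seq_len(n_specific)] <- sample(tissues, n_specific, replace = TRUE)
  assignment <- data.frame(pair = active, scope = scope,
                           stringsAsFactors = FALSE)

  out <- vector("list", n_tissues)
  names(out) <- tissues
  for (ti in seq_len(n_tissues)) {
    keys <- active[scope %in% c("shared", tissues[ti])]
    truth <- make_truth(config, n_genes, keys)
    out[[ti]] <- gen_cohort(config, n_genes, truth,
                            dir = if (is.null(dir)) NULL
                                  else file.path(dir, tissues[ti]))
  }
  attr(out, "assignment") <- assignment
  out
}
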