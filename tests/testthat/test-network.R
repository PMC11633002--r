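make_pair_fixture <- function() {
  genes <- paste0("g", 1:5)
  tab <- expand.grid(predictor = genes, response = genes,
                     stringsAsFactors = FALSE)
  tab <- tab[tab$predictor != tab$response, ]
  tab$p_interaction <- 0.9
  # g1 -> {g2, g3, g4}; g5 -> g1 strongly significant
  tab$p_interaction[tab$predictor == "g1" &
                      tab$response %in% c("g2", "g3", "g4")] <- 1e-8
  tab$p_interaction[tab$predictor == "g5" & tab$response == "g1"] <- 1e-8
  tab
}

test_that("network edges are exactly the stratified-FDR-significant pairs", {
  tab <- make_pair_fixture()
  net <- build_network(tab, "interaction", q = 0.05)
  got <- sort(paste(net$edges$predictor, net$edges$response))
  expect_identical(got, sort(c("g1 g2", "g1 g3", "g1 g4", "g5 g1")))
  expect_equal(sum(net$outdegree), nrow(net$edges))   # handshake identity
  expect_equal(sum(net$indegree), nrow(net$edges))
  # no significant rows -> empty edge set
  tab$p_interaction[] <- 0.9
  expect_equal(nrow(build_network(tab, "interaction")$edges), 0L)
  expect_error(build_network(tab, "joint"),
               class = "splicecor_missing_column")
})

test_that("networks rebuilt from a serialized table are identical", {
  tab <- make_pair_fixture()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(tab, path)
  net1 <- build_network(tab, "interaction")
  net2 <- build_network(read_pair_table(path), "interaction")
  expect_identical(net1$edges$predictor, net2$edges$predictor)
  expect_identical(net1$edges$response, net2$edges$response)
  expect_equal(net1$outdegree, net2$outdegree)
})

test_that("hub detection thresholds outdegree with deterministic ordering", {
  # star graph: center -> 6 targets
  genes <- c("hub", paste0("t", 1:6))
  tab <- expand.grid(predictor = genes, response = genes,
                     stringsAsFactors = FALSE)
  tab <- tab[tab$predictor != tab$response, ]
  tab$p_interaction <- ifelse(tab$predictor == "hub", 1e-9, 0.8)
  net <- build_network(tab, "interaction")
  hubs <- detect_hubs(net, 5)
  expect_identical(hubs$gene, "hub")
  expect_identical(hubs$outdegree, 6L)
  expect_equal(nrow(detect_hubs(net, 7)), 0L)

  # a twelve-target hub is reported with its outdegree
  genes <- c("big", paste0("t", 1:12))
  tab <- expand.grid(predictor = genes, response = genes,
                     stringsAsFactors = FALSE)
  tab <- tab[tab$predictor != tab$response, ]
  tab$p_interaction <- ifelse(tab$predictor == "big", 1e-9, 0.8)
  hubs <- detect_hubs(build_network(tab, "interaction"), 5)
  expect_identical(hubs$gene[1], "big")
  expect_identical(hubs$outdegree[1], 12L)

  # relabeling nodes relabels hubs and nothing else
  tab2 <- tab
  tab2$predictor <- toupper(tab2$predictor)
  tab2$response <- toupper(tab2$response)
  hubs2 <- detect_hubs(build_network(tab2, "interaction"), 5)
  expect_identical(hubs2$gene, toupper(hubs$gene))
  expect_identical(hubs2$outdegree, hubs$outdegree)
})

test_that("pathway-size adjustment divides total outdegree by pathway size", {
  tab <- make_pair_fixture()
  net <- build_network(tab, "interaction")
  expect_equal(size_adjusted_outdegree(net, paste0("g", 1:5)), 4 / 5)
  # empty edge set -> 0
  tab$p_interaction[] <- 0.9
  net0 <- build_network(tab, "interaction")
  expect_equal(size_adjusted_outdegree(net0, paste0("g", 1:5)), 0)
  expect_error(size_adjusted_outdegree(net, character(0)),
               class = "splicecor_domain_error")
  # same edge density in pathways of different sizes -> equal adjusted means
  mk <- function(genes, per_gene_edges) {
    tb <- expand.grid(predictor = genes, response = genes,
                      stringsAsFactors = FALSE)
    tb <- tb[tb$predictor != tb$response, ]
    tb$p_interaction <- 0.9
    for (g in genes) {
      tgt <- setdiff(genes, g)[seq_len(per_gene_edges)]
      tb$p_interaction[tb$predictor == g & tb$response %in% tgt] <- 1e-9
    }
    build_network(tb, "interaction")
  }
  netA <- mk(paste0("a", 1:4), 2)
  netB <- mk(paste0("b", 1:8), 2)
  expect_equal(size_adjusted_outdegree(netA, paste0("a", 1:4)),
               size_adjusted_outdegree(netB, paste0("b", 1:8)))
})

test_that("tissue sharing counts significant tissues per pair and per hub", {
  tab <- make_pair_fixture()
  tab2 <- tab
  tab2$p_interaction[tab2$predictor == "g5"] <- 0.9  # g5->g1 only in tissue 1
  tabs <- list(t1 = tab, t2 = tab2, t3 = tab2)
  ts <- tissue_sharing(tabs, "interaction", q = 0.05, min_outdegree = 3)
  sh <- ts$pair_sharing
  expect_equal(sh$n_tissues[sh$predictor == "g5" & sh$response == "g1"], 1)
  expect_equal(sh$n_tissues[sh$predictor == "g1" & sh$response == "g2"], 3)
  expect_equal(dim(ts$outdegree), c(5L, 3L))
  expect_equal(ts$hub_sharing$gene, "g1")
  expect_equal(ts$hub_sharing$n_tissues_as_hub, 3)
  # identical tables across tissues -> all significant pairs shared by all
  ts2 <- tissue_sharing(list(a = tab, b = tab, c = tab), "interaction")
  expect_true(all(ts2$pair_sharing$n_tissues %in% c(0, 3)))
  # key mismatch detected
  bad <- tab[-1, ]
  expect_error(tissue_sharing(list(a = tab, b = bad), "interaction"),
               class = "splicecor_key_mismatch")
})

test_that("differential correlation calibrates, detects, and nulls out on copies", {
  set.seed(11)
  pnull <- replicate(400, {
    n <- 60; x <- rnorm(2 * n); g <- rep(0:1, each = n); Z <- cbind(rnorm(2 * n))
    y <- 0.5 * x + 0.3 * Z[, 1] + rnorm(2 * n)
    differential_correlation(y, x, Z, g)$p_value
  })
  expect_gt(mean(pnull <= 0.05), 0.03)
  expect_lt(mean(pnull <= 0.05), 0.07)

  ppow <- replicate(60, {
    n <- 100; x <- rnorm(2 * n); g <- rep(0:1, each = n); Z <- cbind(rnorm(2 * n))
    y <- ifelse(g == 0, x, -x) + 0.3 * Z[, 1] + rnorm(2 * n, sd = 0.5)
    differential_correlation(y, x, Z, g)$p_value
  })
  expect_gte(mean(ppow < 1e-6), 0.95)

  # two copies of the same samples: interaction coefficient exactly 0
  n <- 30; x <- rnorm(n); Z <- cbind(rnorm(n)); y <- x + rnorm(n)
  dc <- differential_correlation(c(y, y), c(x, x), rbind(Z, Z),
                                 rep(0:1, each = n))
  expect_equal(dc$estimate, 0, tolerance = 1e-10)

  expect_error(differential_correlation(c(y, y), c(x, rep(1, n)),
                                        rbind(Z, Z), rep(0:1, each = n)),
               class = "splicecor_domain_error")
})

test_that("network serialization writes edge lists and GraphML", {
  tab <- make_pair_fixture()
  net <- build_network(tab, "interaction")
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, ep)
  back <- utils::read.delim(ep)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(all(c("predictor", "response", "test_label", "p",
                    "q_threshold") %in% names(back)))
  write_network_graphml(net, gp)
  expect_true(file.size(gp) > 0)
})
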