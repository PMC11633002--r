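#!/usr/bin/env Rscript
# Step 4: directed co-expression networks at the 5% stratified FDR for
# each test; hub genes (outdegree >= 5), pathway-size-adjusted mean
# outdegrees, and the tissue-sharing profile of interaction effects
# across the simulated tissues.

suppressMessages(library(splicecor))
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

tab <- read_pair_table("results/pair_results.tsv")
for (test in c("interaction", "joint", "correlation")) {
  net <- build_network(tab, test, q = 0.05)
  write_edge_list(net, sprintf("results/networks/%s_edges.tsv", test))
  write_network_graphml(net, sprintf("results/networks/%s.graphml", test))
  hubs <- detect_hubs(net, min_outdegree = 5)
  adj <- size_adjusted_outdegree(net, net$nodes)
  message(sprintf("%-11s network: %d edges, %d hub(s), %.2f mean outdegree/gene",
                  test, nrow(net$edges), nrow(hubs), adj))
  if (nrow(hubs))
    message("  hubs: ", paste(sprintf("%s(%d)", hubs$gene, hubs$outdegree),
                              collapse = ", "))
}

tissue_tabs <- lapply(list.dirs("results/sim/tissues", recursive = FALSE),
                      function(d) {
                        f <- file.path(d, "pair_results.tsv")
                        if (file.exists(f)) read_pair_table(f) else NULL
                      })
tissue_tabs <- Filter(Negate(is.null), tissue_tabs)
if (length(tissue_tabs) >= 2) {
  names(tissue_tabs) <- paste0("tissue", seq_along(tissue_tabs))
  for (test in c("interaction", "correlation")) {
    ts <- tissue_sharing(tissue_tabs, test, q = 0.05)
    tabulated <- table(factor(
      ts$pair_sharing$n_tissues[ts$pair_sharing$n_tissues > 0],
      levels = seq_along(tissue_tabs)))
    message(sprintf("%-11s sharing across %d tissues: %s",
                    test, length(tissue_tabs),
                    paste(sprintf("%s tissue(s): %d", names(tabulated),
                                  tabulated), collapse = " | ")))
    utils::write.table(ts$pair_sharing,
                       sprintf("results/networks/sharing_%s.tsv", test),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
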