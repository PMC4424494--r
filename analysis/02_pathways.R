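#!/usr/bin/env Rscript
# Stage 2 — enumerate source-to-target signalling routes.
#
# Over the network induced by the published pathway strings (UV triggers
# through keratinocyte cascades to melanocyte end processes), we compute
# canonical shortest routes from every trigger to every end process, plus
# the all-tied variant, and extract the S2T sub-network.

suppressPackageStartupMessages(library(pigmentnet))
dir.create("results", showWarnings = FALSE)

net <- printed_paths_fixture()
print(net)

canonical <- source_target_paths(net, mode = "canonical_per_pair")
tied <- source_target_paths(net, mode = "all_tied")
cat(sprintf("connected trigger/end-process pairs: %d\n",
            canonical$connected_pairs))
cat(sprintf("canonical routes: %d; with tied alternates: %d\n",
            canonical$path_count, tied$path_count))

write_path_set(canonical, "results/s2t_paths.tsv", "tsv")
write_path_set(canonical, "results/s2t_paths.json", "json")

sub <- extract_s2t_subnetwork(net, canonical)
write_network(sub, "results/s2t_subnetwork.tsv", "edge-table")
cat(sprintf("S2T sub-network: %d nodes, %d edges; weakly connected: %s\n",
            network_node_count(sub), network_edge_count(sub),
            sub$weakly_connected))

freq <- sort(canonical$frequency, decreasing = TRUE)
inner <- freq[!(names(freq) %in% c(net$sources, net$targets))]
cat("most frequent route mediators:\n")
print(head(inner, 8))

cat("\nwrote results/s2t_paths.{tsv,json}, s2t_subnetwork.tsv\n")
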