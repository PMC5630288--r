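#!/usr/bin/env Rscript
# Inspect the over-representation results of the pipeline run: the global
# DEG enrichment (did the planted terms surface?) and the per-module tables,
# then summarise the findings to results/enrichment_summary.tsv.

suppressPackageStartupMessages(library(netora))

truth <- jsonlite::read_json("results/sim/ground_truth.json")
planted <- unlist(truth$enriched_terms)

glob <- utils::read.table("results/run/enrichment_global.tsv", header = TRUE,
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
sig <- glob[as.numeric(glob$p.adjust) < 0.05, ]
cat(nrow(glob), "terms tested globally;", nrow(sig),
    "significant at adjusted p < 0.05\n")
cat("planted terms recovered:",
    sum(planted %in% sig$term), "of", length(planted), "\n")
print(glob[glob$term %in% planted,
           c("term", "GeneRatio", "BgRatio", "pvalue", "p.adjust", "qvalue")],
      row.names = FALSE)

mod_files <- Sys.glob("results/run/enrichment_module*.tsv")
for (f in mod_files) {
  tab <- utils::read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  n_sig <- sum(as.numeric(tab$p.adjust) < 0.05)
  cat(basename(f), ":", nrow(tab), "terms,", n_sig, "significant\n")
}

utils::write.table(
  data.frame(term = glob$term,
             p_adjust = as.numeric(glob$p.adjust),
             planted = glob$term %in% planted,
             significant = as.numeric(glob$p.adjust) < 0.05),
  "results/enrichment_summary.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("wrote results/enrichment_summary.tsv\n")
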