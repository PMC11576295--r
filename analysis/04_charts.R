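#!/usr/bin/env Rscript
# Radar charts: one item-level map per instrument and the nested
# scale-level map with instrument circles, facet markers and latent
# correlations. Deterministic SVG output under results/charts/.

library(ipvkit)

res <- if (file.exists("results/nested_ipv.rds")) {
  readRDS("results/nested_ipv.rds")
} else {
  reg <- default_registry()
  dat <- validate_responses(read.csv("results/responses.csv",
                                     check.names = FALSE), reg)
  run_nested_ipv(dat, reg)
}
dir.create("results/charts", showWarnings = FALSE, recursive = TRUE)

for (inst in unique(res$item_table$instrument)) {
  sub <- res$item_table[res$item_table$instrument == inst, ]
  ly <- layout_item_chart(sub)
  path <- file.path("results/charts", paste0("items_", inst, ".svg"))
  render_chart(ly, path)
  cat("wrote", path, "\n")
}

ly <- layout_nested_chart(res)
render_chart(ly, "results/charts/nested_model.svg")
cat("wrote results/charts/nested_model.svg\n")
cat("instrument circle offsets (chart units):\n")
print(ly$instruments[, c("pool_id", "aggregate_cd", "x", "y")],
      digits = 3, row.names = FALSE)
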