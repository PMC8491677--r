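#!/usr/bin/env Rscript
# Generate the synthetic study: a 162-vertex icosphere with an 81-vertex
# seed region, three planted latent connectivity axes, network labels,
# autocorrelated scalar maps, depth profiles, and two 75-subject cohorts
# (discovery + replication) sharing the population anatomy.
source("analysis/00_common.R")

pop <- run$population
dir.create("results/bundle", showWarnings = FALSE)
write_gifti_surface(pop$mesh, "results/bundle/mesh.surf.gii")
write_matrix_tsv(pop$latent$coords, "results/bundle/latent_axes.tsv")
write.table(data.frame(vertex = which(pop$mesh$roi_mask),
                       label = pop$labels),
            "results/bundle/labels.tsv", sep = "\t", row.names = FALSE)
for (nm in names(pop$maps)) {
  write_gifti_data(pop$maps[[nm]], sprintf("results/bundle/map_%s.func.gii", nm))
}
write_matrix_tsv(pop$profiles$intensities, "results/bundle/profiles.tsv")
write_endpoints(run$discovery$endpoints$endpoints,
                "results/bundle/endpoints.tsv")

cat(sprintf(paste0(
  "simulated: %d vertices (%d in ROI), %d networks (sizes %s),\n",
  "  %d + %d subject connectomes (%d targets), %d x %d depth profiles\n"),
  nrow(pop$mesh$vertices), sum(pop$mesh$roi_mask), nlevels(pop$labels),
  paste(table(pop$labels), collapse = "/"),
  length(run$discovery$connectomes), length(run$replication$connectomes),
  ncol(run$discovery$connectomes[[1]]$weights),
  nrow(pop$profiles$intensities), pop$profiles$depth_count))
cat("Moran's I of latent axis 1:",
    round(morans_i(pop$latent$coords[, 1],
                   build_adjacency(pop$mesh, "binary", roi_only = TRUE)), 3),
    "(smooth, as planted)\n")
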