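#!/usr/bin/env Rscript
# Build the synthetic study data: control, pre-mitotic (6 h) and
# post-endomitotic MLN (30 h) nuclei with DAPI, marker and replication-domain
# channels, plus halo images, degradation traces and Hi-C/Repli-Seq data.
# Everything downstream (02-07) reads from results/data/.

suppressPackageStartupMessages(library(nucarch))
set.seed(1)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

conditions <- data.frame(
  condition = c("control", "6h", "30h"),
  n_nuclei = c(8, 8, 8),
  n_lobes = c(1, 1, 3),          # MLN after endomitosis
  nucleus_scale = c(0.9, 0.9, 0.9 * 2^(1/3)),  # 30 h nuclei at ~2x volume (4n)
  rd_objects = c(20, 26, 38),    # more, larger, more heterogeneous RDs
  rd_volume = c(0.025, 0.032, 0.038),
  rd_cv = c(0.25, 0.4, 0.55))

manifest <- NULL
for (i in seq_len(nrow(conditions))) {
  cd <- conditions[i, ]
  for (j in seq_len(cd$n_nuclei)) {
    s <- i * 1000 + j
    w_sc35 <- c(8, 2, 1, 0, 0, 0, 0)            # splicing-speckle-like, IC
    w_k27 <- c(0.2, 0.5, 1, 2.5, 2.5, 1, 0.5)   # facultative heterochromatin
    sc <- suppressWarnings(generate_nucleus_scene(nucleus_scene_spec(
      grid_shape = c(96, 96, 24), n_lobes = cd$n_lobes,
      nucleus_scale = cd$nucleus_scale, seed = s,
      markers = list(list(name = "SC35", weights = w_sc35, density = 0.04),
                     list(name = "H3K27me3", weights = w_k27, density = 0.06)),
      rd = list(pattern = "early", n_objects = cd$rd_objects,
                mean_volume = cd$rd_volume, cv = cd$rd_cv, separation = 0.45))))
    stem <- file.path(out, sprintf("%s_nucleus%02d", cd$condition, j))
    for (ch in names(sc$channels))
      write_voxel_grid(sc$channels[[ch]], sprintf("%s_%s.tif", stem, ch))
    write_scene_truth(sc$truth, paste0(stem, "_truth.json"))
    manifest <- rbind(manifest, data.frame(condition = cd$condition, nucleus = j,
                                           seed = s, stem = stem))
  }
}
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
cat(sprintf("wrote %d nuclei across %d conditions\n", nrow(manifest),
            nrow(conditions)))

# degradation traces: 300 cells, ~4% escape degradation
tr <- generate_decay_traces(300, half_life = 35, nonresponder_fraction = 0.04,
                            noise_sd = 3, seed = 42)
write_traces(tr$traces, file.path(out, "rad21_traces.csv"))
write.csv(tr$truth, file.path(out, "rad21_traces_truth.csv"), row.names = FALSE)
cat("wrote degradation traces for 300 cells\n")

# halo images: 20 control + 20 cohesin-depleted cells (larger, variable halos)
halo_manifest <- NULL
for (cond in c("control", "auxin")) {
  scale <- if (cond == "control") 1.0 else 1.5
  for (j in 1:20) {
    s <- if (cond == "control") 5000 + j else 6000 + j
    set.seed(s)
    core <- rlnorm(1, log(2.6), 0.12)
    halo <- core + scale * rlnorm(1, log(1.7), 0.15)
    h <- generate_halo_scene(core, halo, pixel_size = 0.1, noise_sd = 0.02, seed = s)
    f <- file.path(out, sprintf("halo_%s_%02d.tif", cond, j))
    write_voxel_grid(h$image, f)
    halo_manifest <- rbind(halo_manifest,
                           data.frame(condition = cond, cell = j, file = f,
                                      true_R = h$truth$R))
  }
}
write.csv(halo_manifest, file.path(out, "halo_manifest.csv"), row.names = FALSE)
cat("wrote 40 halo images\n")

# Hi-C + Repli-Seq: pre/post cohesin degradation with a strengthening cluster
gd <- generate_contact_data(genome_spec(seed = 77))
write_contacts(gd$pre, file.path(out, "contacts_pre.triplet"))
write_contacts(gd$post, file.path(out, "contacts_post.triplet"))
for (tk in c(nucarch:::histone_marks, "early", "late"))
  write_bedgraph(gd$tracks, gd$tracks[[tk]],
                 file.path(out, sprintf("track_%s.bedgraph", tk)))
write_bedpe(gd$loops, gd$pre$resolution, file.path(out, "loops.bedpe"))
jsonlite::write_json(gd$truth, file.path(out, "genome_truth.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote contact matrices, tracks and loops\n")
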