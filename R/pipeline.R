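#' Run the full tissue-composition pipeline
#'
#' Executes the stages in order for every ROI in the manifest -- Gaussian
#' smoothing, Cloude physicality filtering, M11-normalized element features,
#' polarization basis parameters, per-ROI standardization and super-pixel
#' compression -- then pools the super-pixels, fits the Canberra UMAP atlas,
#' trims low-density bins, clusters by single linkage, spreads labels,
#' projects labels back to per-ROI masks, and tabulates cluster area
#' proportions. Every artifact (config, embedding, labels, linkage tree,
#' marker table, masks) is written under `out_dir`; rerunning with the same
#' config and inputs reproduces the outputs.
#'
#' @param manifest a manifest data.frame (see [read_manifest()]) or the path
#'   to a manifest CSV.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param verbose print stage progress.
#' @return list with `atlas` (clustered `atlas_model`), `sps`, `features`,
#'   `pbps` (per-ROI lists), `masks`, `markers` (marker table), `report`
#'   (when contrasts configured), `meta`, and `config`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) stopf("no ROIs")
  say <- function(...) if (verbose) message(sprintf(...))
  cfg <- config
  n <- nrow(manifest)
  sps <- features <- pbps <- vector("list", n)
  for (i in seq_len(n)) {
    say("[preprocess] %s (%d/%d)", manifest$roi_id[i], i, n)
    img <- read_mueller(manifest$path[i])
    img$roi_id <- manifest$roi_id[i]
    img$patient_id <- manifest$patient_id[i]
    img$group <- manifest$group[i]
    img <- gaussian_smooth(img, cfg$preprocessing$sigma_px)
    if (isTRUE(cfg$preprocessing$cloude))
      img <- cloude_filter(img, cfg$preprocessing$eig_floor)
    feat <- normalized_elements(img)
    pb <- pbp_image(img, cfg$pbp$selection %||% pbp_default_set())
    feat$mask <- feat$mask & pb$mask
    feat <- standardize_features(feat)
    sp <- build_superpixels(feat, k = cfg$superpixel$k,
                            seed = cfg$superpixel$seed + i,
                            batch_size = cfg$superpixel$batch_size,
                            n_init = cfg$superpixel$n_init,
                            max_iter = cfg$superpixel$max_iter,
                            tol = cfg$superpixel$tol,
                            reassignment_ratio = cfg$superpixel$reassignment_ratio)
    sps[[i]] <- superpixel_pbp_means(sp, pb)
    features[[i]] <- feat
    pbps[[i]] <- pb
  }
  say("[atlas] embedding %d super-pixels", sum(vapply(sps, `[[`, 0L, "k")))
  pooled <- pool_superpixels(sps, meta = manifest[c("roi_id", "patient_id",
                                                   "group")])
  # orientation angles (fast axis theta, anisotropy orientation alpha) are
  # circular and sample-orientation dependent: they are excluded from the
  # embedding features unless an explicit selection is configured
  feat_sel <- cfg$atlas$features %||%
    setdiff(colnames(pooled$X), c("theta", "alpha"))
  missing_feat <- setdiff(feat_sel, colnames(pooled$X))
  if (length(missing_feat))
    stopf("atlas features not present in the PBP set: %s",
          paste(missing_feat, collapse = ", "))
  atlas <- fit_atlas(pooled$X[, feat_sel, drop = FALSE], keys = pooled$keys,
                     n_neighbors = cfg$atlas$n_neighbors,
                     metric = cfg$atlas$metric, seed = cfg$atlas$seed,
                     min_dist = cfg$atlas$min_dist,
                     n_epochs = cfg$atlas$n_epochs)
  say("[cluster] trimming and single linkage")
  atlas <- atlas_cluster(atlas, nx = cfg$atlas$nx, ny = cfg$atlas$ny,
                         cutoff = cfg$atlas$cutoff,
                         n_clusters = cfg$atlas$n_clusters,
                         spread_k = cfg$atlas$spread_k,
                         min_frac = cfg$atlas$min_frac)
  say("[markers] %d principal clusters", atlas$n_principal)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- atlas$source_keys$roi_id == manifest$roi_id[i]
    masks[[i]] <- project_labels_to_mask(sps[[i]], atlas$labels[sel])
  }
  markers <- marker_table(masks, manifest)
  report <- if (length(cfg$markers$contrasts))
    marker_report(markers, cfg$markers$contrasts) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(cfg, file.path(out_dir, "config.json"))
    emb <- data.frame(atlas$source_keys,
                      x = atlas$embedding[, 1], y = atlas$embedding[, 2],
                      retained = atlas$retained_mask, label = atlas$labels)
    write.csv(emb, file.path(out_dir, "embedding.csv"), row.names = FALSE)
    link <- data.frame(node_a = atlas$linkage$merge[, 1],
                       node_b = atlas$linkage$merge[, 2],
                       distance = atlas$linkage$height)
    write.csv(link, file.path(out_dir, "linkage.csv"), row.names = FALSE)
    write.csv(markers, file.path(out_dir, "markers.csv"), row.names = FALSE)
    if (!is.null(report)) {
      write.csv(report$percentiles, file.path(out_dir, "report_percentiles.csv"),
                row.names = FALSE)
      write.csv(report$tests, file.path(out_dir, "report_tests.csv"),
                row.names = FALSE)
    }
    saveRDS(masks, file.path(out_dir, "label_masks.rds"))
  }
  list(atlas = atlas, sps = sps, features = features, pbps = pbps,
       masks = masks, markers = markers, report = report,
       meta = manifest, config = cfg)
}
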