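#' Pipeline configuration
#'
#' Collects every stage parameter with validation; unknown keys raise an
#' error before any computation.  The configuration round-trips through
#' [yaml::write_yaml()] / [yaml::read_yaml()] unchanged.
#'
#' @param ... named overrides of the defaults listed below.
#' @return object of class `pipeline_config` (a validated named list).
#' @section Fields:
#' `mode` ("synthetic" or "directory"), `input_dir`, `out_dir`, `seed`,
#' `n_per_class`, `image_size`, `background_amplitude`, `noise_sd`,
#' `rolling_ball_radius`, `rolling_ball_element`, `patch_size`,
#' `max_overlap`, `n_target_per_image`, `std_threshold`,
#' `slope_threshold_deg`, `variance_kept`, `z_cutoff`, `backbone`,
#' `epochs`, `batch_size`, `learning_rate`, `lcfd_max_window`,
#' `lcfd_bins`, `glcm_levels`, `glcm_distance`, `ks_alpha`, `ks_sample`
#' ("histogram" compares averaged-histogram frequency vectors;
#' "patch_means" compares per-patch mean LCFD samples), `write_images`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    mode = "synthetic", input_dir = NA_character_, out_dir = tempfile("demtex_"),
    seed = 1L, n_per_class = 15L, image_size = 384L,
    background_amplitude = 0.25, noise_sd = 0.02,
    rolling_ball_radius = 32, rolling_ball_element = "ball",
    patch_size = 128L, max_overlap = 0.30, n_target_per_image = 16L,
    std_threshold = 0.95, slope_threshold_deg = 0.51,
    variance_kept = 0.95, z_cutoff = 3.0,
    backbone = "small_cnn", epochs = 30L, batch_size = 32L,
    learning_rate = 0.05, lcfd_max_window = 33L, lcfd_bins = 50L,
    glcm_levels = 32L, glcm_distance = 1L, ks_alpha = 0.05,
    ks_sample = "histogram", write_images = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  stopifnot(cfg$mode %in% c("synthetic", "directory"),
            cfg$max_overlap >= 0, cfg$max_overlap < 1,
            cfg$std_threshold > 0, cfg$slope_threshold_deg > 0,
            cfg$variance_kept > 0, cfg$variance_kept <= 1,
            cfg$ks_alpha > 0, cfg$ks_alpha < 1,
            cfg$ks_sample %in% c("histogram", "patch_means"),
            cfg$backbone %in% c("small_cnn", "densenet121"))
  structure(cfg, class = "pipeline_config")
}

# load images for "directory" mode: expects images_manifest.tsv
load_image_dir <- function(dir) {
  man <- read.table(file.path(dir, "images_manifest.tsv"), sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i)
    read_labeled_image(file.path(dir, man$file[i]), man$class_name[i],
                       man$image_id[i]))
}

write_tsv <- function(x, path)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full DEM texture-analysis pipeline
#'
#' Executes all stages in order: image generation (or ingestion),
#' rolling-ball background removal and normalization, Stage-1 full-texture
#' patch selection, class balancing, Stage-2 iterative CNN clustering,
#' LCFD histograms and statistics, the GLCM baseline clustering, K-S
#' separability tests and the fractal-composition report.  All tables are
#' written to `config$out_dir` together with a run log recording every
#' parameter and seed.
#'
#' @param config a [pipeline_config()].
#' @param specs synthetic-mode texture class specifications; defaults to
#'   [default_texture_specs()].
#' @return invisibly, a result bundle: `images`, `patches`, `state`,
#'   `selection_report`, `lcfd` (per-patch values, stats, histograms,
#'   rankings), `glcm` (features, labels, stats), `ks`, `composition`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         specs = default_texture_specs()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("demtex pipeline run\n", file = log_path)
  for (nm in names(config)) logf("param %s = %s", nm,
                                 paste(config[[nm]], collapse = ","))
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %s: done", name)
    out
  }

  images <- stage("input", {
    if (config$mode == "synthetic") {
      imgs <- generate_image_set(specs, config$n_per_class,
                                 config$image_size,
                                 seed = derive_seed(config$seed, "generate"),
                                 background_amplitude =
                                   config$background_amplitude,
                                 noise_sd = config$noise_sd)
      if (isTRUE(config$write_images))
        write_image_set(imgs, file.path(config$out_dir, "images"))
      imgs
    } else load_image_dir(config$input_dir)
  })

  images <- stage("preprocess", lapply(images, preprocess_image,
                                       radius = config$rolling_ball_radius,
                                       element = config$rolling_ball_element))

  sel <- stage("select", select_patches(
    images, config$patch_size, config$max_overlap,
    config$n_target_per_image, config$std_threshold,
    config$slope_threshold_deg, config$variance_kept, config$z_cutoff,
    seed = derive_seed(config$seed, "select")))
  write_tsv(sel$report, file.path(config$out_dir, "selection_report.tsv"))
  logf("selected %d of %d sampled patches", length(sel$patches),
       nrow(sel$report))

  clus <- stage("cluster", {
    n_classes <- length(unique(vapply(sel$patches, `[[`, "", "class_label")))
    cfg <- classifier_config(backbone = config$backbone,
                             n_classes = n_classes, epochs = config$epochs,
                             batch_size = config$batch_size,
                             learning_rate = config$learning_rate,
                             seed = derive_seed(config$seed, "train"))
    cluster_patches(sel$patches, cfg, seed = derive_seed(config$seed, "stage2"))
  })
  patches <- clus$patches
  man <- patch_manifest(patches)
  write_tsv(man, file.path(config$out_dir, "patches_manifest.tsv"))
  write_tsv(cbind(data.frame(actual = rownames(clus$initial_confusion)),
                  as.data.frame.matrix(clus$initial_confusion)),
            file.path(config$out_dir, "initial_confusion.tsv"))

  lcfd <- stage("lcfd", {
    edges <- lcfd_bin_edges(config$lcfd_bins)
    per_patch <- lapply(patches, function(p)
      lcfd_values(lcfd_map(binarize(p), config$lcfd_max_window)))
    names(per_patch) <- man$patch_id
    keep <- lengths(per_patch) > 0L
    per_patch <- per_patch[keep]
    kept_man <- man[keep, ]
    by_cluster <- split(per_patch, kept_man$cluster_label)
    names(by_cluster) <- paste0("cluster_", names(by_cluster))
    by_class <- split(per_patch, kept_man$class_label)
    stats_cluster <- cluster_stats(by_cluster)
    stats_class <- cluster_stats(by_class)
    hist_of <- function(groups) lapply(groups, function(g)
      average_histogram(lapply(g, lcfd_histogram, bin_edges = edges)))
    list(per_patch = per_patch, manifest = kept_man,
         stats_cluster = stats_cluster, stats_class = stats_class,
         hist_cluster = hist_of(by_cluster), hist_class = hist_of(by_class),
         ranking = rank_clusters_by_fractality(stats_cluster))
  })
  write_tsv(lcfd$stats_cluster, file.path(config$out_dir,
                                          "lcfd_stats_clusters.tsv"))
  write_tsv(lcfd$stats_class, file.path(config$out_dir,
                                        "lcfd_stats_classes.tsv"))
  write_tsv(lcfd$ranking, file.path(config$out_dir, "cluster_ranking.tsv"))

  glcm <- stage("glcm", {
    M <- glcm_feature_matrix(patches, config$glcm_levels,
                             config$glcm_distance)
    labels <- glcm_cluster(M, k = length(unique(man$class_label)))
    ids <- intersect(names(lcfd$per_patch), names(labels))
    by_glcm <- split(lcfd$per_patch[ids], labels[ids])
    names(by_glcm) <- paste0("glcm_cluster_", names(by_glcm))
    st <- cluster_stats(by_glcm)
    list(features = M, labels = labels, stats = st,
         ranking = rank_clusters_by_fractality(st))
  })
  write_tsv(data.frame(patch_id = rownames(glcm$features), glcm$features,
                       glcm_cluster = glcm$labels[rownames(glcm$features)]),
            file.path(config$out_dir, "glcm_features.tsv"))
  write_tsv(glcm$stats, file.path(config$out_dir, "lcfd_stats_glcm.tsv"))

  report <- stage("report", {
    samples_of <- function(hists, groups) {
      if (config$ks_sample == "histogram")
        lapply(hists, `[[`, "frequencies")
      else lapply(groups, function(g) vapply(g, mean, 0))
    }
    by_cluster <- split(lcfd$per_patch, lcfd$manifest$cluster_label)
    names(by_cluster) <- paste0("cluster_", names(by_cluster))
    by_class <- split(lcfd$per_patch, lcfd$manifest$class_label)
    ks_of <- function(hists, groups) {
      if (length(groups) < 2L) {
        warning("fewer than two groups: K-S separability skipped")
        return(NULL)
      }
      pairwise_ks_matrix(samples_of(hists, groups), config$ks_alpha)
    }
    ks_cluster <- ks_of(lcfd$hist_cluster, by_cluster)
    ks_class <- ks_of(lcfd$hist_class, by_class)
    assignments <- stats::setNames(lcfd$manifest$cluster_label,
                                   lcfd$manifest$patch_id)
    ranking <- lcfd$ranking
    ranking$cluster <- sub("^cluster_", "", ranking$cluster)
    comp <- fractal_composition(assignments, ranking,
                                stats::setNames(lcfd$manifest$class_label,
                                                lcfd$manifest$patch_id))
    list(ks_cluster = ks_cluster, ks_class = ks_class, composition = comp)
  })
  write_tsv(report$composition, file.path(config$out_dir, "composition.tsv"))
  write_ks <- function(ks, path) {
    if (is.null(ks)) return(invisible())
    write_tsv(cbind(data.frame(group = rownames(ks$p)),
                    as.data.frame.matrix(ks$p)), path)
  }
  write_ks(report$ks_cluster,
           file.path(config$out_dir, "ks_pvalues_clusters.tsv"))
  write_ks(report$ks_class,
           file.path(config$out_dir, "ks_pvalues_classes.tsv"))
  plot_fractal_composition(report$composition,
                           file.path(config$out_dir, "composition.png"))
  logf("pipeline complete")

  invisible(list(images = images, patches = patches, state = clus$state,
                 initial_confusion = clus$initial_confusion,
                 selection_report = sel$report, lcfd = lcfd, glcm = glcm,
                 ks = list(cluster = report$ks_cluster,
                           class = report$ks_class),
                 composition = report$composition, config = config))
}
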