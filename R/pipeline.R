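#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default. Any subset
#' can be overridden; unknown names are rejected.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param ... Overrides: `snr_db`, `calls_per_motif`, `legendre_order`,
#'   `pca_dims`, `k_range`, `dtw_radius`, `n_perm`, `adjust`,
#'   `similarity_per_group`, `popgen` (list passed to [sim_genotypes()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("vocrep_"), seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    snr_db = 15, calls_per_motif = 10L,
    legendre_order = 4L, pca_dims = 10L, k_range = 10:30,
    dtw_radius = 0.35, n_perm = 999L, adjust = "bonferroni",
    similarity_per_group = 6L,
    popgen = list(n_pops = 2L, n_per_pop = 30L, n_loci = 5L,
                  n_alleles = 6L, divergence = 0.15)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

stage_order <- c("simulate", "segment", "features", "cluster", "similarity",
                 "popgen", "stats", "report")

stage_hash <- function(cfg, stage) {
  rlang::hash(list(stage = stage, seed = cfg$seed, snr = cfg$snr_db,
                   cpm = cfg$calls_per_motif, k = cfg$k_range,
                   dims = cfg$pca_dims, order = cfg$legendre_order,
                   radius = cfg$dtw_radius, n_perm = cfg$n_perm,
                   popgen = cfg$popgen, per_group = cfg$similarity_per_group))
}

read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in dependency order: simulate a synthetic
#' corpus, segment it, extract motif/syllable features, cluster the
#' repertoire, compute syllable similarity, simulate and summarize genotypes,
#' run the statistical layer, and write a summary report. Every artifact is
#' a CSV/JSON file under `config$out_dir`; a manifest records each stage's
#' parameter hash so re-running an identical config is a no-op unless
#' `force = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of
#'   `c("simulate","segment","features","cluster","similarity","popgen","stats","report")`.
#' @param force Re-run stages whose manifest entry is current.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = stage_order, force = FALSE) {
  stages <- match.arg(stages, stage_order, several.ok = TRUE)
  stages <- stage_order[stage_order %in% stages]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- read_manifest(config$out_dir)

  need <- function(stage, files) {
    ok <- file.exists(out(files))
    if (!all(ok)) {
      abort(sprintf("missing artifact(s) for stage '%s': run '%s' first",
                    stage, stage))
    }
  }
  cached <- function(stage) {
    !force && identical(manifest[[stage]]$hash, stage_hash(config, stage)) &&
      all(file.exists(out(unlist(manifest[[stage]]$outputs))))
  }
  record <- function(stage, outputs) {
    manifest[[stage]] <<- list(hash = stage_hash(config, stage),
                               seed = config$seed, outputs = outputs)
    write_manifest(config$out_dir, manifest)
    inform(sprintf("[%s] done", stage))
  }

  for (stage in stages) {
    if (cached(stage)) {
      inform(sprintf("[%s] cached, skipping", stage))
      next
    }
    switch(stage,
      simulate = {
        spec <- default_corpus_spec(seed = config$seed,
                                    snr_db = config$snr_db,
                                    calls_per_motif = config$calls_per_motif)
        corpus <- synth_corpus(spec, dir = out("audio"))
        readr::write_csv(corpus$truth, out("truth.csv"))
        record("simulate", c("truth.csv", "audio"))
      },
      segment = {
        need("simulate", "audio")
        truth <- readr::read_csv(out("truth.csv"), show_col_types = FALSE)
        pops <- truth |> dplyr::distinct(.data$file, .data$population)
        paths <- list.files(out("audio"), full.names = TRUE)
        segs <- segment_corpus(paths,
                               populations = setNames(pops$population,
                                                      pops$file))
        readr::write_csv(segs, out("segments.csv"))
        ev <- evaluate_segmentation(segs, truth)
        jsonlite::write_json(
          list(detection_rate = ev$detection_rate,
               boundary_mae_s = ev$boundary_mae_s,
               syllable_count_accuracy = ev$syllable_count_accuracy),
          out("segmentation_eval.json"), auto_unbox = TRUE, digits = NA)
        record("segment", c("segments.csv", "segmentation_eval.json"))
      },
      features = {
        need("segment", "segments.csv")
        truth <- readr::read_csv(out("truth.csv"), show_col_types = FALSE)
        segs <- readr::read_csv(out("segments.csv"), show_col_types = FALSE)
        clips <- bandpassed_clips(list.files(out("audio"), full.names = TRUE))
        motifs <- dplyr::filter(segs, .data$unit_type == "motif")
        mf <- motif_features(clips, motifs, already_bandpassed = TRUE)
        emb <- do.call(rbind, mf$embedding)
        colnames(emb) <- paste0("v", seq_len(ncol(emb)))
        readr::write_csv(dplyr::bind_cols(mf[c("file", "population")],
                                          as_tibble(emb)),
                         out("motif_features.csv"))
        # syllable labels come from the truth table (known templates)
        syls <- dplyr::filter(truth, .data$unit_type == "syllable")
        sf <- syllable_features(clips, syls, order = config$legendre_order,
                                already_bandpassed = TRUE)
        readr::write_csv(sf, out("syllable_features.csv"))
        record("features", c("motif_features.csv", "syllable_features.csv"))
      },
      cluster = {
        need("features", c("motif_features.csv", "syllable_features.csv"))
        mf <- readr::read_csv(out("motif_features.csv"),
                              show_col_types = FALSE)
        red <- reduce_pca(mf, dims = config$pca_dims)
        k_range <- config$k_range[config$k_range < nrow(mf)]
        if (length(k_range) == 0) k_range <- 2:max(2, nrow(mf) - 1)
        sel <- select_k(red, k_range = k_range, seed = config$seed)
        assignments <- dplyr::bind_cols(
          mf[c("file", "population")],
          tibble(cluster = sel$model$cluster))
        readr::write_csv(assignments, out("motif_clusters.csv"))
        jsonlite::write_json(
          list(k_best = sel$k_best,
               mean_silhouette = sel$model$mean_silhouette,
               inertia = sel$model$inertia,
               curve = sel$curve),
          out("cluster_model.json"), auto_unbox = TRUE, digits = NA)
        record("cluster", c("motif_clusters.csv", "cluster_model.json"))
      },
      similarity = {
        need("simulate", "truth.csv")
        truth <- readr::read_csv(out("truth.csv"), show_col_types = FALSE)
        clips <- bandpassed_clips(list.files(out("audio"), full.names = TRUE))
        syls <- dplyr::filter(truth, .data$unit_type == "syllable")
        pick <- syls |>
          dplyr::group_by(.data$population, .data$label) |>
          dplyr::slice_head(n = config$similarity_per_group) |>
          dplyr::ungroup()
        reps <- syllable_reps(clips, pick, already_bandpassed = TRUE)
        dm <- pairwise_matrix(reps, radius = config$dtw_radius)
        write_dist_csv(dm, out("syllable_distances.csv"))
        gc_res <- group_contrast(dm, attr(reps, "labels"))
        jsonlite::write_json(
          list(summary = gc_res$summary,
               H = gc_res$test$H, p = gc_res$test$p),
          out("similarity_contrast.json"), auto_unbox = TRUE, digits = NA)
        record("similarity",
               c("syllable_distances.csv", "similarity_contrast.json"))
      },
      popgen = {
        gt <- do.call(sim_genotypes, c(config$popgen,
                                       list(seed = config$seed)))
        readr::write_csv(gt, out("genotypes.csv"))
        freqs <- allele_freqs(gt)
        readr::write_csv(freqs, out("allele_freqs.csv"))
        readr::write_csv(heterozygosity(freqs, gt),
                         out("heterozygosity.csv"))
        write_dist_csv(genetic_dist_matrix(freqs), out("genetic_dist.csv"))
        record("popgen", c("genotypes.csv", "allele_freqs.csv",
                           "heterozygosity.csv", "genetic_dist.csv"))
      },
      stats = {
        need("cluster", "motif_clusters.csv")
        need("features", "syllable_features.csv")
        assignments <- readr::read_csv(out("motif_clusters.csv"),
                                       show_col_types = FALSE)
        sf <- readr::read_csv(out("syllable_features.csv"),
                              show_col_types = FALSE)
        h_motif <- homogeneity(assignments$population, assignments$cluster)
        syl_mat <- as.matrix(sf[grep("^c[0-9]+$", names(sf))])
        syl_range <- (4:16)[4:16 < nrow(syl_mat)]
        syl_k <- select_k(syl_mat, k_range = syl_range, seed = config$seed)
        h_syl <- homogeneity(sf$population, syl_k$model$cluster)
        mf <- readr::read_csv(out("motif_features.csv"),
                              show_col_types = FALSE)
        red <- reduce_pca(mf, dims = config$pca_dims)
        dm <- dist_matrix(as.matrix(stats::dist(feature_matrix(red))),
                          ids = sprintf("m%d", seq_len(nrow(red))))
        pmv <- permanova(dm, red$population, n_perm = config$n_perm,
                         seed = config$seed)
        res <- list(homogeneity_motif = h_motif,
                    homogeneity_syllable = h_syl,
                    syllable_k = syl_k$k_best,
                    permanova_F = pmv$pseudo_F, permanova_p = pmv$p)
        if (file.exists(out("genetic_dist.csv"))) {
          gd <- read_dist_csv(out("genetic_dist.csv"), kind = "genetic")
          if (nrow(gd) >= 3) {
            acoustic_pop <- sf |>
              dplyr::group_by(.data$population) |>
              dplyr::summarise(f0 = mean(.data$c0), .groups = "drop")
            am <- as.matrix(stats::dist(setNames(acoustic_pop$f0,
                                                 acoustic_pop$population)))
            mt <- mantel_test(gd, dist_matrix(am, kind = "acoustic"),
                              n_perm = config$n_perm, seed = config$seed)
            res$mantel_r <- mt$r
            res$mantel_p <- mt$p
          } else {
            inform("fewer than 3 populations: Mantel test skipped")
          }
        }
        jsonlite::write_json(res, out("stats.json"), auto_unbox = TRUE,
                             digits = NA)
        record("stats", "stats.json")
      },
      report = {
        need("stats", "stats.json")
        files <- c("segmentation_eval.json", "cluster_model.json",
                   "similarity_contrast.json", "stats.json")
        files <- files[file.exists(out(files))]
        report <- purrr::map(setNames(out(files), sub("\\.json$", "", files)),
                             jsonlite::read_json)
        jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                             pretty = TRUE)
        record("report", "report.json")
      }
    )
  }
  invisible(manifest)
}
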