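#' Gradients of one connectivity matrix (threshold, affinity, embed)
#'
#' The per-scan functional-gradient chain: row-wise thresholding at the
#' configured density, normalized-angle affinity, diffusion-map embedding;
#' also returns the mean FC degree of the thresholded matrix.
#'
#' @param fc symmetric FC matrix.
#' @param density row-threshold density (default 0.10).
#' @param n_components embedding axes (default 10).
#' @param alpha anisotropic normalization exponent.
#' @param diffusion_time diffusion time (0 = automatic).
#' @return list with `embedding` (an `embedding_set`) and `mean_degree`.
#' @export
fc_gradients <- function(fc, density = 0.10, n_components = 10, alpha = 0.5,
                         diffusion_time = 0) {
  th <- threshold_rows(fc, density)
  aff <- normalized_angle(th)
  list(embedding = diffusion_embedding(aff, n_components = n_components,
                                       alpha = alpha,
                                       diffusion_time = diffusion_time),
       mean_degree = mean_fc_degree(th))
}

#' Simulate a full synthetic lifespan study
#'
#' Builds the toy cortex, the planted truth and the cohort table, then emits
#' one FC matrix per scan and runs the per-scan gradient chain, returning
#' unaligned embeddings and mean degrees. Per-scan seeds fan out from the
#' master seed via [split_seed()].
#'
#' @param config a [default_config()]-style list.
#' @param design cohort design (default [default_cohort_design()]).
#' @param noiseless disable FC noise and cohort offsets (geometry checks).
#' @param progress print a dot every 50 scans.
#' @return list: `cortex`, `truth`, `cohort`, `embeddings` (list),
#'   `mean_degree` (vector), `free` (unmasked index).
#' @export
simulate_study <- function(config = default_config(),
                           design = default_cohort_design(),
                           noiseless = FALSE, progress = FALSE) {
  cortex <- make_toy_cortex(config$n_vertices, config$n_networks,
                            config$n_parcels, config$medial_fraction,
                            seed = split_seed(config$seed, 1))
  truth <- planted_truth(cortex, seed = config$seed)
  cohort <- sample_cohort(design, seed = split_seed(config$seed, 2))
  free <- which(!cortex$medial_mask)
  offsets <- truth$cohort_offsets
  embeddings <- vector("list", nrow(cohort))
  mean_degree <- numeric(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    age <- cohort$age_years[i]
    coords <- truth_embedding(cortex, truth, age)[free, , drop = FALSE]
    off <- if (noiseless) 0 else unname(offsets[cohort$cohort_id[i]])
    nsd <- if (noiseless) 0 else truth$noise_sd_law(age)
    fc <- simulate_fc(coords, cohort_offset = off, noise_sd = nsd,
                      seed = split_seed(config$seed, 100 + i))
    g <- fc_gradients(fc, density = config$density,
                      n_components = config$n_components,
                      alpha = config$embed_alpha,
                      diffusion_time = config$diffusion_time)
    embeddings[[i]] <- g$embedding
    mean_degree[i] <- g$mean_degree
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(cortex = cortex, truth = truth, cohort = cohort,
       embeddings = embeddings, mean_degree = mean_degree, free = free)
}

#' Template, alignment and per-scan metrics for a simulated study
#'
#' Builds the weighted-PCA lifespan template from all scans' embeddings,
#' aligns every scan, and emits the tidy metrics table (one row per scan).
#'
#' @param study output of [simulate_study()].
#' @param config configuration list.
#' @return list: `template`, `aligned` (list of embeddings), `metrics`
#'   (tibble joined with the cohort table).
#' @export
study_metrics <- function(study, config = default_config()) {
  template <- wpca_template(study$embeddings, ages = study$cohort$age_years,
                            n_bins = config$n_bins, n_keep = config$n_keep)
  aligned <- lapply(study$embeddings, align_to_template, template = template)
  rows <- purrr::map2(aligned, study$mean_degree, function(e, md)
    gradient_metrics(e, template, mean_degree = md))
  metrics <- dplyr::bind_cols(study$cohort, dplyr::bind_rows(rows))
  list(template = template, aligned = aligned, metrics = metrics)
}

#' Lifespan trajectories of the global gradient metrics
#'
#' Harmonizes each metric (density weights, mean and variance adjustment,
#' final weighted fit) and extracts the posterior peak age with its HDI.
#'
#' @param metrics metrics tibble from [study_metrics()].
#' @param config configuration list.
#' @param metrics_cols metric columns to model.
#' @param n_draws posterior draws (defaults to `config$n_draws`).
#' @return tibble: one row per metric with `peak_age`, `peak_lo`, `peak_hi`,
#'   `boundary`, `edf`; the fitted `harmonized_series` in a list column.
#' @export
metric_trajectories <- function(metrics, config = default_config(),
                                metrics_cols = c("dispersion", "grange_SA",
                                                 "grange_VS", "grange_MR"),
                                n_draws = NULL) {
  n_draws <- n_draws %||% config$n_draws
  meta <- split_arousal_cohort(metrics)
  dw <- density_weights(meta$age_years, meta$cohort_strat,
                        n_bins = config$weight_bins)
  purrr::map_dfr(metrics_cols, function(mc) {
    h <- harmonize(meta[[mc]], meta$age_years, meta$individual_id,
                   meta$cohort_strat, k_low = config$k_low,
                   k_high = config$k_high, density_w = dw)
    pk <- peak_age(h$fit, n_draws = n_draws,
                   seed = split_seed(config$seed, 500 + match(mc, metrics_cols)))
    tibble::tibble(metric = mc, peak_age = pk$estimate,
                   peak_lo = pk$hdi[1], peak_hi = pk$hdi[2],
                   boundary = pk$boundary, edf = sum(h$fit$model$edf),
                   fit = list(h))
  })
}

#' Run the synthetic end-to-end pipeline and write a run manifest
#'
#' Executes the requested stages in order (simulate, gradients, template,
#' align, metrics, trajectories, associate, meta_axis, pls), writing each
#' stage's artifacts as TSV under `out_dir` and a JSON manifest recording
#' the configuration, seeds and an md5 content hash per artifact. Identical
#' configuration and seed yield identical manifest hashes.
#'
#' @param config configuration list ([default_config()], possibly from
#'   [read_config()]).
#' @param out_dir output directory (created).
#' @param design cohort design.
#' @return the manifest, invisibly; written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("lifegrad_"),
                         design = default_cohort_design()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  artifacts <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    artifacts <<- c(artifacts, setNames(path, name))
    path
  }

  # simulate + gradients happen jointly (FC matrices are streamed, not kept)
  study <- simulate_study(config, design)
  if ("simulate" %in% stages) {
    emit("cohort.tsv", function(p) write_table(study$cohort, p))
    lab <- tibble::tibble(vertex = seq_len(study$cortex$n_vertices) - 1L,
                          network = study$cortex$network_label,
                          parcel = study$cortex$parcel_label,
                          medial = study$cortex$medial_mask)
    emit("labels.tsv", function(p) write_table(lab, p))
    emit("truth_base_maps.tsv", function(p)
      write_matrix(study$truth$base_maps, p,
                   metadata = list(seed = config$seed, indexing = "0-based")))
  }
  if ("gradients" %in% stages) {
    ev <- t(vapply(study$embeddings, function(e) e$eigenvalues,
                   numeric(config$n_components)))
    rownames(ev) <- study$cohort$scan_id
    emit("eigenvalues.tsv", function(p)
      write_matrix(ev, p, metadata = list(aligned = FALSE)))
  }

  sm <- NULL
  if (any(c("template", "align", "metrics", "trajectories", "associate",
            "meta_axis", "pls") %in% stages)) {
    sm <- study_metrics(study, config)
  }
  if ("template" %in% stages)
    emit("template.tsv", function(p)
      write_matrix(sm$template$axes, p,
                   metadata = list(n_bins = config$n_bins,
                                   indexing = "0-based")))
  if ("metrics" %in% stages)
    emit("metrics.tsv", function(p) write_table(sm$metrics, p))

  if ("trajectories" %in% stages) {
    tr <- metric_trajectories(sm$metrics, config,
                              n_draws = min(config$n_draws, 4000))
    emit("trajectories.tsv", function(p)
      write_table(dplyr::select(tr, -"fit"), p))
    grid <- seq(0.2, 99, length.out = 200)
    curves <- purrr::map_dfr(seq_len(nrow(tr)), function(i)
      tibble::tibble(metric = tr$metric[i], age = grid,
                     fit = predict_curve(tr$fit[[i]]$fit, grid)))
    emit("trajectory_curves.tsv", function(p) write_table(curves, p))
  }

  if ("associate" %in% stages) {
    adult <- sm$metrics[sm$metrics$cohort_id == "adult", ]
    scored <- simulate_scores(adult, "dispersion",
                              beta_grad = config$score_beta_grad,
                              noise_sd = config$score_noise_sd,
                              seed = split_seed(config$seed, 900))
    res <- purrr::map_dfr(
      c("dispersion", "grange_SA", "grange_VS", "grange_MR"),
      function(mc) dplyr::mutate(
        ols_assoc(scored$score, scored$age_years, scored[[mc]]),
        metric = mc, .before = 1))
    adj <- bh_fdr(res$p)
    res$q_value <- adj$q_value; res$reject <- adj$reject
    emit("associations.tsv", function(p) write_table(res, p))
  }

  if (any(c("meta_axis", "pls") %in% stages)) {
    free <- study$free
    parc <- study$cortex$parcel_label[free]
    sa_tmpl <- sm$template$axes[free, "SA"]
    parcel_sa <- as.numeric(tapply(sa_tmpl, parc, mean))
  }
  if ("meta_axis" %in% stages) {
    spec <- tibble::tibble(
      term = sprintf("term_%02d", seq_len(config$n_terms)),
      class = rep(c("association", "unimodal", "intermediate"),
                  length.out = config$n_terms),
      loading = 1)
    tm <- simulate_term_maps(parcel_sa, spec, seed = split_seed(config$seed, 910))
    ca <- canonical_axis(tm, spec$term[spec$class == "association"],
                         spec$term[spec$class == "unimodal"],
                         excluded = spec$term[spec$class == "intermediate"])
    align_rho <- cor(ca$axis, parcel_sa, method = "spearman")
    emit("meta_axis.tsv", function(p)
      write_table(tibble::tibble(parcel = seq_along(parcel_sa) - 1L,
                                 axis = ca$axis, parcel_SA = parcel_sa), p))
    emit("meta_axis_alignment.tsv", function(p)
      write_table(tibble::tibble(rho_axis_SA = align_rho), p))
  }
  if ("pls" %in% stages) {
    expr <- simulate_expression(parcel_sa, n_genes = config$n_genes,
                                frac_coupled = config$frac_coupled,
                                seed = split_seed(config$seed, 920))
    ages <- config$pls_ages
    y_by_age <- setNames(lapply(ages, function(a) {
      coords <- truth_embedding(study$cortex, study$truth, a)[free, "SA"]
      as.numeric(tapply(coords, parc, mean))
    }), ages)
    enr <- pls_enrichment(expr, y_by_age,
                          n_perm = min(config$n_perm, 499),
                          seed = split_seed(config$seed, 930))
    emit("pls_enrichment.tsv", function(p) write_table(enr, p))
  }

  manifest <- list(
    config = config[order(names(config))],
    n_scans = nrow(study$cohort),
    artifacts = lapply(seq_along(artifacts), function(i)
      list(name = names(artifacts)[i],
           md5 = unname(tools::md5sum(artifacts[i])))))
  names(manifest$artifacts) <- names(artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
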