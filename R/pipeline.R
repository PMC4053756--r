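# Run configuration and the end-to-end pipeline driver:
# synthesize (or load) -> normalize -> call domains -> elements -> annotate
# -> expression, with every output reproducible from config + seed.

#' Default run configuration
#'
#' All stage parameters with the published defaults (200-probe windows,
#' threshold 0.8, FDR ceiling 5%, 300-bp smoothing, element rule
#' 1.0 / <0 / 10 probes / 500 bp, 3-kb promoters, SAM delta 4) and a
#' desk-scale synthetic genome. Every stochastic stage derives its seed
#' from the single top-level `seed`.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(
      chrom_lengths = c(chrA = 6e6, chrB = 5e6, chrX = 4e6),
      probe_length = 50, spacing = 50, gc_prob = 0.36
    ),
    architecture = list(
      arm_density = 0.6, center_density = 0.05,
      domain_level = 1.5, element_level_own = 2, element_level_other = -0.5,
      n_elements = c(A = 4, B = 4), n_detached = 3
    ),
    noise = list(sd = 0.5, ar1 = 0.5, gc_slope = 0.02, n_reps = 3),
    normalize = list(gc_bin = 1, min_bin_n = 50, smooth_bp = 300),
    domains = list(window = 200, theta = 0.8, fdr = 0.05),
    elements = list(min_score = 1, max_other = 0, min_probes = 10, max_gap = 500),
    annotate = list(promoter_bp = 3000, flank_bp = 10000, step_bp = 500),
    expression = list(
      n_genes = 300, baseline = 200, fold = 4, dispersion = 0.05,
      groups = c(wt = 3, mutant = 2), delta = 4
    )
  )
}

#' Read / write a run configuration
#'
#' Plain-text YAML mirroring [default_config()]; unknown keys are rejected
#' so configs stay reviewable provenance.
#'
#' @param path YAML file.
#' @return The configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ref <- default_config()
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0) {
    rlang::abort(sprintf("unknown config block(s): %s", paste(extra, collapse = ", ")))
  }
  out <- utils::modifyList(ref, cfg)
  # YAML turns named vectors into lists; restore the ones we rely on
  out$genome$chrom_lengths <- unlist(out$genome$chrom_lengths)
  out$architecture$n_elements <- unlist(out$architecture$n_elements)
  out$expression$groups <- unlist(out$expression$groups)
  out
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  # named vectors become YAML maps (as.list), so names survive the round trip
  for (key in list(c("genome", "chrom_lengths"), c("architecture", "n_elements"), c("expression", "groups"))) {
    config[[key[1]]][[key[2]]] <- as.list(config[[key[1]]][[key[2]]])
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic DamID analysis pipeline
#'
#' Generates a probe layout and planted architecture, simulates replicate
#' DamID tracks for both factors (plus a mutant track for factor A and a
#' null control), normalizes them jointly, calls domains with
#' FDR-calibrated windows, detects factor-exclusive elements and detached
#' regions, annotates synthetic genes (occupancy, enrichment, tissue
#' comparisons, boundary metaprofile), and runs the expression stage with
#' SAM selection. All outputs are written to `out_dir` as plain-text files
#' plus a manifest with parameters and checksums; two runs with the same
#' config are bit-identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all intermediate results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("nedomains_run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- synthesis -----------------------------------------------------------
  res <- list()
  stage("synth", {
    layout <- make_genome(
      config$genome$chrom_lengths,
      probe_length = config$genome$probe_length,
      spacing = config$genome$spacing,
      gc_prob = config$genome$gc_prob,
      seed = config$seed
    )
    arch <- rlang::exec(plant_architecture,
      layout = layout, !!!config$architecture, seed = config$seed + 1
    )
    noise <- rlang::exec(noise_model, !!!config$noise, seed = config$seed + 2)
    sim_a <- simulate_damid(layout, arch, noise, factor = "A", genotype = "wt")
    sim_b <- simulate_damid(layout, arch, noise, factor = "B", genotype = "wt")
    sim_a_mut <- simulate_damid(layout, arch, noise, factor = "A", genotype = "mutant")
    res$layout <- layout
    res$architecture <- arch
    res$raw <- list(
      A = sim_a$signal, B = sim_b$signal, A_mut = sim_a_mut$signal,
      null = sim_a$null
    )
    say("synth: %d probes, %d planted domain intervals", nrow(layout), nrow(arch$domains))
  })

  # --- normalization -------------------------------------------------------
  stage("normalize", {
    res$tracks <- rlang::exec(ma2c_normalize, res$raw,
      gc_bin = config$normalize$gc_bin,
      min_bin_n = config$normalize$min_bin_n,
      smooth_bp = config$normalize$smooth_bp
    )
    for (nm in names(res$tracks)) {
      rc <- attr(res$tracks[[nm]], "replicate_cor")
      say(
        "normalize: %s replicate correlations %s", nm,
        paste(sprintf("%.3f", rc[upper.tri(rc)]), collapse = ", ")
      )
    }
  })

  # --- domain calling ------------------------------------------------------
  stage("domains", {
    dp <- domain_params(
      window = config$domains$window, theta = config$domains$theta,
      fdr = config$domains$fdr
    )
    null_windows <- window_scores(binarize(res$tracks$null), dp)
    res$domains <- purrr::imap(
      list(A = "LAD", B = "EAD"),
      function(lab, fac) {
        ws <- window_scores(binarize(res$tracks[[fac]]), dp)
        cal <- calibrate_fdr(ws, null_windows, dp)
        theta <- if (isTRUE(cal$default_theta_ok)) cal$default_theta else cal$selected_theta
        doms <- call_domains(ws, dp, theta = theta, label = lab)
        gs <- gaps_and_stats(doms, res$layout)
        say(
          "domains: %s theta=%.2f -> %d domains covering %.1f%% of the genome",
          lab, theta, nrow(doms), 100 * gs$summary$coverage
        )
        list(
          windows = ws, calibration = cal, theta = theta, domains = doms,
          gaps = gs$gaps, summary = gs$summary,
          occupancy = chromosome_occupancy(doms, res$layout)
        )
      }
    )
  })

  # --- elements ------------------------------------------------------------
  stage("elements", {
    ep <- rlang::exec(element_params, !!!config$elements)
    res$elements <- list(
      A_only = call_exclusive_elements(res$tracks$A, res$tracks$B, ep, label = "A-only"),
      B_only = call_exclusive_elements(res$tracks$B, res$tracks$A, ep, label = "B-only"),
      detached = call_detached_regions(res$tracks$A, res$tracks$A_mut, ep)
    )
    res$difference <- difference_track(res$tracks$A, res$tracks$B)
    say(
      "elements: %d A-only, %d B-only, %d detached",
      nrow(res$elements$A_only), nrow(res$elements$B_only),
      nrow(res$elements$detached)
    )
  })

  # --- annotation ----------------------------------------------------------
  stage("annotate", {
    genes <- make_genes(res$layout,
      n = config$expression$n_genes,
      seed = config$seed + 3
    )
    occ_a <- gene_occupancy(res$tracks$A, genes)
    occ_b <- gene_occupancy(res$tracks$B, genes)
    tissue_tests <- occ_a |>
      dplyr::mutate(occupancy_b = occ_b$occupancy) |>
      dplyr::filter(!is.na(.data$occupancy), .data$tissue != "none") |>
      dplyr::group_by(.data$tissue) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::group_modify(function(d, key) {
        compare_gene_sets(d$occupancy, d$occupancy_b)
      }) |>
      dplyr::ungroup()
    enr <- if (nrow(res$elements$B_only) > 0) {
      feature_enrichment(res$tracks$B, res$elements$B_only, genes,
        promoter_bp = config$annotate$promoter_bp
      )
    } else {
      NULL
    }
    prof <- if (nrow(res$domains$B$domains) > 0) {
      boundary_metaprofile(res$tracks$A, res$domains$B$domains,
        flank_bp = config$annotate$flank_bp, step_bp = config$annotate$step_bp
      )
    } else {
      NULL
    }
    res$genes <- genes
    res$annotate <- list(
      occupancy_a = occ_a, occupancy_b = occ_b,
      tissue_tests = tissue_tests, enrichment = enr, metaprofile = prof,
      factor_correlation = track_correlation(res$tracks$A, res$tracks$B)
    )
    say("annotate: factor A vs B correlation r=%.3f", res$annotate$factor_correlation)
  })

  # --- expression ----------------------------------------------------------
  stage("expression", {
    sim <- simulate_expression(
      res$genes, res$architecture,
      baseline = config$expression$baseline,
      derepression_fold = config$expression$fold,
      dispersion = config$expression$dispersion,
      groups = config$expression$groups,
      seed = config$seed + 4
    )
    mat <- expression_matrix(sim)
    grp <- names(config$expression$groups)
    fit <- sam_select(mat,
      group_a = grp[1], group_b = grp[2],
      delta = config$expression$delta, seed = config$seed + 5
    )
    sig <- fit$table$locus[fit$table$significant]
    fc <- fold_change_table(mat, group_a = grp[1], group_b = grp[2])
    released <- res$genes$gene_id[overlaps_any(res$genes, res$architecture$detached)]
    class_summary <- fc |>
      dplyr::mutate(
        class = ifelse(.data$locus %in% released, "released", "other"),
        log2_fc = log2(.data$fold_change)
      ) |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        n = dplyr::n(),
        median_log2_fc = stats::median(.data$log2_fc, na.rm = TRUE),
        .groups = "drop"
      )
    res$expression <- list(
      simulated = sim, matrix = mat, sam = fit, significant = sig,
      fold_changes = fc, class_summary = class_summary
    )
    say(
      "expression: %d significant loci at delta=%g; released-class median log2FC %.2f",
      length(sig), config$expression$delta,
      class_summary$median_log2_fc[class_summary$class == "released"] %||% NA_real_
    )
  })

  # --- outputs -------------------------------------------------------------
  stage("write", {
    paths <- c(config = file.path(out_dir, "config.yaml"))
    write_config(config, paths[["config"]])
    for (nm in names(res$tracks)) {
      p <- file.path(out_dir, sprintf("track_%s.bedgraph", nm))
      write_probe_track(res$tracks[[nm]], p,
        sidecar = if (nm == "A") file.path(out_dir, "probes_gc.tsv") else NULL
      )
      paths[[paste0("track_", nm)]] <- p
    }
    for (fac in names(res$domains)) {
      p <- file.path(out_dir, sprintf("domains_%s.bed", fac))
      write_intervals(res$domains[[fac]]$domains, p)
      paths[[paste0("domains_", fac)]] <- p
      pt <- file.path(out_dir, sprintf("fdr_table_%s.tsv", fac))
      readr::write_tsv(res$domains[[fac]]$calibration$table, pt, progress = FALSE)
      paths[[paste0("fdr_table_", fac)]] <- pt
    }
    for (nm in names(res$elements)) {
      p <- file.path(out_dir, sprintf("elements_%s.bed", nm))
      write_intervals(res$elements[[nm]], p)
      paths[[paste0("elements_", nm)]] <- p
    }
    truth <- file.path(out_dir, "truth_domains.bed")
    write_intervals(
      res$architecture$domains |>
        dplyr::filter(.data$factor == "A") |>
        dplyr::mutate(label = "true-A") |>
        dplyr::select("chrom", "start", "end", "label"),
      truth
    )
    paths[["truth_domains"]] <- truth
    pg <- file.path(out_dir, "genes.bed12")
    write_gene_models(res$genes, pg)
    paths[["genes"]] <- pg
    ps <- file.path(out_dir, "gene_sets.tsv")
    write_gene_sets(res$genes, ps)
    paths[["gene_sets"]] <- ps
    pe <- file.path(out_dir, "sam_table.tsv")
    readr::write_tsv(res$expression$sam$table, pe, progress = FALSE)
    paths[["sam_table"]] <- pe
    pf <- file.path(out_dir, "fold_changes.tsv")
    readr::write_tsv(res$expression$fold_changes, pf, progress = FALSE)
    paths[["fold_changes"]] <- pf
    if (!is.null(res$annotate$enrichment)) {
      pn <- file.path(out_dir, "enrichment.tsv")
      readr::write_tsv(res$annotate$enrichment, pn, progress = FALSE)
      paths[["enrichment"]] <- pn
    }
    if (!is.null(res$annotate$metaprofile)) {
      pm <- file.path(out_dir, "metaprofile.tsv")
      readr::write_tsv(res$annotate$metaprofile, pm, progress = FALSE)
      paths[["metaprofile"]] <- pm
    }
    log_path <- file.path(out_dir, "run.log")
    writeLines(log_lines, log_path)
    manifest <- list(
      package = "nedomains",
      version = as.character(utils::packageVersion("nedomains")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      files = as.list(stats::setNames(
        unname(tools::md5sum(unlist(paths))),
        basename(unlist(paths))
      ))
    )
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    res$manifest <- manifest
    res$paths <- paths
  })

  invisible(res)
}
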