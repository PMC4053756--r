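#' Build a synthetic tiling-array probe layout
#'
#' Lays fixed-length probes at a regular spacing along each chromosome,
#' mimicking a high-density whole-genome tiling design (50-bp probes by
#' default), and draws an integer GC count per probe.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param probe_length Probe length in bp.
#' @param spacing Start-to-start distance between consecutive probes (bp).
#' @param gc_model Either `"binomial"` (GC count ~ Binomial(probe_length,
#'   gc_prob)), `"uniform"` (uniform on 0..probe_length), or a function of a
#'   single integer `n` returning `n` integer GC counts.
#' @param gc_prob Per-base GC probability for the binomial model.
#' @param seed Integer seed; the layout is a pure function of its arguments.
#' @return A tibble with columns `chrom`, `start`, `end`, `gc` (0-based
#'   half-open coordinates), carrying `chrom_lengths`, `probe_length` and
#'   `spacing` as attributes.
#' @examples
#' layout <- make_genome(c(chrA = 1e5), seed = 1)
#' nrow(layout) # floor((1e5 - 50) / 50) + 1
#' @export
make_genome <- function(chrom_lengths, probe_length = 50, spacing = 50,
                        gc_model = c("binomial", "uniform"), gc_prob = 0.36,
                        seed = 1) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    rlang::abort("chrom_lengths must be a named vector")
  }
  if (probe_length <= 0 || spacing < 1) {
    rlang::abort("probe_length must be positive and spacing >= 1")
  }
  if (any(chrom_lengths < probe_length)) {
    rlang::abort("every chromosome must be at least one probe long")
  }
  draw_gc <- if (is.function(gc_model)) {
    gc_model
  } else {
    switch(match.arg(gc_model),
      binomial = function(n) stats::rbinom(n, size = probe_length, prob = gc_prob),
      uniform = function(n) sample.int(probe_length + 1L, n, replace = TRUE) - 1L
    )
  }
  withr::with_seed(seed, {
    layout <- purrr::map_dfr(names(chrom_lengths), function(ch) {
      n <- floor((chrom_lengths[[ch]] - probe_length) / spacing) + 1
      start <- as.integer((seq_len(n) - 1) * spacing)
      tibble::tibble(
        chrom = ch,
        start = start,
        end = start + as.integer(probe_length),
        gc = as.integer(draw_gc(n))
      )
    })
    if (any(layout$gc < 0 | layout$gc > probe_length)) {
      rlang::abort("gc_model produced GC counts outside 0..probe_length")
    }
    structure(layout,
      chrom_lengths = chrom_lengths,
      probe_length = probe_length, spacing = spacing
    )
  })
}

#' Chromosome lengths of a probe layout
#' @param layout A layout from [make_genome()].
#' @return Named numeric vector of chromosome lengths (bp).
#' @export
chrom_lengths <- function(layout) attr(layout, "chrom_lengths")

# Resolve a layout or a named length vector into named lengths.
as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    cl <- attr(x, "chrom_lengths")
    if (is.null(cl)) rlang::abort("layout carries no chrom_lengths attribute")
    return(cl)
  }
  if (is.null(names(x))) rlang::abort("chrom_lengths must be named")
  x
}

default_arms <- function(chrom_lengths, arm_fraction = 0.3) {
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- unname(chrom_lengths[[ch]])
    a <- floor(len * arm_fraction)
    tibble::tibble(
      chrom = ch,
      start = c(0L, as.integer(len - a)),
      end = c(as.integer(a), as.integer(len)),
      region = "arm"
    )
  })
}

# Rescale positive lengths toward sum `target` while keeping every value in
# [lo, hi]; values pinned at a bound are left there and the rest re-scaled.
rescale_to_sum <- function(lens, target, lo, hi) {
  for (i in 1:100) {
    lens <- pmin(pmax(lens, lo), hi)
    s <- sum(lens)
    if (abs(s - target) < 1) break
    adj <- if (s < target) lens < hi else lens > lo
    if (!any(adj)) break
    lens[adj] <- lens[adj] * (target - sum(lens[!adj])) / sum(lens[adj])
  }
  lens <- round(pmin(pmax(lens, lo), hi))
  d <- target - sum(lens)
  j <- which.max(lens)
  lens[j] <- min(hi, max(lo, lens[j] + d))
  lens
}

# Alternate gap/domain intervals along [s, e) whose domain bp sums to
# round(density * (e - s)). Lengths are drawn from lognormals and rescaled
# within the truncation bounds, so the realized density is exact (up to
# bound effects) and no planted domain falls below the size floor.
fill_region <- function(s, e, density, domain_size, domain_range, gap_size, gap_min) {
  len <- e - s
  target <- round(density * len)
  if (target < domain_range[1]) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  k <- max(1, round(target / exp(domain_size[["meanlog"]])))
  while (k > 1 && k * domain_range[1] > target) k <- k - 1
  while (k * domain_range[2] < target) k <- k + 1
  # need k+1 gaps of at least gap_min
  while (k > 1 && (len - target) < (k + 1) * gap_min) k <- k - 1
  lens <- stats::rlnorm(k, domain_size[["meanlog"]], domain_size[["sdlog"]])
  lens <- rescale_to_sum(lens, target, domain_range[1], domain_range[2])
  gaps <- stats::rlnorm(k + 1, gap_size[["meanlog"]], gap_size[["sdlog"]])
  gaps <- rescale_to_sum(gaps, len - sum(lens), gap_min, Inf)
  starts <- s + cumsum(gaps)[seq_len(k)] + c(0, cumsum(lens))[seq_len(k)]
  out <- tibble::tibble(start = as.integer(starts), end = as.integer(pmin(starts + lens, e)))
  out[out$end > out$start & out$start < e, , drop = FALSE]
}

#' Plant a latent nuclear-envelope association architecture
#'
#' Generates ground-truth domains shared by two factors (A, the lamin-like
#' tether; B, the emerin-like membrane factor), factor-exclusive elements
#' (regions kept by one factor where the other factor's domain is punched
#' out), and detached regions (factor-A domains that lose association in a
#' mutant genotype). Arms are enriched for domains relative to chromosome
#' centers, and the realized base-pair density per region is exact by
#' construction.
#'
#' @param layout Probe layout from [make_genome()].
#' @param arm_density,center_density Target fraction of arm / center bp
#'   covered by domains.
#' @param arms Optional tibble (`chrom`, `start`, `end`) of arm intervals;
#'   defaults to the outer 30% on each side of every chromosome.
#' @param domain_level Mean probe score inside planted domains (score units).
#' @param domain_size Named vector `c(meanlog=, sdlog=)` of the lognormal
#'   domain-size distribution (bp).
#' @param domain_range Truncation bounds for domain sizes (bp); the lower
#'   bound defaults above one 200-probe window span so planted truth is
#'   recoverable in principle.
#' @param gap_size,gap_min Lognormal parameters and lower bound for gaps
#'   between planted domains (bp).
#' @param n_elements Named integer vector `c(A=, B=)`: number of exclusive
#'   elements to plant per factor.
#' @param element_length Length-2 numeric range of element sizes (bp).
#' @param element_level_own,element_level_other Mean probe score of an
#'   element on its own factor's track and on the other factor's track.
#' @param n_detached Number of factor-A domains marked detached (present in
#'   wild type, absent in the mutant genotype).
#' @param min_probes Minimum qualifying probes an element must be able to
#'   hold; planting errors out if `element_length` cannot fit them.
#' @param seed Integer seed.
#' @return An object of class `ne_architecture`: a list of tibbles
#'   `domains` (chrom, start, end, factor, level), `elements` (chrom, start,
#'   end, factor, level_own, level_other), `detached` and `arms`.
#' @export
plant_architecture <- function(layout,
                               arm_density = 0.6, center_density = 0.05,
                               arms = NULL,
                               domain_level = 1.5,
                               domain_size = c(meanlog = log(23000), sdlog = 0.6),
                               domain_range = c(10500, 300000),
                               gap_size = c(meanlog = log(15000), sdlog = 0.5),
                               gap_min = 5000,
                               n_elements = c(A = 5, B = 5),
                               element_length = c(600, 3000),
                               element_level_own = 1.5,
                               element_level_other = -0.5,
                               n_detached = 3,
                               min_probes = 10,
                               seed = 1) {
  if (arm_density < 0 || arm_density > 1 || center_density < 0 || center_density > 1) {
    rlang::abort("densities must lie in [0, 1]")
  }
  spacing <- attr(layout, "spacing")
  if (element_length[1] < min_probes * spacing) {
    rlang::abort(sprintf(
      "unplantable elements: minimum element length %d bp cannot hold %d probes at %d bp spacing",
      element_length[1], min_probes, spacing
    ))
  }
  cl <- chrom_lengths(layout)
  if (is.null(arms)) arms <- default_arms(cl)
  arms$region <- "arm"
  centers <- complement_intervals(arms, cl) |> dplyr::mutate(region = "center")
  partition <- dplyr::bind_rows(arms, centers) |> dplyr::arrange(.data$chrom, .data$start)

  withr::with_seed(seed, {
    core <- purrr::pmap_dfr(
      partition[c("chrom", "start", "end", "region")],
      function(chrom, start, end, region) {
        dens <- if (region == "arm") arm_density else center_density
        fill_region(start, end, dens, domain_size, domain_range, gap_size, gap_min) |>
          dplyr::mutate(chrom = chrom, .before = 1)
      }
    ) |> dplyr::arrange(.data$chrom, .data$start)

    # Exclusive elements: hosted in distinct core domains, punched out of the
    # other factor's copy of that domain.
    n_elements <- n_elements[c("A", "B")]
    n_elements[is.na(n_elements)] <- 0
    total_el <- sum(n_elements)
    # keep punched-out flanks at least one domain-floor wide, so the pieces
    # the hole leaves behind remain resolvable domains in their own right
    margin <- max(1000, domain_range[1])
    hosts_ok <- which(core$end - core$start >= element_length[2] + 2 * margin)
    if (total_el > length(hosts_ok)) {
      rlang::abort("not enough sufficiently large planted domains to host the requested elements")
    }
    host_idx <- if (total_el > 0) sample(hosts_ok, total_el) else integer()
    elements <- purrr::map_dfr(seq_len(total_el), function(i) {
      h <- core[host_idx[i], ]
      w <- round(stats::runif(1, element_length[1], element_length[2]))
      pos <- round(stats::runif(1, h$start + margin, h$end - margin - w))
      tibble::tibble(
        chrom = h$chrom, start = as.integer(pos), end = as.integer(pos + w),
        factor = if (i <= n_elements[["A"]]) "A" else "B",
        level_own = element_level_own, level_other = element_level_other
      )
    })
    if (total_el == 0) {
      elements <- tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        factor = character(), level_own = numeric(), level_other = numeric()
      )
    }

    # Per-factor domain sets: the other factor's domains lose the element bp.
    punch <- function(dom, holes) {
      if (nrow(holes) == 0) {
        return(dom)
      }
      purrr::map_dfr(names(cl), function(ch) {
        d <- dom[dom$chrom == ch, , drop = FALSE]
        h <- holes[holes$chrom == ch, , drop = FALSE]
        if (nrow(d) == 0) {
          return(d[0, ])
        }
        if (nrow(h) == 0) {
          return(d)
        }
        ir <- IRanges::setdiff(tbl_to_ir(d), tbl_to_ir(h))
        ir_to_tbl(ir, ch)
      })
    }
    dom_a <- punch(core, elements[elements$factor == "B", , drop = FALSE])
    dom_b <- punch(core, elements[elements$factor == "A", , drop = FALSE])
    domains <- dplyr::bind_rows(
      dom_a |> dplyr::mutate(factor = "A"),
      dom_b |> dplyr::mutate(factor = "B")
    ) |>
      dplyr::mutate(level = domain_level) |>
      dplyr::arrange(.data$factor, .data$chrom, .data$start)

    # Detached regions: whole core domains (element-free) that factor A
    # abandons in the mutant.
    free_idx <- setdiff(seq_len(nrow(core)), host_idx)
    if (n_detached > length(free_idx)) {
      rlang::abort("not enough element-free domains to mark as detached")
    }
    det_idx <- if (n_detached > 0) sample(free_idx, n_detached) else integer()
    detached <- core[sort(det_idx), c("chrom", "start", "end")]

    structure(
      list(
        domains = domains, elements = elements, detached = detached,
        arms = arms[c("chrom", "start", "end", "region")]
      ),
      class = "ne_architecture",
      params = list(
        arm_density = arm_density, center_density = center_density,
        domain_level = domain_level, element_level_own = element_level_own,
        element_level_other = element_level_other, seed = seed
      )
    )
  })
}

#' @export
print.ne_architecture <- function(x, ...) {
  cat("<ne_architecture>\n")
  cat(sprintf(
    "  %d domain intervals per factor (A: %d, B: %d)\n",
    nrow(x$domains), sum(x$domains$factor == "A"), sum(x$domains$factor == "B")
  ))
  cat(sprintf(
    "  %d exclusive elements (A-only: %d, B-only: %d), %d detached regions\n",
    nrow(x$elements), sum(x$elements$factor == "A"),
    sum(x$elements$factor == "B"), nrow(x$detached)
  ))
  invisible(x)
}

#' Latent mean signal of a planted architecture
#'
#' The noise-free per-probe mean track for one factor and genotype: the
#' planted level inside that factor's domains, the element levels inside
#' exclusive elements, zero elsewhere. In the mutant genotype factor A's
#' detached regions drop to zero.
#'
#' @param layout Probe layout.
#' @param architecture An `ne_architecture`.
#' @param factor `"A"` or `"B"`.
#' @param genotype `"wt"` or `"mutant"`.
#' @return Numeric vector of per-probe means, aligned with `layout` rows.
#' @export
latent_mean <- function(layout, architecture, factor = c("A", "B"),
                        genotype = c("wt", "mutant")) {
  factor <- match.arg(factor)
  genotype <- match.arg(genotype)
  mu <- numeric(nrow(layout))
  dom <- architecture$domains |> dplyr::filter(.data$factor == !!factor)
  mu[overlaps_any(layout, dom)] <- dom$level[1] %||% 0
  if (genotype == "mutant" && factor == "A" && nrow(architecture$detached) > 0) {
    mu[overlaps_any(layout, architecture$detached)] <- 0
  }
  el <- architecture$elements
  if (nrow(el) > 0) {
    own <- el[el$factor == factor, , drop = FALSE]
    oth <- el[el$factor != factor, , drop = FALSE]
    if (nrow(own) > 0) mu[overlaps_any(layout, own)] <- own$level_own[1]
    if (nrow(oth) > 0) mu[overlaps_any(layout, oth)] <- oth$level_other[1]
  }
  mu
}

#' Probe-level noise model for simulated DamID tracks
#'
#' @param sd Stationary standard deviation of the AR(1) probe noise
#'   (score units).
#' @param ar1 Lag-1 autocorrelation coefficient in \[0, 1).
#' @param gc_slope Linear GC bias: score units per GC count, applied to the
#'   mean-centered GC count (so the bias itself has zero genome-wide mean).
#' @param n_reps Number of biological replicates to simulate.
#' @param seed Integer seed fixing all draws.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sd = 0.5, ar1 = 0.5, gc_slope = 0.02, n_reps = 3, seed = 1) {
  if (sd < 0) rlang::abort("noise sd must be >= 0")
  if (ar1 < 0 || ar1 >= 1) rlang::abort("ar1 must lie in [0, 1)")
  if (n_reps < 1) rlang::abort("n_reps must be >= 1")
  structure(
    list(sd = sd, ar1 = ar1, gc_slope = gc_slope, n_reps = n_reps, seed = seed),
    class = "noise_model"
  )
}

# Stationary AR(1) draw: x1 ~ N(0,1), x_t = rho x_{t-1} + sqrt(1-rho^2) e_t,
# scaled to stationary standard deviation `sd`.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) {
    return(numeric(n))
  }
  eps <- stats::rnorm(n)
  if (rho == 0) {
    return(sd * eps)
  }
  x <- numeric(n)
  x[1] <- eps[1]
  if (n > 1) {
    x[-1] <- as.numeric(
      stats::filter(sqrt(1 - rho^2) * eps[-1], rho, method = "recursive", init = x[1])
    )
  }
  sd * x
}

#' Simulate replicate DamID tracks plus a null control
#'
#' Produces per-probe log-ratio scores: planted latent mean, plus a linear
#' GC bias, plus AR(1) Gaussian noise, for each replicate. The null control
#' emulates a control-vs-control self-comparison: latent mean zero
#' everywhere, same bias and noise law.
#'
#' @param layout Probe layout from [make_genome()].
#' @param architecture Planted truth from [plant_architecture()].
#' @param noise A [noise_model()].
#' @param factor Which factor's track to simulate (`"A"` or `"B"`).
#' @param genotype `"wt"` or `"mutant"` (mutant drops factor-A detached
#'   regions to zero).
#' @return A list with elements `signal` and `null`, each a probe-track
#'   tibble (`chrom`, `start`, `end`, `gc`, `rep1`..`repK`).
#' @export
simulate_damid <- function(layout, architecture, noise = noise_model(),
                           factor = c("A", "B"), genotype = c("wt", "mutant")) {
  factor <- match.arg(factor)
  genotype <- match.arg(genotype)
  if (!inherits(noise, "noise_model")) rlang::abort("noise must be a noise_model()")
  mu <- latent_mean(layout, architecture, factor, genotype)
  gc_bias <- noise$gc_slope * (layout$gc - mean(layout$gc))
  n_by_chrom <- rle(layout$chrom)$lengths
  make_track <- function(mean_vec, seed_offset) {
    withr::with_seed(noise$seed + seed_offset, {
      reps <- purrr::map(seq_len(noise$n_reps), function(r) {
        e <- unlist(purrr::map(n_by_chrom, ar1_noise, sd = noise$sd, rho = noise$ar1))
        mean_vec + gc_bias + e
      })
      names(reps) <- paste0("rep", seq_len(noise$n_reps))
      dplyr::bind_cols(
        layout[c("chrom", "start", "end", "gc")],
        tibble::as_tibble(reps)
      )
    })
  }
  offset <- switch(paste(factor, genotype),
    "A wt" = 0L, "B wt" = 1000L, "A mutant" = 2000L, "B mutant" = 3000L
  )
  list(
    signal = make_track(mu, offset),
    null = make_track(numeric(nrow(layout)), 9000L)
  )
}

#' Generate synthetic gene models
#'
#' Random non-overlapping gene spans with 1--8 exons, strand, and tissue
#' labels, for occupancy, enrichment and expression simulations.
#'
#' @param layout Probe layout (or named chromosome length vector).
#' @param n Number of genes to attempt (overlapping draws are discarded).
#' @param mean_length Mean gene length (bp).
#' @param tissues Character vector of tissue labels sampled per gene.
#' @param tissue_prob Sampling probabilities for `tissues`.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`, `tissue`,
#'   `exons` (list column of start/end tibbles in absolute coordinates).
#' @export
make_genes <- function(layout, n = 200, mean_length = 2500,
                       tissues = c(
                         "muscle", "intestine", "serpentine", "neuron",
                         "germline", "ubiquitous", "none"
                       ),
                       tissue_prob = c(0.08, 0.1, 0.06, 0.06, 0.12, 0.08, 0.5),
                       seed = 1) {
  cl <- as_chrom_lengths(layout)
  withr::with_seed(seed, {
    n_try <- 3L * n # oversample; overlapping draws are discarded below
    chroms <- sample(names(cl), n_try, replace = TRUE, prob = unname(cl) / sum(cl))
    lens <- pmax(300, round(stats::rlnorm(n_try, log(mean_length), 0.6)))
    starts <- purrr::map2_int(chroms, lens, function(ch, l) {
      as.integer(floor(stats::runif(1, 0, max(1, cl[[ch]] - l))))
    })
    genes <- tibble::tibble(
      chrom = chroms, start = starts, end = starts + as.integer(lens),
      strand = sample(c("+", "-"), n_try, replace = TRUE),
      tissue = sample(tissues, n_try, replace = TRUE, prob = tissue_prob)
    ) |> dplyr::arrange(.data$chrom, .data$start)
    # drop overlapping genes, keep first
    keep <- genes |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(ok = .data$start >= dplyr::lag(cummax(.data$end), default = -1L)) |>
      dplyr::ungroup() |>
      dplyr::pull("ok")
    genes <- genes[keep, ]
    if (nrow(genes) > n) {
      genes <- dplyr::arrange(genes[sort(sample(nrow(genes), n)), ], .data$chrom, .data$start)
    }
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    # exon counts around the 4-8 typical of compact metazoan genes, capped
    # for very short spans
    genes$exons <- purrr::pmap(genes[c("start", "end")], function(start, end) {
      len <- end - start
      kmax <- min(8, max(1, len %/% 150))
      k <- if (kmax <= 4) kmax else sample(4:kmax, 1)
      m <- min(2 * (k - 1), len - 1)
      m <- m - (m %% 2) # even number of interior cut points
      cuts <- sort(sample(seq_len(len - 1), m))
      bounds <- c(0, cuts, len)
      ex_start <- start + as.integer(bounds[seq(1, length(bounds) - 1, by = 2)])
      ex_end <- start + as.integer(bounds[seq(2, length(bounds), by = 2)])
      tibble::tibble(start = ex_start, end = ex_end)
    })
    genes[c("gene_id", "chrom", "start", "end", "strand", "tissue", "exons")]
  })
}

#' Simulate per-exon expression coverage with planted de-repression
#'
#' Every gene gets a baseline mean exon coverage; genes overlapping the
#' architecture's detached (released) intervals get `baseline * fold` in the
#' non-reference groups, emulating transcriptional de-repression when the
#' locus leaves the nuclear envelope. Noise is a gamma-Poisson mixture per
#' exon; `dispersion = 0` is exactly noise-free.
#'
#' @param genes Gene models from [make_genes()].
#' @param architecture An `ne_architecture` (its `detached` intervals define
#'   the de-repressed set).
#' @param baseline Mean exon coverage in the reference group.
#' @param derepression_fold Fold increase for de-repressed genes in
#'   non-reference groups; must be > 0.
#' @param dispersion Gamma-Poisson dispersion (0 = deterministic).
#' @param groups Named integer vector of replicates per group; the first
#'   group is the reference (wild type) and must have >= 2 samples, as must
#'   every other group.
#' @param seed Integer seed.
#' @return Long tibble `locus`, `exon`, `chrom`, `start`, `end`, `sample`,
#'   `group`, `coverage`, with the planted de-repressed gene ids in the
#'   `derepressed` attribute.
#' @export
simulate_expression <- function(genes, architecture, baseline = 50,
                                derepression_fold = 4, dispersion = 0.05,
                                groups = c(wt = 3, mutant = 2), seed = 1) {
  if (derepression_fold <= 0) rlang::abort("derepression_fold must be > 0")
  if (any(groups < 2)) rlang::abort("each group needs >= 2 samples")
  if (any(purrr::map_int(genes$exons, nrow) == 0)) {
    rlang::abort("gene with zero exons cannot be simulated")
  }
  dere <- genes$gene_id[overlaps_any(genes, architecture$detached)]
  exons <- genes |>
    dplyr::select("gene_id", "chrom", "exons") |>
    tidyr::unnest("exons") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon = paste0(.data$gene_id, ".e", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::rename(locus = "gene_id")
  samples <- tibble::tibble(
    group = rep(names(groups), groups),
    sample = paste0(rep(names(groups), groups), unlist(purrr::map(groups, seq_len)))
  )
  ref <- names(groups)[1]
  withr::with_seed(seed, {
    out <- tidyr::crossing(exons, samples) |>
      dplyr::mutate(
        m = baseline *
          ifelse(.data$locus %in% dere & .data$group != ref, derepression_fold, 1)
      )
    out$coverage <- if (dispersion == 0) {
      out$m
    } else {
      lam <- stats::rgamma(nrow(out), shape = 1 / dispersion, rate = 1 / (out$m * dispersion))
      as.numeric(stats::rpois(nrow(out), lam))
    }
    structure(
      out[c("locus", "exon", "chrom", "start", "end", "sample", "group", "coverage")],
      derepressed = dere
    )
  })
}

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x
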