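#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators in one
#' validated object. Defaults reproduce the study conditions: two patient
#' cohorts of 90 and 110, five highly co-expressed cluster miRNAs
#' (pairwise correlation 0.85, inside the observed 0.74-0.93 range),
#' proportional-hazards outcomes with hazard ratio 0.40 per score unit, a
#' ~30% event rate by 60 months, recurrence-site mix 21/20/59%
#' central/lateral/distant, planted targets at Spearman rho -0.5 among
#' 2000 candidate genes, the 200/400/700/1000 s/mm^2 diffusion protocol,
#' and xenograft growth with treatment-induced delays of 20 vs 4 days for
#' the overexpressing vs control line.
#'
#' @param seed master seed; every generator derives its stream from it.
#' @param n_patients named integer vector, patients per cohort.
#' @param n_mirnas number of score miRNAs (default 5).
#' @param inter_mirna_rho pairwise correlation of the miRNAs on log2
#'   scale, in (0, 1).
#' @param mirna_mean,mirna_sd marginal mean and sd of log2 expression.
#' @param log_hr_score log hazard ratio per unit score (default
#'   log(0.40)).
#' @param event_rate baseline event probability by `censor_months`
#'   (default 0.30).
#' @param site_mix named probabilities (central, lateral, distant)
#'   summing to 1.
#' @param censor_months administrative censoring horizon (default 60).
#' @param followup_range months of follow-up, drawn uniformly.
#' @param n_genes,n_true_targets candidate gene pool and planted targets.
#' @param target_rho planted Spearman correlation, in (-1, 0).
#' @param dwi_shape,b_values,s0,dwi_noise_sd,adc_viable,adc_necrotic,
#'   necrosis_fraction diffusion-phantom parameters (noise sd on the
#'   signal scale; s0/dwi_noise_sd is the SNR).
#' @param histo_shape,n_nuclei,n_touching_pairs,n_necrotic_nuclei,
#'   nucleus_radius,histo_necrosis_fraction,hypoxia_fraction,gfp_fraction
#'   histology-phantom parameters (radius in px, fractions of ROI/viable
#'   area).
#' @param td_days named doubling times (days) per line;
#'   `delay_days` named post-irradiation growth delays per line;
#'   `n_tumors_per_group` tumors per line x irradiation group;
#'   `growth_days` measurement days; `growth_noise_sd` lognormal
#'   measurement noise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = c(explorative = 90L, validation = 110L),
                       n_mirnas = 5L,
                       inter_mirna_rho = 0.85,
                       mirna_mean = 8, mirna_sd = 1,
                       log_hr_score = log(0.40),
                       event_rate = 0.30,
                       site_mix = c(central = 0.21, lateral = 0.20,
                                    distant = 0.59),
                       censor_months = 60,
                       followup_range = c(36, 90),
                       n_genes = 2000L, n_true_targets = 50L,
                       target_rho = -0.5,
                       dwi_shape = c(64L, 64L),
                       b_values = c(200, 400, 700, 1000),
                       s0 = 1000, dwi_noise_sd = 50,
                       adc_viable = 8e-4, adc_necrotic = 1.4e-3,
                       necrosis_fraction = 0.25,
                       histo_shape = c(256L, 256L),
                       n_nuclei = 70L, n_touching_pairs = 6L,
                       n_necrotic_nuclei = 10L, nucleus_radius = 7L,
                       histo_necrosis_fraction = 0.20,
                       hypoxia_fraction = 0.15,
                       gfp_fraction = 0.90,
                       td_days = c(mir = 4.5, control = 4.5),
                       delay_days = c(mir = 20, control = 4),
                       n_tumors_per_group = 8L,
                       growth_days = seq(0, 40, by = 2),
                       growth_noise_sd = 0.05) {
  if (abs(sum(site_mix) - 1) > 1e-12) stop("site_mix must sum to 1")
  if (any(c(n_patients, n_mirnas, n_genes, n_true_targets,
            n_tumors_per_group) < 0)) {
    stop("counts must be non-negative")
  }
  if (n_true_targets > n_genes) stop("n_true_targets must be <= n_genes")
  if (abs(target_rho) >= 1) stop("target_rho must be in (-1, 0)")
  if (target_rho >= 0) stop("target_rho must be negative")
  if (inter_mirna_rho <= 0 || inter_mirna_rho >= 1) {
    stop("inter_mirna_rho must be in (0, 1)")
  }
  if (dwi_noise_sd < 0 || growth_noise_sd < 0) {
    stop("noise sd must be non-negative")
  }
  if (event_rate <= 0 || event_rate >= 1) stop("event_rate must be in (0,1)")
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic sub-stream: each generator stage draws from its own seed
# so stages can be re-run independently and outputs are byte-identical for
# equal (config, seed).
stage_seed <- function(config, stage, index = 0L) {
  offsets <- c(cohort = 101L, genes = 211L, sets = 307L, dwi = 401L,
               histology = 503L, growth = 601L)
  (config$seed * 1009L + offsets[[stage]] + index * 13L) %% .Machine$integer.max
}

#' Generate a synthetic patient cohort
#'
#' Draws the miRNA expression matrix from a multivariate Gaussian on the
#' log2 scale with the requested inter-member correlation, computes the
#' true score, and simulates exponential proportional-hazards recurrence
#' times with per-patient hazard `lambda0 * exp(log_hr_score * score)`.
#' The recurrence site is a multinomial draw from the site mix,
#' independent of time (one site per patient).
#'
#' @param config a [sim_config()].
#' @param cohort cohort name, one of `names(config$n_patients)`.
#' @return List with `mirna` (expression matrix, miRNAs x patients),
#'   `clinical` (clinical table for [build_endpoint()]), and `truth`
#'   (true score, hazard ratio, baseline hazard).
#' @export
gen_cohort <- function(config, cohort = names(config$n_patients)[1L]) {
  ci <- match(cohort, names(config$n_patients))
  if (is.na(ci)) stop("unknown cohort: ", cohort)
  n <- config$n_patients[[ci]]
  if (n < 10L) stop("need at least 10 patients per cohort")
  k <- config$n_mirnas
  sigma <- matrix(config$inter_mirna_rho, k, k)
  diag(sigma) <- 1
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("requested inter-miRNA correlation is not positive definite")
  })
  set.seed(stage_seed(config, "cohort", ci))
  z <- matrix(stats::rnorm(k * n), k, n)
  expr <- config$mirna_mean + config$mirna_sd * t(ch) %*% z
  rownames(expr) <- if (k == length(MIR200_MEMBERS)) {
    MIR200_MEMBERS
  } else sprintf("miR-sim-%02d", seq_len(k))
  colnames(expr) <- sprintf("%s_P%03d", toupper(substr(cohort, 1, 1)),
                            seq_len(n))
  score <- compute_score(expr, members = rownames(expr))
  lambda0 <- -log(1 - config$event_rate) / config$censor_months
  hazard <- lambda0 * exp(config$log_hr_score * score)
  t_event <- stats::rexp(n, rate = hazard)
  followup <- stats::runif(n, config$followup_range[1L],
                           config$followup_range[2L])
  recurred <- t_event <= followup
  site <- sample(names(config$site_mix), n, replace = TRUE,
                 prob = config$site_mix)
  figo <- sample(c("IB-IIB", "IIIA-IVA"), n, replace = TRUE,
                 prob = c(0.6, 0.4))
  volume <- exp(stats::rnorm(n, log(36.6), 0.6))
  nodes <- stats::rbinom(n, 1L, 0.35)
  hypox <- stats::rnorm(n)
  clinical <- data.frame(
    patient_id = colnames(expr),
    cohort = cohort,
    followup_months = followup,
    recurrence_site = ifelse(recurred, site, NA_character_),
    recurrence_months = ifelse(recurred, t_event, NA_real_),
    figo = figo,
    tumor_volume_cm3 = volume,
    lymph_nodes = nodes,
    hypoxia_score = hypox,
    hypoxia_class = as.character(dichotomize_hypoxia(hypox)),
    stringsAsFactors = FALSE)
  list(mirna = expr, clinical = clinical,
       truth = list(score = score, true_hr = exp(config$log_hr_score),
                    lambda0 = lambda0))
}

#' Generate gene expression with planted miRNA targets
#'
#' Planted target genes are negative linear transforms of a designated
#' miRNA plus Gaussian noise calibrated (via the bivariate-normal
#' rank-correlation identity) so their expected Spearman correlation with
#' that miRNA equals `target_rho`; the remaining genes are independent
#' noise. The candidate map lists every gene as a candidate of every
#' miRNA, mimicking broad database-derived candidate lists.
#'
#' @param config a [sim_config()].
#' @param mirna miRNA expression matrix from [gen_cohort()].
#' @param cohort cohort name (drives the random stream).
#' @param n_true_targets override of `config$n_true_targets` (e.g. 0 for
#'   a null simulation).
#' @param candidate_fraction fraction of the gene pool listed as database
#'   candidates of each miRNA (each miRNA's planted targets are always
#'   included, as a validated database would list them).
#' @return List with `genes` (matrix genes x patients), `truth`
#'   (data frame of planted gene/miRNA assignments), and `candidate_map`
#'   (named list miRNA -> candidate gene ids).
#' @export
gen_gene_expression <- function(config, mirna,
                                cohort = names(config$n_patients)[1L],
                                n_true_targets = config$n_true_targets,
                                candidate_fraction = 0.6) {
  if (n_true_targets > config$n_genes) {
    stop("n_true_targets must be <= n_genes")
  }
  if (abs(config$target_rho) >= 1) stop("|target_rho| must be < 1")
  ci <- match(cohort, names(config$n_patients))
  n <- ncol(mirna)
  set.seed(stage_seed(config, "genes", ci))
  ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  genes <- matrix(stats::rnorm(config$n_genes * n, mean = 6, sd = 1),
                  config$n_genes, n, dimnames = list(ids, colnames(mirna)))
  truth <- data.frame(gene = character(), mirna = character())
  if (n_true_targets > 0L) {
    target_ids <- ids[seq_len(n_true_targets)]
    assigned <- rownames(mirna)[(seq_len(n_true_targets) - 1L) %%
                                  nrow(mirna) + 1L]
    # Spearman rho_s of a bivariate normal with Pearson rho_p is
    # (6/pi) asin(rho_p/2); invert to calibrate the noise level.
    rho_p <- 2 * sin(pi * config$target_rho / 6)
    noise_sd <- config$mirna_sd * sqrt(1 / rho_p^2 - 1)
    for (i in seq_len(n_true_targets)) {
      m <- mirna[assigned[i], ]
      genes[target_ids[i], ] <- 6 - (m - config$mirna_mean) +
        stats::rnorm(n, sd = noise_sd)
    }
    truth <- data.frame(gene = target_ids, mirna = assigned,
                        stringsAsFactors = FALSE)
  }
  # candidate lists mimic a target database: a broad per-miRNA subset of
  # the gene pool, always containing that miRNA's planted targets. The
  # draw is keyed to the config (not the cohort) so both cohorts share
  # one database.
  set.seed(stage_seed(config, "genes", 0L))
  n_cand <- round(candidate_fraction * config$n_genes)
  candidate_map <- lapply(rownames(mirna), function(mi) {
    cand <- sample(ids, n_cand)
    sort(unique(c(cand, truth$gene[truth$mirna == mi])))
  })
  names(candidate_map) <- rownames(mirna)
  list(genes = genes, truth = truth, candidate_map = candidate_map)
}

#' Generate a gene-set collection with one planted enriched set
#'
#' Builds `n_sets` random gene sets plus one planted set drawing the
#' requested fraction of its members from the true-target list, for
#' exercising over-representation analysis with known ground truth.
#'
#' @param gene_ids universe of gene ids.
#' @param true_targets ids the planted set is enriched for.
#' @param n_sets number of random (non-planted) sets.
#' @param planted_set_fraction fraction of the planted set drawn from
#'   `true_targets`, in \[0, 1\].
#' @param set_size size range of the random sets.
#' @param planted_size size of the planted set.
#' @param seed integer seed.
#' @return Named list of gene sets with attributes `category` (named
#'   vector) and `planted` (name of the planted set, absent when
#'   `true_targets` is empty).
#' @export
gen_gene_sets <- function(gene_ids, true_targets = character(),
                          n_sets = 50L, planted_set_fraction = 0.8,
                          set_size = c(10L, 100L), planted_size = 40L,
                          seed = 1L) {
  if (!length(gene_ids)) stop("gene ids must be non-empty")
  if (planted_set_fraction < 0 || planted_set_fraction > 1) {
    stop("planted_set_fraction must be in [0, 1]")
  }
  set.seed(seed)
  sets <- list()
  if (n_sets > 0L) {
    sizes <- sample(seq(set_size[1L], set_size[2L]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(s) sample(gene_ids, min(s,
                                                           length(gene_ids))))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  }
  planted_name <- NULL
  if (length(true_targets)) {
    k_true <- min(round(planted_set_fraction * planted_size),
                  length(true_targets))
    # when fewer targets exist than requested, shrink the set so the
    # realized target fraction still matches the request
    n_other <- if (planted_set_fraction > 0) {
      round(k_true * (1 - planted_set_fraction) / planted_set_fraction)
    } else planted_size
    rest <- setdiff(gene_ids, true_targets)
    planted <- c(sample(true_targets, k_true),
                 if (n_other > 0L) sample(rest, min(n_other, length(rest))))
    sets <- c(stats::setNames(list(planted), "PLANTED_SET"), sets)
    planted_name <- "PLANTED_SET"
  }
  cats <- sample(c("process", "component", "function", "pathway"),
                 length(sets), replace = TRUE)
  attr(sets, "category") <- stats::setNames(cats, names(sets))
  attr(sets, "planted") <- planted_name
  sets
}

#' Generate a diffusion-weighted phantom
#'
#' Mono-exponential decay S(b) = S0 exp(-b ADC) with additive Gaussian
#' signal noise, over a circular tumor ROI containing a necrotic blob of
#' elevated ADC occupying exactly the requested fraction of the ROI (to
#' one-voxel rounding, by construction).
#'
#' @param config a [sim_config()].
#' @param noise_sd override of `config$dwi_noise_sd` (0 for a noiseless
#'   phantom).
#' @return List with `series` (a [dwi_series()]) and `truth` (true ADC
#'   map, necrosis mask, necrotic fraction).
#' @export
gen_dwi <- function(config, noise_sd = config$dwi_noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (length(unique(config$b_values)) < 2L) {
    stop("need at least 2 distinct b-values")
  }
  nx <- config$dwi_shape[1L]; ny <- config$dwi_shape[2L]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  dist_c <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  roi <- dist_c <= 0.4 * min(nx, ny)
  n_roi <- sum(roi)
  k <- round(config$necrosis_fraction * n_roi)
  # exact-count necrotic blob: the k ROI voxels closest to a seed point
  seed_pt <- c(cx + 0.15 * nx, cy)
  dist_seed <- sqrt(outer((seq_len(nx) - seed_pt[1L])^2,
                          (seq_len(ny) - seed_pt[2L])^2, "+"))
  necro <- matrix(FALSE, nx, ny)
  if (k > 0L) {
    roi_idx <- which(roi)
    necro[roi_idx[order(dist_seed[roi])[seq_len(k)]]] <- TRUE
  }
  adc_true <- matrix(config$adc_viable, nx, ny)
  adc_true[necro] <- config$adc_necrotic
  set.seed(stage_seed(config, "dwi"))
  nb <- length(config$b_values)
  sig <- array(0, dim = c(nx, ny, nb))
  for (i in seq_len(nb)) {
    sig[, , i] <- config$s0 * exp(-config$b_values[i] * adc_true) +
      if (noise_sd > 0) stats::rnorm(nx * ny, sd = noise_sd) else 0
  }
  list(series = dwi_series(sig, config$b_values, roi = roi),
       truth = list(adc_true = adc_true, necrosis = necro,
                    necrotic_fraction = k / n_roi))
}

# draw disc pixel coordinates around a center
disc_mask <- function(shape, cx, cy, r) {
  xr <- max(1L, floor(cx - r)):min(shape[1L], ceiling(cx + r))
  yr <- max(1L, floor(cy - r)):min(shape[2L], ceiling(cy + r))
  sub <- outer((xr - cx)^2, (yr - cy)^2, "+") <= r^2
  cbind(rep(xr, times = length(yr))[as.vector(sub)],
        rep(yr, each = length(xr))[as.vector(sub)])
}

#' Generate a synthetic histology scene
#'
#' Renders adjacent-section stain images through the H-DAB forward model:
#' a Ki-67 section with disc nuclei (including deliberately touching
#' pairs that exceed the cluster-area rule, and nuclei placed in
#' necrosis), a GFP section marking tumor parenchyma, and a pimonidazole
#' section marking hypoxia. Necrotic, hypoxic and GFP-positive regions
#' occupy exact pixel counts so the downstream fractions have known
#' truth.
#'
#' @param config a [sim_config()].
#' @param quantize round rendered images to 8-bit (default TRUE; FALSE
#'   keeps exact float values for round-trip checks).
#' @return List with `images` (ki67, gfp, pimonidazole RGB arrays),
#'   `masks` (roi, necrosis, hypoxia, gfp), and `truth` (expected nucleus
#'   count inside viable parenchyma, per-region fractions, all nucleus
#'   centers).
#' @export
gen_histology <- function(config, quantize = TRUE) {
  shape <- config$histo_shape
  roi <- matrix(TRUE, shape[1L], shape[2L])
  npix <- prod(shape)
  # necrosis: exact pixel count, leading columns (column-major order)
  k_nec <- round(config$histo_necrosis_fraction * npix)
  necro <- matrix(FALSE, shape[1L], shape[2L])
  if (k_nec > 0L) necro[seq_len(k_nec)] <- TRUE
  viable_idx <- which(!necro)
  k_hyp <- round(config$hypoxia_fraction * length(viable_idx))
  hypox <- matrix(FALSE, shape[1L], shape[2L])
  if (k_hyp > 0L) hypox[viable_idx[seq_len(k_hyp)]] <- TRUE
  k_gfp <- round(config$gfp_fraction * length(viable_idx))
  gfp <- matrix(FALSE, shape[1L], shape[2L])
  if (k_gfp > 0L) {
    gfp[viable_idx[seq(length(viable_idx), by = -1L,
                       length.out = k_gfp)]] <- TRUE
  }
  r <- config$nucleus_radius
  set.seed(stage_seed(config, "histology"))
  place <- function(n, region, min_dist, existing) {
    centers <- existing
    tries <- 0L
    while (nrow(centers) - nrow(existing) < n && tries < 20000L) {
      tries <- tries + 1L
      cx <- stats::runif(1, r + 1, shape[1L] - r - 1)
      cy <- stats::runif(1, r + 1, shape[2L] - r - 1)
      if (!region[round(cx), round(cy)]) next
      if (nrow(centers) &&
          min(sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)) <
            min_dist) next
      centers <- rbind(centers, c(cx, cy))
    }
    centers
  }
  core_parenchyma <- gfp & !necro & !hypox
  none <- matrix(numeric(), 0L, 2L)
  sep <- 2 * r + 4
  # touching pairs go in first (second disc at 1.7 r from the first: the
  # union is one overlapping component above the cluster-area rule whose
  # two distance-transform maxima stay clearly separated after
  # pixelation); the base is placed with the partner offset added to the
  # exclusion radius so the appended partner also keeps its distance from
  # everything
  pair_off <- 1.7 * r
  pair_region <- core_parenchyma
  margin <- ceiling(pair_off + r) + 2L
  pair_region[(shape[1L] - margin):shape[1L], ] <- FALSE
  pairs <- none
  for (i in seq_len(config$n_touching_pairs)) {
    n_before <- nrow(pairs)
    pairs <- place(1L, pair_region, sep + pair_off, pairs)
    if (nrow(pairs) == n_before) next
    base <- pairs[nrow(pairs), ]
    pairs <- rbind(pairs, base + c(pair_off, 0))
  }
  n_placed_pairs <- nrow(pairs)
  with_singles <- place(config$n_nuclei, core_parenchyma, sep, pairs)
  n_placed_singles <- nrow(with_singles) - n_placed_pairs
  all_centers <- place(config$n_necrotic_nuclei, necro, sep, with_singles)
  n_placed_nec <- nrow(all_centers) - nrow(with_singles)
  nuc <- matrix(FALSE, shape[1L], shape[2L])
  for (i in seq_len(nrow(all_centers))) {
    nuc[disc_mask(shape, all_centers[i, 1L], all_centers[i, 2L], r)] <- TRUE
  }
  render <- function(dab_mask, hema_conc = 0.25) {
    render_stains(matrix(hema_conc, shape[1L], shape[2L]),
                  dab_mask * 1.0, quantize = quantize)
  }
  list(images = list(ki67 = render(nuc),
                     gfp = render(gfp),
                     pimonidazole = render(hypox)),
       masks = list(roi = roi, necrosis = necro, hypoxia = hypox,
                    gfp = gfp, nuclei = nuc),
       truth = list(
         n_nuclei_parenchyma = n_placed_singles + n_placed_pairs,
         n_singles = n_placed_singles,
         n_pairs = n_placed_pairs / 2L,
         n_necrotic_nuclei = n_placed_nec,
         necrotic_fraction = k_nec / npix,
         hypoxic_fraction = k_hyp / length(viable_idx),
         gfp_fraction = k_gfp / length(viable_idx),
         centers = all_centers))
}

#' Generate xenograft growth curves
#'
#' Exponential growth V(t) = V0 2^((t - delay)+ / Td) with a per-line
#' post-irradiation delay during which the volume is static, and
#' multiplicative lognormal measurement noise. With linear T1.5x
#' interpolation the built-in growth delay equals the line's `delay_days`
#' and the enhancement factor equals their ratio.
#'
#' @param config a [sim_config()].
#' @param noise_sd override of `config$growth_noise_sd`.
#' @return List with `curves` (long data frame: tumor, line, irradiated,
#'   day, volume_mm3) and `truth` (per-line Td, delay, expected EF).
#' @export
gen_growth <- function(config, noise_sd = config$growth_noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(stage_seed(config, "growth"))
  lines <- names(config$td_days)
  rows <- list()
  for (ln in lines) {
    for (irr in c(FALSE, TRUE)) {
      delay <- if (irr) config$delay_days[[ln]] else 0
      for (i in seq_len(config$n_tumors_per_group)) {
        v0 <- exp(stats::rnorm(1, log(250), 0.2))
        t_eff <- pmax(config$growth_days - delay, 0)
        v <- v0 * 2^(t_eff / config$td_days[[ln]])
        if (noise_sd > 0) {
          v <- v * exp(stats::rnorm(length(v), sd = noise_sd))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          tumor = sprintf("%s_%s_%02d", ln, if (irr) "irr" else "unirr", i),
          line = ln, irradiated = irr, day = config$growth_days,
          volume_mm3 = v, stringsAsFactors = FALSE)
      }
    }
  }
  curves <- do.call(rbind, rows)
  ef_true <- if (config$delay_days[["control"]] > 0) {
    config$delay_days[["mir"]] / config$delay_days[["control"]]
  } else NA_real_
  list(curves = curves,
       truth = list(td_days = config$td_days,
                    delay_days = config$delay_days, ef = ef_true))
}
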