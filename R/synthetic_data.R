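# Synthetic datasets with the statistical structure the analysis assumes:
# multi-donor, multi-t-type cells; negative-binomial counts with library-size
# variation; overlapping gene sets; a latent cell-size factor that jointly
# elevates total dendritic length, AP rise speed and a planted gene module;
# and spike traces with closed-form derivatives. Every draw flows from one
# seed via keyed substreams, so adding cells or genes to a config does not
# perturb unrelated draws.

#' Synthetic dataset configuration
#'
#' Defaults emulate a Patch-seq-like study: a few donors, five L2/L3
#' glutamatergic t-types with preferred cortical depths, ~5e5 counts per cell
#' over the simulated gene universe, log-normal baseline abundances and
#' negative-binomial counts. A latent per-cell size factor `z` (standard
#' normal around a t-type shift) jointly drives total dendritic length
#' (log-linear), AP rise speed (linear) and the planted genes
#' (log-linear fold change `exp(beta_g z)`).
#'
#' @param n_donors number of donors (cells cycle over donors), default 3.
#' @param t_types `data.frame` with `name`, `depth_min`, `depth_max`
#'   (relative L2/L3 depth range per type).
#' @param n_cells_per_type cells per t-type (scalar or per-type vector).
#' @param type_effects named additive shifts of the latent factor per t-type
#'   (elevated in the large deep-L3 types by default).
#' @param n_genes size of the simulated gene universe.
#' @param library_size list `mean` (expected counts per cell) and `cv`
#'   (log-normal coefficient of variation).
#' @param baseline_expression list `mean`, `sd` of per-gene log10 abundance;
#'   after drawing, baselines are shifted so total abundance is 1e6, making
#'   them true expected log10 CPM (the `mean` sets only the pre-shift
#'   location; `sd` sets the spread). A fraction `prop_low` of genes is
#'   shifted down by `low_shift` log10 units, emulating genes the cell type
#'   barely expresses (these produce >95% zeros and exercise the prevalence
#'   filter).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion mu^2`; size = 1/dispersion).
#' @param sets list: `names`, `sizes`, `pairwise_overlap` (fractions of the
#'   smaller set for pairs AB, AC, BC), `triple_overlap`; a single size makes
#'   one set with no overlap structure.
#' @param planted list: `n_per_set` planted genes per set, `target_r`
#'   (gene-phenotype correlation on the log10(CPM+1) scale, against the
#'   linear AP phenotype), `prop_positive` sign mix, `baseline_range`
#'   (log10 abundance range planted genes are re-drawn from, keeping them
#'   comfortably expressed), optional `bias_set`/`bias_factor` to draw
#'   planted genes preferentially from one set's members.
#' @param phenotype list: `tdl_base` (um), `tdl_slope` (per unit z),
#'   `tdl_noise` (multiplicative SD), `ap_base` (V/s), `ap_slope` (V/s per
#'   unit z), `ap_noise` (V/s), `couple` (FALSE gives TDL its own latent
#'   factor).
#' @param seed master seed for all substreams.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_donors = 3,
    t_types = data.frame(
      name = c("LTK", "FREM3", "GLP2R", "CARM1P1", "COL22A1"),
      depth_min = c(0.0, 0.0, 0.3, 0.6, 0.6),
      depth_max = c(0.3, 1.0, 0.6, 1.0, 1.0),
      stringsAsFactors = FALSE
    ),
    n_cells_per_type = 50,
    type_effects = c(LTK = -0.6, FREM3 = 0.3, GLP2R = -0.3,
                     CARM1P1 = 0.8, COL22A1 = -0.2),
    n_genes = 2000,
    library_size = list(mean = 5e5, cv = 0.3),
    baseline_expression = list(mean = 0.8, sd = 0.8, prop_low = 0.1,
                               low_shift = -3),
    nb_dispersion = 0.5,
    sets = list(names = c("IQ", "EA", "HAR"), sizes = c(100, 100, 100),
                pairwise_overlap = c(0.25, 0.14, 0.19), triple_overlap = 0.08),
    planted = list(n_per_set = 20, target_r = 0.6, prop_positive = 0.7,
                   baseline_range = c(1.0, 2.5), bias_set = NULL,
                   bias_factor = 1),
    phenotype = list(tdl_base = 6000, tdl_slope = 0.35, tdl_noise = 0.15,
                     ap_base = 350, ap_slope = 60, ap_noise = 30,
                     couple = TRUE),
    seed = 1) {
  if (n_donors < 1) ps_stop("n_donors must be >= 1")
  if (!all(c("name", "depth_min", "depth_max") %in% names(t_types))) {
    ps_stop("t_types needs columns name, depth_min, depth_max")
  }
  n_types <- nrow(t_types)
  n_cells_per_type <- rep_len(as.integer(n_cells_per_type), n_types)
  if (any(n_cells_per_type < 1)) ps_stop("n_cells_per_type must be positive")
  missing_eff <- setdiff(t_types$name, names(type_effects))
  if (length(missing_eff)) {
    type_effects[missing_eff] <- 0
  }
  if (n_genes < 2) ps_stop("n_genes must be >= 2")
  if (abs(planted$target_r) >= 1) ps_stop("target |r| must be < 1")
  if (planted$n_per_set > 0 && !is.null(sets) &&
      planted$n_per_set > min(sets$sizes)) {
    ps_stop("more planted genes per set (%d) than the smallest set (%d)",
            planted$n_per_set, min(sets$sizes))
  }
  structure(
    list(n_donors = as.integer(n_donors), t_types = t_types,
         n_cells_per_type = n_cells_per_type,
         type_effects = type_effects[t_types$name],
         n_genes = as.integer(n_genes), library_size = library_size,
         baseline_expression = baseline_expression,
         nb_dispersion = nb_dispersion, sets = sets, planted = planted,
         phenotype = phenotype, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate gene sets with controlled pairwise overlaps
#'
#' Region sizes are fixed from the overlap fractions (rounded against the
#' smaller set of each pair), then members are sampled without replacement
#' from the gene universe, so realized overlap counts match the rounded
#' targets exactly.
#'
#' @param n_genes universe size (symbols `G00001`, ...), or pass `universe`.
#' @param universe optional explicit character vector of symbols.
#' @param names set names; 1 or 3 sets supported.
#' @param sizes set sizes.
#' @param pairwise_overlap overlap fractions for pairs (AB, AC, BC), each
#'   applied to the smaller set of the pair; ignored for a single set.
#' @param triple_overlap fraction of the smallest set shared by all three.
#' @param seed substream seed.
#' @return A list of [gene_set()] objects.
#' @export
generate_gene_sets <- function(n_genes = NULL, universe = NULL,
                               names = c("IQ", "EA", "HAR"),
                               sizes = c(100, 100, 100),
                               pairwise_overlap = c(0.25, 0.14, 0.19),
                               triple_overlap = 0.08, seed = 1) {
  if (is.null(universe)) {
    if (is.null(n_genes)) ps_stop("give n_genes or universe")
    universe <- sprintf("G%05d", seq_len(n_genes))
  }
  k <- length(sizes)
  if (length(names) != k) ps_stop("names and sizes must have equal length")
  if (!k %in% c(1L, 3L)) ps_stop("1 or 3 sets supported, got %d", k)

  if (k == 1L) {
    if (sizes > length(universe)) ps_stop("set larger than the universe")
    members <- with_substream(seed, "sets", sample(universe, sizes))
    return(list(gene_set(names, members)))
  }

  if (any(pairwise_overlap < 0 | pairwise_overlap > 1) ||
      triple_overlap < 0 || triple_overlap > 1) {
    ps_stop("overlap fractions must lie in [0, 1]")
  }
  t3 <- round(triple_overlap * min(sizes))
  pair_min <- c(min(sizes[1], sizes[2]), min(sizes[1], sizes[3]),
                min(sizes[2], sizes[3]))
  pairs <- round(pairwise_overlap * pair_min)
  if (any(pairs < t3)) {
    ps_stop("pairwise overlaps must be >= the triple overlap (%d)", t3)
  }
  ab <- pairs[1] - t3; ac <- pairs[2] - t3; bc <- pairs[3] - t3
  only_a <- sizes[1] - ab - ac - t3
  only_b <- sizes[2] - ab - bc - t3
  only_c <- sizes[3] - ac - bc - t3
  region_sizes <- c(only_a, only_b, only_c, ab, ac, bc, t3)
  if (any(region_sizes < 0)) {
    ps_stop("infeasible overlap specification (a Venn region went negative)")
  }
  total <- sum(region_sizes)
  if (total > length(universe)) {
    ps_stop("sets need %d distinct genes but the universe has %d",
            total, length(universe))
  }
  picked <- with_substream(seed, "sets", sample(universe, total))
  bounds <- cumsum(region_sizes)
  region <- function(i) {
    lo <- if (i == 1L) 1L else bounds[i - 1L] + 1L
    if (region_sizes[i] == 0L) character() else picked[lo:bounds[i]]
  }
  a <- c(region(1), region(4), region(5), region(7))
  b <- c(region(2), region(4), region(6), region(7))
  c_ <- c(region(3), region(5), region(6), region(7))
  list(gene_set(names[1], a), gene_set(names[2], b), gene_set(names[3], c_))
}

# latent-factor SD over the configured cell mix (unit within-type SD plus
# between-type spread of the effects)
latent_sd <- function(config) {
  eff <- rep(config$type_effects, times = config$n_cells_per_type)
  sqrt(1 + mean(eff^2) - mean(eff)^2)
}

# solve the planted-gene log-fold coefficient beta from a beta = 0 pilot:
# on the log10(CPM+1) scale y ~ const + (beta/ln 10) z + e, so
# (beta/ln10) sd_z = r' / sqrt(1 - r'^2) * sigma_e with r' the required
# gene-latent correlation (target r divided by the latent-phenotype r).
calibrate_beta <- function(target_r, sigma_e, sd_z, r_zp) {
  r_needed <- target_r / r_zp
  if (abs(r_needed) >= 1) {
    ps_stop(paste0("target |r| = %.3g is unattainable: phenotype noise caps ",
                   "the gene-phenotype correlation at %.3g"),
            abs(target_r), r_zp)
  }
  log(10) * (r_needed / sqrt(1 - r_needed^2)) * sigma_e / sd_z
}

#' Generate a full synthetic dataset with ground truth
#'
#' Produces a counts matrix, cell metadata, phenotypes, gene sets and a truth
#' record. Planted genes get a log-fold response `exp(beta_g z)` to the
#' latent size factor, with `beta_g` calibrated against a beta = 0 pilot
#' simulation so their log10(CPM+1) correlation with the AP phenotype hits
#' the configured target; an unattainable target (given phenotype noise)
#' raises an error stating the attainable bound. Same config and seed give
#' bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return A list: `matrix` ([expr_matrix()], counts), `metadata`,
#'   `phenotypes`, `gene_sets`, `truth` (list with `planted` data.frame of
#'   gene/set/sign/target_r/beta, `z` per cell, `type_effects`, `seed`).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    ps_stop("expected a synthetic_config")
  }
  seed <- config$seed
  n_genes <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n_genes))

  be <- config$baseline_expression
  baseline <- with_substream(seed, "baselines", {
    b <- rnorm(n_genes, be$mean, be$sd)
    prop_low <- if (is.null(be$prop_low)) 0 else be$prop_low
    if (prop_low > 0) {
      low <- sample(n_genes, round(prop_low * n_genes))
      b[low] <- b[low] + be$low_shift
    }
    b
  })
  # anchor the scale: total abundance 1e6, so baselines are expected log10 CPM
  baseline <- baseline + 6 - log10(sum(10^baseline))
  names(baseline) <- genes

  sets <- if (is.null(config$sets)) list() else {
    generate_gene_sets(universe = genes, names = config$sets$names,
                       sizes = config$sets$sizes,
                       pairwise_overlap = config$sets$pairwise_overlap,
                       triple_overlap = config$sets$triple_overlap,
                       seed = seed)
  }

  # planted genes: per set, weighted draw (optionally biased toward one
  # set's members), then a sign each; first assignment wins on overlap
  planted_gene <- character()
  planted_set <- character()
  planted_sign <- numeric()
  pl <- config$planted
  if (pl$n_per_set > 0 && length(sets)) {
    bias_members <- if (!is.null(pl$bias_set)) {
      mem <- NULL
      for (s in sets) if (s$name == pl$bias_set) mem <- s$members
      if (is.null(mem)) ps_stop("bias_set '%s' is not a generated set",
                                pl$bias_set)
      mem
    }
    for (s in sets) {
      chosen <- with_substream(seed, paste0("planted:", s$name), {
        w <- rep(1, length(s$members))
        if (!is.null(bias_members)) {
          w[s$members %in% bias_members] <- pl$bias_factor
        }
        sample(s$members, pl$n_per_set, prob = w)
      })
      signs <- with_substream(seed, paste0("signs:", s$name), {
        ifelse(runif(pl$n_per_set) < pl$prop_positive, 1, -1)
      })
      new <- !(chosen %in% planted_gene)
      planted_gene <- c(planted_gene, chosen[new])
      planted_set <- c(planted_set, rep(s$name, sum(new)))
      planted_sign <- c(planted_sign, signs[new])
    }
    baseline[planted_gene] <- with_substream(seed, "planted_baselines", {
      runif(length(planted_gene), pl$baseline_range[1], pl$baseline_range[2])
    })
  }

  # cells: deterministic donor cycling, per-cell keyed substreams
  tt <- config$t_types
  n_cells <- sum(config$n_cells_per_type)
  cell_type <- rep(tt$name, times = config$n_cells_per_type)
  cell_id <- sprintf("cell_%s_%03d", cell_type,
                     unlist(lapply(config$n_cells_per_type, seq_len)))
  donor <- sprintf("donor%d", (seq_len(n_cells) - 1L) %% config$n_donors + 1L)

  depth <- numeric(n_cells)
  z <- numeric(n_cells)
  z_tdl <- numeric(n_cells)
  lib <- numeric(n_cells)
  tdl_eps <- numeric(n_cells)
  ap_eps <- numeric(n_cells)
  log_cv <- sqrt(log(1 + config$library_size$cv^2))
  for (i in seq_len(n_cells)) {
    row <- match(cell_type[i], tt$name)
    draws <- with_substream(seed, paste0("cell:", cell_id[i]), {
      list(depth = runif(1, tt$depth_min[row], tt$depth_max[row]),
           z = rnorm(1), z2 = rnorm(1),
           lib = rlnorm(1, log(config$library_size$mean) - log_cv^2 / 2,
                        log_cv),
           tdl_eps = rnorm(1, 0, config$phenotype$tdl_noise),
           ap_eps = rnorm(1, 0, config$phenotype$ap_noise))
    })
    depth[i] <- draws$depth
    z[i] <- config$type_effects[[cell_type[i]]] + draws$z
    z_tdl[i] <- if (isTRUE(config$phenotype$couple)) z[i] else
      config$type_effects[[cell_type[i]]] + draws$z2
    lib[i] <- draws$lib
    tdl_eps[i] <- draws$tdl_eps
    ap_eps[i] <- draws$ap_eps
  }

  ph <- config$phenotype
  tdl <- ph$tdl_base * exp(ph$tdl_slope * z_tdl) * pmax(1 + tdl_eps, 0.05)
  ap <- pmax(ph$ap_base + ph$ap_slope * z + ap_eps, 1)

  # beta calibration from a beta = 0 pilot simulation
  beta <- setNames(numeric(n_genes), genes)
  if (length(planted_gene)) {
    sd_z <- latent_sd(config)
    r_zp <- ph$ap_slope * sd_z / sqrt((ph$ap_slope * sd_z)^2 + ph$ap_noise^2)
    n_pilot <- 300L
    w <- 10^baseline
    p_rel <- w / sum(w)
    sigma_e <- with_substream(seed, "pilot", {
      lib_p <- rlnorm(n_pilot, log(config$library_size$mean) - log_cv^2 / 2,
                      log_cv)
      mu <- outer(lib_p, p_rel)
      cnt <- matrix(rnbinom(n_pilot * n_genes, size = 1 / config$nb_dispersion,
                            mu = mu), n_pilot, n_genes)
      cpm <- cnt / rowSums(cnt) * 1e6
      apply(log10(cpm[, match(planted_gene, genes), drop = FALSE] + 1), 2, sd)
    })
    beta[planted_gene] <- planted_sign *
      calibrate_beta(abs(pl$target_r), sigma_e, sd_z, r_zp)
  }

  w0 <- 10^baseline
  counts <- matrix(0, n_cells, n_genes, dimnames = list(cell_id, genes))
  size_nb <- 1 / config$nb_dispersion
  for (i in seq_len(n_cells)) {
    w <- w0 * exp(beta * z[i])
    mu <- lib[i] * w / sum(w)
    counts[i, ] <- with_substream(seed, paste0("counts:", cell_id[i]), {
      rnbinom(n_genes, size = size_nb, mu = mu)
    })
  }

  metadata <- data.frame(
    cell_id = cell_id, donor_id = donor, area = "MTG",
    cell_class = "glutamatergic", t_type = cell_type,
    relative_depth = depth, stringsAsFactors = FALSE
  )
  phenotypes <- data.frame(cell_id = cell_id, tdl = tdl, ap_rise_speed = ap,
                           stringsAsFactors = FALSE)
  truth <- list(
    planted = data.frame(gene = planted_gene, set = planted_set,
                         sign = ifelse(planted_sign >= 0, "+", "-"),
                         target_r = planted_sign * abs(pl$target_r),
                         beta = unname(beta[planted_gene]),
                         stringsAsFactors = FALSE),
    z = setNames(z, cell_id),
    type_effects = config$type_effects,
    baseline_log10 = baseline,
    seed = seed
  )
  list(matrix = expr_matrix(counts, state = "counts"), metadata = metadata,
       phenotypes = phenotypes, gene_sets = sets, truth = truth)
}

#' Generate current-clamp sweeps with known spike derivatives
#'
#' Each spike is a Gaussian depolarization
#' `v(t) = baseline + A exp(-(t - t0)^2 / (2 s^2))` whose maximum derivative
#' has the closed form `A e^{-1/2} / s` (in V/s when A is in mV and s in
#' seconds, divided by 1000), recorded in the truth table.
#'
#' @param spike_times list with one numeric vector of spike times (s) per
#'   sweep; an empty vector makes a subthreshold sweep.
#' @param amplitudes spike amplitude(s) above baseline in mV (recycled).
#' @param duration sweep duration in seconds.
#' @param sampling_rate Hz, default 50 kHz.
#' @param baseline resting potential in mV.
#' @param spike_sd Gaussian width parameter s, seconds.
#' @param noise_sd additive Gaussian voltage noise SD, mV (0 = clean).
#' @param step_currents stimulus metadata per sweep (pA, recycled).
#' @param seed substream seed for the noise.
#' @return A list: `sweeps` (list of [cc_sweep()]), `truth` (`data.frame`
#'   with `sweep`, `spike_time`, `amplitude`, `max_dvdt` in V/s).
#' @export
generate_traces <- function(spike_times, amplitudes = 100, duration = 0.6,
                            sampling_rate = 5e4, baseline = -70,
                            spike_sd = 3e-4, noise_sd = 0,
                            step_currents = NA_real_, seed = 1) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  n_sweeps <- length(spike_times)
  amplitudes <- rep_len(amplitudes, n_sweeps)
  step_currents <- rep_len(step_currents, n_sweeps)
  time <- seq(0, duration, by = 1 / sampling_rate)

  sweeps <- vector("list", n_sweeps)
  truth_rows <- list()
  for (j in seq_len(n_sweeps)) {
    st <- sort(spike_times[[j]])
    if (any(st < 0 | st > duration)) {
      ps_stop("sweep %d: spike times outside [0, %g] s", j, duration)
    }
    if (length(st) > 1L && any(diff(st) < 8 * spike_sd)) {
      ps_stop("sweep %d: spikes closer than the waveform support (%g s)",
              j, 8 * spike_sd)
    }
    v <- rep(baseline, length(time))
    for (t0 in st) {
      v <- v + amplitudes[j] * exp(-(time - t0)^2 / (2 * spike_sd^2))
    }
    if (noise_sd > 0) {
      v <- v + with_substream(seed, paste0("trace:", j), {
        rnorm(length(time), 0, noise_sd)
      })
    }
    sweeps[[j]] <- cc_sweep(time, v, sampling_rate, step_currents[j])
    if (length(st)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sweep = j, spike_time = st, amplitude = amplitudes[j],
        max_dvdt = amplitudes[j] * exp(-0.5) / spike_sd / 1000
      )
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else {
    data.frame(sweep = integer(), spike_time = numeric(),
               amplitude = numeric(), max_dvdt = numeric())
  }
  list(sweeps = sweeps, truth = truth)
}
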