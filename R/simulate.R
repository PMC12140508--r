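#' Configuration for the synthetic Repli-seq / chromatin / OK-seq generator
#'
#' Collects every tunable of the generator in one validated list. Defaults
#' emulate the study conditions the pipeline is designed for: a two-chromosome
#' 50 Mb-per-chromosome genome in 50 kb bins, three replicates per condition,
#' megabase-scale RT domains, 21 chromatin features of which three are causal
#' for RT, roughly 30% of the genome changing RT during differentiation, and
#' replication origins every ~200 kb whose efficiency responds to the RT
#' change.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param bin_size RT bin width in bp.
#' @param n_replicates Repli-seq replicates per condition.
#' @param depth Expected reads per bin per S-phase fraction.
#' @param noise_sd Replicate-level RT noise (log2 units) added before read
#'   sampling.
#' @param n_features Number of chromatin features profiled.
#' @param causal_weights Numeric vector of true linear weights for the first
#'   `length(causal_weights)` features (CPM per log2-RT unit); remaining
#'   features get weight 0. Feature 1 is the differentiation-coupled feature.
#' @param changed_fraction Fraction of the genome (by bins) with nonzero
#'   latent delta-RT, half shifting earlier and half later.
#' @param delta_magnitude Absolute latent delta-RT (log2 units) in changed
#'   domains.
#' @param coupling Strength linking the coupled feature's EpiLC signal change
#'   to delta-RT (CPM per log2 unit).
#' @param suppression Multiplier applied to both the coupled feature's change
#'   and delta-RT in the "mutant" genotype (0 = complete loss of the
#'   differentiation response, 1 = indistinguishable from control).
#' @param domain_bins_min,domain_bins_max Uniform range of RT-domain lengths
#'   in bins.
#' @param smooth_bins Gaussian kernel sd (in bins) used to round domain edges
#'   into a piecewise-smooth landscape.
#' @param peak_density Probability that a bin carries a peak of a given
#'   feature.
#' @param peak_width Feature peak width in bp.
#' @param peak_baseline Baseline peak signal (CPM).
#' @param peak_noise_sd Per-peak signal noise sd (CPM).
#' @param replicate_signal_sd Replicate-level peak signal noise sd (CPM).
#' @param feature_replicates Peak-calling replicates per feature.
#' @param total_reads Sequenced reads per feature library.
#' @param background_fraction Fraction of feature reads falling outside
#'   peaks (sets the background density).
#' @param origin_spacing Mean distance between replication origins in bp.
#' @param efficiency_range Uniform range of baseline origin efficiencies.
#' @param efficiency_coupling Origin-efficiency shift per unit latent
#'   delta-RT in the EpiLC state.
#' @param okazaki_length_mean,okazaki_length_sd Okazaki fragment length
#'   distribution (bp, normal, truncated at 50 bp).
#' @param n_okazaki_fragments OK-seq fragments sampled per library.
#' @param n_tss Number of transcription start sites for the expression table.
#' @param expression_origin_cor Rank correlation knob between expression and
#'   nearest-origin efficiency (0 = independent).
#' @param seed Master seed; every sub-simulation derives an independent
#'   stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 5e7,
                       bin_size = 5e4,
                       n_replicates = 3,
                       depth = 50,
                       noise_sd = 0.2,
                       n_features = 21,
                       causal_weights = c(1.0, 0.6, -0.8),
                       changed_fraction = 0.3,
                       delta_magnitude = 1.0,
                       coupling = 0.8,
                       suppression = 0,
                       domain_bins_min = 10,
                       domain_bins_max = 40,
                       smooth_bins = 1,
                       peak_density = 0.8,
                       peak_width = 2000,
                       peak_baseline = 4,
                       peak_noise_sd = 0.5,
                       replicate_signal_sd = 0.2,
                       feature_replicates = 2,
                       total_reads = 1e6,
                       background_fraction = 0.02,
                       origin_spacing = 2e5,
                       efficiency_range = c(0.15, 0.45),
                       efficiency_coupling = 0.3,
                       okazaki_length_mean = 150,
                       okazaki_length_sd = 15,
                       n_okazaki_fragments = 5e5,
                       n_tss = 500,
                       expression_origin_cor = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  pos <- c("n_chromosomes", "chrom_length", "bin_size", "n_replicates",
           "depth", "n_features", "delta_magnitude", "domain_bins_min",
           "domain_bins_max", "peak_density", "peak_width", "peak_baseline",
           "feature_replicates", "total_reads", "origin_spacing",
           "okazaki_length_mean", "okazaki_length_sd",
           "n_okazaki_fragments", "n_tss")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || any(cfg[[p]] <= 0)) {
      abort(paste0("sim_config: `", p, "` must be positive"))
    }
  }
  if (cfg$changed_fraction < 0 || cfg$changed_fraction > 1) {
    abort("sim_config: changed_fraction must be in [0, 1]")
  }
  if (cfg$bin_size > cfg$chrom_length) {
    abort("sim_config: bin_size exceeds chromosome length")
  }
  if (length(cfg$causal_weights) > cfg$n_features) {
    abort("sim_config: more causal weights than features")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic substream seed derived from the master seed and a key string.
child_seed <- function(seed, key) {
  s <- as.double(seed) %% 2147483647
  for (ci in utf8ToInt(key)) s <- (s * 31 + ci) %% 2147483647
  as.integer(max(s, 1))
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

gaussian_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Simulate a latent replication-timing landscape with differentiation shifts
#'
#' Draws, per chromosome, contiguous RT domains with levels uniform in
#' \[-3, 3\] (log2 early/late units), rounds their edges with a narrow
#' Gaussian kernel into a piecewise-smooth landscape, and selects a subset of
#' domains covering about `changed_fraction` of the genome to shift RT during
#' differentiation, half toward earlier (positive delta) and half toward
#' later. Replication origins are scattered along each chromosome with
#' baseline efficiencies; in the differentiated (EpiLC) state an origin's
#' efficiency moves with the local latent delta-RT.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_truth`: `genome`, `bin_size`,
#'   `rt` (latent RT bin track), `delta_rt` (latent delta-RT bin track),
#'   `breakpoints` (tibble of true domain boundaries: `chrom`, `bin`, `pos`),
#'   `feature_weights` (tibble `feature`, `weight`, `coupled`),
#'   `origins` (interval tibble with baseline `efficiency`), and `config`.
#' @export
simulate_rt_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gen <- genome(paste0("chr", seq_len(config$n_chromosomes)),
                rep(config$chrom_length, config$n_chromosomes))
  with_seed(child_seed(config$seed, "landscape"), {
    rt <- bin_track(gen, config$bin_size)
    delta <- bin_track(gen, config$bin_size)
    bps <- list()
    domains <- list()
    for (ch in gen$chrom) {
      idx <- which(rt$chrom == ch)
      n <- length(idx)
      lens <- integer(0)
      while (sum(lens) < n) {
        lens <- c(lens, sample(config$domain_bins_min:config$domain_bins_max, 1))
      }
      lens[length(lens)] <- n - sum(lens[-length(lens)])
      levels <- runif(length(lens), -3, 3)
      dom_id <- rep(seq_along(lens), lens)
      vals <- levels[dom_id]
      rt$value[idx] <- gaussian_smooth(vals, config$smooth_bins)
      cum <- cumsum(lens)
      bp_bins <- cum[-length(cum)]
      bps[[ch]] <- tibble::tibble(chrom = ch, bin = bp_bins,
                                  pos = bp_bins * config$bin_size)
      domains[[ch]] <- tibble::tibble(chrom = ch, domain = seq_along(lens),
                                      n_bins = lens)
      # delta-RT: pick domains until ~changed_fraction of bins are covered
      dvals <- rep(0, n)
      if (config$changed_fraction > 0) {
        ord <- sample(seq_along(lens))
        target <- config$changed_fraction * n
        chosen <- integer(0)
        tot <- 0
        for (d in ord) {
          if (tot >= target) break
          chosen <- c(chosen, d)
          tot <- tot + lens[d]
        }
        sign_up <- rep(c(1, -1), length.out = length(chosen))[sample(length(chosen))]
        for (k in seq_along(chosen)) {
          dvals[dom_id == chosen[k]] <- sign_up[k] * config$delta_magnitude
        }
        dvals <- gaussian_smooth(dvals, config$smooth_bins)
      }
      delta$value[idx] <- dvals
    }
    origins <- purrr::map_dfr(gen$chrom, function(ch) {
      n_ori <- max(1L, rpois(1, config$chrom_length / config$origin_spacing))
      pos <- sort(round(runif(n_ori, 1, config$chrom_length - 1)))
      tibble::tibble(chrom = ch, start = pos, end = pos + 1,
                     efficiency = runif(n_ori, config$efficiency_range[1],
                                        config$efficiency_range[2]))
    })
    structure(list(
      genome = gen,
      bin_size = config$bin_size,
      rt = rt,
      delta_rt = delta,
      breakpoints = dplyr::bind_rows(bps),
      domains = dplyr::bind_rows(domains),
      feature_weights = tibble::tibble(
        feature = sprintf("feat%02d", seq_len(config$n_features)),
        weight = c(config$causal_weights,
                   rep(0, config$n_features - length(config$causal_weights))),
        coupled = seq_len(config$n_features) == 1L
      ),
      origins = origins,
      config = config
    ), class = "synthetic_truth")
  })
}

# Latent RT of a (state, genotype) combination.
latent_rt <- function(truth, state, genotype) {
  sup <- if (genotype == "mutant") truth$config$suppression else 1
  v <- truth$rt$value
  if (state == "epilc") v <- v + sup * truth$delta_rt$value
  v
}

# Latent delta applied to the coupled feature / origin efficiency.
latent_delta <- function(truth, state, genotype) {
  if (state != "epilc") return(rep(0, nrow(truth$rt)))
  sup <- if (genotype == "mutant") truth$config$suppression else 1
  sup * truth$delta_rt$value
}

#' Simulate binned early/late Repli-seq read counts
#'
#' For each bin the replicate-level RT is the latent RT plus
#' `Normal(0, noise_sd)`; total reads are `Poisson(2 * depth)` and early
#' reads are `Binomial(N, p)` with the logistic link
#' `p = 2^RT / (1 + 2^RT)`, so that `log2(early/late)` recovers the latent
#' RT exactly at infinite depth. Each (state, genotype, replicate) gets an
#' independent random stream derived from the master seed.
#'
#' @param truth A `synthetic_truth` from [simulate_rt_landscape()].
#' @param state `"naive"` or `"epilc"`.
#' @param genotype `"control"` or `"mutant"`.
#' @param replicates Which replicates to simulate (default all).
#' @return A long tibble: `chrom`, `start`, `end`, `replicate`, `early`,
#'   `late`.
#' @export
simulate_repliseq_counts <- function(truth, state = "naive",
                                     genotype = "control",
                                     replicates = seq_len(truth$config$n_replicates)) {
  cfg <- truth$config
  rt0 <- latent_rt(truth, state, genotype)
  purrr::map_dfr(replicates, function(r) {
    with_seed(child_seed(cfg$seed, paste("repliseq", state, genotype, r)), {
      rt_r <- rt0 + rnorm(length(rt0), 0, cfg$noise_sd)
      p <- 2^rt_r / (1 + 2^rt_r)
      n <- rpois(length(rt0), 2 * cfg$depth)
      early <- rbinom(length(rt0), n, p)
      tibble::tibble(chrom = truth$rt$chrom, start = truth$rt$start,
                     end = truth$rt$end, replicate = r,
                     early = early, late = n - early)
    })
  })
}

#' Simulate early/late Repli-seq fragments
#'
#' Expands [simulate_repliseq_counts()] into per-read fragment intervals
#' placed uniformly within their bin, as a fragment-level entry point for the
#' binning stage of the pipeline.
#'
#' @inheritParams simulate_repliseq_counts
#' @param fragment_length Sequenced fragment length in bp.
#' @return A tibble with `chrom`, `start`, `end`, `replicate`, `fraction`
#'   (`"early"` / `"late"`).
#' @export
simulate_repliseq <- function(truth, state = "naive", genotype = "control",
                              replicates = seq_len(truth$config$n_replicates),
                              fragment_length = 150) {
  counts <- simulate_repliseq_counts(truth, state, genotype, replicates)
  cfg <- truth$config
  long <- tidyr::pivot_longer(counts, c("early", "late"),
                              names_to = "fraction", values_to = "n")
  long <- long[long$n > 0, , drop = FALSE]
  with_seed(child_seed(cfg$seed, paste("repliseq-frag", state, genotype)), {
    idx <- rep(seq_len(nrow(long)), long$n)
    width <- long$end[idx] - long$start[idx]
    off <- floor(runif(length(idx)) * pmax(width - fragment_length, 1))
    start <- long$start[idx] + off
    tibble::tibble(chrom = long$chrom[idx],
                   start = start,
                   end = pmin(start + fragment_length, long$end[idx]),
                   replicate = long$replicate[idx],
                   fraction = long$fraction[idx])
  })
}

#' Simulate chromatin-feature peak calls with signal
#'
#' Peaks of each feature are placed at random bins (one per bin with
#' probability `peak_density`); the per-peak signal is
#' `baseline + weight_f * RT(bin) + noise`, so features with nonzero true
#' weight carry RT information while null features do not. In the EpiLC
#' state the coupled feature (feature 1) additionally shifts by
#' `coupling * delta_RT(bin)`; in the mutant genotype that shift (and the
#' latent delta-RT itself) is multiplied by the suppression factor.
#' Replicate peak sets share locations and differ by replicate-level signal
#' noise. Library totals and outside-peak (background) read counts are
#' returned alongside for background correction.
#'
#' @inheritParams simulate_repliseq_counts
#' @return A list with `peaks` (tibble: `feature`, `replicate`, `chrom`,
#'   `start`, `end`, `signal`) and `library` (tibble: `feature`,
#'   `replicate`, `total_reads`, `outside_reads`).
#' @export
simulate_features <- function(truth, state = "naive", genotype = "control") {
  cfg <- truth$config
  rt_state <- truth$rt$value   # peak signal tracks steady-state RT
  delta <- latent_delta(truth, state, genotype)
  weights <- truth$feature_weights
  # peak locations and per-peak base signal are a property of the feature,
  # shared across states and genotypes; only the coupled shift and the
  # replicate-level noise are condition-specific
  base <- with_seed(child_seed(cfg$seed, "features-base"), {
    purrr::map(seq_len(nrow(weights)), function(f) {
      has_peak <- runif(nrow(truth$rt)) < cfg$peak_density
      idx <- which(has_peak)
      if (!length(idx)) return(NULL)
      offset <- floor(runif(length(idx)) *
                        pmax(truth$rt$end[idx] - truth$rt$start[idx] -
                               cfg$peak_width, 1))
      start <- truth$rt$start[idx] + pmax(offset, 0)
      list(idx = idx, start = start,
           signal = cfg$peak_baseline + weights$weight[f] * rt_state[idx] +
             rnorm(length(idx), 0, cfg$peak_noise_sd))
    })
  })
  with_seed(child_seed(cfg$seed, paste("features", state, genotype)), {
    peaks <- purrr::map_dfr(seq_len(nrow(weights)), function(f) {
      b <- base[[f]]
      if (is.null(b)) return(NULL)
      sig <- b$signal
      if (weights$coupled[f]) sig <- sig + cfg$coupling * delta[b$idx]
      purrr::map_dfr(seq_len(cfg$feature_replicates), function(r) {
        tibble::tibble(
          feature = weights$feature[f], replicate = r,
          chrom = truth$rt$chrom[b$idx],
          start = b$start,
          end = b$start + cfg$peak_width,
          signal = pmax(sig + rnorm(length(b$idx), 0, cfg$replicate_signal_sd), 0)
        )
      })
    })
    library <- tidyr::expand_grid(feature = weights$feature,
                                  replicate = seq_len(cfg$feature_replicates))
    library$total_reads <- cfg$total_reads
    library$outside_reads <- rpois(nrow(library),
                                   cfg$background_fraction * cfg$total_reads)
    list(peaks = sort_intervals(peaks, truth$genome), library = library)
  })
}

# Origin efficiencies for a given state/genotype: in the EpiLC state an
# origin's efficiency moves with the local latent delta-RT (suppressed in
# the mutant), clipped away from 0/1.
origin_efficiencies <- function(truth, state = "naive", genotype = "control") {
  cfg <- truth$config
  ori <- truth$origins
  if (state == "epilc") {
    delta <- latent_delta(truth, state, genotype)
    bin_idx <- match(paste(ori$chrom, (ori$start %/% cfg$bin_size) * cfg$bin_size),
                     paste(truth$rt$chrom, truth$rt$start))
    ori$efficiency <- pmin(pmax(ori$efficiency +
                                  cfg$efficiency_coupling * delta[bin_idx],
                                0.02), 0.98)
  }
  ori
}

# Piecewise-linear rightward-fork (Crick) probability along one chromosome.
# Just left of an origin with efficiency e the probability is (1 - e)/2,
# just right it is (1 + e)/2; between consecutive origins it interpolates
# linearly, and it is constant outside the outermost origins.
crick_probability <- function(pos, origin_pos, efficiency) {
  if (length(origin_pos) == 0) abort("zero origins: fork polarity undefined")
  o <- order(origin_pos)
  origin_pos <- origin_pos[o]
  efficiency <- efficiency[o]
  left <- (1 - efficiency) / 2
  right <- (1 + efficiency) / 2
  xs <- c(origin_pos[1] - 1, rep(origin_pos, each = 2),
          origin_pos[length(origin_pos)] + 1)
  ys <- c(left[1], as.numeric(rbind(left, right)), right[length(right)])
  stats::approx(xs, ys, xout = pos, rule = 2, ties = "ordered")$y
}

#' Simulate stranded Okazaki-fragment reads
#'
#' Fork polarity follows the two-origin linear interpolation: at an origin of
#' efficiency e the rightward-fork probability steps from (1-e)/2 to
#' (1+e)/2 and decays linearly toward the next origin's left-side value.
#' Each fragment's position is uniform along the genome; its strand is Crick
#' (`+`, rightward fork) with that local probability and Watson (`-`)
#' otherwise. Fragment lengths are normal, truncated at 50 bp.
#'
#' @inheritParams simulate_repliseq_counts
#' @param n_fragments Number of fragments to sample (default from config).
#' @param origins Optional origin tibble (`chrom`, `start`, `efficiency`)
#'   overriding the truth's state-specific origins.
#' @return A stranded interval tibble: `chrom`, `start`, `end`, `strand`.
#' @export
simulate_okseq <- function(truth, state = "naive", genotype = "control",
                           n_fragments = truth$config$n_okazaki_fragments,
                           origins = NULL) {
  cfg <- truth$config
  if (is.null(origins)) origins <- origin_efficiencies(truth, state, genotype)
  if (nrow(origins) == 0) abort("zero origins: fork polarity undefined")
  gen <- truth$genome
  with_seed(child_seed(cfg$seed, paste("okseq", state, genotype)), {
    n_per <- stats::rmultinom(1, n_fragments,
                              gen$length / sum(gen$length))[, 1]
    purrr::map_dfr(seq_len(nrow(gen)), function(i) {
      ch <- gen$chrom[i]
      ori <- origins[origins$chrom == ch, , drop = FALSE]
      if (nrow(ori) == 0) abort(paste0("zero origins on ", ch))
      pos <- round(runif(n_per[i], 0, gen$length[i] - 1))
      p <- crick_probability(pos, ori$start, ori$efficiency)
      crick <- runif(n_per[i]) < p
      len <- pmax(round(rnorm(n_per[i], cfg$okazaki_length_mean,
                              cfg$okazaki_length_sd)), 50)
      start <- pmax(pos - len %/% 2, 0)
      tibble::tibble(chrom = ch, start = start,
                     end = pmin(start + len, gen$length[i]),
                     strand = ifelse(crick, "+", "-"))
    })
  })
}

#' Simulate transcription start sites with expression levels
#'
#' TSS positions are uniform along the genome; expression is log-normal.
#' `expression_origin_cor` > 0 rank-correlates expression with the
#' efficiency of the nearest replication origin through a Gaussian copula,
#' emulating the association between origin firing and transcription.
#'
#' @inheritParams simulate_repliseq_counts
#' @return A list with `tss` (interval tibble with `name`, `strand`) and
#'   `expression` (tibble `name`, `expression`).
#' @export
simulate_expression <- function(truth, state = "naive", genotype = "control") {
  cfg <- truth$config
  gen <- truth$genome
  ori <- origin_efficiencies(truth, state, genotype)
  with_seed(child_seed(cfg$seed, paste("expression", state, genotype)), {
    chrom <- sample(gen$chrom, cfg$n_tss, replace = TRUE,
                    prob = gen$length / sum(gen$length))
    pos <- round(runif(cfg$n_tss, 0, chrom_length(gen, chrom) - 1))
    tss <- tibble::tibble(chrom = chrom, start = pos, end = pos + 1,
                          name = sprintf("gene%04d", seq_len(cfg$n_tss)),
                          strand = sample(c("+", "-"), cfg$n_tss, replace = TRUE))
    # nearest-origin efficiency, then a copula mixing it with fresh noise
    eff <- purrr::map_dbl(seq_len(cfg$n_tss), function(i) {
      oc <- ori[ori$chrom == tss$chrom[i], , drop = FALSE]
      oc$efficiency[which.min(abs(oc$start - tss$start[i]))]
    })
    rho <- cfg$expression_origin_cor
    z_eff <- stats::qnorm((rank(eff, ties.method = "first") - 0.5) / cfg$n_tss)
    z <- rho * z_eff + sqrt(1 - rho^2) * rnorm(cfg$n_tss)
    expr <- exp(2 + 1 * z)
    list(tss = sort_intervals(tss, gen),
         expression = tibble::tibble(name = tss$name, expression = expr))
  })
}

#' Simulate a step track with planted breakpoints
#'
#' A single-chromosome bin track alternating between two levels separated by
#' `step` at the given breakpoint bins, plus Gaussian noise — the standard
#' test bed for changepoint recovery.
#'
#' @param n_bins Number of bins.
#' @param breakpoints Integer bin indices (1-based, first bin of each new
#'   segment after the first).
#' @param step Level difference between consecutive segments.
#' @param noise_sd Gaussian noise sd.
#' @param bin_size Bin width in bp.
#' @param seed Seed.
#' @return A bin-track tibble on a one-chromosome genome.
#' @export
simulate_step_track <- function(n_bins, breakpoints, step = 1, noise_sd = 0.2,
                                bin_size = 5e4, seed = 1) {
  stopifnot(all(breakpoints > 1), all(breakpoints <= n_bins))
  gen <- genome("chr1", n_bins * bin_size)
  track <- bin_track(gen, bin_size)
  seg <- findInterval(seq_len(n_bins), sort(breakpoints))
  with_seed(seed, {
    track$value <- (seg %% 2) * step + rnorm(n_bins, 0, noise_sd)
  })
  track
}
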