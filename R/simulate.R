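# Synthetic droplet-culture experiments with known ground truth.
#
# Latent per-SV abundance follows exp() of a modified Gompertz curve on
# the ln scale, so the quantity the fitting stage estimates is exactly the
# simulated curve.  Observations are a multinomial read sample of the
# latent relative abundances plus a lognormal-noise qPCR total.

#' Specify a synthetic droplet community
#'
#' Draws a community of `n_svs` sequence variants with per-SV growth
#' parameters strictly inside the fitting bounds, a growing/non-growing
#' flag (non-growers have `mu = 0`), Dirichlet inoculum fractions, phylum
#' labels, and a known SV x carbon utilization truth matrix with
#' specialist/generalist structure.
#'
#' Defaults emulate a droplet culture of a human stool community: roughly
#' a third of SVs actively grow in the medium, inoculum fractions are
#' drawn from a sparse symmetric Dirichlet so most taxa are rare, and
#' among carbohydrate degraders single-substrate specialists outnumber
#' multi-substrate generalists.
#'
#' @param n_svs Number of sequence variants.
#' @param carbons Character vector of carbon-source conditions to encode
#'   in the truth matrix (polysaccharides; do not include `"none"` or
#'   `"glucose"`, which are handled as controls).
#' @param p_growing Probability that an SV is viable/growing in the base
#'   medium (default 0.35).
#' @param p_degrader Probability that a *growing* SV degrades at least one
#'   polysaccharide (default 0.6).
#' @param p_specialist Probability that a degrader uses exactly one
#'   polysaccharide (default 0.6); generalists draw 2 or more.
#' @param dirichlet_conc Symmetric Dirichlet concentration for inoculum
#'   fractions (default 0.5; values < 1 produce rare-taxon-heavy
#'   communities).
#' @param total_inoculum Total inoculum abundance in qPCR units, used to
#'   place the inoculum offsets `A0 = log(fraction * total_inoculum)`
#'   (default 5e4).
#' @param bounds [gompertz_bounds()] box inside which growth parameters
#'   are drawn.
#' @param phyla,phylum_probs Phylum labels and their sampling
#'   probabilities (defaults: the four dominant gut phyla at gut-like
#'   proportions).
#' @param seed Optional integer seed; identical seeds give identical
#'   specs.
#' @return An object of class `"community_spec"`: a list with
#'   `growth_params` (n_svs x 4 matrix `A`, `mu`, `lam`, `A0`),
#'   `growing`, `initial_fractions`, `taxonomy` (phylum per SV),
#'   `utilization_truth` (logical n_svs x length(carbons)), `carbons`.
#' @export
community_spec <- function(n_svs, carbons = c("inulin", "gos", "dextrin",
                                              "xylan"),
                           p_growing = 0.35, p_degrader = 0.6,
                           p_specialist = 0.6, dirichlet_conc = 0.5,
                           total_inoculum = 5e4,
                           bounds = gompertz_bounds(),
                           phyla = c("Firmicutes", "Bacteroidetes",
                                     "Actinobacteria", "Proteobacteria"),
                           phylum_probs = c(0.45, 0.35, 0.1, 0.1),
                           seed = NULL) {
  if (n_svs < 1L) stop("'n_svs' must be >= 1")
  if (anyDuplicated(carbons)) stop("duplicate carbon names")
  if (any(c("none", "glucose") %in% carbons)) {
    stop("'carbons' must list polysaccharides only; controls are added ",
         "by the simulators")
  }
  .with_seed(seed, {
    sv_ids <- sprintf("SV%03d", seq_len(n_svs))
    # inoculum fractions: symmetric Dirichlet via normalised gammas
    g <- stats::rgamma(n_svs, shape = dirichlet_conc, rate = 1)
    g[g <= 0] <- 1e-12
    fractions <- g / sum(g)

    # growth parameters strictly inside the default fitting box; A0 from
    # the inoculum fraction so the two spec fields agree
    A0 <- log(pmax(fractions * total_inoculum, 1.1))
    A0 <- pmin(pmax(A0, 0.05), bounds$upper[["A0"]] - 0.1)
    A <- stats::runif(n_svs, 1, 8)
    mu <- stats::runif(n_svs, 0.1, 1.2)
    lam <- stats::runif(n_svs, 0.5, 10)
    growing <- stats::runif(n_svs) < p_growing
    mu[!growing] <- 0   # non-growers stay flat
    A[!growing] <- 0

    taxonomy <- sample(phyla, n_svs, replace = TRUE, prob = phylum_probs)

    truth <- matrix(FALSE, n_svs, length(carbons),
                    dimnames = list(sv_ids, carbons))
    for (i in which(growing)) {
      if (stats::runif(1) < p_degrader) {
        k <- if (stats::runif(1) < p_specialist || length(carbons) == 1L) {
          1L
        } else {
          sample(2:length(carbons), 1L)
        }
        truth[i, sample(length(carbons), k)] <- TRUE
      }
    }

    params <- cbind(A = A, mu = mu, lam = lam, A0 = A0)
    rownames(params) <- sv_ids
    structure(
      list(sv_ids = sv_ids, growth_params = params, growing = growing,
           initial_fractions = stats::setNames(fractions, sv_ids),
           taxonomy = stats::setNames(taxonomy, sv_ids),
           utilization_truth = truth, carbons = carbons,
           total_inoculum = total_inoculum),
      class = "community_spec")
  })
}

# Latent absolute abundance of every SV at time t (hours); 'grows' picks
# which SVs follow their growth curve rather than staying at baseline.
.latent_abundance <- function(spec, t, grows = spec$growing) {
  p <- spec$growth_params
  vapply(seq_along(spec$sv_ids), function(i) {
    if (grows[i]) {
      exp(gompertz_ln(t, p[i, "A"], p[i, "mu"], p[i, "lam"], p[i, "A0"]))
    } else {
      exp(p[i, "A0"])
    }
  }, numeric(1L))
}

# Observe one sample: multinomial counts at a fixed depth plus a
# lognormal multiplicative error on the qPCR total (unit mean, given CV).
.observe_sample <- function(latent, read_depth, qpcr_cv) {
  frac <- latent / sum(latent)
  counts <- as.integer(stats::rmultinom(1L, size = read_depth, prob = frac))
  noise <- if (qpcr_cv > 0) {
    sdlog <- sqrt(log(1 + qpcr_cv^2))
    stats::rlnorm(1L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  list(counts = counts, qpcr = sum(latent) * noise)
}

#' Simulate a droplet growth-dynamics time series
#'
#' Generates destructively sampled droplet aliquots at the requested
#' times: per-SV latent abundance follows the exponential of its modified
#' Gompertz curve (so fitted ln-abundance is exactly the latent curve),
#' read counts are multinomial at `read_depth`, and the qPCR total
#' carries multiplicative lognormal noise with coefficient of variation
#' `qpcr_cv`.
#'
#' @param spec A [community_spec()].
#' @param times Sampling times in hours (non-empty, within 0--200 h);
#'   repeat a time to obtain technical replicates.
#' @param read_depth Reads per sample (> 0).
#' @param qpcr_cv Coefficient of variation of the qPCR noise (default
#'   0.1; 0 gives noiseless totals).
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @return A list with `counts` (samples x SVs integer matrix), `qpcr`
#'   (named vector of totals), `metadata` (data frame: `sample`, `time`,
#'   `replicate`), and `truth` (the latent abundance matrix and the
#'   generating `spec`).
#' @export
simulate_timeseries <- function(spec, times, read_depth, qpcr_cv = 0.1,
                                seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(times) == 0L) stop("'times' must be non-empty")
  if (any(times < 0 | times > 200)) {
    stop("'times' must lie within [0, 200] hours")
  }
  if (read_depth <= 0) stop("'read_depth' must be > 0")
  .with_seed(seed, {
    rep_id <- stats::ave(seq_along(times), times, FUN = seq_along)
    sample_ids <- sprintf("t%03g_r%d", times, rep_id)
    n <- length(times)
    counts <- matrix(0L, n, length(spec$sv_ids),
                     dimnames = list(sample_ids, spec$sv_ids))
    latent <- matrix(0, n, length(spec$sv_ids),
                     dimnames = list(sample_ids, spec$sv_ids))
    qpcr <- stats::setNames(numeric(n), sample_ids)
    for (s in seq_len(n)) {
      l <- .latent_abundance(spec, times[s])
      obs <- .observe_sample(l, read_depth, qpcr_cv)
      counts[s, ] <- obs$counts
      latent[s, ] <- l
      qpcr[s] <- obs$qpcr
    }
    list(counts = counts, qpcr = qpcr,
         metadata = data.frame(sample = sample_ids, time = times,
                               replicate = rep_id),
         truth = list(latent = latent, spec = spec))
  })
}

#' Simulate an endpoint carbohydrate-utilization droplet experiment
#'
#' Generates endpoint (default 48 h) droplet cultures for each carbon
#' source and replicate.  An SV follows its growth curve on a
#' polysaccharide only where the spec's utilization truth says so; on
#' glucose every viable (growing) SV grows; on the mandatory no-carbon
#' control every SV stays at its baseline inoculum level.  Replicate
#' noise (multinomial sampling and qPCR noise) is independent across
#' samples.
#'
#' @param spec A [community_spec()].
#' @param carbons Conditions to simulate; must include `"none"`, may
#'   include `"glucose"`, and polysaccharide names must be columns of the
#'   spec's truth matrix.  Duplicates are rejected.
#' @param n_replicates Droplet replicates per condition (default 3).
#' @param read_depth Reads per sample.
#' @param qpcr_cv qPCR noise CV (default 0.1).
#' @param endpoint_time Sampling time in hours (default 48, roughly two
#'   days after inoculation, by when most gut taxa have approached
#'   carrying capacity).
#' @param seed Optional integer seed.
#' @return A list with `counts`, `qpcr`, `metadata` (`sample`,
#'   `condition`, `replicate`) and `truth` (the generating spec).
#' @export
simulate_prebiotic_experiment <- function(spec, carbons = c("none",
                                                            "glucose",
                                                            spec$carbons),
                                          n_replicates = 3, read_depth,
                                          qpcr_cv = 0.1,
                                          endpoint_time = 48,
                                          seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (anyDuplicated(carbons)) stop("duplicate carbon names")
  if (!"none" %in% carbons) {
    stop("the no-carbon control condition \"none\" must be included")
  }
  polys <- setdiff(carbons, c("none", "glucose"))
  if (!all(polys %in% colnames(spec$utilization_truth))) {
    stop("unknown carbon(s): ",
         paste(setdiff(polys, colnames(spec$utilization_truth)),
               collapse = ", "))
  }
  if (read_depth <= 0) stop("'read_depth' must be > 0")
  .with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        condition = carbons, stringsAsFactors = FALSE)
    sample_ids <- sprintf("%s_r%d", grid$condition, grid$replicate)
    counts <- matrix(0L, nrow(grid), length(spec$sv_ids),
                     dimnames = list(sample_ids, spec$sv_ids))
    qpcr <- stats::setNames(numeric(nrow(grid)), sample_ids)
    for (s in seq_len(nrow(grid))) {
      cond <- grid$condition[s]
      grows <- if (cond == "none") {
        rep(FALSE, length(spec$sv_ids))
      } else if (cond == "glucose") {
        spec$growing
      } else {
        spec$growing & spec$utilization_truth[, cond]
      }
      l <- .latent_abundance(spec, endpoint_time, grows = grows)
      obs <- .observe_sample(l, read_depth, qpcr_cv)
      counts[s, ] <- obs$counts
      qpcr[s] <- obs$qpcr
    }
    list(counts = counts, qpcr = qpcr,
         metadata = data.frame(sample = sample_ids,
                               condition = grid$condition,
                               replicate = grid$replicate),
         truth = list(spec = spec))
  })
}

#' Simulate reference well-plate OD endpoints for isolates
#'
#' Emulates the conventional validation arm of a utilization screen:
#' a small panel of isolates grown in well plates on each carbon source,
#' with endpoint OD600 proportional to the utilization truth plus
#' additive noise.  Thresholding the noiseless output at 20% of each
#' isolate's maximum reproduces the truth exactly.
#'
#' @param spec A [community_spec()] with at most ~10 SVs (well-plate
#'   scale).
#' @param carbons Polysaccharide columns of the spec truth to assay
#'   (default: all).
#' @param od_scale OD600 reached on a fully utilised carbon (default 1).
#' @param noise_sd Additive Gaussian noise SD on OD (default 0.02);
#'   negative draws are clamped at 0.
#' @param strength Optional matrix in `[0, 1]` (isolates x carbons)
#'   scaling each true entry's growth relative to `od_scale`, e.g. to
#'   plant weak growers near the 20% call boundary.  Default 1.
#' @param seed Optional integer seed.
#' @return A list with `od` (isolate x carbon matrix) and `truth` (the
#'   logical utilization matrix used).
#' @export
simulate_reference_plates <- function(spec, carbons = spec$carbons,
                                      od_scale = 1, noise_sd = 0.02,
                                      strength = NULL, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (length(spec$sv_ids) > 12L) {
    stop("well-plate simulation expects a small isolate panel (<= 12)")
  }
  truth <- spec$utilization_truth[, carbons, drop = FALSE]
  if (is.null(strength)) {
    strength <- matrix(1, nrow(truth), ncol(truth))
  }
  if (any(strength < 0 | strength > 1)) stop("'strength' must be in [0, 1]")
  .with_seed(seed, {
    od <- od_scale * truth * strength
    od <- od + matrix(stats::rnorm(length(od), sd = noise_sd),
                      nrow(od), ncol(od))
    od[od < 0] <- 0
    dimnames(od) <- dimnames(truth)
    list(od = od, truth = truth)
  })
}
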