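# Dirichlet-multinomial generator of synthetic lake-core bundles with the
# statistical structure the analysis pipeline assumes: blocky three-zone
# assemblage composition, a double-peaked contaminant profile coupled to
# the centropyxid share, compositional LOI series, and a hiatus-bearing
# age-depth model.

#' Configuration for a synthetic lake core
#'
#' Defaults emulate the study design the package targets: a 30-sample,
#' 1 cm-resolution core with zone boundaries after samples 6 and 16, an
#' arsenic-like contaminant with Gaussian peaks centred at depths 8 and
#' 15 cm over a low baseline, logistic coupling of the centropyxid share to
#' the standardized contaminant, specimen counts of 150-300, and a
#' depositional hiatus below the middle zone.
#'
#' @param n_samples number of 1-cm samples.
#' @param b1,b2 zone boundaries: shallow zone = samples `1..b1`, middle =
#'   `b1+1..b2`, deep = `b2+1..n_samples`.
#' @param n_centropyxid,n_difflugiid taxon counts per functional block; one
#'   planktic eutrophication-indicator taxon is always added.
#' @param base_alpha optional 3 x n_taxa matrix of per-zone Dirichlet base
#'   compositions (rows: shallow, middle, deep); a structured default is
#'   built when `NULL`.
#' @param concentration Dirichlet concentration `c` (overdispersion:
#'   smaller = noisier compositions).
#' @param count_range inclusive range of per-sample specimen totals.
#' @param baseline,peak_mu,peak_sigma,peak_height contaminant profile
#'   `a(d) = baseline + sum(height * exp(-0.5 ((d - mu)/sigma)^2))` in ppm.
#' @param beta0,beta1 intercept and slope of
#'   `logit(centropyxid share) = beta0 + beta1 * z(a(d))`.
#' @param organics0,lambda,loi_noise_sd,carbonates LOI model: organics
#'   `= organics0 - lambda * z(a) + noise`, minerogenics closes the
#'   dry-mass sum to 1.
#' @param top_year,hiatus_year calendar years of the core top and of the
#'   deepest dated tie point (at depth `b2`); no ages exist below the
#'   hiatus.
#' @param seed RNG seed; the full bundle is reproducible from it.
#' @return list of class `synthetic_core_config`.
#' @export
synthetic_core_config <- function(n_samples = 30, b1 = 6, b2 = 16,
                                  n_centropyxid = 6, n_difflugiid = 13,
                                  base_alpha = NULL, concentration = 50,
                                  count_range = c(150, 300),
                                  baseline = 150, peak_mu = c(8, 15),
                                  peak_sigma = c(1.5, 2),
                                  peak_height = c(900, 1100),
                                  beta0 = stats::qlogis(0.15), beta1 = 1.2,
                                  organics0 = 0.33, lambda = 0.08,
                                  loi_noise_sd = 0.015, carbonates = 0.02,
                                  top_year = 2012, hiatus_year = 1962,
                                  seed = 42) {
  stopifnot(b1 >= 2, b2 > b1, b2 < n_samples, concentration > 0,
            all(peak_sigma > 0), count_range[1] >= 1)
  taxa <- c(paste0("Centropyxis synthetica ", seq_len(n_centropyxid)),
            "Cucurbitella synthetica",
            paste0("Difflugia synthetica ", seq_len(n_difflugiid)))
  group <- c(rep("centropyxid", n_centropyxid), "difflugiid",
             rep("difflugiid", n_difflugiid))
  in_dc <- c(rep(FALSE, n_centropyxid), FALSE, rep(TRUE, n_difflugiid))
  if (is.null(base_alpha)) {
    nt <- length(taxa)
    base_alpha <- matrix(0.2, 3, nt, dimnames = list(
      c("shallow", "middle", "deep"), taxa))
    base_alpha[, seq_len(n_centropyxid)] <- 1  # relative mix within block
    ct <- n_centropyxid + 1
    di <- (n_centropyxid + 2):nt
    base_alpha["shallow", ct] <- 6                      # eutrophication
    base_alpha["shallow", di[1:4]] <- c(4, 3, 2, 1)
    base_alpha["middle", ct] <- 0.5
    base_alpha["middle", di[5:8]] <- c(3, 3, 2, 1)
    base_alpha["deep", ct] <- 0.2
    base_alpha["deep", di[9:12]] <- c(5, 4, 3, 2)
  }
  if (any(base_alpha <= 0)) stop("base_alpha must be strictly positive")
  structure(list(n_samples = n_samples, b1 = b1, b2 = b2, taxa = taxa,
                 group = group, in_dc_ratio = in_dc,
                 n_centropyxid = n_centropyxid,
                 base_alpha = base_alpha, concentration = concentration,
                 count_range = count_range, baseline = baseline,
                 peak_mu = peak_mu, peak_sigma = peak_sigma,
                 peak_height = peak_height, beta0 = beta0, beta1 = beta1,
                 organics0 = organics0, lambda = lambda,
                 loi_noise_sd = loi_noise_sd, carbonates = carbonates,
                 top_year = top_year, hiatus_year = hiatus_year,
                 seed = seed),
            class = "synthetic_core_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Contaminant depth profile of a configuration
#'
#' @param config a [synthetic_core_config()].
#' @param depth depths at which to evaluate (defaults to sample depths).
#' @return numeric concentrations (ppm).
#' @export
contaminant_profile <- function(config, depth = seq_len(config$n_samples)) {
  a <- rep(config$baseline, length(depth))
  for (j in seq_along(config$peak_mu))
    a <- a + config$peak_height[j] *
      exp(-0.5 * ((depth - config$peak_mu[j]) / config$peak_sigma[j])^2)
  a
}

#' Generate a synthetic lake-core bundle
#'
#' Draws, per sample: the contaminant level `a(d)`; a Dirichlet composition
#' around the zone's base re-weighted so the centropyxid block's expected
#' share is `plogis(beta0 + beta1 * z(a))`; multinomial specimen counts;
#' compositional LOI fractions anti-correlated with the contaminant; and an
#' age-depth table with a hard hiatus at depth `b2`.
#'
#' @param config a [synthetic_core_config()].
#' @return list of class `synthetic_core`: `counts`
#'   ([assemblage_counts()]), `registry`, `geochem`
#'   ([geochem_profile()]), `loi`, `ages`, `truth` (true zones, boundaries,
#'   centropyxid share, contaminant profile, config).
#' @export
generate_core <- function(config) {
  stopifnot(inherits(config, "synthetic_core_config"))
  set.seed(config$seed)
  n <- config$n_samples
  depth <- seq_len(n)
  zone_of <- ifelse(depth <= config$b1, "shallow",
                    ifelse(depth <= config$b2, "middle", "deep"))
  a <- contaminant_profile(config)
  s_a <- stats::sd(a)
  z <- if (s_a > 0) (a - mean(a)) / s_a else rep(0, n)  # flat profile
  pi_c <- stats::plogis(config$beta0 + config$beta1 * z)
  if (any(pi_c <= 0 | pi_c >= 1)) stop("infeasible centropyxid share")
  cent <- seq_len(config$n_centropyxid)
  nt <- length(config$taxa)
  totals <- sample(seq(config$count_range[1], config$count_range[2]), n,
                   replace = TRUE)
  counts <- matrix(0L, n, nt, dimnames = list(paste0("SYN", depth),
                                              config$taxa))
  for (i in seq_len(n)) {
    base <- config$base_alpha[zone_of[i], ]
    w <- base
    w[cent] <- base[cent] / sum(base[cent]) * pi_c[i]
    w[-cent] <- base[-cent] / sum(base[-cent]) * (1 - pi_c[i])
    p <- rdirichlet1(config$concentration * w)
    counts[i, ] <- stats::rmultinom(1, totals[i], p)
  }
  asm <- assemblage_counts(counts, sample_ids = paste0("SYN", depth),
                           depth_top = depth - 1, depth_bottom = depth,
                           mode = "counts")
  registry <- taxon_registry(data.frame(
    taxon_id = config$taxa, group = config$group,
    in_dc_ratio = config$in_dc_ratio))
  # geochemistry: contaminant (As-like) plus standard companions
  As <- a * exp(stats::rnorm(n, 0, 0.03))
  Al <- 10000 * exp(stats::rnorm(n, 0, 0.05))
  S <- 2000 * exp(stats::rnorm(n, 0, 0.08))
  Mn <- 500 * exp(stats::rnorm(n, 0, 0.08))
  Fe <- (28000 + 300 * depth) * exp(stats::rnorm(n, 0, 0.05))
  Hg <- (0.05 + 0.1 * a / max(a)) * exp(stats::rnorm(n, 0, 0.1))
  geochem <- geochem_profile(depth, cbind(As = As, Fe = Fe, Hg = Hg,
                                          S = S, Mn = Mn, Al = Al))
  organics <- config$organics0 - config$lambda * z +
    stats::rnorm(n, 0, config$loi_noise_sd)
  organics <- pmin(pmax(organics, 0.02), 1 - config$carbonates - 0.02)
  loi <- data.frame(depth = depth,
                    water = stats::runif(n, 0.05, 0.15),
                    organics = organics,
                    carbonates = config$carbonates,
                    minerogenics = 1 - organics - config$carbonates)
  class(loi) <- c("loi_table", "data.frame")
  mod_depth <- 0:config$b2
  ages <- data.frame(depth = mod_depth,
                     year = seq(config$top_year, config$hiatus_year,
                                length.out = length(mod_depth)))
  class(ages) <- c("age_depth_table", "data.frame")
  true_zone <- ifelse(zone_of == "deep", 1L, ifelse(zone_of == "middle", 2L, 3L))
  structure(list(counts = asm, registry = registry, geochem = geochem,
                 loi = loi, ages = ages,
                 truth = list(zones = true_zone,
                              boundaries = c(config$b1, config$b2),
                              pi_centropyxid = pi_c, contaminant = a,
                              config = config)),
            class = "synthetic_core")
}

#' @export
print.synthetic_core <- function(x, ...) {
  cat(sprintf("Synthetic core: %d samples, %d taxa, seed %d\n",
              nrow(x$counts$values), ncol(x$counts$values),
              x$truth$config$seed))
  invisible(x)
}

#' Parameter-recovery study over replicate synthetic cores
#'
#' For each replicate (seed `config$seed + r`), runs the standard biotic
#' pipeline (renormalize, square-root transform, Bray-Curtis, CONISS,
#' broken-stick zone count, cut) plus ANOSIM against the true zones and a
#' RELATE rho between the contaminant's Euclidean matrix and the biotic
#' matrix, and compares recovered zonation with the generator's truth.
#'
#' @param config a [synthetic_core_config()].
#' @param n_replicates number of replicates.
#' @param max_k maximum zone count offered to the broken-stick rule.
#' @return list with `replicates` (per-replicate data frame: `k`,
#'   `boundary_hits`, `anosim_R`, `relate_rho`), `zone_rate` (share of
#'   replicates recovering the true zone count), `boundary_rate` (share
#'   with all boundaries within +/-1 sample).
#' @export
recovery_study <- function(config, n_replicates = 50, max_k = 6) {
  res <- vector("list", n_replicates)
  true_b <- c(config$b1, config$b2)
  true_k <- 3L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    core <- generate_core(cfg)
    rel <- to_relative(core$counts)
    d <- bray_curtis(sqrt_transform(rel))            # inference matrix
    zc <- coniss(bray_curtis(rel, allow_untransformed = TRUE))
    k <- broken_stick_select(zc, max_k)$k
    zones <- cut_zones(zc, k)
    found_b <- which(diff(zones) != 0)
    hits <- k == true_k &&
      length(found_b) == length(true_b) &&
      all(abs(sort(found_b) - true_b) <= 1)
    R <- anosim_test(d, core$truth$zones, n_perm = 0)$value
    rho <- relate(euclidean_matrix(core$truth$contaminant), d,
                  n_perm = 0)$value
    res[[r]] <- data.frame(replicate = r, k = k,
                           boundary_hits = hits, anosim_R = R,
                           relate_rho = rho)
  }
  reps <- do.call(rbind, res)
  list(replicates = reps,
       zone_rate = mean(reps$k == true_k),
       boundary_rate = mean(reps$boundary_hits))
}
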