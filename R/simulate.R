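# Seeded synthetic reservoir survey generator.
#
# The generator emulates the statistical structure a monthly multi-site
# phytoplankton survey of a small reservoir is assumed to have: a seasonal
# water-temperature cycle, Gaussian thermal niches and Monod (saturating)
# nitrogen responses per taxon, multiplicative lognormal noise, and one
# high-nutrient, high-variability headwater site. Site disturbance is
# modelled with two distinct noise channels, because they act in opposite
# directions on the community statistics:
#
#   * quiet (downstream) sites: variability is dominated by *synchronous*
#     community-wide pulses (hydrology acting on everyone at once). These
#     produce spiky per-group series (low AVD, because the spikes inflate the
#     standard deviation) while cancelling in relative biomass (low
#     succession rate).
#   * the headwater site: larger idiosyncratic noise plus *asynchronous*
#     per-taxon bloom episodes (two-state Markov chains with ~2-month
#     persistence and a ~5.5x amplitude), and a flattened thermal gate
#     (nutrient-replete growth continues outside the thermal optimum). These
#     produce sustained, balanced excursions per group (high AVD) and
#     frequent compositional reallocation (high succession rate).

PHYLUM_FG_POOL <- list(
  Chlorophyta     = c("J", "F", "G", "N", "T", "X1", "X2", "X3"),
  Bacillariophyta = c("B", "C", "D", "P", "MP", "A"),
  Cyanophyta      = c("S1", "S2", "S_N", "H1", "K", "TC", "Z", "L_M"),
  Dinophyta       = c("L_O", "Y"),
  Euglenophyta    = c("W1", "W2"),
  Cryptophyta     = "Y",
  Chrysophyta     = "E"
)

# representative genus used to name simulated taxa, per (phylum, code)
SIM_GENUS <- c(
  J = "Scenedesmus", F = "Oocystis", G = "Eudorina", N = "Cosmarium",
  T = "Mougeotia", X1 = "Chlorella", X2 = "Chlamydomonas", X3 = "Schroederia",
  B = "Cyclotella", C = "Asterionella", D = "Synedra", P = "Melosira",
  MP = "Navicula", A = "Rhizosolenia", S1 = "Pseudanabaena", S2 = "Spirulina",
  S_N = "Raphidiopsis", H1 = "Anabaena", K = "Aphanocapsa", TC = "Lyngbya",
  Z = "Synechococcus", L_M = "Dactylococcopsis", L_O = "Peridinium",
  W1 = "Euglena", W2 = "Trachelomonas", Y = "Cryptomonas", E = "Dinobryon"
)

SIM_VOL_MEANLOG <- c(Chlorophyta = log(250), Bacillariophyta = log(800),
                     Cyanophyta = log(60), Dinophyta = log(8000),
                     Euglenophyta = log(2500), Cryptophyta = log(1500),
                     Chrysophyta = log(500))

#' Configuration for the synthetic reservoir survey
#'
#' Defaults describe the emulated study design: 5 sites sampled monthly for
#' 48 months, 95 taxa across 7 phyla, a sinusoidal water-temperature cycle
#' spanning 7.1-28.3 deg C, and one headwater site with elevated TN/TP/CODMn,
#' larger noise and asynchronous bloom episodes (see the package vignette for
#' why the disturbance is structured this way).
#'
#' @param n_sites Number of sites (the first is the headwater).
#' @param n_months Number of monthly occasions (>= 2).
#' @param n_taxa Number of taxa.
#' @param phylum_mix Named fractions over the 7 phyla, summing to 1.
#' @param wt_range Annual water-temperature range, deg C (`c(min, max)`).
#' @param start_date First sampling date; subsequent samples are monthly.
#' @param site_profiles `data.frame` with one row per site: `site`,
#'   `headwater`, `nutrient_mult` (TN/TP/NH3N/CODMn multiplier), `sigma`
#'   (idiosyncratic lognormal sdlog), `shared_sigma` (synchronous
#'   community-pulse sdlog), `episode_amp` (bloom-episode amplitude, 1 =
#'   off), `episode_p_on`, `episode_p_stay` (Markov transition parameters),
#'   `niche_floor` (baseline growth outside the thermal optimum) and
#'   `niche_width_min`, `niche_width_max` (thermal niche sd range, deg C).
#'   `NULL` builds the default profile.
#' @param wt_noise_sd Month-to-month water-temperature noise, deg C.
#' @param tn_pulse_amp Amplitude of the spring (May-centred) nitrogen
#'   loading pulse; 0 disables it.
#' @param env_noise_sd Scale factor on the environmental lognormal noise
#'   terms; 0 makes the environment deterministic.
#' @param detection_limit Abundances below this (cells/L) are recorded as 0.
#' @param seed Integer seed used by [simulate_reservoir()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sites = 5, n_months = 48, n_taxa = 95,
                       phylum_mix = c(Chlorophyta = 0.45, Bacillariophyta = 0.26,
                                      Cyanophyta = 0.18, Dinophyta = 0.0275,
                                      Euglenophyta = 0.0275, Cryptophyta = 0.0275,
                                      Chrysophyta = 0.0275),
                       wt_range = c(7.1, 28.3),
                       start_date = as.Date("2020-01-15"),
                       site_profiles = NULL,
                       wt_noise_sd = 0.8, tn_pulse_amp = 1.5,
                       env_noise_sd = 1, detection_limit = 100,
                       seed = 1L) {
  stopifnot(n_sites >= 1, n_months >= 2, n_taxa >= 1)
  if (!setequal(names(phylum_mix), PHYLA)) {
    stop("phylum_mix must be named with the 7 phyla", call. = FALSE)
  }
  if (abs(sum(phylum_mix) - 1) > 1e-9) stop("phylum_mix must sum to 1", call. = FALSE)
  if (length(wt_range) != 2 || wt_range[1] > wt_range[2]) {
    stop("wt_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (is.null(site_profiles)) {
    site <- sprintf("ST%d", seq_len(n_sites))
    hw <- seq_len(n_sites) == 1
    site_profiles <- data.frame(
      site = site, headwater = hw,
      nutrient_mult = ifelse(hw, 2.5, 1),
      sigma = ifelse(hw, 0.5, 0.25),
      shared_sigma = ifelse(hw, 0.3, 1.0),
      episode_amp = ifelse(hw, 5.5, 1),
      episode_p_on = ifelse(hw, 0.45, 0),
      episode_p_stay = ifelse(hw, 0.5, 0),
      niche_floor = ifelse(hw, 0.5, 0.05),
      niche_width_min = ifelse(hw, 6, 2),
      niche_width_max = ifelse(hw, 10, 4),
      stringsAsFactors = FALSE
    )
  }
  require_columns(site_profiles,
                  c("site", "headwater", "nutrient_mult", "sigma", "shared_sigma",
                    "episode_amp", "episode_p_on", "episode_p_stay", "niche_floor",
                    "niche_width_min", "niche_width_max"),
                  "site_profiles")
  if (nrow(site_profiles) != n_sites) {
    stop("site_profiles must have one row per site", call. = FALSE)
  }
  structure(list(
    n_sites = n_sites, n_months = n_months, n_taxa = n_taxa,
    phylum_mix = phylum_mix[PHYLA], wt_range = wt_range,
    start_date = as.Date(start_date), site_profiles = site_profiles,
    wt_noise_sd = wt_noise_sd, tn_pulse_amp = tn_pulse_amp,
    env_noise_sd = env_noise_sd, detection_limit = detection_limit,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# two-state Markov episode indicator
markov_episode <- function(n, p_on, p_stay) {
  if (p_on <= 0) return(integer(n))
  s <- integer(n)
  cur <- stats::rbinom(1, 1, p_on / (p_on + 1 - p_stay))  # stationary start
  for (t in seq_len(n)) {
    s[t] <- cur
    cur <- if (cur == 1) stats::rbinom(1, 1, p_stay) else stats::rbinom(1, 1, p_on)
  }
  s
}

# largest-remainder apportionment of n_taxa across phyla
apportion <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a monthly multi-site reservoir survey
#'
#' Draws taxa (phylum, functional group, cell volume, thermal optimum and
#' niche width, Monod nitrogen half-saturation, baseline abundance), an
#' environmental table (WT sinusoid plus noise; TN/TP/NH3N/CODMn from
#' site-profile baselines with a spring nitrogen pulse; pH, DO, SD), and an
#' abundance table where the expected abundance is
#' `baseline x thermal response x nitrogen response`, modulated by the
#' site's noise channels (idiosyncratic lognormal, synchronous community
#' pulse, and per-taxon bloom episodes at the headwater). Everything is
#' driven by a single seed: the same seed reproduces the tables exactly.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#' @return A list: `abundance` ([phyto_abundance], taxa carrying `fg_code`),
#'   `env` ([phyto_env]) and `truth` (the generator parameters actually
#'   drawn, for parameter-recovery tests).
#' @export
#' @examples
#' sim <- simulate_reservoir(sim_config(n_sites = 2, n_months = 6, n_taxa = 10, seed = 7))
#' sim$abundance
simulate_reservoir <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  ns <- config$n_sites; nm <- config$n_months; nt <- config$n_taxa
  prof <- config$site_profiles

  # ---- taxa ----
  counts <- apportion(config$phylum_mix, nt)
  phylum <- rep(PHYLA, counts)
  fg <- vapply(phylum, function(ph) {
    pool <- PHYLUM_FG_POOL[[ph]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  name <- paste0(SIM_GENUS[fg], " sp. ", seq_len(nt))
  vol <- exp(stats::rnorm(nt, SIM_VOL_MEANLOG[phylum], 0.6))
  taxa <- data.frame(
    taxon_id = sprintf("t%03d", seq_len(nt)), name = name, phylum = phylum,
    cell_volume_um3 = vol, fg_code = unname(fg), stringsAsFactors = FALSE
  )
  wt_mid <- mean(config$wt_range); wt_amp <- diff(config$wt_range) / 2
  topt_lo <- config$wt_range[1] + 1
  topt_hi <- config$wt_range[2] - 1
  topt <- if (topt_hi > topt_lo) stats::runif(nt, topt_lo, topt_hi) else
    rep(mean(config$wt_range), nt)
  K <- exp(stats::rnorm(nt, log(1.0), 0.7))       # Monod half-saturation, mg/L TN
  base <- exp(stats::rnorm(nt, log(2e4), 1.0))    # baseline abundance, cells/L

  # ---- time axis ----
  dates <- seq(config$start_date, by = "month", length.out = nm)
  month_num <- as.integer(format(dates, "%m"))
  # skewed annual temperature cycle: minimum in February, maximum in July --
  # a 5-month warming limb and a 7-month cooling limb, as in monomictic
  # reservoirs where spring warming outpaces autumn cooling
  mm <- month_num
  rising <- mm >= 2 & mm <= 7
  phase <- ifelse(rising,
                  (1 - cos(pi * (mm - 2) / 5)) / 2,
                  (1 + cos(pi * ((mm - 7) %% 12) / 7)) / 2)
  wt_det <- config$wt_range[1] + diff(config$wt_range) * phase
  spring <- exp(-((month_num - 5)^2) / (2 * 1.5^2))  # May-centred loading pulse

  # ---- per-site tables ----
  env_noise <- config$env_noise_sd
  samples <- list(); env_rows <- list(); abundance <- list()
  truth_sites <- list()
  for (s in seq_len(ns)) {
    p <- prof[s, ]
    wt <- wt_det + stats::rnorm(nm, 0, config$wt_noise_sd)
    wt <- pmin(pmax(wt, config$wt_range[1]), config$wt_range[2])
    tn <- 1.5 * p$nutrient_mult * (1 + config$tn_pulse_amp * spring) *
      exp(stats::rnorm(nm, 0, 0.15 * env_noise))
    tp <- 0.045 * p$nutrient_mult * exp(stats::rnorm(nm, 0, 0.2 * env_noise))
    nh3 <- 0.10 * p$nutrient_mult * exp(stats::rnorm(nm, 0, 0.3 * env_noise))
    cod <- 2.6 * sqrt(p$nutrient_mult) * exp(stats::rnorm(nm, 0, 0.12 * env_noise))
    ph <- pmin(pmax(stats::rnorm(nm, 8.1, 0.2 * max(env_noise, 1e-12)), 7.2), 8.9)
    do_ <- pmax(stats::rnorm(nm, 8.5, 1.8 * max(env_noise, 1e-12)), 3.0)
    sd_ <- pmin(pmax(exp(stats::rnorm(nm, log(1.5 / sqrt(p$nutrient_mult)),
                                      0.3 * max(env_noise, 1e-12))), 0.4), 3.9)

    width <- stats::runif(nt, p$niche_width_min, p$niche_width_max)
    shared <- exp(stats::rnorm(nm, 0, p$shared_sigma))
    thermal <- p$niche_floor +
      exp(-outer(wt, topt, `-`)^2 / (2 * matrix(width^2, nm, nt, byrow = TRUE)))
    monod <- outer(tn, K, function(tnv, kv) tnv / (tnv + kv))
    noise <- matrix(exp(stats::rnorm(nm * nt, 0, p$sigma)), nm, nt)
    ep_state <- matrix(0L, nm, nt)
    if (p$episode_amp > 1 && p$episode_p_on > 0) {
      for (j in seq_len(nt)) {
        ep_state[, j] <- markov_episode(nm, p$episode_p_on, p$episode_p_stay)
      }
    }
    ab <- matrix(base, nm, nt, byrow = TRUE) * thermal * monod *
      shared * noise * p$episode_amp^ep_state
    ab[ab < config$detection_limit] <- 0

    samples[[s]] <- data.frame(site = p$site, date = dates, stringsAsFactors = FALSE)
    env_rows[[s]] <- data.frame(WT = wt, pH = ph, DO = do_, SD = sd_, TN = tn,
                                TP = tp, NH3N = nh3, CODMn = cod)
    abundance[[s]] <- ab
    truth_sites[[p$site]] <- list(width = width, episode_state = ep_state,
                                  shared_pulse = shared)
  }

  samples <- do.call(rbind, samples)
  ab_all <- do.call(rbind, abundance)
  # guarantee the validation invariant (>= 1 positive entry per sample);
  # with realistic configurations this never triggers
  empty <- rowSums(ab_all) == 0
  if (any(empty)) ab_all[empty, which.max(base)] <- config$detection_limit

  tab <- phyto_abundance(samples, taxa, ab_all)
  env <- phyto_env(samples, do.call(rbind, env_rows))
  truth <- list(seed = seed, config = config, topt = topt, K = K, base = base,
                sites = truth_sites)
  list(abundance = tab, env = env, truth = truth)
}

#' Small deterministic fixture
#'
#' A hand-set 2-site x 4-month x 6-taxon survey used in documentation and in
#' exact-value unit tests; every abundance is a fixed round number so biomass
#' and dominance can be verified by hand.
#'
#' @return A list with `abundance` ([phyto_abundance]) and `env`
#'   ([phyto_env]).
#' @export
fixture_small <- function() {
  taxa <- data.frame(
    taxon_id = c("cyc", "pse", "per", "cry", "syn", "sce"),
    name = c("Cyclotella sp.", "Pseudanabaena limnetica", "Peridinium sp.",
             "Cryptomonas sp.", "Synedra sp.", "Scenedesmus sp."),
    phylum = c("Bacillariophyta", "Cyanophyta", "Dinophyta", "Cryptophyta",
               "Bacillariophyta", "Chlorophyta"),
    cell_volume_um3 = c(1200, 30, 8000, 2500, 800, 150),
    fg_code = c("B", "S1", "L_O", "Y", "D", "J"),
    stringsAsFactors = FALSE
  )
  dates <- as.Date(c("2020-01-15", "2020-02-15", "2020-03-15", "2020-04-15"))
  samples <- data.frame(site = rep(c("up", "down"), each = 4),
                        date = rep(dates, 2), stringsAsFactors = FALSE)
  # cells/L; rows = samples (up Jan-Apr, down Jan-Apr), cols = taxa above
  abundance <- matrix(c(
    2e5, 8e5, 1e4, 5e4, 1e5,    0,
    1e5, 1e6, 2e4, 8e4, 5e4,  1e4,
    3e5, 6e5, 5e4, 1e5, 2e5,  2e4,
    5e5, 4e5, 8e4, 2e5, 3e5,  5e4,
    1e5, 2e5, 2e4, 2e4, 5e4,    0,
    8e4, 3e5, 3e4, 4e4, 4e4,  5e3,
    1e5, 2e5, 4e4, 6e4, 9e4,  1e4,
    2e5, 1e5, 6e4, 9e4, 1e5,  2e4
  ), nrow = 8, byrow = TRUE)
  env <- data.frame(
    WT = c(8, 10, 15, 20, 7.5, 9, 14, 19),
    pH = rep(8.1, 8), DO = rep(8.5, 8),
    SD = c(0.8, 0.8, 0.7, 0.6, 1.8, 1.8, 1.7, 1.6),
    TN = c(3.2, 3.4, 3.8, 4.0, 1.4, 1.5, 1.6, 1.7),
    TP = c(0.10, 0.11, 0.12, 0.13, 0.04, 0.04, 0.05, 0.05),
    NH3N = c(0.30, 0.32, 0.35, 0.40, 0.08, 0.09, 0.10, 0.11),
    CODMn = c(4.0, 4.1, 4.3, 4.5, 2.2, 2.3, 2.4, 2.5)
  )
  list(abundance = phyto_abundance(samples, taxa, abundance),
       env = phyto_env(samples, env))
}
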