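#' Mesohabitat specifications for the synthetic reach design
#'
#' The six mesohabitat classes of the survey, with their riverbed stability,
#' grain-size range, and near-bed speed mean/SD at high and low flow. The
#' inner meander margin carries the silt-deposition flag: it is stable but
#' silt-laden, and mussels are absent there.
#'
#' Depth is not reported per mesohabitat in the survey summary; the generator
#' uses lognormal depths with mesohabitat-specific medians (thalweg deepest,
#' depositional margins shallow), listed here as `depth_median` (m) and
#' `depth_sdlog`. Sediments are two-component phi-scale mixtures, as is
#' typical of fluvial deposits: a main sand mode (spread range `sort_lo` to
#' `sort_hi` phi units) plus a displaced secondary mode (a gravel lag or silt
#' drape) holding a fraction `mix_lo` to `mix_hi` of the mass. The stable
#' depositional margins are well sorted with little secondary material; the
#' unstable coarse habitats are poorly sorted mixtures. The secondary mode
#' is what decouples the distribution tails (and hence mean particle size
#' and sorting) from the median diameter.
#'
#' @return data frame, one row per mesohabitat.
#' @export
mesohabitat_specs <- function() {
  data.frame(
    mesohabitat = c("outer_meander_margin", "meander_thalweg",
                    "inner_meander_margin", "left_straight_margin",
                    "straight_mid_channel", "right_straight_margin"),
    stable = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    silt = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    grain_lo = c(0.125, 0.5, 0.03, 0.25, 1, 0.5),
    grain_hi = c(0.5, 2, 0.125, 1, 2, 1),
    u_high_mean = c(0.7, 1.2, 0.5, 1.1, 1.7, 1.2),
    u_high_sd = c(0.2, 0.5, 0.1, 0.3, 0.8, 0.3),
    u_low_mean = c(0.4, 0.9, 0.1, 0.6, 1.3, 0.7),
    u_low_sd = c(0.1, 0.3, 0.1, 0.2, 0.5, 0.5),
    depth_median = c(0.30, 1.80, 0.30, 0.45, 1.20, 0.45),
    depth_sdlog = c(0.60, 0.30, 0.40, 0.40, 0.35, 0.40),
    sort_lo = c(0.15, 0.30, 0.20, 0.30, 0.35, 0.30),
    sort_hi = c(0.45, 0.80, 0.60, 0.70, 0.80, 0.70),
    mix_lo = c(0.03, 0.10, 0.05, 0.10, 0.15, 0.10),
    mix_hi = c(0.28, 0.40, 0.30, 0.35, 0.40, 0.35),
    # range of the main-mode median (phi units). The deposit's plot-level
    # medians cluster in a band inside the mesohabitat grain range; the
    # distribution tails (secondary mode, sorting) carry the rest of the
    # range. At the outer margin the band is the fine half of medium sand.
    mode_phi_lo = c(1.5, -1.0, 3.0, 0.0, -1.0, 0.0),
    mode_phi_hi = c(2.1, 1.0, 5.0, 2.0, 0.0, 1.0),
    stringsAsFactors = FALSE)
}

#' Species suitability-window specifications
#'
#' Default planted responses for the two mussel species: unimodal suitability
#' inside the windows read off the habitat model (mean particle size
#' 0.3--0.5 mm for Castalia ambigua and 0.2--0.4 mm for Anodontites
#' elongatus; sorting index 0.1--0.9 and Froude number 0.005--0.075 for both;
#' Reynolds number 500--1800 and 500--1000 respectively). Densities are zero
#' far outside every window.
#'
#' `peak` is the expected density (ind/m^2) at the suitability optimum,
#' `dispersion` the negative-binomial size parameter of the counts, and the
#' `steep_*` columns the logistic edge widths as fractions of each window's
#' width (smaller = harder threshold). Substrate windows (grain size,
#' sorting) have crisp edges; the hydraulic windows (Froude, Reynolds) have
#' wide logistic shoulders, because the ranges are ridge locations of a
#' smooth hydraulic response rather than on/off cutoffs — near-bed hydraulics
#' grade continuously across a reach.
#'
#' @return data frame, one row per species.
#' @export
species_specs <- function() {
  data.frame(
    species = c("castalia", "anodontites"),
    d_lo = c(0.3, 0.2), d_hi = c(0.5, 0.4),
    fr_lo = c(0.005, 0.005), fr_hi = c(0.075, 0.075),
    re_lo = c(500, 500), re_hi = c(1800, 1000),
    so_lo = c(0.1, 0.1), so_hi = c(0.9, 0.9),
    peak = c(120, 60),
    dispersion = c(8, 8),
    steep_d = c(0.10, 0.10),
    steep_so = c(0.15, 0.15),
    steep_fr = c(0.12, 0.12),
    steep_re = c(3.0, 3.0),
    stringsAsFactors = FALSE)
}

#' Default synthetic reach design
#'
#' The survey layout: 6 sites, 6 mesohabitats per 500-m reach, two 100-m
#' transects per mesohabitat, 25 plots of 1 m^2 per transect at low flow
#' (300 plots per reach) of which a random 15 per transect are revisited at
#' high flow (180 plots per reach).
#'
#' @param sites number of sites.
#' @param plots_low plots per transect at low flow.
#' @param plots_high plots per transect revisited at high flow.
#' @param seed master seed recorded with the design.
#' @return list of class `reach_design`.
#' @export
default_design <- function(sites = 6, plots_low = 25, plots_high = 15, seed = 1) {
  if (plots_high > plots_low)
    stop_invalid("high-flow plots must be a subset of low-flow plots")
  if (sites < 1 || plots_low < 1) stop_invalid("counts must be positive")
  structure(list(sites = sites,
                 mesohabitats = mesohabitat_specs(),
                 transects = 2L,
                 transect_length = 100,
                 plots_low = as.integer(plots_low),
                 plots_high = as.integer(plots_high),
                 plot_area = 1,
                 species = species_specs(),
                 high_flow_rise = 1.5,   # seasonal depth increase (m)
                 seed = seed),
            class = "reach_design")
}

# Truncated-at-zero normal draws via inverse CDF.
rtnorm0 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, lo, 1), mean, sd)
}

#' Mean of the zero-truncated normal speed distribution
#'
#' Analytic mean of N(mean, sd) truncated at zero:
#' `mean + sd * phi(a) / (1 - Phi(a))` with `a = -mean/sd`. The difference
#' from `mean` is the truncation bias used in the generator calibration
#' tolerance.
#'
#' @param mean,sd distribution parameters.
#' @return the truncated mean.
#' @export
truncnorm_mean <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

#' Draw near-bed current speeds for a mesohabitat
#'
#' Seeded draws from the mesohabitat's zero-truncated normal speed
#' distribution, parameterized by the survey-summary mean and SD for the
#' requested flow period.
#'
#' @param mesohabitat one of the names in [mesohabitat_specs()].
#' @param period `"low"` or `"high"`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of speeds (m/s), all nonnegative.
#' @export
draw_speed <- function(mesohabitat, period = c("low", "high"), n, seed = NULL) {
  period <- match.arg(period)
  specs <- mesohabitat_specs()
  i <- match(mesohabitat, specs$mesohabitat)
  if (is.na(i)) stop_invalid("unknown mesohabitat: ", mesohabitat)
  if (!is.null(seed)) set.seed(derive_seed(seed, paste0("speed-", mesohabitat, period)))
  m <- if (period == "high") specs$u_high_mean[i] else specs$u_low_mean[i]
  s <- if (period == "high") specs$u_high_sd[i] else specs$u_low_sd[i]
  rtnorm0(n, m, s)
}

#' Simulate the low-flow survey of one reach
#'
#' Lays the six mesohabitat strips end to end along the reach (100 m each),
#' with two transect lines 4 m apart per strip. Plot positions are stratified
#' along each transect with uniform jitter, which avoids clumping as in the
#' field protocol. Per plot: low-flow speed from the mesohabitat's truncated
#' normal, depth from the mesohabitat's lognormal, and a sieve stack drawn
#' from a phi-normal grain-size distribution whose median lies in the
#' mesohabitat's grain-size range (sieve masses are the phi-bin probabilities
#' of a 100-g subsample).
#'
#' @param design a [default_design()].
#' @param site site id (enters the seed, so sites differ deterministically).
#' @param seed integer master seed.
#' @return data frame with one row per plot: identifiers, coordinates `x`,
#'   `y` (m, reach-local), `U_low`, `d_low`, and wide sieve columns.
#' @export
simulate_reach <- function(design = default_design(), site = 1, seed = design$seed) {
  if (!inherits(design, "reach_design")) stop_invalid("invalid design")
  specs <- design$mesohabitats
  set.seed(derive_seed(seed, "reach", site))
  apertures <- c(2, 1, 0.5, 0.25, 0.125, 0.063)
  rows <- list()
  for (m in seq_len(nrow(specs))) {
    for (tr in seq_len(design$transects)) {
      np <- design$plots_low
      # stratified positions with jitter: one plot per stratum of the transect
      strata <- (seq_len(np) - 1) * design$transect_length / np
      xs <- (m - 1) * design$transect_length + strata +
        runif(np, 0.2, design$transect_length / np - 0.2)
      ys <- (tr - 1) * 4 + runif(np, -0.5, 0.5)
      U <- rtnorm0(np, specs$u_low_mean[m], specs$u_low_sd[m])
      d <- exp(rnorm(np, log(specs$depth_median[m]), specs$depth_sdlog[m]))
      # grain-size distribution: two-component phi mixture; the main sand
      # mode's median sits in the mesohabitat's mode band (inside its grain
      # range), the secondary mode (gravel lag or silt drape, 2.5-4 phi
      # away) carries the tails
      phi_lo <- specs$mode_phi_lo[m]
      phi_hi <- specs$mode_phi_hi[m]
      bnds <- -log2(c(4, apertures))            # phi at fraction bounds
      sieve <- t(vapply(seq_len(np), function(i) {
        mu_phi <- runif(1, phi_lo, phi_hi)
        sd_phi <- runif(1, specs$sort_lo[m], specs$sort_hi[m])
        delta <- sample(c(-1, 1), 1) * runif(1, 2.5, 4)
        sd2 <- runif(1, 0.3, 0.8)
        w2 <- runif(1, specs$mix_lo[m], specs$mix_hi[m])
        # grains coarser than the top sieve's nominal bound stay on the top
        # sieve, so the fractions partition the full 100 g
        p <- (1 - w2) * pnorm(c(bnds[-1], Inf), mu_phi, sd_phi) +
          w2 * pnorm(c(bnds[-1], Inf), mu_phi + delta, sd2)
        diff(c(0, p)) * 100                      # 100-g subsample
      }, numeric(7)))
      colnames(sieve) <- c(paste0("sieve_", apertures), "pan")
      rows[[length(rows) + 1]] <- cbind(
        data.frame(site = site, mesohabitat = specs$mesohabitat[m],
                   transect = tr, plot = seq_len(np),
                   x = xs, y = ys, U_low = U, d_low = d,
                   stringsAsFactors = FALSE),
        as.data.frame(sieve))
    }
  }
  out <- do.call(rbind, rows)
  out$plot_id <- paste(out$site, out$mesohabitat, out$transect, out$plot, sep = "-")
  rownames(out) <- NULL
  out
}

#' Add the high-flow revisit to a simulated reach
#'
#' Per transect, a seeded simple random subsample of `design$plots_high`
#' plots receives a high-flow speed draw from the mesohabitat's high-flow
#' distribution and a high-flow depth (low-flow depth plus the seasonal
#' rise).
#'
#' @param plots output of [simulate_reach()].
#' @param design the [default_design()] used.
#' @param seed integer master seed.
#' @return `plots` with columns `U_high`, `d_high` (NA for plots not
#'   revisited).
#' @export
simulate_high_flow <- function(plots, design = default_design(), seed = design$seed) {
  if (design$plots_high > design$plots_low)
    stop_invalid("high-flow subsample larger than available plots")
  specs <- design$mesohabitats
  plots$U_high <- NA_real_
  plots$d_high <- NA_real_
  for (site in unique(plots$site)) {
    set.seed(derive_seed(seed, "highflow", site))
    for (m in specs$mesohabitat) {
      for (tr in seq_len(design$transects)) {
        idx <- which(plots$site == site & plots$mesohabitat == m &
                       plots$transect == tr)
        if (!length(idx)) next
        if (design$plots_high > length(idx))
          stop_invalid("high-flow subsample larger than available plots")
        pick <- sample(idx, design$plots_high)
        i <- match(m, specs$mesohabitat)
        plots$U_high[pick] <- rtnorm0(length(pick), specs$u_high_mean[i],
                                      specs$u_high_sd[i])
        plots$d_high[pick] <- plots$d_low[pick] + design$high_flow_rise
      }
    }
  }
  plots
}

# smooth window factor: ~1 inside [lo, hi], ->0 outside, logistic edges with
# width = steepness * (hi - lo)
window_factor <- function(x, lo, hi, steepness, hard = FALSE) {
  if (hard) return(as.numeric(x >= lo & x <= hi))
  s <- steepness * (hi - lo)
  plogis((x - lo) / s) * plogis((hi - x) / s)
}

#' Plant species densities on a metric-bearing plot table
#'
#' Expected density per plot is `peak * w(D_mean) * w(Fr) * w(Re) * w(So)`
#' (smooth logistic window factors; `hard_edges = TRUE` replaces them by
#' indicator cutoffs), times a spatially correlated cluster field along each
#' transect, times an optional per-site multiplier (the landscape effect).
#' Counts are negative-binomial with the species' dispersion. Plots in the
#' silt-flagged mesohabitat are forced to zero expected density, emulating
#' silt deposition that excludes mussels regardless of hydraulics.
#'
#' @param plots plot table carrying low-flow grain and hydraulic metrics
#'   (`D_mean`, `So`, `Fr`, `Re` columns; see [hydraulic_table()]).
#' @param species a [species_specs()] table.
#' @param seed integer master seed.
#' @param site_multiplier named numeric vector (names = site ids) scaling
#'   expected density per site; default all 1.
#' @param hard_edges use indicator windows instead of logistic edges.
#' @return `plots` with one density column per species (`dens_<species>`,
#'   integer counts per m^2).
#' @export
plant_mussel_density <- function(plots, species = species_specs(), seed = 1,
                                 site_multiplier = NULL, hard_edges = FALSE) {
  need <- c("D_mean", "So", "Fr", "Re")
  if (!all(need %in% names(plots)))
    stop_invalid("plots lack metric columns ", paste(setdiff(need, names(plots)), collapse = ", "),
                 "; compute grain and hydraulic metrics first")
  silt_habs <- mesohabitat_specs()$mesohabitat[mesohabitat_specs()$silt]
  mult <- rep(1, nrow(plots))
  if (!is.null(site_multiplier)) {
    mm <- site_multiplier[as.character(plots$site)]
    if (any(is.na(mm))) stop_invalid("site_multiplier must cover every site")
    mult <- as.numeric(mm)
  }
  for (sp in seq_len(nrow(species))) {
    s <- species[sp, ]
    set.seed(derive_seed(seed, paste0("dens-", s$species)))
    w <- window_factor(plots$D_mean, s$d_lo, s$d_hi, s$steep_d, hard_edges) *
      window_factor(plots$Fr, s$fr_lo, s$fr_hi, s$steep_fr, hard_edges) *
      window_factor(plots$Re, s$re_lo, s$re_hi, s$steep_re, hard_edges) *
      window_factor(plots$So, s$so_lo, s$so_hi, s$steep_so, hard_edges)
    w[plots$mesohabitat %in% silt_habs] <- 0
    # cluster field: Gaussian bumps along each transect (aggregation within
    # suitable mesohabitats), mean ~1 so the windows set the overall level
    cf <- rep(1, nrow(plots))
    for (key in unique(paste(plots$site, plots$mesohabitat, plots$transect))) {
      idx <- which(paste(plots$site, plots$mesohabitat, plots$transect) == key)
      xs <- plots$x[idx]
      ncl <- rpois(1, 3) + 1
      ctr <- runif(ncl, min(xs), max(xs))
      bump <- rowSums(vapply(ctr, function(c0) exp(-(xs - c0)^2 / (2 * 8^2)),
                             numeric(length(idx))))
      cf[idx] <- 0.7 + 0.9 * bump / max(max(bump), 1e-9)
    }
    muvec <- s$peak * w * cf * mult
    plots[[paste0("dens_", s$species)]] <- rnbinom(nrow(plots), size = s$dispersion,
                                                   mu = pmin(muvec, 1e6))
  }
  plots
}

#' Simulate the site-level landscape table
#'
#' Draws the 13 landscape variables (riparian-zone area, patch counts of
#' forest/agriculture/pasture/rural settlements per km^2, canopy cover,
#' buffer percent cover of forest/agriculture/pasture/rural settlements, and
#' distances to the nearest rural settlement and street plus road density in
#' the 200-m buffer) from documented uniform ranges, and returns a per-site
#' density multiplier that increases with the distance to the nearest rural
#' settlement and street and decreases with the percent of rural settlements
#' and road density (a monotone exp-linear link of configurable strength).
#' Agriculture and pasture variables are generated with no effect, matching
#' the null finding for those stressors.
#'
#' @param nsites number of sites (>= 2).
#' @param effect strength of the urbanization effect (0 = no effect; default 1).
#' @param seed integer seed.
#' @return list with `landscape` (data frame, one row per site) and
#'   `multiplier` (named vector of per-site density multipliers, mean ~1).
#' @export
simulate_landscape <- function(nsites = 6, effect = 1, seed = 1) {
  if (nsites < 2) stop_invalid("need at least 2 sites")
  set.seed(derive_seed(seed, "landscape"))
  u <- function(lo, hi) runif(nsites, lo, hi)
  ls <- data.frame(
    site = seq_len(nsites),
    R_Area = u(1, 5),
    N_Forest = u(2, 12),
    N_Agriculture = u(0, 8),
    N_Pasture = u(0, 6),
    N_RuralSet = u(0, 4),
    Can_Cover = u(40, 100),
    P_Forest = u(30, 95),
    P_Agriculture = u(0, 40),
    P_Pasture = u(0, 40),
    D_RuralSet = u(50, 3000),
    D_Street = u(20, 2000),
    P_RuralSet = u(0, 30),
    D_Road = u(0, 6))
  z <- function(v, lo, hi) 2 * (v - lo) / (hi - lo) - 1
  lin <- z(ls$D_RuralSet, 50, 3000) + z(ls$D_Street, 20, 2000) -
    z(ls$P_RuralSet, 0, 30) - z(ls$D_Road, 0, 6)
  mult <- exp(effect * 0.5 * lin)
  mult <- mult / mean(mult)
  names(mult) <- as.character(ls$site)
  list(landscape = ls, multiplier = mult)
}

#' Simulate a full multi-site study
#'
#' Runs the generator end to end: per site, the low-flow survey, the
#' high-flow revisit, grain and hydraulic metrics, then the landscape table
#' and planted species densities (with the landscape multiplier applied).
#'
#' @param design a [default_design()].
#' @param seed integer master seed.
#' @param landscape_effect passed to [simulate_landscape()].
#' @param consts hydraulic constants for the metric computation.
#' @return list with `plots` (all sites, metrics and densities) and
#'   `landscape` (site table with per-site mean densities appended).
#' @export
simulate_study <- function(design = default_design(), seed = design$seed,
                           landscape_effect = 1,
                           consts = hydraulic_constants()) {
  plots <- do.call(rbind, lapply(seq_len(design$sites), function(s)
    simulate_reach(design, site = s, seed = seed)))
  plots <- simulate_high_flow(plots, design, seed = seed)
  plots <- suppressWarnings(hydraulic_table(plots, consts, period = "low"))
  land <- simulate_landscape(design$sites, effect = landscape_effect, seed = seed)
  plots <- plant_mussel_density(plots, design$species, seed = seed,
                                site_multiplier = land$multiplier)
  site_dens <- aggregate(cbind(dens_castalia, dens_anodontites) ~ site,
                         data = plots, FUN = mean)
  landscape <- merge(land$landscape, site_dens, by = "site")
  list(plots = plots, landscape = landscape, multiplier = land$multiplier)
}
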