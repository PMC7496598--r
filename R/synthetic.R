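#' Configuration for the synthetic body-mass-spectrum study
#'
#' Defines the generating laws of a synthetic tracking study spanning the
#' mammalian body-mass spectrum, with the statistical structure the bias
#' analysis rests on: home-range area scales with mass as
#' \eqn{H = B_0 M^b} (lognormal species scatter); the range-crossing time
#' grows with home-range area as \eqn{\tau_p = c_\tau H^{\gamma}}; sampling
#' duration grows only weakly with mass (\eqn{T = T_0 M^{0.24}}); and the
#' GPS duty cycle \code{dt} is fixed across species, so autocorrelation
#' strength varies through \eqn{\tau_p} and the effective sample size
#' \eqn{N_{area} = T/\tau_p} declines with mass (roughly 3-300 across the
#' default mass range).
#'
#' @param n_species number of species.
#' @param individuals_per_species tracks per species.
#' @param mass_range_kg body-mass range (log-uniform sampling).
#' @param B0 home-range normalization (km^2 at 1 kg).
#' @param b allometric scaling exponent of home range on mass.
#' @param hr_sdlog lognormal scatter (SD of log) around the home-range law.
#' @param tau_coef_days \eqn{c_\tau}: range-crossing time in days of a
#'   1-km^2 home range.
#' @param tau_exp \eqn{\gamma}: exponent of crossing time on area.
#' @param tau_sdlog lognormal scatter around the crossing-time law.
#' @param T0_days sampling duration of a 1-kg species, days.
#' @param T_exp exponent of duration on mass (default 0.24).
#' @param T_sdlog lognormal scatter around the duration law.
#' @param dt_hours sampling interval, hours (fixed across species).
#' @param family movement process family for the simulated tracks.
#' @param tau_v_frac \code{tau_v} as a fraction of \code{tau_p} (OUF).
#' @param anisotropy ratio of major to minor range axis variance (1 =
#'   isotropic).
#' @param max_points cap on fixes per track; longer schedules are coarsened
#'   with a logged warning.
#' @param seed master seed (mandatory); all randomness derives from it.
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_species = 40, individuals_per_species = 3,
                         mass_range_kg = c(0.4, 4000),
                         B0 = 0.5, b = 1.1, hr_sdlog = 0.3,
                         tau_coef_days = 0.5, tau_exp = 0.6,
                         tau_sdlog = 0.3,
                         T0_days = 45, T_exp = 0.24, T_sdlog = 0.2,
                         dt_hours = 1, family = "OUF", tau_v_frac = 0.1,
                         anisotropy = 1, max_points = 20000, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(all(mass_range_kg > 0), n_species >= 2,
            individuals_per_species >= 1, dt_hours > 0, B0 > 0,
            tau_coef_days > 0, T0_days > 0, anisotropy >= 1)
  structure(cfg, class = "synth_config")
}

#' Generate the species spectrum (ground truth)
#'
#' Draws species masses log-uniformly over the configured range and applies
#' the generating laws to produce each species' true home-range area,
#' spatial covariance, range-crossing time, velocity timescale, sampling
#' duration and effective sample size, all recorded before any estimation.
#' The true 95\% home-range area relates to the isotropic per-dimension
#' variance by \eqn{H = \pi \chi^2_{2,0.95} \sigma^2}.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A data.frame of class \code{"species_spectrum"}: one row per
#'   species with \code{species, mass_kg, diet_class, hr_area_km2,
#'   sigma_m2, tau_p_s, tau_v_s, T_s, dt_s, n_area_true}.
#' @export
generate_species_spectrum <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    ns <- config$n_species
    mass <- exp(stats::runif(ns, log(config$mass_range_kg[1]),
                             log(config$mass_range_kg[2])))
    mass <- sort(mass)
    hr <- config$B0 * mass^config$b *
      stats::rlnorm(ns, 0, config$hr_sdlog)                       # km^2
    tau_p <- config$tau_coef_days * 86400 * hr^config$tau_exp *
      stats::rlnorm(ns, 0, config$tau_sdlog)                      # s
    T <- config$T0_days * 86400 * mass^config$T_exp *
      stats::rlnorm(ns, 0, config$T_sdlog)                        # s
    diet <- sample(c("carnivore/omnivore", "herbivore/frugivore"),
                   ns, replace = TRUE)
    sigma <- hr * 1e6 / (pi * stats::qchisq(0.95, 2))             # m^2/dim
    out <- data.frame(
      species = sprintf("sp%02d", seq_len(ns)),
      mass_kg = mass, diet_class = diet,
      hr_area_km2 = hr, sigma_m2 = sigma,
      tau_p_s = tau_p,
      tau_v_s = if (config$family == "OUF")
        config$tau_v_frac * tau_p else NA_real_,
      T_s = T, dt_s = config$dt_hours * 3600,
      n_area_true = T / tau_p)
    class(out) <- c("species_spectrum", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' @export
print.species_spectrum <- function(x, ...) {
  cat(sprintf(
    "Synthetic species spectrum: %d species, mass %.3g-%.3g kg, N_area %.2g-%.2g\n",
    nrow(x), min(x$mass_kg), max(x$mass_kg), min(x$n_area_true),
    max(x$n_area_true)))
  print.data.frame(utils::head(x, 4), digits = 3)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

# deterministic per-individual seed stream below 2^31
derive_seed <- function(master, i)
  as.integer((as.numeric(master) * 48271 + 7919 * i) %% 2147483629 + 1)

species_sigma <- function(sigma_m2, anisotropy)
  diag(c(sigma_m2 * anisotropy, sigma_m2 / anisotropy))

#' Simulate the tracks of the synthetic study
#'
#' One track per individual at the configured interval for the species'
#' duration, drawn from its true movement process via exact Gaussian
#' transitions. Schedules exceeding \code{max_points} fixes are coarsened
#' to the cap with a warning. Per-individual seeds are derived
#' deterministically from the master seed.
#'
#' @param truth a \code{\link{generate_species_spectrum}} table.
#' @param config the \code{\link{synth_config}} (defaults to the one the
#'   truth was generated with).
#' @return A named list of \code{\link{track}} objects
#'   (\code{<species>_<i>}).
#' @export
generate_tracks <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(truth, "species_spectrum"),
            inherits(config, "synth_config"))
  out <- list()
  idx <- 0
  for (s in seq_len(nrow(truth))) {
    dt <- truth$dt_s[s]
    T <- truth$T_s[s]
    if (T < 2 * dt) stop("duration shorter than two sampling intervals")
    if (T / dt > config$max_points) {
      dt <- T / config$max_points
      warning(sprintf("%s: schedule coarsened to dt = %.3g h to cap points",
                      truth$species[s], dt / 3600), call. = FALSE)
    }
    times <- seq(0, T, by = dt)
    model <- movement_model(
      config$family, mu = c(0, 0),
      sigma = species_sigma(truth$sigma_m2[s], config$anisotropy),
      tau_p = if (config$family == "IID") NULL else truth$tau_p_s[s],
      tau_v = if (config$family == "OUF") truth$tau_v_s[s] else NULL)
    for (i in seq_len(config$individuals_per_species)) {
      idx <- idx + 1
      id <- sprintf("%s_%d", truth$species[s], i)
      out[[id]] <- simulate_track(model, times,
                                  seed = derive_seed(config$seed, idx),
                                  id = id)
    }
  }
  out
}

#' Generate a random phylogeny over the species
#'
#' Random bifurcating topology built by uniform coalescent-style joins
#' (repeatedly merging two uniformly chosen clades), with Grafen branch
#' lengths applied, so the result is rooted and ultrametric with the
#' species as tips. A stand-in for a literature phylogeny when exercising
#' the pipeline on synthetic data.
#'
#' @param species_labels tip labels (>= 2, unique).
#' @param seed RNG seed.
#' @return A rooted ultrametric \code{ape::phylo} tree.
#' @export
generate_phylogeny <- function(species_labels, seed = NULL) {
  labels <- as.character(species_labels)
  if (length(labels) < 2) stop("need at least 2 species")
  if (anyDuplicated(labels)) stop("duplicate species labels")
  with_seed(seed, {
    clades <- labels
    while (length(clades) > 1) {
      pick <- sample.int(length(clades), 2)
      merged <- sprintf("(%s,%s)", clades[pick[1]], clades[pick[2]])
      clades <- c(clades[-pick], merged)
    }
    tree <- ape::read.tree(text = paste0(clades, ";"))
    grafen_branch_lengths(tree)
  })
}

#' Generate a full synthetic study
#'
#' Spectrum, tracks and phylogeny in one call — the exact input surface of
#' the analysis pipeline.
#'
#' @param config a \code{\link{synth_config}}.
#' @return A list of class \code{"synthetic_study"} with \code{truth},
#'   \code{tracks}, \code{tree}, \code{species} (covariate table) and the
#'   config.
#' @export
synth_study <- function(config) {
  truth <- generate_species_spectrum(config)
  tracks <- generate_tracks(truth, config)
  tree <- generate_phylogeny(truth$species,
                             seed = derive_seed(config$seed, 0))
  structure(list(truth = truth, tracks = tracks, tree = tree,
                 species = truth[, c("species", "mass_kg", "diet_class")],
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d species x %d individuals (%d tracks)\n",
              nrow(x$truth), x$config$individuals_per_species,
              length(x$tracks)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the pipeline's input surface: tracks CSV (native dialect),
#' species covariates CSV (\code{species, mass_kg, diet_class}), the truth
#' table CSV, and the phylogeny in Newick format.
#'
#' @param study a \code{\link{synth_study}} result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(study$tracks, file.path(dir, "tracks.csv"))
  utils::write.csv(study$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(study$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  ape::write.tree(study$tree, file.path(dir, "phylogeny.nwk"))
  invisible(dir)
}
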