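test_that("the species spectrum encodes the generating laws", {
  cfg <- synth_config(n_species = 30, seed = 10)
  sp <- generate_species_spectrum(cfg)
  expect_equal(nrow(sp), 30)
  expect_true(all(sp$mass_kg >= 0.4 & sp$mass_kg <= 4000))
  expect_equal(sp$n_area_true, sp$T_s / sp$tau_p_s)
  # true area ties to sigma via the 95% Gaussian contour
  expect_equal(sp$hr_area_km2 * 1e6, pi * qchisq(0.95, 2) * sp$sigma_m2)

  # composition of the laws: N_area declines with mass
  expect_lt(cor(sp$mass_kg, sp$n_area_true, method = "spearman"), 0)

  # determinism
  sp2 <- generate_species_spectrum(cfg)
  expect_identical(sp, sp2)

  # zero scatter: exact power laws recoverable from logs
  cfg0 <- synth_config(n_species = 20, hr_sdlog = 0, tau_sdlog = 0,
                       T_sdlog = 0, seed = 11)
  s0 <- generate_species_spectrum(cfg0)
  b_hat <- coef(lm(log10(hr_area_km2) ~ log10(mass_kg), s0))[2]
  expect_equal(unname(b_hat), cfg0$b, tolerance = 1e-10)
  t_hat <- coef(lm(log10(T_s) ~ log10(mass_kg), s0))[2]
  expect_equal(unname(t_hat), cfg0$T_exp, tolerance = 1e-10)
  expect_error(synth_config(n_species = 10), "seed")
})

test_that("generated tracks follow their truth", {
  cfg <- synth_config(n_species = 3, individuals_per_species = 2,
                      mass_range_kg = c(1, 50), seed = 12)
  truth <- generate_species_spectrum(cfg)
  tracks <- generate_tracks(truth, cfg)
  expect_length(tracks, 6)
  expect_named(tracks, c("sp01_1", "sp01_2", "sp02_1", "sp02_2",
                         "sp03_1", "sp03_2"))
  # deterministic given the master seed
  tracks2 <- generate_tracks(truth, cfg)
  expect_identical(tracks$sp02_1$xy, tracks2$sp02_1$xy)
  # distinct individuals get distinct paths
  expect_false(identical(tracks$sp01_1$xy, tracks$sp01_2$xy))

  # empirical variance near truth for a long track (many range crossings)
  s <- which.max(truth$n_area_true)
  tr <- tracks[[paste0(truth$species[s], "_1")]]
  v <- mean(apply(tr$xy, 2, var))
  expect_lt(abs(v - truth$sigma_m2[s]) / truth$sigma_m2[s],
            3 * sqrt(2 / truth$n_area_true[s]) + 0.1)

  # the point cap coarsens the schedule rather than truncating the span
  cfg_cap <- synth_config(n_species = 2, individuals_per_species = 1,
                          mass_range_kg = c(100, 200), max_points = 500,
                          seed = 13)
  truth_cap <- generate_species_spectrum(cfg_cap)
  w <- capture_warnings(tr_cap <- generate_tracks(truth_cap, cfg_cap))
  expect_true(length(w) >= 1 && all(grepl("coarsened", w)))
  expect_lte(max(vapply(tr_cap, n_locations, 0L)), 501)
  expect_equal(tr_cap[[1]]$schedule$duration, truth_cap$T_s[1],
               tolerance = 0.01)

  # zero-duration guard
  truth_bad <- truth; truth_bad$T_s[1] <- truth$dt_s[1]
  expect_error(generate_tracks(truth_bad, cfg), "two sampling intervals")
})

test_that("generated phylogenies are valid and serialize", {
  expect_equal(sort(generate_phylogeny(c("a", "b"), seed = 1)$tip.label),
               c("a", "b"))
  expect_error(generate_phylogeny("a", seed = 1), "at least 2")
  expect_error(generate_phylogeny(c("a", "a"), seed = 1), "duplicate")

  tree <- generate_phylogeny(paste0("sp", 1:17), seed = 14)
  expect_true(ape::is.rooted(tree))
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))

  # newick round trip preserves topology and branch lengths
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tree, f)
  back <- ape::read.tree(f)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_equal(phylo_covariance(back)[tree$tip.label, tree$tip.label],
               phylo_covariance(tree), tolerance = 1e-8)
})

test_that("a full synthetic study writes the pipeline's input surface", {
  cfg <- synth_config(n_species = 3, individuals_per_species = 1,
                      mass_range_kg = c(1, 10), seed = 15)
  st <- synth_study(cfg)
  d <- tempfile()
  write_synthetic_study(st, d)
  expect_setequal(list.files(d), c("tracks.csv", "species.csv",
                                   "truth.csv", "phylogeny.nwk"))
  back <- read_tracks(file.path(d, "tracks.csv"))
  expect_length(back, 3)
  expect_equal(back[["sp02_1"]]$xy, st$tracks[["sp02_1"]]$xy,
               tolerance = 1e-6, ignore_attr = TRUE)
  cov <- utils::read.csv(file.path(d, "species.csv"))
  expect_named(cov, c("species", "mass_kg", "diet_class"))
  expect_equal(sort(ape::read.tree(file.path(d, "phylogeny.nwk"))$tip.label),
               sort(st$truth$species))
})
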