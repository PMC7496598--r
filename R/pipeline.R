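#' Study configuration
#'
#' Bundles the inputs and knobs of a full analysis run: either file paths
#' (tracks CSV, species covariates CSV, Newick phylogeny) or a synthetic
#' study / config, plus the coverage quantiles, estimation methods,
#' bootstrap sizes and seed.
#'
#' @param tracks,species,tree file paths (native track CSV dialect,
#'   \code{species, mass_kg, diet_class} CSV, Newick), or pre-loaded
#'   objects (list of tracks, data.frame, \code{phylo}).
#' @param synth alternatively, a \code{\link{synth_config}} or
#'   \code{\link{synth_study}} supplying everything.
#' @param quantiles coverage quantiles (default 0.50 and 0.95).
#' @param methods estimation methods: subset of \code{c("KDE", "AKDE",
#'   "thinKDE")} (thinKDE = conventional KDE on model-informed thinned
#'   data).
#' @param grid density grid specification (see [estimate_density()]).
#' @param gate_boot comparability-gate bootstrap size.
#' @param median_boot bootstrap size for median confidence intervals.
#' @param area_correction apply the small-sample bias correction to the
#'   estimates (reported areas and the cross-validated contours alike).
#' @param seed master seed for every stochastic stage.
#' @return A list of class \code{"study_config"}.
#' @export
study_config <- function(tracks = NULL, species = NULL, tree = NULL,
                         synth = NULL, quantiles = c(0.5, 0.95),
                         methods = c("KDE", "AKDE", "thinKDE"),
                         grid = list(), gate_boot = 200,
                         median_boot = 1000, area_correction = TRUE,
                         seed = 1) {
  stopifnot(length(methods) >= 1,
            all(methods %in% c("KDE", "AKDE", "thinKDE")),
            all(quantiles > 0 & quantiles < 1))
  if (is.null(synth) && is.null(tracks))
    stop("supply either input data or a synthetic config")
  structure(as.list(environment()), class = "study_config")
}

load_study_inputs <- function(config) {
  if (!is.null(config$synth)) {
    st <- if (inherits(config$synth, "synthetic_study")) config$synth
          else synth_study(config$synth)
    return(list(tracks = st$tracks, species = st$species, tree = st$tree,
                truth = st$truth))
  }
  tracks <- if (is.character(config$tracks)) read_tracks(config$tracks)
            else config$tracks
  species <- if (is.character(config$species))
    utils::read.csv(config$species, stringsAsFactors = FALSE)
  else config$species
  tree <- if (is.character(config$tree)) ape::read.tree(config$tree)
          else config$tree
  list(tracks = tracks, species = species, tree = tree, truth = NULL)
}

# species label of an individual id "<species>_<i>"
species_of <- function(id) sub("_[^_]*$", "", id)

analyze_individual <- function(tr, config, seed) {
  out <- list(id = tr$id, status = "ok", messages = character())
  note <- function(msg) out$messages <<- c(out$messages, msg)

  res <- tryCatch(check_range_residency(tr), error = function(e) {
    note(conditionMessage(e)); NULL })
  if (is.null(res)) { out$status <- "screen_failed"; return(out) }
  out$residency <- res$status
  if (identical(res$resident, FALSE)) {
    out$status <- "nonresident"
    return(out)
  }

  fit <- tryCatch(select_movement(tr), error = function(e) {
    note(conditionMessage(e)); NULL })
  if (is.null(fit)) { out$status <- "fit_failed"; return(out) }
  out$fit <- fit
  out$tau_p <- fit$tau_p %||% NA_real_
  out$n_area <- effective_sample_size(fit, tr$schedule)

  # full-data home ranges per method (for the allometry branch)
  areas <- list()
  if ("KDE" %in% config$methods)
    areas$KDE <- kde(tr, grid = config$grid,
                     correction = config$area_correction)
  if ("AKDE" %in% config$methods)
    areas$AKDE <- akde(tr, fit, grid = config$grid,
                       correction = config$area_correction)

  # thinning branch
  thin <- NULL
  if (("thinKDE" %in% config$methods) && !is.null(fit$tau_p)) {
    thin <- thin_report(tr, fit$tau_p)
    if (thin$estimable) {
      refit <- tryCatch(select_movement(thin$track),
                        error = function(e) NULL)
      thin$refit_family <- if (!is.null(refit)) refit$family else NA
      areas$thinKDE <- kde(thin$track, grid = config$grid,
                           correction = config$area_correction)
    } else note("thinned track unestimable (<= 2 locations)")
  }
  out$thin <- thin
  out$areas <- areas

  # block cross-validation
  halves <- tryCatch(split_half(tr), error = function(e) {
    note(conditionMessage(e)); NULL })
  if (is.null(halves)) { out$status <- "too_short_for_crossval"; return(out) }
  g <- comparability_gate(halves$training, halves$heldout,
                          family = fit$family, n_boot = config$gate_boot,
                          seed = seed)
  out$gate <- g
  if (!isTRUE(g$pass)) { out$status <- "gate_excluded"; return(out) }

  fit_tr <- g$fit_training
  out$n_area_train <- effective_sample_size(fit_tr, halves$training$schedule)
  cvests <- list()
  corr <- config$area_correction
  if ("KDE" %in% config$methods)
    cvests$KDE <- kde(halves$training, grid = config$grid,
                      correction = corr)
  if ("AKDE" %in% config$methods)
    cvests$AKDE <- akde(halves$training, fit_tr, grid = config$grid,
                        correction = corr)
  if (("thinKDE" %in% config$methods) && !is.null(fit_tr$tau_p)) {
    thin_tr <- thin_track(halves$training, decay_lag(fit_tr$tau_p, 0.05))
    if (n_locations(thin_tr) > 2)
      cvests$thinKDE <- kde(thin_tr, grid = config$grid,
                            correction = corr)
    else note("thinned training half unestimable")
  }
  cv <- list()
  for (m in names(cvests)) {
    for (q in config$quantiles) {
      br <- bias_ratio(cvests[[m]], halves$heldout, q)
      cv[[paste(m, q)]] <- data.frame(
        method = m, q = q,
        inclusion_pct = round(
          crossval_inclusion(cvests[[m]], halves$heldout, q), 1),
        bias_ratio = br$ratio)
    }
  }
  out$crossval <- do.call(rbind, cv)
  out
}

#' Run the full study
#'
#' Orchestrates the analysis end to end, per individual: range-residency
#' screen, movement-model selection, home-range estimation per method
#' (KDE / AKDE / thinned KDE) on the full data, the comparability-gated
#' half-sample block cross-validation with held-out inclusion and
#' contour-ratio statistics, and the thinning report; then species-level
#' aggregation (medians) and the phylogenetically controlled regressions
#' (allometry per method, the bias-versus-mass model comparison, and the
#' mass -> H -> tau_p -> N_area mechanism chain). Per-individual failures
#' are isolated and logged; the study proceeds.
#'
#' @param config a \code{\link{study_config}}.
#' @return An object of class \code{"study_result"}: \code{individuals}
#'   (per individual x method x quantile table), \code{species}
#'   (aggregates), \code{fits} (regressions), \code{manifest}.
#' @seealso [summary.study_result()], [write_study_result()]
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  inp <- load_study_inputs(config)
  ids <- names(inp$tracks)
  if (is.null(ids)) ids <- vapply(inp$tracks, function(t) t$id, "")

  per <- vector("list", length(inp$tracks))
  for (i in seq_along(inp$tracks)) {
    per[[i]] <- analyze_individual(inp$tracks[[i]], config,
                                   seed = derive_seed(config$seed, 10000 + i))
  }
  names(per) <- ids

  rows <- list()
  for (p in per) {
    base <- data.frame(
      individual_id = p$id, species = species_of(p$id),
      status = p$status,
      family = if (!is.null(p$fit)) p$fit$family else NA,
      tau_p_s = p$tau_p %||% NA_real_,
      n_area = p$n_area %||% NA_real_,
      gate = if (!is.null(p$gate))
        (if (isTRUE(p$gate$pass)) "pass" else "excluded") else NA,
      D_B = if (!is.null(p$gate)) p$gate$D_B else NA_real_,
      data_loss_pct = if (!is.null(p$thin)) p$thin$data_loss_pct
                      else NA_real_,
      thin_unestimable = if (!is.null(p$thin)) !p$thin$estimable else NA,
      lag1_acf_before = if (!is.null(p$thin)) p$thin$lag1_acf_before
                        else NA_real_,
      lag1_acf_after = if (!is.null(p$thin)) p$thin$lag1_acf_after
                       else NA_real_)
    for (m in names(p$areas)) {
      for (q in config$quantiles) {
        r <- base
        r$method <- m; r$q <- q
        r$area_km2 <- area_at_quantile(p$areas[[m]], q)
        cvm <- if (is.null(p$crossval)) NULL
               else p$crossval[p$crossval$method == m & p$crossval$q == q, ]
        hit <- !is.null(cvm) && nrow(cvm) == 1
        r$inclusion_pct <- if (hit) cvm$inclusion_pct else NA_real_
        r$bias_ratio <- if (hit) cvm$bias_ratio else NA_real_
        rows[[length(rows) + 1]] <- r
      }
    }
    if (length(p$areas) == 0) rows[[length(rows) + 1]] <- base
  }
  individuals <- do.call(rbind, lapply(rows, function(r) {
    for (col in c("method", "q", "area_km2", "inclusion_pct", "bias_ratio"))
      if (is.null(r[[col]])) r[[col]] <- NA
    r
  }))
  rownames(individuals) <- NULL

  species_tab <- aggregate_species(individuals, inp$species)
  fits <- study_regressions(species_tab, inp$tree, config)

  manifest <- list(
    seed = config$seed, quantiles = config$quantiles,
    methods = config$methods,
    n_individuals = length(inp$tracks),
    n_species = length(unique(individuals$species)),
    package_version = as.character(utils::packageVersion("hrbias")))
  structure(list(individuals = individuals, species = species_tab,
                 fits = fits, config = config, manifest = manifest,
                 truth = inp$truth, tree = inp$tree),
            class = "study_result")
}

# species-level aggregation by median of individual values
aggregate_species <- function(individuals, covariates) {
  ok <- !is.na(individuals$method)
  d <- individuals[ok, ]
  if (nrow(d) == 0) stop("no individual produced an estimate")
  key <- interaction(d$species, d$method, d$q, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(g) data.frame(
    species = g$species[1], method = g$method[1], q = g$q[1],
    n_individuals = nrow(g),
    area_km2 = stats::median(g$area_km2, na.rm = TRUE),
    tau_p_s = stats::median(g$tau_p_s, na.rm = TRUE),
    n_area = stats::median(g$n_area, na.rm = TRUE),
    T_s = NA_real_,
    inclusion_pct = stats::median(g$inclusion_pct, na.rm = TRUE),
    bias_ratio = stats::median(g$bias_ratio, na.rm = TRUE),
    data_loss_pct = stats::median(g$data_loss_pct, na.rm = TRUE))))
  rownames(agg) <- NULL
  merge(covariates, agg, by = "species")
}

# the phylogenetically controlled regression suite
study_regressions <- function(species_tab, tree, config) {
  fits <- list()
  C <- if (!is.null(tree)) phylo_covariance(tree) else NULL
  hiq <- max(config$quantiles)
  for (m in intersect(c("KDE", "AKDE", "thinKDE"), species_tab$method)) {
    d <- species_tab[species_tab$method == m & species_tab$q == hiq, ]
    d <- d[stats::complete.cases(d[, c("mass_kg", "area_km2")]) &
             d$area_km2 > 0, ]
    if (nrow(d) >= 8) {
      dd <- data.frame(species = d$species,
                       log_area = log10(d$area_km2),
                       log_mass = log10(d$mass_kg))
      fits[[paste0("allometry_", m)]] <-
        tryCatch(pgls(log_area ~ log_mass, dd, C), error = function(e) NULL)
      dinc <- d[!is.na(d$inclusion_pct), ]
      if (nrow(dinc) >= 8)
        fits[[paste0("bias_models_", m)]] <- tryCatch(
          fit_bias_models(dinc$inclusion_pct, log10(dinc$mass_kg), C,
                          species = dinc$species),
          error = function(e) NULL)
      du <- d[!is.na(d$bias_ratio) & d$bias_ratio > 0, ]
      if (nrow(du) >= 8)
        fits[[paste0("underestimation_models_", m)]] <- tryCatch(
          fit_bias_models(underestimation_from_ratio(du$bias_ratio),
                          log10(du$mass_kg), C, species = du$species),
          error = function(e) NULL)
    }
  }
  # mechanism chain on the AKDE branch (or first available method)
  m0 <- if ("AKDE" %in% species_tab$method) "AKDE"
        else species_tab$method[1]
  d <- species_tab[species_tab$method == m0 & species_tab$q == hiq, ]
  d <- d[stats::complete.cases(d[, c("mass_kg", "area_km2", "tau_p_s",
                                     "n_area")]), ]
  if (nrow(d) >= 8) {
    dd <- data.frame(species = d$species,
                     log_mass = log10(d$mass_kg),
                     log_area = log10(d$area_km2),
                     log_tau = log10(d$tau_p_s),
                     log_narea = log10(d$n_area))
    chain <- list(mass_to_area = log_area ~ log_mass,
                  area_to_tau = log_tau ~ log_area,
                  tau_to_narea = log_narea ~ log_tau,
                  mass_to_narea = log_narea ~ log_mass)
    for (nm in names(chain))
      fits[[paste0("chain_", nm)]] <-
        tryCatch(pgls(chain[[nm]], dd, C), error = function(e) NULL)
  }
  fits
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study result: %d individuals, %d species\n",
              x$manifest$n_individuals, x$manifest$n_species))
  cat(sprintf("  methods: %s; quantiles: %s\n",
              paste(x$manifest$methods, collapse = ", "),
              paste(x$manifest$quantiles, collapse = ", ")))
  cat(sprintf("  %d regression fits; seed %d\n", length(x$fits),
              x$manifest$seed))
  invisible(x)
}

#' Summarize a study result
#'
#' Per method and quantile: median held-out inclusion with a bootstrap
#' confidence interval; mean proportional underestimation in the small
#' (< 10 kg) and large (> 100 kg) mass bands; the QAICc-selected
#' bias-versus-mass model; allometric exponents with confidence intervals
#' and the superlinearity verdict; thinning cost.
#'
#' @param object a \code{\link{run_study}} result.
#' @param ... unused.
#' @return A list of class \code{"summary.study_result"} with components
#'   \code{coverage}, \code{mass_bands}, \code{allometry},
#'   \code{bias_model}, \code{thinning}.
#' @export
summary.study_result <- function(object, ...) {
  ind <- object$individuals
  cfg <- object$config
  ok <- !is.na(ind$method)
  cov_rows <- list()
  for (m in unique(ind$method[ok])) for (q in cfg$quantiles) {
    v <- ind$inclusion_pct[ok & ind$method == m & ind$q == q]
    ci <- median_ci(v, n_boot = cfg$median_boot,
                    seed = derive_seed(cfg$seed, 999))
    cov_rows[[paste(m, q)]] <- data.frame(
      method = m, q = q, n = sum(!is.na(v)),
      median_inclusion = ci["median"], lower = ci["lower"],
      upper = ci["upper"])
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL

  hiq <- max(cfg$quantiles)
  bands <- list()
  sp <- object$species
  for (m in unique(sp$method)) {
    d <- sp[sp$method == m & sp$q == hiq & !is.na(sp$bias_ratio), ]
    u <- underestimation_from_ratio(d$bias_ratio)
    bands[[m]] <- data.frame(
      method = m,
      mean_underestimation_small = mean(u[d$mass_kg < 10]) ,
      mean_underestimation_large = mean(u[d$mass_kg > 100]))
  }
  mass_bands <- do.call(rbind, bands)
  rownames(mass_bands) <- NULL

  allom <- list()
  for (m in c("KDE", "AKDE", "thinKDE")) {
    f <- object$fits[[paste0("allometry_", m)]]
    if (!is.null(f)) {
      ts <- test_superlinearity(f)
      allom[[m]] <- data.frame(method = m, b = ts$b,
                               lower = ts$ci[1], upper = ts$ci[2],
                               superlinear = ts$superlinear)
    }
  }
  allometry <- if (length(allom)) do.call(rbind, allom)
  if (!is.null(allometry)) rownames(allometry) <- NULL

  bias_model <- vapply(c("KDE", "AKDE", "thinKDE"), function(m) {
    f <- object$fits[[paste0("bias_models_", m)]]
    if (is.null(f)) NA_character_ else f$selected
  }, "")

  thinning <- if (any(!is.na(ind$data_loss_pct))) {
    first <- ind[!duplicated(ind$individual_id), ]
    data.frame(
      mean_data_loss_pct = mean(first$data_loss_pct, na.rm = TRUE),
      mean_lag1_before = mean(first$lag1_acf_before, na.rm = TRUE),
      mean_lag1_after = mean(first$lag1_acf_after, na.rm = TRUE),
      pct_unestimable = 100 * mean(first$thin_unestimable, na.rm = TRUE))
  }
  structure(list(coverage = coverage, mass_bands = mass_bands,
                 allometry = allometry, bias_model = bias_model,
                 thinning = thinning),
            class = "summary.study_result")
}

#' @export
print.summary.study_result <- function(x, ...) {
  cat("Held-out coverage (median inclusion %, bootstrap 95% CI):\n")
  print(x$coverage, row.names = FALSE, digits = 4)
  cat("\nMean proportional underestimation by mass band:\n")
  print(x$mass_bands, row.names = FALSE, digits = 3)
  if (!is.null(x$allometry)) {
    cat("\nAllometric exponent of home range on mass:\n")
    print(x$allometry, row.names = FALSE, digits = 3)
  }
  cat("\nQAICc-selected bias-versus-mass model:\n")
  print(x$bias_model)
  if (!is.null(x$thinning)) {
    cat("\nThinning cost:\n")
    print(x$thinning, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write study outputs
#'
#' Writes \code{individuals.csv}, \code{species.csv},
#' \code{regressions.json}, \code{report.md} and \code{manifest.json} to a
#' directory.
#'
#' @param result a \code{\link{run_study}} result.
#' @param dir output directory.
#' @export
write_study_result <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(result$species, file.path(dir, "species.csv"),
                   row.names = FALSE)
  reg <- lapply(result$fits, function(f) {
    if (inherits(f, "pgls"))
      list(type = "pgls", coefficients = as.list(coef(f)),
           ci = apply(confint.pgls(f), 1, as.list), aicc = f$aicc)
    else if (inherits(f, "bias_models"))
      list(type = "bias_models", selected = f$selected,
           qaicc = as.list(f$table$qaicc))
  })
  jsonlite::write_json(reg, file.path(dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  s <- summary(result)
  rpt <- c("# Study report", "",
           "## Held-out coverage",
           utils::capture.output(print(s$coverage, row.names = FALSE)),
           "", "## Mass-band underestimation",
           utils::capture.output(print(s$mass_bands, row.names = FALSE)),
           "", "## Allometry",
           utils::capture.output(if (!is.null(s$allometry))
             print(s$allometry, row.names = FALSE) else cat("(none)\n")))
  writeLines(rpt, file.path(dir, "report.md"))
  invisible(dir)
}
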