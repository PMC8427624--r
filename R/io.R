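#' Read a plot survey table
#'
#' CSV header contract: mandatory columns `site`, `mesohabitat`, `transect`,
#' `plot`, `x`, `y`, `U_low`, `d_low`; optional `U_high`, `d_high`, wide
#' sieve columns (`sieve_<aperture>` + `pan`), and species density columns
#' (`dens_*`). Rows violating the type invariants (negative speeds or
#' densities, nonpositive depths, negative sieve masses) are rejected with
#' line-numbered messages and reported, never silently dropped; valid rows
#' are returned with the rejection count attached as attribute `rejected`.
#'
#' @param path CSV file.
#' @return validated plot table (attribute `rejected` = number of rows
#'   removed, `rejected_lines` = their file line numbers).
#' @export
read_plot_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("site", "mesohabitat", "transect", "plot", "x", "y",
                 "U_low", "d_low")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop_invalid("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    attr(df, "rejected") <- 0L
    return(df)
  }
  num_cols <- intersect(c("x", "y", "U_low", "d_low", "U_high", "d_high",
                          grep("^sieve_|^dens_|^pan$", names(df), value = TRUE)),
                        names(df))
  for (cc in num_cols) {
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))) & !is.na(df[[cc]]))
      if (length(bad))
        stop_invalid("non-numeric value in column '", cc, "' at file line(s) ",
                     paste(bad + 1L, collapse = ", "))
      df[[cc]] <- as.numeric(df[[cc]])
    }
  }
  bad <- rep(FALSE, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    if (any(cond))
      message("rejecting row(s) at file line(s) ",
              paste(which(cond) + 1L, collapse = ", "), ": ", why)
    bad | cond
  }
  bad <- flag(df$U_low < 0, "negative low-flow speed")
  bad <- flag(df$d_low <= 0, "nonpositive low-flow depth")
  if ("U_high" %in% names(df)) bad <- flag(df$U_high < 0, "negative high-flow speed")
  if ("d_high" %in% names(df)) bad <- flag(df$d_high <= 0, "nonpositive high-flow depth")
  sieve_cols <- grep("^sieve_|^pan$", names(df), value = TRUE)
  for (cc in sieve_cols) bad <- flag(df[[cc]] < 0, paste("negative mass in", cc))
  dens_cols <- grep("^dens_", names(df), value = TRUE)
  for (cc in dens_cols) bad <- flag(df[[cc]] < 0, paste("negative density in", cc))
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(bad)
  attr(out, "rejected_lines") <- which(bad) + 1L
  out
}

#' Write a plot table as CSV
#' @param plots plot table.
#' @param path output CSV.
#' @export
write_plot_table <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param sites sites simulated (ignored when `input` is given).
#' @param input optional CSV of surveyed plots ([read_plot_table()] contract);
#'   when NULL the synthetic generator supplies the data.
#' @param out_dir output directory for stage tables and the manifest.
#' @param mtry,ntree forest settings for the final models.
#' @param tune run the mtry/ntree tuning sweep (slow) instead of using
#'   `mtry`/`ntree` directly.
#' @param group_by grouping column for the repeated-measures hydraulic model.
#' @param landscape_effect generator effect strength.
#' @param rho_s substrate density override (kg/m^3).
#' @return config list.
#' @export
pipeline_config <- function(seed = 1, sites = 6, input = NULL,
                            out_dir = tempfile("musselhab_run_"),
                            mtry = 3, ntree = 500, tune = FALSE,
                            group_by = "transect_id",
                            landscape_effect = 1, rho_s = 273) {
  list(seed = seed, sites = sites, input = input, out_dir = out_dir,
       mtry = mtry, ntree = ntree, tune = tune, group_by = group_by,
       landscape_effect = landscape_effect, rho_s = rho_s)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos never silently fall back to
#' defaults.
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return config list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) the plot survey, compute grain and hydraulic metrics,
#' fit the repeated-measures hydraulic forest and the landscape forest per
#' species (importance + partial dependence), run the point-pattern stage
#' (kernel intensity with cross-validated bandwidth and the Hopkins-Skellam
#' test on occupied outer-meander-margin plots), and write per-stage CSV/JSON
#' outputs plus a run manifest. Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly written to `manifest.json` in the output
#'   directory).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "input")],
                   stages = list())
  consts <- hydraulic_constants(rho_s = config$rho_s)
  design <- default_design(sites = config$sites, seed = config$seed)

  if (is.null(config$input)) {
    study <- simulate_study(design, seed = config$seed,
                            landscape_effect = config$landscape_effect,
                            consts = consts)
    plots <- study$plots
    landscape <- study$landscape
  } else {
    plots <- read_plot_table(config$input)
    manifest$stages$ingest <- list(rows = nrow(plots),
                                   rejected = attr(plots, "rejected"))
    plots <- suppressWarnings(hydraulic_table(plots, consts, period = "low"))
    landscape <- NULL
  }
  plots$transect_id <- paste(plots$site, plots$mesohabitat, plots$transect,
                             sep = "-")
  write_plot_table(plots, file.path(config$out_dir, "plots.csv"))
  manifest$stages$plots <- list(rows = nrow(plots))

  predictors <- c("D_mean", "So", "ks", "Fr", "Re", "Re_star", "V", "tau", "tau_c")
  species_cols <- grep("^dens_", names(plots), value = TRUE)
  reports <- list()
  for (sc in species_cols) {
    sp <- sub("^dens_", "", sc)
    tab <- plots[!plots$flow_missing, ]
    tab$response <- transform_density(tab[[sc]])
    settings <- list(mtry = config$mtry, ntree = config$ntree)
    if (isTRUE(config$tune)) {
      tuned <- tune_forest(tab, "response", predictors,
                           seed = derive_seed(config$seed, paste0("tune-", sp)),
                           groups = tab[[config$group_by]])
      settings <- tuned$selected
    }
    fit <- fit_repeated_measures_forest(tab, "response", predictors,
                                        mtry = settings$mtry,
                                        ntree = settings$ntree,
                                        seed = derive_seed(config$seed, paste0("fit-", sp)),
                                        groups = tab[[config$group_by]])
    imp <- importance_pct_inc_mse(fit, seed = derive_seed(config$seed, paste0("imp-", sp)))
    pd <- lapply(setNames(predictors, predictors), function(p)
      partial_dependence(fit, p))
    pd_long <- do.call(rbind, lapply(names(pd), function(p)
      data.frame(species = sp, predictor = p, pd[[p]])))
    write.csv(pd_long, file.path(config$out_dir, paste0("pd_", sp, ".csv")),
              row.names = FALSE)
    write.csv(imp, file.path(config$out_dir, paste0("importance_", sp, ".csv")),
              row.names = FALSE)
    reports[[sp]] <- list(mtry = fit$mtry, ntree = fit$ntree,
                          oob_mse = fit$oob_mse,
                          pseudo_r2_pct = 100 * fit$pseudo_r2,
                          importance = imp)
    manifest$stages[[paste0("habitat_model_", sp)]] <-
      list(rows = nrow(tab), predictors = length(predictors))
  }

  if (!is.null(landscape)) {
    land_pred <- c("R_Area", "N_Forest", "N_Agriculture", "N_Pasture",
                   "N_RuralSet", "Can_Cover", "P_Forest", "P_Agriculture",
                   "P_Pasture", "D_RuralSet", "D_Street", "P_RuralSet", "D_Road")
    for (sc in intersect(paste0("dens_", c("castalia", "anodontites")),
                         names(landscape))) {
      sp <- sub("^dens_", "", sc)
      ltab <- landscape
      ltab$response <- transform_density(ltab[[sc]])
      if (nrow(ltab) >= 5 && var(ltab$response) > 0) {
        lfit <- grow_forest(ltab, "response", land_pred,
                            mtry = min(config$mtry, length(land_pred)),
                            ntree = config$ntree,
                            seed = derive_seed(config$seed, paste0("land-", sp)))
        reports[[sp]]$landscape <- list(oob_mse = lfit$oob_mse,
                                        pseudo_r2_pct = 100 * lfit$pseudo_r2)
      }
    }
    write.csv(landscape, file.path(config$out_dir, "landscape.csv"),
              row.names = FALSE)
    manifest$stages$landscape <- list(rows = nrow(landscape))
  }

  # point pattern: occupied plots of site 1 over the reach bounding box
  ppstage <- list()
  site1 <- plots[plots$site == plots$site[1], ]
  for (sc in species_cols) {
    occ <- site1[site1[[sc]] > 0, ]
    sp <- sub("^dens_", "", sc)
    if (nrow(occ) >= 5) {
      win <- c(min(site1$x) - 1, max(site1$x) + 1,
               min(site1$y) - 1, max(site1$y) + 1)
      pat <- point_pattern(occ$x, occ$y, marks = occ[[sc]], window = win)
      bw <- bandwidth_cv(pat, sigmas = seq(1, 20, by = 0.5))
      surf <- kernel_intensity(pat, sigma = bw$sigma, dimyx = 64)
      write_surface_asc(surf, file.path(config$out_dir,
                                        paste0("intensity_", sp, ".asc")))
      hs <- hopkins_skellam(pat, seed = derive_seed(config$seed, paste0("hs-", sp)),
                            nsim = 199)
      ppstage[[sp]] <- list(n_occupied = nrow(occ), sigma = bw$sigma,
                            A = hs$A, p_value = hs$p_value)
    } else {
      ppstage[[sp]] <- list(n_occupied = nrow(occ),
                            note = "too few occupied plots for the spatial stage")
    }
  }
  manifest$stages$pointpattern <- ppstage
  manifest$reports <- reports
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
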