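#' Unit conversions between model output and observation scales
#'
#' `gl_to_mM()` converts a mass concentration to millimolar via
#' `conc * 1000 / molar_mass`. `gl_to_pseudolog10()` converts microbial
#' biomass to pseudo-log10 bacteria/L: the concentration is divided by the
#' mass of one bacterial cell (default 4.6e-12 g) and log10-transformed,
#' with every instance at or below 1 bacterium/L mapped to 0 (so 0 g/L is
#' 0 log10).
#'
#' @param conc Concentration(s), g/L (>= 0 for the pseudo-log10).
#' @param molar_mass Molar mass, g/mol (> 0).
#' @param cell_mass Mass of one bacterial cell, g (> 0).
#' @return Numeric vector on the target scale.
#' @export
#' @examples
#' gl_to_mM(1, 60.05)          # 1 g/L acetate in mM
#' gl_to_pseudolog10(4.6e-03)  # 1e9 cells/L -> 9
gl_to_mM <- function(conc, molar_mass) {
  if (any(!is.finite(molar_mass) | molar_mass <= 0)) {
    stop("molar_mass must be > 0", call. = FALSE)
  }
  conc * 1000 / molar_mass
}

#' @rdname gl_to_mM
#' @export
gl_to_pseudolog10 <- function(conc, cell_mass = 4.6e-12) {
  if (!is.finite(cell_mass) || cell_mass <= 0) {
    stop("cell_mass must be > 0", call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  bact <- conc / cell_mass
  ifelse(bact <= 1, 0, log10(bact))
}

#' Root-mean-square error between paired series
#'
#' @param pred Predicted values.
#' @param obs Observed values, same length as `pred` (paired by time).
#' @return `sqrt(mean((pred - obs)^2))`.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(2, 2, 2))
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    stop("pred and obs must have equal length (", length(pred), " vs ",
         length(obs), ")", call. = FALSE)
  }
  if (length(pred) == 0) stop("empty series", call. = FALSE)
  sqrt(mean((pred - obs)^2))
}

#' RMSE as a percentage of the observation mean
#'
#' @param rmse_value RMSE on the observation scale.
#' @param obs Observed values.
#' @return `100 * rmse_value / mean(obs)`; `NA` when the observation mean
#'   is 0 (undefined, as for a metabolite undetected throughout).
#' @export
rmse_percent <- function(rmse_value, obs) {
  m <- mean(obs)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * rmse_value / m
}

#' Ordinary least squares of modeled on observed values
#'
#' Fits `lm(modeled ~ observed)` and reports the slope, intercept and the
#' slope's two-sided t-test p-value.
#'
#' @param modeled Modeled values.
#' @param observed Observed values (>= 3 pairs, not constant).
#' @return Tibble with columns `slope`, `intercept`, `p_value`, `n`.
#' @export
lm_fit <- function(modeled, observed) {
  if (length(modeled) != length(observed)) {
    stop("modeled and observed must have equal length", call. = FALSE)
  }
  if (length(modeled) < 3) {
    stop("need at least 3 pairs for regression", call. = FALSE)
  }
  if (stats::sd(observed) == 0) {
    stop("observed series is constant; regression design is degenerate",
         call. = FALSE)
  }
  fit <- stats::lm(modeled ~ observed)
  sm <- stats::summary.lm(fit)$coefficients
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 p_value = unname(sm["observed", "Pr(>|t|)"]),
                 n = length(modeled))
}

#' Score a simulation against an observation set
#'
#' For every variable present in both the simulation and the observations,
#' the model trajectory is linearly interpolated to the observation times,
#' converted to the observation scale (pseudo-log10 bacteria/L for genera,
#' mM for metabolites), floored at the detection limits (modeled metabolite
#' values below `detect_mM` and abundances at or below 1 bacterium/L report
#' as 0, mimicking GC-MS/qPCR floors), and compared by RMSE, RMSE% and the
#' regression p-value. Genus observations are matched against group
#' aggregates (strains summed). Observed variables missing from the
#' simulation are listed as unmatched, not dropped.
#'
#' @param sim A `simulation_result`.
#' @param obs Observation tibble with columns `time_h`, `variable`, `kind`
#'   (`"genus"` or `"scfa"`), `value` (pseudo-log10 bacteria/L for genera,
#'   mM for SCFAs).
#' @param detect_mM Metabolite detection limit, mM (default 0.1).
#' @param cell_mass Cell mass for the pseudo-log10 conversion, g.
#' @return A `comparison_report` tibble: `variable`, `kind`, `n`, `rmse`,
#'   `rmse_pct`, `p_value`, `matched`; one row per observed variable, in
#'   observation order.
#' @export
compare <- function(sim, obs, detect_mM = 0.1, cell_mass = 4.6e-12) {
  stopifnot(inherits(sim, "simulation_result"))
  obs <- tibble::as_tibble(obs)
  needed <- c("time_h", "variable", "kind", "value")
  if (!all(needed %in% names(obs))) {
    stop("observations need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (max(obs$time_h) > max(sim$time_h) + 1e-9 ||
      min(obs$time_h) < min(sim$time_h) - 1e-9) {
    stop("simulation (", min(sim$time_h), "-", max(sim$time_h),
         " h) does not span the observation times", call. = FALSE)
  }
  mm <- stats::setNames(sim$species$molar_mass, sim$species$species)
  groups <- unique(sim$groups$group)

  model_series <- function(variable, kind, times) {
    if (kind == "genus") {
      if (!variable %in% groups) return(NULL)
      gg <- sim$groups[sim$groups$group == variable, ]
      y <- stats::approx(gg$time_h, gg$value_gL, xout = times)$y
      gl_to_pseudolog10(pmax(y, 0), cell_mass)
    } else {
      if (!variable %in% colnames(sim$states)) return(NULL)
      y <- stats::approx(sim$time_h, sim$states[, variable],
                         xout = times)$y
      v <- gl_to_mM(pmax(y, 0), mm[[variable]])
      ifelse(v < detect_mM, 0, v)
    }
  }

  vars <- dplyr::distinct(obs, .data$variable, .data$kind)
  rows <- purrr::pmap_dfr(vars, function(variable, kind) {
    oo <- obs[obs$variable == variable & obs$kind == kind, ]
    oo <- oo[order(oo$time_h), ]
    pred <- model_series(variable, kind, oo$time_h)
    if (is.null(pred)) {
      return(tibble::tibble(variable = variable, kind = kind,
                            n = nrow(oo), rmse = NA_real_,
                            rmse_pct = NA_real_, p_value = NA_real_,
                            matched = FALSE))
    }
    r <- rmse(pred, oo$value)
    p <- if (nrow(oo) >= 3 && stats::sd(oo$value) > 0) {
      # a perfect model-observation match triggers the harmless
      # "essentially perfect fit" warning from summary.lm
      suppressWarnings(lm_fit(pred, oo$value)$p_value)
    } else NA_real_
    tibble::tibble(variable = variable, kind = kind, n = nrow(oo),
                   rmse = r, rmse_pct = rmse_percent(r, oo$value),
                   p_value = p, matched = TRUE)
  })
  class(rows) <- c("comparison_report", class(rows))
  rows
}

#' Summarize the core fraction of a relative-abundance table
#'
#' Sums the listed core genera per sample and reports the per-sample core
#' fraction together with its mean and sample (n-1) standard deviation
#' across samples. Genera named in `core_list` but absent from the table
#' count as 0 and are reported in `missing_genera`.
#'
#' @param abundance_table Tibble whose first column (`genus`) names taxa and
#'   whose remaining numeric columns are samples; each sample should sum to
#'   about 100%.
#' @param core_list Character vector of core genus names.
#' @return A `core_summary` list: `per_sample` tibble (`sample`,
#'   `core_fraction`), `mean`, `sd`, `missing_genera`.
#' @export
#' @examples
#' t1 <- table1_fixture()
#' core <- t1$genus[t1$genus != "Others"]
#' core_summary(t1[, c("genus", "fecal_inoculum")], core)$per_sample
core_summary <- function(abundance_table, core_list) {
  tab <- tibble::as_tibble(abundance_table)
  genus_col <- names(tab)[1]
  samples <- names(tab)[-1]
  num <- vapply(tab[samples], is.numeric, logical(1))
  samples <- samples[num]
  if (length(samples) == 0) stop("no numeric sample columns", call. = FALSE)
  missing_genera <- setdiff(core_list, tab[[genus_col]])
  if (length(missing_genera) > 0) {
    warning("core genera absent from table (treated as 0): ",
            paste(missing_genera, collapse = ", "), call. = FALSE)
  }
  in_core <- tab[[genus_col]] %in% core_list
  frac <- vapply(samples, function(sm) {
    sum(tab[[sm]][in_core], na.rm = TRUE)
  }, numeric(1))
  structure(
    list(per_sample = tibble::tibble(sample = samples,
                                     core_fraction = unname(frac)),
         mean = mean(frac),
         sd = if (length(frac) > 1) stats::sd(frac) else NA_real_,
         missing_genera = missing_genera),
    class = "core_summary"
  )
}

#' @export
print.core_summary <- function(x, ...) {
  cat("<core_summary> mean ", round(x$mean, 2), "%",
      if (is.finite(x$sd)) paste0(" +/- ", round(x$sd, 2), "% (SD, n = ",
                                  nrow(x$per_sample), ")"),
      "\n", sep = "")
  print(x$per_sample)
  invisible(x)
}

#' Read or write observation sets as TSV
#'
#' Observation TSVs carry columns `time_h`, `variable`, `kind`
#' (`genus`/`scfa`) and `value` (pseudo-log10 bacteria/L for genera, mM for
#' SCFAs).
#'
#' @param obs Observation tibble.
#' @param path File path.
#' @return `read_observations()` returns the tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- readr::read_tsv(path, col_types = readr::cols(
    time_h = readr::col_double(), variable = readr::col_character(),
    kind = readr::col_character(), value = readr::col_double()))
  validate_observations(obs)
  obs
}

#' @rdname read_observations
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  readr::write_tsv(obs, path)
  invisible(path)
}

validate_observations <- function(obs) {
  if (any(!obs$kind %in% c("genus", "scfa"))) {
    stop("kind must be 'genus' or 'scfa'", call. = FALSE)
  }
  if (any(obs$value < 0, na.rm = TRUE)) {
    stop("observation values must be >= 0", call. = FALSE)
  }
  by_var <- split(obs$time_h, obs$variable)
  if (any(vapply(by_var, function(t) any(diff(sort(t)) <= 0) ||
                   anyDuplicated(t) > 0, logical(1)))) {
    stop("observation times must be strictly increasing per variable",
         call. = FALSE)
  }
  invisible(obs)
}
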