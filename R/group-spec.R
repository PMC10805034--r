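#' Build a pathway specification
#'
#' A pathway couples a set of resources to a set of products through molar
#' stoichiometry and Monod kinetics. `entries` is a tibble with one row per
#' chemical species taking part in the pathway:
#'
#' * `species`: name, resolved against the community species registry;
#' * `rtype`: resource class — `Se` (essential), `S` (substitutable),
#'   `Sw` (water), `Sb` (boosting) or `P` (product);
#' * `molar_mass`: g/mol (per monomer for polymers);
#' * `n_molecules`: molecules per reaction event (dimensionless, > 0);
#' * `half_sat`: Monod half-saturation constant, g/L — required for `Se`,
#'   `S` and `Sb` entries, `NA` otherwise;
#' * `yield`: g biomass per g resource, in (0, 1] — required for `Se` and
#'   `S` entries, `NA` otherwise.
#'
#' @param pathway_id Identifier, unique within a group.
#' @param mu_max Maximum specific growth rate on this pathway, 1/h.
#' @param entries Tibble as described above.
#' @return A validated `pathway_spec` object.
#' @export
pathway_spec <- function(pathway_id, mu_max, entries) {
  entries <- tibble::as_tibble(entries)
  needed <- c("species", "rtype", "molar_mass", "n_molecules")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0) {
    stop("pathway '", pathway_id, "': entries lack column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"half_sat" %in% names(entries)) entries$half_sat <- NA_real_
  if (!"yield" %in% names(entries)) entries$yield <- NA_real_
  entries <- entries[, c("species", "rtype", "molar_mass", "n_molecules",
                         "half_sat", "yield")]
  entries <- lapply(entries, unname)
  entries <- tibble::as_tibble(entries)
  # canonical entry order (resources before products, alphabetical within
  # class) so that serialization round-trips are exact
  entries <- entries[order(match(entries$rtype, resource_classes()),
                           entries$species), ]
  out <- structure(
    list(pathway_id = as.character(pathway_id),
         mu_max = as.numeric(mu_max),
         entries = entries),
    class = "pathway_spec"
  )
  validate_pathway_spec(out)
  out
}

validate_pathway_spec <- function(p, group = NULL) {
  where <- if (is.null(group)) {
    paste0("pathway '", p$pathway_id, "'")
  } else {
    paste0("group '", group, "', pathway '", p$pathway_id, "'")
  }
  e <- p$entries
  bad <- setdiff(e$rtype, resource_classes())
  if (length(bad) > 0) {
    stop(where, ": unknown Rtype label(s) ", paste(bad, collapse = ", "),
         " (valid: ", paste(resource_classes(), collapse = ", "), ")",
         call. = FALSE)
  }
  if (anyDuplicated(e$species)) {
    stop(where, ": duplicated species ",
         paste(unique(e$species[duplicated(e$species)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(p$mu_max) || p$mu_max <= 0) {
    stop(where, ": mu_max must be > 0", call. = FALSE)
  }
  if (!all(is.finite(e$molar_mass)) || any(e$molar_mass <= 0)) {
    stop(where, ": molar_mass must be > 0 for every entry", call. = FALSE)
  }
  if (!all(is.finite(e$n_molecules)) || any(e$n_molecules <= 0)) {
    stop(where, ": n_molecules must be > 0 for every entry", call. = FALSE)
  }
  if (!any(e$rtype %in% c("Se", "S"))) {
    stop(where, ": needs at least one essential or substitutable resource",
         call. = FALSE)
  }
  if (!any(e$rtype == "P")) {
    stop(where, ": needs at least one product entry", call. = FALSE)
  }
  kin <- e$rtype %in% c("Se", "S", "Sb")
  if (any(!is.finite(e$half_sat[kin]) | e$half_sat[kin] <= 0)) {
    stop(where, ": half_sat must be > 0 for Se/S/Sb entries (species ",
         paste(e$species[kin][!is.finite(e$half_sat[kin]) |
                               e$half_sat[kin] <= 0], collapse = ", "),
         ")", call. = FALSE)
  }
  grows <- e$rtype %in% c("Se", "S")
  bad_y <- !is.finite(e$yield[grows]) | e$yield[grows] <= 0 |
    e$yield[grows] > 1
  if (any(bad_y)) {
    stop(where, ": yield must lie in (0, 1] for Se/S entries (species ",
         paste(e$species[grows][bad_y], collapse = ", "), ")", call. = FALSE)
  }
  invisible(p)
}

#' Build a microbial group specification
#'
#' A group bundles one or more fermentation pathways with a trapezoidal pH
#' tolerance profile. The four ascending pH corners define growth limitation:
#' zero growth at or outside the outer pair, maximal growth between the inner
#' pair, linear in between.
#'
#' @param name Genus label (or `"others"` for the aggregate non-core group).
#' @param pathways List of [pathway_spec()] objects.
#' @param ph_corners Numeric of length 4 with `c1 < c2 <= c3 < c4`.
#' @return A validated `group_spec` object.
#' @export
group_spec <- function(name, pathways, ph_corners) {
  if (inherits(pathways, "pathway_spec")) pathways <- list(pathways)
  out <- structure(
    list(name = as.character(name),
         pathways = pathways,
         ph_corners = as.numeric(ph_corners)),
    class = "group_spec"
  )
  validate_group_spec(out)
  out
}

validate_group_spec <- function(g) {
  validate_ph_corners(g$ph_corners, g$name)
  if (length(g$pathways) == 0) {
    stop("group '", g$name, "': needs at least one pathway", call. = FALSE)
  }
  ids <- vapply(g$pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("group '", g$name, "': duplicated pathway id(s) ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (p in g$pathways) validate_pathway_spec(p, group = g$name)
  invisible(g)
}

validate_ph_corners <- function(corners, name = "group") {
  if (length(corners) != 4 || !all(is.finite(corners))) {
    stop("group '", name, "': ph_corners must be four finite values",
         call. = FALSE)
  }
  if (!(corners[1] < corners[2] && corners[2] <= corners[3] &&
        corners[3] < corners[4])) {
    stop("group '", name, "': ph_corners must satisfy c1 < c2 <= c3 < c4 ",
         "(got ", paste(signif(corners, 6), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(corners)
}

#' @export
print.group_spec <- function(x, ...) {
  cat("<group_spec> ", x$name, "\n", sep = "")
  cat("  pathways: ",
      paste(vapply(x$pathways, function(p) p$pathway_id, character(1)),
            collapse = ", "), "\n", sep = "")
  cat("  mu_max (1/h): ",
      paste(vapply(x$pathways, function(p) format(p$mu_max), character(1)),
            collapse = ", "), "\n", sep = "")
  cat("  pH corners: ", paste(x$ph_corners, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Tidy a group specification into one row per stoichiometric entry
#'
#' @param x A `group_spec`.
#' @param ... Unused.
#' @return A tibble with columns `group`, `pathway_id`, `mu_max`, `species`,
#'   `rtype`, `molar_mass`, `n_molecules`, `half_sat`, `yield`.
#' @method tidy group_spec
#' @export
tidy.group_spec <- function(x, ...) {
  purrr::map_dfr(x$pathways, function(p) {
    dplyr::mutate(p$entries,
                  group = x$name, pathway_id = p$pathway_id,
                  mu_max = p$mu_max, .before = 1)
  })
}

#' Species referenced by a group's pathways
#'
#' Water-resource (`Sw`) entries may stay implicit: when the community
#' registry does not track a water pool, their uptake draws on an unlimited
#' reservoir, so they can be excluded from resolution checks.
#'
#' @param g A `group_spec`.
#' @param include_water If `FALSE`, drop `Sw` entries.
#' @return Character vector of unique species names.
#' @export
group_species <- function(g, include_water = TRUE) {
  unique(unlist(lapply(g$pathways, function(p) {
    keep <- if (include_water) TRUE else p$entries$rtype != "Sw"
    p$entries$species[keep]
  })))
}
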