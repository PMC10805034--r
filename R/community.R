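#' Assemble a microbial community
#'
#' A community bundles the member group specifications with the chemical
#' species registry they draw on and the groups' initial relative
#' abundances.
#'
#' @param members List of [group_spec()] objects (names taken from the
#'   specs).
#' @param species Species registry tibble with columns `species`, `role`,
#'   `molar_mass`; defaults to [default_species_registry()].
#' @param initial_abundance Named numeric of relative abundances (%, or any
#'   common scale) per member; defaults to equal shares.
#' @param name Label carried in simulation metadata.
#' @param check If `TRUE` (default), refuse to build a community that fails
#'   [validate_community()]; set to `FALSE` to assemble a community for
#'   inspection.
#' @return A `community` object.
#' @export
community <- function(members,
                      species = default_species_registry(),
                      initial_abundance = NULL,
                      name = "community",
                      check = TRUE) {
  if (inherits(members, "group_spec")) members <- list(members)
  nms <- vapply(members, function(g) g$name, character(1))
  names(members) <- nms
  if (is.null(initial_abundance)) {
    initial_abundance <- stats::setNames(rep(100 / length(members),
                                             length(members)), nms)
  }
  out <- structure(
    list(name = name,
         members = members,
         species = tibble::as_tibble(species),
         initial_abundance = initial_abundance[nms]),
    class = "community"
  )
  if (check) {
    issues <- validate_community(out)
    if (nrow(issues) > 0) {
      stop("invalid community:\n",
           paste(" -", issues$issue, collapse = "\n"), call. = FALSE)
    }
  }
  out
}

#' Cross-check a community against its species registry
#'
#' Reports unresolved species references, duplicated member names, missing
#' molar masses and invalid abundance entries. A clean community yields a
#' zero-row tibble.
#'
#' @param comm A `community`, or a list with the same fields.
#' @return Tibble with columns `member`, `issue`; zero rows when clean.
#' @export
validate_community <- function(comm) {
  issues <- list()
  note <- function(member, issue) {
    issues[[length(issues) + 1]] <<- tibble::tibble(member = member,
                                                    issue = issue)
  }
  nms <- vapply(comm$members, function(g) g$name, character(1))
  if (anyDuplicated(nms)) {
    for (d in unique(nms[duplicated(nms)])) {
      note(d, paste0("duplicated member name '", d, "'"))
    }
  }
  reg <- comm$species
  if (anyDuplicated(reg$species)) {
    note(NA_character_, "duplicated species in registry")
  }
  if (any(!is.finite(reg$molar_mass) | reg$molar_mass <= 0)) {
    note(NA_character_,
         paste0("non-positive molar mass for ",
                paste(reg$species[!is.finite(reg$molar_mass) |
                                    reg$molar_mass <= 0], collapse = ", ")))
  }
  for (g in comm$members) {
    unresolved <- setdiff(group_species(g, include_water = FALSE),
                          reg$species)
    if (length(unresolved) > 0) {
      note(g$name, paste0("group '", g$name, "' references species not in ",
                          "registry: ", paste(unresolved, collapse = ", ")))
    }
  }
  ia <- comm$initial_abundance
  if (length(ia) > 0 && (any(!is.finite(ia)) || any(ia < 0))) {
    note(NA_character_, "initial_abundance must be finite and >= 0")
  }
  if (length(issues) == 0) {
    tibble::tibble(member = character(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' @export
print.community <- function(x, ...) {
  cat("<community> ", x$name, ": ", length(x$members), " group(s), ",
      nrow(x$species), " species\n", sep = "")
  cat("  members: ", paste(names(x$members), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of state variables of the assembled model
#'
#' Counts one state per strain (groups times strains per group) plus one per
#' registry species. The baseline full community with one strain per group
#' has 34 states: 16 core genera + "others" + 4 resources + 13 metabolites.
#'
#' @param comm A `community`.
#' @param strains_per_group Strains per group (default 1).
#' @return Integer state count.
#' @export
#' @examples
#' n_state_variables(builtin_community("bioreactor"))
n_state_variables <- function(comm, strains_per_group = 1) {
  length(comm$members) * strains_per_group + nrow(comm$species)
}

set_group_K <- function(comm, k) {
  # replace every Monod half-saturation constant of each named group
  stopifnot(!is.null(names(k)))
  for (nm in names(k)) {
    g <- comm$members[[nm]]
    if (is.null(g)) stop("no group '", nm, "' in community", call. = FALSE)
    g$pathways <- lapply(g$pathways, function(p) {
      kin <- p$entries$rtype %in% c("Se", "S", "Sb")
      p$entries$half_sat[kin] <- k[[nm]]
      p
    })
    comm$members[[nm]] <- g
  }
  comm
}

group_K <- function(comm) {
  vapply(comm$members, function(g) {
    ks <- unlist(lapply(g$pathways, function(p) {
      p$entries$half_sat[p$entries$rtype %in% c("Se", "S", "Sb")]
    }))
    ks[1]
  }, numeric(1))
}
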