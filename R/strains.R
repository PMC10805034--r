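#' Draw strain variants of a microbial group
#'
#' Strains inherit their parent group's stoichiometry and perturb the kinetic
#' traits: `mu_max` and every half-saturation constant are multiplied by
#' independent uniform factors in `[1 - variability, 1 + variability]`, and
#' the two inner pH corners are shifted by independent uniform offsets in
#' `[-variability, +variability]` pH units. Draws violating the corner
#' ordering are redrawn internally, so every emitted strain is valid. With
#' `variability = 0` the strains equal the parent exactly; a given seed
#' always reproduces the same strains.
#'
#' @param group A [group_spec()].
#' @param n_strains Number of strains (>= 1).
#' @param variability Fractional trait variability in `[0, 1)`; default 0.1.
#' @param seed Integer seed for the strain draw.
#' @return List of `strain_spec` objects (each also a `group_spec`), named
#'   `<group>` when `n_strains == 1`, else `<group>.1`, `<group>.2`, ...
#' @export
#' @examples
#' g <- generate_parameter_sets(1, seed = 1)[[1]]
#' make_strains(g, n_strains = 2, variability = 0.1, seed = 42)
make_strains <- function(group, n_strains, variability = 0.1, seed = 1) {
  stopifnot(inherits(group, "group_spec"))
  if (n_strains < 1) stop("n_strains must be >= 1", call. = FALSE)
  if (variability < 0 || variability >= 1) {
    stop("variability must lie in [0, 1)", call. = FALSE)
  }
  strains <- withr::with_seed(seed, {
    lapply(seq_len(n_strains), function(i) {
      perturb_group(group, i, n_strains, variability)
    })
  })
  names(strains) <- vapply(strains, function(s) s$name, character(1))
  strains
}

perturb_group <- function(group, i, n_strains, variability) {
  fac <- function(n) stats::runif(n, 1 - variability, 1 + variability)
  pathways <- lapply(group$pathways, function(p) {
    e <- p$entries
    kin <- !is.na(e$half_sat)
    e$half_sat[kin] <- e$half_sat[kin] * fac(sum(kin))
    structure(list(pathway_id = p$pathway_id,
                   mu_max = p$mu_max * fac(1),
                   entries = e),
              class = "pathway_spec")
  })
  corners <- group$ph_corners
  if (variability > 0) {
    for (attempt in seq_len(100)) {
      shifted <- corners
      shifted[2:3] <- corners[2:3] +
        stats::runif(2, -variability, variability)
      ok <- shifted[1] < shifted[2] && shifted[2] <= shifted[3] &&
        shifted[3] < shifted[4]
      if (ok) {
        corners <- shifted
        break
      }
    }
  }
  strain_name <- if (n_strains == 1) group$name else {
    paste0(group$name, ".", i)
  }
  out <- structure(
    list(name = strain_name, pathways = pathways, ph_corners = corners,
         parent = group$name, strain_id = i),
    class = c("strain_spec", "group_spec")
  )
  validate_group_spec(out)
  out
}
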