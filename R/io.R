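# Group parameter frames are CSV files mirroring the data-frame organization
# of the model: one column per chemical species plus bookkeeping columns
# (group, param, pathway, units). Each pathway contributes a block of rows
# Rtype / molarMass / numMolecules / stoichiomProduct / halfSat / yield /
# maxGrowthRate; the four pHcorner rows are group-level. Scalar rows carry
# their value replicated across the pathway's species columns.

frame_param_units <- c(Rtype = "", molarMass = "g/mol",
                       numMolecules = "count", stoichiomProduct = "count",
                       halfSat = "g/L", yield = "g/g",
                       maxGrowthRate = "1/h",
                       pHcorner1 = "pH", pHcorner2 = "pH",
                       pHcorner3 = "pH", pHcorner4 = "pH")

#' Write a group specification as a CSV parameter frame
#'
#' The writer is deterministic: the same spec always produces a
#' byte-identical file, and [read_group_frame()] recovers an equal spec.
#'
#' @param spec A [group_spec()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_group_frame <- function(spec, path) {
  validate_group_spec(spec)
  species <- group_species(spec)
  rows <- list()
  fmt <- function(x) {
    ifelse(is.na(x), "", vapply(x, function(v) {
      format(v, digits = 15, scientific = FALSE, trim = TRUE)
    }, character(1)))
  }
  add_row <- function(param, pathway, values) {
    row <- c(group = spec$name, param = param, pathway = pathway,
             units = unname(frame_param_units[param]),
             stats::setNames(rep("", length(species)), species))
    row[names(values)] <- values
    rows[[length(rows) + 1]] <<- row
  }
  for (p in spec$pathways) {
    e <- p$entries
    sp <- e$species
    is_p <- e$rtype == "P"
    add_row("Rtype", p$pathway_id, stats::setNames(e$rtype, sp))
    add_row("molarMass", p$pathway_id, stats::setNames(fmt(e$molar_mass),
                                                       sp))
    add_row("numMolecules", p$pathway_id,
            stats::setNames(fmt(ifelse(is_p, NA, e$n_molecules)), sp))
    add_row("stoichiomProduct", p$pathway_id,
            stats::setNames(fmt(ifelse(is_p, e$n_molecules, NA)), sp))
    add_row("halfSat", p$pathway_id, stats::setNames(fmt(e$half_sat), sp))
    add_row("yield", p$pathway_id, stats::setNames(fmt(e$yield), sp))
    add_row("maxGrowthRate", p$pathway_id,
            stats::setNames(rep(fmt(p$mu_max), length(sp)), sp))
  }
  for (k in 1:4) {
    add_row(paste0("pHcorner", k), "",
            stats::setNames(rep(fmt(spec$ph_corners[k]), length(species)),
                            species))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a group parameter frame
#'
#' Parses and fully validates a CSV parameter frame written in the layout of
#' [write_group_frame()]. Malformed content (unknown Rtype labels, missing
#' rows, non-numeric cells, descending pH corners, yields outside (0, 1])
#' raises a validation error naming the offending row and column.
#'
#' @param path CSV file path.
#' @return A validated [group_spec()].
#' @export
read_group_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c("group", "param", "pathway", "units")
  if (!all(needed %in% names(df))) {
    stop("frame '", path, "': missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  species_cols <- setdiff(names(df), needed)
  gname <- unique(df$group)
  if (length(gname) != 1) {
    stop("frame '", path, "': 'group' column must be constant",
         call. = FALSE)
  }
  df$pathway[is.na(df$pathway)] <- ""

  num_cell <- function(x, param, col) {
    if (is.na(x) || x == "") return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) {
      stop("frame '", path, "', row '", param, "', column '", col,
           "': non-numeric value '", x, "'", call. = FALSE)
    }
    v
  }
  get_row <- function(param, pathway) {
    hit <- df$param == param & df$pathway == pathway
    if (sum(hit) == 0) {
      stop("frame '", path, "': missing row '", param, "'",
           if (nzchar(pathway)) paste0(" for pathway '", pathway, "'"),
           call. = FALSE)
    }
    df[which(hit)[1], species_cols, drop = FALSE]
  }
  scalar_row <- function(param, pathway = "") {
    row <- get_row(param, pathway)
    vals <- vapply(species_cols,
                   function(cc) num_cell(row[[cc]], param, cc), numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      stop("frame '", path, "': row '", param, "' has no value",
           call. = FALSE)
    }
    unname(vals[1])
  }

  pathway_ids <- unique(df$pathway[nzchar(df$pathway)])
  pathways <- lapply(pathway_ids, function(pid) {
    rtype_row <- get_row("Rtype", pid)
    present <- species_cols[!is.na(unlist(rtype_row)) &
                              nzchar(unlist(rtype_row))]
    if (length(present) == 0) {
      stop("frame '", path, "', pathway '", pid, "': empty Rtype row",
           call. = FALSE)
    }
    cell <- function(param, col) num_cell(get_row(param, pid)[[col]],
                                          paste0(param, " (pathway ", pid,
                                                 ")"), col)
    rtype <- unname(unlist(rtype_row[present]))
    bad <- setdiff(rtype, resource_classes())
    if (length(bad) > 0) {
      stop("frame '", path, "', pathway '", pid, "': unknown Rtype ",
           "label(s) ", paste(unique(bad), collapse = ", "), call. = FALSE)
    }
    n_mol <- vapply(seq_along(present), function(i) {
      col <- present[i]
      if (rtype[i] == "P") cell("stoichiomProduct", col) else {
        cell("numMolecules", col)
      }
    }, numeric(1))
    entries <- tibble::tibble(
      species = present,
      rtype = rtype,
      molar_mass = vapply(present, function(cc) cell("molarMass", cc),
                          numeric(1)),
      n_molecules = n_mol,
      half_sat = vapply(present, function(cc) cell("halfSat", cc),
                        numeric(1)),
      yield = vapply(present, function(cc) cell("yield", cc), numeric(1))
    )
    pathway_spec(pid, mu_max = scalar_row("maxGrowthRate", pid),
                 entries = entries)
  })
  corners <- vapply(1:4, function(k) scalar_row(paste0("pHcorner", k)),
                    numeric(1))
  group_spec(gname, pathways, corners)
}

#' Write or read a community directory
#'
#' A community directory contains one CSV parameter frame per member plus a
#' `manifest.yml` listing the members (with per-group strain counts), the
#' species registry and the initial relative abundances. All paths in the
#' manifest are relative to the directory.
#'
#' @param comm A `community`.
#' @param dir Directory path (created if needed).
#' @param strains Named integer vector of strains per group (default 1).
#' @return `write_community()` returns `dir` invisibly; `read_community()`
#'   returns a `community`.
#' @export
write_community <- function(comm, dir, strains = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in comm$members) {
    f <- paste0(g$name, ".csv")
    write_group_frame(g, file.path(dir, f))
    files[g$name] <- f
  }
  if (is.null(strains)) {
    strains <- stats::setNames(rep(1L, length(comm$members)),
                               names(comm$members))
  }
  manifest <- list(
    name = comm$name,
    members = lapply(names(comm$members), function(nm) {
      list(name = nm, file = unname(files[nm]),
           strains = unname(strains[nm]))
    }),
    species = lapply(seq_len(nrow(comm$species)), function(i) {
      list(species = comm$species$species[i],
           role = comm$species$role[i],
           molar_mass = comm$species$molar_mass[i])
    }),
    initial_abundance = as.list(comm$initial_abundance)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_community
#' @export
read_community <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yml")
  if (!file.exists(manifest_path)) {
    stop("no manifest.yml in '", dir, "'", call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  members <- lapply(manifest$members, function(m) {
    read_group_frame(file.path(dir, m$file))
  })
  species <- dplyr::bind_rows(lapply(manifest$species, tibble::as_tibble))
  community(members, species = species,
            initial_abundance = unlist(manifest$initial_abundance),
            name = manifest$name, check = FALSE)
}
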