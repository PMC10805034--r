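# CSV parameter frames, manifests and the builtin fixture library.

test_that("write then read recovers a group specification exactly", {
  specs <- generate_parameter_sets(8, seed = 21)
  for (g in specs[1:5]) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_group_frame(g, path)
    back <- read_group_frame(path)
    expect_equal(back$name, g$name)
    expect_equal(back$ph_corners, g$ph_corners, tolerance = 1e-12)
    expect_equal(tidy(back), tidy(g), tolerance = 1e-12)
  }
})

test_that("writes are deterministic and corners round-trip literally", {
  g <- generate_parameter_sets(1, seed = 3)[[1]]
  g$ph_corners <- c(5, 6, 7, 8)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_group_frame(g, p1)
  write_group_frame(g, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(read_group_frame(p1)$ph_corners, c(5, 6, 7, 8))
})

test_that("a spec with several pathways writes one block per pathway", {
  specs <- generate_parameter_sets(12, seed = 8)
  g <- specs[[which(vapply(specs, function(s) length(s$pathways),
                           integer(1)) == 3)[1]]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_group_frame(g, path)
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  expect_length(unique(df$pathway[!is.na(df$pathway)]), 3)
  expect_equal(sum(df$param == "Rtype"), 3)
})

test_that("malformed frames are rejected with coordinates", {
  g <- generate_parameter_sets(1, seed = 4)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_group_frame(g, path)

  bad_rtype <- sub("(,S,|,Se,)", ",X,", readLines(path))
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad_rtype, p)
  expect_error(read_group_frame(p), "Rtype")

  lines <- readLines(path)
  no_half <- lines[!grepl(",halfSat,", lines)]
  writeLines(no_half, p)
  expect_error(read_group_frame(p), "halfSat")

  corrupted <- sub(",g/mol,[0-9.]+", ",g/mol,oops", lines)
  writeLines(corrupted, p)
  expect_error(read_group_frame(p), "non-numeric")

  expect_error(read_group_frame(withr::local_tempfile()), "no such file")
})

test_that("descending corners and out-of-range yields fail validation", {
  g <- generate_parameter_sets(1, seed = 6)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_group_frame(g, path)
  lines <- readLines(path)
  n_cols <- length(strsplit(lines[1], ",")[[1]])
  swap <- function(par, val) {
    i <- grep(paste0(",", par, ","), lines)
    parts <- strsplit(lines[i], ",")[[1]]
    parts <- c(parts, rep("", n_cols - length(parts)))
    parts[5:length(parts)] <- ifelse(nzchar(parts[5:length(parts)]), val,
                                     "")
    lines[i] <<- paste(parts, collapse = ",")
  }
  swap("pHcorner1", "9")  # above corner 4
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, p)
  expect_error(read_group_frame(p), "ph_corners")

  lines <- readLines(path)
  swap("yield", "1.5")
  writeLines(lines, p)
  expect_error(read_group_frame(p), "yield")
})

test_that("builtin communities are complete and validate cleanly", {
  bio <- builtin_community("bioreactor")
  expect_length(bio$members, 17)
  expect_true("others" %in% names(bio$members))
  expect_equal(nrow(validate_community(bio)), 0)
  expect_equal(n_state_variables(bio), 34)

  cm <- builtin_community("cm_only")
  expect_length(cm$members, 16)
  expect_false("others" %in% names(cm$members))
  expect_equal(nrow(validate_community(cm)), 0)

  oo <- builtin_community("others_only")
  expect_length(oo$members, 1)
  expect_length(oo$members$others$pathways, 10)
  expect_equal(nrow(validate_community(oo)), 0)

  # initial abundances renormalize the inoculum composition
  expect_equal(sum(bio$initial_abundance), 100)
  expect_gt(bio$initial_abundance[["others"]], 50)
})

test_that("the shipped community directories match the in-code definitions", {
  for (which in c("bioreactor", "others_only")) {
    dir <- system.file("extdata", "communities", which,
                       package = "coreferm")
    expect_true(nzchar(dir))
    shipped <- read_community(dir)
    built <- builtin_community(which)
    expect_equal(names(shipped$members), names(built$members))
    expect_equal(nrow(validate_community(shipped)), 0)
    for (nm in names(built$members)) {
      expect_equal(tidy(shipped$members[[nm]]), tidy(built$members[[nm]]),
                   tolerance = 1e-12)
    }
    expect_equal(shipped$initial_abundance, built$initial_abundance,
                 tolerance = 1e-6)
  }
})

test_that("validate_community reports unresolved species and duplicates", {
  g <- generate_parameter_sets(1, seed = 10)[[1]]
  g$pathways[[1]]$entries$species[1] <- "mystery_compound"
  comm <- community(list(g), check = FALSE)
  issues <- validate_community(comm)
  expect_equal(nrow(issues), 1)
  expect_match(issues$issue, "mystery_compound")

  g2 <- generate_parameter_sets(2, seed = 12)
  g2[[2]]$name <- g2[[1]]$name
  comm2 <- community(g2, check = FALSE)
  names(comm2$members) <- vapply(comm2$members, function(x) x$name,
                                 character(1))
  issues2 <- validate_community(comm2)
  expect_true(any(grepl("duplicated", issues2$issue)))

  # a community round-trips through a directory
  bio <- builtin_community("cm_only")
  dir <- withr::local_tempdir()
  write_community(bio, dir)
  back <- read_community(dir)
  expect_equal(names(back$members), names(bio$members))
  expect_equal(nrow(validate_community(back)), 0)
})
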