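#' @name cage_io
#' @title Reading and writing cage structures
#'
#' @description
#' Cage structures travel as standard XYZ files (bead coordinates in
#' Angstrom, bead classes mapped to element symbols) with a JSON sidecar
#' carrying the force-field term lists and properties. XYZ alone is enough
#' for shape and pore analysis; energy evaluation needs the sidecar.
NULL

default_element_map <- c(a = "C", b = "O", c = "N", m = "Pd", n = "Fe")

sidecar_path <- function(path) sub("\\.xyz$", ".json", path)

#' Write a cage structure to XYZ plus a JSON sidecar
#'
#' @param cage a `cage_model` or `cage_opt`.
#' @param path output path (`.xyz`); the sidecar takes the same path with
#'   `.json`.
#' @param element_map named map from bead class to element symbol.
#' @return `path`, invisibly.
#' @export
write_cage <- function(cage, path, element_map = default_element_map) {
  E_b <- NULL
  if (inherits(cage, "cage_opt")) {
    E_b <- cage$E_b
    cage <- cage$cage
  }
  el <- element_map[cage$beads$class]
  comment <- sprintf("topology=%s torsion=%s%s", cage$topology,
                     cage$torsion_state,
                     if (is.null(E_b)) "" else sprintf(" E_b=%.8g", E_b))
  lines <- c(
    as.character(nrow(cage$xyz)),
    comment,
    sprintf("%s %.6f %.6f %.6f", el, cage$xyz[, 1], cage$xyz[, 2],
            cage$xyz[, 3])
  )
  writeLines(lines, path)

  side <- list(
    topology = cage$topology,
    torsion_state = cage$torsion_state,
    n_building_blocks = cage$n_building_blocks,
    beads = as.data.frame(cage$beads),
    bonds = as.data.frame(cage$bonds),
    angles = as.data.frame(cage$angles),
    torsions = as.data.frame(cage$torsions),
    nb_pairs = as.data.frame(cage$nb_pairs)
  )
  if (!is.null(E_b)) {
    side$properties <- list(E_b = E_b)
  }
  jsonlite::write_json(side, sidecar_path(path), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

parse_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) abort(paste0("malformed XYZ (too short): ", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort(paste0("malformed XYZ at line 1 (atom count): ", path))
  if (length(lines) < 2 + n) {
    abort(paste0("truncated XYZ: expected ", n, " atom lines, file ends at line ",
                 length(lines)))
  }
  atoms <- lines[3:(2 + n)]
  parts <- strsplit(trimws(atoms), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 4)
  if (length(bad) > 0) {
    abort(paste0("malformed XYZ at line ", 2 + bad[1], ": ", path))
  }
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) abort(paste0("malformed XYZ coordinates in ", path))
  list(elements = vapply(parts, `[[`, character(1), 1),
       xyz = xyz, comment = lines[2])
}

#' Read a cage structure
#'
#' Reconstructs a `cage_model` from an XYZ file and its JSON sidecar. When
#' the sidecar is missing a coordinates-only model is returned: shape and
#' pore operations work, energy evaluation raises an error.
#'
#' @param path path to the `.xyz` file.
#' @param element_map named map from bead class to element symbol (used to
#'   invert element symbols when no sidecar is present).
#' @return a `cage_model`.
#' @export
read_cage <- function(path, element_map = default_element_map) {
  px <- parse_xyz(path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    inv <- setNames(names(element_map), element_map)
    cls <- unname(inv[px$elements])
    beads <- tibble(class = cls, sigma = 1, index = seq_along(cls))
    return(structure(
      list(topology = NA_character_, beads = beads, xyz = px$xyz,
           bonds = NULL, angles = NULL, torsions = NULL, nb_pairs = NULL,
           torsion_state = NA_character_, n_building_blocks = NA_integer_),
      class = "cage_model"
    ))
  }
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  beads <- as_tibble(side$beads)
  if (nrow(beads) != nrow(px$xyz)) {
    abort(paste0("sidecar bead count (", nrow(beads),
                 ") does not match XYZ atom count (", nrow(px$xyz), ")"))
  }
  empty_tors <- tibble(i = integer(), j = integer(), k = integer(),
                       l = integer(), phi0 = numeric(), p = numeric(),
                       kf = numeric())
  tors <- as_tibble(side$torsions)
  if (nrow(tors) == 0) tors <- empty_tors
  structure(
    list(topology = side$topology, beads = beads, xyz = px$xyz,
         bonds = as_tibble(side$bonds), angles = as_tibble(side$angles),
         torsions = tors, nb_pairs = as_tibble(side$nb_pairs),
         torsion_state = side$torsion_state,
         n_building_blocks = side$n_building_blocks),
    class = "cage_model"
  )
}

#' Run configuration
#'
#' A serialisable bundle of every tunable in a scan run. Round-trips
#' losslessly through YAML.
#'
#' @param topologies topology names to scan.
#' @param grid an [angle_grid()].
#' @param bead_bond_r bond radius for all bead classes (A).
#' @param params [forcefield_params()].
#' @param search [search_config()].
#' @param threshold accessibility threshold on E_b (kJ/mol).
#' @param seed master seed.
#' @param output_dir output directory for CSV/XYZ artefacts.
#' @return a `run_config` list.
#' @export
run_config <- function(topologies = list_topologies()$name,
                       grid = angle_grid(), bead_bond_r = 2,
                       params = forcefield_params(),
                       search = search_config(), threshold = 0.3,
                       seed = 1, output_dir = ".") {
  structure(list(topologies = topologies, grid = unclass(grid),
                 bead_bond_r = bead_bond_r, params = unclass(params),
                 search = unclass(search), threshold = threshold,
                 seed = seed, output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$grid <- do.call(angle_grid, cfg$grid)
  cfg$params <- do.call(forcefield_params, cfg$params)
  cfg$search <- do.call(search_config, cfg$search)
  cfg
}

#' Generate the default fixture set
#'
#' Writes the default bead set and a mini 3x3 angle-grid run configuration,
#' and builds and optimises the two reference cages used across the test
#' suite: torsion-restricted Tri4Di6 with tritopic 120 / ditopic 125, and
#' Tet6Di12 with tetratopic 90 / ditopic 135.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisible character vector of the files written.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  beads <- default_bead_set()
  bead_path <- file.path(dir, "beads.yml")
  yaml::write_yaml(lapply(beads, unclass), bead_path)
  files <- c(files, bead_path)

  cfg <- run_config(
    topologies = c("Tri2Di3", "Tri4Di6"),
    grid = angle_grid(ditopic = c(115, 125, 135), tritopic = c(100, 110, 120),
                      tetratopic = numeric(0), torsion = "on"),
    seed = seed
  )
  cfg_path <- file.path(dir, "mini_grid.yml")
  write_run_config(cfg, cfg_path)
  files <- c(files, cfg_path)

  refs <- list(
    list(name = "Tri4Di6", blocks = list(make_tritopic(120), make_ditopic(125)),
         file = "tri4di6_120_125.xyz"),
    list(name = "Tet6Di12", blocks = list(make_tetratopic(90), make_ditopic(135)),
         file = "tet6di12_90_135.xyz")
  )
  for (r in refs) {
    cage <- build_cage(r$name, r$blocks, torsion = "on")
    opt <- optimise_cage(cage, seed = seed)
    p <- file.path(dir, r$file)
    write_cage(opt, p)
    files <- c(files, p, sidecar_path(p))
  }
  invisible(files)
}
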