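#' Load and validate a run configuration
#'
#' Reads a configuration file (YAML or JSON, decided by the file extension)
#' describing the parameter registry, the factorial scenario grid, and
#' simulation settings, validates every field against the type invariants,
#' and returns a ready-to-run specification. Unknown keys are rejected with
#' a message naming the key, so typos never silently fall back to defaults.
#'
#' Recognized structure (all sections optional; omitted sections fall back
#' to the bundled placeholder registry and the core study grid):
#' \preformatted{
#' registry:
#'   species:
#'     <name>: {r_max, B_max, B0, light_response, provenance}
#'   dispersal:   {L_max, tau, nu, provenance}
#'   recruitment: {R_max, tau, nu, provenance}
#' grid:
#'   species: [...]; model: [dispersal, recruitment]
#'   n_connected: [1, ..., 10]; light_fraction: [1, 0.5, 0.25]
#'   management: [none]; fraction: 0.5
#' sim:
#'   mode: analytic | simulate; n_reps; max_years; time_mode; seed
#' options:
#'   seed_dispersal: immediate | lmax; hazard_map: matched-annual | direct
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `run_config`: list with `registry`
#'   (a [parameter_registry()]), `grid`, `sim` (a [sim_config()] plus
#'   `mode`), and `options`.
#' @seealso [write_config()], [run_scenario_grid()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- read_structured(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping at the top level")
  check_keys(raw, c("registry", "grid", "sim", "options"), "top level")
  registry <- parse_registry(raw$registry)
  grid <- parse_grid(raw$grid, registry)
  sim <- parse_sim(raw$sim)
  opts <- parse_options(raw$options)
  structure(list(registry = registry, grid = grid, sim = sim, options = opts),
            class = "run_config")
}

read_structured <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension '.", ext, "' (use .yaml, .yml or .json)"))
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    stop("unknown key(s) at ", where, ": ",
         paste(sQuote(unknown), collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  invisible(TRUE)
}

parse_registry <- function(reg) {
  if (is.null(reg)) return(generate_fixture_registry())
  check_keys(reg, c("species", "dispersal", "recruitment"), "registry")
  if (is.null(reg$species) || is.null(reg$dispersal) || is.null(reg$recruitment))
    stop("registry must provide 'species', 'dispersal' and 'recruitment'")
  species <- lapply(reg$species, function(sp) {
    check_keys(sp, c("r_max", "B_max", "B0", "light_response", "provenance"),
               "registry species entry")
    gp <- growth_params(
      r_max = sp$r_max %||% stop("species entry missing 'r_max'"),
      B_max = sp$B_max %||% stop("species entry missing 'B_max'"),
      B0 = sp$B0 %||% (0.01 * sp$B_max),
      light_response = sp$light_response %||% "linear")
    list(growth = gp, provenance = sp$provenance %||% "user")
  })
  check_keys(reg$dispersal, c("L_max", "tau", "nu", "provenance"),
             "registry dispersal")
  check_keys(reg$recruitment, c("R_max", "tau", "nu", "provenance"),
             "registry recruitment")
  d <- dispersal_params(reg$dispersal$L_max, reg$dispersal$tau, reg$dispersal$nu)
  attr(d, "provenance") <- reg$dispersal$provenance %||% "user"
  r <- recruitment_params(reg$recruitment$R_max, reg$recruitment$tau,
                          reg$recruitment$nu)
  attr(r, "provenance") <- reg$recruitment$provenance %||% "user"
  parameter_registry(species, d, r)
}

parse_grid <- function(grid, registry) {
  if (is.null(grid)) grid <- list()
  check_keys(grid, c("species", "model", "n_connected", "light_fraction",
                     "management", "fraction"), "grid")
  out <- list(
    species = grid$species %||% names(registry$species),
    model = grid$model %||% c("dispersal", "recruitment"),
    n_connected = as.integer(grid$n_connected %||% 1:10),
    light_fraction = as.numeric(grid$light_fraction %||% c(1, 0.5, 0.25)),
    management = grid$management %||% "none",
    fraction = as.numeric(grid$fraction %||% 0.5))
  bad <- setdiff(out$species, names(registry$species))
  if (length(bad) > 0L)
    stop("grid species not in registry: ", paste(bad, collapse = ", "))
  if (!all(out$model %in% c("dispersal", "recruitment")))
    stop("grid 'model' entries must be 'dispersal' or 'recruitment'")
  if (!all(out$management %in% c("none", "seed", "stabilize", "light")))
    stop("grid 'management' entries must be none/seed/stabilize/light")
  if (any(out$n_connected < 0)) stop("grid 'n_connected' must be >= 0")
  if (any(out$light_fraction <= 0 | out$light_fraction > 1))
    stop("grid 'light_fraction' entries must lie in (0, 1]")
  if (length(out$fraction) != 1L || out$fraction <= 0 || out$fraction >= 1)
    stop("grid 'fraction' must be a single value in (0, 1)")
  out
}

parse_sim <- function(sim) {
  if (is.null(sim)) sim <- list()
  check_keys(sim, c("mode", "n_reps", "max_years", "time_mode", "seed"), "sim")
  mode <- sim$mode %||% "analytic"
  if (!mode %in% c("analytic", "simulate"))
    stop("sim 'mode' must be 'analytic' or 'simulate'; got '", mode, "'")
  cfg <- sim_config(n_reps = sim$n_reps %||% 10000L,
                    seed = sim$seed,
                    max_years = sim$max_years %||% 200,
                    time_mode = sim$time_mode %||% "continuous")
  list(mode = mode, config = cfg)
}

parse_options <- function(opts) {
  if (is.null(opts)) opts <- list()
  check_keys(opts, c("seed_dispersal", "hazard_map"), "options")
  out <- list(seed_dispersal = opts$seed_dispersal %||% "immediate",
              hazard_map = opts$hazard_map %||% "matched-annual")
  if (!out$seed_dispersal %in% c("immediate", "lmax"))
    stop("options 'seed_dispersal' must be 'immediate' or 'lmax'")
  if (!out$hazard_map %in% c("matched-annual", "direct"))
    stop("options 'hazard_map' must be 'matched-annual' or 'direct'")
  out
}

#' Write a run configuration back to disk
#'
#' Serializes a [load_config()] result (or builds one from a registry) so
#' that loading the written file reproduces an equal specification.
#'
#' @param config A `run_config` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    registry = registry_as_list(config$registry),
    grid = config$grid,
    sim = c(list(mode = config$sim$mode),
            config$sim$config[c("n_reps", "max_years", "time_mode")],
            if (!is.null(config$sim$config$seed))
              list(seed = config$sim$config$seed)),
    options = config$options)
  write_structured(out, path)
  invisible(path)
}

write_structured <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
    stop("unsupported output extension '.", ext, "'"))
  invisible(path)
}

#' Read a patch-connectivity matrix from CSV
#'
#' The file is a square matrix of 0/1 entries with a header row of patch
#' identifiers (comma-separated, UTF-8, "." decimal separator); row order
#' must match the header order.
#'
#' @param path CSV path.
#' @return A symmetric 0/1 matrix with patch identifiers as dimnames.
#' @seealso [read_patch_network()]
#' @export
read_adjacency_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("adjacency matrix in ", path, " must be numeric")
  if (nrow(m) != ncol(m))
    stop("adjacency matrix in ", path, " must be square (got ",
         nrow(m), " x ", ncol(m), ")")
  rownames(m) <- colnames(m)
  m
}

#' Read a per-patch biomass vector from CSV
#'
#' Expects columns `patch_id` and `biomass`.
#'
#' @param path CSV path.
#' @return A named numeric vector of biomasses (g dry wt m^-2).
#' @export
read_biomass_vector <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("patch_id", "biomass") %in% names(df)))
    stop("biomass file ", path, " must have columns 'patch_id' and 'biomass'")
  stats::setNames(as.numeric(df$biomass), as.character(df$patch_id))
}

#' Assemble a patch network from CSV files
#'
#' Reads the adjacency matrix and biomass vector and aligns the biomasses
#' to the matrix's patch identifiers.
#'
#' @param q_path Adjacency-matrix CSV (see [read_adjacency_matrix()]).
#' @param biomass_path Biomass CSV (see [read_biomass_vector()]).
#' @param disturbed Index or patch identifier of the disturbed patch.
#' @return A [patch_network()].
#' @export
read_patch_network <- function(q_path, biomass_path, disturbed = 1L) {
  Q <- read_adjacency_matrix(q_path)
  b <- read_biomass_vector(biomass_path)
  ids <- colnames(Q)
  if (!is.null(ids) && all(ids %in% names(b))) {
    b <- b[ids]
  } else if (length(b) != nrow(Q)) {
    stop("biomass entries do not match the adjacency matrix patches")
  }
  patch_network(Q, unname(b), disturbed)
}

#' Write a result table with companion metadata
#'
#' Writes a tidy result table as CSV plus a JSON metadata file recording
#' the parameter registry (with provenance tags), the seed, and the package
#' version, so every output is reproducible from its recorded inputs.
#'
#' @param results A data frame of results.
#' @param out_dir Output directory (created if needed).
#' @param name Base file name (without extension).
#' @param registry The [parameter_registry()] used.
#' @param seed The RNG seed used (or `NULL` for deterministic runs).
#' @param extra Optional named list merged into the metadata.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_results <- function(results, out_dir, name, registry, seed = NULL,
                          extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(out_dir, paste0(name, ".csv"))
  meta_path <- file.path(out_dir, paste0(name, "_metadata.json"))
  utils::write.csv(results, csv_path, row.names = FALSE)
  meta <- c(list(registry = registry_as_list(registry),
                 seed = seed,
                 package_version = as.character(utils::packageVersion("patchrecovery")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(csv = csv_path, metadata = meta_path))
}
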