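#' Write and read simulated dataset bundles
#'
#' Datasets are stored as a single serialized R object (RDS) with a fixed
#' logical layout mirroring the in-memory types: `kspace` (zero-filled
#' complex `nx x ny x Nc x Nt`), `mask`, `coils`, `reference`, optional
#' `truth` (series and T2 map) and `basis`, plus acquisition attributes
#' (`te_ms` or `dwell_s`, `AF`, `seed`). Complex arrays round-trip
#' losslessly.
#'
#' @param path file path
#' @param bundle a named list as described above
#' @return `read_dataset` returns the validated bundle
#' @export
write_dataset <- function(path, bundle) {
  validate_bundle(bundle)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  bundle <- readRDS(path)
  validate_bundle(bundle)
  bundle
}

validate_bundle <- function(bundle) {
  req <- c("kspace")
  miss <- setdiff(req, names(bundle))
  if (length(miss)) stop("dataset missing required keys: ", paste(miss, collapse = ", "))
  ks <- bundle$kspace
  if (!inherits(ks, "kspace")) stop("dataset key 'kspace' must be a kspace object")
  d <- dim(ks$samples)
  if (length(d) != 4L) stop("kspace samples must be a 4D (nx, ny, Nc, Nt) array")
  if (d[3L] != ks$coils$n_coils) stop("kspace coil dimension inconsistent with coil maps")
  if (d[4L] != ks$mask$Nt) stop("kspace frame dimension inconsistent with the mask")
  if (!is.null(bundle$truth) && !is.null(bundle$truth$series)) {
    if (nrow(bundle$truth$series) != prod(ks$grid))
      stop("truth series voxel count inconsistent with the k-space grid")
  }
  invisible(TRUE)
}

#' Write a reconstruction result
#'
#' Stores `U`, `V`, the expanded series and the iteration history.
#'
#' @param path output file
#' @param state a `recon_state`
#' @return `read_recon` returns the state
#' @export
write_recon <- function(path, state) {
  if (!inherits(state, "recon_state")) stop("state must be a recon_state")
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_recon
#' @export
read_recon <- function(path) {
  st <- readRDS(path)
  if (!inherits(st, "recon_state")) stop("file does not contain a recon_state")
  st
}

#' Load a reconstruction configuration from YAML or JSON
#'
#' Accepts the fields of [recon_config()] plus nested `inv` fields of
#' [inversion_config()]; unknown keys and invalid values are rejected with
#' the offending field named.
#'
#' @param path a `.yaml`/`.yml` or `.json` file
#' @return a `recon_config`
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  allowed <- c("rank", "iters", "lambda1", "lambda2", "init_lambda2", "dc_init",
               "refine_steps", "radius", "frozen_levels", "norm_quantile", "inv")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$rank)) stop("config field 'rank' is required")
  num_fields <- c("lambda2", "init_lambda2", "norm_quantile", "radius")
  for (f in num_fields) {
    if (!is.null(raw[[f]]) && (!is.numeric(raw[[f]]) || any(raw[[f]] < 0)))
      stop("config field '", f, "' must be nonnegative numeric")
  }
  inv <- inversion_config()
  if (!is.null(raw$inv)) {
    inv_allowed <- c("start_split", "steps_tail", "steps_proj", "steps_joint",
                     "lr", "radius", "frozen_levels", "seed")
    bad <- setdiff(names(raw$inv), inv_allowed)
    if (length(bad)) stop("unknown config field(s): inv.", paste(bad, collapse = ", inv."))
    inv <- do.call(inversion_config, raw$inv)
  }
  args <- raw[setdiff(names(raw), "inv")]
  args$inv <- inv
  do.call(recon_config, args)
}

#' Run manifest for reproducibility
#'
#' Captures the configuration snapshot, input file checksums, the root seed
#' and the package version; identical manifests imply identical outputs for
#' the deterministic stages. Named RNG substreams are derived from the root
#' seed so phantom, noise, pretraining and inversion draws are independent.
#'
#' @param config a `recon_config` (or any list)
#' @param inputs character vector of input file paths
#' @param seed integer root seed
#' @return a `run_manifest` list
#' @export
run_manifest <- function(config, inputs = character(0), seed = 0L) {
  sums <- if (length(inputs)) tools::md5sum(inputs) else character(0)
  structure(list(config = config, checksums = sums, seed = as.integer(seed),
                 package_version = as.character(utils::packageVersion("subgenrecon")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "run_manifest")
}

#' Named RNG substream seeds from a root seed
#'
#' @param seed root seed
#' @return named integer vector (phantom, noise, pretrain, inversion)
#' @export
seed_streams <- function(seed) {
  s <- as.integer(seed)
  c(phantom = s * 13L + 1L, noise = s * 13L + 5L,
    pretrain = s * 13L + 9L, inversion = s * 13L + 11L) %% 2147483647L
}
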