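## Container layout: a directory with a JSON metadata file and plain CSV
## payloads. Complex arrays are stored as paired re/im columns in the
## column-major order of their dimensions.

write_json_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

cx_to_df <- function(x) data.frame(re = Re(x), im = Im(x))
df_to_cx <- function(df) complex(real = df$re, imaginary = df$im)

#' Write / read a fingerprint dictionary container
#'
#' Directory layout: `meta.json` (grid axes, schedule hash, dimensions),
#' `params.csv`, `norms.csv` and `atoms.csv` (one row per atom). All files
#' are plain text; large dictionaries are better regenerated than stored.
#'
#' @param dictionary a [generate_dictionary()] result.
#' @param dir container directory (created if missing).
#' @return `write_dictionary` returns `dir` invisibly; `read_dictionary`
#'   returns the dictionary.
#' @export
write_dictionary <- function(dictionary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_json_meta(list(kind = "cki_dictionary",
                       n_atoms = nrow(dictionary$atoms),
                       n_points = ncol(dictionary$atoms),
                       grid = unclass(dictionary$grid),
                       schedule_hash = dictionary$schedule_hash),
                  file.path(dir, "meta.json"))
  utils::write.csv(dictionary$params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(norm = dictionary$norms),
                   file.path(dir, "norms.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dictionary$atoms),
                   file.path(dir, "atoms.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop("no meta.json found in ", dir)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(meta$kind, "cki_dictionary")) {
    stop("not a dictionary container: ", dir)
  }
  atoms <- as.matrix(utils::read.csv(file.path(dir, "atoms.csv")))
  dimnames(atoms) <- NULL
  grid <- do.call(param_grid, as.list(meta$grid))
  structure(list(atoms = atoms,
                 params = tibble::as_tibble(
                   utils::read.csv(file.path(dir, "params.csv"))),
                 norms = utils::read.csv(file.path(dir, "norms.csv"))$norm,
                 grid = grid, schedule_hash = meta$schedule_hash),
            class = "cki_dictionary")
}

#' Write / read a raw k-space container
#'
#' Directory layout: `meta.json` (tensor dimensions, trajectory scalars,
#' acquisition metadata), `trajectory.csv` (kx, ky per readout sample) and
#' `tensor.csv` (re/im pairs in column-major order).
#'
#' @param raw a `cki_raw` object (see [forward_simulate()]).
#' @param dir container directory.
#' @return `write_raw` returns `dir` invisibly; `read_raw` the raw object.
#' @export
write_raw <- function(raw, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- raw$trajectory
  write_json_meta(list(kind = "cki_raw", dim = dim(raw$tensor),
                       trajectory = list(kmax = tr$kmax, dwell = tr$dwell,
                                         coverage = tr$coverage,
                                         matrix_size = tr$matrix_size,
                                         fov_mm = tr$fov_mm,
                                         n_turns = tr$n_turns,
                                         density = tr$density),
                       meta = raw$meta),
                  file.path(dir, "meta.json"))
  utils::write.csv(data.frame(kx = Re(tr$kxy), ky = Im(tr$kxy)),
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  utils::write.csv(cx_to_df(as.vector(raw$tensor)),
                   file.path(dir, "tensor.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_raw
#' @export
read_raw <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop("no meta.json found in ", dir)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (!identical(meta$kind, "cki_raw")) stop("not a raw container: ", dir)
  trcsv <- utils::read.csv(file.path(dir, "trajectory.csv"))
  tr <- c(list(kxy = complex(real = trcsv$kx, imaginary = trcsv$ky)),
          meta$trajectory)
  class(tr) <- "cki_trajectory"
  tensor <- array(df_to_cx(utils::read.csv(file.path(dir, "tensor.csv"))),
                  meta$dim)
  structure(list(tensor = tensor, trajectory = tr,
                 meta = as.list(meta$meta)),
            class = "cki_raw")
}

#' Export a signal evolution as a columnar text dump
#'
#' @param evolution a `cki_evolution`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_evolution <- function(evolution, path) {
  utils::write.csv(data.frame(index = seq_along(evolution$samples),
                              target = evolution$target,
                              t = evolution$t, te = evolution$te,
                              re = Re(evolution$samples),
                              im = Im(evolution$samples)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export parameter maps (or any named 3D arrays) as NIfTI volumes
#'
#' One `.nii.gz` per map, with the voxel size derived from the field of
#' view. Requires the `RNifti` package.
#'
#' @param maps a `cki_maps` result or named list of 3D arrays.
#' @param prefix output path prefix (`<prefix>_<name>.nii.gz`).
#' @param fov_mm field of view (mm), for the voxel dimensions.
#' @return Character vector of written paths, invisibly.
#' @export
write_maps_nifti <- function(maps, prefix, fov_mm = c(230, 230, 220)) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the RNifti package is required for NIfTI export")
  }
  m <- if (inherits(maps, "cki_maps")) maps$maps else maps
  paths <- character(0)
  for (nm in names(m)) {
    vol <- m[[nm]]
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- fov_mm / dim(vol)
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
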