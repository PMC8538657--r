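# On-disk conventions: NIfTI-1 volumes with a JSON sidecar for the timing
# and acquisition metadata (frame times, TR/TE, flip angle, baseline count),
# two-column CSV for concentration curves, YAML for pipeline configuration,
# RDS + JSON metadata for fitted model artifacts.

#' Construct a dynamic DCE-MRI series
#'
#' The container every pipeline stage consumes: a 4D intensity tensor in
#' (x, y, z, t) order plus voxel spacing, frame times and the SPGR
#' acquisition parameters.
#'
#' @param data 4D numeric array (x, y, z, t), non-negative.
#' @param spacing voxel spacing (mm, length 3, positive).
#' @param frame_times frame acquisition times (s), strictly increasing,
#'   length matching `dim(data)[4]`.
#' @param TR,TE repetition and echo time (ms).
#' @param flip_angle flip angle (degrees).
#' @param n_baseline number of pre-contrast baseline frames.
#' @return object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, spacing, frame_times, TR, TE, flip_angle,
                           n_baseline) {
  stopifnot(length(dim(data)) == 4,
            length(spacing) == 3, all(spacing > 0),
            length(frame_times) == dim(data)[4],
            TR > 0, flip_angle > 0)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (min(data) < 0)
    stop("intensity tensor must be non-negative", call. = FALSE)
  if (n_baseline < 1 || n_baseline >= length(frame_times))
    stop("n_baseline must be in [1, n_frames)", call. = FALSE)
  structure(list(data = data, spacing = spacing, frame_times = frame_times,
                 TR = TR, TE = TE, flip_angle = flip_angle,
                 n_baseline = as.integer(n_baseline)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<dynamic_series>", paste(d[1:3], collapse = "x"), "voxels x",
      d[4], "frames;",
      "dt =", signif(diff(x$frame_times[1:2]), 4), "s;",
      "TR/TE/FA =", x$TR, "/", x$TE, "/", x$flip_angle, ";",
      x$n_baseline, "baseline frames\n")
  invisible(x)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write / read a dynamic series as NIfTI-1 plus JSON sidecar
#'
#' The intensity tensor and voxel spacing go into the NIfTI file; frame
#' times, TR/TE, flip angle and baseline-frame count go into a JSON sidecar
#' next to it (`<stem>.json`) so they survive bit-exactly.
#'
#' @param series a `dynamic_series`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  img <- RNifti::asNifti(series$data,
                         pixdim = c(series$spacing,
                                    diff(series$frame_times[1:2])))
  RNifti::writeNifti(img, path)
  meta <- list(frame_times = series$frame_times, TR = series$TR,
               TE = series$TE, flip_angle = series$flip_angle,
               n_baseline = series$n_baseline, spacing = series$spacing)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # plain array, no NIfTI baggage
  if (length(dim(arr)) != 4)
    stop("expected a 4D series, got ", length(dim(arr)), "D: ", path,
         call. = FALSE)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (f in c("frame_times", "TR", "TE", "flip_angle", "n_baseline",
              "spacing"))
    if (is.null(meta[[f]]))
      stop("sidecar missing field '", f, "'", call. = FALSE)
  dynamic_series(arr, spacing = meta$spacing,
                 frame_times = meta$frame_times, TR = meta$TR, TE = meta$TE,
                 flip_angle = meta$flip_angle, n_baseline = meta$n_baseline)
}

#' Write / read a compartment label map as integer NIfTI
#'
#' Codes: 0 background, 1 cortex, 2 medulla, 3 pelvis. Reading rejects any
#' other code rather than coercing.
#'
#' @param labels integer 3D array with codes 0--3.
#' @param path `.nii` / `.nii.gz` path.
#' @param spacing voxel spacing (mm).
#' @return `path` (write) / integer array (read).
#' @export
write_labels <- function(labels, path, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(labels)) == 3)
  if (!all(labels %in% 0:3))
    stop("label codes must be in {0,1,2,3}", call. = FALSE)
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)),
                         pixdim = spacing, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3)
    stop("expected a 3D label map: ", path, call. = FALSE)
  if (!all(arr %in% 0:3))
    stop("unknown label codes in ", path, ": ",
         paste(setdiff(unique(c(arr)), 0:3), collapse = ", "),
         call. = FALSE)
  array(as.integer(arr), dim = dim(arr))
}

#' Write / read an arterial input function as two-column CSV
#'
#' Columns `time` (s) and `conc` (mmol/L), with header. Reading validates
#' non-negative concentrations and increasing times.
#'
#' @param aif data frame with columns `time`, `conc`.
#' @param path CSV path.
#' @return `path` (write) / tibble (read).
#' @export
write_aif <- function(aif, path) {
  stopifnot(all(c("time", "conc") %in% names(aif)))
  utils::write.csv(aif[, c("time", "conc")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time", "conc") %in% names(x)))
    stop("AIF CSV must have columns 'time' and 'conc'", call. = FALSE)
  if (any(x$conc < 0))
    stop("AIF concentrations must be non-negative", call. = FALSE)
  if (is.unsorted(x$time, strictly = TRUE))
    stop("AIF times must be strictly increasing", call. = FALSE)
  tibble::as_tibble(x)
}

pipeline_required_keys <- function() {
  c("seed", "patch_size", "unet", "train", "classifier", "pk")
}

#' Load and validate a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @param required top-level keys that must be present; a missing key
#'   raises a configuration error naming it.
#' @return the configuration list.
#' @export
load_config <- function(path, required = pipeline_required_keys()) {
  cfg <- yaml::read_yaml(path)
  for (k in required)
    if (is.null(cfg[[k]]))
      stop("configuration missing required key '", k, "'", call. = FALSE)
  cfg
}

#' Persist / restore a fitted model artifact
#'
#' Stores any fitted object (U-Net, PCA model, classifier) as RDS together
#' with version, seed and configuration-hash metadata in a JSON sidecar, so
#' every artifact records the state that produced it.
#'
#' @param model the fitted object.
#' @param path output `.rds` path.
#' @param seed the seed that produced the model.
#' @param config the configuration list that produced it (hashed).
#' @return `path` (save) / the model with `metadata` attribute (load).
#' @export
save_model <- function(model, path, seed = NA_integer_, config = NULL) {
  saveRDS(model, path)
  meta <- list(package_version = as.character(utils::packageVersion("renodce")),
               seed = seed,
               config_hash = config_hash(config),
               saved_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  mp <- paste0(path, ".json")
  if (file.exists(mp))
    attr(model, "metadata") <- jsonlite::read_json(mp, simplifyVector = TRUE)
  model
}

# Stable hash of a configuration list (serialised to canonical JSON).
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
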