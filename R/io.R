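#' Read and write RNFLT maps
#'
#' Maps are stored as plain-text grids -- one row of tab-separated thickness
#' values per line -- with a JSON sidecar `<path>.json` carrying
#' `pixel_pitch`, `patient_id`, `eye_id`, `laterality`, `acquisition_date`
#' and `signal_strength`. The round trip is lossless (values are written at
#' full precision). A missing sidecar yields default metadata with a
#' warning; ragged or non-numeric rows raise a parse error naming the line.
#'
#' @param map an [rnflt_map()].
#' @param path file path for the grid; the sidecar lives at `<path>.json`.
#' @return `write_rnflt_map()` returns `path` invisibly; `read_rnflt_map()`
#'   returns an [rnflt_map()].
#' @export
write_rnflt_map <- function(map, path) {
  m <- unclass(map)
  txt <- apply(matrix(sprintf("%.17g", m), nrow(m), ncol(m)), 1L,
               paste, collapse = "\t")
  writeLines(txt, path)
  meta <- list(pixel_pitch = attr(map, "pixel_pitch"),
               patient_id = attr(map, "patient_id"),
               eye_id = attr(map, "eye_id"),
               laterality = attr(map, "laterality"),
               acquisition_date = format(attr(map, "acquisition_date")),
               signal_strength = attr(map, "signal_strength"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

parse_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "[\t ]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged grid in %s: line %d has %d values, expected %d",
                 path, which(ncols != ncols[1L])[1L],
                 ncols[which(ncols != ncols[1L])[1L]], ncols[1L]),
         call. = FALSE)
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop(sprintf("non-numeric value in %s at line %d", path, bad[1L]),
         call. = FALSE)
  do.call(rbind, vals)
}

#' @rdname write_rnflt_map
#' @export
read_rnflt_map <- function(path) {
  m <- parse_grid(path)
  sidecar <- paste0(path, ".json")
  meta <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    warning("no sidecar ", sidecar, "; using default metadata", call. = FALSE)
  }
  gv <- function(k, default) {
    v <- meta[[k]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  rnflt_map(m,
            pixel_pitch = gv("pixel_pitch", 0.03),
            patient_id = gv("patient_id", NA_character_),
            eye_id = gv("eye_id", NA_character_),
            laterality = {
              l <- gv("laterality", NA_character_)
              if (is.na(l) || l == "NA") NA_character_ else l
            },
            acquisition_date = {
              dte <- gv("acquisition_date", NA)
              if (identical(dte, "NA")) NA else dte
            },
            signal_strength = gv("signal_strength", NA_real_))
}

#' Read and write boolean masks
#'
#' Masks (disc or artifact) share the map grid format with 0/1 entries; the
#' round trip is bit-exact.
#'
#' @param mask logical matrix (any of the package's mask classes).
#' @param path file path.
#' @param kind class to give the mask on reading: `"disc"`, `"artifact"` or
#'   `"plain"`.
#' @return `read_mask()` returns a logical matrix (classed per `kind`).
#' @export
write_mask <- function(mask, path) {
  utils::write.table(unclass(mask) * 1L, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, kind = c("plain", "disc", "artifact")) {
  kind <- match.arg(kind)
  m <- parse_grid(path)
  if (!all(m %in% c(0, 1)))
    stop("mask file contains entries other than 0/1: ", path, call. = FALSE)
  m <- m == 1
  switch(kind,
         plain = m,
         disc = structure(m, class = c("disc_mask", "matrix", "array")),
         artifact = structure(m, floor_um = 50,
                              class = c("artifact_mask", "matrix", "array")))
}

#' Read and write visual-field series
#'
#' CSV with one exam per row: `exam_date`, `md`, `vfi`, `td_1`..`td_52`,
#' `fixation_loss`, `false_pos`, `false_neg`; the eye id is carried in an
#' `eye_id` column.
#'
#' @param series a [vf_series()].
#' @param path CSV path.
#' @return `read_vf_series()` returns a [vf_series()].
#' @export
write_vf_series <- function(series, path) {
  df <- cbind(eye_id = series$eye_id, series$exams)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vf_series
#' @export
read_vf_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vf_series(eye_id = df$eye_id[1L],
            exams = df[setdiff(names(df), "eye_id")])
}

#' Write and read a synthetic cohort on disk
#'
#' Lays a cohort out as one directory: `manifest.csv` (one row per eye),
#' per-eye map/mask grids with sidecars, optional donor maps, and per-eye VF
#' series CSVs.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir target directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   an `rnflt_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  for (e in cohort$eyes) {
    stem <- file.path(dir, e$eye_id)
    write_rnflt_map(e$map, paste0(stem, "_map.tsv"))
    write_mask(e$disc, paste0(stem, "_disc.tsv"))
    if (!is.null(e$donor))
      write_rnflt_map(e$donor, paste0(stem, "_donor.tsv"))
    write_vf_series(e$vf, paste0(stem, "_vf.csv"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  eyes <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    stem <- file.path(dir, r$eye_id)
    map <- read_rnflt_map(paste0(stem, "_map.tsv"))
    donor_path <- paste0(stem, "_donor.tsv")
    list(patient_id = r$patient_id, eye_id = r$eye_id,
         laterality = r$laterality, severity = r$severity,
         map = map,
         disc = read_mask(paste0(stem, "_disc.tsv"), kind = "disc"),
         donor = if (file.exists(donor_path)) read_rnflt_map(donor_path),
         donor_ar = r$donor_target_ar,
         vf = read_vf_series(paste0(stem, "_vf.csv")),
         md_slope = r$md_slope, md_intercept = r$md_intercept)
  })
  names(eyes) <- manifest$eye_id
  size <- nrow(eyes[[1L]]$map)
  structure(list(eyes = eyes, manifest = manifest, seed = NA_integer_,
                 size = size),
            class = "rnflt_cohort")
}

#' Default run configuration
#'
#' One document holding every tunable of the pipeline, suitable for writing
#' to YAML/JSON and overriding from the command line.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(floor_um = 50,
       ar_high = 0.02, ar_low = 0.05,
       disc_radius_mm = 0.8,
       circle_diameter_mm = 3.46, circle_samples = 256L,
       map_size = 64L,
       w_contrast = 0.1, w_consistency = 0.1, lambda_mask = 5,
       temperature = 0.5, max_shift = 8, max_rot = 10,
       epochs = 10L, batch_size = 8L, lr = 3e-3,
       cv_folds = 3L, n_boot = 1000L,
       window_days = 30, min_exams = 5L, min_years = 4,
       seed = 1L)
}

#' Read a run configuration (YAML or JSON) over the defaults
#'
#' @param path config file; `NULL` returns the defaults.
#' @param overrides named list applied last.
#' @return Named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

write_run_snapshot <- function(cfg, dir) {
  jsonlite::write_json(
    c(cfg, list(package_version = as.character(utils::packageVersion("rnfltcorrect")),
                r_version = R.version.string,
                timestamp = format(Sys.time()))),
    file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}
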