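#' Read a surface point cloud
#'
#' Supports plain XYZ-like text (an optional leading count line, then one
#' `x y z` triple per line, angstrom) and CSV with headers `x,y,z`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"csv"`.
#' @param label label stored on the cloud (defaults to the file name).
#' @return a [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "csv"),
                             label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("MissingFile: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "xyz"
  }
  if (format == "csv") {
    df <- utils::read.csv(path)
    miss <- setdiff(c("x", "y", "z"), names(df))
    if (length(miss)) {
      stop("SchemaError: point-cloud CSV missing column(s) ",
           paste(miss, collapse = ", "))
    }
    return(point_cloud(as.matrix(df[, c("x", "y", "z")]), label = label))
  }
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:],]+")
  if (length(toks) && length(toks[[1]]) == 1) toks <- toks[-1]  # count line
  pts <- t(vapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    v <- v[!is.na(v)]
    if (length(v) < 3) {
      stop("SchemaError: line ", i, " does not contain three coordinates")
    }
    utils::tail(v, 3)  # tolerate a leading atom label
  }, numeric(3)))
  point_cloud(pts, label = label)
}

#' Write a point cloud
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @param format `"xyz"` (count line + triples) or `"csv"`.
#' @export
write_point_cloud <- function(cloud, path, format = c("xyz", "csv")) {
  format <- match.arg(format)
  cloud <- as_point_cloud(cloud)
  if (format == "csv") {
    utils::write.csv(as.data.frame(cloud$points), path, row.names = FALSE)
  } else {
    writeLines(c(as.character(nrow(cloud$points)),
                 apply(cloud$points, 1, function(r)
                   paste(sprintf("%.10g", r), collapse = " "))), path)
  }
  invisible(path)
}

#' Write an ellipsoid to JSON
#'
#' Rotation is stored row-major; lengths in angstrom.
#'
#' @param e an `ellipsoid`.
#' @param path output path.
#' @export
write_ellipsoid_json <- function(e, path) {
  stopifnot(inherits(e, "ellipsoid"))
  jsonlite::write_json(
    list(center = e$center, rotation = as.vector(t(e$rotation)),
         semiaxes = e$semiaxes, fit_rms = e$fit_rms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ellipsoid from JSON
#'
#' @param path JSON file written by [write_ellipsoid_json()].
#' @return an `ellipsoid`.
#' @export
read_ellipsoid_json <- function(path) {
  if (!file.exists(path)) stop("MissingFile: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- ellipsoid(x$semiaxes, matrix(x$rotation, 3, 3, byrow = TRUE), x$center)
  e$fit_rms <- x$fit_rms %||% NA_real_
  e
}

#' Write cavity/correction factors to JSON
#'
#' @param cf a `cavity_factors` object.
#' @param corr optional `correction_factors` object to embed.
#' @param path output path.
#' @export
write_factors_json <- function(cf, path, corr = NULL) {
  stopifnot(inherits(cf, "cavity_factors"))
  x <- list(semiaxes = cf$semiaxes, A = cf$A, h = cf$h,
            eps1 = cf$eps1, eps2 = cf$eps2)
  if (!is.null(corr)) {
    x$corr2 <- as.list(corr$corr2)
    x$rotation <- as.vector(t(corr$rotation))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read correction factors from JSON
#'
#' @param path JSON written by [write_factors_json()] (with `corr` embedded).
#' @return a `correction_factors` object.
#' @export
read_factors_json <- function(path) {
  if (!file.exists(path)) stop("MissingFile: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$corr2) || is.null(x$rotation)) {
    stop("SchemaError: factors JSON lacks corr2/rotation")
  }
  correction_factors(matrix(x$rotation, 3, 3, byrow = TRUE), x$h)
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("MissingFile: ", path)
  df <- utils::read.csv(path)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("SchemaError: ", what, " missing column(s) ",
         paste(miss, collapse = ", "))
  }
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))) &
                   !is.na(df[[col]]))
    if (length(bad)) {
      stop("SchemaError: ", what, " column `", col, "` non-numeric at row ",
           bad[1])
    }
  }
  df
}

#' Read a computed-transitions CSV
#'
#' Columns: `id, energy_ev, mu_x, mu_y, mu_z` and optionally
#' `p_x, p_y, p_z` (atomic units).
#'
#' @param path CSV path.
#' @return a [transitions()] table with per-gauge strengths.
#' @export
read_transitions <- function(path) {
  transitions(read_csv_checked(
    path, c("id", "energy_ev", "mu_x", "mu_y", "mu_z"), "transitions.csv"))
}

#' Read an experimental band table CSV
#'
#' Columns: `band_id, nu_lo_cm1, nu_hi_cm1, f_exp, n_solvent`, optionally
#' `E_exp_cm1`. `f_exp` entries may be left empty when per-band spectra are
#' supplied to [load_dataset()].
#'
#' @param path CSV path.
#' @return a data frame.
#' @export
read_bands <- function(path) {
  read_csv_checked(path, c("band_id", "nu_lo_cm1", "nu_hi_cm1", "n_solvent"),
                   "bands.csv")
}

#' Read a digitized spectrum CSV
#'
#' Columns: `nu_cm1, epsilon`.
#'
#' @param path CSV path.
#' @return a [spectrum_uv()].
#' @export
read_spectrum <- function(path) {
  df <- read_csv_checked(path, c("nu_cm1", "epsilon"), basename(path))
  spectrum_uv(df$nu_cm1, df$epsilon)
}

#' Load a benchmark dataset directory
#'
#' Expects `transitions.csv` and `bands.csv`; optionally `spectra/<band>.csv`
#' per band and `exclusions.txt` (one outlier transition id per line). Bands
#' with a spectrum but no tabulated `f_exp` get it from
#' [f_exp_from_spectrum()]; missing `E_exp_cm1` is filled from
#' [band_mean_energy()] where a spectrum exists.
#'
#' @param path dataset directory.
#' @return list with `transitions`, `bands`, `spectra` (possibly empty list),
#'   `exclusions` (integer vector).
#' @export
load_dataset <- function(path) {
  if (!dir.exists(path)) stop("MissingFile: dataset directory ", path)
  tr <- read_transitions(file.path(path, "transitions.csv"))
  bands <- read_bands(file.path(path, "bands.csv"))
  if (!"f_exp" %in% names(bands)) bands$f_exp <- NA_real_
  if (!"E_exp_cm1" %in% names(bands)) bands$E_exp_cm1 <- NA_real_
  spectra <- list()
  for (k in seq_len(nrow(bands))) {
    sp_path <- file.path(path, "spectra", paste0(bands$band_id[k], ".csv"))
    if (file.exists(sp_path)) {
      s <- read_spectrum(sp_path)
      spectra[[as.character(bands$band_id[k])]] <- s
      lim <- c(bands$nu_lo_cm1[k], bands$nu_hi_cm1[k])
      if (is.na(bands$f_exp[k])) bands$f_exp[k] <- f_exp_from_spectrum(s, lim)
      if (is.na(bands$E_exp_cm1[k])) bands$E_exp_cm1[k] <- band_mean_energy(s, lim)
    }
  }
  if (any(is.na(bands$f_exp))) {
    stop("SchemaError: band(s) ",
         paste(bands$band_id[is.na(bands$f_exp)], collapse = ", "),
         " have neither f_exp nor a spectrum")
  }
  excl_path <- file.path(path, "exclusions.txt")
  exclusions <- if (file.exists(excl_path)) {
    as.integer(readLines(excl_path)[nzchar(trimws(readLines(excl_path)))])
  } else integer()
  message("loaded dataset: ", nrow(tr), " transitions, ", nrow(bands),
          " bands, ", length(spectra), " spectra, ", length(exclusions),
          " exclusion(s)")
  list(transitions = tr, bands = bands, spectra = spectra,
       exclusions = exclusions)
}

#' Write a benchmark dataset directory
#'
#' Inverse of [load_dataset()]; values round-trip exactly (full-precision
#' CSV).
#'
#' @param dataset list as returned by [generate_synthetic_benchmark()] or
#'   [load_dataset()].
#' @param path output directory (created if needed).
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tr <- as.data.frame(dataset$transitions)
  keep <- intersect(c("id", "energy_ev", "mu_x", "mu_y", "mu_z",
                      "p_x", "p_y", "p_z"), names(tr))
  write_csv_full <- function(df, p) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  }
  write_csv_full(tr[, keep], file.path(path, "transitions.csv"))
  bk <- intersect(c("band_id", "nu_lo_cm1", "nu_hi_cm1", "f_exp", "n_solvent",
                    "E_exp_cm1"), names(dataset$bands))
  write_csv_full(as.data.frame(dataset$bands)[, bk], file.path(path, "bands.csv"))
  if (length(dataset$spectra)) {
    dir.create(file.path(path, "spectra"), showWarnings = FALSE)
    for (nm in names(dataset$spectra)) {
      s <- dataset$spectra[[nm]]
      write_csv_full(data.frame(nu_cm1 = s$nu, epsilon = s$eps),
                     file.path(path, "spectra", paste0(nm, ".csv")))
    }
  }
  if (length(dataset$exclusions)) {
    writeLines(as.character(dataset$exclusions), file.path(path, "exclusions.txt"))
  }
  invisible(path)
}
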