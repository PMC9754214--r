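# On-disk formats: two CSV key-point files per sample (stalk + midrib),
# a trait table CSV, and a JSON curve export for visualization.
#
# Key-point file dialect (UTF-8 CSV, header required):
#   point_index,x_cm,y_cm,z_cm
# with optional '#' comment lines; '# sample_id=...' carries the id.

#' Construct a sample record
#'
#' @param sample_id Character id.
#' @param stalk m x 3 matrix of ordered stalk-node key points, bottom to top
#'   (m >= 2).
#' @param midrib n x 3 matrix of ordered midrib key points, base to tip
#'   (n >= 4).
#' @param metadata Optional named list.
#' @return An object of class `"midrib_sample"`.
#' @export
midrib_sample <- function(sample_id, stalk, midrib, metadata = list()) {
  stalk <- .as_points(stalk)
  midrib <- .as_points(midrib)
  if (nrow(stalk) < 2) stop("midrib_sample: need at least 2 stalk points")
  if (nrow(midrib) < 4) stop("midrib_sample: too few midrib points (need >= 4)")
  structure(list(sample_id = as.character(sample_id), stalk = stalk,
                 midrib = midrib, metadata = metadata),
            class = "midrib_sample")
}

#' @export
print.midrib_sample <- function(x, ...) {
  cat("Midrib sample '", x$sample_id, "': ", nrow(x$stalk), " stalk nodes, ",
      nrow(x$midrib), " midrib key points\n", sep = "")
  invisible(x)
}

.read_keypoint_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  comments <- raw[startsWith(trimws(raw), "#")]
  body <- raw[!startsWith(trimws(raw), "#")]
  sample_id <- NA_character_
  for (cl in comments) {
    m <- regmatches(cl, regexec("#\\s*sample_id\\s*=\\s*(\\S+)", cl))[[1]]
    if (length(m) == 2) sample_id <- m[2]
  }
  if (length(body) < 2) stop("malformed key-point file (no data rows): ", path)
  header <- strsplit(trimws(body[1]), ",")[[1]]
  expect <- c("point_index", "x_cm", "y_cm", "z_cm")
  if (!identical(trimws(header), expect)) {
    stop("malformed header in ", path, " (expected ",
         paste(expect, collapse = ","), ")")
  }
  rows <- strsplit(body[-1], ",")
  n <- length(rows)
  pts <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    f <- trimws(rows[[i]])
    if (length(f) != 4) {
      stop("malformed row ", i, " in ", path, ": wrong column count")
    }
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(v))) stop("malformed row ", i, " in ", path, ": non-numeric value")
    pts[i, ] <- v
  }
  list(points = pts, sample_id = sample_id)
}

#' Read one sample from a stalk and a midrib key-point file
#'
#' @param stalk_path,midrib_path Paths to the two CSV key-point files.
#' @return A `midrib_sample`; points in file (acquisition) order, units cm.
#'   The sample id comes from a `# sample_id=` header comment when present,
#'   otherwise from the file-name stem (dropping a `.stalk`/`.midrib`
#'   suffix).
#' @export
read_sample <- function(stalk_path, midrib_path) {
  st <- .read_keypoint_file(stalk_path)
  md <- .read_keypoint_file(midrib_path)
  if (nrow(st$points) < 2) stop("too few stalk points in ", stalk_path)
  if (nrow(md$points) < 4) stop("too few midrib points in ", midrib_path)
  id <- if (!is.na(st$sample_id)) st$sample_id else if (!is.na(md$sample_id)) {
    md$sample_id
  } else {
    sub("\\.(stalk|midrib)$", "", tools::file_path_sans_ext(basename(stalk_path)))
  }
  midrib_sample(id, st$points, md$points)
}

.write_keypoint_file <- function(points, path, sample_id) {
  p <- .as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s", sample_id), con)
  writeLines("point_index,x_cm,y_cm,z_cm", con)
  writeLines(sprintf("%d,%.6f,%.6f,%.6f", seq_len(nrow(p)), p[, 1], p[, 2], p[, 3]), con)
  invisible(path)
}

#' Write a sample as a pair of key-point files
#'
#' Coordinates are written with 6 decimal places; read/write round trips are
#' lossless at that precision.
#'
#' @param sample A `midrib_sample`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths (`<id>.stalk.csv`, `<id>.midrib.csv`).
#' @export
write_sample <- function(sample, dir) {
  stopifnot(inherits(sample, "midrib_sample"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, paste0(sample$sample_id, ".stalk.csv"))
  mp <- file.path(dir, paste0(sample$sample_id, ".midrib.csv"))
  .write_keypoint_file(sample$stalk, sp, sample$sample_id)
  .write_keypoint_file(sample$midrib, mp, sample$sample_id)
  invisible(c(stalk = sp, midrib = mp))
}

#' Column order of the trait table
#' @return Character vector of trait-table column names.
#' @export
trait_columns <- function() {
  c("sample_id", trait_names(), "base_type", "deflected", "valid",
    "n_iterations", "converged")
}

#' Write a trait table CSV
#'
#' One row per sample in a fixed column order, sorted by `sample_id`;
#' missing values are rendered as `NA`, logicals as `true`/`false`.
#'
#' @param rows A data.frame with the columns of [trait_columns()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_traits <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("write_traits: 'rows' must be a non-empty data.frame")
  }
  cols <- trait_columns()
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    stop("write_traits: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- rows[order(rows$sample_id), cols, drop = FALSE]
  fmt_num <- function(v) ifelse(is.na(v), "NA", sprintf("%.6f", v))
  fmt_bool <- function(v) ifelse(is.na(v), "NA", ifelse(v, "true", "false"))
  out <- data.frame(sample_id = df$sample_id, stringsAsFactors = FALSE)
  for (nm in trait_names()) out[[nm]] <- fmt_num(df[[nm]])
  out$base_type <- ifelse(is.na(df$base_type), "", as.character(df$base_type))
  out$deflected <- fmt_bool(df$deflected)
  out$valid <- fmt_bool(df$valid)
  out$n_iterations <- ifelse(is.na(df$n_iterations), "NA",
                             as.character(df$n_iterations))
  out$converged <- fmt_bool(df$converged)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read a trait table CSV written by [write_traits()]
#'
#' @param path Path to the CSV.
#' @return A data.frame with numeric trait columns and logical flags.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  for (nm in trait_names()) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("deflected", "valid", "converged")) {
    df[[nm]] <- ifelse(is.na(df[[nm]]), NA, df[[nm]] == "true")
  }
  df$base_type[!is.na(df$base_type) & df$base_type == ""] <- NA_character_
  df
}

#' Export a processed curve as JSON
#'
#' Writes raw key points, corrected key points, the dense smoothed nodes
#' with per-node curvature and arc length, and the iteration report, for
#' downstream visualization. The structure is described by the schema
#' shipped at `system.file("extdata", "curve-export-schema.json",
#' package = "midribr")`.
#'
#' @param sample_id Character id.
#' @param raw Raw midrib key points (n x 3).
#' @param corrected Corrected key points (n' x 3).
#' @param dense_curve A `midrib_curve`.
#' @param report The smoothing report list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve_json <- function(sample_id, raw, corrected, dense_curve, report, path) {
  if (!inherits(dense_curve, "midrib_curve") || nrow(dense_curve$points) == 0) {
    stop("write_curve_json: invalid or empty dense curve")
  }
  expected <- dense_curve$n_key + (dense_curve$n_key - 1L) * dense_curve$c
  stopifnot(nrow(dense_curve$points) == expected)
  obj <- list(
    sample_id = sample_id,
    raw_points = unname(.as_points(raw)),
    corrected_key_points = unname(.as_points(corrected)),
    dense_nodes = unname(dense_curve$points),
    curvature = dense_curve$curvature,
    arclength = dense_curve$arclength,
    n_key = dense_curve$n_key,
    c = dense_curve$c,
    report = list(
      n_iterations = report$n_iterations,
      converged = report$converged,
      flagged_per_iteration = as.integer(report$flagged_per_iteration),
      max_curvature_final = report$max_curvature_final
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and structurally validate a curve-export JSON
#'
#' @param path Path written by [write_curve_json()].
#' @return The parsed list; errors if required fields are missing or
#'   inconsistent.
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sample_id", "raw_points", "corrected_key_points", "dense_nodes",
            "curvature", "arclength", "n_key", "c", "report")
  missing_f <- setdiff(need, names(obj))
  if (length(missing_f)) {
    stop("curve JSON missing field(s): ", paste(missing_f, collapse = ", "))
  }
  if (nrow(obj$dense_nodes) != obj$n_key + (obj$n_key - 1) * obj$c) {
    stop("curve JSON dense node count inconsistent with n_key and c")
  }
  if (length(obj$curvature) != nrow(obj$dense_nodes)) {
    stop("curve JSON curvature length mismatch")
  }
  obj
}
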